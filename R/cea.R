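#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`: the monetary value of a strategy's health
#' gain at a willingness-to-pay threshold, net of its cost. Vectorised.
#'
#' @param cost Discounted lifetime cost, USD.
#' @param qaly Discounted QALYs.
#' @param wtp Willingness to pay, USD per QALY (>= 0).
#' @return Numeric NMB in USD.
#' @export
#' @examples
#' nmb(35234, 6.95, 1e5)
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) rlang::abort("`wtp` must be non-negative.")
  wtp * qaly - cost
}

#' Dominance classification and efficiency frontier
#'
#' Classifies each strategy as strictly dominated (another strategy costs
#' no more and yields no fewer QALYs, with at least one strict inequality),
#' extendedly dominated (removed from the cost-sorted frontier because the
#' incremental cost-effectiveness ratio to it exceeds the ICER past it), or
#' on the efficiency frontier. ICERs are reported between consecutive
#' frontier members, in increasing order. Strategies with identical
#' (cost, QALY) pairs are resolved toward the first in `order`; the tie is
#' recorded in the result.
#'
#' @param outcomes A data frame with columns `strategy`, `cost`, `qaly`
#'   (e.g. [run_all()] output), at least two rows.
#' @param wtp Willingness to pay used for the NMB column; defaults to the
#'   settings attached to `outcomes`, else USD 100,000.
#' @param order Character vector fixing the strategy tie-break order;
#'   defaults to the row order of `outcomes`.
#' @return An object of class `cea_result`: list with `strategies` (tibble
#'   `strategy`, `cost`, `qaly`, `nmb`, `dominance`), `frontier` (tibble
#'   `strategy`, `cost`, `qaly`, `icer` vs the previous frontier member),
#'   `wtp`, and `ties` (character, possibly empty).
#' @export
#' @examples
#' out <- run_all(base_case_config(), generate_lifetable())
#' classify_dominance(out)
classify_dominance <- function(outcomes, wtp = NULL, order = NULL) {
  df <- tibble::as_tibble(outcomes[, c("strategy", "cost", "qaly")])
  if (nrow(df) < 2L) rlang::abort("need at least two strategies.")
  if (is.null(wtp)) {
    s <- attr(outcomes, "settings")
    wtp <- if (!is.null(s)) s$wtp else 1e5
  }
  if (is.null(order)) order <- df$strategy
  df$.ord <- match(df$strategy, order)

  n <- nrow(df)
  dominated <- logical(n)
  ties <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i]) {
        if (df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i]) {
          dominated[i] <- TRUE
        } else if (df$.ord[j] < df$.ord[i]) {
          # identical pair: keep the first in configured order
          dominated[i] <- TRUE
          ties <- c(ties, sprintf("%s == %s, kept %s",
                                  df$strategy[i], df$strategy[j], df$strategy[j]))
        }
      }
    }
  }

  # frontier: cost-increasing among non-dominated, then strip extended
  # dominance so ICERs are strictly increasing
  cand <- df[!dominated, ]
  cand <- cand[base::order(cand$cost, -cand$qaly, cand$.ord), ]
  ext <- character(0)
  repeat {
    k <- nrow(cand)
    if (k < 3L) break
    icers <- diff(cand$cost) / diff(cand$qaly)
    drop <- which(diff(icers) <= 0)  # ICER past the point not above ICER to it
    if (!length(drop)) break
    ext <- c(ext, cand$strategy[drop[1] + 1L])
    cand <- cand[-(drop[1] + 1L), ]
  }

  icer <- rep(NA_real_, nrow(cand))
  if (nrow(cand) > 1L) {
    icer[-1L] <- diff(cand$cost) / diff(cand$qaly)
  }
  frontier <- tibble::tibble(strategy = cand$strategy, cost = cand$cost,
                             qaly = cand$qaly, icer = icer)

  dominance <- dplyr::case_when(
    dominated ~ "dominated",
    df$strategy %in% ext ~ "extendedly dominated",
    TRUE ~ "frontier"
  )
  strategies <- tibble::tibble(
    strategy = df$strategy, cost = df$cost, qaly = df$qaly,
    nmb = nmb(df$cost, df$qaly, wtp), dominance = dominance
  )
  structure(list(strategies = strategies, frontier = frontier,
                 wtp = wtp, ties = ties),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> WTP %s/QALY\n", format(x$wtp, big.mark = ",")))
  print(x$strategies)
  if (nrow(x$frontier) > 1L) {
    cat("frontier ICERs:\n")
    print(x$frontier)
  } else {
    cat(sprintf("frontier: %s alone\n", x$frontier$strategy))
  }
  invisible(x)
}

#' @export
tidy.cea_result <- function(x, ...) x$strategies

#' @export
glance.cea_result <- function(x, ...) {
  best <- x$strategies$strategy[which.max(x$strategies$nmb)]
  tibble::tibble(
    wtp = x$wtp,
    n_frontier = nrow(x$frontier),
    n_dominated = sum(x$strategies$dominance == "dominated"),
    best_nmb_strategy = best
  )
}

#' Export a CEA summary as JSON
#'
#' Writes the per-strategy costs, QALYs, NMB and dominance flags together
#' with the efficiency frontier and its ICERs.
#'
#' @param result A `cea_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cea_summary <- function(result, path) {
  stopifnot(inherits(result, "cea_result"))
  jsonlite::write_json(
    list(wtp = result$wtp, strategies = result$strategies,
         frontier = result$frontier, ties = result$ties),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
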