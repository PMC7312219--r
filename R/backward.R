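#' Greedy backward-elimination baseline
#'
#' Evaluates the full montage once, then repeatedly removes the channel
#' whose removal yields the highest-accuracy remaining subset, down to one
#' channel. Total evaluator calls are `C*(C+1)/2` (the full-set evaluation
#' plus `C + (C-1) + ... + 2` leave-one-out candidates): 253 calls for the
#' 22-channel montage. Accuracy ties at a level break by removing the
#' lowest-index channel.
#'
#' @param table A `feature_table`, or `NULL` when `evaluator` and `n_chan`
#'   are given.
#' @param evaluator Function `(subset) -> list(accuracy, ...)`; defaults to
#'   [make_evaluator()] on `table`.
#' @param n_chan Number of channels (defaults to the table's).
#' @param portfolio,k,seed Passed to [make_evaluator()] when needed.
#' @return data.frame elimination path, one row per subset size
#'   `C..1`: columns `no`, `acc`, `sensitivity`, `specificity`,
#'   `classifier`, `subset` (list column), plus attribute `n_calls`.
#' @export
backward_elimination <- function(table = NULL, evaluator = NULL,
                                 n_chan = NULL,
                                 portfolio = portfolio_spec(), k = 10,
                                 seed = 1) {
  if (is.null(evaluator)) {
    if (is.null(table)) stop("need a feature table or an evaluator",
                             call. = FALSE)
    evaluator <- make_evaluator(table, portfolio, k = k, seed = seed)
  }
  if (is.null(n_chan)) {
    n_chan <- if (!is.null(table)) n_channels(table)
              else attr(evaluator, "n_channels")
  }
  C <- assert_count(n_chan, "n_chan", min = 2L)
  n_calls <- 0L
  score_of <- function(subset) {
    n_calls <<- n_calls + 1L
    evaluator(subset)
  }
  as_row <- function(subset, score) {
    data.frame(no = length(subset), acc = score$accuracy,
               sensitivity = if (is.null(score$sensitivity)) NA_real_
                             else score$sensitivity,
               specificity = if (is.null(score$specificity)) NA_real_
                             else score$specificity,
               classifier = if (is.null(score$classifier_id)) NA_character_
                            else score$classifier_id,
               subset = I(list(subset)))
  }
  incumbent <- seq_len(C)
  path <- list(as_row(incumbent, score_of(incumbent)))
  while (length(incumbent) > 1L) {
    best_acc <- -Inf
    best_sub <- NULL
    best_score <- NULL
    for (drop_ch in incumbent) {        # ascending: ties remove lowest index
      cand <- setdiff(incumbent, drop_ch)
      sc <- score_of(cand)
      if (sc$accuracy > best_acc) {
        best_acc <- sc$accuracy
        best_sub <- cand
        best_score <- sc
      }
    }
    incumbent <- best_sub
    path[[length(path) + 1L]] <- as_row(incumbent, best_score)
  }
  out <- do.call(rbind, path)
  attr(out, "n_calls") <- n_calls
  out
}
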