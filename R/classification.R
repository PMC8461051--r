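# Maximum-likelihood mindset classification of play records: profile
# likelihood over a beta grid per candidate model, confusion matrix, and
# accuracy as a function of the player's log(beta).

#' Default beta grid for profile likelihood
#'
#' Log-spaced grid, `log(beta)` from -2.5 to 2.5 in steps of 0.125. Beta is
#' a nuisance parameter unknown at classification time; each model's
#' likelihood is maximized over this grid.
#'
#' @return numeric vector of beta values.
#' @export
default_beta_grid <- function() {
  exp(seq(-2.5, 2.5, by = 0.125))
}

#' Classify one play record by maximum likelihood
#'
#' For each candidate model, the record's log-likelihood (sum of log
#' softmax action probabilities, [record_log_likelihood()]) is maximized
#' over the beta grid; the predicted mindset is the model with the larger
#' maximized log-likelihood. Exact ties classify as fixed (deterministic
#' tie rule; ties are flagged in the output). If both likelihoods are
#' `-Inf` the record is unclassifiable and `predicted` is `NA`. With
#' `oracle_beta = TRUE` the record's own generating beta is used instead
#' of the grid (sensitivity-analysis mode).
#'
#' @param record a [play_record()].
#' @param q_fixed,q_malleable solved `q_table`s of the two models.
#' @param beta_grid nonempty numeric vector of candidate beta values.
#' @param oracle_beta evaluate at the record's generating beta instead of
#'   maximizing over the grid.
#' @return one-row data.frame: record identifiers, true mindset, beta,
#'   maximized log-likelihoods and maximizing betas per model, `predicted`,
#'   `correct`, `tie`.
#' @export
classify_record <- function(record, q_fixed, q_malleable,
                            beta_grid = default_beta_grid(),
                            oracle_beta = FALSE) {
  if (length(beta_grid) == 0L) stop("beta_grid must be nonempty")
  grid <- if (oracle_beta) record$beta else beta_grid
  ll_f <- record_loglik_grid(record, q_fixed, grid)
  ll_m <- record_loglik_grid(record, q_malleable, grid)
  best_f <- max(ll_f)
  best_m <- max(ll_m)
  tie <- is.finite(best_f) && best_f == best_m
  predicted <- if (!is.finite(best_f) && !is.finite(best_m)) {
    NA_character_
  } else if (best_f >= best_m) "fixed" else "malleable"
  data.frame(
    player_id = record$player_id, run_index = record$run_index,
    mindset = record$mindset, beta = record$beta,
    loglik_fixed = best_f, loglik_malleable = best_m,
    beta_hat_fixed = if (is.finite(best_f)) grid[which.max(ll_f)] else NA_real_,
    beta_hat_malleable = if (is.finite(best_m)) grid[which.max(ll_m)] else NA_real_,
    predicted = predicted,
    correct = !is.na(predicted) & predicted == record$mindset,
    tie = tie
  )
}

#' Classify a collection of play records
#'
#' @param records list of [play_record()]s (e.g. a cohort).
#' @inheritParams classify_record
#' @return data.frame with one [classify_record()] row per record.
#' @export
classify_records <- function(records, q_fixed, q_malleable,
                             beta_grid = default_beta_grid(),
                             oracle_beta = FALSE) {
  out <- do.call(rbind, lapply(records, classify_record,
                               q_fixed = q_fixed, q_malleable = q_malleable,
                               beta_grid = beta_grid,
                               oracle_beta = oracle_beta))
  rownames(out) <- NULL
  out
}

#' Row-normalized confusion matrix
#'
#' Rows are the generating mindset, columns the classified-as mindset;
#' each row sums to 1. Unclassifiable records (predicted `NA`) are
#' excluded.
#'
#' @param results a [classify_records()] data.frame.
#' @return 2x2 numeric matrix.
#' @export
confusion_matrix <- function(results) {
  res <- results[!is.na(results$predicted), ]
  lev <- c("fixed", "malleable")
  tab <- table(factor(res$mindset, lev), factor(res$predicted, lev))
  if (any(rowSums(tab) == 0)) {
    stop("need at least one classified record per generating mindset")
  }
  m <- unclass(tab / rowSums(tab))
  dimnames(m) <- list(generating = lev, classified_as = lev)
  m
}

#' Per-player classification accuracy by log(beta)
#'
#' Aggregates classification results to one row per simulated player: the
#' proportion of that player's records classified correctly, paired with
#' the player's log(beta). Sorted by log(beta).
#'
#' @param results a [classify_records()] data.frame.
#' @return data.frame with columns `player_id`, `mindset`, `log_beta`,
#'   `accuracy`, `n_records`.
#' @export
accuracy_by_beta <- function(results) {
  agg <- aggregate(correct ~ player_id + mindset + beta, data = results,
                   FUN = mean)
  n <- aggregate(correct ~ player_id + mindset + beta, data = results,
                 FUN = length)
  out <- data.frame(player_id = agg$player_id, mindset = agg$mindset,
                    log_beta = log(agg$beta), accuracy = agg$correct,
                    n_records = n$correct)
  out[order(out$log_beta), ]
}
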