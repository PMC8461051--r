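#' @importFrom Matrix sparseMatrix
#' @importFrom stats rlnorm runif var aggregate
NULL

#' Softmax (Boltzmann) action probabilities
#'
#' Converts a row of action values into choice probabilities
#' `p(a) = exp(beta * Q(a)) / sum_a' exp(beta * Q(a'))`, computed with a
#' max-shift for overflow safety. `beta = 0` gives the uniform distribution;
#' as `beta -> Inf` the distribution concentrates on the maximizing actions
#' (`beta = Inf` is accepted and returns the uniform distribution over
#' argmax actions).
#'
#' @param q_row named numeric vector of action values.
#' @param beta nonnegative inverse-temperature (decision-noise) parameter.
#' @return named numeric vector of probabilities summing to 1.
#' @export
#' @examples
#' softmax_action_probs(c(a = 1, b = 0), beta = 1) # ~ (0.731, 0.269)
softmax_action_probs <- function(q_row, beta) {
  if (length(q_row) == 0L) stop("empty action set")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("beta must be a single nonnegative number")
  }
  if (any(!is.finite(q_row))) stop("q_row must be finite")
  if (is.infinite(beta)) {
    p <- as.numeric(q_row == max(q_row))
  } else {
    p <- exp(beta * (q_row - max(q_row)))
  }
  p <- p / sum(p)
  names(p) <- names(q_row)
  p
}

#' Sample one action from a discrete distribution
#'
#' Draws from the session RNG stream, so results are reproducible after
#' `set.seed()`.
#'
#' @param dist named numeric vector of probabilities (nonnegative, summing
#'   to 1 within 1e-9).
#' @return the name of the sampled action.
#' @export
sample_action <- function(dist) {
  if (length(dist) == 0L || is.null(names(dist))) {
    stop("dist must be a named probability vector")
  }
  if (any(is.na(dist)) || any(dist < 0) || abs(sum(dist) - 1) > 1e-9) {
    stop("invalid distribution: probabilities must be nonnegative and sum to 1")
  }
  names(dist)[sample.int(length(dist), 1L, prob = dist)]
}

validate_transitions <- function(transitions, n_states) {
  req <- c("state", "action", "next_state", "prob", "reward")
  if (!all(req %in% names(transitions))) {
    stop("transitions must have columns: ", paste(req, collapse = ", "))
  }
  if (any(transitions$prob < 0)) stop("negative transition probability")
  ok_next <- is.na(transitions$next_state) |
    (transitions$next_state >= 1L & transitions$next_state <= n_states)
  if (!all(ok_next)) stop("next_state index out of range")
  key <- paste(transitions$state, transitions$action)
  sums <- rowsum(transitions$prob, key)
  bad <- abs(sums - 1) > 1e-9
  if (any(bad)) {
    stop("transition probabilities do not sum to 1 for (state, action): ",
         paste(utils::head(rownames(sums)[bad], 3L), collapse = "; "))
  }
  invisible(TRUE)
}

# Policy-weighted state values from a dense Q matrix (NA = unavailable).
# beta = Inf gives the greedy (max) backup; states with no available action
# (terminal states) have value 0.
state_values <- function(qmat, beta) {
  avail <- !is.na(qmat)
  has_action <- rowSums(avail) > 0L
  cols <- lapply(seq_len(ncol(qmat)), function(j) qmat[, j])
  rmax <- do.call(pmax, c(cols, list(na.rm = TRUE)))
  if (is.infinite(beta)) {
    v <- rmax
  } else {
    z <- exp(beta * (qmat - rmax))
    z[!avail] <- 0
    q0 <- qmat
    q0[!avail] <- 0
    v <- rowSums(z * q0) / rowSums(z)
  }
  v[!has_action] <- 0
  v
}

#' Solve a discrete MDP by softmax-consistent Q-value iteration
#'
#' Iterates the Q fixed point
#' `Q(s,a) = sum_s' p(s'|s,a) (r(s,a,s') + gamma * sum_a' p(a'|s') Q(s',a'))`
#' where the inner action distribution `p(a'|s')` is the softmax policy
#' `p(a|s) propto exp(beta * Q(s,a))`. With `beta = Inf` the inner term is
#' the greedy maximum and the iteration is standard value iteration.
#' Transitions into the terminal region (`next_state = NA`) contribute zero
#' future value; terminal states in the space (no outgoing rows) have
#' value 0.
#'
#' @param transitions data.frame with columns `state` (integer index),
#'   `action` (character), `next_state` (integer index or `NA` for an exit
#'   to the absorbing terminal), `prob`, `reward`. Probabilities must sum to
#'   1 over each available `(state, action)` pair.
#' @param n_states number of states in the space.
#' @param gamma discount factor in `[0, 1)`.
#' @param beta inverse-temperature used in the inner policy expectation;
#'   `Inf` (the default) gives standard value iteration.
#' @param tol sup-norm convergence tolerance (> 0).
#' @param max_iter maximum number of sweeps before declaring failure.
#' @param actions optional character vector fixing the action ordering.
#' @param check validate the transition table first (disable for repeated
#'   solves of an already validated model).
#' @return an object of class `q_table`: list with dense matrix `q`
#'   (`n_states` x actions, `NA` where an action is unavailable), `gamma`,
#'   `beta`, `iterations`, `residual`, `residuals` (per-sweep history),
#'   `converged`, `actions`, `n_states`.
#' @export
q_iteration <- function(transitions, n_states, gamma = 0.98, beta = Inf,
                        tol = 1e-6, max_iter = 10000L, actions = NULL,
                        check = TRUE) {
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1) {
    stop("gamma must be in [0, 1): discounted convergence is not guaranteed otherwise")
  }
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  if (is.na(beta) || beta < 0) stop("beta must be nonnegative")
  if (check) validate_transitions(transitions, n_states)

  acts <- if (is.null(actions)) sort(unique(transitions$action)) else actions
  ai <- match(transitions$action, acts)
  if (anyNA(ai)) stop("transition table uses actions not in `actions`")

  sa_key <- (ai - 1) * n_states + transitions$state
  sa_levels <- sort(unique(sa_key))
  sa_idx <- match(sa_key, sa_levels)
  n_sa <- length(sa_levels)

  r_sa <- as.vector(rowsum(transitions$prob * transitions$reward,
                           sa_idx, reorder = TRUE))
  keep <- !is.na(transitions$next_state) & transitions$prob > 0
  pmat <- Matrix::sparseMatrix(
    i = sa_idx[keep], j = as.integer(transitions$next_state[keep]),
    x = transitions$prob[keep], dims = c(n_sa, n_states)
  )

  qmat <- matrix(NA_real_, n_states, length(acts),
                 dimnames = list(NULL, acts))
  q_v <- rep(0, n_sa)
  residuals <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    qmat[sa_levels] <- q_v
    v <- state_values(qmat, beta)
    q_new <- r_sa + gamma * as.vector(pmat %*% v)
    resid <- max(abs(q_new - q_v))
    residuals <- c(residuals, resid)
    q_v <- q_new
    iterations <- it
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(errorCondition(
      sprintf("q_iteration did not converge in %d iterations (last residual %.3g)",
              max_iter, residuals[length(residuals)]),
      residual = residuals[length(residuals)],
      class = c("mdp_no_convergence", "error", "condition")
    ))
  }
  qmat[sa_levels] <- q_v
  structure(
    list(q = qmat, gamma = gamma, beta = beta, iterations = iterations,
         residual = residuals[length(residuals)], residuals = residuals,
         converged = TRUE, actions = acts, n_states = n_states),
    class = "q_table"
  )
}

#' @export
print.q_table <- function(x, ...) {
  cat(sprintf("<q_table> %d states x %d actions; gamma = %g, beta = %s; %d iterations (residual %.2g)\n",
              x$n_states, length(x$actions), x$gamma,
              format(x$beta), x$iterations, x$residual))
  invisible(x)
}

#' Write a solved Q table as a flat CSV
#'
#' One row per available (state index, action) pair with its value.
#'
#' @param q a [q_iteration()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_q_table <- function(q, path) {
  idx <- which(!is.na(q$q), arr.ind = TRUE)
  flat <- data.frame(
    state = idx[, 1L],
    action = q$actions[idx[, 2L]],
    value = q$q[idx]
  )
  flat <- flat[order(flat$state, match(flat$action, q$actions)), ]
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Log-likelihood of a play record's actions under a solved model
#'
#' Sums, over the record's steps, the log softmax probability of the
#' recorded action given the recorded state: only action probabilities
#' enter; state-transition probabilities do not. Probabilities are
#' restricted and renormalized to the actions available in each recorded
#' state. An action unavailable under the evaluating model yields
#' `-Inf` (with a diagnostic attribute via [classify_record()]).
#'
#' @param record a [play_record()].
#' @param q a solved `q_table` for the evaluating model.
#' @param beta the inverse-temperature at which to evaluate the policy.
#' @return the summed log-likelihood (0 for an empty record).
#' @export
record_log_likelihood <- function(record, q, beta) {
  as.numeric(record_loglik_grid(record, q, beta))
}

#' Record log-likelihood over a grid of beta values
#'
#' Vectorized form of [record_log_likelihood()]: one value per element of
#' `betas`.
#'
#' @inheritParams record_log_likelihood
#' @param betas numeric vector of nonnegative beta values.
#' @return numeric vector, `length(betas)` log-likelihoods.
#' @export
record_loglik_grid <- function(record, q, betas) {
  if (any(is.na(betas)) || any(betas < 0)) stop("betas must be nonnegative")
  steps <- record$steps
  total <- rep(0, length(betas))
  if (is.null(steps) || nrow(steps) == 0L) return(total)
  for (i in seq_len(nrow(steps))) {
    row <- q$q[steps$state_before[i], ]
    av <- which(!is.na(row))
    a <- match(steps$action[i], q$actions)
    if (is.na(a) || !(a %in% av)) {
      total <- rep(-Inf, length(betas))
      attr(total, "unavailable_step") <- i
      return(total)
    }
    qa <- row[av]
    m <- max(qa)
    lse <- betas * m + log(exp(outer(betas, qa - m)) %*% rep(1, length(qa)))
    total <- total + (betas * row[a] - as.vector(lse))
  }
  total
}
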