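# Cohort generation: lognormal decision-noise draws, paired fixed/malleable
# players sharing each draw, and seeded, independently re-simulable play
# records.

#' Draw decision-noise parameters
#'
#' One lognormal(meanlog = 0, sdlog = 1) draw per player, from the session
#' RNG. The median of the distribution is 1 (a moderately noisy decision
#' maker); small values approach uniform-random play, large values
#' near-optimal play.
#'
#' @param n number of draws (>= 1).
#' @return numeric vector of positive beta values.
#' @export
draw_betas <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  stats::rlnorm(n, meanlog = 0, sdlog = 1)
}

#' Derive a per-record seed from a master seed
#'
#' Deterministic integer mixing (a repeated multiplicative-congruential
#' step modulo 2^31 - 1) of the master seed with index components, so any
#' single record is re-simulable in isolation.
#'
#' @param ... integer components (master seed, mindset index, player index,
#'   run index).
#' @return a single integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(...) {
  comps <- c(...)
  x <- 11
  for (k in comps) {
    x <- (x * 69069 + (as.double(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(x) + 1L
}

#' Construct a play record
#'
#' @param player_id player identifier.
#' @param mindset `"fixed"` or `"malleable"`.
#' @param beta the player's decision-noise parameter.
#' @param run_index 1-based run number within the player.
#' @param seed the RNG seed the record was (or can be) simulated from.
#' @param steps data.frame with columns `step`, `state_before`,
#'   `action`, `feedback`, `state_after` (states as integer indices into
#'   [water_state_space()]).
#' @param end_reason `"STOP"` (the player stopped) or `"cap"` (episode hit
#'   the step cap).
#' @return an object of class `play_record`.
#' @export
play_record <- function(player_id, mindset, beta, run_index, seed, steps,
                        end_reason) {
  stopifnot(end_reason %in% c("STOP", "cap"))
  structure(
    list(player_id = player_id, mindset = mindset, beta = beta,
         run_index = as.integer(run_index), seed = as.integer(seed),
         steps = steps, end_reason = end_reason),
    class = "play_record"
  )
}

#' @export
print.play_record <- function(x, ...) {
  cat(sprintf("<play_record> %s run %d (beta %.3g, seed %d): %d steps, end = %s\n",
              x$player_id, x$run_index, x$beta, x$seed,
              nrow(x$steps), x$end_reason))
  invisible(x)
}

#' Simulate one play record
#'
#' Runs one episode: from the profile's initial state, repeatedly draws an
#' action from the softmax policy over the actions available in the current
#' state (at the player's `beta`), applies [real_world_step()], and appends
#' the step. Play halts when STOP is drawn or after `env$max_steps` actions
#' (`end_reason = "cap"`). The record is fully reproducible from
#' `(profile, q, beta, env, seed)`.
#'
#' @param profile a [mindset_profile()].
#' @param q the profile's solved `q_table`.
#' @param beta the player's decision-noise parameter.
#' @param env an [environment_config()].
#' @param seed integer seed for this record.
#' @param player_id,run_index metadata stored in the record.
#' @return a [play_record()].
#' @export
simulate_record <- function(profile, q, beta, env = environment_config(),
                            seed = 1L, player_id = profile$label,
                            run_index = 1L) {
  if (!inherits(q, "q_table")) stop("q must be a solved q_table")
  set.seed(seed)
  space <- water_state_space()
  s <- initial_state(profile)
  n_max <- env$max_steps
  state_before <- integer(n_max)
  action <- character(n_max)
  feedback <- character(n_max)
  state_after <- integer(n_max)
  end_reason <- "cap"
  t <- 0L
  while (t < n_max) {
    t <- t + 1L
    i <- encode_state(space, s)
    av <- available_actions(s)
    probs <- softmax_action_probs(q$q[i, av], beta)
    a <- sample_action(probs)
    out <- real_world_step(s, a, profile, env)
    state_before[t] <- i
    action[t] <- a
    feedback[t] <- out$feedback$valence
    state_after[t] <- encode_state(space, out$state)
    s <- out$state
    if (a == "STOP") {
      end_reason <- "STOP"
      break
    }
  }
  keep <- seq_len(t)
  play_record(
    player_id = player_id, mindset = profile$label, beta = beta,
    run_index = run_index, seed = seed,
    steps = data.frame(step = keep, state_before = state_before[keep],
                       action = action[keep], feedback = feedback[keep],
                       state_after = state_after[keep]),
    end_reason = end_reason
  )
}

#' Re-simulate a record from its stored seed
#'
#' Determinism check: reruns [simulate_record()] with the record's own
#' metadata and the given profile/Q/environment.
#'
#' @param record a [play_record()].
#' @param q the solved `q_table` for the record's mindset.
#' @param env the environment the record was simulated under.
#' @return a [play_record()] that should be identical to `record`.
#' @export
replay_record <- function(record, q, env = environment_config()) {
  simulate_record(mindset_profile(record$mindset), q, record$beta, env,
                  seed = record$seed, player_id = record$player_id,
                  run_index = record$run_index)
}

#' Simulation settings for a cohort
#'
#' Defaults are the package's scaled study conditions (50 players per
#' mindset, 20 runs each); `full_scale = TRUE` selects the full design of
#' 500 paired players with 100 records each.
#'
#' @param n_players_per_mindset players per mindset; each draws one beta
#'   shared by its fixed/malleable pair.
#' @param runs_per_player independent play records per player.
#' @param master_seed integer master seed; all per-record seeds derive from
#'   it via [derive_seed()].
#' @param env an [environment_config()].
#' @param gamma discount factor used when solving the profiles' MDPs.
#' @param solve_beta inverse-temperature for the Q solve (`Inf` = standard
#'   value iteration; beta is decision noise at sampling time only).
#' @param full_scale use the full 500 x 100 design.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_players_per_mindset = 50L,
                              runs_per_player = 20L,
                              master_seed = 1L,
                              env = environment_config(),
                              gamma = 0.98,
                              solve_beta = Inf,
                              full_scale = FALSE) {
  if (full_scale) {
    n_players_per_mindset <- 500L
    runs_per_player <- 100L
  }
  if (n_players_per_mindset < 1L || runs_per_player < 1L) {
    stop("counts must be >= 1")
  }
  structure(
    list(n_players_per_mindset = as.integer(n_players_per_mindset),
         runs_per_player = as.integer(runs_per_player),
         master_seed = as.integer(master_seed),
         env = env, gamma = gamma, solve_beta = solve_beta),
    class = "simulation_config"
  )
}

#' Simulate a paired fixed/malleable cohort
#'
#' Draws `n_players_per_mindset` beta values (lognormal(0, 1), seeded from
#' the master seed), creates one fixed and one malleable player per beta
#' (the paired design), and simulates `runs_per_player` records per player
#' with per-record seeds derived deterministically from the master seed.
#'
#' @param config a [simulation_config()].
#' @param q_fixed,q_malleable solved `q_table`s for the two profiles; if
#'   `NULL` they are solved here (a few seconds of startup).
#' @param progress print a line per player.
#' @return an object of class `play_cohort`: a list of [play_record()]s
#'   with the config and the beta draws attached as attributes.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            q_fixed = NULL, q_malleable = NULL,
                            progress = FALSE) {
  profiles <- list(fixed = mindset_profile("fixed"),
                   malleable = mindset_profile("malleable"))
  qs <- list(fixed = q_fixed, malleable = q_malleable)
  for (m in names(qs)) {
    if (is.null(qs[[m]])) {
      qs[[m]] <- solve_mindset_mdp(profiles[[m]], config$env,
                                   gamma = config$gamma,
                                   beta = config$solve_beta)
    }
  }
  set.seed(derive_seed(config$master_seed, 0L))
  betas <- draw_betas(config$n_players_per_mindset)

  records <- vector("list",
                    2L * config$n_players_per_mindset * config$runs_per_player)
  k <- 0L
  for (i in seq_len(config$n_players_per_mindset)) {
    for (mi in 1:2) {
      m <- names(profiles)[mi]
      pid <- sprintf("%s_%03d", m, i)
      for (r in seq_len(config$runs_per_player)) {
        k <- k + 1L
        records[[k]] <- simulate_record(
          profiles[[m]], qs[[m]], betas[i], config$env,
          seed = derive_seed(config$master_seed, mi, i, r),
          player_id = pid, run_index = r
        )
      }
    }
    if (progress) {
      message(sprintf("player %d/%d done", i, config$n_players_per_mindset))
    }
  }
  structure(records, class = "play_cohort", config = config, betas = betas)
}

#' @export
print.play_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<play_cohort> %d records (%d players/mindset x %d runs, master seed %d)\n",
              length(x), cfg$n_players_per_mindset, cfg$runs_per_player,
              cfg$master_seed))
  invisible(x)
}
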