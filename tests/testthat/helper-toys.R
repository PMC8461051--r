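# Toy environments and independent oracles used across the suite.

# Two-state chain: s1 -a-> s2 (r = 0), s2 -b-> terminal (r = 5).
toy_chain <- function() {
  data.frame(state = c(1L, 2L), action = c("a", "b"),
             next_state = c(2L, NA), prob = 1, reward = c(0, 5))
}

# Random acyclic layered toy: `layers` layers of `width` states, every
# state has 2 actions, each action a 2-outcome lottery over next-layer
# states (or terminal from the last layer), rewards in [-1, 1].
random_acyclic_toy <- function(layers = 3L, width = 2L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  idx <- function(l, w) (l - 1L) * width + w
  for (l in seq_len(layers)) {
    for (w in seq_len(width)) {
      for (a in c("a", "b")) {
        p <- runif(1, 0.2, 0.8)
        if (l < layers) {
          nxt <- sample.int(width, 2L, replace = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            state = idx(l, w), action = a,
            next_state = c(idx(l + 1L, nxt[1L]), idx(l + 1L, nxt[2L])),
            prob = c(p, 1 - p), reward = runif(2, -1, 1)
          )
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            state = idx(l, w), action = a, next_state = NA_integer_,
            prob = 1, reward = runif(1, -1, 1)
          )
        }
      }
    }
  }
  list(trans = do.call(rbind, rows), n_states = layers * width)
}

# Independent oracle: recursive backward evaluation of the softmax-
# consistent Q fixed point by exhaustive expansion over action sequences.
# Valid for acyclic environments; shares no code with q_iteration().
oracle_q_fun <- function(trans, gamma, beta) {
  oracle_v <- function(s) {
    acts <- unique(trans$action[trans$state == s])
    if (length(acts) == 0L) return(0)
    q <- vapply(acts, function(a) oracle_q(s, a), numeric(1))
    if (is.infinite(beta)) return(max(q))
    w <- exp(beta * (q - max(q)))
    sum(w / sum(w) * q)
  }
  oracle_q <- function(s, a) {
    rows <- trans[trans$state == s & trans$action == a, ]
    total <- 0
    for (i in seq_len(nrow(rows))) {
      v_next <- if (is.na(rows$next_state[i])) 0 else oracle_v(rows$next_state[i])
      total <- total + rows$prob[i] * (rows$reward[i] + gamma * v_next)
    }
    total
  }
  list(q = oracle_q, v = oracle_v)
}

# A toy record over the water task, built by forcing a scripted action
# sequence through the real environment under a fixed seed.
scripted_record <- function(actions, profile = mindset_profile("malleable"),
                            env = environment_config(), seed = 1L,
                            player_id = "scripted") {
  set.seed(seed)
  space <- water_state_space()
  s <- initial_state(profile)
  steps <- vector("list", length(actions))
  for (i in seq_along(actions)) {
    out <- real_world_step(s, actions[i], profile, env)
    steps[[i]] <- data.frame(
      step = i, state_before = encode_state(space, s), action = actions[i],
      feedback = out$feedback$valence,
      state_after = encode_state(space, out$state)
    )
    s <- out$state
  }
  play_record(player_id, profile$label, beta = 1, run_index = 1L,
              seed = seed, steps = do.call(rbind, steps),
              end_reason = if (actions[length(actions)] == "STOP") "STOP" else "cap")
}

# Shared expensive fixtures: the two solved water-task models and the
# scaled study cohort (50 players per mindset x 20 runs, master seed 42),
# computed once per test run.
water_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      qf <- solve_mindset_mdp(mindset_profile("fixed"))
      qm <- solve_mindset_mdp(mindset_profile("malleable"))
      cfg <- simulation_config(master_seed = 42L)
      cohort <- simulate_cohort(cfg, qf, qm)
      cache <<- list(q_fixed = qf, q_malleable = qm, config = cfg,
                     cohort = cohort)
    }
    cache
  }
})
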