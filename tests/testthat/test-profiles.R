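test_that("profile constants encode the two mindsets", {
  fx <- mindset_profile("fixed")
  ml <- mindset_profile("malleable")
  expect_equal(fx$initial_beliefs, c(old = 2L, mid = 1L, young = -2L))
  expect_equal(ml$initial_beliefs, c(old = 0L, mid = 0L, young = 0L))
  expect_equal(unname(fx$belief_bands), c(0.5, 1.5, 3.5))
  expect_equal(unname(ml$belief_bands), c(1, 3, 6))
  expect_equal(fx$time_cost, -0.75)
  expect_equal(ml$time_cost, -0.5)
  expect_equal(fx$water_reward, 5)
  expect_equal(ml$water_reward, 5)
})

test_that("belief strength is the summed absolute belief", {
  expect_equal(belief_strength(c(0, 0, 0)), 0L)
  expect_equal(belief_strength(c(2, 1, -2)), 5L)
  expect_equal(belief_strength(unname(correct_beliefs())), 6L)
  expect_error(belief_strength(c(3, 0, 0)), "\\[-2, 2\\]")
})

test_that("terminal reward combines the water and the matching belief band", {
  fx <- mindset_profile("fixed")
  ml <- mindset_profile("malleable")
  expect_equal(terminal_reward(fx, initial_state(fx)), 1.5)
  expect_equal(terminal_reward(ml, initial_state(ml)), 0)
  done <- water_state(old = 2, mid = -2, young = 2, got_water = 1)
  expect_equal(terminal_reward(ml, done), 11)
  expect_equal(terminal_reward(fx, done), 8.5)
  # band edges: strength 1, 2 -> bit; 3, 5 -> moderate; 6 -> strong
  expect_equal(terminal_reward(ml, water_state(old = 1)), 1)
  expect_equal(terminal_reward(ml, water_state(old = 2, mid = 1)), 3)
  expect_equal(terminal_reward(ml, water_state(old = 2, mid = 2, young = 1)), 3)
})

test_that("terminal reward is monotone in belief strength for both profiles", {
  for (p in list(mindset_profile("fixed"), mindset_profile("malleable"))) {
    vals <- vapply(0:2, function(y) {
      terminal_reward(p, water_state(old = 2, mid = -2, young = y))
    }, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("subjective expectations follow each mindset's learning rule", {
  fx <- mindset_profile("fixed")
  ml <- mindset_profile("malleable")
  env <- environment_config()

  # fixed, certain belief: formal greet to OLD expected to please, no change
  s <- water_state(old = 2, mid = 1, young = -2, in_conv = 1, npc_age = 3)
  d <- subjective_transition(fx, s, "GREET_FORMAL", env)
  expect_equal(nrow(d), 1L)
  expect_equal(d$prob, 1)
  expect_equal(d$npc_happy, 1L)
  expect_equal(d$old, 2L)

  # malleable, uncertain: 50/50 pleased, belief expected to move +-1 at
  # the updating propensity 0.95
  s0 <- water_state(in_conv = 1, npc_age = 1)
  d0 <- subjective_transition(ml, s0, "GREET_FORMAL", env)
  expect_equal(sum(d0$prob), 1, tolerance = 1e-12)
  expect_equal(sum(d0$prob[d0$npc_happy == 1L]), 0.5, tolerance = 1e-12)
  expect_equal(sum(d0$prob[d0$young == 1L]), 0.5 * 0.95, tolerance = 1e-12)
  expect_equal(sum(d0$prob[d0$young == -1L]), 0.5 * 0.95, tolerance = 1e-12)
  expect_equal(sum(d0$prob[d0$young == 0L]), 0.05, tolerance = 1e-12)

  # malleable at |b| = 1 expects confirmation only: no unlearning branch
  s1 <- water_state(young = 1, in_conv = 1, npc_age = 1, greeted = 1,
                    got_water = 1)
  d1 <- subjective_transition(ml, s1, "ASK_FORMAL", env)
  expect_true(all(d1$young %in% c(1L, 2L)))
  expect_equal(sum(d1$prob[d1$young == 2L]), 0.75 * 0.6, tolerance = 1e-12)

  # LEAVE is a deterministic reset for any profile
  dl <- subjective_transition(fx, s1, "LEAVE", env)
  expect_equal(nrow(dl), 1L)
  expect_equal(dl$in_conv, 0L)
  expect_equal(dl$npc_age, 0L)
  expect_error(subjective_transition(fx, s0, "ASK_FORMAL", env),
               "not available")
})

test_that("fixed points of the subjective models match the mindset rules", {
  fx <- mindset_profile("fixed")
  ml <- mindset_profile("malleable")
  for (b in c(-2L, -1L, 1L, 2L)) {
    for (d in c(-1L, 1L)) {
      expect_equal(fx$subjective_update_prob(b, d), 0)
    }
  }
  expect_gt(fx$subjective_update_prob(0L, 1L), 0)
  for (d in c(-1L, 1L)) {
    expect_equal(ml$subjective_update_prob(2L, d), 0)
    expect_equal(ml$subjective_update_prob(-2L, d), 0)
  }
  expect_gt(ml$subjective_update_prob(1L, 1L), 0)
  expect_gt(ml$subjective_update_prob(-1L, -1L), 0)
})

test_that("the assembled cognitive MDP is a proper distribution over the space", {
  ml <- mindset_profile("malleable")
  mdp <- build_cognitive_mdp(ml)
  expect_silent(mindsetmdp:::validate_transitions(mdp$transitions,
                                                 mdp$space$n_states))
  # rewards: time cost everywhere, terminal reward added on STOP
  tr <- mdp$transitions
  stopr <- tr[tr$action == "STOP", ]
  sp <- mdp$space
  st <- decode_state(sp, stopr$state)
  expected <- ml$time_cost +
    vapply(seq_len(nrow(st)), function(i) terminal_reward(ml, st[i, ]),
           numeric(1))
  expect_equal(stopr$reward, expected, tolerance = 1e-12)
  expect_true(all(tr$reward[tr$action != "STOP"] == ml$time_cost))
})

test_that("the vectorized MDP builder agrees with the scalar subjective model", {
  env <- environment_config()
  sp <- water_state_space()
  set.seed(5)
  for (profile in list(mindset_profile("fixed"), mindset_profile("malleable"))) {
    mdp <- build_cognitive_mdp(profile, env)
    tr <- mdp$transitions
    for (rep in 1:40) {
      i <- sample.int(sp$n_states, 1)
      s <- decode_state(sp, i)[1, ]
      a <- sample(available_actions(s), 1)
      rows <- tr[tr$state == i & tr$action == a, ]
      d <- subjective_transition(profile, s, a, env)
      if (a == "STOP") {
        expect_true(all(is.na(rows$next_state)))
        expect_equal(sum(rows$prob), 1)
        next
      }
      want <- encode_state(sp, d[, sp$vars$name])
      got <- stats::aggregate(prob ~ next_state, rows, sum)
      agg <- stats::aggregate(d$prob, list(next_state = want), sum)
      agg <- agg[order(agg$next_state), ]
      got <- got[order(got$next_state), ]
      expect_equal(got$next_state, agg$next_state)
      expect_equal(got$prob, agg$x, tolerance = 1e-12)
    }
  }
})

test_that("fixed and malleable situation dynamics differ only through beliefs and rewards", {
  env <- environment_config()
  fxm <- build_cognitive_mdp(mindset_profile("fixed"), env)$transitions
  mlm <- build_cognitive_mdp(mindset_profile("malleable"), env)$transitions
  nav <- c("SELECT_NPC_YOUNG", "SELECT_NPC_MID", "SELECT_NPC_OLD", "LEAVE")
  a <- fxm[fxm$action %in% nav, c("state", "action", "next_state", "prob")]
  b <- mlm[mlm$action %in% nav, c("state", "action", "next_state", "prob")]
  a <- a[order(a$state, a$action, a$next_state), ]
  b <- b[order(b$state, b$action, b$next_state), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})
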