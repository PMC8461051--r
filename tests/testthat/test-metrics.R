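make_record_with_beliefs <- function(profile, final_beliefs, got_water = 0L) {
  sp <- water_state_space()
  s0 <- initial_state(profile)
  s1 <- water_state(old = final_beliefs[["old"]], mid = final_beliefs[["mid"]],
                    young = final_beliefs[["young"]], got_water = got_water)
  play_record("synthetic", profile$label, 1, 1L, 1L,
              data.frame(step = 1L, state_before = encode_state(sp, s0),
                         action = "STOP", feedback = "NONE",
                         state_after = encode_state(sp, s1)),
              "STOP")
}

test_that("learning score is the total absolute belief movement", {
  fx <- mindset_profile("fixed")
  ml <- mindset_profile("malleable")
  correct <- correct_beliefs()
  # maximum attainable learning: 7 for fixed initials, 6 for malleable
  expect_equal(learning_score(make_record_with_beliefs(fx, correct)), 7L)
  expect_equal(learning_score(make_record_with_beliefs(ml, correct)), 6L)
  # no movement scores zero
  expect_equal(learning_score(make_record_with_beliefs(fx, fx$initial_beliefs)), 0L)
  expect_equal(learning_score(make_record_with_beliefs(ml, c(old = 1, mid = 0, young = -1))), 2L)
})

test_that("learning scores over a cohort stay within each profile's range", {
  fx <- water_fixture()
  for (rec in fx$cohort[seq(1, 2000, by = 61)]) {
    ls <- learning_score(rec)
    expect_gte(ls, 0L)
    expect_lte(ls, if (rec$mindset == "fixed") 7L else 6L)
  }
})

test_that("conversation segmentation counts dialog turns between select and leave", {
  env <- environment_config(p_reveal_happy = 0, p_reveal_unhappy = 0)
  rec <- scripted_record(
    c("SELECT_NPC_OLD", "GREET_FORMAL", "ASK_FORMAL", "LEAVE",
      "SELECT_NPC_MID", "GREET_INFORMAL"),
    mindset_profile("fixed"), env = env, seed = 8)
  convs <- segment_conversations(rec)
  expect_length(convs, 2L)
  expect_equal(convs[[1L]]$age_class, "OLD")
  expect_equal(convs[[1L]]$n_turns, 2L)
  expect_equal(convs[[2L]]$age_class, "MID")
  expect_equal(convs[[2L]]$n_turns, 1L)
  # correctness is judged against the true culture
  expect_identical(convs[[1L]]$correct, c(TRUE, TRUE))
  expect_identical(convs[[2L]]$correct, TRUE)
  # a record with no SELECT has no conversations
  rec2 <- scripted_record("STOP", mindset_profile("fixed"), seed = 1)
  expect_length(segment_conversations(rec2), 0L)
})

test_that("conversation count equals the number of SELECT actions cohort-wide", {
  fx <- water_fixture()
  for (rec in fx$cohort[seq(1, 2000, by = 173)]) {
    expect_length(segment_conversations(rec),
                  sum(startsWith(rec$steps$action, "SELECT_NPC_")))
  }
})

test_that("quitting uses strict thresholds and the water-seeking universe", {
  env0 <- environment_config(p_reveal_happy = 0, p_reveal_unhappy = 0)
  # 3 dialog turns without water -> conversational quit
  rec <- scripted_record(
    c("SELECT_NPC_OLD", "GREET_FORMAL", "ASK_FORMAL", "ASK_FORMAL", "LEAVE",
      "STOP"),
    mindset_profile("fixed"), env = env0, seed = 3)
  qf <- quit_flags(rec)
  expect_identical(qf$conversational, TRUE)
  # 4 dialog turns -> not a quit
  rec4 <- scripted_record(
    c("SELECT_NPC_OLD", "GREET_FORMAL", "ASK_FORMAL", "ASK_FORMAL",
      "ASK_FORMAL", "LEAVE", "STOP"),
    mindset_profile("fixed"), env = env0, seed = 3)
  expect_identical(quit_flags(rec4)$conversational, FALSE)
  # exactly 3 conversations without water -> not a game quit (strict <3)
  rec3 <- scripted_record(
    rep(c("SELECT_NPC_OLD", "GREET_FORMAL", "LEAVE"), 3),
    mindset_profile("fixed"), env = env0, seed = 3)
  expect_false(quit_flags(rec3)$game)
  rec2 <- scripted_record(
    c(rep(c("SELECT_NPC_OLD", "GREET_FORMAL", "LEAVE"), 2), "STOP"),
    mindset_profile("fixed"), env = env0, seed = 3)
  expect_true(quit_flags(rec2)$game)
  # with the water obtained, never a game quit; short post-water
  # conversations fall outside the conversational-quitting universe
  env1 <- environment_config(p_reveal_happy = 1, p_reveal_unhappy = 1)
  recw <- scripted_record(
    c("SELECT_NPC_OLD", "GREET_FORMAL", "ASK_FORMAL", "LEAVE",
      "SELECT_NPC_MID", "GREET_INFORMAL", "LEAVE", "STOP"),
    mindset_profile("fixed"), env = env1, seed = 3)
  qw <- quit_flags(recw)
  expect_false(qw$game)
  expect_identical(qw$conversational, c(FALSE, NA))
})

test_that("responsiveness requires two later correct uses after an incorrect one", {
  conv <- function(correct) list(age_class = "OLD", actions = rep("x", length(correct)),
                                 correct = correct, feedback = rep("", length(correct)),
                                 got_water = FALSE, water_seeking = TRUE,
                                 n_turns = length(correct))
  expect_equal(responsiveness(conv(c(FALSE, TRUE, TRUE))), "responsive")
  expect_equal(responsiveness(conv(c(FALSE, TRUE))), "unresponsive")
  expect_equal(responsiveness(conv(c(TRUE, TRUE))), "not_applicable")
  expect_equal(responsiveness(conv(c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))),
               "responsive")
  expect_equal(responsiveness(conv(c(TRUE, TRUE, FALSE))), "unresponsive")
  expect_equal(responsiveness(conv(logical(0))), "not_applicable")
})

test_that("age-class selection proportions count conversation openings", {
  env0 <- environment_config(p_reveal_happy = 0, p_reveal_unhappy = 0)
  rec <- scripted_record(
    c("SELECT_NPC_YOUNG", "LEAVE", "SELECT_NPC_YOUNG", "LEAVE",
      "SELECT_NPC_MID", "LEAVE", "SELECT_NPC_OLD", "LEAVE", "STOP"),
    mindset_profile("fixed"), env = env0, seed = 2)
  pr <- npc_age_proportions(list(rec))
  expect_equal(pr, c(YOUNG = 0.5, MID = 0.25, OLD = 0.25))
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  rec2 <- scripted_record("STOP", mindset_profile("fixed"), seed = 1)
  expect_error(npc_age_proportions(list(rec2)), "no conversations")
})

test_that("welch_t matches the reference implementation and pooled-SD d", {
  a <- c(1, 2, 3)
  b <- c(2, 4, 6)
  w <- welch_t(a, b)
  ref <- stats::t.test(a, b, var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(w$t, -1.549, tolerance = 1e-3)
  expect_equal(w$df, 2.94, tolerance = 1e-2)
  expect_equal(w$p, ref$p.value, tolerance = 1e-9)
  expect_equal(w$d, (2 - 4) / sqrt((1 + 4) / 2), tolerance = 1e-9)
  # identical non-constant groups: t = 0, p = 1, d = 0
  w0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_equal(w0$d, 0)
  # antisymmetry of d under group swap
  expect_equal(welch_t(a, b)$d, -welch_t(b, a)$d)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("chi_square_prop is the uncorrected 1-df Pearson test", {
  eq <- chi_square_prop(30, 100, 30, 100)
  expect_equal(eq$chisq, 0)
  expect_equal(eq$p, 1)
  x <- chi_square_prop(30, 100, 10, 100)
  expect_equal(x$chisq, 12.5, tolerance = 1e-9)
  expect_equal(x$df, 1L, ignore_attr = TRUE)
  # symmetric under swapping the groups
  expect_equal(chi_square_prop(30, 100, 10, 100)$chisq,
               chi_square_prop(10, 100, 30, 100)$chisq)
  expect_error(chi_square_prop(0, 10, 0, 10), "margin")
  expect_error(chi_square_prop(11, 10, 1, 10), "exceed")
})

test_that("player summaries aggregate exactly runs_per_player records", {
  fx <- water_fixture()
  sm <- summarize_players(fx$cohort)
  expect_equal(nrow(sm), 2L * fx$config$n_players_per_mindset)
  expect_true(all(sm$n_games == fx$config$runs_per_player))
  expect_true(all(sm$conv_quits <= sm$water_seeking_conversations))
  expect_true(all(sm$water_seeking_conversations <= sm$total_conversations))
  expect_true(all(sm$responsive <= sm$incorrect_convs))
  expect_equal(sm$sel_young + sm$sel_mid + sm$sel_old, sm$total_conversations)
})

test_that("responsiveness denominators partition conversations with an incorrect use", {
  fx <- water_fixture()
  rec <- fx$cohort[[5L]]
  convs <- segment_conversations(rec)
  states <- vapply(convs, responsiveness, character(1))
  expect_equal(sum(states != "not_applicable"),
               sum(vapply(convs, function(cv) any(!cv$correct), logical(1))))
})
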