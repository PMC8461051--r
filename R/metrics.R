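# Behavioral validity metrics: cultural learning, conversation structure,
# quitting, responsiveness to feedback, villager-age selection, and the
# group-comparison layer (Welch t, Cohen's d, 2x2 chi-squared).

#' Cultural learning score of a record
#'
#' Sum over the three formality beliefs of the absolute difference between
#' the record's final and initial values. Because all real-world belief
#' changes move toward the correct values, this measures how much culture
#' was learned: the maximum is 7 for fixed initials (0 + 3 + 4) and 6 for
#' malleable initials (2 + 2 + 2).
#'
#' @param record a [play_record()].
#' @return integer learning score.
#' @export
learning_score <- function(record) {
  steps <- record$steps
  if (nrow(steps) == 0L) return(0L)
  space <- water_state_space()
  first <- decode_state(space, steps$state_before[1L])
  last <- decode_state(space, steps$state_after[nrow(steps)])
  bel <- c("old", "mid", "young")
  as.integer(sum(abs(last[1L, bel] - first[1L, bel])))
}

#' Split a record into conversations
#'
#' Each SELECT action opens a conversation; LEAVE, STOP, or the end of the
#' record closes it. Dialog turns are the greet/ask actions inside
#' (selection and leaving are navigation, not dialog).
#'
#' @param record a [play_record()].
#' @param culture the true norm, used to flag each dialog action's
#'   formality as correct or incorrect for the villager's age class.
#' @return list of conversations, each a list with `age_class`, `n_turns`,
#'   `actions` (dialog actions), `correct` (logical per dialog action),
#'   `feedback` (valence per dialog action), `got_water` (did the water
#'   location become known during this conversation), `water_seeking` (was
#'   the water location still unknown when the conversation opened).
#' @export
segment_conversations <- function(record, culture = default_culture()) {
  steps <- record$steps
  convs <- list()
  cur <- NULL
  if (nrow(steps) == 0L) return(convs)
  space <- water_state_space()
  water_after <- decode_state(space, steps$state_after)[, "got_water"]
  water_before <- decode_state(space, steps$state_before)[, "got_water"]
  close_conv <- function() {
    if (!is.null(cur)) {
      cur$n_turns <- length(cur$actions)
      convs[[length(convs) + 1L]] <<- cur
      cur <<- NULL
    }
  }
  for (i in seq_len(nrow(steps))) {
    a <- steps$action[i]
    if (startsWith(a, "SELECT_NPC_")) {
      if (!is.null(cur)) stop("malformed record: SELECT inside a conversation")
      cls <- sub("SELECT_NPC_", "", a)
      cur <- list(age_class = cls, actions = character(0),
                  correct = logical(0), feedback = character(0),
                  got_water = FALSE,
                  water_seeking = water_before[i] == 0L)
    } else if (a %in% c("GREET_FORMAL", "GREET_INFORMAL",
                        "ASK_FORMAL", "ASK_INFORMAL")) {
      if (is.null(cur)) stop("malformed record: dialog action outside a conversation")
      formal <- a %in% c("GREET_FORMAL", "ASK_FORMAL")
      likes <- culture[[tolower(cur$age_class)]]
      cur$actions <- c(cur$actions, a)
      cur$correct <- c(cur$correct, formal == likes)
      cur$feedback <- c(cur$feedback, steps$feedback[i])
      if (water_after[i] > water_before[i]) cur$got_water <- TRUE
    } else if (a %in% c("LEAVE", "STOP")) {
      close_conv()
    }
  }
  close_conv()
  convs
}

#' Quitting flags for a record
#'
#' Conversational quitting: a water-seeking conversation (one opened while
#' the water location was still unknown) ended without the location
#' becoming known in it and with fewer than 4 dialog turns — leaving
#' without gaining the information. Conversations opened after the water
#' is already known cannot gain it and are flagged `NA` (outside the
#' quitting universe). Game quitting: the record ended without the water
#' and with fewer than 3 conversations.
#'
#' @param record a [play_record()].
#' @param convs precomputed [segment_conversations()] output (optional).
#' @return list with `conversational` (logical per conversation, `NA` for
#'   non-water-seeking conversations) and `game` (single logical).
#' @export
quit_flags <- function(record, convs = segment_conversations(record)) {
  conv_quit <- vapply(convs, function(cv) {
    if (!cv$water_seeking) return(NA)
    !cv$got_water && cv$n_turns < 4L
  }, logical(1))
  steps <- record$steps
  got_water_final <- if (nrow(steps) == 0L) 0L else {
    decode_state(water_state_space(), steps$state_after[nrow(steps)])[1L, "got_water"]
  }
  list(conversational = conv_quit,
       game = got_water_final == 0L && length(convs) < 3L)
}

#' Responsiveness of a conversation to negative feedback
#'
#' A conversation is responsive when some incorrect-formality action is
#' followed, later in the same conversation, by at least two
#' correct-formality actions; it is unresponsive when an incorrect
#' formality occurred but was not followed that way; and not applicable
#' when no incorrect formality occurred (one cannot respond to negative
#' feedback never received). Correctness is judged against the true
#' culture, not the player's beliefs.
#'
#' @param conversation one element of [segment_conversations()].
#' @param culture unused placeholder kept for explicitness; correctness
#'   flags are precomputed by [segment_conversations()].
#' @return `"responsive"`, `"unresponsive"` or `"not_applicable"`.
#' @export
responsiveness <- function(conversation, culture = default_culture()) {
  correct <- conversation$correct
  wrong <- which(!correct)
  if (length(wrong) == 0L) return("not_applicable")
  first_wrong <- wrong[1L]
  later_correct <- if (first_wrong < length(correct)) {
    sum(correct[(first_wrong + 1L):length(correct)])
  } else 0L
  if (later_correct >= 2L) "responsive" else "unresponsive"
}

#' Villager age-class selection proportions
#'
#' Proportion of conversations opened with each age class across a
#' collection of records.
#'
#' @param records a list of [play_record()]s (e.g. a cohort or subset).
#' @return named numeric vector over YOUNG, MID, OLD summing to 1.
#' @export
npc_age_proportions <- function(records) {
  counts <- c(YOUNG = 0, MID = 0, OLD = 0)
  for (r in records) {
    for (cv in segment_conversations(r)) {
      counts[cv$age_class] <- counts[cv$age_class] + 1
    }
  }
  if (sum(counts) == 0) stop("no conversations in these records")
  counts / sum(counts)
}

#' Welch two-sample comparison with pooled-SD Cohen's d
#'
#' Two-sided Welch t-test (unequal variances, Welch-Satterthwaite degrees
#' of freedom) via [stats::t.test()], plus the pooled-SD effect size
#' `d = (mean_a - mean_b) / sqrt((var_a + var_b) / 2)`.
#'
#' @param group_a,group_b numeric vectors (each n >= 2 after NA removal).
#' @param metric label carried into the output.
#' @return one-row data.frame: group means/SDs/ns, `t`, `df`, `p`, `d`.
#' @export
welch_t <- function(group_a, group_b, metric = "metric") {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both groups: the Welch statistic is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(
    metric = metric,
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    d = (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  )
}

#' Chi-squared test for two proportions
#'
#' 1-df Pearson chi-squared on the 2x2 success/failure table, without
#' continuity correction, via [stats::chisq.test()].
#'
#' @param successes_a,total_a,successes_b,total_b counts.
#' @param metric label carried into the output.
#' @return one-row data.frame: proportions, counts, `chisq`, `df`, `p`.
#' @export
chi_square_prop <- function(successes_a, total_a, successes_b, total_b,
                            metric = "proportion") {
  if (total_a < 1L || total_b < 1L) stop("totals must be >= 1")
  if (successes_a > total_a || successes_b > total_b) {
    stop("successes cannot exceed totals")
  }
  tab <- matrix(c(successes_a, total_a - successes_a,
                  successes_b, total_b - successes_b),
                nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a margin of the 2x2 table is zero; the test is undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  data.frame(
    metric = metric,
    prop_a = successes_a / total_a, n_a = total_a,
    prop_b = successes_b / total_b, n_b = total_b,
    chisq = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value
  )
}

#' Per-player metric summaries
#'
#' Aggregates each player's records: mean learning score, mean
#' conversations per game, dialog turns per conversation (pooled over the
#' player's conversations), quitting counts, responsiveness counts, and
#' villager-age selection counts. Group comparisons of means run on these
#' per-player aggregates; the chi-squared comparisons pool the counts.
#'
#' @param cohort a [simulate_cohort()] result (or any list of records).
#' @param culture the true norm for correctness judgments.
#' @return data.frame, one row per player.
#' @export
summarize_players <- function(cohort, culture = default_culture()) {
  ids <- vapply(cohort, function(r) r$player_id, character(1))
  rows <- lapply(split(seq_along(cohort), ids), function(ii) {
    recs <- cohort[ii]
    learn <- vapply(recs, learning_score, integer(1))
    n_convs <- 0L; n_turns <- 0L; conv_quits <- 0L; game_quits <- 0L
    seeking_convs <- 0L; responsive <- 0L; incorrect_convs <- 0L
    sel <- c(YOUNG = 0L, MID = 0L, OLD = 0L)
    for (r in recs) {
      convs <- segment_conversations(r, culture)
      qf <- quit_flags(r, convs)
      n_convs <- n_convs + length(convs)
      n_turns <- n_turns + sum(vapply(convs, function(cv) cv$n_turns, integer(1)))
      seeking_convs <- seeking_convs + sum(!is.na(qf$conversational))
      conv_quits <- conv_quits + sum(qf$conversational, na.rm = TRUE)
      game_quits <- game_quits + qf$game
      for (cv in convs) {
        sel[cv$age_class] <- sel[cv$age_class] + 1L
        resp <- responsiveness(cv, culture)
        if (resp != "not_applicable") {
          incorrect_convs <- incorrect_convs + 1L
          if (resp == "responsive") responsive <- responsive + 1L
        }
      }
    }
    data.frame(
      player_id = recs[[1L]]$player_id, mindset = recs[[1L]]$mindset,
      beta = recs[[1L]]$beta, n_games = length(recs),
      mean_learning = mean(learn),
      mean_conversations = n_convs / length(recs),
      mean_turns_per_conversation = if (n_convs > 0L) n_turns / n_convs else NA_real_,
      total_conversations = n_convs,
      water_seeking_conversations = seeking_convs, conv_quits = conv_quits,
      game_quits = as.integer(game_quits),
      responsive = responsive, incorrect_convs = incorrect_convs,
      sel_young = sel[["YOUNG"]], sel_mid = sel[["MID"]], sel_old = sel[["OLD"]]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mindset, out$player_id), ]
}

#' Compare fixed and malleable groups on all validity criteria
#'
#' Runs the four behavioral criteria and the exploratory age-selection
#' analysis: Welch t-tests (with pooled-SD Cohen's d) on per-player mean
#' learning, conversations per game and dialog turns per conversation;
#' chi-squared tests on pooled conversational-quit, game-quit and
#' responsiveness proportions (the latter on both denominators: all
#' conversations, and conversations containing at least one incorrect
#' formality); and the 3x2 chi-squared over age-class selections plus the
#' OLD-selection two-proportion test. Group "a" is fixed, "b" malleable.
#'
#' @param summaries a [summarize_players()] data.frame.
#' @return list of class `mindset_comparison` with elements `welch`
#'   (data.frame of the three mean comparisons), `proportions` (data.frame
#'   of the 2x2 chi-squared comparisons), `age_selection` (list with the
#'   3x2 test and the selection proportions by mindset).
#' @export
compare_mindsets <- function(summaries) {
  fx <- summaries[summaries$mindset == "fixed", ]
  ml <- summaries[summaries$mindset == "malleable", ]
  if (nrow(fx) == 0L || nrow(ml) == 0L) stop("need both mindsets in summaries")

  welch <- rbind(
    welch_t(fx$mean_learning, ml$mean_learning, "mean_learning"),
    welch_t(fx$mean_conversations, ml$mean_conversations, "conversations_per_game"),
    welch_t(fx$mean_turns_per_conversation, ml$mean_turns_per_conversation,
            "turns_per_conversation")
  )
  props <- rbind(
    chi_square_prop(sum(fx$conv_quits), sum(fx$water_seeking_conversations),
                    sum(ml$conv_quits), sum(ml$water_seeking_conversations),
                    "conversational_quitting"),
    chi_square_prop(sum(fx$game_quits), sum(fx$n_games),
                    sum(ml$game_quits), sum(ml$n_games),
                    "game_quitting"),
    chi_square_prop(sum(fx$responsive), sum(fx$total_conversations),
                    sum(ml$responsive), sum(ml$total_conversations),
                    "responsiveness_all_conversations"),
    chi_square_prop(sum(fx$responsive), sum(fx$incorrect_convs),
                    sum(ml$responsive), sum(ml$incorrect_convs),
                    "responsiveness_incorrect_conversations"),
    chi_square_prop(sum(fx$sel_old), sum(fx$total_conversations),
                    sum(ml$sel_old), sum(ml$total_conversations),
                    "old_npc_selection")
  )
  sel_tab <- rbind(
    fixed = c(YOUNG = sum(fx$sel_young), MID = sum(fx$sel_mid), OLD = sum(fx$sel_old)),
    malleable = c(YOUNG = sum(ml$sel_young), MID = sum(ml$sel_mid), OLD = sum(ml$sel_old))
  )
  age_test <- suppressWarnings(stats::chisq.test(sel_tab, correct = FALSE))
  structure(
    list(welch = welch, proportions = props,
         age_selection = list(
           counts = sel_tab,
           proportions = sel_tab / rowSums(sel_tab),
           chisq = unname(age_test$statistic),
           df = unname(age_test$parameter),
           p = age_test$p.value
         )),
    class = "mindset_comparison"
  )
}

#' @export
print.mindset_comparison <- function(x, ...) {
  cat("Welch comparisons on per-player means (a = fixed, b = malleable):\n")
  print(x$welch, row.names = FALSE, digits = 4)
  cat("\nPooled proportion comparisons (a = fixed, b = malleable):\n")
  print(x$proportions, row.names = FALSE, digits = 4)
  cat("\nVillager age-class selection proportions:\n")
  print(round(x$age_selection$proportions, 3))
  cat(sprintf("chi-squared = %.1f, df = %d, p = %.3g\n",
              x$age_selection$chisq, x$age_selection$df, x$age_selection$p))
  invisible(x)
}
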