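# The two cultural-mindset cognitive profiles. Each profile bundles the
# mindset's initial beliefs, its goals (belief-band rewards, water reward,
# per-move time cost) and its subjective expectations about how its own
# beliefs change -- the three mechanisms (goals, initial beliefs, belief
# updating) that differentiate fixed from malleable decision making.
#
# Subjective belief-change expectation: learning is anticipated as
# confirmation, at the player's own updating propensity. At complete
# uncertainty (belief 0) the player expects the feedback -- unpredictable
# to them -- to move the belief one step in whichever direction it
# indicates (a 50/50 split under their own happiness expectation). At a
# moderate belief (|b| = 1) a malleable player expects confirming feedback
# to strengthen the belief toward its extreme and does not anticipate
# unlearning from disconfirming feedback; a fixed player expects no change
# at all away from 0 (change "only if completely uncertain"). The
# probability that an anticipated change actually happens reuses the
# real-world updating propensities keyed on current certainty |b| (the
# player knows roughly how much evidence they need), so planned
# conversations are several dialog turns deep rather than instantaneous.
# Beliefs at an extreme (|b| = 2) are subjective fixed points for both.

#' A cultural-mindset profile
#'
#' The fixed mindset starts with moderate-to-strong preset beliefs
#' (old, mid, young) = (2, 1, -2), values belief certainty mildly
#' (band rewards 0.5 / 1.5 / 3.5), pays a high time cost (-0.75 per move)
#' and subjectively expects its beliefs to change only when completely
#' uncertain (belief = 0). The malleable mindset starts agnostic (0, 0, 0),
#' values certainty highly (1 / 3 / 6 -- full cultural understanding is
#' worth more than the water), pays a lower time cost (-0.5) and expects to
#' learn whenever a belief is not yet at an extreme (|belief| < 2). Both
#' value finding the water at 5.
#'
#' @param label `"fixed"` or `"malleable"`.
#' @return an object of class `mindset_profile` with fields `label`,
#'   `initial_beliefs` (old, mid, young), `water_reward`, `belief_bands`
#'   (rewards for belief strength 0 < s < 3, 3 <= s < 6, s = 6),
#'   `time_cost`, and `subjective_update_prob(b, d)`, the vectorized
#'   subjective belief-change kernel: the probability the player assigns
#'   to their belief moving one step in direction `d` (+1 toward "likes
#'   formal", -1 away) given its current value `b`. When a move is
#'   anticipated, the new value is `b + d`.
#' @export
mindset_profile <- function(label = c("fixed", "malleable")) {
  label <- match.arg(label)
  if (label == "fixed") {
    structure(list(
      label = "fixed",
      initial_beliefs = c(old = 2L, mid = 1L, young = -2L),
      water_reward = 5,
      belief_bands = c(bit = 0.5, moderate = 1.5, strong = 3.5),
      time_cost = -0.75,
      # expects change only at complete uncertainty, at own propensity
      subjective_update_prob = function(b, d) ifelse(b == 0L, 0.6, 0)
    ), class = "mindset_profile")
  } else {
    structure(list(
      label = "malleable",
      initial_beliefs = c(old = 0L, mid = 0L, young = 0L),
      water_reward = 5,
      belief_bands = c(bit = 1, moderate = 3, strong = 6),
      time_cost = -0.5,
      # expects to learn unless maxed: any direction at 0, confirmation
      # (strengthening only) at |b| = 1, fixed point at |b| = 2
      subjective_update_prob = function(b, d) {
        ifelse(b == 0L, 0.95,
               ifelse(abs(b) == 1L & d == sign(b), 0.6, 0))
      }
    ), class = "mindset_profile")
  }
}

#' @export
print.mindset_profile <- function(x, ...) {
  cat(sprintf("<mindset_profile> %s: beliefs (%d, %d, %d), bands (%g, %g, %g), time cost %g\n",
              x$label, x$initial_beliefs[["old"]], x$initial_beliefs[["mid"]],
              x$initial_beliefs[["young"]], x$belief_bands[[1L]],
              x$belief_bands[[2L]], x$belief_bands[[3L]], x$time_cost))
  invisible(x)
}

#' Initial game state for a profile
#'
#' @param profile a [mindset_profile()].
#' @return named state vector: the profile's initial beliefs, all status
#'   flags zero.
#' @export
initial_state <- function(profile) {
  b <- profile$initial_beliefs
  water_state(old = b[["old"]], mid = b[["mid"]], young = b[["young"]])
}

#' Belief strength
#'
#' Sum of the absolute values of the three formality beliefs -- the
#' quantity the belief-band rewards condition on. It measures certainty,
#' not correctness.
#'
#' @param beliefs numeric vector of the three belief values (each in -2..2).
#' @return integer in 0..6.
#' @export
belief_strength <- function(beliefs) {
  if (any(abs(beliefs) > 2)) stop("beliefs must be in [-2, 2]")
  as.integer(sum(abs(beliefs)))
}

#' End-of-play reward for a final state
#'
#' All rewards except the per-move time cost are granted at the end of
#' play: the water reward if `got_water = 1`, plus the single belief-band
#' reward whose strength condition holds (nothing for strength 0). The
#' time cost is not included here; it accrues per move during play.
#'
#' @param profile a [mindset_profile()].
#' @param final_state the state at episode end.
#' @return the terminal reward.
#' @export
#' @examples
#' fx <- mindset_profile("fixed")
#' terminal_reward(fx, initial_state(fx)) # 1.5: strength 5 band, no water
terminal_reward <- function(profile, final_state) {
  s <- belief_strength(final_state[c("old", "mid", "young")])
  band <- if (s == 0L) 0 else if (s < 3L) {
    profile$belief_bands[["bit"]]
  } else if (s < 6L) {
    profile$belief_bands[["moderate"]]
  } else {
    profile$belief_bands[["strong"]]
  }
  profile$water_reward * final_state[["got_water"]] + band
}

# Subjective probability that an age class likes formal address, linearly
# interpolating the belief value into [0, 1].
subjective_p_likes_formal <- function(b) (b + 2) / 4

#' Subjective next-state distribution
#'
#' The player's internal model of what an action will do. Navigation
#' (select / leave / stop) is deterministic. For a greet or ask, the player
#' expects the villager to become happy with probability equal to its own
#' belief that the class likes the formality used (`(b + 2) / 4` for
#' formal, the complement for informal); an ask is additionally expected to
#' reveal the water with the environment's reveal probabilities (shared
#' basic reasoning with the real world) provided the request has not yet
#' been resolved in this conversation (first ask, water still unknown).
#' The player also anticipates its own belief change through the
#' profile's `subjective_update_prob` kernel: at belief 0 a one-step move
#' in the direction the feedback indicates, at the player's own updating
#' propensity; at |belief| = 1 a malleable player expects confirming
#' feedback to strengthen the belief (and no unlearning otherwise) while
#' a fixed player expects no change; extremes are fixed points.
#'
#' @param profile a [mindset_profile()].
#' @param state named state vector.
#' @param action an action available in `state`.
#' @param env an [environment_config()] (reveal probabilities).
#' @return data.frame: columns `prob` plus the nine state variables; one
#'   row per anticipated outcome, probabilities summing to 1. For STOP the
#'   single row carries `terminal = TRUE`.
#' @export
subjective_transition <- function(profile, state, action,
                                  env = environment_config()) {
  if (!action %in% available_actions(state)) {
    stop("action ", action, " is not available in this state")
  }
  as_row <- function(s, prob, terminal = FALSE) {
    cbind(data.frame(prob = prob, terminal = terminal),
          as.data.frame(t(s)))
  }
  if (startsWith(action, "SELECT_NPC_")) {
    s <- state
    s[["in_conv"]] <- 1L
    s[["npc_age"]] <- match(sub("SELECT_NPC_", "", action), AGE_CLASSES)
    s[["greeted"]] <- s[["asked"]] <- s[["npc_happy"]] <- 0L
    return(as_row(s, 1))
  }
  if (action == "LEAVE") {
    s <- state
    s[["in_conv"]] <- s[["npc_age"]] <- 0L
    s[["greeted"]] <- s[["asked"]] <- s[["npc_happy"]] <- 0L
    return(as_row(s, 1))
  }
  if (action == "STOP") {
    return(as_row(state, 1, terminal = TRUE))
  }

  cls <- AGE_CLASSES_LOWER[state[["npc_age"]]]
  b <- state[[cls]]
  formal <- action %in% c("GREET_FORMAL", "ASK_FORMAL")
  p_happy <- if (formal) subjective_p_likes_formal(b) else 1 - subjective_p_likes_formal(b)
  is_ask <- startsWith(action, "ASK")

  out <- list()
  for (happy in c(1L, 0L)) {
    p_happy_branch <- if (happy == 1L) p_happy else 1 - p_happy
    if (p_happy_branch == 0) next
    # feedback direction: happy confirms the formality used, unhappy refutes it
    dir <- if (xor(formal, happy == 1L)) -1L else 1L
    p_move <- profile$subjective_update_prob(b, dir)
    for (moved in c(TRUE, FALSE)) {
      p_branch <- p_happy_branch * if (moved) p_move else 1 - p_move
      if (p_branch == 0) next
      s <- state
      s[["npc_happy"]] <- happy
      if (is_ask) s[["asked"]] <- 1L else s[["greeted"]] <- 1L
      if (moved) s[[cls]] <- b + dir
      if (is_ask && state[["got_water"]] == 0L && state[["asked"]] == 0L) {
        p_reveal <- if (happy == 1L) env$p_reveal_happy else env$p_reveal_unhappy
        for (water in c(1L, 0L)) {
          p_w <- if (water == 1L) p_reveal else 1 - p_reveal
          if (p_w == 0) next
          sw <- s
          sw[["got_water"]] <- water
          out[[length(out) + 1L]] <- as_row(sw, p_branch * p_w)
        }
      } else {
        out[[length(out) + 1L]] <- as_row(s, p_branch)
      }
    }
  }
  do.call(rbind, out)
}

#' Assemble a mindset's subjective MDP over the full water-task space
#'
#' Builds the transition/reward table for [q_iteration()]: subjective
#' transitions for every (state, available action) pair over all 16,000
#' states, a reward of `time_cost` on every move, and
#' `time_cost + terminal_reward(state)` on the STOP transition into the
#' absorbing terminal. Construction is vectorized; the scalar contract is
#' [subjective_transition()].
#'
#' @param profile a [mindset_profile()].
#' @param env an [environment_config()].
#' @return an object of class `cognitive_mdp`: list with `transitions`
#'   (data.frame `state`, `action`, `next_state`, `prob`, `reward`),
#'   `space`, `actions`, `profile`, `env`.
#' @export
build_cognitive_mdp <- function(profile, env = environment_config()) {
  space <- water_state_space()
  n <- space$n_states
  S <- as.data.frame(decode_state(space, seq_len(n)))
  idx <- seq_len(n)
  tc <- profile$time_cost
  blocks <- list()
  add <- function(state, action, next_state, prob, reward) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      state = state, action = action, next_state = next_state,
      prob = prob, reward = reward
    )
  }
  encode_mod <- function(base, ...) {
    # encode states equal to `base` rows with some columns overridden
    mod <- list(...)
    m <- base
    for (nm in names(mod)) m[[nm]] <- mod[[nm]]
    encode_state(space, m)
  }

  ## outside a conversation: select any age class, or stop
  out <- S$in_conv == 0L
  strength <- abs(S$old) + abs(S$mid) + abs(S$young)
  band <- ifelse(strength == 0, 0,
          ifelse(strength < 3, profile$belief_bands[["bit"]],
          ifelse(strength < 6, profile$belief_bands[["moderate"]],
                 profile$belief_bands[["strong"]])))
  term_r <- profile$water_reward * S$got_water + band
  add(idx[out], "STOP", NA_integer_, 1, tc + term_r[out])
  for (a in 1:3) {
    add(idx[out], paste0("SELECT_NPC_", AGE_CLASSES[a]),
        encode_mod(S[out, ], in_conv = 1L, npc_age = a,
                   greeted = 0L, asked = 0L, npc_happy = 0L),
        1, tc)
  }

  ## in a conversation: leave is always available
  inc <- S$in_conv == 1L
  add(idx[inc], "LEAVE",
      encode_mod(S[inc, ], in_conv = 0L, npc_age = 0L,
                 greeted = 0L, asked = 0L, npc_happy = 0L),
      1, tc)

  ## greets and asks, per outcome branch; the water-reveal split applies
  ## only to asks made before the water location is known
  dialog_rows <- function(mask, action, reveal = FALSE) {
    Sm <- S[mask, ]
    cls_i <- Sm$npc_age                      # 1 young, 2 mid, 3 old
    b <- ifelse(cls_i == 1L, Sm$young, ifelse(cls_i == 2L, Sm$mid, Sm$old))
    formal <- action %in% c("GREET_FORMAL", "ASK_FORMAL")
    is_ask <- startsWith(action, "ASK")
    p_likes <- (b + 2) / 4
    p_happy <- if (formal) p_likes else 1 - p_likes
    for (happy in c(1L, 0L)) {
      p_happy_branch <- if (happy == 1L) p_happy else 1 - p_happy
      dir <- if (xor(formal, happy == 1L)) -1L else 1L
      p_move <- profile$subjective_update_prob(b, dir)
      for (moved in c(TRUE, FALSE)) {
        p_branch <- p_happy_branch * if (moved) p_move else 1 - p_move
        nb <- if (moved) b + dir else b
        base <- Sm
        base$young <- ifelse(cls_i == 1L, nb, Sm$young)
        base$mid <- ifelse(cls_i == 2L, nb, Sm$mid)
        base$old <- ifelse(cls_i == 3L, nb, Sm$old)
        base$npc_happy <- happy
        if (is_ask) base$asked <- 1L else base$greeted <- 1L
        if (is_ask && reveal) {
          p_reveal <- if (happy == 1L) env$p_reveal_happy else env$p_reveal_unhappy
          for (water in c(1L, 0L)) {
            p_w <- if (water == 1L) p_reveal else 1 - p_reveal
            p <- p_branch * p_w
            keep <- p > 0
            if (!any(keep)) next
            add(idx[mask][keep], action,
                encode_mod(base[keep, ], got_water = water),
                p[keep], tc)
          }
        } else {
          keep <- p_branch > 0
          if (any(keep)) {
            add(idx[mask][keep], action, encode_state(space, base[keep, ]),
                p_branch[keep], tc)
          }
        }
      }
    }
  }
  greet_ok <- inc & S$greeted == 0L & S$npc_age > 0L
  ask_all <- inc & S$greeted == 1L & S$npc_age > 0L
  # the first ask of a conversation can reveal the water; repeat asks cannot
  ask_first <- ask_all & S$got_water == 0L & S$asked == 0L
  ask_again <- ask_all & !(S$got_water == 0L & S$asked == 0L)
  for (a in c("GREET_FORMAL", "GREET_INFORMAL")) dialog_rows(greet_ok, a)
  for (a in c("ASK_FORMAL", "ASK_INFORMAL")) {
    dialog_rows(ask_first, a, reveal = TRUE)
    dialog_rows(ask_again, a, reveal = FALSE)
  }

  trans <- do.call(rbind, blocks)
  rownames(trans) <- NULL
  structure(
    list(transitions = trans, space = space, actions = WATER_ACTIONS,
         profile = profile, env = env),
    class = "cognitive_mdp"
  )
}

#' Solve a mindset's subjective MDP
#'
#' Convenience wrapper: [build_cognitive_mdp()] then [q_iteration()]. The
#' cohort pipeline solves each profile once at `beta = Inf` (standard value
#' iteration); the decision-noise parameter enters only the action-sampling
#' policy.
#'
#' @inheritParams build_cognitive_mdp
#' @inheritParams q_iteration
#' @return a `q_table`.
#' @export
solve_mindset_mdp <- function(profile, env = environment_config(),
                              gamma = 0.98, beta = Inf, tol = 1e-6,
                              max_iter = 10000L) {
  mdp <- build_cognitive_mdp(profile, env)
  q_iteration(mdp$transitions, n_states = mdp$space$n_states,
              gamma = gamma, beta = beta, tol = tol, max_iter = max_iter,
              actions = mdp$actions, check = FALSE)
}
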