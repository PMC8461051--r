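# The Ask-for-Water task: a newcomer to a village must learn an unfamiliar
# formality norm (which age classes prefer formal address) while trying to
# find out where the water source is. The player selects a villager, greets,
# and asks for directions; culturally appropriate address makes the villager
# happy, and a happy villager is more likely to reveal the water location.

#' Action set of the water task
#'
#' Three conversation-opening selections (one per villager age class), formal
#' and informal variants of greeting and asking, leaving a conversation, and
#' stopping play.
#'
#' @format character vector of the nine action names.
#' @export
WATER_ACTIONS <- c(
  "SELECT_NPC_YOUNG", "SELECT_NPC_MID", "SELECT_NPC_OLD",
  "GREET_FORMAL", "GREET_INFORMAL",
  "ASK_FORMAL", "ASK_INFORMAL",
  "LEAVE", "STOP"
)

AGE_CLASSES <- c("YOUNG", "MID", "OLD")

# Real-world belief updating: probability that a piece of feedback
# actually moves a belief one step toward its correct value, keyed on the
# current value of a belief whose correct value is +2.
UPDATE_TABLE <- list(
  fixed     = c(`-2` = 0.20, `-1` = 0.40, `0` = 0.60, `1` = 0.80, `2` = 0),
  malleable = c(`-2` = 0.30, `-1` = 0.60, `0` = 0.95, `1` = 0.60, `2` = 0)
)

#' The water task's belief-augmented state space
#'
#' Nine discrete variables: the three formality beliefs (one per villager
#' age class, each in -2..2), conversation status (`in_conv`, `npc_age`
#' with NONE = 0 / YOUNG = 1 / MID = 2 / OLD = 3, `greeted`, `asked`,
#' `npc_happy`) and quest status (`got_water`). 5*5*5*2*4*2*2*2*2 = 16,000
#' states in total.
#'
#' @return a [state_space()].
#' @export
water_state_space <- function() {
  state_space(data.frame(
    name = c("old", "mid", "young", "in_conv", "npc_age",
             "greeted", "asked", "npc_happy", "got_water"),
    min = c(-2L, -2L, -2L, 0L, 0L, 0L, 0L, 0L, 0L),
    max = c(2L, 2L, 2L, 1L, 3L, 1L, 1L, 1L, 1L)
  ))
}

#' Construct a water-task state
#'
#' @param old,mid,young formality beliefs, integers in -2..2.
#' @param in_conv,greeted,asked,npc_happy,got_water binary status flags.
#' @param npc_age 0 (none), 1 (young), 2 (mid) or 3 (old).
#' @return named integer state vector.
#' @export
water_state <- function(old = 0L, mid = 0L, young = 0L, in_conv = 0L,
                        npc_age = 0L, greeted = 0L, asked = 0L,
                        npc_happy = 0L, got_water = 0L) {
  c(old = as.integer(old), mid = as.integer(mid), young = as.integer(young),
    in_conv = as.integer(in_conv), npc_age = as.integer(npc_age),
    greeted = as.integer(greeted), asked = as.integer(asked),
    npc_happy = as.integer(npc_happy), got_water = as.integer(got_water))
}

#' The village's true formality norm
#'
#' High-status age classes (old and young) prefer formal address; the
#' middle-aged prefer informal address. The implied fully correct beliefs
#' are (old, mid, young) = (2, -2, 2).
#'
#' @return named logical vector over `young`, `mid`, `old`: does the class
#'   like formal address?
#' @export
default_culture <- function() {
  c(young = TRUE, mid = FALSE, old = TRUE)
}

#' Fully correct belief vector implied by a culture
#'
#' @param culture a culture vector as from [default_culture()].
#' @return named integer vector `(old, mid, young)` of -2/+2 values.
#' @export
correct_beliefs <- function(culture = default_culture()) {
  c(old = if (culture[["old"]]) 2L else -2L,
    mid = if (culture[["mid"]]) 2L else -2L,
    young = if (culture[["young"]]) 2L else -2L)
}

#' Environment configuration for the water task
#'
#' @param p_reveal_happy probability that a happy villager reveals the water
#'   location after being asked (default 0.8).
#' @param p_reveal_unhappy the same for an unhappy villager (default 0.1);
#'   must not exceed `p_reveal_happy`.
#' @param max_steps episode cap; an episode hitting it is force-terminated
#'   with `end_reason = "cap"`.
#' @param culture the true formality norm (overridable for counterfactual
#'   experiments).
#' @return an object of class `environment_config`.
#' @export
environment_config <- function(p_reveal_happy = 0.8, p_reveal_unhappy = 0.1,
                               max_steps = 50L,
                               culture = default_culture()) {
  if (p_reveal_unhappy < 0 || p_reveal_unhappy > p_reveal_happy ||
      p_reveal_happy > 1) {
    stop("need 0 <= p_reveal_unhappy <= p_reveal_happy <= 1")
  }
  if (max_steps < 1L) stop("max_steps must be >= 1")
  if (!identical(sort(names(culture)), sort(AGE_CLASSES_LOWER))) {
    stop("culture must be a named logical over young, mid, old")
  }
  structure(
    list(p_reveal_happy = p_reveal_happy,
         p_reveal_unhappy = p_reveal_unhappy,
         max_steps = as.integer(max_steps),
         culture = culture),
    class = "environment_config"
  )
}

AGE_CLASSES_LOWER <- c("young", "mid", "old")

#' Actions available in a state
#'
#' Outside a conversation the player may select any villager age class or
#' stop. In a conversation: before greeting, a formal/informal greet or
#' leave; after greeting, a formal/informal ask (repeatable) or leave.
#' Dialog remains available after the water location is known (play can
#' continue for cultural learning; asking again simply cannot reveal the
#' water twice). Total over all states; a post-STOP terminal is outside
#' the state space and has no actions.
#'
#' @param state a named state vector (see [water_state()]).
#' @return character vector of available action names.
#' @export
available_actions <- function(state) {
  if (state[["in_conv"]] == 0L) {
    return(c("SELECT_NPC_YOUNG", "SELECT_NPC_MID", "SELECT_NPC_OLD", "STOP"))
  }
  if (state[["npc_age"]] == 0L) {
    return("LEAVE")
  }
  if (state[["greeted"]] == 0L) {
    return(c("GREET_FORMAL", "GREET_INFORMAL", "LEAVE"))
  }
  c("ASK_FORMAL", "ASK_INFORMAL", "LEAVE")
}

#' Probability that feedback actually updates a belief
#'
#' The real-world belief-update model: after positive or negative feedback
#' concerning an age class, the player's belief for that class moves one
#' step toward its correct value with this probability. The update table is
#' keyed on the current value of a belief whose correct value is +2; for a
#' class whose correct value is -2 (middle-aged under the default culture)
#' the table is mirrored, i.e. current value `v` uses the row for `-v`.
#' A belief already at its correct extreme cannot be updated further
#' (probability 0). Fixed-mindset updating implements confirmation bias
#' (more likely the closer feedback is to the held belief); malleable
#' updating peaks at complete uncertainty.
#'
#' @param mindset `"fixed"` or `"malleable"`.
#' @param age_class `"YOUNG"`, `"MID"` or `"OLD"` (case-insensitive).
#' @param current_value the current belief value, integer in -2..2.
#' @param culture the true norm (determines each class's correct value).
#' @return a probability.
#' @export
#' @examples
#' belief_update_probability("fixed", "YOUNG", -2) # 0.20
#' belief_update_probability("malleable", "MID", 0) # 0.95
belief_update_probability <- function(mindset, age_class, current_value,
                                      culture = default_culture()) {
  tab <- UPDATE_TABLE[[mindset]]
  if (is.null(tab)) stop("unknown mindset label: ", mindset)
  cls <- tolower(age_class)
  if (!cls %in% AGE_CLASSES_LOWER) stop("unknown age class: ", age_class)
  if (current_value < -2L || current_value > 2L) {
    stop("current_value must be in [-2, 2]")
  }
  correct <- if (culture[[cls]]) 2L else -2L
  if (current_value == correct) return(0)
  key <- if (correct == 2L) current_value else -current_value
  unname(tab[[as.character(key)]])
}

#' One real-world environment step
#'
#' Applies an action to the true environment: selection opens a
#' conversation; a greet or ask makes the villager happy if and only if its
#' formality matches the true norm for that age class, generating positive
#' or negative feedback; an ask additionally reveals the water location
#' with probability `p_reveal_happy` (happy) or `p_reveal_unhappy`
#' (unhappy). After any feedback, the belief for the current age class
#' moves one step toward its correct value with probability
#' [belief_update_probability()] (at most one step per piece of feedback).
#' LEAVE resets the conversation-status fields; STOP ends play.
#'
#' Stochastic draws come from the session RNG (for an ask: the water-reveal
#' draw, then the belief-update draw), so episodes are reproducible under
#' `set.seed()`.
#'
#' @param state named state vector.
#' @param action an action available in `state`.
#' @param profile a [mindset_profile()] (supplies the update propensities).
#' @param env an [environment_config()].
#' @return list with elements `state` (next state) and `feedback` (list with
#'   `valence` POSITIVE/NEGATIVE/NONE, narrative `tag`, and the `age_class`
#'   concerned or `NA`).
#' @export
real_world_step <- function(state, action, profile, env = environment_config()) {
  if (!action %in% available_actions(state)) {
    stop("action ", action, " is not available in this state")
  }
  s <- state
  feedback <- list(valence = "NONE", tag = "none", age_class = NA_character_)

  if (startsWith(action, "SELECT_NPC_")) {
    s[["in_conv"]] <- 1L
    s[["npc_age"]] <- match(sub("SELECT_NPC_", "", action), AGE_CLASSES)
    s[["greeted"]] <- 0L
    s[["asked"]] <- 0L
    s[["npc_happy"]] <- 0L
  } else if (action == "LEAVE") {
    s[["in_conv"]] <- 0L
    s[["npc_age"]] <- 0L
    s[["greeted"]] <- 0L
    s[["asked"]] <- 0L
    s[["npc_happy"]] <- 0L
  } else if (action == "STOP") {
    # terminal; state unchanged
  } else {
    cls <- AGE_CLASSES_LOWER[s[["npc_age"]]]
    formal <- action %in% c("GREET_FORMAL", "ASK_FORMAL")
    happy <- identical(formal, unname(env$culture[[cls]]))
    s[["npc_happy"]] <- as.integer(happy)
    if (startsWith(action, "GREET")) s[["greeted"]] <- 1L else s[["asked"]] <- 1L
    feedback <- list(
      valence = if (happy) "POSITIVE" else "NEGATIVE",
      tag = if (happy) "nice_reply" else "subtle_frown",
      age_class = toupper(cls)
    )
    if (startsWith(action, "ASK") && s[["got_water"]] == 0L &&
        state[["asked"]] == 0L) {
      # the water request resolves once per conversation: the villager
      # either provides directions on the first ask or does not
      p_reveal <- if (happy) env$p_reveal_happy else env$p_reveal_unhappy
      if (runif(1L) < p_reveal) s[["got_water"]] <- 1L
    }
    b <- s[[cls]]
    p_upd <- belief_update_probability(profile$label, cls, b, env$culture)
    if (p_upd > 0 && runif(1L) < p_upd) {
      correct <- if (env$culture[[cls]]) 2L else -2L
      s[[cls]] <- b + as.integer(sign(correct - b))
    }
  }
  list(state = s, feedback = feedback)
}

#' The six villagers
#'
#' The roster is narrative annotation only: the state abstracts villagers to
#' their age class, and repeated conversations with the same age class are
#' allowed.
#'
#' @return data.frame with columns `name`, `gender`, `age`, `profession`
#'   (two villagers per age class).
#' @export
roster <- function() {
  data.frame(
    name = c("Stan", "Belle", "Emma", "Mick", "Brim", "Clayton"),
    gender = c("male", "female", "female", "male", "female", "male"),
    age = c("young", "young", "middle-aged", "middle-aged", "elder", "elder"),
    profession = c("Student", "Mayor", "Sheriff", "Pilot", "Nanosmith", "Farmer")
  )
}
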