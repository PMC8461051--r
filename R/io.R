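# Formats: play records as JSON Lines (one record per line, schema
# versioned), run configuration as YAML, summaries as CSV, and a plain-text
# results report.

RECORD_SCHEMA <- "mindsetmdp/1"

record_to_list <- function(record) {
  list(
    schema = RECORD_SCHEMA,
    player_id = record$player_id,
    mindset = record$mindset,
    beta = record$beta,
    run_index = record$run_index,
    seed = record$seed,
    end_reason = record$end_reason,
    steps = record$steps
  )
}

#' Write play records as JSON Lines
#'
#' One record per line. Writing the same records twice produces
#' byte-identical files.
#'
#' @param records list of [play_record()]s.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                  digits = I(17), dataframe = "columns"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read play records from JSON Lines
#'
#' @param path file written by [write_records()].
#' @return list of [play_record()]s (empty list for an empty file).
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) {
                    stop(sprintf("cannot parse record on line %d of %s: %s",
                                 i, path, conditionMessage(e)))
                  })
    if (is.null(x$schema) || !identical(x$schema, RECORD_SCHEMA)) {
      stop(sprintf("unsupported record schema on line %d: %s (expected %s)",
                   i, x$schema %||% "<missing>", RECORD_SCHEMA))
    }
    steps <- as.data.frame(x$steps)
    steps$step <- as.integer(steps$step)
    steps$state_before <- as.integer(steps$state_before)
    steps$state_after <- as.integer(steps$state_after)
    play_record(x$player_id, x$mindset, x$beta, x$run_index, x$seed,
                steps, x$end_reason)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CONFIG_KEYS <- c("version", "master_seed", "n_players_per_mindset",
                 "runs_per_player", "gamma", "solve_beta", "environment",
                 "beta_grid", "output_dir")
ENV_KEYS <- c("p_reveal_happy", "p_reveal_unhappy", "max_steps", "culture")

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults. Missing keys take the package defaults.
#'
#' @param path YAML file.
#' @return list with `config` (a [simulation_config()]), `beta_grid`, and
#'   `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  env_y <- y$environment %||% list()
  unknown_env <- setdiff(names(env_y), ENV_KEYS)
  if (length(unknown_env) > 0L) {
    stop("unknown environment keys: ", paste(unknown_env, collapse = ", "))
  }
  culture <- if (is.null(env_y$culture)) default_culture() else {
    unlist(env_y$culture)[c("young", "mid", "old")]
  }
  env <- environment_config(
    p_reveal_happy = env_y$p_reveal_happy %||% 0.8,
    p_reveal_unhappy = env_y$p_reveal_unhappy %||% 0.1,
    max_steps = env_y$max_steps %||% 50L,
    culture = culture
  )
  solve_beta <- y$solve_beta %||% Inf
  if (identical(solve_beta, "Inf")) solve_beta <- Inf
  cfg <- simulation_config(
    n_players_per_mindset = y$n_players_per_mindset %||% 50L,
    runs_per_player = y$runs_per_player %||% 20L,
    master_seed = y$master_seed %||% 1L,
    env = env, gamma = y$gamma %||% 0.98, solve_beta = solve_beta
  )
  beta_grid <- if (is.null(y$beta_grid)) default_beta_grid() else {
    exp(seq(y$beta_grid$log_min, y$beta_grid$log_max, by = y$beta_grid$step))
  }
  list(config = cfg, beta_grid = beta_grid,
       output_dir = y$output_dir %||% ".")
}

#' Write a run configuration to YAML
#'
#' Round-trips losslessly through [read_run_config()].
#'
#' @param config a [simulation_config()].
#' @param path output file.
#' @param beta_grid_spec optional list with `log_min`, `log_max`, `step`.
#' @param output_dir output directory recorded in the file.
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path, beta_grid_spec = NULL,
                             output_dir = ".") {
  y <- list(
    version = RECORD_SCHEMA,
    master_seed = config$master_seed,
    n_players_per_mindset = config$n_players_per_mindset,
    runs_per_player = config$runs_per_player,
    gamma = config$gamma,
    solve_beta = if (is.infinite(config$solve_beta)) "Inf" else config$solve_beta,
    environment = list(
      p_reveal_happy = config$env$p_reveal_happy,
      p_reveal_unhappy = config$env$p_reveal_unhappy,
      max_steps = config$env$max_steps,
      culture = as.list(config$env$culture)
    ),
    output_dir = output_dir
  )
  if (!is.null(beta_grid_spec)) y$beta_grid <- beta_grid_spec
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a plain-text results report
#'
#' Mirrors the structure of the simulation study's results: the four
#' behavioral criteria, the exploratory age-selection analysis, and the
#' classification summary (overall accuracy, confusion matrix, tie tally).
#'
#' @param comparison a [compare_mindsets()] result.
#' @param classification a [classify_records()] data.frame, or `NULL` to
#'   omit the classification section.
#' @param path output text file.
#' @param master_seed seed recorded in the provenance header.
#' @return the path, invisibly.
#' @export
write_report <- function(comparison, classification = NULL, path,
                         master_seed = NA_integer_) {
  w <- comparison$welch
  p <- comparison$proportions
  line <- function(...) sprintf(...)
  welch_line <- function(m, label) {
    r <- w[w$metric == m, ]
    line("%s: fixed %.3f (SD %.3f) vs malleable %.3f (SD %.3f); t(%.2f) = %.2f, p = %.3g, d = %.2f",
         label, r$mean_a, r$sd_a, r$mean_b, r$sd_b, r$df, r$t, r$p, r$d)
  }
  prop_line <- function(m, label) {
    r <- p[p$metric == m, ]
    line("%s: fixed %.1f%% vs malleable %.1f%%; chi-squared(%d) = %.1f, p = %.3g",
         label, 100 * r$prop_a, 100 * r$prop_b, r$df, r$chisq, r$p)
  }
  out <- c(
    "# Cultural-mindset simulation report",
    line("master seed: %s", master_seed),
    "",
    "## Cultural learning",
    welch_line("mean_learning", "mean learning score"),
    "",
    "## Efficiency and time to task completion",
    welch_line("conversations_per_game", "conversations per game"),
    welch_line("turns_per_conversation", "dialog turns per conversation"),
    "",
    "## Persistence",
    prop_line("conversational_quitting", "conversational quitting"),
    prop_line("game_quitting", "game quitting"),
    "",
    "## Responsiveness to feedback",
    prop_line("responsiveness_all_conversations",
              "responsiveness (all conversations)"),
    prop_line("responsiveness_incorrect_conversations",
              "responsiveness (conversations with an incorrect formality)"),
    "",
    "## Exploratory: villager age-class selection",
    line("fixed (Y/M/O): %s", paste(sprintf("%.3f", comparison$age_selection$proportions["fixed", ]), collapse = " / ")),
    line("malleable (Y/M/O): %s", paste(sprintf("%.3f", comparison$age_selection$proportions["malleable", ]), collapse = " / ")),
    line("chi-squared(%d) = %.1f, p = %.3g", comparison$age_selection$df,
         comparison$age_selection$chisq, comparison$age_selection$p)
  )
  if (!is.null(classification)) {
    cm <- confusion_matrix(classification)
    out <- c(
      out, "",
      "## Mindset classification",
      line("overall accuracy: %.3f (%d records, %d ties classified as fixed)",
           mean(classification$correct, na.rm = TRUE),
           nrow(classification), sum(classification$tie)),
      line("confusion matrix (rows = generating): fixed %.2f / %.2f; malleable %.2f / %.2f",
           cm["fixed", "fixed"], cm["fixed", "malleable"],
           cm["malleable", "fixed"], cm["malleable", "malleable"])
    )
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
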