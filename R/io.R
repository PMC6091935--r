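# Reading and writing survey tables and flat key-value configuration.

#' Write / read a respondent table as CSV
#'
#' The CSV schema is the column dictionary produced by [simulate_survey()];
#' `read_survey_csv()` can additionally rename columns of a deposited table
#' via a user-editable codebook, a named character vector mapping the
#' package's standard column names to the file's column names, e.g.
#' `c(claim = "claimedwin", won = "rolled6")`.
#'
#' @param data Respondent tibble.
#' @param path File path.
#' @param codebook Optional named character vector; names are the standard
#'   schema names, values the file's column names.
#' @return `read_survey_csv()` returns a tibble; `write_survey_csv()`
#'   returns `path` invisibly.
#' @export
write_survey_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path, codebook = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(codebook)) {
    missing <- setdiff(unname(codebook), names(d))
    if (length(missing)) {
      abort(sprintf("Codebook refers to absent column(s): %s.",
                    paste(missing, collapse = ", ")))
    }
    names(d)[match(codebook, names(d))] <- names(codebook)
  }
  d
}

design_to_kv <- function(design) {
  kv <- list(kind = design$kind)
  for (f in c("p_z", "p_u", "p_yes", "p_no")) {
    if (!is.null(design[[f]])) kv[[f]] <- design[[f]]
  }
  if (!is.null(design$unrelated_question)) {
    kv$unrelated_question <- design$unrelated_question
  }
  kv
}

#' Serialize a design catalogue to a flat key-value file
#'
#' Writes / reads the technique catalogue as YAML, one block per design
#' with keys `kind`, `p_z`, `p_u`, `p_yes`, `p_no`, `unrelated_question`
#' (only the keys relevant to the design's kind are present).
#'
#' @param designs Named list of [rrt_design()] objects.
#' @param path File path.
#' @return `read_design_catalogue()` returns a named list of designs;
#'   `write_design_catalogue()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yml")
#' write_design_catalogue(default_designs(), p)
#' read_design_catalogue(p)
#' @export
write_design_catalogue <- function(designs, path) {
  stopifnot(all(vapply(designs, inherits, logical(1), "rrt_design")))
  yaml::write_yaml(purrr::map(designs, design_to_kv), path, precision = 15)
  invisible(path)
}

#' @rdname write_design_catalogue
#' @export
read_design_catalogue <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(kv) {
    rrt_design(kind = kv$kind,
               p_z = kv$p_z, p_u = kv$p_u,
               p_yes = kv$p_yes, p_no = kv$p_no,
               unrelated_question = unlist(kv$unrelated_question))
  })
}

#' Serialize a simulation configuration to a flat key-value file
#'
#' Writes / reads a [simulation_config()] as YAML: scalar rates at the top
#' level, the per-technique behavior models and the design catalogue as
#' nested key-value blocks.
#'
#' @param config An `rrt_sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns an `rrt_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "rrt_sim_config"))
  kv <- list(
    n = config$n, game_split = config$game_split,
    arm_probs = as.list(config$arm_probs), win_prob = config$win_prob,
    cheat_propensity_prediction = config$cheat_propensity_prediction,
    cheat_propensity_rollsix = config$cheat_propensity_rollsix,
    behavior = purrr::map(config$behavior, unclass),
    designs = purrr::map(config$designs, design_to_kv),
    item_prevalence = as.list(config$item_prevalence),
    p_incomplete = config$p_incomplete,
    p_screener_fail = config$p_screener_fail,
    p_no_roll = config$p_no_roll,
    p_false_loser = config$p_false_loser,
    seed = config$seed
  )
  yaml::write_yaml(kv, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- yaml::read_yaml(path)
  simulation_config(
    n = kv$n, game_split = kv$game_split,
    arm_probs = unlist(kv$arm_probs), win_prob = kv$win_prob,
    cheat_propensity_prediction = kv$cheat_propensity_prediction,
    cheat_propensity_rollsix = kv$cheat_propensity_rollsix,
    behavior = purrr::map(kv$behavior, ~ do.call(behavior_model, .x)),
    designs = purrr::map(kv$designs, function(d) {
      rrt_design(d$kind, p_z = d$p_z, p_u = d$p_u, p_yes = d$p_yes,
                 p_no = d$p_no, unrelated_question = unlist(d$unrelated_question))
    }),
    item_prevalence = unlist(kv$item_prevalence),
    p_incomplete = kv$p_incomplete, p_screener_fail = kv$p_screener_fail,
    p_no_roll = kv$p_no_roll, p_false_loser = kv$p_false_loser,
    seed = kv$seed
  )
}

#' Export analysis tables as tidy CSV
#'
#' Writes the comparative, aggregate and individual analysis tables of an
#' [run_analysis()] result (item x technique x game x metric rows) to
#' `<stem>_comparative.csv`, `<stem>_aggregate.csv`,
#' `<stem>_individual.csv`, plus `<stem>_ledger.csv`.
#'
#' @param results An `rrt_results` object.
#' @param stem Path stem for the output files.
#' @return Invisibly, the paths written.
#' @export
write_results_csv <- function(results, stem) {
  stopifnot(inherits(results, "rrt_results"))
  paths <- character(0)
  for (part in c("comparative", "aggregate", "individual", "ledger")) {
    p <- paste0(stem, "_", part, ".csv")
    readr::write_csv(tibble::as_tibble(results[[part]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
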