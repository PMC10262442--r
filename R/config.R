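#' Load an item schema from a YAML or CSV dictionary
#'
#' YAML files carry an `n_levels` list (15 integers, ordered decision then
#' movement then assets); CSV files carry one row per item with an
#' `n_levels` column.
#'
#' @param path file path (`.yaml`/`.yml` or `.csv`).
#' @return an [item_schema()].
#' @export
load_item_schema <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    item_schema(as.integer(unlist(raw$n_levels)))
  } else {
    item_schema(as.integer(utils::read.csv(path)$n_levels))
  }
}

#' Load analysis settings from a YAML configuration
#'
#' Reads the keys understood by [run_analysis()] (`indices`, `outcomes`,
#' `learners`, `g_learners`, `n_folds`, `seed`, `g_bounds`, `stratify`,
#' `min_stratum_n`, `gcomp`, `n_boot`) and validates them; unknown keys
#' error, so typos cannot silently change an analysis.
#'
#' @param path YAML file path.
#' @return named list of arguments for [run_analysis()].
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("indices", "outcomes", "learners", "g_learners", "n_folds",
               "seed", "g_bounds", "stratify", "min_stratum_n", "gcomp",
               "n_boot")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown analysis config keys: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$outcomes)) {
    bad <- setdiff(raw$outcomes, outcome_spec_kinds())
    if (length(bad) > 0) {
      stop(sprintf("unknown outcome specs: %s", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(raw$g_bounds)) raw$g_bounds <- as.numeric(unlist(raw$g_bounds))
  for (nm in c("n_folds", "seed", "min_stratum_n", "n_boot")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.integer(raw[[nm]])
  }
  for (nm in c("indices", "outcomes", "learners", "g_learners")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.character(unlist(raw[[nm]]))
  }
  raw
}
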