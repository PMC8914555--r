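config_schema <- function() {
  list(
    seed = list(default = 1L, check = function(v) is.numeric(v)),
    generator = list(
      n_per_class = list(default = 30L,
                         check = function(v) is.numeric(v) && v >= 2),
      heavy_tail_threshold = list(default = 0.5,
                                  check = function(v) is.numeric(v) && v > 0),
      use_printed_chicken_fe = list(default = FALSE,
                                    check = is.logical),
      correlation = list(default = 0,
                         check = function(v) is.numeric(v) && v >= 0 && v < 1)),
    dataset = list(
      kind = list(default = "absolute",
                  allowed = c("absolute", "relative"))),
    normalization = list(
      scope = list(default = "whole_dataset",
                   allowed = c("whole_dataset", "training_only"))),
    selection = list(
      method = list(default = "anova", allowed = c("anova", "swda")),
      alpha = list(default = 0.05,
                   check = function(v) is.numeric(v) && v > 0 && v < 1),
      f_enter = list(default = 3.84, check = function(v) is.numeric(v)),
      f_remove = list(default = 2.71, check = function(v) is.numeric(v))),
    reduction = list(
      method = list(default = "pca", allowed = c("pca", "fisher_lda")),
      n_components = list(default = NULL,
                          check = function(v) is.null(v) ||
                            (is.numeric(v) && v >= 1))),
    split = list(
      fraction = list(default = 1 / 3,
                      check = function(v) is.numeric(v) && v > 0 && v < 1),
      space = list(default = "model_input",
                   allowed = c("model_input", "raw_standardized"))),
    elm = list(
      activation = list(default = "sig",
                        allowed = c("sig", "sin", "hardlim")),
      l_min = list(default = 1L,
                   check = function(v) is.numeric(v) && v >= 1),
      l_max = list(default = 100L,
                   check = function(v) is.numeric(v) && v >= 1),
      output_encoding = list(default = "onehot",
                             allowed = c("onehot", "label"))),
    experiment = list(
      n_reps = list(default = 12L,
                    check = function(v) is.numeric(v) && v >= 1)))
}

is_leaf_spec <- function(x) {
  is.list(x) && ("default" %in% names(x)) &&
    (("allowed" %in% names(x)) || ("check" %in% names(x)))
}

validate_against <- function(schema, values, path) {
  for (key in names(values)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(schema)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    spec <- schema[[key]]
    if (is_leaf_spec(spec)) {
      v <- values[[key]]
      if (!is.null(spec$allowed)) {
        if (!is.character(v) || length(v) != 1L || !v %in% spec$allowed) {
          stop("config key ", full, " must be one of: ",
               paste(spec$allowed, collapse = ", "), call. = FALSE)
        }
      } else if (!is.null(spec$check) && !isTRUE(spec$check(v))) {
        stop("invalid value for config key ", full, call. = FALSE)
      }
    } else {
      if (!is.list(values[[key]])) {
        stop("config key ", full, " must be a mapping", call. = FALSE)
      }
      validate_against(spec, values[[key]], c(path, key))
    }
  }
}

schema_defaults <- function(schema) {
  out <- list()
  for (key in names(schema)) {
    spec <- schema[[key]]
    out[key] <- if (is_leaf_spec(spec)) list(spec$default)
                else list(schema_defaults(spec))
  }
  out
}

merge_config <- function(defaults, values) {
  for (key in names(values)) {
    if (is.list(defaults[[key]]) && is.list(values[[key]]) &&
        !is_leaf_spec(values[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], values[[key]])
    } else {
      defaults[key] <- values[key]
    }
  }
  defaults
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML file of nested option overrides, validates every key
#' against the pipeline schema (unknown keys and out-of-range values are
#' rejected with the allowed alternatives named), and merges it over the
#' defaults. With `path = NULL` the pure defaults are returned.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return A nested `run_config` list (`seed`, `generator`, `dataset`,
#'   `normalization`, `selection`, `reduction`, `split`, `elm`,
#'   `experiment`).
#' @export
load_config <- function(path = NULL) {
  schema <- config_schema()
  cfg <- schema_defaults(schema)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    validate_against(schema, user, character(0))
    cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

#' Translate a run config into `run_grid()` options
#'
#' @param config A `run_config` from [load_config()].
#' @return Named list accepted by the `options` argument of
#'   [run_grid()] / [run_configuration()].
#' @export
as_run_options <- function(config) {
  stopifnot(inherits(config, "run_config"))
  list(alpha = config$selection$alpha,
       f_enter = config$selection$f_enter,
       f_remove = config$selection$f_remove,
       l_range = c(as.integer(config$elm$l_min),
                   as.integer(config$elm$l_max)),
       output_encoding = config$elm$output_encoding,
       test_fraction = config$split$fraction,
       split_space = config$split$space,
       n_components = config$reduction$n_components)
}

#' Tabulate ratio-of-means consistency for every summary cell
#'
#' For each (species, element) cell, compares the ratio-of-means fraction
#' computed from the absolute summary (see [relative_consistency()]) with
#' the packaged relative mean.
#'
#' @param summary_abs,summary_rel Class summaries (defaults: packaged
#'   references).
#' @return Data frame with columns `species`, `element`,
#'   `ratio_of_means`, `relative_mean`, `deviation` (relative),
#'   `flagged` (deviation above 10%).
#' @export
consistency_table <- function(summary_abs = load_reference_summary("absolute"),
                              summary_rel = load_reference_summary("relative")) {
  rows <- lapply(species_levels(), function(sp) {
    do.call(rbind, lapply(element_panel(), function(el) {
      ratio <- relative_consistency(summary_abs, summary_rel, sp, el)
      ref <- summary_cell(summary_rel, sp, el)$mean
      data.frame(species = sp, element = el, ratio_of_means = ratio,
                 relative_mean = ref, deviation = abs(ratio - ref) / ref,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$deviation > 0.10
  out
}
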