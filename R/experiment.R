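#' The 24 pipeline configuration keys
#'
#' Full factorial of 2 dataset kinds x 2 selectors x 2 reducers x 3
#' activations, in canonical report order (dataset outermost, activation
#' innermost). With 12 repetitions per configuration the grid totals 288
#' model fits.
#'
#' @return Data frame with columns `config_id`, `dataset_kind`,
#'   `selector`, `reducer`, `activation` (24 rows).
#' @export
config_keys <- function() {
  grid <- expand.grid(activation = c("hardlim", "sig", "sin"),
                      reducer = c("pca", "fisher_lda"),
                      selector = c("anova", "swda"),
                      dataset_kind = c("absolute", "relative"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("dataset_kind", "selector", "reducer", "activation")]
  cbind(config_id = seq_len(nrow(grid)), grid)
}

default_run_options <- function() {
  list(alpha = 0.05, f_enter = 3.84, f_remove = 2.71,
       l_range = c(1L, 100L), output_encoding = "onehot",
       normalization_scope = "whole_dataset", test_fraction = 1 / 3,
       split_space = "model_input", n_components = NULL)
}

merge_options <- function(options) {
  base <- default_run_options()
  if (length(options) == 0L) return(base)
  unknown <- setdiff(names(options), names(base))
  if (length(unknown) > 0L) {
    stop("unknown run option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(options)] <- options
  base
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

# Per-(configuration, repetition) ELM seeds. One master seed spawns the
# full 24 x n_reps seed matrix, so a single configuration run reproduces
# exactly the corresponding slice of a full grid run.
rep_seed_matrix <- function(master_seed, n_reps) {
  set.seed(as.integer(master_seed))
  matrix(sample.int(.Machine$integer.max - 1L, 24L * n_reps),
         nrow = 24L, ncol = n_reps)
}

config_index <- function(dataset_kind, selector, reducer, activation) {
  keys <- config_keys()
  i <- which(keys$dataset_kind == dataset_kind & keys$selector == selector &
             keys$reducer == reducer & keys$activation == activation)
  if (length(i) != 1L) stop("invalid configuration key", call. = FALSE)
  i
}

# Deterministic part of a branch: kind transform, Z-score, selection,
# reduction, Kennard-Stone split. Shared by all repetitions.
prepare_branch <- function(profiles, dataset_kind, selector, reducer, opts) {
  tbl <- with_stage("dataset_kind", {
    if (dataset_kind == "relative") to_relative(profiles) else profiles
  })
  std <- with_stage("normalization", {
    zscore_apply(tbl, zscore_fit(tbl, scope = "whole_dataset"))
  })
  sel <- with_stage("selection", {
    if (selector == "anova") anova_screen(std, alpha = opts$alpha)
    else swda(std, f_enter = opts$f_enter, f_remove = opts$f_remove)
  })
  if (length(sel$selected) == 0L) {
    stop("stage 'selection': no element passed the ", selector,
         " criterion", call. = FALSE)
  }
  Xsel <- as.matrix(std[, sel$selected, drop = FALSE])
  y <- as.character(std$species)
  model <- with_stage("reduction", {
    if (reducer == "pca") fit_pca(Xsel) else fit_lda(Xsel, y)
  })
  k <- min(retained_components(reducer, dataset_kind, selector,
                               override = opts$n_components),
           ncol(model$basis))
  scores <- project(model, Xsel, k)
  split_X <- if (opts$split_space == "raw_standardized") {
    profile_matrix(std)
  } else {
    scores
  }
  split <- with_stage("split", {
    stratified_split(split_X, y, test_fraction = opts$test_fraction)
  })
  list(scores = scores, y = y, split = split, selection = sel,
       model = model, k = k)
}

#' Run one pipeline configuration over repeated ELM fits
#'
#' Applies the branch pipeline in order — dataset kind transform,
#' Z-score, element selection, dimension reduction with the branch
#' default component count, species-stratified Kennard-Stone split — then
#' fits and tunes one ELM per repetition. The deterministic stages are
#' computed once; only the ELM's random input weights vary across
#' repetitions, each drawing a seed from the master seed's
#' per-(configuration, repetition) stream.
#'
#' @param profiles Absolute-content [element_profile()] table.
#' @param dataset_kind `"absolute"` or `"relative"`.
#' @param selector `"anova"` or `"swda"`.
#' @param reducer `"pca"` or `"fisher_lda"`.
#' @param activation `"hardlim"`, `"sig"` or `"sin"`.
#' @param n_reps Repetitions (default 12).
#' @param master_seed Master seed for the repetition seed streams.
#' @param options Named list overriding [pipeline defaults][run_grid]
#'   (alpha, f_enter, f_remove, l_range, output_encoding, test_fraction,
#'   split_space, n_components).
#' @return A `config_result` list with the per-repetition test accuracies
#'   (and their mean/SD), tuned hidden sizes, train accuracies, the
#'   selection and projection objects and the split.
#' @export
run_configuration <- function(profiles, dataset_kind, selector, reducer,
                              activation, n_reps = 12L, master_seed = 1L,
                              options = list()) {
  stopifnot(n_reps >= 1L)
  opts <- merge_options(options)
  branch <- prepare_branch(profiles, dataset_kind, selector, reducer, opts)
  cfg_i <- config_index(dataset_kind, selector, reducer, activation)
  seeds <- rep_seed_matrix(master_seed, n_reps)[cfg_i, ]
  Xtr <- branch$scores[branch$split$train, , drop = FALSE]
  Xte <- branch$scores[branch$split$test, , drop = FALSE]
  ytr <- branch$y[branch$split$train]
  yte <- branch$y[branch$split$test]
  reps <- lapply(seq_len(n_reps), function(r) {
    with_stage("elm", {
      tuned <- tune_hidden(Xtr, ytr, Xte, yte, activation = activation,
                           l_range = opts$l_range, seed = seeds[r],
                           output_encoding = opts$output_encoding)
      data.frame(rep = r, best_l = tuned$best_l,
                 train_accuracy = tuned$train_accuracy,
                 test_accuracy = tuned$test_accuracy)
    })
  })
  reps <- do.call(rbind, reps)
  acc <- reps$test_accuracy
  structure(list(
    dataset_kind = dataset_kind, selector = selector, reducer = reducer,
    activation = activation, config_id = cfg_i,
    accuracies = acc, mean = mean(acc),
    sd = if (n_reps > 1L) stats::sd(acc) else 0,
    sd_defined = n_reps > 1L,
    reps = reps, n_reps = n_reps,
    selection = branch$selection, model = branch$model,
    n_components = branch$k, split = branch$split,
    input_dim = branch$k,
    output_dim = if (opts$output_encoding == "label") 1L
                 else length(unique(branch$y))),
    class = "config_result")
}

#' Run the full configuration grid
#'
#' Evaluates every configuration in [config_keys()] (or a subset) with
#' `n_reps` repetitions each — 24 x 12 = 288 ELM fits at the defaults —
#' and assembles a report with per-configuration mean and SD accuracy,
#' compact significance letters, pooled comparisons by reducer and by
#' dataset kind, and the single best run.
#'
#' @inheritParams run_configuration
#' @param keys Subset of [config_keys()] rows to run (default: all 24).
#' @param alpha Significance level for the letter display.
#' @return A `grid_report` list: `summary` (one row per configuration
#'   with mean, sd, letter), `runs` (one row per fit), `pooled`
#'   (by-reducer and by-dataset aggregates), `best` (see
#'   [best_model_summary()]), `total_fits`, `n_reps`, `master_seed`.
#' @export
run_grid <- function(profiles, n_reps = 12L, master_seed = 1L,
                     keys = config_keys(), options = list(), alpha = 0.05) {
  results <- lapply(seq_len(nrow(keys)), function(i) {
    run_configuration(profiles,
                      dataset_kind = keys$dataset_kind[i],
                      selector = keys$selector[i],
                      reducer = keys$reducer[i],
                      activation = keys$activation[i],
                      n_reps = n_reps, master_seed = master_seed,
                      options = options)
  })
  runs <- do.call(rbind, lapply(results, function(r) {
    cbind(config_id = r$config_id, dataset_kind = r$dataset_kind,
          selector = r$selector, reducer = r$reducer,
          activation = r$activation, r$reps,
          input_dim = r$input_dim, output_dim = r$output_dim)
  }))
  summary_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(config_id = r$config_id, dataset_kind = r$dataset_kind,
               selector = r$selector, reducer = r$reducer,
               activation = r$activation, mean = r$mean, sd = r$sd,
               stringsAsFactors = FALSE)
  }))
  pooled <- list(
    by_reducer = stats::aggregate(test_accuracy ~ reducer, runs,
                                  function(v) c(mean = mean(v),
                                                sd = stats::sd(v))),
    by_dataset = stats::aggregate(test_accuracy ~ dataset_kind, runs,
                                  function(v) c(mean = mean(v),
                                                sd = stats::sd(v))))
  report <- structure(list(summary = summary_df, runs = runs,
                           results = results, pooled = pooled,
                           total_fits = nrow(runs), n_reps = n_reps,
                           master_seed = master_seed),
                      class = "grid_report")
  if (nrow(keys) >= 2L && n_reps >= 2L) {
    report$summary$letter <- grid_letters(report, alpha = alpha)
  }
  report$best <- best_model_summary(report)
  report
}

#' Compact significance letters across grid configurations
#'
#' One-way ANOVA of the repetition accuracies across configurations,
#' followed by Tukey HSD and a compact letter display (see
#' [compact_letter_display()]): configurations sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param report A `grid_report`.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of letters aligned with `report$summary`.
#' @export
grid_letters <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "grid_report"))
  runs <- report$runs
  lab <- sprintf("c%02d", runs$config_id)
  cld <- compact_letter_display(runs$test_accuracy, lab, alpha = alpha)
  unname(cld[sprintf("c%02d", report$summary$config_id)])
}

#' Best single run of a grid
#'
#' The repetition with the highest test accuracy; ties break toward the
#' higher training accuracy, then toward the canonical configuration
#' order. Reports the network structure as
#' "input dim - hidden neurons - output dim" (one output neuron under
#' label coding, one per class under one-hot).
#'
#' @param report A `grid_report`.
#' @return List with the winning configuration key, repetition, hidden
#'   size, structure string, and train/test accuracy and misclassified
#'   counts.
#' @export
best_model_summary <- function(report) {
  stopifnot(inherits(report, "grid_report"))
  runs <- report$runs
  ord <- order(-runs$test_accuracy, -runs$train_accuracy, runs$config_id,
               runs$rep)
  w <- runs[ord[1L], ]
  res <- report$results[[which(vapply(report$results, function(r) {
    r$config_id == w$config_id
  }, logical(1)))[1L]]]
  n_te <- length(res$split$test)
  n_tr <- length(res$split$train)
  list(dataset_kind = w$dataset_kind, selector = w$selector,
       reducer = w$reducer, activation = w$activation, rep = w$rep,
       best_l = w$best_l,
       structure = sprintf("%d-%d-%d", w$input_dim, w$best_l, w$output_dim),
       train_accuracy = w$train_accuracy, test_accuracy = w$test_accuracy,
       train_misclassified = round((100 - w$train_accuracy) / 100 * n_tr),
       test_misclassified = round((100 - w$test_accuracy) / 100 * n_te))
}

#' @export
print.grid_report <- function(x, ...) {
  cat(sprintf("<grid_report> %d configurations x %d repetitions = %d fits (master seed %d)\n",
              nrow(x$summary), x$n_reps, x$total_fits, x$master_seed))
  df <- x$summary
  df$mean <- sprintf("%.1f", df$mean)
  df$sd <- sprintf("%.2f", df$sd)
  print(df, row.names = FALSE)
  if (!is.null(x$best)) {
    cat(sprintf("best run: %s/%s/%s/%s rep %d, structure %s, train %.1f%%, test %.1f%%\n",
                x$best$dataset_kind, x$best$selector, x$best$reducer,
                x$best$activation, x$best$rep, x$best$structure,
                x$best$train_accuracy, x$best$test_accuracy))
  }
  invisible(x)
}
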