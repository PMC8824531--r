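# Configuration, orchestration, input validation, and the command-line
# surface (see inst/cli/eegdecode for the executable wrapper).

#' Validate an epoch set against the pipeline's inclusion rules
#'
#' Checks per-class trial counts against the minimum (default 20),
#' sample finiteness, and region coverage. Reports violations without
#' mutating the data.
#'
#' @param ep an [epoch_set()].
#' @param min_trials per-class minimum (default 20).
#' @param rmap optional [region_map()] to check coverage for.
#' @return list with `ok` and a character vector `violations`; non-
#'   finite samples are located by (trial, channel, sample).
#' @export
validate_input <- function(ep, min_trials = 20, rmap = NULL) {
  v <- character(0)
  cnt <- table(ep$labels)
  if (length(cnt) < 2) {
    v <- c(v, sprintf("only %d class(es); need >= 2", length(cnt)))
  }
  low <- names(cnt)[cnt < min_trials]
  for (cl in low) {
    v <- c(v, sprintf("class %s has %d trials; minimum is %d",
                      cl, cnt[[cl]], min_trials))
  }
  bad <- which(!is.finite(ep$data), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    for (i in seq_len(min(nrow(bad), 10))) {
      v <- c(v, sprintf("non-finite sample at trial %d, channel %d (%s), sample %d",
                        bad[i, 1], bad[i, 2],
                        ep$channel_names[bad[i, 2]], bad[i, 3]))
    }
    if (nrow(bad) > 10) v <- c(v, sprintf("... %d more", nrow(bad) - 10))
  }
  if (!is.null(rmap)) {
    cov <- tryCatch({ region_indices(rmap, ep$channel_names); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(cov)) v <- c(v, cov)
  }
  list(ok = length(v) == 0, violations = v)
}

#' Full pipeline configuration from a JSON file or list
#'
#' Keys mirror the arguments of [pipeline_config()],
#' [cross_validate_pipeline()] and [synthetic_spec()]: `data` (exchange
#' directory) or `synthetic` (spec fields), `families`, `selection`,
#' `n_filter`, `n_select`, `balance`, `classifier`, `multiclass`,
#' `cv_folds`, `permutations`, `min_trials`, `seed`.
#'
#' @param path JSON file, or a list with the same structure.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else path
  known <- c("data", "synthetic", "families", "selection", "n_filter",
             "n_select", "balance", "k_neighbors", "classifier",
             "classifier_params", "multiclass", "cv_folds", "permutations",
             "min_trials", "seed", "out_dir", "norm_pool", "window")
  bad <- setdiff(names(cfg), known)
  abort_if(length(bad) > 0, "unknown config key(s): %s",
           paste(bad, collapse = ", "))
  defaults <- list(families = FEATURE_FAMILIES, selection = "filter+wrapper",
                   n_filter = 100, n_select = 10, balance = TRUE,
                   k_neighbors = 5, classifier = "naive_bayes",
                   multiclass = "tree", cv_folds = 5, permutations = 0,
                   min_trials = 20, seed = 0, norm_pool = "train",
                   window = list(start = 0, end = 2000,
                                 width = 400, step = 200))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  abort_if(!cfg$classifier %in% c("naive_bayes", "lasso", "logistic",
                                  "linear_svm"),
           "unknown classifier '%s'", cfg$classifier)
  abort_if(!cfg$selection %in% c("none", "filter", "filter+wrapper"),
           "unknown selection method '%s'", cfg$selection)
  abort_if(!cfg$multiclass %in% c("voting", "tree"),
           "unknown multiclass method '%s'", cfg$multiclass)
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Loads (or generates) epochs, validates them, runs the cross-validated
#' evaluation (plus the permutation chance level when `permutations` >
#' 0), and writes `report.json` and a structured log to `out_dir` when
#' given.
#'
#' @param config path to a JSON config or an equivalent list
#'   ([read_run_config()]).
#' @param out_dir output directory (overrides the config key).
#' @return the `evaluation_report` (with `chance_level` attached when
#'   permutations were run).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    options(eegdecode.log_file = file.path(out_dir, "run.log"))
    on.exit(options(eegdecode.log_file = NULL))
  }
  log_msg("run", "start (seed %d)", cfg$seed)
  if (!is.null(cfg$synthetic)) {
    sargs <- cfg$synthetic
    if (!is.null(sargs$n_trials)) {
      sargs$n_trials <- unlist(sargs$n_trials)
      storage.mode(sargs$n_trials) <- "integer"
    }
    sargs$seed <- sargs$seed %||% cfg$seed
    spec <- do.call(synthetic_spec, sargs)
    ep <- generate_epochs(spec)$epochs
    log_msg("data", "generated %d synthetic trials", n_trials(ep))
  } else {
    abort_if(is.null(cfg$data), "config needs `data` or `synthetic`")
    ep <- read_epochs(cfg$data)
    log_msg("data", "loaded %d trials from %s", n_trials(ep), cfg$data)
  }
  val <- validate_input(ep, cfg$min_trials)
  if (!val$ok) {
    for (v in val$violations) log_msg("validate", "%s", v)
    stop(paste(c("input validation failed:", val$violations),
               collapse = "\n  "), call. = FALSE)
  }
  pcfg <- pipeline_config(
    selection = cfg$selection, n_filter = cfg$n_filter,
    n_select = cfg$n_select, balance = cfg$balance,
    k_neighbors = cfg$k_neighbors,
    classifier = do.call(classifier_spec,
                         c(list(kind = cfg$classifier),
                           cfg$classifier_params %||% list())),
    seed = cfg$seed)
  grid <- make_window_grid(cfg$window$start, cfg$window$end,
                           cfg$window$width, cfg$window$step)
  report <- cross_validate_pipeline(
    ep, pcfg, outer_folds = cfg$cv_folds, grid = grid,
    multiclass = cfg$multiclass, min_trials = cfg$min_trials,
    families = cfg$families, norm_pool = cfg$norm_pool)
  if (cfg$permutations > 0) {
    ch <- permutation_chance_level(ep, pcfg, n_perm = cfg$permutations,
                                   seed = derive_seed(cfg$seed, "chance"),
                                   outer_folds = cfg$cv_folds, grid = grid,
                                   multiclass = cfg$multiclass,
                                   min_trials = cfg$min_trials,
                                   families = cfg$families,
                                   norm_pool = cfg$norm_pool)
    report$chance_level <- ch$chance_level
    report$chance_percentile <- ch$percentile
    report$n_perm <- ch$n_perm
  }
  log_msg("run", "mean balanced accuracy %.4f", report$mean_balanced_accuracy)
  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write an evaluation report as JSON (timestamps excluded)
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  obj <- list(
    mean_balanced_accuracy = report$mean_balanced_accuracy,
    fold_balanced_accuracy = report$fold_balanced_accuracy,
    n_trials = report$n_trials, n_classes = report$n_classes,
    outer_folds = report$outer_folds, multiclass = report$multiclass,
    seed = report$seed, leaky_normalization = report$leaky_normalization,
    chance_level = report$chance_level,
    selection = lapply(report$fold_logs, function(l) {
      if (!is.null(l$selection) && inherits(l$selection, "selection_result")) {
        list(method = l$selection$method, selected = l$selection$selected)
      } else NULL
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic data to an exchange directory),
#' `extract` (feature matrix TSV), `run` (full evaluation), `chance`
#' (permutation null), `inspect` (pretty-print a report). Exit codes:
#' 0 success, 1 validation error, 2 runtime error.
#'
#' @param args command-line arguments (default: `commandArgs()`).
#' @return exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: eegdecode <generate|extract|run|chance|inspect> --config FILE [--out DIR] [--seed N]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--report", type = "character", default = NULL))),
    args = args[-1])
  status <- tryCatch({
    if (cmd == "inspect") {
      abort_if(is.null(opts$report), "inspect needs --report FILE")
      rep <- jsonlite::read_json(opts$report, simplifyVector = TRUE)
      cat(jsonlite::toJSON(rep, pretty = TRUE, auto_unbox = TRUE), "\n")
      return(invisible(0L))
    }
    abort_if(is.null(opts$config), "%s needs --config FILE", cmd)
    cfg <- read_run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- opts$seed
    switch(cmd,
      generate = {
        abort_if(is.null(cfg$synthetic), "generate needs a `synthetic` block")
        sargs <- cfg$synthetic
        if (!is.null(sargs$n_trials)) {
          sargs$n_trials <- unlist(sargs$n_trials)
          storage.mode(sargs$n_trials) <- "integer"
        }
        sargs$seed <- sargs$seed %||% cfg$seed
        gen <- generate_epochs(do.call(synthetic_spec, sargs))
        abort_if(is.null(opts$out), "generate needs --out DIR")
        write_epochs(gen$epochs, opts$out)
        message("wrote ", opts$out)
      },
      extract = {
        abort_if(is.null(cfg$data), "extract needs `data` in the config")
        ep <- read_epochs(cfg$data)
        fm <- extract_all(ep, families = cfg$families)
        abort_if(is.null(opts$out), "extract needs --out DIR")
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_feature_matrix(fm, file.path(opts$out, "features.tsv"))
        message("wrote ", file.path(opts$out, "features.tsv"))
      },
      run = {
        run_pipeline(cfg, out_dir = opts$out)
      },
      chance = {
        cfg$permutations <- max(cfg$permutations, 20)
        run_pipeline(cfg, out_dir = opts$out)
      },
      stop(usage, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("validation", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}
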