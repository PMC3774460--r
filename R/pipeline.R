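#' Pipeline orchestration and reporting
#'
#' One call runs the full evaluation chain: load (or simulate) the hospital
#' matrix, tendency-normalize it, weight it (published hierarchy weights or
#' user AHP judgments at levels 1-2, entropy weights at level 3), score and
#' rank with weighted TOPSIS, train the network surrogate with LOOCV, and
#' benchmark PLSR.  Every artifact is a plain CSV (full precision) plus a
#' timestamped text log; the run is deterministic given the seed.
#'
#' @name cli_reporting
NULL

#' Pipeline run configuration
#'
#' @param hierarchy path to a hierarchy JSON, or an `indicator_hierarchy`;
#'   `NULL` uses the packaged configuration.
#' @param matrix path to a hospital-matrix CSV, or a numeric matrix; `NULL`
#'   simulates one with [simulate_hospitals()].
#' @param out_dir output directory (created if absent).
#' @param seed integer seed driving simulation and training (mandatory for
#'   any stochastic stage).
#' @param use_entropy recompute level-3 weights from the data (`TRUE`,
#'   default) or keep the hierarchy's stored level-3 weights.
#' @param pairwise_l1,pairwise_l2 optional AHP judgment matrices (see
#'   [hybrid_weights()]); `NULL` keeps the hierarchy's stored level-1/2
#'   weights.
#' @param hidden hidden sizes to try; `NULL` uses
#'   [hidden_size_candidates()] for the data dimensions.
#' @param train_cfg a [train_config()]; its seed is overridden by `seed`.
#' @param plsr_components PLSR component count; `NULL` selects by LOOCV.
#' @return a `run_config` list.
#' @export
run_config <- function(hierarchy = NULL, matrix = NULL, out_dir = tempfile("hospeval_"),
                       seed = 1L, use_entropy = TRUE,
                       pairwise_l1 = NULL, pairwise_l2 = NULL,
                       hidden = NULL, train_cfg = train_config(),
                       plsr_components = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(hierarchy = hierarchy, matrix = matrix, out_dir = out_dir,
                 seed = as.integer(seed), use_entropy = isTRUE(use_entropy),
                 pairwise_l1 = pairwise_l1, pairwise_l2 = pairwise_l2,
                 hidden = hidden, train_cfg = train_cfg,
                 plsr_components = plsr_components),
            class = "run_config")
}

#' Run the full evaluation pipeline
#'
#' Stages: load/validate hierarchy -> load or simulate matrix -> tendency
#' normalization -> weighting -> weighted TOPSIS -> hidden-size selection by
#' LOOCV -> network LOOCV report -> PLSR baseline and error table.  Artifacts
#' written under `cfg$out_dir`: `weights.csv`, `normalized.csv`,
#' `topsis.csv`, `hidden_sizes.csv`, `cv_folds.csv`, `plsr_error_table.csv`,
#' `summary.json`, `run.log`.
#'
#' @param cfg a [run_config()].
#' @param select_hidden try every candidate size (slow) instead of the
#'   single default size 10; default `FALSE`.
#' @return invisible list with all stage objects and `artifacts` (paths).
#' @export
run_pipeline <- function(cfg, select_hidden = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  logmsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...), con)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " start")
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        logmsg("stage ", name, " FAILED: ", conditionMessage(e))
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        logmsg("stage ", name, " warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  h <- stage("hierarchy", {
    if (inherits(cfg$hierarchy, "indicator_hierarchy")) cfg$hierarchy
    else if (is.null(cfg$hierarchy)) hubei_hierarchy()
    else load_hierarchy(cfg$hierarchy)
  })
  logmsg("hierarchy: ", length(leaf_ids(h)), " leaves")

  sim <- NULL
  m <- stage("matrix", {
    if (is.matrix(cfg$matrix)) cfg$matrix
    else if (is.null(cfg$matrix)) {
      sim <- simulate_hospitals(sim_config(seed = cfg$seed), h)
      logmsg("simulated ", nrow(sim$matrix), " hospitals (seed ", cfg$seed, ")")
      sim$matrix
    } else read_matrix_csv(cfg$matrix)
  })

  nm <- stage("normalize", normalize_matrix(m, h))
  w <- stage("weights", {
    if (cfg$use_entropy || !is.null(cfg$pairwise_l1) || !is.null(cfg$pairwise_l2)) {
      hybrid_weights(nm, h, cfg$pairwise_l1, cfg$pairwise_l2)
    } else comprehensive_weights(h)
  })
  top <- stage("topsis", weighted_topsis(nm, w))

  tc <- cfg$train_cfg
  tc$seed <- cfg$seed
  hs <- NULL
  hidden <- 10L
  if (select_hidden) {
    cand <- cfg$hidden %||% hidden_size_candidates(ncol(m), 1)
    hs <- stage("select_hidden", select_hidden_size(m, top$C_i, cand, tc))
    hidden <- hs$best
    logmsg("selected hidden size ", hidden)
  } else if (!is.null(cfg$hidden)) {
    hidden <- cfg$hidden[1]
  }
  cv <- stage("loocv", loocv(m, top$C_i, hidden, tc))
  pl <- stage("plsr", plsr_loocv(m, top$C_i, cfg$plsr_components))
  et <- stage("error_table", error_table(pl$folds$observed, pl$folds$predicted,
                                         pl$folds$held_out))

  art <- list(
    weights = file.path(cfg$out_dir, "weights.csv"),
    normalized = file.path(cfg$out_dir, "normalized.csv"),
    topsis = file.path(cfg$out_dir, "topsis.csv"),
    cv_folds = file.path(cfg$out_dir, "cv_folds.csv"),
    plsr_error_table = file.path(cfg$out_dir, "plsr_error_table.csv"),
    summary = file.path(cfg$out_dir, "summary.json"),
    log = log_path)
  utils::write.csv(data.frame(id = names(w), comprehensive_weight = as.numeric(w)),
                   art$weights, row.names = FALSE, quote = FALSE)
  write_matrix_csv(nm, art$normalized)
  utils::write.csv(as.data.frame(top), art$topsis, row.names = FALSE, quote = FALSE)
  utils::write.csv(cv$folds, art$cv_folds, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(et), art$plsr_error_table, row.names = FALSE,
                   quote = FALSE)
  if (select_hidden) {
    art$hidden_sizes <- file.path(cfg$out_dir, "hidden_sizes.csv")
    utils::write.csv(hs$table, art$hidden_sizes, row.names = FALSE, quote = FALSE)
  }
  summary <- list(seed = cfg$seed, n_hospitals = nrow(m),
                  n_indicators = ncol(m), hidden = hidden,
                  bpnn = list(r2 = cv$r2, rmse = cv$rmse, mape = cv$mape),
                  plsr = list(r2 = pl$r2, rmse = pl$rmse, mape = pl$mape,
                              components = pl$components))
  jsonlite::write_json(summary, art$summary, auto_unbox = TRUE, digits = NA)
  logmsg(sprintf("done: BPNN pooled R2 %.4f vs PLSR %.4f", cv$r2, pl$r2))

  invisible(list(hierarchy = h, matrix = m, normalized = nm, weights = w,
                 topsis = top, hidden = hidden, hidden_table = hs,
                 cv = cv, plsr = pl, error_table = et, quality = sim$quality,
                 artifacts = art))
}

#' Command-line entry point
#'
#' Thin wrapper over [run_pipeline()]; see `inst/cli/hospeval.R` for the
#' executable script.  Flags: `--hierarchy`, `--matrix`, `--out`, `--seed`,
#' `--hidden`, `--algorithm {lm,gd}`, `--plsr-components`,
#' `--select-hidden`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, 0 on success (invisibly).
#' @export
hospeval_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the CLI requires the 'optparse' package", call. = FALSE)
  }
  parser <- optparse::OptionParser(
    prog = "hospeval",
    description = "Hospital performance evaluation: TOPSIS + neural-network surrogate")
  parser <- optparse::add_option(parser, "--hierarchy", type = "character",
                                 default = NULL, help = "hierarchy JSON [packaged default]")
  parser <- optparse::add_option(parser, "--matrix", type = "character",
                                 default = NULL, help = "hospital matrix CSV [simulate]")
  parser <- optparse::add_option(parser, "--out", type = "character",
                                 default = "hospeval_out", help = "output directory")
  parser <- optparse::add_option(parser, "--seed", type = "integer", default = 1L)
  parser <- optparse::add_option(parser, "--hidden", type = "integer", default = 10L)
  parser <- optparse::add_option(parser, "--algorithm", type = "character",
                                 default = "lm", help = "lm or gd")
  parser <- optparse::add_option(parser, "--plsr-components", type = "integer",
                                 default = NULL, dest = "plsr_components")
  parser <- optparse::add_option(parser, "--select-hidden", action = "store_true",
                                 default = FALSE, dest = "select_hidden",
                                 help = "sweep hidden sizes by LOOCV")
  opt <- optparse::parse_args(parser, args = args)
  res <- tryCatch({
    cfg <- run_config(hierarchy = opt$hierarchy, matrix = opt$matrix,
                      out_dir = opt$out, seed = opt$seed, hidden = opt$hidden,
                      train_cfg = train_config(algorithm = opt$algorithm),
                      plsr_components = opt$plsr_components)
    run_pipeline(cfg, select_hidden = opt$select_hidden)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(1L))
  }
  cat("TOPSIS ranking:\n")
  print(rank_table(res$topsis))
  cat(sprintf("\nBPNN (41-%d-1) LOOCV pooled R2 = %.4f, RMSE = %.4f\n",
              res$hidden, res$cv$r2, res$cv$rmse))
  cat(sprintf("PLSR (%d components) LOOCV pooled R2 = %.4f, RMSE = %.4f\n",
              res$plsr$components, res$plsr$r2, res$plsr$rmse))
  cat("artifacts in ", normalizePath(res$artifacts$log, mustWork = FALSE), "\n")
  invisible(0L)
}
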