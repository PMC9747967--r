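# End-to-end orchestration: configuration, staged execution with
# logging, artifact writing, and a reproducibility manifest.

.default_config <- function() {
  list(
    input_dir = NULL,            # NULL => simulate
    out_dir = NULL,
    sim = list(),                # overrides for sim_config()
    qc = list(),                 # overrides for qc_params()
    markers = default_leukocyte_markers(),
    cytokines = default_cytokines(),
    signatures = list(fc_cuts = as.list(default_fc_cuts()),
                      p_cut = 0.05, padj_cut = 0.05,
                      spatial_fc_cut = 1, spatial_p_cut = 0.05,
                      use_adjusted = TRUE,
                      literature = list()),
    dge = list(covariates = c("cdr", "project", "patient", "annotation",
                              "condition")),
    radii = 0:9,
    adjacency_mode = "index",
    require_leukocyte = TRUE,
    p_method = "t",
    seed = 1L)
}

.config_error <- function(...) {
  stop(structure(class = c("spotniche_config_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

#' Build a pipeline configuration
#'
#' Merges user settings over the committed defaults (QC thresholds,
#' marker and cytokine lists, per-cytokine fold-change cutoffs, radii
#' 0 to 9).  Unknown keys are rejected.
#'
#' @param config A named list, a YAML file path, or `NULL` for defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .config_error("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (inherits(config, "pipeline_config")) return(config)
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    .config_error("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", "))
  }
  merged <- utils::modifyList(def, config)
  if (!is.null(merged$radii)) merged$radii <- as.integer(unlist(merged$radii))
  structure(merged, class = "pipeline_config")
}

.log_stage <- function(stage, expr, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (!quiet) message(sprintf("[spotniche] %s ...", stage))
  out <- tryCatch(force(expr), error = function(e) {
    stop(structure(class = c("spotniche_stage_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", stage,
                                          conditionMessage(e)),
                        call = NULL, stage = stage)))
  })
  if (!quiet) {
    message(sprintf("[spotniche] %s done (%.1fs)", stage,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load), QC, normalization, spot labeling,
#' signature derivation from the stimulation table, the per-cytokine
#' radius sweep, pseudo-bulk and clustered correlations, and the
#' non-cluster DEG contrast.  All artifacts are written under `out_dir`
#' together with a run manifest (config hash, seed, package and R
#' versions).
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @param out_dir Output directory (overrides the config entry).
#' @param quiet Suppress per-stage logging to standard error.
#' @return Invisibly, the result bundle: `dataset`, `qc_report`,
#'   `factors`, `labels`, `signatures`, `sweeps`, `pseudo_bulk`,
#'   `noncluster_deg`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) .config_error("out_dir must be set")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- NULL
  if (is.null(cfg$input_dir)) {
    sim <- .log_stage("simulate", {
      sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
      simulate_dataset(sc)
    }, quiet)
    raw <- sim$dataset
    stim <- simulate_stim_table(sim$truth, seed = cfg$seed)
  } else {
    raw <- .log_stage("load", load_dataset(cfg$input_dir), quiet)
    stim_path <- file.path(cfg$input_dir, "stim_deg.csv")
    if (!file.exists(stim_path)) {
      .config_error("signature source missing: no stim_deg.csv in %s",
                    cfg$input_dir)
    }
    stim <- read_stim_table(stim_path)
  }

  qc <- .log_stage("qc", do.call(apply_qc,
                                 list(raw, do.call(qc_params, cfg$qc))), quiet)
  ds <- qc$dataset
  factors <- .log_stage("normalize", compute_norm_factors(ds), quiet)
  labels <- .log_stage("label",
                       label_spots(ds, cfg$markers, cfg$cytokines), quiet)

  # spatial side of the signature cascade: cytokine+ vs cytokine- spots
  # in the epidermis, reduced design (cdr + annotation + condition)
  spatial_lists <- .log_stage("spatial-deg", {
    lapply(setNames(cfg$cytokines, cfg$cytokines), function(cy) {
      tryCatch({
        cond <- contrast_cytokine(ds, labels, cy)
        design <- build_design(ds, factors, cond,
                               covariates = intersect(cfg$dge$covariates,
                                                      c("cdr", "annotation",
                                                        "condition")))
        deg <- fit_nb_glm(ds, design)
        call_degs(deg, fc_cut = cfg$signatures$spatial_fc_cut,
                  p_cut = cfg$signatures$spatial_p_cut,
                  use_adjusted = cfg$signatures$use_adjusted)
      }, error = function(e) {
        warning("spatial DEG failed for ", cy, ": ", conditionMessage(e),
                call. = FALSE)
        character(0)
      })
    })
  }, quiet)

  sigs <- .log_stage("signatures", {
    derive_signatures(stim, spatial_lists, cfg$cytokines,
                      fc_cuts = unlist(cfg$signatures$fc_cuts)[cfg$cytokines],
                      literature = cfg$signatures$literature)
  }, quiet)
  write_signatures(sigs, file.path(cfg$out_dir, "signatures.json"))

  # a cytokine whose derived signature came up empty (a real possibility
  # at small scale: the in-vivo contrast is diluted when amplified zones
  # tile the epidermis) is skipped with a warning, not fatal
  sweeps <- .log_stage("radius-sweep", {
    lapply(setNames(cfg$cytokines, cfg$cytokines), function(cy) {
      tryCatch(radius_sweep(ds, labels, cy, sigs[[cy]], radii = cfg$radii,
                            require_leukocyte = cfg$require_leukocyte,
                            adjacency_mode = cfg$adjacency_mode,
                            p_method = cfg$p_method),
               error = function(e) {
                 warning("radius sweep skipped for ", cy, ": ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    })
  }, quiet)

  pseudo <- .log_stage("pseudo-bulk", {
    lapply(setNames(cfg$cytokines, cfg$cytokines), function(cy) {
      if (length(sigs[[cy]]$genes) == 0) return(NULL)
      tryCatch(pseudo_bulk_correlation(ds, labels, cy, sigs[[cy]],
                                       p_method = cfg$p_method),
               error = function(e) NULL)
    })
  }, quiet)

  noncluster <- .log_stage("noncluster-deg", {
    lapply(setNames(cfg$cytokines, cfg$cytokines), function(cy) {
      if (is.null(sweeps[[cy]])) return(NULL)
      cond <- tryCatch(contrast_noncluster(ds, labels,
                                           sweeps[[cy]]$clusters, cy),
                       error = function(e) NULL)
      if (is.null(cond)) return(NULL)
      design <- build_design(ds, factors, cond,
                             covariates = cfg$dge$covariates)
      fit_nb_glm(ds, design)
    })
  }, quiet)

  .log_stage("write", {
    done <- sweeps[!vapply(sweeps, is.null, TRUE)]
    write.csv(cluster_table(unlist(lapply(done, `[[`, "clusters"),
                                   recursive = FALSE)),
              file.path(cfg$out_dir, "clusters.csv"), row.names = FALSE,
              quote = FALSE)
    sweep_json <- lapply(done, function(sw) {
      list(optimal_radius = sw$optimal_radius,
           optimal_r = sw$optimal$r, optimal_p = sw$optimal$p_value,
           table = sw$table)
    })
    jsonlite::write_json(sweep_json, file.path(cfg$out_dir, "sweep.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(labels$table, file.path(cfg$out_dir, "labels.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(qc$report[c("n_spots_in", "n_spots_out",
                                     "n_genes_in", "n_genes_out",
                                     "spots_removed", "genes_removed",
                                     "per_rule")],
                         file.path(cfg$out_dir, "qc_report.json"),
                         auto_unbox = TRUE)
    for (cy in cfg$cytokines) {
      if (!is.null(noncluster[[cy]])) {
        write.csv(noncluster[[cy]],
                  file.path(cfg$out_dir, sprintf("deg_noncluster_%s.csv", cy)),
                  row.names = FALSE, quote = FALSE)
      }
    }
  }, quiet)

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  cfg_list <- unclass(cfg)
  cfg_list$radii <- as.list(cfg_list$radii)
  yaml::write_yaml(cfg_list, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("spotniche")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = ds, qc_report = qc$report, factors = factors,
                 labels = labels, signatures = sigs, sweeps = sweeps,
                 pseudo_bulk = pseudo, noncluster_deg = noncluster,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `qc`, `label`, `signatures`,
#' `dge`, `cluster`, `sweep`, `correlate` and `run-all` (see the
#' `inst/cli/spotniche.R` wrapper script).  Exit codes: 0 success, 2
#' configuration error, 3 data error, 4 stage failure.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
spotniche_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: spotniche <command> [--config FILE] [--in DIR] [--out DIR]",
    "                 [--seed N] [--cytokine NAME] [--radius N] [--quiet]",
    "commands: simulate qc label signatures dge cluster sweep correlate run-all",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, input = NULL, out = NULL, seed = NULL,
              cytokine = NULL, radius = NULL, quiet = FALSE)
  code <- tryCatch({
    i <- 2
    while (i <= length(args)) {
      a <- args[i]
      take <- function() {
        if (i + 1 > length(args)) .config_error("missing value for %s", a)
        args[i + 1]
      }
      switch(a,
             "--config" = { opt$config <- take(); i <- i + 2 },
             "--in" = { opt$input <- take(); i <- i + 2 },
             "--out" = { opt$out <- take(); i <- i + 2 },
             "--seed" = { opt$seed <- as.integer(take()); i <- i + 2 },
             "--cytokine" = { opt$cytokine <- take(); i <- i + 2 },
             "--radius" = { opt$radius <- as.integer(take()); i <- i + 2 },
             "--quiet" = { opt$quiet <- TRUE; i <- i + 1 },
             .config_error("unknown option: %s", a))
    }
    cfg <- pipeline_config(opt$config)
    if (!is.null(opt$input)) cfg$input_dir <- opt$input
    if (!is.null(opt$seed)) cfg$seed <- opt$seed
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    run_cmd <- function() {
      switch(cmd,
        "simulate" = {
          if (is.null(cfg$out_dir)) .config_error("--out required for simulate")
          sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
          sim <- simulate_dataset(sc)
          stim <- simulate_stim_table(sim$truth, seed = cfg$seed)
          write_simulated_dataset(sim, cfg$out_dir, stim = stim)
        },
        "run-all" = run_pipeline(cfg, quiet = opt$quiet),
        "qc" = , "label" = , "signatures" = , "dge" = , "cluster" = ,
        "sweep" = , "correlate" = {
          # partial runs reuse the pipeline up to the requested stage;
          # artifacts for completed stages are written either way
          res <- run_pipeline(cfg, quiet = opt$quiet)
          if (cmd == "sweep" && !is.null(opt$cytokine)) {
            sw <- res$sweeps[[opt$cytokine]]
            if (is.null(sw)) .config_error("unknown cytokine %s", opt$cytokine)
            jsonlite::write_json(
              list(optimal_radius = sw$optimal_radius, table = sw$table),
              file.path(cfg$out_dir, sprintf("sweep_%s.json", opt$cytokine)),
              auto_unbox = TRUE, digits = NA, dataframe = "rows")
          }
          res
        },
        .config_error("unknown command: %s", cmd))
    }
    run_cmd()
    0L
  },
  spotniche_config_error = function(e) {
    message("config error: ", conditionMessage(e))
    2L
  },
  spotniche_stage_error = function(e) {
    if (identical(e$stage, "load")) {
      message("data error: ", conditionMessage(e))
      3L
    } else {
      message("stage failure: ", conditionMessage(e))
      4L
    }
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    4L
  })
  invisible(code)
}
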