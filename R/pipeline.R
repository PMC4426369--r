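#' Default end-to-end pipeline configuration
#'
#' Stage parameters default to the analysis constants: 120-bp tag extension,
#' 10-bp profile bins, 100-bp TSS sliding windows, 150-bp dA/dT windows with
#' the >=6-of-7 tract rule, the 1.5-fold responsive and 0.2 memory
#' classification thresholds, and the two-SD conservation band.
#'
#' @param outdir Output directory for all artifacts.
#' @param seed Master seed; the simulation and every bootstrap stream derive
#'   from it.
#' @param sim A [sim_config()] (its `seed` is overridden by `seed`).
#' @param stages Character vector of stages to run, in dependency order,
#'   from `c("simulate", "coverage", "profiles", "atprofile", "classify",
#'   "compare")`.
#' @param extend_length,profile_flank,profile_bin,at_flank,at_window,
#'   responsive_fold,memory_cutoff,n_boot Stage parameters.
#' @param write_tracks Write full per-bp Z-score tracks (large; default
#'   FALSE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = c("simulate", "coverage", "profiles",
                                       "atprofile", "classify", "compare"),
                            extend_length = 120L,
                            profile_flank = 500L,
                            profile_bin = 10L,
                            at_flank = 500L,
                            at_window = 150L,
                            responsive_fold = 1.5,
                            memory_cutoff = 0.2,
                            n_boot = 10000L,
                            write_tracks = FALSE) {
  sim$seed <- as.integer(seed)
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              stages = stages, extend_length = as.integer(extend_length),
              profile_flank = as.integer(profile_flank),
              profile_bin = as.integer(profile_bin),
              at_flank = as.integer(at_flank),
              at_window = as.integer(at_window),
              responsive_fold = responsive_fold,
              memory_cutoff = memory_cutoff,
              n_boot = as.integer(n_boot),
              write_tracks = isTRUE(write_tracks))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  known <- c("simulate", "coverage", "profiles", "atprofile", "classify",
             "compare")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (cfg$extend_length < 1L) stop("extend_length must be positive")
  if (cfg$profile_bin < 1L || cfg$profile_flank < cfg$profile_bin) {
    stop("profile_flank/profile_bin invalid")
  }
  if (cfg$at_window < 8L) stop("at_window must be at least 8 bp")
  if (cfg$at_flank < 1L) stop("at_flank must be positive")
  if (cfg$responsive_fold <= 1) stop("responsive_fold must exceed 1")
  if (cfg$memory_cutoff <= 0 ||
      cfg$memory_cutoff >= log2(cfg$responsive_fold)) {
    stop("memory_cutoff must lie in (0, log2(responsive_fold))")
  }
  if (cfg$n_boot < 1L) stop("n_boot must be positive")
  validate_sim_config(cfg$sim)
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; a `sim:` block mirrors
#' [sim_config()].
#'
#' @param path YAML file path.
#' @param outdir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$noise_mean_by_class)) {
    sim_args$noise_mean_by_class <- unlist(sim_args$noise_mean_by_class)
  }
  sim <- do.call(sim_config, c(sim_args, list(seed = y$seed %||% 1L)))
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(pipeline_config, c(args, list(sim = sim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline end-to-end
#'
#' Stages run in dependency order: simulate the study, build coverage and
#' Z-score tracks per condition, motif-centered meta-profiles per class and
#' condition, class-averaged dA/dT profiles, target classification, and the
#' bootstrap noise comparison. Every output file is recorded in a manifest
#' (file, stage, md5) written as `manifest.tsv`; rerunning with the same
#' config reproduces byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress stage messages (default FALSE).
#' @return Invisibly, a list with `manifest` (data.frame) and in-memory
#'   stage results (`sim`, `zscores`, `profiles`, `at_profile`, `classes`,
#'   `comparison`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[memorychrom] ", ...)
  manifest <- data.frame(file = character(), stage = character(),
                         md5 = character())
  record <- function(paths, stage) {
    ok <- file.exists(paths)
    manifest <<- rbind(manifest,
                       data.frame(file = basename(paths[ok]), stage = stage,
                                  md5 = unname(tools::md5sum(paths[ok]))))
  }
  res <- list()
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    say("stage ", stage, " ...")
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    res$sim <<- simulate_dataset(config$sim)
    paths <- write_sim_output(res$sim, config$outdir)
    record(paths, "simulate")
  })

  run_stage("coverage", function() {
    stopifnot(!is.null(res$sim))
    res$zscores <<- lapply(res$sim$tags, function(tg) {
      normalize_zscore(coverage_track(tg, res$sim$genome,
                                      config$extend_length))
    })
    if (config$write_tracks) {
      for (cond in names(res$zscores)) {
        p <- file.path(config$outdir, paste0("zscore_", cond, ".tsv"))
        write_track(res$zscores[[cond]], p)
        record(p, "coverage")
      }
    }
  })

  run_stage("profiles", function() {
    stopifnot(!is.null(res$zscores))
    cls <- S4Vectors::mcols(res$sim$sites)$class_label
    out <- list()
    for (cond in names(res$zscores)) {
      for (cl in sort(unique(cls))) {
        prof <- motif_centered_profile(res$zscores[[cond]],
                                       res$sim$sites[cls == cl],
                                       flank = config$profile_flank,
                                       bin = config$profile_bin)
        prof$condition <- cond
        prof$class_label <- cl
        out[[paste(cond, cl, sep = ".")]] <- prof
      }
    }
    res$profiles <<- out
    p <- file.path(config$outdir, "motif_profiles.tsv")
    write_table_strict(do.call(rbind, lapply(out, as.data.frame)), p)
    record(p, "profiles")
  })

  run_stage("atprofile", function() {
    stopifnot(!is.null(res$sim))
    res$at_profile <<- class_average_at_profile(res$sim$genome,
                                                res$sim$sites,
                                                flank = config$at_flank,
                                                window = config$at_window)
    p <- file.path(config$outdir, "at_profile.tsv")
    write_table_strict(as.data.frame(res$at_profile), p)
    record(p, "atprofile")
  })

  run_stage("classify", function() {
    stopifnot(!is.null(res$sim))
    res$classes <<- suppressMessages(
      classify_table(res$sim$expression, config$responsive_fold,
                     config$memory_cutoff))
    p <- file.path(config$outdir, "classes.tsv")
    write_table_strict(res$classes, p)
    record(p, "classify")
  })

  run_stage("compare", function() {
    stopifnot(!is.null(res$classes))
    records <- merge(res$classes, res$sim$metrics, by = "gene_id")
    records$noise <- center_metric(records$noise)
    summ <- class_metric_summary(records, "noise", n_boot = config$n_boot,
                                 seed = config$seed)
    res$comparison <<- list(
      summary = summ,
      difference = compare_classes(summ, "memory", "responsive"))
    p <- file.path(config$outdir, "noise_summary.tsv")
    write_table_strict(as.data.frame(summ), p)
    record(p, "compare")
  })

  manifest_path <- file.path(config$outdir, "manifest.tsv")
  write_table_strict(manifest, manifest_path)
  say("done in ", round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        1), " s; ", nrow(manifest), " artifact(s)")
  invisible(c(list(manifest = manifest), res))
}
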