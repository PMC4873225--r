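#' Pipeline configuration
#'
#' Flat configuration for the end-to-end run: which stages to execute, the
#' master seed, the simulation and prioritization parameters and the
#' output directory. May be loaded from a YAML file with
#' [read_pipeline_config()]; every piece of randomness flows from the one
#' seed through the hierarchical stream of [sim_config()].
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param stages character subset of
#'   `c("simulate", "prioritize", "qpcrval", "assays", "morphometry")`.
#' @param sim a [sim_config()]; rebuilt with `seed` when omitted.
#' @param prioritization a [prioritization_config()].
#' @param conditions named list mapping assay condition names to organoid
#'   generation overrides (`protrusion_count`, `dead_fraction`,
#'   `wound_rate`); the first entry is the control.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "prioritize", "qpcrval",
                                       "assays", "morphometry"),
                            sim = NULL,
                            prioritization = prioritization_config(),
                            conditions = list(
                              untreated = list(),
                              silenced = list(protrusion_count = 0L,
                                              dead_fraction = 0.2,
                                              wound_rate = 0.05)),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  known <- c("simulate", "prioritize", "qpcrval", "assays", "morphometry")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages,
                 sim = sim %||% sim_config(seed = seed),
                 prioritization = prioritization,
                 conditions = conditions, log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `out_dir`, `seed`, `stages`, `log_level` plus nested
#' `sim` and `prioritization` blocks whose keys are passed to
#' [sim_config()] and [prioritization_config()].
#'
#' @param path YAML file.
#' @param overrides named list applied over the file's top-level keys
#'   (command-line flags beat config keys).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  seed <- y$seed %||% 1L
  sim_args <- y$sim %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  args <- list(
    out_dir = y$out_dir %||% "prostmark_out",
    seed = seed,
    sim = do.call(sim_config, sim_args),
    prioritization = do.call(prioritization_config,
                             y$prioritization %||% list())
  )
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$log_level)) args$log_level <- y$log_level
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> prioritize -> qpcrval -> assays -> morphometry on
#' synthetic inputs, writing every stage's artifacts under
#' `config$out_dir` and assembling a run manifest (config hash, per-file
#' md5 digests, stage wall-clock times, package version). Stage failures
#' abort with the stage name; stages are independently skippable through
#' `config$stages`. Identical configurations reproduce identical digests.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  downstream <- setdiff(config$stages, "simulate")
  if (length(downstream) && !"simulate" %in% config$stages)
    stop("pipeline validation: stages ",
         paste(downstream, collapse = ", "),
         " need inputs from the simulate stage; enable it")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) {
    if (config$log_level == "info") message("[prostmark] ", ...)
  }
  cfg_core <- unclass(config)
  cfg_core$out_dir <- NULL   # the hash identifies the analysis, not where
  cfg_core$log_level <- NULL # it is written or how chatty the run is
  manifest <- list(config_hash = hash_object(cfg_core),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("prostmark")),
                   stages = list())
  run_stage <- function(name, fun) {
    if (!name %in% c("simulate", config$stages) &&
        !(name %in% config$stages)) return(invisible(NULL))
    log_msg("stage ", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = digest_dir(file.path(out, name)))
    res
  }

  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    d <- file.path(out, "simulate")
    state$cohort <- gen_expression_cohort(config$sim)
    write_cohort(state$cohort, file.path(d, "cohort"))
    state$qpcr <- gen_qpcr_cohort(config$sim)
    write_qpcr(state$qpcr, file.path(d, "qpcr"))
    state$images <- list()
    state$wounds <- list()
    idx <- 0L
    for (cc in names(config$conditions)) {
      idx <- idx + 1L
      ov <- config$conditions[[cc]]
      sc <- config$sim
      for (k in intersect(names(ov), c("protrusion_count", "dead_fraction",
                                       "wound_rate")))
        sc[[k]] <- ov[[k]]
      class(sc) <- "sim_config"
      state$images[[cc]] <- gen_organoid_image(sc, index = idx)
      write_organoid_tiff(state$images[[cc]],
                          file.path(d, paste0("organoid_", cc, ".tiff")))
      state$wounds[[cc]] <- gen_wound_series(sc)
    }
    invisible(NULL)
  })

  if ("prioritize" %in% config$stages) run_stage("prioritize", function() {
    if (is.null(state$cohort))
      stop("no cohort available (enable the simulate stage)")
    if (is.null(state$cohort$citations))
      stop("literature: citation table is missing")
    trace <- run_prioritization(state$cohort, config$prioritization)
    write_trace(trace, file.path(out, "prioritize"))
    state$trace <- trace
  })

  if ("qpcrval" %in% config$stages) run_stage("qpcrval", function() {
    report <- validation_report(state$qpcr)
    write_report(report, file.path(out, "qpcrval"))
    state$report <- report
  })

  if ("assays" %in% config$stages) run_stage("assays", function() {
    d <- file.path(out, "assays")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    wm <- do.call(rbind, lapply(names(state$wounds), function(cc) {
      m <- wound_metrics(state$wounds[[cc]])
      m$condition <- cc
      m
    }))
    write_tsv(wm, file.path(d, "wound_metrics.tsv"))
    state$wound_metrics <- wm
  })

  if ("morphometry" %in% config$stages) run_stage("morphometry", function() {
    d <- file.path(out, "morphometry")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    recs <- do.call(rbind, lapply(names(state$images), function(cc) {
      r <- morphometric_record(state$images[[cc]])
      r$condition <- cc
      r
    }))
    write_tsv(recs, file.path(d, "features.tsv"))
    cs <- condition_summary(recs, names(config$conditions)[1])
    write_tsv(cs, file.path(d, "condition_summary.tsv"))
    state$morphometry <- recs
  })

  write_manifest(manifest, out)
  log_msg("done; manifest at ", file.path(out, "manifest.json"))
  invisible(manifest)
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# md5 digest of an arbitrary R object via its deparsed form
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

digest_dir <- function(dir) {
  if (!dir.exists(dir)) return(list())
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  if (!length(files)) return(list())
  md5 <- tools::md5sum(files)
  stats::setNames(as.list(unname(md5)),
                  substring(files, nchar(dir) + 2L))
}
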