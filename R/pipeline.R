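#' Configure an end-to-end pipeline run
#'
#' A pipeline run either simulates a survey with known ground truth
#' (`mode = "simulate"`) or ingests field data (`mode = "ingest"`: a plant
#' table CSV and a directory of quadrat photographs), estimates percent
#' cover, derives traits, fits one hierarchical model per (species x
#' trait) job plus the community percent-cover model, runs the fit
#' checks, and emits a report shaped like the published estimates table.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param seed Integer seed; mandatory, drives every stochastic stage.
#' @param sim A [sim_config()] (simulate mode). Defaults to
#'   `sim_config(seed = seed)`.
#' @param params A [survey_params()] object (simulate mode); defaults to
#'   [table1_defaults()].
#' @param plant_csv,image_dir Input paths (ingest mode).
#' @param sampler List with `chains`, `iter`, `warmup` for
#'   [sample_posterior()].
#' @param thresholds Diagnostic thresholds: `rhat` (1.1), `ess` (1000),
#'   `pareto_k` (0.5).
#' @param diagnostics `"basic"` (R-hat/ESS only, default) or `"full"`
#'   (adds the skew posterior predictive check and PSIS-LOO).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"), seed,
                            sim = NULL, params = table1_defaults(),
                            plant_csv = NULL, image_dir = NULL,
                            sampler = list(chains = 3, iter = 5000,
                                           warmup = 1000),
                            thresholds = list(rhat = 1.1, ess = 1000,
                                              pareto_k = 0.5),
                            diagnostics = c("basic", "full")) {
  mode <- match.arg(mode)
  diagnostics <- match.arg(diagnostics)
  if (missing(seed)) abort_config("`seed` is mandatory.")
  if (mode == "simulate") {
    if (is.null(sim)) sim <- sim_config(seed = seed)
    if (!inherits(params, "survey_params")) {
      abort_config("`params` must be a survey_params object.")
    }
  } else if (is.null(plant_csv) || is.null(image_dir)) {
    abort_config("ingest mode needs `plant_csv` and `image_dir`.")
  }
  structure(list(mode = mode, seed = as.integer(seed), sim = sim,
                 params = params, plant_csv = plant_csv,
                 image_dir = image_dir, sampler = sampler,
                 thresholds = thresholds, diagnostics = diagnostics),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim` and
#' `params` sub-documents use the [sim_config()] argument names and the
#' [write_survey_params()] layout respectively.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(x$sim)) {
    sim_args <- x$sim
    if (is.null(sim_args$seed)) sim_args$seed <- x$seed
    sim <- do.call(sim_config, sim_args)
  }
  params <- if (!is.null(x$params_file)) read_survey_params(x$params_file)
    else table1_defaults()
  pipeline_config(
    mode = x$mode %||% "simulate", seed = x$seed, sim = sim, params = params,
    plant_csv = x$plant_csv, image_dir = x$image_dir,
    sampler = x$sampler %||% list(chains = 3, iter = 5000, warmup = 1000),
    thresholds = x$thresholds %||% list(rhat = 1.1, ess = 1000,
                                        pareto_k = 0.5),
    diagnostics = x$diagnostics %||% "basic"
  )
}

run_stage <- function(stage, code) {
  inform(sprintf("[stage: %s] starting", stage))
  tryCatch(force(code), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "trampler_stage_error", stage = stage, parent = e)
  })
}

# One model job per species x trait, plus the community cover model; the
# published table has 12 such rows (reproduction is skipped for taxa
# flagged no-reproduction).
default_jobs <- function(params) {
  jobs <- list(list(species = "All plants", trait = "percent_cover",
                    family = "beta"))
  for (sp in names(params$species)) {
    jobs <- c(jobs,
              list(list(species = sp, trait = "height", family = "negbin"),
                   list(species = sp, trait = "diameter", family = "negbin")))
    if (params$species[[sp]]$reproduction) {
      jobs <- c(jobs, list(list(species = sp, trait = "reproduction",
                                family = "beta")))
    }
  }
  jobs
}

quadrat_id_fields <- function(quadrat_id) {
  parts <- strsplit(quadrat_id, "_")
  tibble::tibble(
    pair_id = vapply(parts, `[`, character(1), 1L),
    disturbed = as.integer(vapply(parts, `[`, character(1), 2L) == "D"),
    quadrat = as.integer(vapply(parts, `[`, character(1), 3L))
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- survey generation or ingest, percent
#' cover estimation, trait derivation, one hierarchical fit per job,
#' diagnostics, report assembly -- logging each stage with its row counts.
#' A stage failure aborts with a stage-tagged error
#' (`trampler_stage_error`); in that case any outputs already produced are
#' written to `out_dir` (when given) next to a manifest recording which
#' stages completed. Identical config and seed reproduce the bundle
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report (CSV + JSON),
#'   per-model summaries, diagnostics and the manifest are written there.
#' @return An object of class `trample_pipeline`: list with `report`
#'   (the combined table), `fits`, `diagnostics`, `cover`, `traits`,
#'   `manifest`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("`config` must come from pipeline_config().")
  }
  manifest <- list()
  done <- function(stage, rows) {
    manifest[[length(manifest) + 1L]] <<-
      tibble::tibble(stage = stage, rows = as.integer(rows),
                     seed = config$seed)
    inform(sprintf("[stage: %s] done (%d rows)", stage, rows))
  }
  partial <- new.env(parent = emptyenv())
  on.exit({
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      if (length(manifest) > 0) {
        jsonlite::write_json(dplyr::bind_rows(manifest),
                             file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(partial$report)) {
        write_report(partial$report, file.path(out_dir, "report"))
      }
    }
  }, add = TRUE)

  if (config$mode == "simulate") {
    design <- run_stage("design", make_design(config$sim))
    done("design", nrow(design))
    cover_tbl <- run_stage("cover", {
      imgs <- simulate_cover_images(design, config$params,
                                    seed = sub_seed(config$seed, 11L))
      est <- dplyr::bind_rows(lapply(seq_len(nrow(imgs)), function(i) {
        estimate_cover(imgs$image[[i]], quadrat_id = imgs$quadrat_id[i])
      }))
      out <- dplyr::bind_cols(imgs[, c("pair_id", "trail", "transect_id",
                                       "disturbed", "quadrat", "elevation_m",
                                       "true_cover")],
                              est)
      dplyr::arrange(out, .data$quadrat_id)
    })
    done("cover", nrow(cover_tbl))
    plants <- run_stage("plants", {
      simulate_traits(design, config$params,
                      seed = sub_seed(config$seed, 12L))
    })
    done("plants", nrow(plants))
  } else {
    plants <- run_stage("plants", {
      if (!file.exists(config$plant_csv)) {
        stop(sprintf("plant table '%s' not found", config$plant_csv))
      }
      read_plant_table(config$plant_csv)
    })
    done("plants", nrow(plants))
    cover_tbl <- run_stage("cover", {
      est <- batch_estimate(config$image_dir)
      meta <- quadrat_id_fields(est$quadrat_id)
      elev <- unique(plants[, c("pair_id", "elevation_m")])
      out <- dplyr::left_join(dplyr::bind_cols(meta, est), elev,
                              by = "pair_id")
      dplyr::arrange(out, .data$quadrat_id)
    })
    done("cover", nrow(cover_tbl))
  }

  traits <- run_stage("traits", {
    relative_reproduction(derive_traits(plants))
  })
  done("traits", nrow(traits))

  jobs <- default_jobs(config$params)
  fits <- list()
  diags <- list()
  rows <- list()
  for (i in seq_along(jobs)) {
    job <- jobs[[i]]
    label <- paste(job$species, job$trait, sep = " / ")
    fit <- run_stage(paste0("fit: ", label), {
      if (job$trait == "percent_cover") {
        dat <- cover_tbl
        dat$percent_cover <- adjust_unit_interval(dat$green_fraction)
        response <- "percent_cover"
      } else if (job$trait == "reproduction") {
        dat <- traits[traits$species == job$species &
                        !is.na(traits$relative_repro), , drop = FALSE]
        dat$reproduction <- adjust_unit_interval(dat$relative_repro)
        response <- "reproduction"
      } else {
        col <- paste0(job$trait, "_cm")
        dat <- traits[traits$species == job$species, , drop = FALSE]
        dat[[job$trait]] <- round_for_nb(dat[[col]])
        response <- job$trait
      }
      spec <- model_spec(response, job$family)
      md <- build_model_data(dat, spec)
      sample_posterior(md, chains = config$sampler$chains,
                       iter = config$sampler$iter,
                       warmup = config$sampler$warmup,
                       seed = sub_seed(config$seed, 500L + i))
    })
    fits[[label]] <- fit
    diags[[label]] <- run_stage(paste0("diagnostics: ", label), {
      diagnose(fit, seed = sub_seed(config$seed, 800L + i),
               thresholds = config$thresholds,
               loo = config$diagnostics == "full")
    })
    s <- summarize_fit(fit)
    fx <- function(term, what) s[[what]][s$parameter == term]
    rows[[label]] <- tibble::tibble(
      species = job$species, trait = job$trait, family = job$family,
      n = fit$data$n,
      intercept_est = fx("(Intercept)", "mean"),
      intercept_lo = fx("(Intercept)", "lower"),
      intercept_hi = fx("(Intercept)", "upper"),
      intercept_effect = fx("(Intercept)", "effect"),
      dist_est = fx("disturbance", "mean"),
      dist_lo = fx("disturbance", "lower"),
      dist_hi = fx("disturbance", "upper"),
      dist_effect = fx("disturbance", "effect"),
      elev_est = fx("elevation", "mean"),
      elev_lo = fx("elevation", "lower"),
      elev_hi = fx("elevation", "upper"),
      elev_effect = fx("elevation", "effect"),
      int_est = fx("disturbance:elevation", "mean"),
      int_lo = fx("disturbance:elevation", "lower"),
      int_hi = fx("disturbance:elevation", "upper"),
      int_effect = fx("disturbance:elevation", "effect"),
      max_rhat = max(s$rhat), min_ess_bulk = min(s$ess_bulk),
      min_ess_tail = min(s$ess_tail)
    )
    done(paste0("fit: ", label), fit$data$n)
  }
  report <- dplyr::bind_rows(rows)
  partial$report <- report
  done("report", nrow(report))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (label in names(diags)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", label)
      write_diagnostics(diags[[label]],
                        file.path(out_dir, paste0("diagnostics_", safe,
                                                  ".json")))
      utils::write.csv(as.data.frame(summarize_fit(fits[[label]])),
                       file.path(out_dir, paste0("fit_", safe, ".csv")),
                       row.names = FALSE)
    }
  }
  structure(list(report = report, fits = fits, diagnostics = diags,
                 cover = cover_tbl, traits = traits,
                 manifest = dplyr::bind_rows(manifest), config = config),
            class = "trample_pipeline")
}

#' Write the combined model report
#'
#' Writes the Table-1-shaped report as CSV and JSON with a fixed column
#' order; effect columns flag parameters whose 95% credible interval
#' excludes zero. Byte-for-byte reproducible for identical input.
#'
#' @param report The `report` tibble from [run_pipeline()] (>= 1 row).
#' @param path Output path without extension; `.csv` and `.json` are
#'   appended.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, path) {
  if (!is.data.frame(report) || nrow(report) == 0L) {
    abort("`report` must have at least one row",
          class = "trampler_report_error")
  }
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = csv, json = json))
}

#' @export
print.trample_pipeline <- function(x, ...) {
  cat(sprintf("<trample_pipeline> %s mode, seed %d: %d models\n",
              x$config$mode, x$config$seed, nrow(x$report)))
  print(x$report[, c("species", "trait", "n", "dist_est", "dist_lo",
                     "dist_hi", "dist_effect")])
  invisible(x)
}
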