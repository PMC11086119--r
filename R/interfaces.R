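# I/O, run configuration and the end-to-end pipeline:
# simulate -> fit -> variability -> correlation/PCA -> classifier.

#' Write a spectrum CSV
#'
#' Dialect: optional `# key=value` metadata comment lines, then a header
#' `frequency_ghz,eps_real,eps_imag` and one row per point at full float
#' precision.
#'
#' @param spectrum a [milk_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  lines <- character(0)
  if (length(spectrum$meta))
    lines <- sprintf("# %s=%s", names(spectrum$meta),
                     vapply(spectrum$meta, function(v)
                       format(v, digits = 17, scientific = FALSE),
                       character(1)))
  lines <- c(lines, "frequency_ghz,eps_real,eps_imag",
             sprintf("%.17g,%.17g,%.17g", spectrum$frequency_ghz,
                     spectrum$eps_real, spectrum$eps_imag))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrum CSV
#'
#' Parses the dialect of [write_spectrum_csv()]; columns are matched by
#' header name, so reordered columns are accepted.  Invariants are
#' validated on read unless `validate = FALSE` (noisy measured spectra may
#' legitimately graze the physicality limits).
#'
#' @param path input file path.
#' @param validate check spectrum invariants after parsing.
#' @return a [milk_spectrum()].
#' @export
read_spectrum_csv <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_spectrum_csv: empty file: ", path, call. = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2)
    stop("read_spectrum_csv: no data rows in ", path, call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  required <- c("frequency_ghz", "eps_real", "eps_imag")
  if (!all(required %in% header))
    stop("read_spectrum_csv: header must contain frequency_ghz, eps_real, eps_imag (line 1)",
         call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  df[required] <- lapply(df[required], function(col)
    suppressWarnings(as.numeric(col)))
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad))
    stop(sprintf("read_spectrum_csv: malformed row at data line %d", bad[1]),
         call. = FALSE)
  if (any(diff(df$frequency_ghz) <= 0))
    stop("read_spectrum_csv: frequencies are not strictly increasing",
         call. = FALSE)
  milk_spectrum(df$frequency_ghz, df$eps_real, df$eps_imag, meta = meta,
                validate = validate)
}

#' Write / read a cohort table CSV
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) utils::read.csv(path)

#' Run configuration
#'
#' Bundles every knob of a full pipeline run: the design preset, fitting
#' options, the variability stage pairing, classifier hyperparameters and
#' the root seed.  Round-trips losslessly through YAML.
#'
#' @param design_preset name understood by [design_preset()].
#' @param seed root seed; every stochastic stage derives a named child
#'   seed from it.
#' @param fit_n_starts optimisation starts per spectrum fit.
#' @param freeze_jonscher keep the Jonscher tail frozen at zero.
#' @param drop_pairing length-2 stage pairing for the headline drop.
#' @param test_per_class,epochs,learning_rate,batch_size classifier
#'   settings.
#' @param write_spectra also write one CSV per simulated spectrum.
#' @return list of class `run_config`.
#' @export
run_config <- function(design_preset = "random_fixture", seed = 1L,
                       fit_n_starts = 1L, freeze_jonscher = TRUE,
                       drop_pairing = NULL,
                       test_per_class = 10L, epochs = 20L,
                       learning_rate = 1e-3, batch_size = 32L,
                       write_spectra = FALSE) {
  cfg <- list(design_preset = design_preset, seed = as.integer(seed),
              fit_n_starts = as.integer(fit_n_starts),
              freeze_jonscher = isTRUE(freeze_jonscher),
              drop_pairing = drop_pairing,
              test_per_class = as.integer(test_per_class),
              epochs = as.integer(epochs),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              write_spectra = isTRUE(write_spectra))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort, fits every spectrum, computes the
#' staged variability summary and headline drop, the correlation matrix,
#' the PCA export, and trains the classifier; writes every artifact into
#' `out_dir` and finishes with a manifest (JSON) listing each file with
#' its MD5 content hash, all seeds and the package version.  Identical
#' config and seed reproduce identical manifests.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param cohort_cfg a [cohort_config()].
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         cohort_cfg = cohort_config()) {
  if (missing(out_dir)) stop("run_pipeline: out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("run_pipeline: cannot create output directory ", out_dir, call. = FALSE)
  files <- character(0)
  stage <- "setup"
  manifest_path <- file.path(out_dir, "manifest.json")

  emit <- function(name) files <<- c(files, name)
  run <- tryCatch({
    stage <- "simulate"
    design <- design_preset(config$design_preset, seed = config$seed)
    cohort <- simulate_cohort(design, cohort_cfg)
    write_cohort_csv(cohort$table, file.path(out_dir, "cohort.csv"))
    emit("cohort.csv")
    if (config$write_spectra) {
      spec_dir <- file.path(out_dir, "spectra")
      dir.create(spec_dir, showWarnings = FALSE)
      for (id in names(cohort$spectra)) {
        write_spectrum_csv(cohort$spectra[[id]],
                           file.path(spec_dir, paste0(id, ".csv")))
        emit(file.path("spectra", paste0(id, ".csv")))
      }
    }

    stage <- "fit"
    cohort <- fit_cohort(cohort, fit_options(
      n_starts = config$fit_n_starts,
      freeze_jonscher = config$freeze_jonscher,
      seed = derive_seed(config$seed, "fit")))
    write_cohort_csv(cohort$table, file.path(out_dir, "fits.csv"))
    emit("fits.csv")

    stage <- "variability"
    summ <- stage_dispersion(cohort$table)
    write_cohort_csv(summ, file.path(out_dir, "stage_summary.csv"))
    emit("stage_summary.csv")
    pairing <- config$drop_pairing
    if (is.null(pairing))
      pairing <- if (any(cohort$table$stage == "stage3"))
        c("stage1", "stage3") else c("before", "after")
    drop <- NULL
    if (all(pairing %in% cohort$table$stage)) {
      vd <- variability_drop(cohort$table, "delta_eps", pairing)
      drop <- list(parameter = "delta_eps", reference = pairing[1],
                   comparison = pairing[2], drop_pct = vd$drop_pct,
                   sd_reference = vd$sd_reference,
                   sd_comparison = vd$sd_comparison)
      jsonlite::write_json(drop, file.path(out_dir, "drop_report.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("drop_report.json")
    }

    stage <- "multivariate"
    cm <- correlation_matrix(cohort$table)
    utils::write.csv(cm$r, file.path(out_dir, "correlation_r.csv"))
    utils::write.csv(cm$p, file.path(out_dir, "correlation_p.csv"))
    emit("correlation_r.csv"); emit("correlation_p.csv")
    pca <- pca_project(cohort$table)
    bp <- biplot_export(pca, cohort$table$stage)
    write_cohort_csv(bp, file.path(out_dir, "pca_biplot.csv"))
    emit("pca_biplot.csv")

    stage <- "classifier"
    lab_preg <- with(cohort$table,
                     pregnant_outcome & !is.na(days_since_insemination) &
                       days_since_insemination >= 1)
    cls <- NULL
    n_min <- min(sum(lab_preg), sum(!lab_preg))
    if (n_min > config$test_per_class + 5) {
      cls <- classify_pregnancy(
        cohort$table[, c("delta_eps", "tau_ps", "alpha", "sigma_dc")],
        lab_preg, seed = derive_seed(config$seed, "classifier"),
        test_per_class = config$test_per_class, epochs = config$epochs,
        learning_rate = config$learning_rate, batch_size = config$batch_size)
      write_cohort_csv(cls$curves, file.path(out_dir, "learning_curves.csv"))
      emit("learning_curves.csv")
      jsonlite::write_json(
        list(test_accuracy = cls$test_accuracy, test_loss = cls$test_loss,
             n_train = cls$n_train, n_test = cls$n_test),
        file.path(out_dir, "classifier_metrics.json"),
        auto_unbox = TRUE, digits = NA)
      emit("classifier_metrics.json")
    }
    list(cohort = cohort, drop = drop, classifier = cls)
  }, error = function(e) {
    partial <- list(status = "error", failed_stage = stage,
                    message = conditionMessage(e),
                    files = manifest_file_hashes(out_dir, files))
    jsonlite::write_json(partial, manifest_path, auto_unbox = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    status = "ok",
    package_version = as.character(utils::packageVersion("lactowave")),
    seed = config$seed,
    child_seeds = list(fit = derive_seed(config$seed, "fit"),
                       classifier = derive_seed(config$seed, "classifier")),
    config = unclass(config),
    files = manifest_file_hashes(out_dir, files))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest)
}

manifest_file_hashes <- function(out_dir, files) {
  lapply(stats::setNames(files, files), function(f) {
    unname(tools::md5sum(file.path(out_dir, f)))
  })
}
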