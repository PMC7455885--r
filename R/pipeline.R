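# End-to-end orchestration: generate -> label/select -> extract -> train,
# with on-disk artifacts (NIfTI volumes and masks, streamline JSON,
# clinical CSV, feature CSVs, model reports) and full-run determinism.

.pkg_version <- function() {
  as.character(utils::packageVersion("opgpredict"))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Write a volume as NIfTI-1
#' @param vol 3D numeric array
#' @param spacing_mm voxel spacing (mm), stored in the header pixdim
#' @param path output path (.nii.gz)
#' @export
write_volume_nifti <- function(vol, spacing_mm, path) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#' @param path .nii/.nii.gz path
#' @return `list(data, spacing_mm)`
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Write a streamline set as JSON
#'
#' Line-set dialect: an object with `units` ("mm") and `lines`, a list of
#' polylines, each a list of [x, y, z] world-mm triplets.
#'
#' @param lines a [streamline_set]
#' @param path output .json path
#' @export
write_streamlines_json <- function(lines, path) {
  jsonlite::write_json(
    list(units = "mm",
         lines = lapply(lines$lines, function(m)
           lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))),
    path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Read a streamline JSON file written by [write_streamlines_json]
#' @param path .json path
#' @return a [streamline_set]
#' @export
read_streamlines_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  streamline_set(lapply(obj$lines, function(l)
    matrix(unlist(l), ncol = 3, byrow = TRUE)))
}

#' Write a cohort's imaging and clinical artifacts
#'
#' One NIfTI file per modality per scan plus one per region mask, a
#' streamline JSON per scan and side, and the clinical CSV.
#'
#' @param cohort list of subjects
#' @param dir output directory (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort) {
    for (k in seq_along(subj$scans)) {
      scan <- subj$scans[[k]]
      stem <- sprintf("%s_s%d", subj$subject_id, k)
      for (mod in OPG_MODALITIES)
        write_volume_nifti(scan$volumes[[mod]], scan$spacing_mm,
                           file.path(dir, "images",
                                     sprintf("%s_%s.nii.gz", stem, mod)))
      for (rn in c("ON_L", "ON_R", "OR_L", "OR_R")) {
        rm <- subj$masks[[k]][[rn]]
        write_volume_nifti(array(as.numeric(rm$mask), dim(rm$mask)),
                           rm$spacing_mm,
                           file.path(dir, "images",
                                     sprintf("%s_mask_%s.nii.gz", stem, rn)))
      }
      for (side in c("L", "R"))
        write_streamlines_json(
          subj$streamlines[[k]][[paste0("streamlines_", side)]],
          file.path(dir, "images",
                    sprintf("%s_streamlines_%s.json", stem, side)))
    }
  }
  write_clinical_records(cohort, file.path(dir, "clinical.csv"))
  invisible(dir)
}

#' Validate on-disk imaging inputs
#'
#' Diagnostic mode: checks that NIfTI headers (dimensions and spacing)
#' agree across the modalities of each scan, that mask volumes are binary
#' and on the scan grid, and that streamline JSON files parse. Never
#' raises; returns a pass/fail table.
#'
#' @param dir directory holding an `images/` tree as written by
#'   [write_cohort]
#' @return data frame with columns `scan`, `check`, `pass`, `detail`
#' @export
validate_inputs <- function(dir) {
  img_dir <- file.path(dir, "images")
  rows <- list()
  add <- function(scan, check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      scan = scan, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  files <- list.files(img_dir, pattern = "\\.nii(\\.gz)?$")
  mods <- files[!grepl("_mask_", files)]
  stems <- unique(sub("_[A-Z0-9]+\\.nii(\\.gz)?$", "", mods))
  for (stem in stems) {
    fs <- file.path(img_dir, grep(paste0("^", stem, "_[A-Z0-9]+\\.nii"),
                                  files, value = TRUE))
    hdr <- lapply(fs, function(f)
      tryCatch(read_volume_nifti(f), error = function(e) NULL))
    if (any(vapply(hdr, is.null, logical(1)))) {
      add(stem, "nifti_readable", FALSE, "unreadable volume")
      next
    }
    dims <- lapply(hdr, function(h) dim(h$data))
    sps <- lapply(hdr, function(h) round(h$spacing_mm, 6))
    ok <- length(unique(dims)) == 1L && length(unique(sps)) == 1L
    add(stem, "modalities_coregistered", ok,
        if (ok) "" else "header mismatch across modalities")
    mask_fs <- file.path(img_dir,
                         grep(paste0("^", stem, "_mask_"), files, value = TRUE))
    for (mf in mask_fs) {
      h <- tryCatch(read_volume_nifti(mf), error = function(e) NULL)
      if (is.null(h)) {
        add(stem, "mask_readable", FALSE, basename(mf))
        next
      }
      binary <- all(h$data %in% c(0, 1))
      add(stem, "mask_binary", binary,
          if (binary) basename(mf) else paste("non-binary values in", basename(mf)))
      ongrid <- identical(dim(h$data), dims[[1]])
      add(stem, "mask_on_grid", ongrid,
          if (ongrid) basename(mf) else paste("grid mismatch in", basename(mf)))
    }
  }
  for (sf in list.files(img_dir, pattern = "_streamlines_.*\\.json$",
                        full.names = TRUE)) {
    ok <- tryCatch({ read_streamlines_json(sf); TRUE },
                   error = function(e) FALSE)
    add(basename(sf), "streamlines_parse", ok,
        if (ok) "" else "unparseable streamline file")
  }
  if (!length(rows))
    return(data.frame(scan = character(0), check = character(0),
                      pass = logical(0), detail = character(0)))
  do.call(rbind, rows)
}

.serialize_report <- function(report) {
  list(scheme = report$scheme,
       n_folds = report$n_folds,
       selected_features = as.list(report$selected_features),
       confusion = as.list(report$confusion),
       accuracy = report$accuracy,
       sensitivity = report$sensitivity,
       specificity = report$specificity,
       undefined_metrics = report$undefined_metrics,
       auc = report$roc$auc,
       auc_ci = report$roc$auc_ci,
       optimal_cutoff = report$roc$optimal_cutoff,
       optimal_sensitivity = report$roc$optimal_sensitivity,
       optimal_specificity = report$roc$optimal_specificity,
       feature_ranking = report$feature_ranking,
       notes = report$notes)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full progression-prediction pipeline
#'
#' Generates (or accepts) a cohort, applies the labeling and windowing
#' rules, extracts static and dynamic feature tables, trains and
#' cross-validates the three models, and writes every artifact to
#' `outdir`: the cohort manifest, clinical CSV, config echo (with hash
#' and package version), feature CSVs with schema sidecars, model report
#' JSONs, ROC point CSVs and a run log. Identical config + seed gives
#' byte-identical CSV/JSON artifacts.
#'
#' @param config a [cohort_config]
#' @param outdir output directory
#' @param schemes model schemes to run, subset of
#'   c("static", "dynamic1", "dynamic2")
#' @param n_quantiles,outlier_low_pct,outlier_high_pct extraction knobs
#' @param match_histograms match every volume to the reference (the first
#'   control subject's index scan) before extraction
#' @param max_features,cost model knobs
#' @param select_features run sequential forward selection per fold
#'   (FALSE uses every feature, e.g. for quick demonstration runs)
#' @param n_boot bootstrap resamples for AUC CIs
#' @param overwrite allow writing into a directory holding a completed
#'   run (default FALSE: refuses instead of silently overwriting)
#' @param write_images also write per-scan NIfTI volumes and masks
#' @return named list of `model_report`s (invisibly), one per scheme
#' @export
run_pipeline <- function(config, outdir,
                         schemes = c("static", "dynamic1", "dynamic2"),
                         n_quantiles = 10L, outlier_low_pct = 1,
                         outlier_high_pct = 99, match_histograms = TRUE,
                         max_features = 10L, cost = 1, select_features = TRUE,
                         n_boot = 2000L, overwrite = FALSE,
                         write_images = FALSE) {
  done_marker <- file.path(outdir, "run_complete.json")
  if (file.exists(done_marker) && !overwrite)
    stop_config("outdir", "already holds a completed run (set overwrite = TRUE)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logmsg <- function(...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", "opgpredict", sprintf(...)))
  }
  hash <- .config_hash(config)
  logmsg("config hash %s, package version %s, seed %d",
         hash, .pkg_version(), config$seed)

  cohort <- .stage("simulate", generate_cohort(config))
  logmsg("generated %d subjects", length(cohort))
  ruled <- .stage("label", apply_cohort_rules(cohort))
  manifest <- ruled$manifest
  manifest$config_hash <- hash
  jsonlite::write_json(list(package_version = .pkg_version(),
                            config_hash = hash, manifest = manifest),
                       file.path(outdir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  write_clinical_records(cohort, file.path(outdir, "clinical.csv"))
  if (write_images) .stage("export", write_cohort(cohort, outdir))
  # config echo with resolved seed
  cfg_lines <- c(sprintf("package_version: %s", .pkg_version()),
                 sprintf("config_hash: %s", hash),
                 vapply(names(unclass(config)), function(nm)
                   sprintf("%s: %s", nm,
                           paste(format(config[[nm]]), collapse = " ")),
                   character(1)))
  writeLines(cfg_lines, file.path(outdir, "config_echo.yaml"))

  reference <- NULL
  if (match_histograms) {
    ctrl <- Filter(function(s) s$group == "control", ruled$cohort)
    if (length(ctrl))
      reference <- ctrl[[1L]]$scans[[length(ctrl[[1L]]$scans)]]
    logmsg("histogram-matching reference: index scan of %s",
           if (length(ctrl)) ctrl[[1L]]$subject_id else "none")
  }

  tables <- list()
  if ("static" %in% schemes)
    tables$static <- .stage("extract", assemble_static(
      ruled$cohort, n_quantiles, reference, outlier_low_pct, outlier_high_pct))
  if ("dynamic1" %in% schemes)
    tables$dynamic1 <- .stage("extract", assemble_dynamic(
      ruled$cohort, "successive", n_quantiles, reference,
      outlier_low_pct, outlier_high_pct))
  if ("dynamic2" %in% schemes)
    tables$dynamic2 <- .stage("extract", assemble_dynamic(
      ruled$cohort, "all_pairs", n_quantiles, reference,
      outlier_low_pct, outlier_high_pct))
  for (nm in names(tables))
    write_feature_table(tables[[nm]],
                        file.path(outdir, sprintf("features_%s.csv", nm)))

  reports <- list()
  for (nm in names(tables)) {
    logmsg("training %s model on %d rows x %d features", nm,
           nrow(tables[[nm]]), length(feature_cols(tables[[nm]])))
    rep <- .stage("train", evaluate_progression_model(
      tables[[nm]], max_features = max_features, cost = cost,
      select_features = select_features, n_boot = n_boot,
      seed = config$seed))
    reports[[nm]] <- rep
    out <- .serialize_report(rep)
    out$config_hash <- hash
    jsonlite::write_json(out, file.path(outdir, sprintf("report_%s.json", nm)),
                         auto_unbox = TRUE, digits = 10)
    utils::write.csv(data.frame(threshold = rep$roc$thresholds,
                                sensitivity = rep$roc$sensitivity,
                                specificity = rep$roc$specificity),
                     file.path(outdir, sprintf("roc_%s.csv", nm)),
                     row.names = FALSE)
    logmsg("%s: accuracy %.3f, AUC %.3f", nm, rep$accuracy, rep$roc$auc)
  }
  writeLines(log_lines, file.path(outdir, "run.log"))
  jsonlite::write_json(list(package_version = .pkg_version(),
                            config_hash = hash,
                            schemes = names(reports)),
                       done_marker, auto_unbox = TRUE)
  invisible(reports)
}
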