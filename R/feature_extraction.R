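# Per-region, per-modality intensity features; linear histogram matching;
# static and dynamic (delta) feature table assembly.

#' Feature table container
#'
#' A data frame of named features with metadata columns `subject_id`
#' (always), `scan_id` and `group` (where applicable). The attribute
#' `feature_cols` lists the model-input columns in their deterministic
#' order; `scheme` is one of "static", "dynamic1", "dynamic2".
#'
#' @param df data frame
#' @param scheme table scheme
#' @param feature_cols character vector of feature column names
#' @return object of classes `feature_table` and `data.frame`
#' @export
feature_table <- function(df, scheme = c("static", "dynamic1", "dynamic2"),
                          feature_cols) {
  scheme <- match.arg(scheme)
  if (!all(feature_cols %in% colnames(df)))
    stop("schema error: feature_cols missing from the table", call. = FALSE)
  structure(df, scheme = scheme, feature_cols = feature_cols,
            class = c("feature_table", "data.frame"))
}

#' Feature column names of a table
#' @param x a [feature_table]
#' @return character vector
#' @export
feature_cols <- function(x) attr(x, "feature_cols")

#' Feature matrix of a table
#' @param x a [feature_table]
#' @return numeric matrix (rows x features)
#' @export
feature_matrix <- function(x) {
  as.matrix(as.data.frame(x)[, feature_cols(x), drop = FALSE])
}

#' Linear histogram matching with outlier exclusion
#'
#' Maps a volume's intensities affinely onto a reference: voxels outside
#' the source's `[outlier_low_pct, outlier_high_pct]` percentile window are
#' excluded from the fit, the remaining range is mapped so that the source
#' percentile pair coincides with the reference's, and the affine map is
#' then applied to every voxel (including the excluded ones).
#'
#' @param volume numeric array to rescale
#' @param reference_volume numeric array providing the target percentiles
#' @param outlier_low_pct,outlier_high_pct percentile window (0 <= low <
#'   high <= 100), default 1 and 99
#' @return rescaled array, same shape as `volume`
#' @export
histogram_match <- function(volume, reference_volume,
                            outlier_low_pct = 1, outlier_high_pct = 99) {
  if (!length(volume) || !length(reference_volume))
    stop_empty_region("volume")
  if (outlier_low_pct < 0 || outlier_high_pct > 100 ||
      outlier_low_pct >= outlier_high_pct)
    stop_config("outlier percentiles", "need 0 <= low < high <= 100")
  p <- c(outlier_low_pct, outlier_high_pct) / 100
  src <- stats::quantile(volume, p, names = FALSE)
  ref <- stats::quantile(reference_volume, p, names = FALSE)
  if (src[2] - src[1] <= 0)
    stop("degenerate-scale error: source volume is constant over the fit window",
         call. = FALSE)
  slope <- (ref[2] - ref[1]) / (src[2] - src[1])
  out <- ref[1] + (volume - src[1]) * slope
  if (is.array(volume)) array(out, dim(volume)) else out
}

# quantile probabilities: K evenly spaced interior points, symmetric about
# the median ((k - 0.5)/K), so no duplication of min/max
.quantile_probs <- function(K) (seq_len(K) - 0.5) / K

.stat_names <- function(K) {
  c("min", "max", "mean", "sd", sprintf("q%02d", round(100 * .quantile_probs(K))))
}

#' Per-region, per-modality intensity features
#'
#' For every (region mask, modality) pair, computes min, max, mean, SD and
#' `n_quantiles` evenly spaced quantiles of the voxel intensities inside
#' the region, across all co-registered modalities of the scan.
#'
#' @param scan a [multimodal_scan]
#' @param masks list of [region_mask]s (typically ON_L, ON_R, OR_L, OR_R)
#' @param n_quantiles number of distribution quantiles K (default 10)
#' @return named numeric vector `<region>_<modality>_<stat>` of length
#'   `length(masks) * 7 * (4 + n_quantiles)`
#' @export
extract_region_features <- function(scan, masks, n_quantiles = 10L) {
  probs <- .quantile_probs(n_quantiles)
  out <- numeric(0)
  for (rm in masks) {
    if (!any(rm$mask)) stop_empty_region(rm$label)
    sel <- which(rm$mask)
    for (mod in OPG_MODALITIES) {
      v <- scan$volumes[[mod]][sel]
      stats_v <- c(min(v), max(v), mean(v),
                   if (length(v) > 1L) stats::sd(v) else 0,
                   stats::quantile(v, probs, names = FALSE))
      names(stats_v) <- paste(rm$label, mod, .stat_names(n_quantiles), sep = "_")
      out <- c(out, stats_v)
    }
  }
  out
}

# full feature vector for one scan of one subject: intensity block over the
# four visual-pathway regions + ON morphology block
.scan_features <- function(subject, k, n_quantiles, reference = NULL,
                           outlier_low_pct = 1, outlier_high_pct = 99) {
  scan <- subject$scans[[k]]
  if (!is.null(reference)) {
    vols <- lapply(OPG_MODALITIES, function(mod)
      histogram_match(scan$volumes[[mod]], reference$volumes[[mod]],
                      outlier_low_pct, outlier_high_pct))
    names(vols) <- OPG_MODALITIES
    scan <- multimodal_scan(vols, scan$spacing_mm, scan$time_years)
  }
  masks <- subject$masks[[k]]
  c(extract_region_features(scan, masks, n_quantiles),
    morphology_features(masks$ON_L),
    morphology_features(masks$ON_R))
}

#' Assemble the static feature table
#'
#' One row per scan (subject id carried along): intensity features of the
#' four visual-pathway regions across all modalities, plus optic-nerve
#' morphology, in a deterministic column order. When `reference` is given,
#' every volume is first histogram-matched to the reference scan's volume
#' of the same modality.
#'
#' @param cohort list of subjects as produced by [generate_cohort] (or
#'   relabelled by [apply_cohort_rules])
#' @param n_quantiles distribution quantiles per feature block
#' @param reference optional [multimodal_scan] used as the histogram
#'   matching target (default: no matching)
#' @param outlier_low_pct,outlier_high_pct percentile window for matching
#' @return a [feature_table] with scheme "static"
#' @export
assemble_static <- function(cohort, n_quantiles = 10L, reference = NULL,
                            outlier_low_pct = 1, outlier_high_pct = 99) {
  rows <- list()
  meta <- list()
  for (subj in cohort) {
    for (k in seq_along(subj$scans)) {
      rows[[length(rows) + 1L]] <-
        .scan_features(subj, k, n_quantiles, reference,
                       outlier_low_pct, outlier_high_pct)
      meta[[length(meta) + 1L]] <-
        data.frame(subject_id = subj$subject_id,
                   scan_id = sprintf("%s_s%d", subj$subject_id, k),
                   group = subj$group, stringsAsFactors = FALSE)
    }
  }
  nm <- names(rows[[1L]])
  if (!all(vapply(rows, function(r) identical(names(r), nm), logical(1))))
    stop("schema error: inconsistent feature sets across scans", call. = FALSE)
  mat <- do.call(rbind, rows)
  df <- cbind(do.call(rbind, meta),
              as.data.frame(mat, check.names = FALSE))
  rownames(df) <- NULL
  feature_table(df, "static", nm)
}

.scan_pairs <- function(s, scheme) {
  if (scheme == "successive") {
    if (s < 2L) return(NULL)
    cbind(earlier = seq_len(s - 1L), later = 2:s)
  } else {
    pr <- t(utils::combn(s, 2L))
    cbind(earlier = pr[, 1], later = pr[, 2])
  }
}

#' Assemble a dynamic (delta) feature table
#'
#' One row per subject with at least two scans: the base features of the
#' index (most recent) scan plus one difference block per scan pair in the
#' scheme, computed as later minus earlier. `successive` uses consecutive
#' pairs only (s - 1 blocks for s scans); `all_pairs` uses every
#' chronological pair (s(s-1)/2 blocks). Subjects with a single scan are
#' excluded with a warning.
#'
#' @param cohort list of subjects
#' @param scheme "successive" (dynamic 1) or "all_pairs" (dynamic 2)
#' @inheritParams assemble_static
#' @return a [feature_table] with scheme "dynamic1" or "dynamic2"
#' @export
assemble_dynamic <- function(cohort, scheme = c("successive", "all_pairs"),
                             n_quantiles = 10L, reference = NULL,
                             outlier_low_pct = 1, outlier_high_pct = 99) {
  scheme <- match.arg(scheme)
  rows <- list(); meta <- list()
  for (subj in cohort) {
    s <- length(subj$scans)
    if (s < 2L) {
      warning(sprintf("subject %s excluded from dynamic table: only %d scan",
                      subj$subject_id, s), call. = FALSE)
      next
    }
    per_scan <- lapply(seq_len(s), function(k)
      .scan_features(subj, k, n_quantiles, reference,
                     outlier_low_pct, outlier_high_pct))
    base <- per_scan[[s]]
    pairs <- .scan_pairs(s, scheme)
    deltas <- lapply(seq_len(nrow(pairs)), function(p) {
      d <- per_scan[[pairs[p, "later"]]] - per_scan[[pairs[p, "earlier"]]]
      names(d) <- sprintf("delta_s%d-s%d_%s", pairs[p, "later"],
                          pairs[p, "earlier"], names(d))
      d
    })
    rows[[length(rows) + 1L]] <- c(base, unlist(deltas))
    meta[[length(meta) + 1L]] <-
      data.frame(subject_id = subj$subject_id, group = subj$group,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("insufficient-data error: no subject has >= 2 scans", call. = FALSE)
  nm <- names(rows[[1L]])
  if (!all(vapply(rows, function(r) identical(names(r), nm), logical(1))))
    stop("schema error: inconsistent feature sets across subjects", call. = FALSE)
  df <- cbind(do.call(rbind, meta),
              as.data.frame(do.call(rbind, rows), check.names = FALSE))
  rownames(df) <- NULL
  feature_table(df, if (scheme == "successive") "dynamic1" else "dynamic2", nm)
}

#' Write a feature table with its sidecar schema
#'
#' Round-trips a [feature_table] to CSV plus a JSON sidecar carrying the
#' scheme and the deterministic column order.
#'
#' @param x a [feature_table]
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.schema.json`
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(list(scheme = attr(x, "scheme"),
                            feature_cols = feature_cols(x)),
                       paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table]
#' @param path CSV path
#' @return a [feature_table]
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sc <- jsonlite::read_json(paste0(path, ".schema.json"), simplifyVector = TRUE)
  feature_table(df, sc$scheme, sc$feature_cols)
}
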