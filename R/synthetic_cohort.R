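# Synthetic longitudinal multi-modal cohorts with known ground truth.
#
# The generator emulates a matched case-control imaging study of optic
# pathway glioma (OPG): two groups of subjects, 1-3 surveillance scans each
# inside a 2-year window, seven co-registered modalities on one grid,
# tubular optic-nerve (ON) masks, streamline-defined optic-radiation (OR)
# masks, and a group-dependent scaled-FA signal inside the ORs.

#' Imaging modalities carried by every scan
#' @export
OPG_MODALITIES <- c("T1", "T1CE", "T2", "FLAIR", "FA", "TR", "RAD")

# background mean intensity per modality (arbitrary scaled units)
.modality_background <- c(T1 = 10, T1CE = 12, T2 = 8, FLAIR = 9,
                          FA = 4, TR = 5, RAD = 4.5)

#' Configuration for a synthetic OPG cohort
#'
#' Bundles the cohort design: group sizes, scans per subject, grid geometry,
#' and the group-conditional scaled-FA distribution inside the optic
#' radiations. Defaults reproduce the reference study conditions: 19
#' progression cases matched to 19 controls, and OR scaled-FA distributed
#' 6.23 +/- 3.56 in cases versus 2.38 +/- 1.79 in controls.
#'
#' The printed group SDs are between-subject SDs: each subject receives a
#' latent OR-FA level drawn from a normal with between-subject SD
#' sqrt(sd^2 - noise_sd^2), and voxels scatter around that latent with SD
#' `noise_sd`, so voxel values marginally follow the configured group
#' normal while subject OR-mean FA reproduces the printed between-subject
#' spread. Scaled FA is a signed arbitrary-unit quantity (an affine
#' histogram rescaling of diffusion anisotropy), so it is not clamped at
#' zero; anatomical modality backgrounds are.
#'
#' @param n_cases,n_controls subjects per group (>= 1)
#' @param scans_per_subject scans per subject, 1-3
#' @param grid_shape integer 3-vector of voxels per axis (each >= 16)
#' @param voxel_spacing_mm numeric 3-vector, mm per voxel
#' @param fa_mean_case,fa_sd_case,fa_mean_control,fa_sd_control scaled-FA
#'   group distribution inside the ORs (arbitrary units; SDs > 0)
#' @param drift_per_interval named numeric vector: per-modality mean shift
#'   applied inside the ORs between consecutive scans of case subjects
#'   (later scan = earlier + drift), so the index scan carries the full
#'   group distribution
#' @param noise_sd within-subject voxel SD of OR intensities; must be
#'   smaller than both group SDs
#' @param on_radius_mm optic-nerve tube radius
#' @param progression_radius_factor multiplicative ON radius increase on the
#'   index scan of cases (the radiographic-progression signal)
#' @param n_streamlines streamlines per optic radiation
#' @param seed integer seed controlling all randomness of the cohort
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_cases = 19L, n_controls = 19L,
                          scans_per_subject = 3L,
                          grid_shape = c(32L, 32L, 32L),
                          voxel_spacing_mm = c(1, 1, 1),
                          fa_mean_case = 6.23, fa_sd_case = 3.56,
                          fa_mean_control = 2.38, fa_sd_control = 1.79,
                          drift_per_interval = c(FA = 1.25),
                          noise_sd = 0.5,
                          on_radius_mm = 2.5,
                          progression_radius_factor = 1.3,
                          n_streamlines = 25L,
                          seed = 1L) {
  n_cases <- assert_count(n_cases, "n_cases")
  n_controls <- assert_count(n_controls, "n_controls")
  scans_per_subject <- assert_count(scans_per_subject, "scans_per_subject")
  if (scans_per_subject > 3L)
    stop_config("scans_per_subject", "must be between 1 and 3")
  if (length(grid_shape) != 3L || any(grid_shape < 16))
    stop_config("grid_shape", "must be 3 axes of >= 16 voxels")
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop_config("voxel_spacing_mm", "must be 3 positive spacings")
  for (f in c("fa_sd_case", "fa_sd_control"))
    if (get(f) <= 0) stop_config(f, "SD must be > 0")
  if (noise_sd <= 0 || noise_sd >= min(fa_sd_case, fa_sd_control))
    stop_config("noise_sd", "must be positive and below both group SDs")
  if (!is.numeric(drift_per_interval) ||
      (length(drift_per_interval) && is.null(names(drift_per_interval))))
    stop_config("drift_per_interval", "must be a named numeric vector")
  if (length(drift_per_interval) &&
      !all(names(drift_per_interval) %in% OPG_MODALITIES))
    stop_config("drift_per_interval",
                paste("names must be among", paste(OPG_MODALITIES, collapse = ", ")))
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(
    n_cases = n_cases, n_controls = n_controls,
    scans_per_subject = scans_per_subject,
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    fa_mean_case = fa_mean_case, fa_sd_case = fa_sd_case,
    fa_mean_control = fa_mean_control, fa_sd_control = fa_sd_control,
    drift_per_interval = drift_per_interval,
    noise_sd = noise_sd,
    on_radius_mm = on_radius_mm,
    progression_radius_factor = progression_radius_factor,
    n_streamlines = as.integer(n_streamlines),
    seed = seed), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic OPG cohort configuration\n")
  cat(sprintf("  %d cases / %d controls, %d scan(s) per subject\n",
              x$n_cases, x$n_controls, x$scans_per_subject))
  cat(sprintf("  grid %s voxels at %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_spacing_mm, collapse = "x")))
  cat(sprintf("  OR scaled-FA: cases %.2f +/- %.2f, controls %.2f +/- %.2f\n",
              x$fa_mean_case, x$fa_sd_case, x$fa_mean_control, x$fa_sd_control))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Construct a multimodal scan object
#'
#' @param volumes named list of 3D arrays, one per modality in
#'   [OPG_MODALITIES], identical dimensions
#' @param spacing_mm voxel spacing, mm
#' @param time_years scan time relative to the index scan (<= 0)
#' @return object of class `multimodal_scan`
#' @export
multimodal_scan <- function(volumes, spacing_mm, time_years) {
  if (!setequal(names(volumes), OPG_MODALITIES))
    stop("scan must carry exactly the modalities: ",
         paste(OPG_MODALITIES, collapse = ", "))
  dims <- lapply(volumes, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop_geometry("all modalities of a scan must share one grid")
  structure(list(volumes = volumes[OPG_MODALITIES],
                 spacing_mm = as.numeric(spacing_mm),
                 time_years = time_years),
            class = "multimodal_scan")
}

#' Construct a region mask
#'
#' @param mask 3D logical array on the scan grid
#' @param label region label, e.g. "ON_L", "OR_R", "ROI_A"
#' @param spacing_mm voxel spacing, mm
#' @return object of class `region_mask`
#' @export
region_mask <- function(mask, label, spacing_mm) {
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, label = label,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "region_mask")
}

#' Construct a streamline set
#'
#' @param lines list of n x 3 numeric matrices (world mm), each with >= 2 rows
#' @return object of class `streamline_set`
#' @export
streamline_set <- function(lines) {
  ok <- vapply(lines, function(l) is.matrix(l) && ncol(l) == 3 && nrow(l) >= 2,
               logical(1))
  if (length(lines) && !all(ok))
    stop("every streamline must be an n x 3 matrix with >= 2 points")
  structure(list(lines = lines, count = length(lines)),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("Streamline set: %d polyline(s)\n", x$count))
  invisible(x)
}

# small axis-aligned box mask used as streamline seed/target ROI
make_box_mask <- function(grid_shape, spacing_mm, centre_mm, half_mm, label) {
  ax <- lapply(1:3, function(a) {
    w <- (seq_len(grid_shape[a]) - 1) * spacing_mm[a]
    abs(w - centre_mm[a]) <= half_mm[a]
  })
  m <- array(FALSE, grid_shape)
  m[ax[[1]], ax[[2]], ax[[3]]] <- TRUE
  region_mask(m, label, spacing_mm)
}

# distance from each of a set of points to a polyline (min over segments)
.dist_to_polyline <- function(pts, path) {
  d2 <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(path) - 1L)) {
    a <- path[k, ]; b <- path[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- if (len2 > 0) pmin(1, pmax(0, (ap %*% ab) / len2)) else 0
    proj <- sweep(t %*% t(ab), 2, a, "+")
    d2 <- pmin(d2, rowSums((pts - proj)^2))
  }
  sqrt(d2)
}

# tube membership: perpendicular distance <= radius to some segment, with
# the projection falling inside the segment, so tube ends are flat (no
# spherical caps) and the voxel count tracks the analytic cylinder volume
.in_tube <- function(pts, path, radius) {
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(path) - 1L)) {
    a <- path[k, ]; b <- path[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    ap <- sweep(pts, 2, a)
    t <- as.numeric(ap %*% ab) / len2
    proj <- sweep(outer(t, ab), 2, a, "+")
    d2 <- rowSums((pts - proj)^2)
    inside <- inside | (t >= 0 & t <= 1 & d2 <= radius^2)
  }
  inside
}

#' Generate a tubular region mask around a polyline
#'
#' Stands in for manual optic-nerve segmentation: the mask is the set of
#' voxels whose centres lie within `radius_mm` of the axis path.
#'
#' @param grid_shape integer 3-vector
#' @param spacing_mm numeric 3-vector, mm
#' @param axis_path n x 3 matrix of world-mm points along the tube axis
#' @param radius_mm tube radius; must be at least half the minimum in-plane
#'   spacing so the tube is at least one voxel wide
#' @param label region label for the mask
#' @return a [region_mask]
#' @export
generate_tube_mask <- function(grid_shape, spacing_mm, axis_path, radius_mm,
                               label = "ON") {
  if (radius_mm < min(spacing_mm[1:2]) / 2)
    stop_geometry("tube radius is below half the in-plane voxel spacing")
  idx <- world_to_index(axis_path, spacing_mm)
  if (!all(index_in_grid(idx, grid_shape)))
    stop_geometry("axis path leaves the grid")
  # restrict the distance computation to a bounding box around the path
  lo <- pmax(1L, apply(idx, 2, min) - ceiling(radius_mm / spacing_mm) - 1L)
  hi <- pmin(grid_shape, apply(idx, 2, max) + ceiling(radius_mm / spacing_mm) + 1L)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  centres <- as.matrix(expand.grid(x = (xs - 1) * spacing_mm[1],
                                   y = (ys - 1) * spacing_mm[2],
                                   z = (zs - 1) * spacing_mm[3]))
  inside <- .in_tube(centres, axis_path, radius_mm)
  m <- array(FALSE, grid_shape)
  sub <- array(inside, dim = c(length(xs), length(ys), length(zs)))
  m[xs, ys, zs] <- sub
  if (!any(m)) stop_geometry("tube mask is empty")
  region_mask(m, label, spacing_mm)
}

# voxel centres (world mm) of the true voxels of a mask
.mask_centres <- function(rm) {
  idx <- which(rm$mask, arr.ind = TRUE)
  sweep(idx - 1, 2, rm$spacing_mm, "*")
}

#' Generate synthetic streamlines between two seed regions
#'
#' Emulates a tractography output restricted to a bundle: each valid
#' polyline starts at a voxel centre of `roi_a` and ends at a voxel centre
#' of `roi_b`, with a gentle bow in between. A configurable fraction of
#' decoy lines is added that provably avoids `roi_a`, so ROI-logic
#' filtering has true negatives to reject.
#'
#' @param roi_a,roi_b disjoint [region_mask] seed and target regions
#' @param n_lines total number of polylines
#' @param decoy_fraction fraction (rounded to a count) of lines violating
#'   the A-AND-B criterion
#' @param seed optional integer; when given, the global RNG state is saved
#'   and restored around the draw so the call is reproducible in isolation
#' @return a [streamline_set]; attribute `n_decoys` records the decoy count
#' @export
generate_streamlines <- function(roi_a, roi_b, n_lines = 25L,
                                 decoy_fraction = 0, seed = NULL) {
  if (!any(roi_a$mask) || !any(roi_b$mask))
    stop_geometry("streamline seed ROI is empty")
  if (any(roi_a$mask & roi_b$mask))
    stop_geometry("seed ROIs must be disjoint")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  spacing <- roi_a$spacing_mm
  grid_shape <- dim(roi_a$mask)
  ca <- .mask_centres(roi_a); cb <- .mask_centres(roi_b)
  n_decoy <- round(decoy_fraction * n_lines)
  n_valid <- n_lines - n_decoy
  lines <- vector("list", n_lines)
  for (i in seq_len(n_valid)) {
    a <- ca[sample.int(nrow(ca), 1L), ]
    b <- cb[sample.int(nrow(cb), 1L), ]
    t <- seq(0, 1, length.out = 12L)
    base <- outer(1 - t, a) + outer(t, b)
    # bow perpendicular to the chord, plus small jitter on interior points
    perp <- c(-(b - a)[3], 0, (b - a)[1])
    if (sum(perp^2) < 1e-9) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    amp <- stats::runif(1, 0, 1.5)
    pts <- base + outer(sin(pi * t) * amp, perp)
    pts[2:11, ] <- pts[2:11, ] + matrix(stats::rnorm(10L * 3L, 0, 0.15), 10L, 3L)
    pts[1, ] <- a; pts[12L, ] <- b
    lines[[i]] <- pts
  }
  for (i in seq_len(n_decoy)) {
    # short segments constructed (and verified) to avoid roi_a entirely
    repeat {
      p <- c(stats::runif(1, 0, (grid_shape[1] - 1) * spacing[1]),
             stats::runif(1, 0, (grid_shape[2] - 1) * spacing[2]),
             stats::runif(1, 0, (grid_shape[3] - 1) * spacing[3]))
      q <- p + stats::rnorm(3, 0, spacing)
      q <- pmin(pmax(q, 0), (grid_shape - 1) * spacing)
      seg <- rbind(p, q)
      if (!.line_hits_mask(seg, roi_a)) break
    }
    lines[[n_valid + i]] <- seg
  }
  out <- streamline_set(lines)
  attr(out, "n_decoys") <- n_decoy
  out
}

# Two-level intensity model for the scaled-FA signal. The printed group
# SDs are between-subject SDs, so each subject carries a latent region
# mean from N(mean, sd_b) with sd_b = sqrt(sd^2 - noise_sd^2), and voxels
# scatter around it as N(latent, noise_sd): voxel marginals are exactly
# the configured N(mean, sd), and subject OR-means reproduce the printed
# between-subject spread. Scaled FA is a signed arbitrary-unit quantity
# (the affine histogram rescaling can produce negative values), so these
# draws are not clamped at zero.

# subject latent from a uniform draw (inverse CDF), so one uniform per
# subject pins the latent across all of its scans
.subject_latent <- function(u, mean, sd, noise_sd) {
  mean + sqrt(sd^2 - noise_sd^2) * stats::qnorm(u)
}

.draw_region_intensity <- function(n, latent, noise_sd) {
  latent + stats::rnorm(n, 0, noise_sd)
}

.subject_geometry <- function(cfg, on_radius_mm) {
  g <- cfg$grid_shape; s <- cfg$voxel_spacing_mm
  W <- (g - 1) * s  # world extent, mm
  t <- seq(0, 1, length.out = 15L)
  paths <- list(
    ON_L = cbind(0.32 * W[1] + 1.2 * sin(pi * t),
                 (0.10 + 0.35 * t) * W[2],
                 0.5 * W[3] + 0.8 * sin(2 * pi * t) * 0.5),
    ON_R = cbind(0.68 * W[1] - 1.2 * sin(pi * t),
                 (0.10 + 0.35 * t) * W[2],
                 0.5 * W[3] + 0.8 * sin(2 * pi * t) * 0.5))
  masks <- list()
  for (side in c("L", "R")) {
    on_lab <- paste0("ON_", side)
    masks[[on_lab]] <- generate_tube_mask(g, s, paths[[on_lab]],
                                          on_radius_mm, label = on_lab)
    xc <- if (side == "L") 0.40 * W[1] else 0.60 * W[1]
    roi_a <- make_box_mask(g, s, c(xc, 0.52 * W[2], 0.5 * W[3]),
                           c(1.5, 1.5, 1.5) * s, "ROI_A")
    roi_b <- make_box_mask(g, s, c(xc + if (side == "L") -2 else 2,
                                   0.88 * W[2], 0.5 * W[3]),
                           c(3, 1.5, 2.5) * s, "ROI_B")
    sl <- generate_streamlines(roi_a, roi_b, n_lines = cfg$n_streamlines)
    or_lab <- paste0("OR_", side)
    or <- streamlines_to_mask(sl, g, s)
    or$label <- or_lab
    masks[[or_lab]] <- or
    masks[[paste0("streamlines_", side)]] <- sl
  }
  masks
}

#' Generate a synthetic longitudinal OPG cohort
#'
#' Produces `n_cases + n_controls` subjects, each with 1-3 co-registered
#' multimodal scans, optic-nerve and optic-radiation masks, streamline
#' sets, a visual-acuity (logMAR) series and per-scan radiographic flags.
#' Scaled-FA voxels inside the ORs follow the group's configured truncated
#' normal; case subjects additionally carry the configured per-interval
#' drift across successive scans and an ON radius increase on the index
#' scan (the radiographic-progression signal). Case subjects always have
#' at least one progression indicator; controls never do.
#'
#' @param config a [cohort_config]
#' @return list of `synthetic_subject` objects (fields `subject_id`,
#'   `group`, `scans`, `masks`, `streamlines`, `va_series`,
#'   `radiographic_flags`), deterministic for a fixed config seed
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_config("config", "must be a cohort_config object")
  set.seed(config$seed)
  g <- config$grid_shape; s <- config$voxel_spacing_mm
  nvox <- prod(g)
  # geometry is shared across subjects (the progression signal is the index
  # scan radius bump); compute the two variants once
  geo_base <- .subject_geometry(config, config$on_radius_mm)
  geo_prog <- .subject_geometry(config, config$on_radius_mm *
                                  config$progression_radius_factor)
  ids <- c(sprintf("case%03d", seq_len(config$n_cases)),
           sprintf("ctrl%03d", seq_len(config$n_controls)))
  groups <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  subjects <- vector("list", length(ids))
  ns <- config$scans_per_subject
  for (si in seq_along(ids)) {
    grp <- groups[si]
    mu <- if (grp == "case") config$fa_mean_case else config$fa_mean_control
    sg <- if (grp == "case") config$fa_sd_case else config$fa_sd_control
    fa_latent <- .subject_latent(stats::runif(1), mu, sg, config$noise_sd)
    # index scan at t = 0, preceding scans at negative times within 2 years
    gaps <- stats::runif(ns - 1, 0.3, 0.9)
    times <- rev(-c(0, cumsum(gaps)))
    scans <- vector("list", ns); masks <- vector("list", ns)
    streamlines <- vector("list", ns); flags <- logical(ns)
    for (k in seq_len(ns)) {
      is_index <- k == ns
      geo <- if (grp == "case" && is_index) geo_prog else geo_base
      steps_back <- ns - k
      vols <- list()
      for (mod in OPG_MODALITIES) {
        v <- array(stats::rnorm(nvox, .modality_background[[mod]], 1), g)
        v[v < 0] <- 0
        # ON regions run slightly bright on T2/FLAIR (group-independent)
        if (mod %in% c("T2", "FLAIR")) {
          onv <- geo$ON_L$mask | geo$ON_R$mask
          v[onv] <- v[onv] + 2
        }
        drift <- if (grp == "case") config$drift_per_interval[mod] else NA_real_
        drift <- if (is.na(drift)) 0 else drift
        orv <- geo$OR_L$mask | geo$OR_R$mask
        n_or <- sum(orv)
        if (mod == "FA") {
          v[orv] <- .draw_region_intensity(n_or, fa_latent - steps_back * drift,
                                           config$noise_sd)
        } else if (drift != 0) {
          v[orv] <- v[orv] - steps_back * drift
          v[v < 0] <- 0
        }
        vols[[mod]] <- v
      }
      scans[[k]] <- multimodal_scan(vols, s, times[k])
      masks[[k]] <- geo[c("ON_L", "ON_R", "OR_L", "OR_R")]
      streamlines[[k]] <- geo[c("streamlines_L", "streamlines_R")]
      flags[k] <- grp == "case" && is_index
    }
    # visual acuity: controls fluctuate below the 0.2 logMAR threshold;
    # about half of cases additionally worsen by 0.3 at the index visit
    base_va <- round(stats::runif(1, 0.0, 0.3), 2)
    va <- base_va + round(stats::runif(ns, -0.05, 0.05), 2)
    va_worsens <- grp == "case" && stats::runif(1) < 0.5
    if (va_worsens) va[ns] <- va[ns - (ns > 1)] + 0.3
    subjects[[si]] <- structure(list(
      subject_id = ids[si], group = grp, scans = scans, masks = masks,
      streamlines = streamlines,
      va_series = data.frame(time_years = times,
                             logmar_od = va,
                             logmar_os = rep(0.0, ns)),
      radiographic_flags = flags), class = "synthetic_subject")
  }
  subjects
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject %s (%s): %d scan(s) at t = %s yr\n",
              x$subject_id, x$group, length(x$scans),
              paste(sprintf("%.2f", vapply(x$scans, `[[`, 0, "time_years")),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a subject-level progression feature table
#'
#' Draws one informative column (the subject-level OR scaled-FA mean, from
#' the configured group distributions) plus `n_noise` standard-normal noise
#' columns, for model-level experiments at the study's subject scale
#' without synthesising full image volumes.
#'
#' @param n_cases,n_controls subjects per group
#' @param fa_mean_case,fa_sd_case,fa_mean_control,fa_sd_control group
#'   distribution of the informative feature
#' @param n_noise number of uninformative N(0,1) feature columns
#' @param truncate_at_zero draw the informative feature from the
#'   zero-truncated group normals instead of the plain normals; the
#'   default FALSE is the binormal reading of the printed group summaries
#'   and matches the image generator's signed scaled-FA model
#' @param seed integer seed
#' @return a [feature_table] with scheme "static", one row per subject;
#'   the informative column is named `OR_FA_mean`
#' @export
simulate_progression_features <- function(n_cases = 19L, n_controls = 19L,
                                          fa_mean_case = 6.23,
                                          fa_sd_case = 3.56,
                                          fa_mean_control = 2.38,
                                          fa_sd_control = 1.79,
                                          n_noise = 50L,
                                          truncate_at_zero = FALSE,
                                          seed = 1L) {
  set.seed(seed)
  n <- n_cases + n_controls
  rdraw <- if (truncate_at_zero) rtnorm0 else stats::rnorm
  fa <- c(rdraw(n_cases, fa_mean_case, fa_sd_case),
          rdraw(n_controls, fa_mean_control, fa_sd_control))
  noise <- matrix(stats::rnorm(n * n_noise), n, n_noise,
                  dimnames = list(NULL, sprintf("noise_%02d", seq_len(n_noise))))
  df <- data.frame(subject_id = c(sprintf("case%03d", seq_len(n_cases)),
                                  sprintf("ctrl%03d", seq_len(n_controls))),
                   group = rep(c("case", "control"), c(n_cases, n_controls)),
                   OR_FA_mean = fa, noise, check.names = FALSE,
                   stringsAsFactors = FALSE)
  feature_table(df, scheme = "static",
                feature_cols = c("OR_FA_mean", colnames(noise)))
}
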