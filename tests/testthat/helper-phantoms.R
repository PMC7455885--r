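# Phantom builders and independent oracles used across the suite.

# 2D digital disk slice: voxel centres within radius_vox of the centre
make_disk_slice <- function(radius_vox, size = 2 * radius_vox + 5) {
  c0 <- (size + 1) / 2
  outer(seq_len(size), seq_len(size), function(i, j)
    (i - c0)^2 + (j - c0)^2 <= radius_vox^2)
}

# straight digital cylinder along the slice axis
make_cylinder_mask <- function(radius_mm, length_mm, spacing = c(1, 1, 1),
                               pad = 5) {
  nxy <- ceiling(2 * radius_mm / spacing[1]) + 2 * pad
  nz <- ceiling(length_mm / spacing[3]) + 2 * pad
  path <- cbind((nxy - 1) * spacing[1] / 2, (nxy - 1) * spacing[2] / 2,
                seq(pad, pad + length_mm / spacing[3],
                    length.out = 11) * spacing[3])
  generate_tube_mask(c(nxy, nxy, nz), spacing, path, radius_mm, "ON_L")
}

# independent perimeter oracle for convex blobs: order the boundary voxels
# by angle around the centroid and sum consecutive distances (closing the
# loop) -- no contour-following involved
oracle_perimeter_convex <- function(sl, spacing = c(1, 1)) {
  nr <- nrow(sl); nc <- ncol(sl)
  is_boundary <- function(i, j) {
    if (!sl[i, j]) return(FALSE)
    (i == 1 || !sl[i - 1, j]) || (i == nr || !sl[i + 1, j]) ||
      (j == 1 || !sl[i, j - 1]) || (j == nc || !sl[i, j + 1])
  }
  bd <- which(matrix(mapply(is_boundary, row(sl), col(sl)), nr, nc),
              arr.ind = TRUE)
  ctr <- colMeans(bd)
  ang <- atan2(bd[, 1] - ctr[1], bd[, 2] - ctr[2])
  bd <- bd[order(ang), , drop = FALSE]
  closed <- rbind(bd, bd[1, , drop = FALSE])
  steps <- diff(closed)
  sum(sqrt((steps[, 1] * spacing[1])^2 + (steps[, 2] * spacing[2])^2))
}

# independent streamline/mask membership predicate, written as naive
# per-point loops over the contract's sampling: segment subdivision to at
# most half-voxel steps, nearest-centre membership
oracle_line_hits_mask <- function(line, rm) {
  step <- min(rm$spacing_mm) / 2
  for (k in seq_len(nrow(line) - 1)) {
    a <- line[k, ]; b <- line[k + 1, ]
    nseg <- max(1, ceiling(sqrt(sum((b - a)^2)) / step))
    for (t in (0:nseg) / nseg) {
      p <- (1 - t) * a + t * b
      idx <- round(p / rm$spacing_mm) + 1
      if (all(idx >= 1) && all(idx <= dim(rm$mask)) &&
          rm$mask[idx[1], idx[2], idx[3]])
        return(TRUE)
    }
  }
  FALSE
}

# independent rasterization oracle: naive per-segment loop at the same
# contract sampling density
oracle_rasterize <- function(lines, grid_shape, spacing) {
  m <- array(FALSE, grid_shape)
  step <- min(spacing) / 2
  for (l in lines$lines) {
    for (k in seq_len(nrow(l) - 1)) {
      a <- l[k, ]; b <- l[k + 1, ]
      nseg <- max(1, ceiling(sqrt(sum((b - a)^2)) / step))
      for (t in (0:nseg) / nseg) {
        p <- (1 - t) * a + t * b
        idx <- round(p / spacing) + 1
        if (all(idx >= 1) && all(idx <= grid_shape))
          m[idx[1], idx[2], idx[3]] <- TRUE
      }
    }
  }
  m
}

# small cohort config for fast end-to-end tests
tiny_config <- function(...) {
  cohort_config(n_cases = 2L, n_controls = 2L, scans_per_subject = 2L,
                grid_shape = c(16L, 16L, 16L), seed = 7L, ...)
}

# hand-built subject with the given per-scan constant FA value inside a
# fixed box region; all other modalities constant 1
make_flat_subject <- function(id, group, fa_values, times = NULL) {
  g <- c(16L, 16L, 16L); sp <- c(1, 1, 1)
  n <- length(fa_values)
  if (is.null(times)) times <- seq(-0.5 * (n - 1), 0, by = 0.5)
  box <- array(FALSE, g); box[6:10, 6:10, 6:10] <- TRUE
  masks_one <- list(
    ON_L = opgpredict::region_mask(box, "ON_L", sp),
    ON_R = opgpredict::region_mask(box, "ON_R", sp),
    OR_L = opgpredict::region_mask(box, "OR_L", sp),
    OR_R = opgpredict::region_mask(box, "OR_R", sp))
  scans <- lapply(seq_len(n), function(k) {
    vols <- lapply(OPG_MODALITIES, function(mod)
      array(if (mod == "FA") fa_values[k] else 1, g))
    names(vols) <- OPG_MODALITIES
    opgpredict::multimodal_scan(vols, sp, times[k])
  })
  structure(list(subject_id = id, group = group, scans = scans,
                 masks = rep(list(masks_one), n),
                 streamlines = rep(list(NULL), n),
                 va_series = data.frame(time_years = times,
                                        logmar_od = rep(0.1, n),
                                        logmar_os = rep(0, n)),
                 radiographic_flags = c(rep(FALSE, n - 1), group == "case")),
            class = "synthetic_subject")
}
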