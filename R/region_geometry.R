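# Optic-nerve morphometry and ROI-logic streamline filtering.
#
# Conventions: slices for per-slice operators are taken along the third
# array axis (axial acquisition). A boundary voxel is a true voxel with at
# least one false 4-neighbour in-plane; the perimeter walk is Moore
# (8-connected) contour following, with steps weighted 1 or sqrt(2) times
# the in-plane spacing. Voxel centres sit at world = (index - 1) * spacing.

.check_mask <- function(mask, what = "mask") {
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  if (!any(m)) stop_empty_region(what)
  m
}

#' Region volume
#'
#' Volume is exact by definition: the count of true voxels times the voxel
#' volume, i.e. the segmented area accumulated across all slices.
#'
#' @param mask a [region_mask]
#' @return volume in mm^3
#' @export
compute_volume <- function(mask) {
  m <- .check_mask(mask, mask$label %||% "mask")
  sum(m) * prod(mask$spacing_mm)
}

# 8-connected component labelling of a 2D logical matrix (BFS flood fill)
.label_components_2d <- function(sl) {
  lab <- matrix(0L, nrow(sl), ncol(sl))
  nxt <- 0L
  idx <- which(sl)
  nr <- nrow(sl); nc <- ncol(sl)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (sl[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# boundary voxels: true with >= 1 false 4-neighbour in-plane (grid edge
# counts as false)
.boundary_2d <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sl
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  core & !nb
}

# Moore contour following around one 8-connected component.
# Returns the ordered closed sequence of boundary voxel (row, col) pairs.
.trace_contour <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  idx <- which(comp)
  if (length(idx) == 1L) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    return(matrix(c(r, c), 1L, 2L))
  }
  # clockwise Moore neighbourhood starting west
  moves <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                 c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && comp[r, c]
  start <- idx[1L]  # column-major scan order: first in lowest column
  sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
  path <- matrix(c(sr, sc), 1L, 2L)
  # the start voxel is the first in column-major scan order, so its west
  # neighbour is false: pretend we arrived moving east
  prev_dir <- 5L
  cur <- c(sr, sc)
  first_move <- NULL
  repeat {
    # search clockwise starting one step back from the backtrack direction
    found <- FALSE
    for (k in 0:7) {
      d <- ((prev_dir - 1L + 5L + k) %% 8L) + 1L  # start behind-left
      rr <- cur[1] + moves[d, 1]; cc <- cur[2] + moves[d, 2]
      if (inside(rr, cc)) {
        nxt <- c(rr, cc)
        if (is.null(first_move)) first_move <- d
        else if (all(cur == c(sr, sc)) && d == first_move) return(path)
        path <- rbind(path, nxt)
        prev_dir <- d
        cur <- nxt
        found <- TRUE
        break
      }
    }
    if (!found) return(path)  # isolated voxel (shouldn't reach here)
    if (nrow(path) > 8L * length(idx)) return(path)  # safety stop
  }
}

#' Slice perimeter by boundary walking
#'
#' Orders the boundary voxels of each in-plane component by 8-connected
#' contour traversal and sums the Euclidean distances between consecutive
#' boundary voxels, closing the loop, scaled by the in-plane spacing.
#' Multiple components contribute the sum of their perimeters. A single
#' voxel is a degenerate loop of perimeter 0.
#'
#' @param mask_slice 2D logical matrix (one axial slice)
#' @param spacing_mm in-plane spacing, length-2 numeric (mm)
#' @return perimeter in mm
#' @export
compute_perimeter <- function(mask_slice, spacing_mm) {
  sl <- .check_mask(mask_slice, "slice")
  if (!is.matrix(sl)) stop_geometry("perimeter expects a 2D slice")
  lab <- .label_components_2d(sl)
  total <- 0
  for (comp_id in seq_len(max(lab))) {
    comp <- lab == comp_id
    contour <- .trace_contour(comp)
    if (nrow(contour) < 2L) next
    steps <- diff(rbind(contour, contour[1L, , drop = FALSE]))
    total <- total + sum(sqrt((steps[, 1] * spacing_mm[1])^2 +
                                (steps[, 2] * spacing_mm[2])^2))
  }
  total
}

#' Thickness samples of a tubular region
#'
#' Draws a centreline as the chain of per-slice in-plane centroids ordered
#' along the slice axis, then records, for every boundary voxel, the
#' in-plane distance (mm) from its centre to the centreline point of its
#' slice. Returns the full sample set; multiple in-plane components pool
#' their boundary samples against the slice centroid.
#'
#' @param mask a [region_mask] of a tubular region
#' @return numeric vector of thickness samples in mm
#' @export
compute_thickness <- function(mask) {
  m <- .check_mask(mask, mask$label %||% "mask")
  s <- mask$spacing_mm
  samples <- numeric(0)
  for (z in seq_len(dim(m)[3])) {
    sl <- m[, , z]
    if (!any(sl)) next
    ij <- which(sl, arr.ind = TRUE)
    centroid <- colMeans(sweep(ij - 1, 2, s[1:2], "*"))
    bd <- which(.boundary_2d(sl), arr.ind = TRUE)
    pts <- sweep(bd - 1, 2, s[1:2], "*")
    samples <- c(samples,
                 sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2))
  }
  if (!length(samples)) stop_empty_region(mask$label %||% "mask")
  samples
}

#' Tortuosity index of a slice
#'
#' The ratio of cross-sectional area to perimeter: a more tortuous,
#' boundary-convoluted nerve has a higher perimeter for the same area and
#' therefore a smaller index.
#'
#' @param area_mm2 slice area in mm^2
#' @param perimeter_mm slice perimeter in mm (> 0)
#' @return area / perimeter
#' @export
compute_tortuosity_index <- function(area_mm2, perimeter_mm) {
  if (perimeter_mm <= 0)
    stop("undefined-ratio error: perimeter must be > 0", call. = FALSE)
  area_mm2 / perimeter_mm
}

# does a polyline intersect a mask? vertices plus midpoint subdivision to
# at most half-voxel spacing, then nearest-centre membership
.densify <- function(line, max_step) {
  out <- line[1, , drop = FALSE]
  for (k in seq_len(nrow(line) - 1L)) {
    a <- line[k, ]; b <- line[k + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / max_step))
    t <- seq_len(nseg) / nseg
    out <- rbind(out, outer(1 - t, a) + outer(t, b))
  }
  out
}

.line_hits_mask <- function(line, rm) {
  pts <- .densify(line, min(rm$spacing_mm) / 2)
  idx <- world_to_index(pts, rm$spacing_mm)
  ok <- index_in_grid(idx, dim(rm$mask))
  if (!any(ok)) return(FALSE)
  idx <- idx[ok, , drop = FALSE]
  any(rm$mask[cbind(idx[, 1], idx[, 2], idx[, 3])])
}

#' Filter streamlines by ROI logic (A AND B NOT C)
#'
#' Keeps exactly the polylines that intersect at least one voxel of both
#' inclusion regions and no voxel of the exclusion region. Intersection is
#' tested at polyline vertices plus midpoint subdivision to at most
#' half-voxel spacing, preventing tunnelling through thin ROIs.
#'
#' @param lines a [streamline_set]
#' @param roi_a,roi_b inclusion [region_mask]s
#' @param roi_c optional exclusion [region_mask] (NULL for no exclusion)
#' @return a [streamline_set] of the retained polylines
#' @export
filter_streamlines <- function(lines, roi_a, roi_b, roi_c = NULL) {
  grids <- list(dim(roi_a$mask), dim(roi_b$mask))
  if (!is.null(roi_c)) grids <- c(grids, list(dim(roi_c$mask)))
  if (length(unique(lapply(grids, as.integer))) != 1L)
    stop_geometry("ROI masks must share one grid")
  keep <- vapply(lines$lines, function(l) {
    .line_hits_mask(l, roi_a) && .line_hits_mask(l, roi_b) &&
      (is.null(roi_c) || !.line_hits_mask(l, roi_c))
  }, logical(1))
  streamline_set(lines$lines[keep])
}

#' Voxelize streamlines to a region mask
#'
#' Marks every voxel traversed by any polyline segment, sampling each
#' segment at steps of at most half the minimum voxel spacing.
#'
#' @param lines a nonempty [streamline_set]
#' @param grid_shape integer 3-vector
#' @param spacing_mm numeric 3-vector (mm)
#' @param label region label for the mask
#' @return a [region_mask]
#' @export
streamlines_to_mask <- function(lines, grid_shape, spacing_mm, label = "OR") {
  if (lines$count == 0L) stop_empty_region("streamline set")
  m <- array(FALSE, grid_shape)
  max_step <- min(spacing_mm) / 2
  for (l in lines$lines) {
    pts <- .densify(l, max_step)
    idx <- world_to_index(pts, spacing_mm)
    ok <- index_in_grid(idx, grid_shape)
    idx <- idx[ok, , drop = FALSE]
    if (nrow(idx)) m[cbind(idx[, 1], idx[, 2], idx[, 3])] <- TRUE
  }
  region_mask(m, label, spacing_mm)
}

.summ_stats <- function(x) {
  c(min = min(x), max = max(x), mean = mean(x),
    sd = if (length(x) > 1L) stats::sd(x) else 0)
}

#' Morphology feature summary for a tubular region
#'
#' Per-slice perimeter and tortuosity index and per-boundary-voxel
#' thickness, each summarised as min/max/mean/SD, plus the exact region
#' volume.
#'
#' @param mask a [region_mask]
#' @return named numeric vector `<label>_<operator>_<stat>` (volume is a
#'   single value `<label>_volume`)
#' @export
morphology_features <- function(mask) {
  m <- .check_mask(mask, mask$label %||% "mask")
  s <- mask$spacing_mm
  per <- numeric(0); tort <- numeric(0)
  for (z in seq_len(dim(m)[3])) {
    sl <- m[, , z]
    if (!any(sl)) next
    p <- compute_perimeter(sl, s[1:2])
    area <- sum(sl) * s[1] * s[2]
    per <- c(per, p)
    if (p > 0) tort <- c(tort, compute_tortuosity_index(area, p))
  }
  th <- compute_thickness(mask)
  sp <- .summ_stats(per)
  st <- .summ_stats(th)
  sq <- .summ_stats(if (length(tort)) tort else 0)
  out <- c(volume = compute_volume(mask),
           stats::setNames(sp, paste0("perimeter_", names(sp))),
           stats::setNames(st, paste0("thickness_", names(st))),
           stats::setNames(sq, paste0("tortuosity_", names(sq))))
  stats::setNames(out, paste0(mask$label, "_", names(out)))
}
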