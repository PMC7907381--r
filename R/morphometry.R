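# Segmentation and quantification: seeded region growing, gallium
# exclusion, voxel-count void volume, 50%-contrast wall thickness, and the
# pit measurements (maximal chamber diameter, central membrane thickness,
# slit-canal width).
#
# Note on polarity: tomograms here store delta-proportional values, so
# gallium is numerically LARGER than wall and air is near zero. Displays
# that render high delta dark (as is common) will show gallium darker;
# the ordering on delta is the invariant.

as_volume_values <- function(x) {
  if (inherits(x, "tomogram")) x$values
  else if (inherits(x, "phantom_volume")) x$labels
  else x
}

#' Seeded 3D region growing
#'
#' Flood fill from a seed voxel including connected voxels whose value
#' differs from the seed value by at most `tolerance` (spatial proximity +
#' grayscale similarity).
#'
#' @param volume A `tomogram` or 3D numeric array.
#' @param seed Integer voxel index `c(x, y, z)`, 1-based.
#' @param tolerance Grayscale tolerance (>= 0).
#' @param connectivity 6 (face, default — conservative against leakage
#'   through diagonal gaps) or 26.
#' @return A `segmentation_result`: logical `mask`, `seed`, `seed_value`,
#'   `tolerance`, `connectivity`.
#' @export
region_grow <- function(volume, seed, tolerance, connectivity = 6) {
  v <- as_volume_values(volume)
  d <- dim(v)
  if (length(d) != 3) stop("invalid-argument: volume must be 3D")
  seed <- as.integer(round(seed))
  if (length(seed) != 3 || any(seed < 1) || any(seed > d)) {
    stop("invalid-seed: seed voxel out of bounds")
  }
  if (tolerance < 0) stop("invalid-argument: tolerance must be >= 0")
  if (!connectivity %in% c(6, 26)) {
    stop("invalid-argument: connectivity must be 6 or 26")
  }
  sv <- v[seed[1], seed[2], seed[3]]
  mask <- cpp_region_grow(as.numeric(v), d[1], d[2], d[3],
                          seed[1] - 1L, seed[2] - 1L, seed[3] - 1L,
                          sv - tolerance, sv + tolerance,
                          as.integer(connectivity))
  structure(list(mask = array(mask, dim = d), seed = seed, seed_value = sv,
                 tolerance = tolerance, connectivity = connectivity),
            class = "segmentation_result")
}

as_mask <- function(x) {
  if (inherits(x, "segmentation_result")) x$mask else x
}

#' Remove gallium voxels from a segmentation mask
#'
#' Drops voxels whose delta estimate exceeds `ga_threshold` (gallium has a
#' distinctly higher refractive-index decrement than the wall polymer, so
#' a threshold separates it).
#'
#' @param tomogram A `tomogram` or 3D array of delta estimates.
#' @param mask Logical array or `segmentation_result`.
#' @param ga_threshold Threshold on the delta estimate.
#' @return Same type as `mask`, gallium voxels removed.
#' @export
exclude_gallium <- function(tomogram, mask, ga_threshold) {
  v <- as_volume_values(tomogram)
  if (inherits(mask, "segmentation_result")) {
    mask$mask <- mask$mask & !(v > ga_threshold)
    mask
  } else {
    mask & !(v > ga_threshold)
  }
}

#' Voxel-count void volume
#'
#' @param mask Logical array or `segmentation_result`.
#' @param pitch_nm Voxel pitch (nm), positive.
#' @return List: `voxel_count`, `volume_um3` (count x pitch^3; report to 4
#'   significant figures when printing).
#' @export
void_volume <- function(mask, pitch_nm) {
  if (pitch_nm <= 0) stop("invalid-argument: pitch must be positive")
  m <- as_mask(mask)
  count <- sum(m)
  list(voxel_count = as.integer(count),
       volume_um3 = count * (pitch_nm * 1e-3)^3)
}

# Locate the two 50%-contrast edge crossings of a single-wall profile.
# Edges are found as the dominant gradient extremes; each edge's 50%
# level is computed from its local base and top plateaus (medians just
# outside the edge), which makes the crossing insensitive to large-scale
# level errors elsewhere along the probe. A profile with more than two
# comparably strong edges (e.g. crossing two walls) or without contrast
# is rejected (NULL).
profile_crossings <- function(p, threshold_frac = 0.5) {
  n <- length(p)
  if (n < 12) return(NULL)
  g <- diff(p)
  gmax <- max(abs(g))
  if (gmax <= 1e-9 * max(abs(p), 1e-12)) return(NULL)
  e1 <- which.max(g)
  e2 <- which.min(g)
  if (e1 >= e2) return(NULL)
  # count separated strong edges: more than one rising or falling group
  # means the probe crosses more than one wall
  strong <- which(abs(g) > 0.5 * gmax)
  groups <- cumsum(c(1, diff(strong) > 5))
  if (length(unique(groups)) > 2) return(NULL)
  # for a symmetric (erf-like) edge the 50%-contrast crossing coincides
  # with the gradient extremum; its position is refined by a parabola fit
  # on the derivative, which is independent of plateau levels elsewhere
  refine <- function(e, sign) {
    if (e <= 1 || e >= length(g)) return(e + 0.5)
    y0 <- sign * g[e - 1]; y1 <- sign * g[e]; y2 <- sign * g[e + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
    e + 0.5 + max(-1, min(1, off))
  }
  if (!is.null(threshold_frac) && abs(threshold_frac - 0.5) > 1e-9) {
    # non-midpoint thresholds need explicit level crossings on the edge
    cross_at <- function(e, rising) {
      base_idx <- max(1, e - 15):max(1, e - 5)
      top_idx <- min(n, e + 5):min(n, e + 15)
      base <- stats::median(p[if (rising) base_idx else top_idx])
      top <- stats::median(p[if (rising) top_idx else base_idx])
      half <- base + threshold_frac * (top - base)
      win <- max(1, e - 6):min(n - 1, e + 6)
      s <- p - half
      idx <- win[s[win] * s[win + 1] < 0 | s[win] == 0]
      if (length(idx) == 0) return(NA_real_)
      i <- idx[which.min(abs(idx - e))]
      i + s[i] / (s[i] - s[i + 1] + (s[i] == s[i + 1]))
    }
    out <- c(cross_at(e1, TRUE), cross_at(e2, FALSE))
    if (anyNA(out)) return(NULL)
    return(out)
  }
  c(refine(e1, 1), refine(e2, -1))
}

#' Wall thickness from 50%-contrast probe lines
#'
#' Each probe samples the tomogram along a line expected to cross exactly
#' one wall; the thickness is the distance between the two half-contrast
#' edge crossings. Probes with a different crossing count are excluded
#' (logged via attribute); if all are excluded the measurement fails.
#'
#' @param tomogram A `tomogram` or 3D array.
#' @param probes List of probes: each `list(start = c(x, y, z), direction
#'   = unit vector, length = n_samples)`; sampling is trilinear at 1-voxel
#'   steps.
#' @param pitch_nm Pitch; taken from the tomogram when available.
#' @param threshold_frac Edge threshold as a fraction of contrast.
#' @param smooth_sigma Gaussian smoothing of the sampled profile (voxels)
#'   before crossing detection; suppresses spurious crossings from
#'   reconstruction noise while leaving symmetric edge midpoints in
#'   place. 0 disables.
#' @return Mean thickness in um; attributes `"per_probe_um"` (NA where
#'   excluded) and `"n_valid"`.
#' @export
wall_thickness <- function(tomogram, probes, pitch_nm = NULL,
                           threshold_frac = 0.5, smooth_sigma = 1.5) {
  v <- as_volume_values(tomogram)
  if (inherits(tomogram, "tomogram")) {
    pitch_nm <- pitch_nm %||% tomogram$voxel_pitch_nm
  }
  if (is.null(pitch_nm)) stop("invalid-argument: pitch_nm required")
  per <- vapply(probes, function(pr) {
    dirn <- pr$direction / sqrt(sum(pr$direction^2))
    t <- seq(0, pr$length - 1)
    pts <- cbind(pr$start[1] + t * dirn[1], pr$start[2] + t * dirn[2],
                 pr$start[3] + t * dirn[3])
    d <- dim(v)
    keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 &
      pts[, 2] <= d[2] & pts[, 3] >= 1 & pts[, 3] <= d[3]
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 4) return(NA_real_)
    p <- trilinear_sample(v, pts)
    if (smooth_sigma > 0) {
      hw <- ceiling(4 * smooth_sigma)
      kern <- stats::dnorm(-hw:hw, sd = smooth_sigma)
      p <- as.numeric(stats::filter(p, kern / sum(kern), sides = 2))
      keep2 <- !is.na(p)
      p <- p[keep2]
      if (length(p) < 4) return(NA_real_)
    }
    cr <- profile_crossings(p, threshold_frac)
    if (is.null(cr) || length(cr) != 2) return(NA_real_)
    (cr[2] - cr[1]) * pitch_nm * 1e-3
  }, numeric(1))
  if (all(is.na(per))) {
    stop("measurement-failed: no probe produced exactly two edge crossings")
  }
  out <- mean(per, na.rm = TRUE)
  attr(out, "per_probe_um") <- per
  attr(out, "n_valid") <- sum(!is.na(per))
  out
}

#' Default probe set for the tracheid double-wall phantom
#'
#' Probes crossing the four outer wall segments of the central wall cross:
#' the two arms of the wall normal to x probed along x, the two arms
#' normal to y probed along y, `n_per_arm` probes each, placed at offsets
#' clear of the central crossing and inside the specimen pillar.
#'
#' @param vol The tracheid `phantom_volume` (for dimensions), or a list
#'   with `pitch_nm` and grid `dim`.
#' @param n_per_arm Probes per wall arm.
#' @param margin_vox Probe overshoot beyond each wall face (voxels).
#' @return List of probes for [wall_thickness()].
#' @export
wall_probes <- function(vol, n_per_arm = 5, margin_vox = 12) {
  d <- dim(as_volume_values(vol))
  pitch <- vol$pitch_nm %||% vol$voxel_pitch_nm
  wt_vox <- vol$ground_truth$wall_thickness_nm / pitch
  rp_vox <- if (is.finite(vol$pillar_radius_nm %||% Inf)) {
    vol$pillar_radius_nm / pitch
  } else 0.5 * min(d[1], d[2])
  c1 <- (d[1] + 1) / 2; c2 <- (d[2] + 1) / 2; c3 <- (d[3] + 1) / 2
  half_len <- wt_vox / 2 + margin_vox
  # lateral offsets: beyond the crossing wall, inside the pillar chord
  lo <- wt_vox / 2 + margin_vox / 2
  hi <- sqrt(max(rp_vox^2 - (half_len + 2)^2, 0))
  if (hi <= lo) stop("invalid-spec: pillar too small for wall probes")
  off <- seq(lo + 0.2 * (hi - lo), hi - 0.1 * (hi - lo),
             length.out = n_per_arm)
  probes <- list()
  for (s in c(-1, 1)) {
    for (o in off) {
      probes[[length(probes) + 1]] <- list(
        start = c(c1 - half_len, c2 + s * o, c3),
        direction = c(1, 0, 0), length = ceiling(2 * half_len))
      probes[[length(probes) + 1]] <- list(
        start = c(c1 + s * o, c2 - half_len, c3),
        direction = c(0, 1, 0), length = ceiling(2 * half_len))
    }
  }
  probes
}

# connected component of a 2D logical slice containing (i, j); 4-connected
slice_component <- function(slice, i, j) {
  d <- dim(slice)
  m <- cpp_region_grow(as.numeric(slice), d[1], d[2], 1L,
                       i - 1L, j - 1L, 0L, 0.5, 1.5, 6L)
  matrix(m, d[1], d[2])
}

# binary opening (erosion then dilation, 4-neighbourhood, radius r):
# removes bridges and blobs thinner than ~2r+1 px while preserving the
# extent of larger shapes
open2d <- function(m, r = 2) {
  shift_or <- function(x, f) {
    d <- dim(x)
    out <- x
    out[-1, ] <- f(out[-1, ], x[-d[1], ])
    out[-d[1], ] <- f(out[-d[1], ], x[-1, ])
    out[, -1] <- f(out[, -1], x[, -d[2]])
    out[, -d[2]] <- f(out[, -d[2]], x[, -1])
    out
  }
  for (i in seq_len(r)) m <- shift_or(m, `&`)
  for (i in seq_len(r)) m <- shift_or(m, `|`)
  m
}

dilate2d <- function(m, r = 2) {
  d <- dim(m)
  for (i in seq_len(r)) {
    x <- m
    m[-1, ] <- m[-1, ] | x[-d[1], ]
    m[-d[1], ] <- m[-d[1], ] | x[-1, ]
    m[, -1] <- m[, -1] | x[, -d[2]]
    m[, -d[2]] <- m[, -d[2]] | x[, -1]
  }
  m
}

# maximal Feret (caliper) extent of a set of pixels, in pixel units,
# counting the unit extent of the end pixels
feret_extent_px <- function(comp) {
  pts <- which(comp, arr.ind = TRUE)
  if (nrow(pts) == 0) return(NA_real_)
  if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
  dmax <- 0
  for (i in seq_len(nrow(pts))) {
    dd <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    dmax <- max(dmax, dd)
  }
  sqrt(dmax) + 1
}

#' Pit morphometry on a void mask
#'
#' Measures, on the void segmentation of a pit pair: the central membrane
#' thickness (gap between the two chamber halves along the canal axis
#' through the centre line), the maximal chamber diameter (largest Feret
#' extent of the chamber void across membrane-parallel slices) and the
#' slit-canal width (Feret extent of the canal cross-section at the
#' aperture, i.e. the last slice before the lumen). Slices whose central
#' void component touches the slice border are taken as lumen and end the
#' walk.
#'
#' @param void_mask Logical array or `segmentation_result` of the void.
#' @param membrane_axis Canal axis: 1/2/3 or "x"/"y"/"z".
#' @param pitch_nm Voxel pitch (nm).
#' @param centre Optional `c(y0, z0)`-style in-plane centre line (indices
#'   in the two non-axis dimensions); default: rounded mask centroid.
#' @param roi_radius_nm Optional cylindrical region of interest about the
#'   canal axis: mask voxels outside it are ignored and a component
#'   reaching the ROI boundary counts as lumen (keeps segmentation leaks
#'   outside the pit from distorting the walk).
#' @param direction_quantile Per-slice diameters are taken over ray
#'   directions at this quantile; 1 (default) is the exact maximal Feret
#'   extent, slightly smaller values (e.g. 0.85) ignore a few leak-
#'   contaminated directions in noisy segmentations of round sections
#'   (at the cost of understating strongly elongated ones).
#' @return List: `chamber_diameter_nm`, `membrane_thickness_nm`,
#'   `canal_width_nm`, `pit_void_voxel_count`.
#' @export
pit_metrics <- function(void_mask, membrane_axis = 1, pitch_nm,
                        centre = NULL, roi_radius_nm = NULL,
                        direction_quantile = 1) {
  m <- as_mask(void_mask)
  if (is.character(membrane_axis)) {
    membrane_axis <- match(membrane_axis, c("x", "y", "z"))
  }
  perm <- c(membrane_axis, setdiff(1:3, membrane_axis))
  m <- aperm(m, perm)
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("topology-error: empty mask")
  cx <- mean(idx[, 1])
  if (is.null(centre)) {
    centre <- c(round(mean(idx[, 2])), round(mean(idx[, 3])))
  }
  roi_area <- NULL
  if (!is.null(roi_radius_nm)) {
    rvox <- roi_radius_nm / pitch_nm
    rr2 <- outer((seq_len(d[2]) - centre[1])^2,
                 (seq_len(d[3]) - centre[2])^2, "+")
    inside <- rr2 <= rvox^2
    for (x in seq_len(d[1])) m[x, , ] <- m[x, , ] & inside
    roi_area <- sum(inside)
  }
  y0 <- centre[1]; z0 <- centre[2]
  # membrane gap per axial line (the interior non-void run nearest the
  # mask centroid), aggregated as the median over the bundle of lines
  # within a few voxels of the canal axis: robust to noise voxels and to
  # per-line boundary flicker
  line_gap <- function(prof) {
    r <- rle(prof)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    interior <- which(!r$values & seq_along(r$values) > 1 &
                        seq_along(r$values) < length(r$values))
    if (length(interior) == 0) return(NA_real_)
    mid <- (starts[interior] + ends[interior]) / 2
    r$lengths[interior[which.min(abs(mid - cx))]]
  }
  ys <- max(1, y0 - 3):min(d[2], y0 + 3)
  zs <- max(1, z0 - 3):min(d[3], z0 + 3)
  gaps <- c(vapply(ys, function(y) vapply(zs, function(z) {
    line_gap(m[, y, z])
  }, numeric(1)), numeric(length(zs))))
  if (mean(is.na(gaps)) > 0.7 || all(is.na(gaps))) {
    stop("topology-error: no membrane gap flanked by chamber voids found")
  }
  # mid-run position consistency: use the central line's gap location
  membrane_nm <- stats::median(gaps, na.rm = TRUE) * pitch_nm
  # locate the membrane run on the axis bundle for the walk start
  prof <- apply(m[, ys, zs, drop = FALSE], 1, mean) >= 0.5
  r <- rle(prof)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  interior <- which(!r$values & seq_along(r$values) > 1 &
                      seq_along(r$values) < length(r$values))
  if (length(interior) == 0) {
    stop("topology-error: no membrane gap flanked by chamber voids found")
  }
  mid <- (starts[interior] + ends[interior]) / 2
  g <- interior[which.min(abs(mid - cx))]

  # Per-slice pit cross-section by radial boundary casting: along rays
  # from the canal axis, the void radius in a direction is the largest
  # mask radius followed by a sustained (>= 6-voxel) wall run. This is
  # robust both to artifact holes inside the void (they do not terminate
  # the ray) and to thin segmentation leaks through the wall (they lack
  # the sustained-void continuation), where connected-component
  # measurements proved brittle.
  r_max <- floor(min(y0 - 1, d[2] - y0, z0 - 1, d[3] - z0,
                     if (is.null(roi_area)) Inf else
                       sqrt(roi_area / pi)) - 1)
  n_phi <- 72L
  phis <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ray_iy <- lapply(phis, function(p) pmin(pmax(
    round(y0 + (1:r_max) * cos(p)), 1), d[2]))
  ray_iz <- lapply(phis, function(p) pmin(pmax(
    round(z0 + (1:r_max) * sin(p)), 1), d[3]))
  ray_radii <- function(raw) {
    vapply(seq_len(n_phi), function(k) {
      v <- raw[cbind(ray_iy[[k]], ray_iz[[k]])]
      # scan outward: the boundary is the last void voxel before the
      # first sustained (>= 6 voxel) wall run; artifact holes narrower
      # than that are bridged, and void beyond the wall (lumina, air
      # outside the specimen, leaks) is never reached
      last_void <- 0L
      gap <- 0L
      for (r in seq_len(r_max)) {
        if (isTRUE(v[r])) {
          last_void <- r
          gap <- 0L
        } else {
          gap <- gap + 1L
          if (gap >= 6L && last_void > 0L) break
        }
      }
      last_void
    }, numeric(1))
  }
  walk <- function(from, step) {
    ferets <- numeric(0)
    voxels <- 0
    x <- from
    misses <- 0
    while (x >= 1 && x <= d[1]) {
      raw <- m[x, , ]
      R <- if (any(raw)) ray_radii(raw) else rep(0, n_phi)
      if (stats::median(R) > 0.9 * r_max) break     # lumen
      if (max(R) == 0) {
        misses <- misses + 1                        # axis artifact
        if (misses > 4) break
        x <- x + step
        next
      }
      misses <- 0
      half <- seq_len(n_phi / 2)
      dia <- R[half] + R[half + n_phi / 2]
      ferets <- c(ferets,
                  stats::quantile(dia, direction_quantile,
                                  names = FALSE) + 1)
      voxels <- voxels + sum(raw & rr_le(R))
      x <- x + step
    }
    list(ferets = ferets, voxels = voxels)
  }
  # membership test: voxel radius below the cast radius of its direction
  vox_r <- sqrt(outer((seq_len(d[2]) - y0)^2, (seq_len(d[3]) - z0)^2, "+"))
  vox_phi <- (atan2(rep(seq_len(d[3]) - z0, each = d[2]),
                    rep(seq_len(d[2]) - y0, d[3])) %% (2 * pi))
  vox_bin <- matrix(pmin(floor(vox_phi / (2 * pi) * n_phi) + 1, n_phi),
                    d[2], d[3])
  rr_le <- function(R) vox_r <= R[vox_bin] + 0.5
  up <- walk(ends[g] + 1, 1L)
  down <- walk(starts[g] - 1, -1L)
  if (length(up$ferets) == 0 || length(down$ferets) == 0) {
    stop("topology-error: expected chamber voids on both membrane sides")
  }
  list(chamber_diameter_nm = max(c(up$ferets, down$ferets)) * pitch_nm,
       membrane_thickness_nm = membrane_nm,
       canal_width_nm = max(up$ferets[length(up$ferets)],
                            down$ferets[length(down$ferets)]) * pitch_nm,
       pit_void_voxel_count = up$voxels + down$voxels)
}

#' Assemble a morphometry report
#'
#' @param pit Output of [pit_metrics()] or NULL.
#' @param wall_um Mean wall thickness (um) or NULL.
#' @param void Output of [void_volume()] or NULL.
#' @return A one-row data.frame (`morphometry_report`) with a polarity
#'   note column.
#' @export
morphometry_report <- function(pit = NULL, wall_um = NULL, void = NULL) {
  out <- data.frame(
    wall_thickness_um = if (is.null(wall_um)) NA_real_ else
      as.numeric(wall_um),
    chamber_diameter_nm = pit$chamber_diameter_nm %||% NA_real_,
    membrane_thickness_nm = pit$membrane_thickness_nm %||% NA_real_,
    canal_width_um = if (is.null(pit$canal_width_nm)) NA_real_ else
      pit$canal_width_nm * 1e-3,
    voxel_count = void$voxel_count %||% NA_integer_,
    void_volume_um3 = void$volume_um3 %||% NA_real_)
  attr(out, "note") <- paste(
    "values are delta-proportional: gallium > wall > air;",
    "dark-gallium displays invert this polarity")
  class(out) <- c("morphometry_report", class(out))
  out
}
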