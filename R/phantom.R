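# Labelled 3D wood-anatomy phantoms.
#
# Both phantoms live inside a cylindrical pillar (axis = z, the rotation
# axis), mirroring FIB-milled specimen pillars; keeping all material inside
# the inscribed cylinder also keeps every projection untruncated. Labels:
# 0 air/void, 1 cell wall, 2 pit membrane, 3 gallium. The ground-truth
# morphometry record is written at construction from the spec and never
# recomputed.
#
# Pit-pair geometry (canal axis x, membrane plane x = 0): two wall slabs
# |x| <= wall_thickness fused around the pit; the chamber is a biconvex
# lens formed by two half-ellipsoid caps whose flat bases (diameter =
# chamber_diameter) face each other across the planar membrane;
# slit-shaped canals (stadium cross-section in (y, z)) connect the chamber
# apices to the lumina. The membrane spans the widest plane of the lens,
# so the maximal chamber diameter is realized immediately adjacent to the
# membrane, as in bordered/simple pit anatomy.

#' Pit-pair construction spec
#'
#' Defaults are the reference beech fiber pit dimensions: maximal chamber
#' diameter 4,230 nm, central membrane thickness 428 nm, slit canal maximum
#' width 1.053 um.
#'
#' @param chamber_diameter_nm Maximal chamber diameter (lens base).
#' @param membrane_thickness_nm Membrane thickness at the pit centre.
#' @param canal_slit_width_nm Maximum (long-axis) width of the slit canal.
#' @param canal_slit_minor_nm Minor width of the slit cross-section (the
#'   reference prints only the maximum; the minor axis is a free parameter).
#' @param chamber_depth_nm Total lens depth along the canal axis, membrane
#'   included; cap height is `(chamber_depth - membrane_thickness)/2`.
#' @param wall_thickness_nm Half of the fused double wall, i.e. one cell's
#'   wall measured from the membrane mid-plane.
#' @param orientation Axis of the pit canal, `"x"` or `"y"`.
#' @return An object of class `pit_spec`.
#' @export
pit_spec <- function(chamber_diameter_nm = 4230,
                     membrane_thickness_nm = 428,
                     canal_slit_width_nm = 1053,
                     canal_slit_minor_nm = 312,
                     chamber_depth_nm = 1988,
                     wall_thickness_nm = 1694,
                     orientation = c("x", "y")) {
  orientation <- match.arg(orientation)
  s <- list(chamber_diameter_nm = chamber_diameter_nm,
            membrane_thickness_nm = membrane_thickness_nm,
            canal_slit_width_nm = canal_slit_width_nm,
            canal_slit_minor_nm = canal_slit_minor_nm,
            chamber_depth_nm = chamber_depth_nm,
            wall_thickness_nm = wall_thickness_nm,
            orientation = orientation)
  num <- unlist(s[1:6])
  if (any(num <= 0)) {
    stop("invalid-spec: ", names(num)[which(num <= 0)[1]], " must be positive")
  }
  if (membrane_thickness_nm >= chamber_diameter_nm) {
    stop("invalid-spec: membrane_thickness_nm must be < chamber_diameter_nm")
  }
  if (canal_slit_minor_nm > canal_slit_width_nm) {
    stop("invalid-spec: canal_slit_minor_nm must be <= canal_slit_width_nm")
  }
  structure(s, class = "pit_spec")
}

#' Assemble a phantom volume from a label grid
#'
#' Low-level constructor for custom phantoms: a 3D integer label grid
#' (0 = air) plus a label-to-material map.
#'
#' @param labels 3D integer array.
#' @param pitch_nm Isotropic voxel pitch (nm).
#' @param materials Named list of [material()]s keyed by label.
#' @param ground_truth Optional morphometry record of the construction.
#' @param pillar_radius_nm Optional specimen pillar radius.
#' @return A `phantom_volume`.
#' @export
as_phantom_volume <- function(labels, pitch_nm,
                              materials = default_materials(),
                              ground_truth = list(),
                              pillar_radius_nm = NA_real_) {
  phantom_volume(labels, pitch_nm, materials, ground_truth,
                 pillar_radius_nm)
}

phantom_volume <- function(labels, pitch_nm, materials, ground_truth,
                           pillar_radius_nm = NA_real_) {
  lev <- sort(unique(as.integer(labels)))
  missing_mat <- setdiff(as.character(lev[lev != 0]), names(materials))
  if (length(missing_mat)) {
    stop("invalid-spec: no material registered for label(s) ",
         paste(missing_mat, collapse = ", "))
  }
  structure(list(labels = labels, pitch_nm = pitch_nm, materials = materials,
                 ground_truth = ground_truth,
                 pillar_radius_nm = pillar_radius_nm),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("phantom volume %d x %d x %d at %.1f nm pitch\n",
              d[1], d[2], d[3], x$pitch_nm))
  tab <- table(x$labels)
  for (l in names(tab)) {
    nm <- if (l == "0") "air" else x$materials[[l]]$name
    cat(sprintf("  label %s (%s): %d voxels\n", l, nm, tab[[l]]))
  }
  invisible(x)
}

#' Map phantom labels to a per-voxel delta (or beta) volume
#'
#' @param vol A `phantom_volume`.
#' @param which `"delta"` or `"beta"`.
#' @return 3D numeric array of the chosen optical constant.
#' @export
material_volume <- function(vol, which = c("delta", "beta")) {
  which <- match.arg(which)
  lev <- sort(unique(as.integer(vol$labels)))
  lut <- numeric(max(lev) + 1)
  for (l in lev) {
    if (l == 0) next
    lut[l + 1] <- vol$materials[[as.character(l)]][[which]]
  }
  array(lut[vol$labels + 1L], dim = dim(vol$labels))
}

# analytic CSG void volume (chamber caps + canals), nm^3
pit_void_analytic_nm3 <- function(spec) {
  a <- spec$chamber_diameter_nm / 2
  h <- (spec$chamber_depth_nm - spec$membrane_thickness_nm) / 2
  if (h <= 0) return(0)
  v_caps <- 2 * (2 / 3) * pi * a^2 * h   # two half-ellipsoids
  L <- spec$canal_slit_width_nm
  w <- spec$canal_slit_minor_nm
  canal_len <- spec$wall_thickness_nm - spec$chamber_depth_nm / 2
  v_canals <- if (canal_len > 0) {
    2 * ((L - w) * w + pi * (w / 2)^2) * canal_len
  } else 0
  v_caps + v_canals
}

#' Build the pit-pair phantom
#'
#' Constructive solid geometry on a labelled voxel grid: two fused wall
#' slabs, a biconvex chamber split by a planar membrane, and two slit
#' canals joining the chamber to the lumina of the neighbouring cells.
#'
#' @param spec A [pit_spec()].
#' @param grid_shape Integer vector of 3 (voxels per axis).
#' @param pitch_nm Isotropic voxel pitch (nm).
#' @param pillar_radius_nm Specimen pillar radius; default 0.47 of the
#'   smaller in-plane extent, `Inf` disables the pillar clip.
#' @param pillar_height_nm Specimen pillar height (along z); default 0.94
#'   of the z extent so the pillar ends inside the frame, `Inf` disables.
#' @param materials Label-to-material map, default [default_materials()].
#' @return A `phantom_volume` whose `ground_truth` echoes the spec and the
#'   analytic CSG void volume.
#' @export
build_pit_pair_phantom <- function(spec = pit_spec(),
                                   grid_shape = c(256, 256, 256),
                                   pitch_nm = 26,
                                   pillar_radius_nm = NULL,
                                   pillar_height_nm = NULL,
                                   materials = default_materials()) {
  stopifnot(inherits(spec, "pit_spec"))
  n <- as.integer(grid_shape)
  if (length(n) != 3) stop("invalid-spec: grid_shape must have length 3")
  if (is.null(pillar_radius_nm)) {
    pillar_radius_nm <- 0.47 * min(n[1], n[2]) * pitch_nm
  }
  if (is.null(pillar_height_nm)) {
    pillar_height_nm <- 0.94 * n[3] * pitch_nm
  }
  margin <- 5 * pitch_nm
  a <- spec$chamber_diameter_nm / 2
  if (is.finite(pillar_radius_nm) && a + margin > pillar_radius_nm) {
    stop("invalid-spec: chamber_diameter_nm does not fit the pillar ",
         "with a 5-voxel margin")
  }
  if (is.finite(pillar_radius_nm) &&
      spec$canal_slit_width_nm / 2 + margin > pillar_radius_nm) {
    stop("invalid-spec: canal_slit_width_nm does not fit the pillar")
  }
  if (2 * spec$wall_thickness_nm + 2 * margin > n[1] * pitch_nm) {
    stop("invalid-spec: wall_thickness_nm does not fit the grid")
  }
  if (spec$chamber_diameter_nm + 2 * margin > min(n[2], n[3]) * pitch_nm) {
    stop("invalid-spec: chamber_diameter_nm does not fit the grid")
  }

  mem2 <- spec$membrane_thickness_nm / 2
  h <- (spec$chamber_depth_nm - spec$membrane_thickness_nm) / 2
  W <- spec$wall_thickness_nm
  apex <- spec$chamber_depth_nm / 2
  L2 <- (spec$canal_slit_width_nm - spec$canal_slit_minor_nm) / 2
  w2 <- spec$canal_slit_minor_nm / 2

  xs <- (seq_len(n[1]) - 1 - (n[1] - 1) / 2) * pitch_nm
  ys <- (seq_len(n[2]) - 1 - (n[2] - 1) / 2) * pitch_nm
  zs <- (seq_len(n[3]) - 1 - (n[3] - 1) / 2) * pitch_nm
  X <- matrix(xs, n[1], n[2])
  Y <- matrix(ys, n[1], n[2], byrow = TRUE)
  pillar <- X^2 + Y^2 <= pillar_radius_nm^2
  absX <- abs(X)
  in_wall <- pillar & (absX <= W)

  labels <- array(0L, dim = n)
  for (k in seq_len(n[3])) {
    zc <- zs[k]
    if (abs(zc) > pillar_height_nm / 2) next
    lab <- matrix(0L, n[1], n[2])
    lab[in_wall] <- 1L
    if (h > 0) {
      # half-ellipsoid caps based on the membrane planes x = +/- mem2
      r2 <- Y^2 + zc^2
      cap <- (absX >= mem2 &
                ((absX - mem2) / h)^2 + r2 / a^2 <= 1)
      lab[cap & in_wall] <- 0L
    }
    # membrane disc spanning the lens base
    lab[absX <= mem2 & Y^2 + zc^2 <= a^2 & pillar] <- 2L
    # slit canals (stadium cross-section in (y, z), long axis y)
    if (apex < W) {
      dseg2 <- pmax(abs(Y) - L2, 0)^2 + zc^2
      lab[absX >= apex & absX <= W & dseg2 <= w2^2] <- 0L
    }
    labels[, , k] <- lab
  }

  gt <- list(chamber_diameter_nm = spec$chamber_diameter_nm,
             membrane_thickness_nm = spec$membrane_thickness_nm,
             canal_width_nm = spec$canal_slit_width_nm,
             wall_thickness_um = 2 * spec$wall_thickness_nm / 1e3,
             void_volume_um3 = pit_void_analytic_nm3(spec) * 1e-9,
             spec = spec)
  vol <- phantom_volume(labels, pitch_nm, materials, gt, pillar_radius_nm)
  vol$pillar_height_nm <- pillar_height_nm
  if (spec$orientation == "y") {
    vol$labels <- aperm(vol$labels, c(2, 1, 3))[, rev(seq_len(n[1])), ]
  }
  vol
}

#' Build the tracheid double-wall phantom
#'
#' Square-lumen cells separated by fused double walls of the given total
#' thickness (default 3,617 nm), laid out on a square lattice of period
#' `wall_thickness + lumen_width`; at the default grid this yields a
#' central wall cross separating four lumina.
#'
#' @param wall_thickness_nm Total double-wall thickness.
#' @param lumen_width_nm Lumen width between wall faces.
#' @param grid_shape,pitch_nm,pillar_radius_nm,pillar_height_nm,materials
#'   As in [build_pit_pair_phantom()]; `pillar_radius_nm = Inf` with
#'   `pillar_height_nm = Inf` gives unclipped slabs whose analytic voxel
#'   volume is stored in the ground truth.
#' @return A `phantom_volume`.
#' @export
build_tracheid_phantom <- function(wall_thickness_nm = 3617,
                                   lumen_width_nm = 2600,
                                   grid_shape = c(256, 256, 256),
                                   pitch_nm = 26,
                                   pillar_radius_nm = NULL,
                                   pillar_height_nm = NULL,
                                   materials = default_materials()) {
  n <- as.integer(grid_shape)
  if (wall_thickness_nm < 0 || lumen_width_nm <= 0) {
    stop("invalid-spec: wall and lumen dimensions must be positive")
  }
  if (is.null(pillar_radius_nm)) {
    pillar_radius_nm <- 0.47 * min(n[1], n[2]) * pitch_nm
  }
  if (is.null(pillar_height_nm)) {
    pillar_height_nm <- 0.94 * n[3] * pitch_nm
  }
  if (wall_thickness_nm > 0.9 * min(n[1], n[2]) * pitch_nm) {
    stop("invalid-spec: wall_thickness_nm does not fit the grid")
  }
  period <- wall_thickness_nm + lumen_width_nm
  xs <- (seq_len(n[1]) - 1 - (n[1] - 1) / 2) * pitch_nm
  ys <- (seq_len(n[2]) - 1 - (n[2] - 1) / 2) * pitch_nm
  # distance to the nearest lattice line (multiples of the period)
  dlat <- function(v) abs(v - period * round(v / period))
  wx <- dlat(xs) <= wall_thickness_nm / 2
  wy <- dlat(ys) <= wall_thickness_nm / 2
  X <- matrix(xs, n[1], n[2])
  Y <- matrix(ys, n[1], n[2], byrow = TRUE)
  pillar <- X^2 + Y^2 <= pillar_radius_nm^2
  plane <- (outer(wx, wy, "|")) & pillar
  labels <- array(rep(ifelse(plane, 1L, 0L), n[3]), dim = n)
  zs <- (seq_len(n[3]) - 1 - (n[3] - 1) / 2) * pitch_nm
  labels[, , abs(zs) > pillar_height_nm / 2] <- 0L

  # analytic wall volume for the unclipped lattice (bands fully crossing)
  nbx <- sum(abs(period * seq(-n[1], n[1])) <= max(abs(xs)))
  nby <- nbx
  ex <- n[1] * pitch_nm; ey <- n[2] * pitch_nm
  ez <- min(n[3] * pitch_nm, pillar_height_nm)
  v_wall <- (nbx * wall_thickness_nm * ey + nby * wall_thickness_nm * ex -
               nbx * nby * wall_thickness_nm^2) * ez
  gt <- list(wall_thickness_um = wall_thickness_nm / 1e3,
             wall_thickness_nm = wall_thickness_nm,
             lumen_width_nm = lumen_width_nm,
             wall_volume_nm3_unclipped = v_wall)
  vol <- phantom_volume(labels, pitch_nm, materials, gt, pillar_radius_nm)
  vol$pillar_height_nm <- pillar_height_nm
  vol
}

shift_mask <- function(m, d) {
  out <- array(FALSE, dim = dim(m))
  n <- dim(m)
  src <- dst <- lapply(n, seq_len)
  ax <- which(d != 0)
  if (d[ax] > 0) {
    dst[[ax]] <- (1 + d[ax]):n[ax]; src[[ax]] <- 1:(n[ax] - d[ax])
  } else {
    dst[[ax]] <- 1:(n[ax] + d[ax]); src[[ax]] <- (1 - d[ax]):n[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Coat exposed cell-wall surfaces with gallium
#'
#' Relabels a surface shell of wall voxels (label 1) adjacent to air to the
#' gallium label (3), emulating FIB gallium implantation. The shell equals
#' the k-iteration morphological boundary peel, k = `round(thickness/pitch)`.
#'
#' @param vol A `phantom_volume`.
#' @param thickness_nm Coating thickness (>= 0); must not exceed the wall
#'   thickness.
#' @param faces Directions in which a face counts as exposed: `"all"` or a
#'   subset of `c("+x","-x","+y","-y","+z","-z")`.
#' @return The modified `phantom_volume`.
#' @export
add_gallium_layer <- function(vol, thickness_nm, faces = "all") {
  stopifnot(inherits(vol, "phantom_volume"))
  if (thickness_nm < 0) stop("invalid-spec: thickness_nm must be >= 0")
  wall_ref <- vol$ground_truth$wall_thickness_um * 1e3
  if (is.numeric(wall_ref) && length(wall_ref) == 1 && !is.na(wall_ref) &&
      thickness_nm >= wall_ref) {
    stop("invalid-spec: gallium thickness exceeds the wall thickness")
  }
  k <- round(thickness_nm / vol$pitch_nm)
  if (k == 0) return(vol)
  dirs <- list("+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
               "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
               "+z" = c(0, 0, 1), "-z" = c(0, 0, -1))
  if (identical(faces, "all")) faces <- names(dirs)
  if (!all(faces %in% names(dirs))) {
    stop("invalid-spec: unknown face in 'faces'")
  }
  reach <- vol$labels == 0L
  for (i in seq_len(k)) {
    grown <- reach
    for (f in faces) grown <- grown | shift_mask(reach, dirs[[f]])
    reach <- grown
  }
  ga <- reach & vol$labels == 1L
  vol$labels[ga] <- 3L
  if (is.null(vol$materials[["3"]])) {
    vol$materials[["3"]] <- default_materials()[["3"]]
  }
  vol
}

#' Structured illumination flat field
#'
#' Mean-one positive image composed of a horizontal sinusoidal ripple plus
#' a few sharp random horizontal stripes, emulating monochromator
#' illumination artifacts. Frames are indexed `[u, v]` with `v` the
#' vertical (rotation-axis) coordinate; horizontal stripes are constant
#' along `u` and vary with `v`.
#'
#' @param shape `c(nu, nv)` in pixels.
#' @param ripple_amplitude Relative ripple amplitude, `< 1`.
#' @param ripple_period_px Ripple period along `v` (pixels).
#' @param n_stripes Number of sharp stripes.
#' @param stripe_amplitude Maximum relative stripe amplitude.
#' @param stripe_width_px Gaussian stripe width (pixels).
#' @param seed Integer seed; the image is deterministic under it.
#' @return `nu x nv` matrix with mean exactly 1.
#' @export
make_illumination <- function(shape = c(256, 256),
                              ripple_amplitude = 0.08,
                              ripple_period_px = 32,
                              n_stripes = 4,
                              stripe_amplitude = 0.15,
                              stripe_width_px = 1.2,
                              seed = NULL) {
  if (ripple_amplitude >= 1 || ripple_amplitude < 0) {
    stop("invalid-argument: ripple_amplitude must be in [0, 1)")
  }
  if (ripple_amplitude + stripe_amplitude * max(n_stripes > 0, 0) >= 1) {
    stop("invalid-argument: combined amplitudes give non-physical ",
         "negative intensity")
  }
  nu <- shape[1]; nv <- shape[2]
  with_seed(seed, {
    v <- seq_len(nv)
    prof <- 1 + ripple_amplitude *
      sin(2 * pi * v / ripple_period_px + stats::runif(1, 0, 2 * pi))
    if (n_stripes > 0) {
      pos <- stats::runif(n_stripes, 1, nv)
      amp <- stats::runif(n_stripes, 0.3, 1) * stripe_amplitude *
        sample(c(-1, 1), n_stripes, replace = TRUE)
      for (j in seq_len(n_stripes)) {
        prof <- prof + amp[j] * exp(-(v - pos[j])^2 / (2 * stripe_width_px^2))
      }
    }
    if (any(prof <= 0)) {
      stop("invalid-argument: non-physical negative intensity in flat field")
    }
    img <- matrix(prof, nu, nv, byrow = TRUE)
    img / mean(img)
  })
}
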