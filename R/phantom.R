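#' Specification of one synthetic orbital cavity
#'
#' Describes an idealized bony orbital cavity used by [generate_phantom()]:
#' a cone with elliptic (default) or rectangular cross-section whose rim
#' opens anteriorly and tapers linearly to the apex, surrounded by a bony
#' wall of constant thickness. The rim defaults follow adult orbital
#' anatomy: a 40 mm horizontal by 35 mm vertical opening and a depth of
#' 45 mm from rim to apex. Gap openings cut radial sectors through the
#' wall, standing in for the orbital fissures and the infraorbital groove.
#'
#' @param rim_width Horizontal rim dimension in mm (> 0).
#' @param rim_height Vertical rim dimension in mm (> 0).
#' @param depth Rim-plane-to-apex distance in mm (> 0).
#' @param rim_center World position (mm) of the rim centre; the cavity
#'   extends dorsally (toward smaller y) from this plane.
#' @param shape `"elliptic-cone"` (closed-form areas and volumes) or
#'   `"rectangular-pyramid"`.
#' @param gap_specs List of gap openings, each a list with `depth_range`
#'   (mm behind the rim, length 2), `angle_deg` (position around the wall;
#'   0 = lateral for the right orbit convention used by
#'   [default_phantom_spec()], 90 = superior) and `width_mm` (arc width).
#' @param implant Optional implanted sphere: list with `center` (world mm)
#'   and `diameter` (mm); rendered at bone intensity.
#' @return An object of class `orbit_spec`.
#' @export
orbit_spec <- function(rim_width = 40, rim_height = 35, depth = 45,
                       rim_center = c(0, 0, 0),
                       shape = c("elliptic-cone", "rectangular-pyramid"),
                       gap_specs = list(), implant = NULL) {
  shape <- match.arg(shape)
  if (rim_width <= 0 || rim_height <= 0 || depth <= 0)
    stop("orbit_spec: rim_width, rim_height and depth must all be > 0",
         call. = FALSE)
  rim_center <- as.numeric(rim_center)
  stopifnot(length(rim_center) == 3L)
  for (g in gap_specs) {
    if (length(g$depth_range) != 2L || g$width_mm <= 0)
      stop("orbit_spec: each gap needs a depth_range of length 2 and width_mm > 0",
           call. = FALSE)
    if (g$width_mm >= pi * (rim_width + rim_height) / 2)
      stop("orbit_spec: gap width must be smaller than the wall perimeter",
           call. = FALSE)
  }
  if (!is.null(implant)) {
    stopifnot(length(implant$center) == 3L, implant$diameter > 0)
    u <- rim_center[2] - implant$center[2]  # depth of implant centre
    r <- implant$diameter / 2
    sc <- ellipse_semiaxes(rim_width, rim_height, depth, u)
    if (u - r < 0 || u + r > depth ||
        sqrt(sum(((implant$center[c(1, 3)] - rim_center[c(1, 3)]) /
                  (sc - r))^2)) > 1)
      stop("orbit_spec: implant must lie entirely inside the cavity",
           call. = FALSE)
  }
  structure(list(rim_width = rim_width, rim_height = rim_height,
                 depth = depth, rim_center = rim_center, shape = shape,
                 gap_specs = gap_specs, implant = implant),
            class = "orbit_spec")
}

# cavity cross-section semi-axes at depth u behind the rim (linear taper;
# ventral of the rim, u < 0, the cone law extrapolates so the bony frame
# has a short anterior lip rather than a knife edge)
ellipse_semiaxes <- function(rim_width, rim_height, depth, u) {
  f <- pmax(1 - u / depth, 0)
  c(rim_width / 2, rim_height / 2) * f
}

#' Specification of a bilateral phantom head volume
#'
#' Groups two [orbit_spec()]s with the voxel geometry and the intensity
#' model of a CBCT-like scan. Intensities are abstract scanner units (CBCT
#' grey values are not Hounsfield-calibrated); bone must exceed both soft
#' intensities by at least five noise standard deviations so that a
#' two-class histogram split separates bone reliably.
#'
#' @param left,right [orbit_spec()]s for the two cavities.
#' @param voxel_spacing Isotropic voxel edge in mm (default 0.3, typical
#'   large-FOV CBCT).
#' @param bone_intensity,cavity_intensity,background_intensity Intensities
#'   of wall/implant, cavity interior, and everything else.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param wall_thickness Bony wall thickness in mm.
#' @param margin_mm Padding added around the cavities when choosing the
#'   grid extent.
#' @param rng_seed Integer seed used when noise is added.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(left, right, voxel_spacing = 0.3,
                         bone_intensity = 1000, cavity_intensity = 100,
                         background_intensity = 0, noise_sd = 50,
                         wall_thickness = 2, margin_mm = 6, rng_seed = 1L) {
  stopifnot(inherits(left, "orbit_spec"), inherits(right, "orbit_spec"))
  if (voxel_spacing <= 0)
    stop("phantom_spec: 'voxel_spacing' must be > 0", call. = FALSE)
  if (bone_intensity - max(cavity_intensity, background_intensity) <
      5 * noise_sd)
    stop("phantom_spec: bone_intensity must exceed cavity and background ",
         "intensities by at least 5 * noise_sd", call. = FALSE)
  if (wall_thickness <= 0)
    stop("phantom_spec: 'wall_thickness' must be > 0", call. = FALSE)
  structure(list(left = left, right = right, voxel_spacing = voxel_spacing,
                 bone_intensity = bone_intensity,
                 cavity_intensity = cavity_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, wall_thickness = wall_thickness,
                 margin_mm = margin_mm, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Default bilateral phantom
#'
#' Bilateral elliptic-cone orbits with adult rim dimensions (40 x 35 mm),
#' 45 mm depth, centres 64 mm apart, 0.3 mm voxels, and two wall gaps per
#' side emulating the superior and inferior orbital fissures (mirrored
#' between sides so the noiseless phantom is midsagittally symmetric).
#'
#' @param noise_sd Noise standard deviation (default 50 intensity units
#'   against a 1000-unit bone/soft-tissue contrast).
#' @param rng_seed Integer seed for the additive noise.
#' @param gaps If `FALSE`, generate unbroken walls.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(noise_sd = 50, rng_seed = 1L, gaps = TRUE) {
  gap_r <- if (gaps) list(
    list(depth_range = c(8, 30), angle_deg = -40, width_mm = 3),   # inferior orbital fissure
    list(depth_range = c(15, 35), angle_deg = 115, width_mm = 3))  # superior orbital fissure
  else list()
  # mirror about the midsagittal plane: angle -> 180 - angle
  gap_l <- lapply(gap_r, function(g) {
    g$angle_deg <- 180 - g$angle_deg
    g
  })
  phantom_spec(
    left = orbit_spec(rim_center = c(-32, 0, 0), gap_specs = gap_l),
    right = orbit_spec(rim_center = c(32, 0, 0), gap_specs = gap_r),
    noise_sd = noise_sd, rng_seed = rng_seed)
}

#' Shrink one side of a phantom
#'
#' Multiplies one orbit's rim width, rim height and depth by
#' `(1 - shrink_fraction)`, leaving the other side untouched. Emulates an
#' operated orbit that is uniformly smaller than its healthy counterpart;
#' the analytic cavity volume scales by `(1 - shrink_fraction)^3`.
#'
#' @param spec A `phantom_spec`.
#' @param shrink_fraction In `[0, 1)`.
#' @param side Which side to shrink.
#' @return A modified `phantom_spec`.
#' @export
make_asymmetric_pair <- function(spec, shrink_fraction, side = c("left", "right")) {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- match.arg(side)
  if (shrink_fraction < 0 || shrink_fraction >= 1)
    stop("make_asymmetric_pair: 'shrink_fraction' must be in [0, 1)",
         call. = FALSE)
  s <- 1 - shrink_fraction
  o <- spec[[side]]
  spec[[side]] <- orbit_spec(o$rim_width * s, o$rim_height * s, o$depth * s,
                             o$rim_center, o$shape, o$gap_specs, o$implant)
  spec
}

# logical masks for one orbit on an x/z in-plane grid at depth u (vectors
# xg, zg are world coordinates); returns list(cavity, wall, gap)
orbit_plane_masks <- function(o, wall, xg, zg, u) {
  nx <- length(xg); nz <- length(zg)
  if (u < -wall || u > o$depth + wall)
    return(list(cavity = matrix(FALSE, nx, nz), wall = matrix(FALSE, nx, nz),
                gap = matrix(FALSE, nx, nz)))
  dx <- xg - o$rim_center[1]
  dz <- zg - o$rim_center[3]
  DX <- matrix(dx, nx, nz); DZ <- matrix(dz, nx, nz, byrow = TRUE)
  sc <- ellipse_semiaxes(o$rim_width, o$rim_height, o$depth, u)
  if (o$shape == "elliptic-cone") {
    inside <- if (all(sc > 0))
      (DX / sc[1])^2 + (DZ / sc[2])^2 <= 1 else matrix(FALSE, nx, nz)
    outer_ <- (DX / (sc[1] + wall))^2 + (DZ / (sc[2] + wall))^2 <= 1
  } else {
    inside <- if (all(sc > 0))
      abs(DX) <= sc[1] & abs(DZ) <= sc[2] else matrix(FALSE, nx, nz)
    outer_ <- abs(DX) <= sc[1] + wall & abs(DZ) <= sc[2] + wall
  }
  wall_m <- outer_ & !inside
  gap_m <- matrix(FALSE, nx, nz)
  if (length(o$gap_specs) && any(wall_m)) {
    # mirror the angular convention for the left orbit so that specs
    # written for a right orbit transfer symmetrically
    phi <- atan2(DZ, DX) * 180 / pi
    rbar <- mean(sc) + wall / 2
    for (g in o$gap_specs) {
      if (u < g$depth_range[1] || u > g$depth_range[2]) next
      half_deg <- (g$width_mm / rbar) * (180 / pi) / 2
      d <- abs(((phi - g$angle_deg + 180) %% 360) - 180)
      gap_m <- gap_m | (wall_m & d <= half_deg)
    }
  }
  list(cavity = inside, wall = wall_m & !gap_m, gap = wall_m & gap_m)
}

#' Generate a synthetic CBCT-like phantom volume
#'
#' Voxelizes a [phantom_spec()] onto a grid aligned with the world origin:
#' cavity interiors get `cavity_intensity`, bony walls (minus any gap
#' sectors) and implants get `bone_intensity`, everything else
#' `background_intensity`, then seeded Gaussian noise is added. The grid
#' is snapped to the voxel lattice so that the midsagittal plane (x = 0)
#' and the rim plane (y = 0) land exactly on voxel centres. The bony
#' frame carries a short anterior lip (one wall thickness, following the
#' extrapolated cone law) ventral of the rim plane, so the wall does not
#' end in a knife edge at the entry.
#'
#' An optional rigid `pre_transform` is applied to the geometry (not by
#' resampling), producing a volume of the same anatomy scanned in a
#' different head pose; the returned landmarks are transformed with it.
#'
#' @param spec A [phantom_spec()].
#' @param pre_transform Optional [rigid_transform()] applied to the
#'   geometry before voxelization.
#' @return A list with elements `volume` (a [volume_image()]), `truth`
#'   (a `ground_truth` object, see [analytic_area()]), and `landmarks`
#'   (a [landmark_set()] with entry-dorsal and rim landmarks).
#' @export
generate_phantom <- function(spec, pre_transform = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$left; R <- spec$right
  w <- spec$wall_thickness
  # overlapping cavities are a geometry error
  gapx <- abs(R$rim_center[1] - L$rim_center[1])
  if (gapx < (L$rim_width + R$rim_width) / 2 + 2 * w)
    stop("generate_phantom: left and right cavities overlap", call. = FALSE)

  sp <- spec$voxel_spacing
  m <- spec$margin_mm
  lim <- function(getter) range(vapply(list(L, R), getter, numeric(2)))
  xr <- lim(function(o) o$rim_center[1] + c(-1, 1) * (o$rim_width / 2 + w))
  zr <- lim(function(o) o$rim_center[3] + c(-1, 1) * (o$rim_height / 2 + w))
  yr <- lim(function(o) c(o$rim_center[2] - o$depth - w, o$rim_center[2]))
  if (!is.null(pre_transform)) {
    # bounding box of the posed geometry
    corners <- as.matrix(expand.grid(xr, yr, zr))
    tc <- apply_transform(pre_transform, corners)
    xr <- range(tc[, 1]); yr <- range(tc[, 2]); zr <- range(tc[, 3])
  }
  # snap bounds to the voxel lattice so that x = 0 (midsagittal) and the
  # rim plane y = 0 coincide with voxel centres whenever in range
  lo <- floor((c(xr[1], yr[1], zr[1]) - m) / sp)
  hi <- ceiling((c(xr[2], yr[2], zr[2]) + m) / sp)
  dims <- as.integer(hi - lo + 1)
  origin <- lo * sp
  # lattice-index products keep the grid bit-exactly mirror-symmetric
  xg <- (lo[1]:hi[1]) * sp
  yg <- (lo[2]:hi[2]) * sp
  zg <- (lo[3]:hi[3]) * sp

  vox <- array(spec$background_intensity, dims)
  inv <- if (is.null(pre_transform)) NULL else invert_transform(pre_transform)

  for (j in seq_len(dims[2])) {
    if (is.null(inv)) {
      plane <- matrix(spec$background_intensity, dims[1], dims[3])
      for (o in list(L, R)) {
        msk <- orbit_plane_masks(o, w, xg, zg, o$rim_center[2] - yg[j])
        plane[msk$cavity] <- spec$cavity_intensity
        plane[msk$gap] <- spec$cavity_intensity
        plane[msk$wall] <- spec$bone_intensity
        if (!is.null(o$implant)) {
          DX <- matrix(xg - o$implant$center[1], dims[1], dims[3])
          DZ <- matrix(zg - o$implant$center[3], dims[1], dims[3], byrow = TRUE)
          r2 <- (o$implant$diameter / 2)^2 - (yg[j] - o$implant$center[2])^2
          if (r2 > 0) plane[DX^2 + DZ^2 <= r2] <- spec$bone_intensity
        }
      }
      vox[, j, ] <- plane
    } else {
      # posed geometry: evaluate the untransformed model at inv(world)
      pts <- cbind(rep(xg, times = dims[3]), yg[j],
                   rep(zg, each = dims[1]))
      src <- apply_transform(inv, pts)
      plane <- rep(spec$background_intensity, nrow(src))
      for (o in list(L, R)) {
        u <- o$rim_center[2] - src[, 2]
        val <- classify_point_orbit(o, w, src[, 1], src[, 3], u)
        plane[val == 1L] <- spec$cavity_intensity
        plane[val == 2L] <- spec$bone_intensity
        if (!is.null(o$implant)) {
          d2 <- (src[, 1] - o$implant$center[1])^2 +
                (src[, 2] - o$implant$center[2])^2 +
                (src[, 3] - o$implant$center[3])^2
          plane[d2 <= (o$implant$diameter / 2)^2] <- spec$bone_intensity
        }
      }
      vox[, j, ] <- matrix(plane, dims[1], dims[3])
    }
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$rng_seed)
    vox <- vox + array(rnorm(length(vox), sd = spec$noise_sd), dims)
  }

  truth <- structure(list(spec = spec), class = "ground_truth")
  lm <- phantom_landmarks(spec, pre_transform)
  list(volume = volume_image(vox, spacing = rep(sp, 3), origin = origin),
       truth = truth, landmarks = lm)
}

# pointwise classification (0 background, 1 cavity/gap, 2 wall) used for
# posed-geometry voxelization
classify_point_orbit <- function(o, wall, x, z, u) {
  out <- integer(length(x))
  ok <- u >= -wall & u <= o$depth + wall
  if (!any(ok)) return(out)
  f <- pmax(1 - u / o$depth, 0)
  a <- o$rim_width / 2 * f; b <- o$rim_height / 2 * f
  dx <- x - o$rim_center[1]; dz <- z - o$rim_center[3]
  if (o$shape == "elliptic-cone") {
    inside <- ok & a > 0 & (dx / a)^2 + (dz / b)^2 <= 1
    outer_ <- ok & (dx / (a + wall))^2 + (dz / (b + wall))^2 <= 1
  } else {
    inside <- ok & a > 0 & abs(dx) <= a & abs(dz) <= b
    outer_ <- ok & abs(dx) <= a + wall & abs(dz) <= b + wall
  }
  wall_m <- outer_ & !inside
  if (length(o$gap_specs) && any(wall_m)) {
    phi <- atan2(dz, dx) * 180 / pi
    rbar <- (a + b) / 2 + wall / 2
    for (g in o$gap_specs) {
      inrange <- u >= g$depth_range[1] & u <= g$depth_range[2]
      half_deg <- (g$width_mm / pmax(rbar, 1e-9)) * (180 / pi) / 2
      d <- abs(((phi - g$angle_deg + 180) %% 360) - 180)
      cut <- wall_m & inrange & d <= half_deg
      inside <- inside | cut
      wall_m <- wall_m & !cut
    }
  }
  out[inside] <- 1L
  out[wall_m] <- 2L
  out
}

#' Analytic cross-section area of a phantom cavity
#'
#' Closed-form cavity cross-section area at a given depth behind the rim.
#' For the elliptic cone this is
#' `pi * (rim_width/2) * (rim_height/2) * (1 - depth_mm/depth)^2`.
#'
#' @param gt A `ground_truth` object from [generate_phantom()].
#' @param side `"left"` or `"right"`.
#' @param depth_mm Depth behind the rim plane, in `[0, depth]`.
#' @return Area in mm^2.
#' @export
analytic_area <- function(gt, side = c("left", "right"), depth_mm) {
  stopifnot(inherits(gt, "ground_truth"))
  side <- match.arg(side)
  o <- gt$spec[[side]]
  if (any(depth_mm < 0 | depth_mm > o$depth))
    stop("analytic_area: 'depth_mm' outside [0, ", o$depth, "] mm",
         call. = FALSE)
  f <- (1 - depth_mm / o$depth)^2
  if (o$shape == "elliptic-cone")
    pi * (o$rim_width / 2) * (o$rim_height / 2) * f
  else
    o$rim_width * o$rim_height * f
}

#' Analytic cavity volume over a depth interval
#'
#' Integral of the analytic cross-section area between two depths behind
#' the rim. The interval is clipped at the apex; ventral of the rim
#' (negative depths) the cross-section follows the extrapolated cone law,
#' so that midpoint-rule reference slabs, which extend half a slice
#' interval in front of slice 1, have a well-defined analytic volume.
#'
#' @inheritParams analytic_area
#' @param from_mm,to_mm Depth interval bounds in mm (`from_mm < to_mm`).
#' @return Volume in mm^3.
#' @export
analytic_volume <- function(gt, side = c("left", "right"), from_mm, to_mm) {
  stopifnot(inherits(gt, "ground_truth"), from_mm < to_mm)
  side <- match.arg(side)
  o <- gt$spec[[side]]
  a <- from_mm; b <- min(to_mm, o$depth)
  if (b <= a) return(0)
  base <- if (o$shape == "elliptic-cone")
    pi * (o$rim_width / 2) * (o$rim_height / 2)
  else o$rim_width * o$rim_height
  # integral of (1 - u/D)^2 du = -D/3 * (1 - u/D)^3
  D <- o$depth
  base * D / 3 * ((1 - a / D)^3 - (1 - b / D)^3)
}

#' Landmarks of a phantom
#'
#' Entry-dorsal and rim landmarks of a phantom in world coordinates. In
#' the idealized geometry the most dorsal point of the orbital entry is
#' taken as the rim centre on the rim plane.
#'
#' @param spec A [phantom_spec()].
#' @param pre_transform Optional [rigid_transform()] applied to the
#'   landmark positions (matching a posed [generate_phantom()] call).
#' @return A [landmark_set()].
#' @export
phantom_landmarks <- function(spec, pre_transform = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  pts <- list(
    right_entry_dorsal = spec$right$rim_center,
    left_entry_dorsal = spec$left$rim_center,
    right_rim_superior = spec$right$rim_center + c(0, 0, spec$right$rim_height / 2),
    right_rim_inferior = spec$right$rim_center - c(0, 0, spec$right$rim_height / 2),
    left_rim_superior = spec$left$rim_center + c(0, 0, spec$left$rim_height / 2),
    left_rim_inferior = spec$left$rim_center - c(0, 0, spec$left$rim_height / 2))
  if (!is.null(pre_transform))
    pts <- lapply(pts, function(p) apply_transform(pre_transform, p))
  landmark_set(pts)
}

#' Write or read a phantom spec as JSON
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `read_phantom_spec` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$left <- unclass(x$left); x$right <- unclass(x$right)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(o) orbit_spec(
    o$rim_width, o$rim_height, o$depth, as.numeric(o$rim_center), o$shape,
    gap_specs = if (is.null(o$gap_specs)) list() else
      lapply(seq_len(NROW(o$gap_specs)), function(i) {
        g <- if (is.data.frame(o$gap_specs)) o$gap_specs[i, ] else o$gap_specs[[i]]
        list(depth_range = as.numeric(unlist(g$depth_range)),
             angle_deg = g$angle_deg, width_mm = g$width_mm)
      }),
    implant = if (is.null(x$implant) || length(o$implant) == 0) NULL else
      list(center = as.numeric(o$implant$center), diameter = o$implant$diameter))
  phantom_spec(mk(x$left), mk(x$right), x$voxel_spacing, x$bone_intensity,
               x$cavity_intensity, x$background_intensity, x$noise_sd,
               x$wall_thickness, x$margin_mm, x$rng_seed)
}
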