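#' Rigid transform into the canonical measurement frame
#'
#' Computes the rigid transform that reorients a head volume so that the
#' line connecting the most dorsal points of the two orbital entries is
#' parallel to the left-right axis (equal ventrodorsal and equal
#' inferior-superior coordinates for the two landmarks) and their midpoint
#' sits at the world origin. The rotation is the minimal rotation achieving
#' this; roll about the inter-orbital axis is left at zero unless rim
#' landmarks are supplied, in which case the mean superior-inferior rim
#' axis is brought vertical. After alignment the orbital frame plane is
#' y = 0 and slices proceed dorsally (toward negative y).
#'
#' @param lm A [landmark_set()].
#' @return A [rigid_transform()] mapping original world coordinates to
#'   canonical-frame coordinates.
#' @export
canonical_transform <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  r <- lm$right_entry_dorsal; l <- lm$left_entry_dorsal
  d <- r - l
  r1 <- rotation_between(d, c(1, 0, 0))

  rim_pairs <- list(c("right_rim_superior", "right_rim_inferior"),
                    c("left_rim_superior", "left_rim_inferior"))
  axes <- list()
  for (p in rim_pairs)
    if (all(p %in% names(lm)))
      axes[[length(axes) + 1L]] <- lm[[p[1]]] - lm[[p[2]]]
  if (length(axes)) {
    v <- as.numeric(r1 %*% Reduce("+", axes) / length(axes))
    proj <- sqrt(v[2]^2 + v[3]^2)
    if (proj < 1e-9) {
      warning("canonical_transform: rim landmarks leave roll unconstrained; ",
              "roll set to zero", call. = FALSE)
      rot <- r1
    } else {
      rot <- rotation_about_axis("x", atan2(v[2], v[3]) * 180 / pi)$rotation %*% r1
    }
  } else {
    rot <- r1
  }
  mid <- (r + l) / 2
  rigid_transform(rot, -as.numeric(rot %*% mid))
}

#' Align a volume into the canonical measurement frame
#'
#' Applies [canonical_transform()] to the landmarks and rigidly resamples
#' the volume accordingly (trilinear interpolation, same grid as the
#' input). After alignment the entry-dorsal landmarks share their
#' ventrodorsal and vertical coordinates and their midpoint is at the
#' origin, so the orbital frame plane is y = 0.
#'
#' @param vol A [volume_image()].
#' @param lm A [landmark_set()]; all landmarks must lie inside the volume.
#' @return A list with `volume` (the aligned [volume_image()]) and
#'   `transform` (the [rigid_transform()] used).
#' @export
align_volume <- function(vol, lm) {
  stopifnot(inherits(vol, "volume_image"), inherits(lm, "landmark_set"))
  for (nm in names(lm)) {
    p <- lm[[nm]]
    for (ax in 1:3) {
      ext <- volume_extent(vol, ax)
      half <- vol$spacing[ax] / 2
      if (p[ax] < ext[1] - half || p[ax] > ext[2] + half)
        stop("align_volume: landmark '", nm, "' lies outside the volume ",
             "extent along axis ", ax, call. = FALSE)
    }
  }
  t <- canonical_transform(lm)
  list(volume = resample_rigid(vol, t), transform = t)
}
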