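#' In-plane rigid transform
#'
#' Locates the phantom in image coordinates: counter-clockwise in-plane
#' rotation (degrees), in-plane translation (mm) and a z-offset (mm) locating
#' the module planes.  Applying a transform and then its inverse is the
#' identity to within numerical precision.
#'
#' @param rotation_deg rotation in degrees, normalized to (-180, 180].
#' @param translation length-2 translation, mm.
#' @param z_offset axial offset, mm.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation_deg = 0, translation = c(0, 0),
                            z_offset = 0) {
  stopifnot(length(translation) == 2)
  r <- ((rotation_deg + 180) %% 360) - 180
  if (r == -180) r <- 180
  structure(list(rotation_deg = r, translation = as.numeric(translation),
                 z_offset = z_offset), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tf a \code{rigid_transform}.
#' @export
invert_transform <- function(tf) {
  th <- -tf$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid_transform(-tf$rotation_deg, -as.numeric(R %*% tf$translation),
                  -tf$z_offset)
}

#' @rdname rigid_transform
#' @param xy n x 2 matrix of in-plane points (mm).
#' @export
apply_transform <- function(tf, xy) {
  xy <- matrix(xy, ncol = 2)
  th <- tf$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(xy %*% t(R), 2, -tf$translation)
}

#' Locate the two metal ball bearings
#'
#' Thresholds the volume at \code{threshold} HU, labels in-plane connected
#' components of the projected metal mask, and returns the intensity-weighted
#' (sub-voxel) 3D centroids of the two components.  Any count other than two
#' candidate objects is an error naming the count: with more than two metal
#' objects rejecting is safer than guessing.
#'
#' @param vol a \code{volume_grid}.
#' @param threshold metal threshold in HU (default 1500, far above the bone inserts and bars at 955 HU and well below the
#'   metal markers at 3000 HU).
#' @return A 2 x 3 matrix of (x, y, z) centroids in mm, ordered by x.
#' @export
find_ball_bearings <- function(vol, threshold = 1500) {
  mask <- vol$data > threshold
  if (!any(mask)) stop("found 0 metal objects (expected 2)")
  proj <- apply(mask, c(1, 2), any)
  lab <- EBImage::bwlabel(proj * 1)
  ncomp <- max(lab)
  if (ncomp != 2) stop("found ", ncomp, " metal objects (expected 2)")
  ax <- vol_axes(vol)
  ks <- which(apply(mask, 3, any))
  ks <- seq(max(1, min(ks) - 1), min(dim(vol$data)[3], max(ks) + 1))
  out <- matrix(NA_real_, 2, 3)
  for (cc in 1:2) {
    ij <- which(lab == cc, arr.ind = TRUE)
    # expand the footprint by one voxel to catch partial-volume tails
    ii <- seq(max(1, min(ij[, 1]) - 1), min(dim(vol$data)[1], max(ij[, 1]) + 1))
    jj <- seq(max(1, min(ij[, 2]) - 1), min(dim(vol$data)[2], max(ij[, 2]) + 1))
    sub <- vol$data[ii, jj, ks, drop = FALSE]
    w <- pmax(sub, 0)                      # weight: HU above water background
    W <- sum(w)
    out[cc, ] <- c(
      sum(w * array(ax$x[ii], dim(sub))) / W,
      sum(w * aperm(array(ax$y[jj], dim(sub)[c(2, 1, 3)]), c(2, 1, 3))) / W,
      sum(w * aperm(array(ax$z[ks], dim(sub)[c(3, 2, 1)]), c(3, 2, 1))) / W
    )
  }
  out[order(out[, 1]), , drop = FALSE]
}

#' Estimate the phantom's pose in a volume
#'
#' Translation comes from the binary-mask centroid of non-air voxels
#' (threshold -300 HU); rotation from the ball-bearing pair, compared with
#' its nominal direction (modulo 180 degrees); z-offset from the axial extent
#' of the mask when the volume covers the phantom ends, otherwise 0.  The
#' residual distance between predicted and measured marker positions is
#' attached as attribute \code{"residual_mm"} (NA when markers are not in the
#' field of view).
#'
#' @param vol a \code{volume_grid}.
#' @param spec the \code{phantom_spec} scanned.
#' @param air_threshold HU threshold separating phantom from background.
#' @param metal_threshold HU threshold for the markers.
#' @return A \code{rigid_transform}.
#' @export
estimate_phantom_transform <- function(vol, spec,
                                       air_threshold = -300,
                                       metal_threshold = 1500) {
  mask <- vol$data > air_threshold
  if (!any(mask)) stop("empty phantom mask: volume contains only air")
  ax <- vol_axes(vol)
  idx <- which(mask, arr.ind = TRUE)
  tx <- mean(ax$x[idx[, 1]])
  ty <- mean(ax$y[idx[, 2]])

  kz <- which(apply(mask, 3, any))
  nz <- dim(vol$data)[3]
  z_off <- 0
  if (min(kz) > 1 && max(kz) < nz) {
    half_slab <- vol$spacing[3] / 2
    lo <- ax$z[min(kz)] - half_slab
    hi <- ax$z[max(kz)] + half_slab
    z_off <- mean(c(lo, hi))               # nominal phantom centre is z = 0
  }

  rot <- 0; residual <- NA_real_
  mk <- NULL
  for (m in spec$modules) if (!is.null(m$markers)) mk <- m$markers
  bb <- tryCatch(find_ball_bearings(vol, metal_threshold),
                 error = function(e) NULL)
  if (!is.null(bb) && !is.null(mk)) {
    v_meas <- bb[2, 1:2] - bb[1, 1:2]
    v_nom <- mk$b - mk$a
    a_meas <- atan2(v_meas[2], v_meas[1])
    a_nom <- atan2(v_nom[2], v_nom[1])
    rot <- (a_meas - a_nom) * 180 / pi
    rot <- ((rot + 90) %% 180) - 90        # BB pair fixes angle mod 180
    tf0 <- rigid_transform(rot, c(tx, ty), z_off)
    pred <- apply_transform(tf0, rbind(mk$a, mk$b))
    residual <- mean(sqrt(rowSums((pred - bb[, 1:2])^2)))
  }
  tf <- rigid_transform(rot, c(tx, ty), z_off)
  attr(tf, "residual_mm") <- residual
  tf
}

#' Map nominal ROIs into image coordinates
#'
#' Applies a rigid transform to a nominal ROI layout (as produced by
#' \code{\link{nominal_roi_layout}}, with z already in centred physical
#' coordinates).  Areas are preserved; circular-ROI bounds are checked
#' against the volume and any ROI falling outside is an error naming it.
#'
#' @param layout data frame with columns \code{name, x, y, z, diameter} (and
#'   optionally pattern geometry columns).
#' @param tf a \code{rigid_transform}.
#' @param vol optional \code{volume_grid} for bounds checking.
#' @return The transformed layout.
#' @export
map_rois <- function(layout, tf, vol = NULL) {
  p <- apply_transform(tf, cbind(layout$x, layout$y))
  out <- layout
  out$x <- p[, 1]; out$y <- p[, 2]
  out$z <- layout$z + tf$z_offset
  if ("orientation" %in% names(out))
    out$orientation <- out$orientation + tf$rotation_deg
  if (!is.null(vol)) {
    ax <- vol_axes(vol)
    half <- ifelse(is.na(out$diameter), 0, out$diameter / 2)
    bad <- out$x - half < min(ax$x) | out$x + half > max(ax$x) |
           out$y - half < min(ax$y) | out$y + half > max(ax$y)
    if (any(bad))
      stop("mapped ROI(s) outside image bounds: ",
           paste(out$name[bad], collapse = ", "))
  }
  out
}
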