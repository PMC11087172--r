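#' @title ACR CT accreditation phantom: reference geometry
#'
#' @description
#' A single, immutable description of the ACR CT accreditation phantom that
#' both the scan simulator and the analyzer consume, so that nominal ROI
#' positions and ground-truth materials always agree.
#'
#' The phantom is a 20 cm diameter x 16 cm long water-equivalent cylinder
#' (optional 33 cm outer body ring) holding four axial modules:
#' \enumerate{
#'   \item HU-accuracy inserts (polyethylene, bone, acrylic, air, water),
#'   \item a low-contrast rod for contrast-to-noise measurements,
#'   \item a uniform slab carrying two metal ball bearings spaced 100 mm
#'     apart for image-scaling checks,
#'   \item eight high-contrast bar patterns from 4 to 12 line pairs/cm.
#' }
#'
#' Coordinates: right-handed phantom frame in millimetres, origin at the
#' phantom centre, z along the phantom axis.  Module z-extents are stored
#' relative to the inferior face, tiling \code{[0, length]}; the physical
#' (centred) z of a module position is \code{z - length/2}.
#'
#' In-module insert coordinates, ball-bearing positions and bar-pattern
#' placement are not standardized in public summaries of the phantom; the
#' fixed layout below (72 degree insert spacing, peripheral uniformity ROIs
#' 10 mm in from the edge) is this package's documented convention, and only
#' internal consistency between simulator and analyzer matters.
#'
#' @name phantom_reference
NULL

# Nominal HU per phantom material.  Scalars only: energy dependence of the
# real materials is out of scope.
.acr_materials <- c(
  water = 0, air = -1000, acrylic = 120, bone = 955,
  polyethylene = -95, low_contrast = 6, metal = 3000
)

#' Nominal phantom materials
#'
#' @return Named numeric vector of nominal HU per material label.
#' @export
acr_materials <- function() .acr_materials

#' Default ACR head phantom specification
#'
#' Builds the reference description of the 20 cm x 16 cm head phantom with
#' its four modules.  All downstream code (simulation, localization, ROI
#' layout) derives geometry from this object.
#'
#' @param insert_radius_mm radial position of the five HU inserts (default 60).
#' @param insert_diameter_mm diameter of each HU insert (default 25).
#' @param bb_separation_mm nominal ball-bearing separation (default 100).
#' @return An object of class \code{phantom_spec}.
#' @examples
#' spec <- default_head_phantom()
#' spec$head_diameter      # 200 mm
#' @export
default_head_phantom <- function(insert_radius_mm = 60,
                                 insert_diameter_mm = 25,
                                 bb_separation_mm = 100) {
  mats <- .acr_materials
  # HU inserts at 72 degree spacing, alphabetical by material for determinism
  ins_mat <- c("acrylic", "air", "bone", "polyethylene", "water")
  ang <- (90 - 72 * (seq_along(ins_mat) - 1)) * pi / 180
  inserts <- data.frame(
    material = ins_mat,
    x = insert_radius_mm * cos(ang),
    y = insert_radius_mm * sin(ang),
    diameter = insert_diameter_mm,
    stringsAsFactors = FALSE
  )

  # CNR module: one 25 mm low-contrast rod (nominal +6 HU over water);
  # the background reference ROI sits at the mirrored position.
  cnr_rod <- data.frame(
    material = "low_contrast", x = 0, y = 30, diameter = 25,
    stringsAsFactors = FALSE
  )

  # Ball bearings: 100 mm apart along x, low in the uniformity slab so they
  # stay clear of all five uniformity ROIs.
  half <- bb_separation_mm / 2
  markers <- list(
    a = c(-half, -75), b = c(half, -75),
    z = 100,                       # face-referenced module-centre z
    nominal_separation = bb_separation_mm,
    diameter = 5
  )

  # Bar patterns: 12 x 12 mm patches on a 58 mm ring, ACR frequencies.
  freqs <- c(4, 5, 6, 7, 8, 9, 10, 12)
  pang <- (90 - 45 * (seq_along(freqs) - 1)) * pi / 180
  patterns <- data.frame(
    frequency = freqs,
    x = 58 * cos(pang),
    y = 58 * sin(pang),
    width = 12, height = 12,
    orientation = 0,
    bar_material = "bone",
    stringsAsFactors = FALSE
  )

  spec <- structure(list(
    head_diameter = 200,
    length = 160,
    body_ring = NULL,
    materials = mats,
    body_material = "water",
    uniformity_edge_margin = 10,
    modules = list(
      list(name = "hu_inserts", z = c(0, 40), inserts = inserts),
      list(name = "cnr", z = c(40, 80), inserts = cnr_rod),
      list(name = "uniformity", z = c(80, 120), markers = markers),
      list(name = "resolution", z = c(120, 160), patterns = patterns)
    )
  ), class = "phantom_spec")
  validate_phantom(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the structural invariants: module z-extents tile \code{[0, length]},
#' every insert lies fully inside the phantom radius, nominal HU values are
#' within the representable CT range, and the marker separation equals its
#' nominal value exactly in the phantom frame.
#'
#' @param spec a \code{phantom_spec}.
#' @return \code{spec}, invisibly; errors if an invariant fails.
#' @export
validate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$materials < -1024 | spec$materials > 3071))
    stop("nominal HU outside [-1024, 3071]")
  if (anyDuplicated(names(spec$materials)))
    stop("material names must be unique")
  zs <- t(vapply(spec$modules, function(m) m$z, numeric(2)))
  o <- order(zs[, 1])
  zs <- zs[o, , drop = FALSE]
  if (abs(zs[1, 1]) > 1e-9 || abs(zs[nrow(zs), 2] - spec$length) > 1e-9 ||
      (nrow(zs) > 1 && any(abs(zs[-1, 1] - zs[-nrow(zs), 2]) > 1e-9)))
    stop("module z-extents must tile [0, length] without overlap")
  r <- spec$head_diameter / 2
  for (m in spec$modules) {
    if (!is.null(m$inserts)) {
      d <- sqrt(m$inserts$x^2 + m$inserts$y^2) + m$inserts$diameter / 2
      if (any(m$inserts$diameter <= 0) || any(d >= r))
        stop("insert must lie fully inside the phantom radius")
      if (!all(m$inserts$material %in% names(spec$materials)))
        stop("unknown insert material")
    }
    if (!is.null(m$markers)) {
      sep <- sqrt(sum((m$markers$a - m$markers$b)^2))
      if (abs(sep - m$markers$nominal_separation) > 1e-9)
        stop("marker separation must equal nominal_separation exactly")
    }
    if (!is.null(m$patterns)) {
      f <- m$patterns$frequency
      if (length(f) != 8 || any(diff(f) <= 0) || min(f) != 4 || max(f) != 12)
        stop("bar patterns must be 8 strictly increasing frequencies spanning 4-12 lp/cm")
    }
  }
  if (!is.null(spec$body_ring) &&
      spec$body_ring$outer_diameter <= spec$head_diameter)
    stop("body ring outer diameter must exceed the head diameter")
  invisible(spec)
}

#' Attach the body ring
#'
#' Returns a copy of the spec with the optional outer body ring (330 mm outer
#' diameter, water-equivalent) present; the input is not modified.
#'
#' @param spec a \code{phantom_spec} without a ring.
#' @param outer_diameter_mm outer diameter of the ring (default 330).
#' @return A new \code{phantom_spec} with the ring.
#' @export
with_body_ring <- function(spec, outer_diameter_mm = 330) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$body_ring)) stop("body ring already present")
  spec$body_ring <- list(outer_diameter = outer_diameter_mm,
                         material = "water")
  validate_phantom(spec)
  spec
}

#' Nominal ROI layout for a module
#'
#' Produces the analyzer's nominal ROIs in the phantom frame:
#' \itemize{
#'   \item HU module: one ROI centred on each of the five material inserts;
#'   \item CNR module: ROI A on the low-contrast rod, ROI B at the mirrored
#'     background position;
#'   \item uniformity module: five equal-area ROIs, one central and four
#'     peripheral at 12/3/6/9 o'clock, centres \code{edge_margin} + ROI radius
#'     in from the phantom edge;
#'   \item resolution module: one rectangular patch per bar pattern
#'     (returned with \code{width}/\code{height} instead of a diameter).
#' }
#'
#' @param spec a \code{phantom_spec}.
#' @param module_index integer 1..4.
#' @param roi_area_mm2 disc area for HU/CNR ROIs (default 200 mm^2).
#' @param uniformity_area_mm2 disc area for uniformity ROIs (default 400 mm^2).
#' @return A data frame with columns \code{name, x, y, z, diameter} (and
#'   pattern geometry columns for the resolution module); \code{z} is the
#'   face-referenced module-centre coordinate.
#' @export
nominal_roi_layout <- function(spec, module_index,
                               roi_area_mm2 = 200,
                               uniformity_area_mm2 = 400) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!(module_index %in% seq_along(spec$modules)))
    stop("invalid module index: ", module_index)
  m <- spec$modules[[module_index]]
  zc <- mean(m$z)
  d_roi <- 2 * sqrt(roi_area_mm2 / pi)
  switch(m$name,
    hu_inserts = data.frame(
      name = m$inserts$material,
      x = m$inserts$x, y = m$inserts$y, z = zc,
      diameter = d_roi, stringsAsFactors = FALSE
    ),
    cnr = data.frame(
      name = c("A", "B"),
      x = c(m$inserts$x[1], -m$inserts$x[1]),
      y = c(m$inserts$y[1], -m$inserts$y[1]),
      z = zc, diameter = d_roi, stringsAsFactors = FALSE
    ),
    uniformity = {
      d_u <- 2 * sqrt(uniformity_area_mm2 / pi)
      rad <- spec$head_diameter / 2 - spec$uniformity_edge_margin - d_u / 2
      ang <- c(90, 0, 270, 180) * pi / 180
      data.frame(
        name = c("center", "p12", "p3", "p6", "p9"),
        x = c(0, rad * cos(ang)), y = c(0, rad * sin(ang)),
        z = zc, diameter = d_u, stringsAsFactors = FALSE
      )
    },
    resolution = data.frame(
      name = sprintf("lp%g", m$patterns$frequency),
      x = m$patterns$x, y = m$patterns$y, z = zc,
      diameter = NA_real_,
      frequency = m$patterns$frequency,
      width = m$patterns$width, height = m$patterns$height,
      orientation = m$patterns$orientation,
      stringsAsFactors = FALSE
    ),
    stop("unknown module: ", m$name)
  )
}

#' Radius of the peripheral uniformity ROI ring
#'
#' Shared between the ROI layout and the cupping degradation (which is
#' normalized to reach its full amplitude at this radius).
#'
#' @param spec a \code{phantom_spec}.
#' @param uniformity_area_mm2 uniformity ROI area (default 400 mm^2).
#' @return Radius in mm.
#' @export
uniformity_ring_radius <- function(spec, uniformity_area_mm2 = 400) {
  d_u <- 2 * sqrt(uniformity_area_mm2 / pi)
  spec$head_diameter / 2 - spec$uniformity_edge_margin - d_u / 2
}

#' Apply an in-plane rigid transform to a phantom spec
#'
#' Rotates then translates every in-plane coordinate (insert centres, marker
#' positions, pattern centres and orientations).  Used for property testing;
#' distances between points are preserved.
#'
#' @param spec a \code{phantom_spec}.
#' @param rotation_deg counter-clockwise rotation in degrees.
#' @param shift length-2 translation in mm.
#' @return The transformed \code{phantom_spec}.
#' @export
transform_phantom <- function(spec, rotation_deg = 0, shift = c(0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr <- function(xy) as.numeric(R %*% xy + shift)
  spec$modules <- lapply(spec$modules, function(m) {
    if (!is.null(m$inserts)) {
      p <- t(apply(cbind(m$inserts$x, m$inserts$y), 1, tr))
      m$inserts$x <- p[, 1]; m$inserts$y <- p[, 2]
    }
    if (!is.null(m$markers)) {
      m$markers$a <- tr(m$markers$a)
      m$markers$b <- tr(m$markers$b)
    }
    if (!is.null(m$patterns)) {
      p <- t(apply(cbind(m$patterns$x, m$patterns$y), 1, tr))
      m$patterns$x <- p[, 1]; m$patterns$y <- p[, 2]
      m$patterns$orientation <- m$patterns$orientation + rotation_deg
    }
    m
  })
  spec
}

#' Write / read a phantom spec as YAML
#'
#' Serialization is lossless: \code{read_phantom(write_phantom(spec, f))}
#' reproduces the spec.
#'
#' @param spec a \code{phantom_spec}.
#' @param path file path.
#' @return \code{write_phantom}: the path, invisibly.  \code{read_phantom}:
#'   the \code{phantom_spec}.
#' @export
write_phantom <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$materials <- as.list(x$materials)   # yaml drops names of atomic vectors
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  x <- yaml::read_yaml(path)
  x$materials <- unlist(x$materials)
  x$modules <- lapply(x$modules, function(m) {
    for (f in c("inserts", "patterns"))
      if (!is.null(m[[f]]))
        m[[f]] <- as.data.frame(lapply(m[[f]], unlist),
                                stringsAsFactors = FALSE)
    if (!is.null(m$markers)) {
      m$markers$a <- as.numeric(unlist(m$markers$a))
      m$markers$b <- as.numeric(unlist(m$markers$b))
    }
    m$z <- as.numeric(unlist(m$z))
    m
  })
  if (!is.null(x$body_ring)) x$body_ring <- lapply(x$body_ring, unlist)
  spec <- structure(x, class = "phantom_spec")
  validate_phantom(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  ring <- if (is.null(x$body_ring)) "none"
          else sprintf("%g mm outer diameter", x$body_ring$outer_diameter)
  cat(sprintf("ACR CT phantom spec: %g mm diameter x %g mm, body ring: %s\n",
              x$head_diameter, x$length, ring))
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat(sprintf("  module %d: %-11s z = [%g, %g] mm\n", i, m$name,
                m$z[1], m$z[2]))
  }
  invisible(x)
}
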