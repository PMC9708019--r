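#' Annular plane
#'
#' The aortic annular plane: reference plane through the basal attachment
#' points of the valve cusps. The normal is a unit vector pointing from the
#' ventricle toward the aorta, so that signed distances along it are
#' negative on the ventricular side (matching the usual sign convention for
#' the depth of the membranous-septum landmark P3).
#'
#' @param origin numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3, plane normal pointing ventricle -> aorta;
#'   normalised internally, must be non-zero.
#' @return An object of class `annular_plane`.
#' @export
annular_plane <- function(origin = c(0, 0, 0), normal = c(0, 0, -1)) {
  origin <- as.numeric(origin)
  normal <- as.numeric(normal)
  stopifnot(length(origin) == 3L, length(normal) == 3L,
            all(is.finite(origin)), all(is.finite(normal)))
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("annular plane normal must be non-zero")
  structure(list(origin = origin, normal = normal / nn),
            class = "annular_plane")
}

#' Membranous-septum landmarks
#'
#' P1 and P3 mark the beginning and end of the inferior border of the
#' membranous septum (IBMS); P2 is an optional intermediate point used to
#' track its course. `rcc_reference_angle` gives the circumferential
#' position (degrees) of the right-coronary cusp on the annulus and fixes
#' the direction in which the ROI is extended.
#'
#' @param p1,p3 numeric length-3 points (mm); must differ.
#' @param p2 optional numeric length-3 intermediate point.
#' @param rcc_reference_angle circumferential angle of the RCC (degrees).
#' @return An object of class `tavi_landmarks`.
#' @export
landmarks <- function(p1, p3, p2 = NULL, rcc_reference_angle = 30) {
  if (missing(p1) || missing(p3) || is.null(p1) || is.null(p3))
    stop("landmarks P1 and P3 are required")
  p1 <- as.numeric(p1); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 3L, length(p3) == 3L,
            all(is.finite(p1)), all(is.finite(p3)))
  if (!is.null(p2)) {
    p2 <- as.numeric(p2)
    stopifnot(length(p2) == 3L, all(is.finite(p2)))
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3,
                 rcc_reference_angle = as.numeric(rcc_reference_angle) %% 360),
            class = "tavi_landmarks")
}

#' Parametric aortic-root geometry
#'
#' A wall surface sampled on an axial x circumferential grid. The annular
#' plane sits at z = 0 with z increasing toward the ventricle (the
#' implantation direction), so the depth of implantation and the grid share
#' sign. `r_free` holds the unloaded wall radius at each node;
#' `k_wall` is the linear radial wall stiffness (MPa per mm of radial
#' displacement). Calcification nodules locally stiffen the wall by a
#' multiplicative factor.
#'
#' @param z numeric vector of axial stations (mm), strictly increasing;
#'   interpreted as cell centres of a uniform grid.
#' @param theta numeric vector of circumferential angles (degrees) in
#'   `[0, 360)`, strictly increasing, uniform; cell centres.
#' @param r_free matrix `length(z) x length(theta)` of unloaded radii (mm),
#'   all positive; a scalar is recycled (circular cylinder).
#' @param k_wall radial wall stiffness (MPa/mm), positive.
#' @param perimeter annular perimeter (mm); default `2*pi*` mean radius at
#'   the station closest to z = 0.
#' @param nodules data frame of calcification nodules with columns
#'   `z`, `theta`, `half_width_deg`, `half_width_mm`, `multiplier` (>= 1),
#'   or NULL for none.
#' @param plane an [annular_plane()]; default canonical plane at z = 0.
#' @return An object of class `aortic_root_geometry`.
#' @export
aortic_root_geometry <- function(z, theta, r_free, k_wall,
                                 perimeter = NULL, nodules = NULL,
                                 plane = annular_plane()) {
  z <- as.numeric(z); theta <- as.numeric(theta)
  stopifnot(length(z) >= 2L, length(theta) >= 2L,
            all(diff(z) > 0), all(diff(theta) > 0),
            all(theta >= 0), all(theta < 360))
  if (length(r_free) == 1L)
    r_free <- matrix(r_free, length(z), length(theta))
  r_free <- as.matrix(r_free)
  stopifnot(nrow(r_free) == length(z), ncol(r_free) == length(theta))
  if (any(!is.finite(r_free)) || any(r_free <= 0))
    stop("r_free must be positive everywhere")
  if (!is.finite(k_wall) || k_wall <= 0) stop("k_wall must be positive")
  if (!is.null(nodules)) {
    nodules <- as.data.frame(nodules)
    need <- c("z", "theta", "half_width_deg", "half_width_mm", "multiplier")
    if (!all(need %in% names(nodules)))
      stop("nodules need columns: ", paste(need, collapse = ", "))
    if (nrow(nodules) > 0 && any(nodules$multiplier < 1))
      stop("calcification stiffness multipliers must be >= 1")
  }
  if (is.null(perimeter)) {
    i0 <- which.min(abs(z))
    perimeter <- 2 * pi * mean(r_free[i0, ])
  }
  stopifnot(perimeter > 0)
  structure(list(z = z, theta = theta, r_free = r_free, k_wall = k_wall,
                 perimeter = perimeter, nodules = nodules, plane = plane),
            class = "aortic_root_geometry")
}

#' Circular-cylinder root geometry
#'
#' Convenience constructor for an idealised root: constant radius, uniform
#' grid. Useful for analytic cross-checks and as the base anatomy of the
#' mechanistic cohort generator.
#'
#' @param radius wall radius (mm).
#' @param z_range axial extent (mm), annulus at 0, positive toward ventricle.
#' @param dz axial grid step (mm).
#' @param dtheta circumferential grid step (degrees); must divide 360.
#' @param ... passed to [aortic_root_geometry()] (`k_wall`, `nodules`, ...).
#' @export
cylinder_root_geometry <- function(radius, z_range = c(-10, 20),
                                   dz = 0.25, dtheta = 1, k_wall = 0.5, ...) {
  stopifnot(radius > 0, dz > 0, dtheta > 0, abs(360 / dtheta - round(360 / dtheta)) < 1e-9)
  z <- seq(z_range[1] + dz / 2, z_range[2] - dz / 2, by = dz)
  theta <- seq(0, 360 - dtheta, by = dtheta) + dtheta / 2
  aortic_root_geometry(z = z, theta = theta, r_free = radius,
                       k_wall = k_wall, perimeter = 2 * pi * radius, ...)
}

# Axial (grid) coordinate of a 3-D point: z increases toward the ventricle,
# i.e. opposite to the plane normal (which points ventricle -> aorta).
.grid_z <- function(p, plane) -sum((p - plane$origin) * plane$normal)

.grid_theta <- function(p, plane) {
  # circumferential angle in the annular plane, degrees in [0, 360)
  n <- plane$normal
  # build an in-plane orthonormal basis; deterministic choice
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  v <- p - plane$origin
  (atan2(sum(v * e2), sum(v * e1)) * 180 / pi) %% 360
}

#' IBMS length
#'
#' Length of the inferior border of the membranous septum, computed as the
#' Euclidean distance between landmarks P1 and P3.
#'
#' @param lm a [landmarks()] object.
#' @return Length in mm (>= 0).
#' @export
ibms_length <- function(lm) {
  stopifnot(inherits(lm, "tavi_landmarks"))
  sqrt(sum((lm$p3 - lm$p1)^2))
}

#' IBMS angle to the annular plane
#'
#' Angle alpha between the segment P1--P3 and the annular plane, in
#' degrees, in `[0, 90]` (the complement of the angle to the plane normal).
#'
#' @param lm a [landmarks()] object with P1 != P3.
#' @param plane an [annular_plane()].
#' @return Angle in degrees.
#' @export
ibms_angle <- function(lm, plane) {
  stopifnot(inherits(lm, "tavi_landmarks"), inherits(plane, "annular_plane"))
  v <- lm$p3 - lm$p1
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("IBMS segment has zero length; P1 and P3 coincide")
  s <- abs(sum(v * plane$normal)) / nv
  asin(min(1, max(0, s))) * 180 / pi
}

#' Signed depth of P3 below the annular plane
#'
#' Signed distance of landmark P3 from the annular plane, negative when P3
#' lies on the ventricular side (the plane normal points ventricle ->
#' aorta). Cohorts therefore typically show a negative mean D3.
#'
#' @inheritParams ibms_angle
#' @return Signed distance in mm.
#' @export
p3_depth <- function(lm, plane) {
  stopifnot(inherits(lm, "tavi_landmarks"), inherits(plane, "annular_plane"))
  sum((lm$p3 - plane$origin) * plane$normal)
}

#' Perimeter-derived annular diameter
#'
#' @param perimeter annular perimeter (mm), positive.
#' @return Diameter = perimeter / pi (mm).
#' @export
perimeter_derived_diameter <- function(perimeter) {
  if (!is.numeric(perimeter) || any(!is.finite(perimeter)) || any(perimeter <= 0))
    stop("perimeter must be positive")
  perimeter / pi
}

#' Device sizing index
#'
#' Ratio of the nominal device diameter to the perimeter-derived annular
#' diameter; values above 1 indicate oversizing.
#'
#' @param nominal_device_diameter nominal device diameter (mm), positive.
#' @param annular_diameter perimeter-derived annular diameter (mm), positive.
#' @return Dimensionless ratio.
#' @export
sizing_index <- function(nominal_device_diameter, annular_diameter) {
  if (!is.numeric(nominal_device_diameter) || any(!is.finite(nominal_device_diameter)) ||
      any(nominal_device_diameter <= 0))
    stop("nominal device diameter must be positive")
  if (!is.numeric(annular_diameter) || any(!is.finite(annular_diameter)) ||
      any(annular_diameter <= 0))
    stop("annular diameter must be positive")
  nominal_device_diameter / annular_diameter
}

#' Depth of implantation from frame inflow positions
#'
#' Mean of the signed distances between the inflow edge of the valve frame
#' and the annular plane, measured on the non-coronary and left-coronary
#' cusp sides.
#'
#' @param frame_inflow_positions named or unnamed numeric length-2 vector of
#'   signed depths (mm) at the NCC and LCC sides, or a list with elements
#'   `ncc` and `lcc`.
#' @param plane unused placeholder kept for interface symmetry (depths are
#'   already measured relative to the plane).
#' @return DOI in mm.
#' @export
doi_from_frame <- function(frame_inflow_positions, plane = NULL) {
  x <- frame_inflow_positions
  if (is.list(x)) {
    if (!all(c("ncc", "lcc") %in% names(x)))
      stop("need inflow depths on both the NCC and LCC sides")
    x <- c(x$ncc, x$lcc)
  }
  x <- as.numeric(x)
  if (length(x) != 2L || any(!is.finite(x)))
    stop("need inflow depths on both the NCC and LCC sides")
  mean(x)
}

# Project the IBMS landmarks onto the (theta, z) wall grid and return the
# piecewise-linear curve z(theta) over the covered angular span, plus the
# direction (+1/-1 in theta) toward the RCC reference angle.
.ibms_on_grid <- function(geometry, lm) {
  plane <- geometry$plane
  pts <- Filter(Negate(is.null), list(lm$p1, lm$p2, lm$p3))
  th <- vapply(pts, .grid_theta, numeric(1), plane = plane)
  zz <- vapply(pts, .grid_z, numeric(1), plane = plane)
  # unwrap angles along the P1 -> P3 path so the curve is monotone in theta
  for (k in seq_along(th)[-1]) {
    d <- th[k] - th[k - 1]
    if (d > 180) th[k] <- th[k] - 360
    if (d < -180) th[k] <- th[k] + 360
  }
  if (sqrt(sum((lm$p3 - lm$p1)^2)) < 1e-12)
    stop("IBMS landmarks coincide; cannot build ROI")
  zr <- range(geometry$z)
  if (any(zz < zr[1] - 1e-9) || any(zz > zr[2] + 1e-9))
    stop("IBMS projects outside the axial range of the geometry grid")
  # direction toward RCC from the span, via shortest signed angular path
  span <- range(th)
  rcc <- lm$rcc_reference_angle
  mid <- mean(span)
  d <- ((rcc - mid + 180) %% 360) - 180
  dir_rcc <- if (d >= 0) +1 else -1
  list(theta = th, z = zz, span = span, dir_rcc = dir_rcc)
}

#' Conduction-system region of interest
#'
#' Builds the ROI used for contact-pressure analysis: the wall patch between
#' the IBMS curve (piecewise-linear through P1, optionally P2, and P3,
#' extended circumferentially by `extension_deg` toward the right-coronary
#' cusp) and the plane `depth_limit` mm below the annular level. Within the
#' extension the IBMS boundary is continued at the level of its endpoint
#' projection.
#'
#' @param geometry an [aortic_root_geometry()].
#' @param lm a [landmarks()] object.
#' @param extension_deg circumferential extension toward the RCC (degrees,
#'   default 25).
#' @param depth_limit axial cut-off below the annulus (mm, default 15).
#' @return An object of class `roi_patch`: logical `mask` over the
#'   `(z, theta)` grid, matrix `cell_area` (mm^2), and the total `area`.
#' @export
build_roi <- function(geometry, lm, extension_deg = 25, depth_limit = 15) {
  stopifnot(inherits(geometry, "aortic_root_geometry"),
            inherits(lm, "tavi_landmarks"),
            extension_deg >= 0, depth_limit > 0)
  ib <- .ibms_on_grid(geometry, lm)
  lo <- ib$span[1]; hi <- ib$span[2]
  if (ib$dir_rcc > 0) hi <- hi + extension_deg else lo <- lo - extension_deg

  th <- geometry$theta
  z <- geometry$z
  dth <- diff(th[1:2]); dz <- diff(z[1:2])

  # angular membership on the circle (candidate shifts by +-360)
  th_un <- outer(th, c(-360, 0, 360), "+")
  inside <- apply(th_un >= lo - 1e-9 & th_un <= hi + 1e-9, 1, any)
  th_eff <- apply(th_un, 1, function(v) {
    ok <- v >= lo - 1e-9 & v <= hi + 1e-9
    if (any(ok)) v[which(ok)[1]] else NA_real_
  })

  # IBMS boundary level per angle: interpolate inside the landmark span,
  # constant continuation at the endpoint level elsewhere in the extension
  zb <- rep(NA_real_, length(th))
  o <- order(ib$theta)
  tk <- ib$theta[o]; zk <- ib$z[o]
  for (j in which(inside)) {
    t_eff <- th_eff[j]
    zb[j] <- if (t_eff <= tk[1]) zk[1]
             else if (t_eff >= tk[length(tk)]) zk[length(tk)]
             else stats::approx(tk, zk, xout = t_eff)$y
  }

  mask <- matrix(FALSE, length(z), length(th))
  for (j in which(inside))
    mask[, j] <- z >= zb[j] - 1e-9 & z <= depth_limit + 1e-9
  cell_area <- geometry$r_free * (dth * pi / 180) * dz
  area <- sum(cell_area[mask])
  if (area <= 0) stop("ROI patch is empty; check landmarks and grid extent")
  structure(list(mask = mask, cell_area = cell_area, area = area,
                 theta_bounds = c(lo, hi), depth_limit = depth_limit),
            class = "roi_patch")
}
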