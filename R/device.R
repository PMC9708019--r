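#' TAVI device model
#'
#' Describes a valve frame for the radial-equilibrium deployment model.
#' Self-expanding frames are force-controlled: the radial contact pressure
#' the frame can exert decreases with the local diameter and vanishes at the
#' nominal diameter. Mechanically expanding frames are displacement-
#' controlled: they are driven to the nominal diameter regardless of the
#' wall load.
#'
#' @param device_id short identifier, e.g. `"CV 29"`.
#' @param family `"CV"`, `"ER/EPRO"` or `"LT"`.
#' @param nominal_diameter nominal (labelled) frame diameter at the inflow
#'   (mm).
#' @param frame_length frame length (mm).
#' @param mode `"force"` (self-expanding) or `"displacement"`
#'   (mechanically expanding).
#' @param peak_pressure contact pressure at the crimped diameter (MPa);
#'   only used by the default linear force curve.
#' @param crimped_diameter crimped frame diameter (mm).
#' @param p_dev optional custom radial pressure curve `function(d, z_local)`
#'   returning MPa; must be non-negative and non-increasing in `d`. Default:
#'   linear ramp from `peak_pressure` at `crimped_diameter` to 0 at
#'   `nominal_diameter` (clamped at 0 beyond).
#' @return An object of class `tavi_device`.
#' @export
device_model <- function(device_id, family, nominal_diameter, frame_length,
                         mode = c("force", "displacement"),
                         peak_pressure = 2, crimped_diameter = 6,
                         p_dev = NULL) {
  mode <- match.arg(mode)
  stopifnot(nominal_diameter > 0, frame_length > 0,
            peak_pressure >= 0, crimped_diameter > 0,
            crimped_diameter < nominal_diameter)
  if (is.null(p_dev)) {
    d_nom <- nominal_diameter; d_cr <- crimped_diameter; pk <- peak_pressure
    p_dev <- function(d, z_local = 0) pmax(0, pk * (d_nom - d) / (d_nom - d_cr))
  }
  structure(list(device_id = device_id, family = family,
                 nominal_diameter = nominal_diameter,
                 frame_length = frame_length, mode = mode,
                 peak_pressure = peak_pressure,
                 crimped_diameter = crimped_diameter, p_dev = p_dev),
            class = "tavi_device")
}

#' Device catalogue
#'
#' The eight devices used in the cohort: CoreValve (CV) 26/29/31 and Evolut
#' R / Evolut PRO (ER/EPRO) 26/29, both self-expanding (force-controlled),
#' and the mechanically expanding Lotus (LT) 23/25/27
#' (displacement-controlled). Frame lengths are nominal published
#' dimensions; the default force curves are the package's simplified linear
#' characteristics and can be overridden per device.
#'
#' @param path optional YAML file describing the catalogue; defaults to the
#'   configuration shipped with the package.
#' @return Named list of [device_model()] objects, length 8.
#' @export
device_catalogue <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "devices.yaml", package = "tavicap",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg$devices, function(d)
    device_model(device_id = d$device_id, family = d$family,
                 nominal_diameter = d$nominal_diameter,
                 frame_length = d$frame_length, mode = d$mode,
                 peak_pressure = d$peak_pressure,
                 crimped_diameter = d$crimped_diameter))
  names(out) <- vapply(out, function(d) d$device_id, character(1))
  out
}

# Per-node effective stiffness: wall stiffness times the largest
# calcification multiplier covering the node (1 if none).
.effective_stiffness <- function(geometry) {
  k <- matrix(geometry$k_wall, length(geometry$z), length(geometry$theta))
  nd <- geometry$nodules
  if (is.null(nd) || nrow(nd) == 0L) return(k)
  for (i in seq_len(nrow(nd))) {
    dth <- abs(((outer(rep(1, length(geometry$z)), geometry$theta) - nd$theta[i] + 180) %% 360) - 180)
    dzz <- abs(outer(geometry$z - nd$z[i], rep(1, length(geometry$theta))))
    hit <- dth <= nd$half_width_deg[i] & dzz <= nd$half_width_mm[i]
    k[hit] <- pmax(k[hit], geometry$k_wall * nd$multiplier[i])
  }
  k
}

#' Deploy a device into a root geometry
#'
#' Solves, independently at every wall node covered by the frame, the radial
#' equilibrium between the linear wall response
#' `p_wall(r) = k_eff * (r - r_free)` (zero for `r <= r_free`) and the
#' device's radial pressure curve. For force-controlled (self-expanding)
#' frames the equilibrium radius is the unique root of
#' `p_wall(r) = p_dev(2r)` (bisection, monotone bracket); for
#' displacement-controlled frames the wall is displaced to the nominal
#' radius and the pressure is the resulting wall reaction. Nodes outside the
#' frame's axial span carry zero pressure.
#'
#' @param geometry an [aortic_root_geometry()].
#' @param device a [tavi_device][device_model()].
#' @param doi depth of implantation (mm): axial position of the frame inflow
#'   edge below the annular plane (positive toward the ventricle).
#' @param rotation circumferential frame rotation (degrees); retained for
#'   interface completeness, irrelevant for the axisymmetric default frames.
#' @param tol bisection tolerance on the equilibrium radius (mm).
#' @return An object of class `contact_pressure_field` with matrices
#'   `pressure` (MPa) and `r_eq` (mm) on the geometry grid.
#' @export
deploy <- function(geometry, device, doi, rotation = 0, tol = 1e-9) {
  stopifnot(inherits(geometry, "aortic_root_geometry"),
            inherits(device, "tavi_device"), is.finite(doi))
  z <- geometry$z
  covered <- z <= doi + 1e-9 & z >= doi - device$frame_length - 1e-9
  if (!any(covered))
    stop("frame does not overlap the axial range of the grid (check DOI)")
  k_eff <- .effective_stiffness(geometry)
  p <- matrix(0, length(z), length(geometry$theta))
  r_eq <- geometry$r_free

  idx <- which(covered)
  rf <- geometry$r_free[idx, , drop = FALSE]
  ke <- k_eff[idx, , drop = FALSE]
  zl <- doi - z[idx]  # distance from the inflow edge along the frame

  if (device$mode == "displacement") {
    r_nom <- device$nominal_diameter / 2
    pr <- pmax(0, ke * (r_nom - rf))
    re <- ifelse(r_nom > rf, r_nom, rf)
  } else {
    zl_m <- matrix(zl, nrow = length(idx), ncol = ncol(rf))
    # interference only where the frame still pushes at the free radius
    pdev_at_rf <- matrix(device$p_dev(as.vector(2 * rf), as.vector(zl_m)),
                         nrow = nrow(rf))
    active <- pdev_at_rf > 0
    re <- rf
    pr <- matrix(0, nrow(rf), ncol(rf))
    if (any(active)) {
      a <- rf[active]
      b <- rep(device$nominal_diameter / 2, sum(active))
      keA <- ke[active]; rfA <- rf[active]; zlA <- zl_m[active]
      g <- function(r) keA * (r - rfA) - device$p_dev(2 * r, zlA)
      # widen the upper bracket if a custom curve is still positive there
      gb <- g(b)
      it <- 0L
      while (any(gb < 0) && it < 60L) {
        b[gb < 0] <- b[gb < 0] + device$nominal_diameter / 4
        gb <- g(b); it <- it + 1L
      }
      if (any(gb < 0))
        stop("deploy: failed to bracket the equilibrium radius; ",
             "device pressure curve may not vanish at large diameters")
      for (k in seq_len(ceiling(log2((max(b - a)) / tol)) + 2L)) {
        m <- (a + b) / 2
        gm <- g(m)
        hi <- gm > 0
        b[hi] <- m[hi]; a[!hi] <- m[!hi]
      }
      rA <- (a + b) / 2
      re[active] <- rA
      pr[active] <- keA * (rA - rfA)
    }
  }
  p[idx, ] <- pr
  r_eq[idx, ] <- re
  p[p < 0] <- 0
  structure(list(pressure = p, r_eq = r_eq, doi = doi,
                 device_id = device$device_id),
            class = "contact_pressure_field")
}

#' Maximum contact pressure in the ROI
#'
#' @param field a `contact_pressure_field` from [deploy()].
#' @param roi an `roi_patch` from [build_roi()].
#' @return Cpmax in MPa (0 if there is no contact within the ROI).
#' @export
cp_max <- function(field, roi) {
  stopifnot(inherits(field, "contact_pressure_field"),
            inherits(roi, "roi_patch"))
  if (!any(roi$mask)) stop("ROI is empty")
  m <- field$pressure[roi$mask]
  if (length(m) == 0L) return(0)
  max(m)
}

#' Contact pressure index
#'
#' Percentage of the ROI area subjected to contact pressure (pressure above
#' a small threshold guarding against floating-point noise).
#'
#' @inheritParams cp_max
#' @param eps contact threshold (MPa, default 1e-6).
#' @return CPI in percent, in `[0, 100]`.
#' @export
cpi <- function(field, roi, eps = 1e-6) {
  stopifnot(inherits(field, "contact_pressure_field"),
            inherits(roi, "roi_patch"))
  if (!any(roi$mask)) stop("ROI is empty")
  contact <- roi$mask & field$pressure > eps
  100 * sum(roi$cell_area[contact]) / roi$area
}

#' Export a contact-pressure field as a tidy table
#'
#' @param field a `contact_pressure_field`.
#' @param geometry the geometry it was computed on.
#' @return Data frame with columns `z`, `theta`, `r_eq`, `pressure`.
#' @export
field_as_table <- function(field, geometry) {
  stopifnot(inherits(field, "contact_pressure_field"),
            inherits(geometry, "aortic_root_geometry"))
  data.frame(z = rep(geometry$z, times = length(geometry$theta)),
             theta = rep(geometry$theta, each = length(geometry$z)),
             r_eq = as.vector(field$r_eq),
             pressure = as.vector(field$pressure))
}
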