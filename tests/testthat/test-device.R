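test_that("device catalogue has the eight cohort devices with sane curves", {
  cat8 <- device_catalogue()
  expect_length(cat8, 8)
  expect_setequal(names(cat8),
                  c("CV 26", "CV 29", "CV 31", "ER/EPRO 26", "ER/EPRO 29",
                    "LT 23", "LT 25", "LT 27"))
  expect_equal(cat8[["CV 29"]]$nominal_diameter, 29)
  expect_equal(cat8[["LT 25"]]$mode, "displacement")
  d_grid <- seq(5, 35, by = 0.25)
  for (dev in cat8) {
    p <- dev$p_dev(d_grid, 0)
    expect_true(all(p >= 0))
    expect_true(all(diff(p) <= 1e-12))          # non-increasing in diameter
    expect_true(all(p[d_grid >= dev$nominal_diameter] == 0))
  }
})

test_that("deployment reproduces the concentric-cylinder equilibrium", {
  geo <- cylinder_root_geometry(12, k_wall = 0.2, dz = 0.5, dtheta = 2)
  dev <- linear_test_device(r_zero = 13, slope = 0.1)
  f <- deploy(geo, dev, doi = 15)
  covered <- geo$z <= 15
  # k (r - rf) = s (r0 - r)  =>  r_eq = (k rf + s r0) / (k + s)
  r_exp <- (0.2 * 12 + 0.1 * 13) / 0.3
  expect_equal(max(abs(f$r_eq[covered, ] - r_exp)), 0, tolerance = 1e-9)
  expect_equal(max(abs(f$pressure[covered, ] - 0.2 * (r_exp - 12))), 0,
               tolerance = 1e-9)
  expect_true(all(f$pressure[!covered, ] == 0))
})

test_that("an undersized device exerts no pressure", {
  geo <- cylinder_root_geometry(13, k_wall = 0.5, dz = 0.5, dtheta = 2)
  dev <- device_model("SMALL", "CV", nominal_diameter = 20, frame_length = 40,
                      mode = "force")
  f <- deploy(geo, dev, doi = 10)
  expect_true(all(f$pressure == 0))
  expect_equal(f$r_eq, geo$r_free)
})

test_that("a calcification nodule locally raises the contact pressure", {
  # nodule sized to cover exactly one grid cell centre (z = 4.75, theta = 89)
  nod <- data.frame(z = 4.75, theta = 89, half_width_deg = 0.9,
                    half_width_mm = 0.24, multiplier = 5)
  geo <- cylinder_root_geometry(12, k_wall = 0.2, dz = 0.5, dtheta = 2,
                                nodules = nod)
  dev <- linear_test_device(r_zero = 13, slope = 0.1)
  f <- deploy(geo, dev, doi = 15)
  i <- which.min(abs(geo$z - 4.75)); j <- which.min(abs(geo$theta - 89))
  # analytic equilibrium with k_eff = 1.0: r = (1*12 + 0.1*13)/1.1
  r_nod <- (1.0 * 12 + 0.1 * 13) / 1.1
  expect_equal(f$r_eq[i, j], r_nod, tolerance = 1e-9)
  expect_equal(f$pressure[i, j], 1.0 * (r_nod - 12), tolerance = 1e-9)
  expect_gt(f$pressure[i, j], f$pressure[i, j + 1])
  expect_gt(f$pressure[i, j], f$pressure[i + 1, j])
})

test_that("displacement-controlled frames push the wall to the nominal radius", {
  geo <- cylinder_root_geometry(11, k_wall = 0.5, dz = 0.5, dtheta = 2)
  lt <- device_catalogue()[["LT 25"]]
  f <- deploy(geo, lt, doi = 8)
  covered <- geo$z <= 8 & geo$z >= 8 - lt$frame_length
  expect_equal(unique(as.vector(round(f$r_eq[covered, ], 9))), 12.5)
  expect_equal(unique(as.vector(round(f$pressure[covered, ], 9))), 0.5 * (12.5 - 11))
})

test_that("Cpmax and CPI match brute-force oracles on fabricated fields", {
  geo <- cylinder_root_geometry(12, dz = 0.5, dtheta = 2)
  lm <- ibms_arc_landmarks(12)
  roi <- build_roi(geo, lm)
  zero <- fake_field(matrix(0, length(geo$z), length(geo$theta)), geo)
  expect_equal(cp_max(zero, roi), 0)
  expect_equal(cpi(zero, roi), 0)
  one_cell <- matrix(0, length(geo$z), length(geo$theta))
  ij <- which(roi$mask, arr.ind = TRUE)[1, ]
  one_cell[ij[1], ij[2]] <- 0.55
  expect_equal(cp_max(fake_field(one_cell, geo), roi), 0.55)
  set.seed(3)
  rnd <- matrix(abs(rnorm(length(geo$z) * length(geo$theta))),
                length(geo$z), length(geo$theta))
  f <- fake_field(rnd, geo)
  # exhaustive masked scan
  expect_equal(cp_max(f, roi), max(rnd[roi$mask]))
  expect_equal(cpi(f, roi), 100)
  # exactly half of the ROI columns in contact -> 50% by area weighting
  half <- matrix(0, length(geo$z), length(geo$theta))
  cols <- which(colSums(roi$mask) > 0)
  half[, cols[seq_len(length(cols) / 2)]] <- 1
  expect_equal(cpi(fake_field(half, geo), roi), 50, tolerance = 1e-9)
  expect_error(cp_max(f, structure(list(mask = roi$mask & FALSE,
                                        cell_area = roi$cell_area, area = 1),
                                   class = "roi_patch")), "empty")
})

test_that("Cpmax/CPI are monotone in oversizing and DOI", {
  geo <- cylinder_root_geometry(12, k_wall = 0.5, dz = 0.5, dtheta = 2)
  lm <- ibms_arc_landmarks(12)
  roi <- build_roi(geo, lm)
  scales <- c(0.9, 1.0, 1.05, 1.1, 1.2, 1.3)
  res <- t(vapply(scales, function(s) {
    dev <- device_model("S", "CV", nominal_diameter = 24 * s,
                        frame_length = 50, mode = "force",
                        peak_pressure = 2, crimped_diameter = 6)
    f <- deploy(geo, dev, doi = 16)
    c(cp_max(f, roi), cpi(f, roi))
  }, numeric(2)))
  expect_true(all(diff(res[, 1]) >= -1e-12))
  expect_true(all(diff(res[, 2]) >= -1e-12))
  # deeper implantation covers more of the ROI until the frame passes it
  dev <- device_model("S", "CV", nominal_diameter = 27, frame_length = 12,
                      mode = "force", peak_pressure = 2, crimped_diameter = 6)
  cpis <- vapply(c(2, 6, 10, 15), function(doi)
    cpi(deploy(geo, dev, doi = doi), roi), numeric(1))
  expect_true(all(diff(cpis) >= -1e-12))
})

test_that("stiffer walls yield higher pressure and smaller equilibrium radius", {
  dev <- linear_test_device(r_zero = 13.5, slope = 0.15)
  out <- t(vapply(c(0.1, 0.3, 0.6, 1.2), function(k) {
    geo <- cylinder_root_geometry(12, k_wall = k, dz = 1, dtheta = 10)
    f <- deploy(geo, dev, doi = 10)
    c(f$pressure[1, 1], f$r_eq[1, 1])
  }, numeric(2)))
  expect_true(all(diff(out[, 1]) > 0))
  expect_true(all(diff(out[, 2]) < 0))
})

test_that("Cpmax and CPI are stable under grid refinement", {
  lmf <- function(r) ibms_arc_landmarks(r)
  dev <- device_catalogue()[["CV 29"]]
  vals <- t(vapply(list(c(1, 0.5), c(0.5, 0.25)), function(g) {
    geo <- cylinder_root_geometry(12.2, k_wall = 0.5, dtheta = g[1], dz = g[2])
    roi <- build_roi(geo, lmf(12.2))
    f <- deploy(geo, dev, doi = 6)
    c(cp_max(f, roi), cpi(f, roi))
  }, numeric(2)))
  expect_equal(vals[2, 1], vals[1, 1], tolerance = 0.02)
  expect_equal(vals[2, 2], vals[1, 2], tolerance = 0.02)
})

test_that("field export table matches the grid", {
  geo <- cylinder_root_geometry(12, dz = 2, dtheta = 30)
  dev <- device_catalogue()[["CV 26"]]
  f <- deploy(geo, dev, doi = 8)
  tab <- field_as_table(f, geo)
  expect_equal(nrow(tab), length(geo$z) * length(geo$theta))
  expect_equal(max(tab$pressure), max(f$pressure))
})
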