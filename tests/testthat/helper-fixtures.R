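# Shared fixtures: small geometries, landmark sets and fabricated
# contact-pressure fields used across the unit tests.

# Landmarks for a 30-degree IBMS arc at constant depth on a cylinder of
# radius r, ending at theta3 and rising toward the RCC at +30 degrees.
ibms_arc_landmarks <- function(r, theta1 = 340, theta3 = 310,
                               z1 = 0, z3 = 0, rcc = 30) {
  landmarks(
    p1 = c(r * cos(theta1 * pi / 180), r * sin(theta1 * pi / 180), z1),
    p3 = c(r * cos(theta3 * pi / 180), r * sin(theta3 * pi / 180), z3),
    rcc_reference_angle = rcc)
}

# Fabricate a contact-pressure field on a geometry grid from a matrix.
fake_field <- function(pressure, geometry) {
  structure(list(pressure = pressure, r_eq = geometry$r_free,
                 doi = NA_real_, device_id = "fake"),
            class = "contact_pressure_field")
}

# Linear self-expanding test device with the closed-form-friendly curve
# p_dev(2r) = slope * (r_zero - r), expressed as a function of diameter.
linear_test_device <- function(r_zero = 13, slope = 0.1, d_nom = 2 * r_zero,
                               frame_length = 50) {
  device_model("TEST", "CV", nominal_diameter = d_nom,
               frame_length = frame_length, mode = "force",
               p_dev = function(d, z_local = 0) pmax(0, slope * (r_zero - d / 2)))
}

# Small cohort with planted signal for fast ML tests.
toy_cohort <- function(n, seed = 1, signal = TRUE) {
  co <- sample_cohort_statistical(n, seed)
  if (!signal) {
    set.seed(seed + 1)
    co$ca <- sample(co$ca)                      # break the feature-outcome link
    co$lbbb_rbbb <- co$ca; co$ppi <- 0L         # keep the composite invariant
  }
  co
}
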