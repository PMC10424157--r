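# Laminar-flow shear models: operating points, series solution vs
# finite-difference oracle, plan profiles, inversion.

test_that("unit conversions round-trip exactly", {
  for (x in c(1, 300, 0.017, 1e5)) {
    expect_equal(m3s_to_ul_min(ul_min_to_m3s(x)), x, tolerance = 1e-12)
    expect_equal(m3s_to_ml_day(ml_day_to_m3s(x)), x, tolerance = 1e-12)
    expect_equal(dyn_cm2_to_pa(pa_to_dyn_cm2(x)), x, tolerance = 1e-12)
  }
  # exact definitions
  expect_identical(ul_min_to_m3s(1), 1 / 6e10)
  expect_identical(ml_day_to_m3s(1), 1e-6 / 86400)
})

test_that("inlet velocity matches Q over the port area", {
  g <- paper_geometry()
  v <- inlet_velocity(q300(), g)
  expect_equal(v, 5.2e-4, tolerance = 0.005)      # 2 s.f.
  expect_equal(v, ul_min_to_m3s(300) / (pi * 3.5e-3^2 / 4), tolerance = 1e-12)
  expect_identical(inlet_velocity(flow_condition(0, "ul/min"), g), 0)
  v2 <- inlet_velocity(flow_condition(600, "ul/min"), g)
  expect_equal(v2, 1.0394e-3, tolerance = 1e-4)
  expect_equal(v2, 2 * v, tolerance = 1e-12)
})

test_that("parallel-plate shear has its closed-form value and is linear", {
  g <- paper_geometry()
  tau <- plate_shear(q300(), g)
  expect_equal(tau, 0.0375, tolerance = 1e-10)    # 6 mu Q / (w h^2) by hand
  expect_equal(pa_to_dyn_cm2(tau), 0.375, tolerance = 1e-10)
  expect_identical(plate_shear(flow_condition(0, "ul/min"), g), 0)
  for (q in c(17, 450, 2000)) {
    t1 <- plate_shear(flow_condition(q, "ul/min"), g)
    t2 <- plate_shear(flow_condition(2 * q, "ul/min"), g)
    expect_equal(t2, 2 * t1, tolerance = 1e-12)
  }
})

test_that("rectangular-duct series reaches the infinite-plate limit", {
  g_wide <- channel_geometry(0.4e-3, 0.4, 50e-3, 3.5e-3)  # aspect 1000
  ratio <- rect_duct_shear(q300(), g_wide) / plate_shear(q300(), g_wide)
  expect_lt(abs(ratio - 1), 0.005)
  # finite aspect exceeds the plate value at fixed Q
  g <- paper_geometry()
  expect_gt(rect_duct_shear(q300(), g), plate_shear(q300(), g))
})

test_that("duct series is converged at the default truncation", {
  for (ar in c(1, 12.5)) {
    g <- channel_geometry(0.4e-3, 0.4e-3 * ar, 50e-3, 3.5e-3)
    t1 <- rect_duct_shear(q300(), g, n_terms = 101)
    t2 <- rect_duct_shear(q300(), g, n_terms = 202)
    expect_lt(abs(t2 - t1) / t1, 1e-9)
  }
  expect_error(rect_duct_shear(q300(), paper_geometry(), n_terms = 0),
               "n_terms")
})

test_that("duct series agrees with the finite-difference Poisson oracle", {
  # the slide cross-section and the square duct here; the wider aspect-ratio
  # sweep runs in the acceptance suite
  for (ar in c(1, 12.5)) {
    g <- channel_geometry(0.4e-3, 0.4e-3 * ar, 50e-3, 3.5e-3)
    se <- rect_duct_shear(q300(), g)
    fd <- fd_duct_shear(q300(), g, n_y = 201, n_z = 201)
    expect_lt(abs(se - fd) / fd, 0.01)
  }
})

test_that("every shear model is homogeneous of degree one in flow rate", {
  g <- paper_geometry()
  gr <- ibidi_slide_geometry("rectangle")
  k <- 3.7
  q1 <- flow_condition(41, "ul/min"); q2 <- flow_condition(41 * k, "ul/min")
  expect_equal(plate_shear(q2, g), k * plate_shear(q1, g), tolerance = 1e-12)
  expect_equal(rect_duct_shear(q2, g), k * rect_duct_shear(q1, g),
               tolerance = 1e-12)
  p1 <- plan_shear_profile(q1, g); p2 <- plan_shear_profile(q2, g)
  expect_equal(p2$shear, k * p1$shear, tolerance = 1e-12)
})

test_that("plan profile is constant for a rectangle and dips mid-ellipse", {
  pr <- plan_shear_profile(q300(), ibidi_slide_geometry("rectangle"))
  expect_true(all(abs(pr$shear - plate_shear(q300(), paper_geometry())) <
                  1e-15))
  pe <- plan_shear_profile(q300(), paper_geometry(), n_positions = 101)
  # mid-length: full width, so the lubrication value equals plate shear
  expect_equal(pe$summary, plate_shear(q300(), paper_geometry()),
               tolerance = 1e-12)
  expect_equal(which.min(pe$shear), (length(pe$shear) + 1) / 2)
  # symmetric about mid-length
  expect_equal(pe$shear, rev(pe$shear), tolerance = 1e-12)
  # clipped away from the degenerate tips: all finite, none excluded
  expect_true(all(is.finite(pe$shear)))
  expect_length(pe$shear, 101)
})

test_that("flow-rate inversion hits the target and respects linearity", {
  g <- paper_geometry()
  fl <- fluid_properties()
  q <- flow_rate_for_shear(dyn_cm2_to_pa(0.35), g, fl, model = "plate")
  expect_equal(m3s_to_ul_min(q), 280, tolerance = 1e-6)
  # round trip at arbitrary rates, both models
  for (model in c("plate", "rect_duct")) {
    for (q0 in ul_min_to_m3s(c(12, 300, 990))) {
      cond <- flow_condition(q0, "m3/s")
      tau <- switch(model, plate = plate_shear(cond, g),
                    rect_duct = rect_duct_shear(cond, g))
      qf <- flow_rate_for_shear(tau, g, fl, model = model)
      expect_lt(abs(qf - q0) / q0, 1e-6)
    }
  }
  # tau linear in Q => recovered rates scale like the targets
  q_lo <- flow_rate_for_shear(dyn_cm2_to_pa(0.0008), g, fl)
  q_hi <- flow_rate_for_shear(dyn_cm2_to_pa(0.35), g, fl)
  expect_equal(q_lo / q_hi, 0.0008 / 0.35, tolerance = 1e-6)
  expect_error(flow_rate_for_shear(-1, g, fl), "target_shear")
})

test_that("the two culture operating points are mutually consistent", {
  g <- paper_geometry()
  c_nut <- flow_condition(1, "ml/day")
  c_phys <- flow_condition(300, "ul/min")
  expected <- (1000 / 1440) / 300
  expect_equal(plate_shear(c_nut, g) / plate_shear(c_phys, g), expected,
               tolerance = 1e-12)
  expect_equal(rect_duct_shear(c_nut, g) / rect_duct_shear(c_phys, g),
               expected, tolerance = 1e-12)
  pn <- plan_shear_profile(c_nut, g); pp <- plan_shear_profile(c_phys, g)
  expect_equal(pn$summary / pp$summary, expected, tolerance = 1e-12)
})

test_that("geometry and condition constructors validate their inputs", {
  expect_error(channel_geometry(0, 5e-3, 50e-3, 3.5e-3), "height")
  expect_error(channel_geometry(5e-3, 4e-4, 50e-3, 3.5e-3), "exceed")
  expect_error(flow_condition(-1, "ul/min"), "non-negative")
  expect_error(fluid_properties(-1), "positive")
  expect_error(rect_duct_shear(q300(),
                               channel_geometry(4e-4, 4e-4, 1e-2, 1e-3)),
               NA)  # square duct allowed (width == height)
})
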