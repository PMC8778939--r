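test_that("numerical IFP matches the sinh closed form on a homogeneous sphere", {
  # single-material configuration: Starling source everywhere ("full")
  flow <- flow_params(starling_normal = "full")
  g <- default_grid(n = c(30, 120, 240))
  sol <- solve_ifp(g, flow)
  ana <- analytic_ifp_sphere(flow, R = 3e-2, r = g$r)
  pe <- sol$pe
  expect_lt(max(abs(sol$p - ana)) / pe, 2e-3)
})

test_that("nested default geometry has the expected central plateau", {
  g <- default_grid()
  sol <- solve_ifp(g, flow_params())
  # pe = 15.6 - 0.82 (20 - 15) = 11.5 mmHg; alpha ~ 37 so the center sits on pe
  expect_equal(convert_units(sol$pe, "Pa", "mmHg"), 11.5, tolerance = 1e-12)
  expect_equal(sol$p_mmHg[1], 11.5, tolerance = 2e-3)
  # pressure non-increasing with radius inside the tumor
  tum <- g$region %in% c("injection", "tumor")
  expect_true(all(diff(sol$p[tum]) < 1e-9))
  # velocity: zero at the center by symmetry, peak near the tumor periphery
  expect_equal(sol$u_node[1], 0)
  r_peak <- g$face_r[which.max(sol$u_face)]
  expect_gt(r_peak, 0.8e-2)
  expect_lt(r_peak, 1.2e-2)
  # filtration velocity non-negative wherever p < pe
  expect_true(all(sol$u_face[g$face_r < 0.9e-2] >= -1e-15))
})

test_that("no vascular conductivity means no flow", {
  g <- default_grid()
  sol <- solve_ifp(g, flow_params(vessel_hydraulic_conductivity = 0))
  expect_equal(max(abs(sol$p)), 0)
  expect_equal(max(abs(sol$u_face)), 0)
})

test_that("global fluid mass balance closes", {
  g <- default_grid()
  for (mode in c("sink", "balanced", "full")) {
    sol <- solve_ifp(g, flow_params(starling_normal = mode))
    expect_lt(sol$mass_balance, 1e-3, label = paste("mode", mode))
  }
})

test_that("analytic sphere solution has the right limits", {
  flow <- flow_params()
  pe <- flow$vascular_pressure - 0.82 *
    (flow$plasma_osmotic_pressure - flow$interstitial_osmotic_pressure)
  R <- 1e-2
  alpha <- R * sqrt(flow$vessel_hydraulic_conductivity *
                      flow$vessel_area_density / flow$hydraulic_conductivity)
  # center -> pe (1 - alpha / sinh(alpha)) ~ pe for alpha >> 1
  p0 <- analytic_ifp_sphere(flow, R, 0)
  expect_equal(p0, pe * (1 - alpha / sinh(alpha)), tolerance = 1e-12)
  expect_equal(p0 / pe, 1, tolerance = 1e-10)
  # vanishing source -> zero pressure everywhere
  f0 <- flow_params(vessel_hydraulic_conductivity = 0)
  expect_equal(analytic_ifp_sphere(f0, R, c(0, R / 2, R)), rep(0, 3))
  # boundary condition
  expect_equal(analytic_ifp_sphere(flow, R, R), 0, tolerance = 1e-12)
})
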