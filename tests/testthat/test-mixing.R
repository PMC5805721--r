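test_that("normalization divides by the event's river sample and anchors it at 1", {
  chem <- tiny_chem()
  cn <- normalize_to_river(chem)
  # river rows are exactly 1 for every reactive solute
  riv <- cn$location_class == "river"
  expect_equal(cn$doc_norm[riv], c(1, 1))
  expect_equal(cn$dic_norm[riv], c(1, 1))
  expect_equal(cn$no3_norm[riv], c(1, 1))
  # direct ratio: hyporheic DOC 0.9 over river 1.4
  expect_equal(cn$doc_norm[cn$sample_id == "h1"], 0.9 / 1.4)
  # groundwater nitrate ~20x river shows up as ~20 on the normalized axis
  expect_equal(cn$no3_norm[cn$sample_id == "w1"], 9.9 / 0.5)
  # chloride is the tracer and is never normalized
  expect_null(cn$cl_norm)
})

test_that("normalization fails without a usable river reference", {
  chem <- tiny_chem()
  expect_error(normalize_to_river(chem[chem$location_class != "river", ]),
               "event 1")
  zero <- chem
  zero$doc[1] <- 0
  expect_error(normalize_to_river(zero), "zero or missing")
})

test_that("end members are means over the pure-GW and river sample sets", {
  cn <- normalize_to_river(tiny_chem())
  em <- estimate_endmembers(cn, cl_pure_threshold = 17.5)
  expect_equal(em$cl_gw, mean(c(19, 21, 18.5, 20.5)))
  expect_equal(em$cl_rw, 1.5)
  expect_equal(em$n_pure, 4L)
  expect_error(estimate_endmembers(cn, cl_pure_threshold = 50), "no sample")
})

test_that("gw_fraction is exact linear un-mixing, unclamped, and inverts mixing", {
  em <- structure(list(cl_gw = 20, cl_rw = 1.5), class = "endmembers")
  expect_equal(gw_fraction(1.5, em), 0)
  expect_equal(gw_fraction(10.75, em), 0.5)
  # above the mean-defined end member: legal fractions beyond 1
  expect_gt(gw_fraction(22, em), 1)
  expect_equal(gw_fraction(22, em), (22 - 1.5) / 18.5)
  # round trip: mix then un-mix
  f <- seq(-0.1, 1.2, by = 0.01)
  cl <- f * em$cl_gw + (1 - f) * em$cl_rw
  expect_lt(max(abs(gw_fraction(cl, em) - f)), 1e-12)
  degenerate <- structure(list(cl_gw = 5, cl_rw = 5), class = "endmembers")
  expect_error(gw_fraction(3, degenerate), "degenerate")
})

test_that("mixing predictions interpolate the normalized end members", {
  expect_equal(mixing_prediction(0, 0.25), 1)
  expect_equal(mixing_prediction(1, 0.25), 0.25)
  expect_equal(mixing_prediction(0.5, 0.2), 0.6)
})

test_that("conservative solutes show zero deviation without noise", {
  p <- generator_params(seed = 11, noise_cv = 0)
  mix <- mixing_model(normalize_to_river(generate_chemistry(p)))
  expect_lt(max(abs(mix$no3_dev)), 1e-10)
  # river samples sit exactly on the model for every solute
  riv <- mix$location_class == "river"
  expect_lt(max(abs(mix$doc_dev[riv])), 1e-10)
  expect_lt(max(abs(mix$dic_dev[riv])), 1e-10)
})

test_that("deviation sign convention: DOC loss negative, DIC gain positive", {
  p <- generator_params(seed = 12, noise_cv = 0)
  mix <- mixing_model(normalize_to_river(generate_chemistry(p)))
  reacted <- mix$f_gw > 0.02 & mix$f_gw < 0.8
  expect_true(all(mix$doc_dev[reacted] < 0))
  expect_true(all(mix$dic_dev[reacted] > 0))
})

test_that("deviation regression recovers constructed anticorrelation", {
  mix <- data.frame(f_gw = runif(20, 0, 0.09),
                    doc_dev = seq(-0.5, -0.02, length.out = 20))
  mix$dic_dev <- -0.3 * mix$doc_dev
  r <- suppressWarnings(deviation_regression(mix))  # exact fit by design
  expect_lt(r$slope, 0)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, -0.3, tolerance = 1e-10)
  expect_error(deviation_regression(mix, f_max = 0), "fewer than 3")
})

test_that("the DOC curve anchors at the river end member and warns on extrapolation", {
  p <- generator_params(seed = 13, noise_cv = 0)
  mix <- mixing_model(normalize_to_river(generate_chemistry(p)))
  curve <- fit_doc_curve(mix)
  expect_equal(curve(0), 1, tolerance = 0.02)
  expect_warning(curve(1.2), "extrapolat")
  expect_error(fit_doc_curve(mix[mix$f_gw < 0.5, ]), "span")
})

test_that("noise-free changepoint lands exactly on the generator's threshold", {
  p <- generator_params(seed = 14, noise_cv = 0)
  mix <- mixing_model(normalize_to_river(generate_chemistry(p)))
  cp <- changepoint_estimate(mix)
  expect_equal(cp$f_star, 0.10, tolerance = 0.011)
  expect_false(cp$low_confidence)
})

test_that("conservative DOC (no respiration) flags a low-confidence changepoint", {
  p <- generator_params(seed = 15, respiration_strength = 0, noise_cv = 0.02)
  mix <- mixing_model(normalize_to_river(generate_chemistry(p)))
  cp <- changepoint_estimate(mix)
  expect_true(cp$low_confidence)
})

test_that("excluding events changes membership but not the formulas", {
  p <- generator_params(seed = 16)
  cn <- normalize_to_river(generate_chemistry(p))
  full <- mixing_model(cn)
  sub <- mixing_model(cn, exclude_events = c(1, 2))
  expect_false(any(sub$event %in% c(1, 2)))
  # samples retained in both get identical normalized values
  shared <- intersect(full$sample_id, sub$sample_id)
  expect_equal(sub$doc_norm[match(shared, sub$sample_id)],
               full$doc_norm[match(shared, full$sample_id)])
})
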