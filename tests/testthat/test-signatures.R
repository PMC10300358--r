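make_curve <- function(fluor, grid, channel = "BS1") {
  structure(list(temperature = grid$temperature, fluorescence = fluor,
                 channel = channel), class = "melt_curve")
}

test_that("derivative of constant and linear curves is exact", {
  g <- small_grid(256)
  flat <- derivative_signature(make_curve(rep(1, g$n_points), g))
  expect_lt(max(abs(flat$values)), 1e-9)
  lin <- derivative_signature(make_curve(2 - 0.2 * (g$temperature - 40), g))
  inner <- 10:(g$n_points - 10)
  expect_equal(lin$values[inner], rep(-0.2, length(inner)), tolerance = 1e-9)
})

test_that("a single melting transition yields a trough at its tm", {
  g <- small_grid()
  seg <- segment_model(list(melt_component(75, 0.5, 1)), channel = "BS1",
                       include_marker = FALSE)
  cv <- simulate_curve(seg, g, zero_noise(), seed = 1)
  sig <- derivative_signature(cv)
  # oracle: argmin of the analytic derivative scanned over the grid
  analytic <- meltbarcode:::curve_derivative(seg$components, g$temperature)
  oracle_t <- g$temperature[which.min(analytic)]
  expect_lte(abs(g$temperature[which.min(sig$values)] - oracle_t),
             g$step + 1e-9)
  expect_lte(abs(oracle_t - 75), g$step)
})

test_that("window/order preconditions are enforced", {
  g <- small_grid(256)
  cv <- make_curve(rep(1, g$n_points), g)
  expect_error(derivative_signature(cv, window = 10), "odd")
  expect_error(derivative_signature(cv, window = 5, polyorder = 5), "less than")
  short <- make_curve(rep(1, 20), acquisition_grid(n_points = 20))
  expect_error(derivative_signature(short, window = 31), "shorter")
})

test_that("marker detection finds the rightmost trough and tracks offsets", {
  g <- small_grid()
  panel <- default_panel_cached()
  seg <- panel$bs1[[1]]
  sig0 <- derivative_signature(simulate_curve(seg, g, zero_noise(), seed = 1))
  expect_lte(abs(detect_tm_marker(sig0) - TM_MARKER_TM), g$step + 1e-9)
  sig_off <- derivative_signature(
    simulate_curve(seg, g, zero_noise(), seed = 1, temperature_offset = 0.8))
  expect_lte(abs(detect_tm_marker(sig_off) - (TM_MARKER_TM + 0.8)),
             g$step + 1e-9)
  flat <- meltbarcode:::new_signature(g$temperature, rep(0, g$n_points), "BS1")
  expect_true(is.na(detect_tm_marker(flat)))
  bs2 <- meltbarcode:::new_signature(g$temperature, rep(0, g$n_points), "BS2")
  expect_error(detect_tm_marker(bs2), "BS1")
})

test_that("temperature correction undoes an injected offset on both channels", {
  g <- small_grid(2048)
  panel <- default_panel_cached()
  model <- panel[1, ]
  sig_at <- function(offset) {
    r <- simulate_run(model, g, zero_noise(), seed = 2, failure = "none")
    s1 <- derivative_signature(make_curve(
      simulate_curve(model$bs1[[1]], g, zero_noise(), 1,
                     temperature_offset = offset)$fluorescence, g, "BS1"))
    s2 <- derivative_signature(make_curve(
      simulate_curve(model$bs2[[1]], g, zero_noise(), 1,
                     temperature_offset = offset)$fluorescence, g, "BS2"))
    s1$tm_detected <- detect_tm_marker(s1)
    list(s1 = s1, s2 = s2)
  }
  ref <- sig_at(0)
  ref_trough_bs2 <- g$temperature[which.min(ref$s2$values)]
  for (delta in c(-2, -0.8, 0.8, 2)) {
    sh <- sig_at(delta)
    cr <- temperature_correct(sh$s1, sh$s2, TM_MARKER_TM, grid = g)
    expect_true(cr$bs1$corrected && cr$bs2$corrected)
    trough <- g$temperature[which.min(cr$bs2$values)]
    expect_lte(abs(trough - ref_trough_bs2), g$step + 1e-9)
  }
  # identity shift leaves the signature unchanged up to interpolation
  id <- temperature_correct(ref$s1, ref$s2,
                            reference_tm = ref$s1$tm_detected, grid = g)
  expect_equal(id$bs2$values, ref$s2$values, tolerance = 1e-8)
  # an uncorrectable run signals failure instead of passing silently
  nos <- ref$s1; nos$tm_detected <- NA_real_
  expect_error(temperature_correct(nos, ref$s2), "QC")
})

test_that("shifts past the grid edge are zero-filled", {
  g <- small_grid(512)
  vals <- exp(-(g$temperature - 45)^2)
  sig1 <- meltbarcode:::new_signature(g$temperature, vals, "BS1",
                                      tm_detected = 80)
  sig2 <- meltbarcode:::new_signature(g$temperature, vals, "BS2")
  cr <- temperature_correct(sig1, sig2, reference_tm = 84, grid = g)  # +4 shift
  expect_true(all(cr$bs2$values[g$temperature < 44] == 0))
})

test_that("resampling is the identity on its own grid and stable round-trip", {
  g <- small_grid()
  seg <- segment_model(list(melt_component(70, 1, 1)), channel = "BS2",
                       include_marker = FALSE)
  sig <- derivative_signature(simulate_curve(seg, g, zero_noise(), seed = 1))
  same <- resample_signature(sig, g)
  expect_equal(same$values, sig$values, tolerance = 1e-12)
  coarse <- acquisition_grid(n_points = 1019L)
  down <- resample_signature(sig, coarse)
  analytic <- meltbarcode:::curve_derivative(seg$components, coarse$temperature)
  expect_lt(max(abs(down$values - analytic)), 1e-3 * diff(range(sig$values)))
  fine <- acquisition_grid(n_points = 4L * (g$n_points - 1L) + 1L)
  back <- resample_signature(resample_signature(sig, fine), g)
  expect_lt(max(abs(back$values - sig$values)), 1e-6)
})

test_that("differentiation is linear in amplitude and shift-equivariant", {
  g <- small_grid()
  seg <- segment_model(list(melt_component(68, 0.8, 0.9)), channel = "BS2",
                       include_marker = FALSE)
  cv <- simulate_curve(seg, g, zero_noise(), seed = 1)
  sig <- derivative_signature(cv)
  scaled <- cv; scaled$fluorescence <- 3 * cv$fluorescence
  expect_equal(derivative_signature(scaled)$values, 3 * sig$values,
               tolerance = 1e-9)
  shifted <- simulate_curve(seg, g, zero_noise(), seed = 1,
                            temperature_offset = 1.0)
  sig_sh <- derivative_signature(shifted)
  t_ref <- g$temperature[which.min(sig$values)]
  t_sh <- g$temperature[which.min(sig_sh$values)]
  expect_lte(abs((t_sh - t_ref) - 1.0), g$step + 1e-9)
})

test_that("corpus signature computation corrects runs and flags missing markers", {
  panel <- mini_panel()
  corpus <- generate_corpus(panel, mini_design(panel[1:2, ], n_specimens = 1L,
                                               n_test = 0L),
                            small_grid(), noise_model())
  sigs <- compute_signatures(corpus$training, small_grid())
  expect_true(all(sigs$marker_found))
  expect_true(all(vapply(sigs$sig_bs1, `[[`, logical(1), "corrected")))
  expect_equal(length(sigs$sig_bs1[[1]]$values), 1024L)
})
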