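test_that("segment merging concatenates and zero-fills", {
  g <- small_grid(256)
  s1 <- meltbarcode:::new_signature(g$temperature, rep(1, 256), "BS1")
  s2 <- meltbarcode:::new_signature(g$temperature, rep(2, 256), "BS2")
  v <- merge_segments(s1, s2)
  expect_length(v, 512)
  expect_equal(unname(v[1:256]), rep(1, 256))
  expect_true(startsWith(names(v)[1], "BS1@"))
  expect_true(startsWith(names(v)[257], "BS2@"))
  v2 <- merge_segments(s1, NULL)
  expect_equal(unname(v2[257:512]), rep(0, 256))
  other <- meltbarcode:::new_signature(small_grid(128)$temperature,
                                       rep(1, 128), "BS2")
  expect_error(merge_segments(s1, other), "different grids")
})

test_that("the default grid yields the 8,152-wide feature space", {
  g <- acquisition_grid()
  panel <- default_panel_cached()
  run <- simulate_run(panel[1, ], g, zero_noise(), seed = 1, failure = "none")
  sigs <- compute_signatures(run, g)
  v <- merge_segments(sigs$sig_bs1[[1]], sigs$sig_bs2[[1]])
  expect_length(v, 8152)
})

test_that("feature matrices are deterministic, labelled, and validated", {
  panel <- mini_panel()[1:3, ]
  corpus <- generate_corpus(panel, mini_design(panel, n_specimens = 1L,
                                               n_test = 0L),
                            small_grid(256), noise_model())
  sigs <- compute_signatures(corpus$training, small_grid(256))
  feats <- build_feature_matrix(sigs, small_grid(256))
  expect_equal(dim(feats), c(9L, 512L))
  expect_equal(rownames(feats$x), sort(sigs$run_id))
  expect_identical(feats$meta$run_id, rownames(feats$x))
  single <- build_feature_matrix(sigs[1, ], small_grid(256))
  expect_equal(dim(single), c(1L, 512L))
  expect_error(build_feature_matrix(sigs[c(1, 1), ], small_grid(256)),
               "duplicate")
  tt <- as_tibble(feats)
  expect_equal(nrow(tt), 9)
  expect_equal(ncol(tt), 512 + ncol(feats$meta))
})

test_that("zero-noise feature values equal the analytic derivative", {
  g <- small_grid()
  panel <- default_panel_cached()
  model <- panel[match("Galeocerdo cuvier", panel$species_name), ]
  run <- simulate_run(model, g, zero_noise(), seed = 1, failure = "none")
  sigs <- compute_signatures(run, g)
  feats <- build_feature_matrix(sigs, g)
  k <- which.min(abs(g$temperature - 75)) # interior grid point
  analytic <- meltbarcode:::curve_derivative(model$bs1[[1]]$components,
                                             g$temperature[k])
  expect_lt(abs(unname(feats$x[1, k]) - analytic), 1e-3)
})

test_that("identical-pair species have matching expected feature vectors", {
  panel <- default_panel_cached()
  g <- small_grid(256)
  mean_vec <- function(sp) {
    model <- panel[match(sp, panel$species_name), ]
    runs <- purrr::map(1:8, function(s)
      simulate_run(model, g, noise_model(), seed = s, run_id = paste0("r", s),
                   failure = "none"))
    sigs <- compute_signatures(purrr::list_rbind(runs), g)
    colMeans(do.call(rbind, purrr::map2(sigs$sig_bs1, sigs$sig_bs2,
                                        merge_segments)))
  }
  a <- mean_vec("Mobula birostris")
  b <- mean_vec("Mobula mobular")
  # same seeds, identical generative models: identical in expectation and draw
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("variable importance is scaled, normalized and informative", {
  panel <- mini_panel()[c(1, 2), ]
  corpus <- generate_corpus(panel, mini_design(panel, n_specimens = 6L,
                                               n_test = 0L),
                            small_grid(256), noise_model())
  sigs <- compute_signatures(corpus$training, small_grid(256))
  feats <- build_feature_matrix(sigs, small_grid(256))
  split <- split_corpus(feats, 0.7, seed = 2)
  model <- train_fann(split$train, split$validation,
                      net_config(hidden = 8L, epochs = 15L, seed = 3))
  imp <- variable_importance(model)
  expect_equal(imp$scaled_importance[1], 1)
  expect_equal(sum(imp$percentage), 100, tolerance = 1e-6)
  expect_equal(nrow(imp), 512)
  expect_error(variable_importance(structure(list(), class = "fann_model")),
               "trained")
})

test_that("importance concentrates where two species actually differ", {
  # two species sharing BS1 entirely; BS2 differs by one transition
  seg <- function(tms, channel) {
    segment_model(purrr::map(tms, ~melt_component(.x, 0.8, 1)),
                  channel = channel)
  }
  mk <- function(name, bs2_tm) {
    tibble::tibble(species_name = name, group = "shark", cites_listed = TRUE,
                   bs1_failure_prob = 0, bs2_failure_prob = 0,
                   bs1 = list(seg(c(55, 70), "BS1")),
                   bs2 = list(seg(bs2_tm, "BS2")))
  }
  panel <- dplyr::bind_rows(mk("sp one", 62), mk("sp two", 72))
  corpus <- generate_corpus(panel, mini_design(panel, n_specimens = 6L,
                                               n_test = 0L),
                            small_grid(256), noise_model())
  sigs <- compute_signatures(corpus$training, small_grid(256))
  feats <- build_feature_matrix(sigs, small_grid(256))
  split <- split_corpus(feats, 0.7, seed = 2)
  # the l1 sparsity penalty prunes weights on uninformative inputs, so the
  # first-layer aggregation localizes to the discriminating transition band
  model <- train_fann(split$train, split$validation,
                      net_config(hidden = 4L, epochs = 100L, seed = 3,
                                 l1 = 0.03, learning_rate = 0.01,
                                 batch_size = 8L))
  top <- variable_importance(model, top_n = 10)
  in_band <- vapply(strsplit(top$feature, "@"), function(p) {
    p[1] == "BS2" && abs(as.numeric(p[2]) - 67) <= 9
  }, logical(1))
  expect_gte(sum(in_band), 6)
})
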