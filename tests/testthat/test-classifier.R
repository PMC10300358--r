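# small, well-separated two-species features, cached
two_species_feats <- function() {
  cached("two_species_feats", {
    panel <- mini_panel()[1:2, ]
    corpus <- generate_corpus(panel, mini_design(panel, n_specimens = 14L,
                                                 n_test = 0L, replicates = 3L),
                              small_grid(256), noise_model())
    sigs <- compute_signatures(corpus$training, small_grid(256))
    build_feature_matrix(sigs, small_grid(256))
  })
}

test_that("stratified splitting keeps proportions and is reproducible", {
  feats <- two_species_feats()
  sp <- split_corpus(feats, 0.7, seed = 4)
  expect_equal(nrow(sp$train$x) + nrow(sp$validation$x), nrow(feats$x))
  expect_length(intersect(sp$train$meta$run_id, sp$validation$meta$run_id), 0)
  per_class <- table(sp$train$meta$species) / table(feats$meta$species)
  expect_true(all(abs(per_class - 0.7) < 0.05))
  sp2 <- split_corpus(feats, 0.7, seed = 4)
  expect_identical(sp$train$meta$run_id, sp2$train$meta$run_id)
  # one class of 10 rows splits 7/3
  ten <- meltbarcode:::features_subset(
    feats, which(feats$meta$species == feats$meta$species[1])[1:10])
  sp10 <- split_corpus(ten, 0.7, seed = 1)
  expect_equal(nrow(sp10$train$x), 7)
  expect_equal(nrow(sp10$validation$x), 3)
})

test_that("grouped splitting never separates a specimen's replicates", {
  feats <- two_species_feats()
  sp <- split_corpus(feats, 0.7, seed = 4, group_by_specimen = TRUE)
  expect_length(intersect(sp$train$meta$specimen_id,
                          sp$validation$meta$specimen_id), 0)
})

test_that("singleton strata go to train with a warning", {
  feats <- two_species_feats()
  idx <- c(which(feats$meta$species == feats$meta$species[1])[1],
           which(feats$meta$species != feats$meta$species[1])[1:6])
  sub <- meltbarcode:::features_subset(feats, idx)
  expect_warning(sp <- split_corpus(sub, 0.7, seed = 1), "single")
  expect_true(feats$meta$run_id[idx[1]] %in% sp$train$meta$run_id)
})

test_that("well-separated species are classified perfectly", {
  feats <- two_species_feats()
  sp <- split_corpus(feats, 0.7, seed = 4)
  model <- train_fann(sp$train, sp$validation,
                      net_config(hidden = 8L, epochs = 15L, seed = 1))
  expect_equal(model$validation_accuracy, 100)
  expect_equal(nrow(model$history), 15)
  # margin check: winning scores are confident, not borderline
  pred <- predict(model, sp$validation)
  expect_true(all(pred$margin > 0.5))
  # a training row of a perfectly fitted model predicts its own label
  expect_equal(predict(model, sp$train)$predicted, sp$train$meta$species)
})

test_that("an overwhelming l2 penalty collapses scores towards uniform", {
  feats <- two_species_feats()
  sp <- split_corpus(feats, 0.7, seed = 4)
  model <- train_fann(sp$train, sp$validation,
                      net_config(hidden = 8L, epochs = 15L, seed = 1,
                                 l2 = 10))
  pred <- predict(model, sp$validation)
  expect_true(all(pred$score < 0.6))
})

test_that("degenerate inputs are rejected", {
  feats <- two_species_feats()
  one_class <- meltbarcode:::features_subset(
    feats, which(feats$meta$species == feats$meta$species[1]))
  expect_error(train_fann(one_class, config = net_config()), "2 classes")
  expect_error(net_config(hidden = integer()), "hidden")
  expect_error(net_config(l1 = -1), "penalties")
})

test_that("prediction is deterministic and duplicates agree", {
  feats <- two_species_feats()
  sp <- split_corpus(feats, 0.7, seed = 4)
  cfg <- net_config(hidden = 8L, epochs = 10L, seed = 9)
  m1 <- train_fann(sp$train, sp$validation, cfg)
  m2 <- train_fann(sp$train, sp$validation, cfg)
  expect_identical(m1$weights, m2$weights)
  dup <- sp$validation$x[c(1, 1, 2), ]
  rownames(dup) <- c("a", "b", "c")
  pred <- predict(m1, dup)
  expect_identical(pred$predicted[1], pred$predicted[2])
  expect_equal(pred$score[1], pred$score[2])
  expect_equal(rowSums(as.matrix(pred[, m1$classes])), rep(1, 3),
               tolerance = 1e-9)
})

test_that("identical-signature twins split the score mass", {
  panel <- mini_panel()[4:5, ]  # delta and its twin share all components
  corpus <- generate_corpus(panel, mini_design(panel, n_specimens = 10L,
                                               n_test = 2L),
                            small_grid(256), noise_model())
  sigs <- compute_signatures(corpus$training, small_grid(256))
  feats <- build_feature_matrix(sigs, small_grid(256))
  sp <- split_corpus(feats, 0.7, seed = 4)
  model <- train_fann(sp$train, sp$validation,
                      net_config(hidden = 8L, epochs = 15L, seed = 1))
  test_sigs <- compute_signatures(corpus$test, small_grid(256))
  pred <- predict(model, build_feature_matrix(test_sigs, small_grid(256)))
  expect_true(all(pred$score < 0.95))
})

test_that("a single-hidden-layer reference fit agrees on separable data", {
  skip_if_not_installed("nnet")
  feats <- two_species_feats()
  sp <- split_corpus(feats, 0.7, seed = 4)
  # independent check: nnet's single-layer network on the same features
  y <- nnet::class.ind(factor(sp$train$meta$species))
  set.seed(1)
  ref <- nnet::nnet(sp$train$x, y, size = 4, softmax = TRUE, trace = FALSE,
                    MaxNWts = 10000)
  scores <- predict(ref, sp$validation$x)
  ref_pred <- colnames(scores)[max.col(scores)]
  expect_equal(mean(ref_pred == sp$validation$meta$species), 1)
})
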