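#' Simulate one raw melt curve
#'
#' Fluorescence along the ramp is a decreasing-logistic mixture over the
#' segment's melting transitions plus a linear baseline:
#' \deqn{F(T) = b_0 + b_1 (T - T_{min}) + \sum_k a_k \,
#'   \mathrm{logistic}\!\left(\frac{tm_k - T}{w_k}\right)}
#' Noise enters as (i) one global log-normal amplitude scale, (ii) a single
#' rigid temperature offset applied to the whole curve, and (iii) i.i.d.
#' additive fluorescence noise; a small per-component amplitude jitter models
#' within-species variation. Identical seeds give identical output.
#'
#' @param segment A [segment_model()].
#' @param grid An [acquisition_grid()].
#' @param noise A [noise_model()]; use [zero_noise()] for the exact
#'   closed-form mixture.
#' @param seed Integer seed for the curve's noise draws.
#' @param temperature_offset Optional pre-drawn temperature offset (degC);
#'   when supplied (as for the two channels of one run, which share the
#'   instrument's drift) no offset is drawn from `noise`.
#' @return A list of class `melt_curve` with `temperature`, `fluorescence`
#'   and `channel`.
#' @examples
#' seg <- segment_model(list(melt_component(75, 0.5, 1)), channel = "BS2",
#'                      include_marker = FALSE)
#' cv <- simulate_curve(seg, acquisition_grid(n_points = 256), zero_noise(), seed = 1)
#' range(cv$fluorescence)
#' @export
simulate_curve <- function(segment, grid, noise = noise_model(), seed = 1,
                           temperature_offset = NULL) {
  stopifnot(inherits(segment, "segment_model"), inherits(grid, "acq_grid"),
            inherits(noise, "noise_model"))
  for (cp in segment$components) {
    if (!all(is.finite(c(cp$tm, cp$width, cp$amplitude))))
      stop("non-finite melt component parameters")
  }
  set.seed(as.integer(seed))
  scale <- if (noise$amplitude_scale_sigma > 0)
    exp(stats::rnorm(1, 0, noise$amplitude_scale_sigma)) else 1
  if (is.null(temperature_offset)) {
    temperature_offset <- if (noise$temperature_offset_sigma > 0)
      stats::rnorm(1, 0, noise$temperature_offset_sigma) else 0
  }
  comps <- segment$components
  if (noise$per_component_jitter > 0 && length(comps)) {
    jit <- exp(stats::rnorm(length(comps), 0, noise$per_component_jitter))
    comps <- purrr::map2(comps, jit, function(cp, j) {
      cp$amplitude <- cp$amplitude * j
      cp
    })
  }
  # offset shifts the apparent transition positions: evaluate at T - offset
  f <- curve_values(comps, grid$temperature - temperature_offset,
                    baseline_slope = segment$baseline_slope)
  f <- (f - 0.1) * scale + 0.1   # amplitude scale acts on signal, not baseline
  if (noise$additive_noise_sigma > 0)
    f <- f + stats::rnorm(grid$n_points, 0, noise$additive_noise_sigma)
  f <- pmax(f, 0)
  structure(list(temperature = grid$temperature, fluorescence = f,
                 channel = segment$channel),
            class = "melt_curve")
}

#' Simulate one qPCR run (a BS1/BS2 curve pair)
#'
#' Draws per-segment hybridization failure from the species model's failure
#' propensities unless a mode is pinned via `failure`. A failed BS1 retains
#' only the internal temperature marker; a failed BS2 is baseline plus
#' noise. Both channels share one instrument temperature offset. When
#' `contaminant` is given (replicate-inconsistency injection) the curves are
#' simulated from that species' model while the truth label stays the run's
#' species.
#'
#' @param model One row of a panel tibble (see [build_default_panel()]).
#' @param grid An [acquisition_grid()].
#' @param noise A [noise_model()]; degraded samples use its processed sigma.
#' @param seed Integer seed.
#' @param run_id,specimen_id,replicate,condition Run metadata.
#' @param failure `NULL` to draw from the model's propensities, else one of
#'   `"none"`, `"hybridization_bs1"`, `"hybridization_bs2"`,
#'   `"inconsistent"`.
#' @param contaminant Optional one-row panel tibble used as the generative
#'   model for an `"inconsistent"` run.
#' @return A one-row tibble (`run_id`, `specimen_id`, `species`, `replicate`,
#'   `condition`, `injected_failure`, list-columns `bs1`, `bs2`).
#' @export
simulate_run <- function(model, grid, noise = noise_model(), seed = 1,
                         run_id = "R1", specimen_id = "S1", replicate = 1L,
                         condition = c("fresh", "processed"), failure = NULL,
                         contaminant = NULL) {
  condition <- match.arg(condition)
  noise <- condition_noise(noise, condition)
  seeds <- derive_seeds(seed, 4)
  if (is.null(failure)) {
    set.seed(seeds[1])
    f1 <- stats::runif(1) < model$bs1_failure_prob
    f2 <- stats::runif(1) < model$bs2_failure_prob
    failure <- if (f1) "hybridization_bs1" else if (f2) "hybridization_bs2" else "none"
  }
  failure <- match.arg(failure, c("none", "hybridization_bs1",
                                  "hybridization_bs2", "inconsistent"))
  src <- if (failure == "inconsistent" && !is.null(contaminant)) contaminant else model
  seg1 <- src$bs1[[1]]
  seg2 <- src$bs2[[1]]
  if (failure == "hybridization_bs1")
    seg1 <- segment_model(list(), channel = "BS1", include_marker = TRUE)
  if (failure == "hybridization_bs2")
    seg2 <- segment_model(list(), channel = "BS2", include_marker = FALSE)
  set.seed(seeds[2])
  offset <- if (noise$temperature_offset_sigma > 0)
    stats::rnorm(1, 0, noise$temperature_offset_sigma) else 0
  bs1 <- simulate_curve(seg1, grid, noise, seed = seeds[3],
                        temperature_offset = offset)
  bs2 <- simulate_curve(seg2, grid, noise, seed = seeds[4],
                        temperature_offset = offset)
  tibble::tibble(
    run_id = run_id, specimen_id = specimen_id,
    species = model$species_name, replicate = as.integer(replicate),
    condition = condition, injected_failure = failure,
    bs1 = list(bs1), bs2 = list(bs2)
  )
}

#' Read the packaged specimen allocation
#'
#' Per-species counts of training specimens (3 replicate runs each) and of
#' independent single-run test specimens. The default allocation reproduces
#' the study design: 130 training specimens (390 runs) and 68 test
#' specimens over 28 species, with unequal, opportunistic per-species
#' counts (minimum 3 training specimens).
#'
#' @param path Optional path to an allocation CSV
#'   (`species_name,n_specimens,n_test`).
#' @return A tibble.
#' @export
default_allocation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "specimen_allocation.csv",
                        package = "meltbarcode")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read the packaged failure-injection manifest
#'
#' The fixed list of 33 runs (of the default 390-run training corpus) that
#' carry an injected failure: poor BS1 or BS2 probe-barcode hybridization,
#' or a replicate-inconsistent signature simulated from a pinned
#' contaminant species.
#'
#' @param path Optional path to a manifest CSV
#'   (`run_id,failure,contaminant_species`).
#' @return A tibble.
#' @export
default_failure_manifest <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "failure_manifest.csv",
                        package = "meltbarcode")
  man <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           na.strings = character()))
  man
}

#' Corpus design: specimens, replicates, test set and injected failures
#'
#' @param allocation Tibble of per-species specimen counts; see
#'   [default_allocation()].
#' @param replicates Training replicates per specimen (default 3).
#' @param failure_manifest Tibble of pinned failures; see
#'   [default_failure_manifest()]. May have zero rows.
#' @param seed Integer seed controlling condition assignment and noise.
#' @return A list of class `corpus_design`.
#' @export
corpus_design <- function(allocation = default_allocation(), replicates = 3L,
                          failure_manifest = default_failure_manifest(),
                          seed = 1L) {
  stopifnot(all(c("species_name", "n_specimens", "n_test") %in% names(allocation)))
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("`replicates` must be >= 1")
  design <- structure(
    list(allocation = allocation, replicates = replicates,
         failure_manifest = failure_manifest, seed = as.integer(seed)),
    class = "corpus_design")
  ids <- design_run_ids(design)
  bad <- setdiff(failure_manifest$run_id, ids)
  if (length(bad))
    stop("failure manifest references runs absent from the design: ",
         paste(bad, collapse = ", "))
  design
}

# all training run ids implied by a design
design_run_ids <- function(design) {
  n_spec <- sum(design$allocation$n_specimens)
  as.vector(t(outer(sprintf("S%03d", seq_len(n_spec)),
                    paste0("_r", seq_len(design$replicates)), paste0)))
}

#' Generate the full training and test corpus
#'
#' Simulates the study corpus: for each species, `n_specimens` training
#' specimens with `replicates` runs each, plus `n_test` single-run
#' independent test specimens. About half of all specimens are flagged
#' `processed` and simulated with the degraded amplitude noise. Failures are
#' injected exactly where the design's manifest pins them; all other runs
#' are failure-free, so the corpus (and everything downstream) is a pure
#' function of the panel, the design and the seed.
#'
#' @param panel A panel tibble from [build_default_panel()].
#' @param design A [corpus_design()].
#' @param grid An [acquisition_grid()].
#' @param noise A [noise_model()].
#' @return A list of class `melt_corpus`: `training` and `test` run tibbles,
#'   the truth manifest (`truth`), and the `grid`.
#' @export
generate_corpus <- function(panel, design = corpus_design(),
                            grid = acquisition_grid(),
                            noise = noise_model()) {
  alloc <- design$allocation
  bad <- setdiff(alloc$species_name, panel$species_name)
  if (length(bad))
    stop("allocation species not in panel: ", paste(bad, collapse = ", "))
  man <- design$failure_manifest

  spec_tbl <- tidyr::uncount(
    dplyr::select(alloc, species_name, n_specimens),
    .data$n_specimens)
  spec_tbl$specimen_id <- sprintf("S%03d", seq_len(nrow(spec_tbl)))
  test_tbl <- tidyr::uncount(dplyr::select(alloc, species_name, n_test),
                             .data$n_test)
  test_tbl$specimen_id <- sprintf("T%03d", seq_len(nrow(test_tbl)))

  set.seed(design$seed)
  n_all <- nrow(spec_tbl) + nrow(test_tbl)
  processed <- logical(n_all)
  processed[sample.int(n_all, floor(n_all / 2))] <- TRUE
  spec_tbl$condition <- ifelse(processed[seq_len(nrow(spec_tbl))],
                               "processed", "fresh")
  test_tbl$condition <- ifelse(processed[nrow(spec_tbl) + seq_len(nrow(test_tbl))],
                               "processed", "fresh")

  run_tbl <- tidyr::crossing(spec_tbl, replicate = seq_len(design$replicates))
  run_tbl$run_id <- paste0(run_tbl$specimen_id, "_r", run_tbl$replicate)
  run_tbl <- dplyr::arrange(run_tbl, .data$run_id)
  idx <- match(run_tbl$run_id, man$run_id)
  run_tbl$failure <- ifelse(is.na(idx), "none", man$failure[idx])
  run_tbl$contaminant <- ifelse(is.na(idx), "", man$contaminant_species[idx])

  run_seeds <- derive_seeds(design$seed + 1L, nrow(run_tbl) + nrow(test_tbl))
  sim_one <- function(i, row, seed) {
    model <- panel[match(row$species_name, panel$species_name), ]
    contaminant <- NULL
    if (nzchar(row$contaminant %||% "")) {
      contaminant <- panel[match(row$contaminant, panel$species_name), ]
      if (nrow(contaminant) == 0 || anyNA(contaminant$species_name))
        stop("manifest contaminant species not in panel: ", row$contaminant)
    }
    simulate_run(model, grid, noise, seed = seed, run_id = row$run_id,
                 specimen_id = row$specimen_id, replicate = row$replicate,
                 condition = row$condition, failure = row$failure,
                 contaminant = contaminant)
  }
  training <- purrr::list_rbind(lapply(seq_len(nrow(run_tbl)), function(i) {
    sim_one(i, run_tbl[i, ], run_seeds[i])
  }))
  test_tbl$run_id <- paste0(test_tbl$specimen_id, "_r1")
  test_tbl$replicate <- 1L
  test_tbl$failure <- "none"
  test_tbl$contaminant <- ""
  test <- purrr::list_rbind(lapply(seq_len(nrow(test_tbl)), function(i) {
    sim_one(i, test_tbl[i, ], run_seeds[nrow(run_tbl) + i])
  }))
  truth <- dplyr::select(run_tbl, run_id, specimen_id, species = species_name,
                         replicate, condition, injected_failure = failure)
  structure(list(training = training, test = test, truth = truth, grid = grid),
            class = "melt_corpus")
}

#' @export
print.melt_corpus <- function(x, ...) {
  cat(sprintf("<melt_corpus> %d training runs (%d specimens), %d test runs; grid %d points\n",
              nrow(x$training), length(unique(x$training$specimen_id)),
              nrow(x$test), x$grid$n_points))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
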