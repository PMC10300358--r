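# shared fixtures, built in code and cached for the session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_grid <- function(n = 1024L) acquisition_grid(n_points = n)

# a hand-built panel of well-separated species plus one identical pair
mini_panel <- function() {
  seg <- function(tms, channel, widths = rep(0.8, length(tms)),
                  amps = rep(1, length(tms))) {
    segment_model(purrr::pmap(list(tms, widths, amps), melt_component),
                  channel = channel)
  }
  make <- function(name, group, bs1_tms, bs2_tms) {
    tibble::tibble(species_name = name, group = group, cites_listed = TRUE,
                   amplifies_bs1 = TRUE, amplifies_bs2 = TRUE,
                   bs1_failure_prob = 0, bs2_failure_prob = 0,
                   bs1 = list(seg(bs1_tms, "BS1")),
                   bs2 = list(seg(bs2_tms, "BS2")))
  }
  panel <- dplyr::bind_rows(
    make("Species alpha", "shark", c(55, 70), c(50, 62)),
    make("Species beta", "shark", c(48, 63), c(57, 73)),
    make("Species gamma", "ray", c(52, 76), c(45, 66)),
    make("Species delta", "ray", c(60, 74), c(53, 70)))
  twin <- panel[4, ]
  twin$species_name <- "Species delta-twin"
  dplyr::bind_rows(panel, twin)
}

mini_design <- function(panel, n_specimens = 2L, n_test = 1L, replicates = 3L,
                        manifest = NULL, seed = 7L) {
  alloc <- tibble::tibble(species_name = panel$species_name,
                          n_specimens = as.integer(n_specimens),
                          n_test = as.integer(n_test))
  if (is.null(manifest))
    manifest <- tibble::tibble(run_id = character(), failure = character(),
                               contaminant_species = character())
  corpus_design(alloc, replicates = replicates, failure_manifest = manifest,
                seed = seed)
}

default_panel_cached <- function() cached("default_panel", build_default_panel(1))

# full-scale default corpus shared by the acceptance checks
default_corpus_cached <- function() {
  cached("default_corpus", {
    generate_corpus(default_panel_cached(), corpus_design(seed = 42),
                    acquisition_grid(), noise_model())
  })
}

default_qc_cached <- function() {
  cached("default_qc", {
    corpus <- default_corpus_cached()
    sigs <- compute_signatures(corpus$training, acquisition_grid())
    filter_corpus(sigs)
  })
}

# which truth/prediction mismatches fall inside a configured look-alike pair
errors_within_pairs <- function(truth, predicted) {
  pairs <- lookalike_pairs()
  wrong <- truth != predicted
  in_pair <- mapply(function(tr, pr) {
    any((pairs$species_a == tr & pairs$species_b == pr) |
          (pairs$species_b == tr & pairs$species_a == pr))
  }, truth[wrong], predicted[wrong])
  list(n_errors = sum(wrong), n_in_pairs = sum(in_pair))
}
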