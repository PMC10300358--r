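#' Read the packaged species-status table
#'
#' The 28-species panel sheet: scientific and common name, shark/ray group,
#' CITES listing, per-segment amplification condition, and the visual /
#' deep-learning distinguishability and misassignment-risk flags.
#'
#' @param path Path to a species-status CSV; defaults to the copy shipped
#'   with the package.
#' @return A tibble with 28 rows and logical flag columns.
#' @export
read_species_status_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_status.csv", package = "meltbarcode")
  }
  if (!file.exists(path) || file.size(path) == 0)
    stop("species status table missing or empty: ", path)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_name", "english_name", "group", "cites_listed",
            "amplifies_bs1", "amplifies_bs2", "visual_distinguishable",
            "dl_distinguishable", "dl_misassignment_risk")
  missing <- setdiff(need, names(tbl))
  if (length(missing))
    stop("species status table missing columns: ", paste(missing, collapse = ", "))
  if (nrow(tbl) != 28)
    stop("species status table must have exactly 28 rows, got ", nrow(tbl))
  if (anyDuplicated(tbl$species_name))
    stop("duplicated species names in status table")
  flags <- c("cites_listed", "amplifies_bs1", "amplifies_bs2",
             "visual_distinguishable", "dl_distinguishable",
             "dl_misassignment_risk")
  for (f in flags) tbl[[f]] <- parse_yes_no(tbl[[f]], f)
  tibble::as_tibble(tbl)
}

parse_yes_no <- function(x, what) {
  out <- dplyr::case_match(tolower(trimws(as.character(x))),
                           c("yes", "true", "1") ~ TRUE,
                           c("no", "false", "0") ~ FALSE,
                           .default = NA)
  if (anyNA(out)) stop("column `", what, "` has values other than Yes/No")
  out
}

#' Panel species names in reporting order
#'
#' @return Character vector of the 28 scientific names, in the order used by
#'   the species-status sheet and every confusion matrix.
#' @export
panel_species <- function() read_species_status_table()$species_name

# closed-form noiseless melt curve for a component list
curve_values <- function(components, temperature, baseline_slope = 0,
                         baseline = 0.1) {
  f <- rep(baseline, length(temperature)) +
    baseline_slope * (temperature - temperature[1])
  for (cp in components) {
    f <- f + cp$amplitude * stats::plogis((cp$tm - temperature) / cp$width)
  }
  f
}

# closed-form derivative dF/dT of the noiseless curve
curve_derivative <- function(components, temperature, baseline_slope = 0) {
  d <- rep(baseline_slope, length(temperature))
  for (cp in components) {
    z <- stats::plogis((cp$tm - temperature) / cp$width)
    d <- d - cp$amplitude * z * (1 - z) / cp$width
  }
  d
}

# correlation distance between two vectors (1 - Pearson r); 0 if degenerate
cor_distance <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
  1 - stats::cor(a, b)
}

# draw one random segment model: 2-3 well-separated transitions
random_segment <- function(channel) {
  n <- sample(2:3, 1)
  repeat {
    tms <- sort(stats::runif(n, 46, 79))
    if (n == 1 || min(diff(tms)) >= 3.5) break
  }
  widths <- stats::runif(n, 0.7, 1.2)
  amps <- stats::runif(n, 0.5, 1.3)
  comps <- purrr::pmap(list(tms, widths, amps), melt_component)
  segment_model(comps, channel = channel)
}

#' Build the default 28-species generative panel
#'
#' Constructs one generative melt-signature model per panel species: a
#' sigmoid-mixture segment model for each barcode channel (BS1 always
#' carrying the internal temperature marker), per-segment hybridization
#' failure propensities elevated for species whose status sheet marks the
#' segment as non-amplifying, and three configured look-alike pairs:
#'
#' * tiger shark and giant shovelnose ray: identical components in both
#'   segments;
#' * giant oceanic manta and giant devil ray: identical in both segments;
#' * silky and blue shark: identical BS1, BS2 shifted by 0.15 degC.
#'
#' All remaining species receive pairwise-distinct transition sets
#' (rejection-sampled so that no two species are close in both segments).
#'
#' @param seed Integer seed; the panel is a pure function of it.
#' @return A tibble with one row per species: metadata columns from the
#'   status sheet, `bs1_failure_prob`, `bs2_failure_prob`, and list-columns
#'   `bs1`, `bs2` of [segment_model()]s.
#' @export
build_default_panel <- function(seed = 1) {
  status <- read_species_status_table()
  set.seed(as.integer(seed))
  tgrid <- seq(40, 87, length.out = 512)
  bs1 <- vector("list", nrow(status))
  bs2 <- vector("list", nrow(status))
  sig1 <- list(); sig2 <- list()
  for (i in seq_len(nrow(status))) {
    for (try in 1:200) {
      s1 <- random_segment("BS1")
      s2 <- random_segment("BS2")
      d1 <- curve_derivative(s1$components, tgrid)
      d2 <- curve_derivative(s2$components, tgrid)
      clash <- FALSE
      for (j in seq_len(i - 1)) {
        if (cor_distance(d1, sig1[[j]]) < 0.15 &&
            cor_distance(d2, sig2[[j]]) < 0.15) { clash <- TRUE; break }
      }
      if (!clash) break
    }
    if (clash) stop("could not draw a distinct signature for species ", i)
    bs1[[i]] <- s1; bs2[[i]] <- s2
    sig1[[i]] <- d1; sig2[[i]] <- d2
  }
  panel <- status
  panel$bs1_failure_prob <- ifelse(panel$amplifies_bs1, 0.02, 0.3)
  panel$bs2_failure_prob <- ifelse(panel$amplifies_bs2, 0.02, 0.3)
  panel$bs1 <- bs1
  panel$bs2 <- bs2

  copy_pair <- function(panel, from, to, shift_bs2 = 0) {
    i <- match(from, panel$species_name)
    j <- match(to, panel$species_name)
    panel$bs1[[j]] <- panel$bs1[[i]]
    s2 <- panel$bs2[[i]]
    if (shift_bs2 != 0) {
      s2$components <- lapply(s2$components, function(cp) {
        cp$tm <- cp$tm + shift_bs2
        cp
      })
    }
    panel$bs2[[j]] <- s2
    panel
  }
  panel <- copy_pair(panel, "Galeocerdo cuvier", "Glaucostegus typus")
  panel <- copy_pair(panel, "Mobula birostris", "Mobula mobular")
  panel <- copy_pair(panel, "Carcharhinus falciformis", "Prionace glauca",
                     shift_bs2 = 0.15)
  panel
}

#' The configured look-alike species pairs
#'
#' @return A tibble of the three species pairs built with (near-)identical
#'   signatures in both barcode segments.
#' @export
lookalike_pairs <- function() {
  tibble::tibble(
    species_a = c("Galeocerdo cuvier", "Mobula birostris",
                  "Carcharhinus falciformis"),
    species_b = c("Glaucostegus typus", "Mobula mobular", "Prionace glauca"),
    identical_bs1 = c(TRUE, TRUE, TRUE),
    identical_bs2 = c(TRUE, TRUE, FALSE)
  )
}
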