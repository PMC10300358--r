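#' Flag probe-barcode hybridization failures
#'
#' A BS1 channel fails hybridization when, after masking a band around the
#' internal temperature marker's trough, the residual signature energy (sum
#' of squared derivative values) falls below `theta_h` times the marker
#' trough's energy — i.e. only the marker melted. A BS2 channel fails when
#' its total signature energy falls below `theta_h` times the corpus-median
#' BS2 energy. A BS1 signature with no detectable marker also fails.
#'
#' @param sigs Signature tibble from [compute_signatures()].
#' @param theta_h Relative-energy threshold (default 0.1).
#' @param marker_band Half-width (degC) of the masked marker band.
#' @param reference_tm Nominal marker temperature on corrected signatures.
#' @return A tibble `run_id`, `fail_bs1`, `fail_bs2`.
#' @export
flag_hybridization_failure <- function(sigs, theta_h = 0.1, marker_band = 1.5,
                                       reference_tm = TM_MARKER_TM) {
  bs1_fail <- purrr::map2_lgl(sigs$sig_bs1, sigs$marker_found, function(s, found) {
    if (!found) return(TRUE)
    centre <- if (s$corrected) reference_tm else s$tm_detected
    in_band <- abs(s$temperature - centre) <= marker_band
    marker_energy <- sum(s$values[in_band]^2)
    residual <- sum(s$values[!in_band]^2)
    residual < theta_h * marker_energy
  })
  bs2_energy <- purrr::map_dbl(sigs$sig_bs2, function(s) sum(s$values^2))
  bs2_fail <- bs2_energy < theta_h * stats::median(bs2_energy)
  tibble::tibble(run_id = sigs$run_id, fail_bs1 = bs1_fail, fail_bs2 = bs2_fail)
}

# concatenated BS1+BS2 signature vector of one run
concat_signature <- function(s1, s2) c(s1$values, s2$values)

#' Flag replicate-inconsistent runs within each specimen
#'
#' A run is inconsistent when its mean correlation distance (1 - Pearson r
#' of the concatenated BS1+BS2 signature) to the specimen's other
#' replicates exceeds `theta_c`. Outliers are removed worst-first and the
#' distances recomputed, so a single aberrant replicate does not drag its
#' consistent siblings over the threshold. Singleton specimens are never
#' flagged.
#'
#' @param sigs Signature tibble from [compute_signatures()] (training runs).
#' @param theta_c Correlation-distance threshold (default 0.2).
#' @return A tibble `run_id`, `fail_inconsistent`.
#' @export
flag_replicate_inconsistency <- function(sigs, theta_c = 0.2) {
  flags <- stats::setNames(logical(nrow(sigs)), sigs$run_id)
  for (sp in unique(sigs$specimen_id)) {
    rows <- which(sigs$specimen_id == sp)
    if (length(rows) < 2) next
    vecs <- lapply(rows, function(i)
      concat_signature(sigs$sig_bs1[[i]], sigs$sig_bs2[[i]]))
    names(vecs) <- sigs$run_id[rows]
    active <- seq_along(vecs)
    while (length(active) >= 2) {
      dmat <- outer(active, active, Vectorize(function(i, j)
        if (i == j) NA_real_ else cor_distance(vecs[[i]], vecs[[j]])))
      mean_d <- rowMeans(dmat, na.rm = TRUE)
      worst <- which.max(mean_d)
      if (mean_d[worst] > theta_c) {
        flags[names(vecs)[active[worst]]] <- TRUE
        active <- active[-worst]
      } else break
    }
  }
  tibble::tibble(run_id = sigs$run_id, fail_inconsistent = unname(flags))
}

#' Filter a corpus by the run quality-control rules
#'
#' Applies hybridization-failure detection first, then replicate
#' consistency among the surviving runs of each specimen, mirroring the
#' study's filtering of ambiguous qPCR runs before training. Returns the
#' retained signature tibble and a QC report tallying removals by cause and
#' reliability by sample condition.
#'
#' @param sigs Signature tibble from [compute_signatures()].
#' @param theta_h Hybridization relative-energy threshold.
#' @param theta_c Replicate correlation-distance threshold.
#' @param marker_band,reference_tm Passed to [flag_hybridization_failure()].
#' @return A list of class `qc_result`: `retained` (signature tibble) and
#'   `report` (a `qc_report`).
#' @export
filter_corpus <- function(sigs, theta_h = 0.1, theta_c = 0.2,
                          marker_band = 1.5, reference_tm = TM_MARKER_TM) {
  if (nrow(sigs) == 0) stop("empty corpus")
  hyb <- flag_hybridization_failure(sigs, theta_h, marker_band, reference_tm)
  status <- rep("pass", nrow(sigs))
  status[hyb$fail_bs2] <- "fail_hybridization_bs2"
  status[hyb$fail_bs1] <- "fail_hybridization_bs1"
  survivors <- sigs[status == "pass", ]
  inc <- flag_replicate_inconsistency(survivors, theta_c)
  status[match(inc$run_id[inc$fail_inconsistent], sigs$run_id)] <- "fail_inconsistent"

  runs <- tibble::tibble(
    run_id = sigs$run_id, specimen_id = sigs$specimen_id,
    species = sigs$species, condition = sigs$condition, status = status)
  by_condition <- runs |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(),
                     n_reliable = sum(.data$status == "pass"),
                     reliability_pct = round(100 * .data$n_reliable / .data$n, 1),
                     .groups = "drop")
  by_species <- runs |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = dplyr::n(),
      bs1_ok = sum(!.data$status %in% "fail_hybridization_bs1"),
      bs2_ok = sum(!.data$status %in% "fail_hybridization_bs2"),
      retained = sum(.data$status == "pass"),
      .groups = "drop")
  report <- structure(
    list(runs = runs,
         n_input = nrow(sigs),
         n_retained = sum(status == "pass"),
         n_removed = sum(status != "pass"),
         removals = table(status[status != "pass"]),
         by_condition = by_condition,
         by_species = by_species,
         theta_h = theta_h, theta_c = theta_c),
    class = "qc_report")
  structure(list(retained = sigs[status == "pass", ], report = report),
            class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d runs in, %d retained, %d removed\n",
              x$n_input, x$n_retained, x$n_removed))
  if (length(x$removals)) print(x$removals)
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @rdname qc_tidiers
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$runs

#' Tidy and summarize QC reports
#'
#' `tidy()` returns the per-run status table; `glance()` a one-row summary
#' with input/retained/removed counts and per-cause tallies.
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @name qc_tidiers
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  rem <- as.list(x$removals)
  tibble::tibble(
    n_input = x$n_input, n_retained = x$n_retained, n_removed = x$n_removed,
    fail_hybridization_bs1 = rem[["fail_hybridization_bs1"]] %||% 0L,
    fail_hybridization_bs2 = rem[["fail_hybridization_bs2"]] %||% 0L,
    fail_inconsistent = rem[["fail_inconsistent"]] %||% 0L)
}

#' Reliability of melt profiles by sample condition
#'
#' Share of runs passing every QC rule, split by fresh vs processed tissue;
#' the headline robustness figure for degraded trade samples.
#'
#' @param report A `qc_report`, or a tibble with `condition` and a logical
#'   `reliable` column.
#' @return Tibble with `condition`, `n`, `n_reliable`, `reliability_pct`
#'   (one decimal).
#' @export
condition_reliability <- function(report) {
  if (inherits(report, "qc_report")) return(report$by_condition)
  stopifnot(all(c("condition", "reliable") %in% names(report)))
  report |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), n_reliable = sum(.data$reliable),
                     reliability_pct = round(100 * .data$n_reliable / .data$n, 1),
                     .groups = "drop")
}
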