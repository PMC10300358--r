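#' First-derivative fluorescent signature of a melt curve
#'
#' The classifier's unit of analysis is the first derivative dF/dT of the
#' melt curve, computed by Savitzky-Golay local-polynomial differentiation;
#' melting transitions appear as negative troughs centred at their melting
#' temperature.
#'
#' @param curve A `melt_curve` (see [simulate_curve()] / [read_melt_export()]).
#' @param window Odd smoothing window length (points, default 11).
#' @param polyorder Local polynomial order (default 3, must be < `window`).
#' @return A list of class `melt_signature`: `temperature`, `values`,
#'   `channel`, `tm_detected` (NA until [detect_tm_marker()]), `corrected`.
#' @export
derivative_signature <- function(curve, window = 11L, polyorder = 3L) {
  stopifnot(inherits(curve, "melt_curve"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be less than `window`")
  n <- length(curve$fluorescence)
  if (n < window)
    stop("curve has ", n, " points, shorter than the smoothing window ", window)
  dt <- mean(diff(curve$temperature))
  vals <- signal::sgolayfilt(curve$fluorescence, p = polyorder, n = window,
                             m = 1, ts = dt)
  new_signature(curve$temperature, vals, curve$channel)
}

new_signature <- function(temperature, values, channel, tm_detected = NA_real_,
                          corrected = FALSE) {
  structure(list(temperature = temperature, values = values,
                 channel = channel, tm_detected = tm_detected,
                 corrected = corrected),
            class = "melt_signature")
}

#' @export
print.melt_signature <- function(x, ...) {
  cat(sprintf("<melt_signature> %s, %d points%s%s\n", x$channel,
              length(x$values),
              if (is.na(x$tm_detected)) "" else
                sprintf(", marker at %.2f degC", x$tm_detected),
              if (x$corrected) ", corrected" else ""))
  invisible(x)
}

#' Locate the internal temperature marker in a BS1 signature
#'
#' The marker melts above every species transition and appears as the
#' rightmost trough of the BS1 signature. The rightmost local minimum
#' inside the search window whose depth exceeds `min_depth` is returned;
#' `NA` if no qualifying trough exists (a quality-control failure upstream).
#'
#' @param sig A BS1 `melt_signature`.
#' @param search_window Temperature interval (degC) scanned for the marker.
#' @param min_depth Minimum trough depth (signature units) to qualify.
#' @param min_prominence Minimum trough prominence: the smaller of the rises
#'   separating the trough from a deeper point (or the window edge) on each
#'   side. Screens out noise ripples on transition slopes.
#' @return The marker temperature, or `NA_real_`.
#' @export
detect_tm_marker <- function(sig, search_window = c(80, 87), min_depth = 0.05,
                             min_prominence = 0.05) {
  stopifnot(inherits(sig, "melt_signature"))
  if (!identical(sig$channel, "BS1"))
    stop("the temperature marker exists only in the BS1 channel")
  in_win <- sig$temperature >= search_window[1] &
    sig$temperature <= search_window[2]
  v <- sig$values[in_win]
  t <- sig$temperature[in_win]
  n <- length(v)
  if (n < 3) return(NA_real_)
  i <- 2:(n - 1)
  cand <- i[v[i] <= v[i - 1] & v[i] <= v[i + 1] & v[i] <= -min_depth]
  if (!length(cand)) return(NA_real_)
  prominence <- vapply(cand, function(k) {
    left <- if (k > 1) v[1:(k - 1)] else numeric()
    deeper <- which(left < v[k])
    lmax <- max(left[if (length(deeper)) (max(deeper) + 1):(k - 1) else
      seq_along(left)], -Inf)
    right <- if (k < n) v[(k + 1):n] else numeric()
    deeper_r <- which(right < v[k])
    rmax <- max(right[seq_len(if (length(deeper_r)) min(deeper_r) - 1 else
      length(right))], -Inf)
    min(lmax, rmax) - v[k]
  }, numeric(1))
  cand <- cand[prominence >= min_prominence]
  if (!length(cand)) return(NA_real_)
  t[max(cand)]
}

#' Correct a run's signatures for instrument temperature drift
#'
#' Shifts both channels of a run by `reference_tm - tm_detected` (the
#' marker's offset from its nominal melting temperature) and re-interpolates
#' onto the canonical grid; regions shifted past the grid edge are
#' zero-filled. One shift per run, applied identically to BS1 and BS2.
#'
#' @param bs1 BS1 `melt_signature` with `tm_detected` set (see
#'   [detect_tm_marker()]).
#' @param bs2 The run's BS2 `melt_signature`.
#' @param reference_tm Nominal marker melting temperature (degC).
#' @param grid Canonical [acquisition_grid()] to interpolate onto; defaults
#'   to the signatures' own grid.
#' @return A list with corrected `bs1` and `bs2` signatures and the applied
#'   `shift`.
#' @export
temperature_correct <- function(bs1, bs2, reference_tm = TM_MARKER_TM,
                                grid = NULL) {
  stopifnot(inherits(bs1, "melt_signature"), inherits(bs2, "melt_signature"))
  if (is.na(bs1$tm_detected))
    stop("BS1 signature has no detected marker; run fails hybridization QC")
  shift <- reference_tm - bs1$tm_detected
  target <- if (is.null(grid)) bs1$temperature else grid$temperature
  shift_one <- function(sig) {
    out <- new_signature(
      target,
      interp_zero(sig$temperature + shift, sig$values, target),
      sig$channel,
      tm_detected = if (sig$channel == "BS1") reference_tm else NA_real_,
      corrected = TRUE)
    out
  }
  list(bs1 = shift_one(bs1), bs2 = shift_one(bs2), shift = shift)
}

# linear interpolation with zero fill outside the observed range
interp_zero <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear",
                yleft = 0, yright = 0, ties = "ordered")$y
}

#' Resample a signature onto an acquisition grid
#'
#' Linear interpolation onto the canonical grid (zero-filled outside the
#' signature's range), so every run shares one feature space.
#'
#' @param sig A `melt_signature`.
#' @param grid Target [acquisition_grid()].
#' @return A `melt_signature` on `grid`.
#' @export
resample_signature <- function(sig, grid) {
  stopifnot(inherits(sig, "melt_signature"), inherits(grid, "acq_grid"))
  new_signature(grid$temperature,
                interp_zero(sig$temperature, sig$values, grid$temperature),
                sig$channel, tm_detected = sig$tm_detected,
                corrected = sig$corrected)
}

#' Optional per-segment min-max amplitude normalization
#'
#' Amplitude variation (degraded DNA) is a known weakness of
#' signature-based assignment; by default signatures are fed to the
#' classifier un-normalized, and this switch rescales a signature to
#' `[-1, 0]` range by its deepest trough for sensitivity analyses.
#'
#' @param sig A `melt_signature`.
#' @return The rescaled signature.
#' @export
normalize_signature <- function(sig) {
  rng <- max(abs(sig$values))
  if (rng == 0) return(sig)
  sig$values <- sig$values / rng
  sig
}

#' Compute corrected signatures for a corpus of runs
#'
#' Maps raw curve pairs to temperature-corrected derivative signatures:
#' Savitzky-Golay differentiation per channel, marker detection in BS1, one
#' rigid shift per run applied to both channels, re-interpolation onto the
#' canonical grid. Runs whose BS1 marker cannot be found are kept
#' uncorrected and flagged (`marker_found = FALSE`) for QC.
#'
#' @param runs A run tibble (from [generate_corpus()]`$training` or
#'   [read_melt_export()]).
#' @param grid The canonical [acquisition_grid()].
#' @param window,polyorder Savitzky-Golay parameters.
#' @param reference_tm Nominal marker temperature (degC).
#' @param correct Apply the marker temperature correction (default TRUE).
#' @param normalize Apply per-segment min-max normalization (default FALSE).
#' @return The run tibble with list-columns `sig_bs1`, `sig_bs2` replacing
#'   the raw curves, plus `tm_detected` and `marker_found`.
#' @export
compute_signatures <- function(runs, grid, window = 11L, polyorder = 3L,
                               reference_tm = TM_MARKER_TM, correct = TRUE,
                               normalize = FALSE) {
  out <- runs
  res <- purrr::map2(runs$bs1, runs$bs2, function(c1, c2) {
    s1 <- derivative_signature(c1, window, polyorder)
    s2 <- derivative_signature(c2, window, polyorder)
    tm <- detect_tm_marker(s1)
    s1$tm_detected <- tm
    if (correct && !is.na(tm)) {
      cr <- temperature_correct(s1, s2, reference_tm, grid = grid)
      s1 <- cr$bs1; s2 <- cr$bs2
    } else {
      s1 <- resample_signature(s1, grid)
      s2 <- resample_signature(s2, grid)
    }
    if (normalize) {
      s1 <- normalize_signature(s1); s2 <- normalize_signature(s2)
    }
    list(s1 = s1, s2 = s2, tm = tm)
  })
  out$bs1 <- NULL
  out$bs2 <- NULL
  out$sig_bs1 <- purrr::map(res, "s1")
  out$sig_bs2 <- purrr::map(res, "s2")
  out$tm_detected <- purrr::map_dbl(res, "tm")
  out$marker_found <- !is.na(out$tm_detected)
  out
}
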