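#' Confusion matrix of species assignments
#'
#' Exact counts of true vs predicted species, with rows/columns fixed to
#' the panel order so matrices are comparable across evaluations.
#'
#' @param truth,predicted Character vectors of equal length.
#' @param labels Class label order; defaults to the union of observed
#'   labels ordered by the panel sheet (unknown labels appended).
#' @return An integer matrix of class `confusion_matrix` (true x predicted).
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length")
  if (is.null(labels)) {
    seen <- union(truth, predicted)
    panel <- tryCatch(panel_species(), error = function(e) character())
    labels <- c(intersect(panel, seen), setdiff(seen, panel))
  }
  bad <- setdiff(union(truth, predicted), labels)
  if (length(bad)) stop("labels not in panel: ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = labels),
              factor(predicted, levels = labels))
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(truth = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d assignments, accuracy %.2f%%\n",
              nrow(x), sum(x), accuracy(x)))
  invisible(x)
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  out <- as.data.frame.table(unclass(x), responseName = "n",
                             stringsAsFactors = FALSE)
  tibble::as_tibble(out)
}

#' Overall assignment accuracy
#'
#' @param cm A `confusion_matrix`.
#' @return Percent correct (100 x trace / total), rounded to two decimals.
#' @examples
#' accuracy(confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
#'                           labels = c("a", "b")))
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  round(100 * sum(diag(cm)) / total, 2)
}

#' Deep-learning distinguishability of each species
#'
#' A species is distinguishable by the classifier when none of its test
#' specimens is misassigned and no other species' specimen is assigned to
#' it. A correctly assigned species is still flagged at risk of
#' misassignment when any of its winning scores beats the runner-up by less
#' than `margin_threshold`. Species absent from the test set are marked
#' unassessed.
#'
#' @param predictions Prediction tibble from [predict.fann_model()].
#' @param truth Character vector of true species, aligned with
#'   `predictions`.
#' @param species All panel species to report on.
#' @param margin_threshold Minimum safe score margin (default 0.1).
#' @return Tibble `species`, `assessed`, `dl_distinguishable`,
#'   `misassignment_risk`.
#' @export
dl_distinguishability <- function(predictions, truth,
                                  species = panel_species(),
                                  margin_threshold = 0.1) {
  stopifnot(nrow(predictions) == length(truth))
  pred <- predictions$predicted
  purrr::map(species, function(sp) {
    assessed <- any(truth == sp)
    if (!assessed) {
      return(tibble::tibble(species = sp, assessed = FALSE,
                            dl_distinguishable = NA, misassignment_risk = NA))
    }
    own_ok <- all(pred[truth == sp] == sp)
    no_influx <- !any(pred == sp & truth != sp)
    risk <- own_ok &&
      any(predictions$margin[truth == sp] < margin_threshold)
    tibble::tibble(species = sp, assessed = TRUE,
                   dl_distinguishable = own_ok && no_influx,
                   misassignment_risk = risk)
  }) |> purrr::list_rbind()
}

#' Visual distinguishability proxy from mean signatures
#'
#' The study's visual assessment is human judgment; this reproducible proxy
#' flags a species indistinguishable when some other species' noise-free
#' mean signature lies within correlation distance `delta` in *both*
#' barcode segments (a species differing in at least one segment remains
#' tellable apart). Symmetric by construction.
#'
#' @param panel Panel tibble from [build_default_panel()].
#' @param delta Correlation-distance threshold (default 0.05).
#' @param n_points Internal evaluation grid resolution.
#' @return Tibble `species`, `visual_distinguishable`, `closest_species`,
#'   `min_joint_distance`.
#' @export
visual_distinguishability <- function(panel, delta = 0.05, n_points = 1024) {
  tgrid <- seq(40, 87, length.out = n_points)
  d1 <- lapply(panel$bs1, function(s) curve_derivative(s$components, tgrid))
  d2 <- lapply(panel$bs2, function(s) curve_derivative(s$components, tgrid))
  n <- nrow(panel)
  if (n == 1)
    return(tibble::tibble(species = panel$species_name,
                          visual_distinguishable = TRUE,
                          closest_species = NA_character_,
                          min_joint_distance = NA_real_))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    joint <- vapply(seq_len(n), function(j) {
      if (i == j) return(Inf)
      max(cor_distance(d1[[i]], d1[[j]]), cor_distance(d2[[i]], d2[[j]]))
    }, numeric(1))
    j_min <- which.min(joint)
    out[[i]] <- tibble::tibble(
      species = panel$species_name[i],
      visual_distinguishable = joint[j_min] > delta,
      closest_species = panel$species_name[j_min],
      min_joint_distance = joint[j_min])
  }
  purrr::list_rbind(out)
}

#' Panel-level distinguishability tallies
#'
#' Recomputes from the species-status flags the headline panel accounting:
#' species distinguishable visually and by the classifier, CITES-listing
#' totals with the shark/ray split, the visual-and-CITES overlap, and the
#' combined (visual OR deep-learning) union — flagging, rather than
#' reproducing, any internal inconsistency between the flags and externally
#' reported union counts.
#'
#' @param status A species-status tibble, see [read_species_status_table()].
#' @return A list of class `panel_tallies`.
#' @export
panel_tallies <- function(status = read_species_status_table()) {
  if (nrow(status) != 28) stop("expected the 28-species status table")
  combined <- status$visual_distinguishable | status$dl_distinguishable
  tallies <- list(
    n_species = nrow(status),
    n_sharks = sum(status$group == "shark"),
    n_rays = sum(status$group == "ray"),
    visual_total = sum(status$visual_distinguishable),
    dl_total = sum(status$dl_distinguishable),
    cites_total = sum(status$cites_listed),
    cites_sharks = sum(status$cites_listed & status$group == "shark"),
    cites_rays = sum(status$cites_listed & status$group == "ray"),
    visual_cites = sum(status$visual_distinguishable & status$cites_listed),
    combined_total = sum(combined),
    combined_cites = sum(combined & status$cites_listed),
    visually_indistinct_cites =
      sum(!status$visual_distinguishable & status$cites_listed),
    misassignment_risk_total = sum(status$dl_misassignment_risk)
  )
  structure(tallies, class = "panel_tallies")
}

#' @export
print.panel_tallies <- function(x, ...) {
  cat("<panel_tallies>\n")
  cat(sprintf("  species: %d (%d sharks, %d rays); CITES-listed: %d (%d sharks, %d rays)\n",
              x$n_species, x$n_sharks, x$n_rays, x$cites_total,
              x$cites_sharks, x$cites_rays))
  cat(sprintf("  visually distinguishable: %d (of which CITES: %d)\n",
              x$visual_total, x$visual_cites))
  cat(sprintf("  classifier-distinguishable: %d; combined visual|classifier: %d (CITES: %d)\n",
              x$dl_total, x$combined_total, x$combined_cites))
  cat(sprintf("  CITES among visually indistinguishable: %d; misassignment-risk species: %d\n",
              x$visually_indistinct_cites, x$misassignment_risk_total))
  invisible(x)
}

#' @method glance panel_tallies
#' @export
glance.panel_tallies <- function(x, ...) tibble::as_tibble(unclass(x))
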