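#' Merge a run's two barcode-segment signatures into one feature vector
#'
#' Concatenates the BS1 and BS2 derivative signatures of a run into a
#' single vector of `2 x n_points` fluorescence-derivative features (8,152
#' at the default grid). A missing/failed segment may be passed as `NULL`
#' and is zero-filled, so species amplifying at only one segment remain
#' classifiable.
#'
#' @param bs1,bs2 `melt_signature`s on the same grid (either may be `NULL`).
#' @return A named numeric vector (`BS1@<temp>`, `BS2@<temp>`).
#' @export
merge_segments <- function(bs1, bs2) {
  if (is.null(bs1) && is.null(bs2)) stop("both segments missing")
  temp <- if (!is.null(bs1)) bs1$temperature else bs2$temperature
  if (!is.null(bs1) && !is.null(bs2)) {
    if (length(bs1$temperature) != length(bs2$temperature) ||
        max(abs(bs1$temperature - bs2$temperature)) > 1e-8)
      stop("BS1 and BS2 signatures are on different grids")
  }
  v1 <- if (is.null(bs1)) numeric(length(temp)) else bs1$values
  v2 <- if (is.null(bs2)) numeric(length(temp)) else bs2$values
  out <- c(v1, v2)
  names(out) <- feature_names(temp)
  out
}

feature_names <- function(temperature) {
  c(sprintf("BS1@%.3f", temperature), sprintf("BS2@%.3f", temperature))
}

#' Assemble the classifier feature matrix
#'
#' One row per QC-passed run (replicates are independent rows), columns the
#' merged BS1+BS2 signature values; rows ordered by run id so assembly is
#' deterministic.
#'
#' @param sigs Signature tibble (e.g. `filter_corpus()$retained`).
#' @param grid The canonical [acquisition_grid()] the signatures live on.
#' @return An object of class `melt_features`: list with `meta` (tibble of
#'   `run_id`, `specimen_id`, `species`, `replicate`, `condition`), numeric
#'   matrix `x` (runs x features) and the `grid`.
#' @export
build_feature_matrix <- function(sigs, grid) {
  if (anyDuplicated(sigs$run_id))
    stop("duplicate run ids: ",
         paste(unique(sigs$run_id[duplicated(sigs$run_id)]), collapse = ", "))
  ord <- order(sigs$run_id)
  sigs <- sigs[ord, ]
  x <- do.call(rbind, purrr::map2(sigs$sig_bs1, sigs$sig_bs2, merge_segments))
  rownames(x) <- sigs$run_id
  meta <- tibble::tibble(
    run_id = sigs$run_id, specimen_id = sigs$specimen_id,
    species = sigs$species,
    replicate = sigs$replicate %||% NA_integer_,
    condition = sigs$condition %||% NA_character_)
  structure(list(meta = meta, x = x, grid = grid), class = "melt_features")
}

#' @export
print.melt_features <- function(x, ...) {
  cat(sprintf("<melt_features> %d runs x %d features, %d species\n",
              nrow(x$x), ncol(x$x), length(unique(x$meta$species))))
  invisible(x)
}

#' @export
dim.melt_features <- function(x) dim(x$x)

#' @method as_tibble melt_features
#' @export
as_tibble.melt_features <- function(x, ...) {
  dplyr::bind_cols(x$meta, tibble::as_tibble(x$x, .name_repair = "minimal"))
}

#' @method tidy melt_features
#' @export
tidy.melt_features <- function(x, ...) {
  tibble::as_tibble(x$meta)
}

# subset rows of a feature matrix
features_subset <- function(feats, idx) {
  structure(list(meta = feats$meta[idx, ], x = feats$x[idx, , drop = FALSE],
                 grid = feats$grid), class = "melt_features")
}

#' Rank classifier input variables by importance
#'
#' Garson-style first-layer aggregation: a feature's relative importance is
#' the sum of absolute first-layer weights leaving it; scaled importance
#' divides by the maximum, and the percentage column normalizes scaled
#' importance to sum to 100.
#'
#' @param model A trained `fann_model`.
#' @param top_n Optionally return only the top rows.
#' @return Tibble `feature`, `relative_importance`, `scaled_importance`,
#'   `percentage`, sorted by decreasing importance.
#' @export
variable_importance <- function(model, top_n = NULL) {
  if (!inherits(model, "fann_model") || is.null(model$weights))
    stop("`model` must be a trained fann_model")
  w1 <- model$weights$W[[1]]
  rel <- unname(rowSums(abs(w1)))
  scaled <- rel / max(rel)
  pct <- 100 * scaled / sum(scaled)
  out <- tibble::tibble(feature = model$feature_names,
                        relative_importance = rel,
                        scaled_importance = scaled,
                        percentage = pct)
  out <- dplyr::arrange(out, dplyr::desc(.data$relative_importance))
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}
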