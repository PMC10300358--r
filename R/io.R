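#' Write a corpus of runs as instrument-style melt exports
#'
#' One CSV per optical channel (first column `temperature`, one fluorescence
#' column per run id) plus a metadata manifest
#' (`run_id,specimen_id,species,replicate,condition`). Temperatures are
#' written to three decimals, comma-separated, UTF-8, with a header row.
#'
#' @param runs Run tibble (see [generate_corpus()]).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (`<prefix>_bs1.csv`, `_bs2.csv`,
#'   `_metadata.csv`).
#' @return Invisibly, the three file paths.
#' @export
write_melt_export <- function(runs, dir, prefix = "melt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_bs1.csv", "_bs2.csv",
                                           "_metadata.csv")))
  for (ch in 1:2) {
    curves <- runs[[c("bs1", "bs2")[ch]]]
    df <- data.frame(temperature = round(curves[[1]]$temperature, 3))
    for (i in seq_len(nrow(runs))) df[[runs$run_id[i]]] <- curves[[i]]$fluorescence
    readr::write_csv(df, paths[ch])
  }
  meta <- dplyr::select(runs, "run_id", "specimen_id", "species",
                        "replicate", "condition")
  readr::write_csv(meta, paths[3])
  invisible(paths)
}

#' Read instrument-style melt-curve exports
#'
#' Loads the two per-channel CSVs and the metadata manifest written by
#' [write_melt_export()] (or an equivalent instrument export using that
#' dialect) into a run tibble. Every run id in the metadata must be present
#' in both channel files; temperatures must agree between channels and be
#' strictly increasing.
#'
#' @param bs1_file,bs2_file Channel CSVs: `temperature` column then one
#'   column per run id.
#' @param metadata_file Manifest CSV with at least `run_id`, `specimen_id`,
#'   `species`, `replicate`, `condition`.
#' @return A run tibble with `melt_curve` list-columns `bs1`, `bs2`.
#' @export
read_melt_export <- function(bs1_file, bs2_file, metadata_file) {
  ch1 <- readr::read_csv(bs1_file, show_col_types = FALSE)
  ch2 <- readr::read_csv(bs2_file, show_col_types = FALSE)
  meta <- readr::read_csv(metadata_file, show_col_types = FALSE)
  for (tb in list(ch1, ch2)) {
    if (names(tb)[1] != "temperature")
      stop("channel file must start with a `temperature` column")
    if (any(diff(tb$temperature) <= 0))
      stop("non-monotone temperature column in channel export")
  }
  if (!"run_id" %in% names(meta)) stop("metadata must have a `run_id` column")
  miss1 <- setdiff(meta$run_id, names(ch1))
  if (length(miss1))
    stop("runs missing from BS1 export: ", paste(miss1, collapse = ", "))
  miss2 <- setdiff(meta$run_id, names(ch2))
  if (length(miss2))
    stop("runs missing from BS2 export: ", paste(miss2, collapse = ", "))
  make_curves <- function(ch, label) {
    lapply(meta$run_id, function(id)
      structure(list(temperature = ch$temperature,
                     fluorescence = ch[[id]], channel = label),
                class = "melt_curve"))
  }
  out <- tibble::as_tibble(meta)
  out$bs1 <- make_curves(ch1, "BS1")
  out$bs2 <- make_curves(ch2, "BS2")
  out
}

#' Write signature tables as CSV
#'
#' One row per run, columns the grid temperatures of the requested channel.
#'
#' @param sigs Signature tibble from [compute_signatures()].
#' @param path Output CSV path.
#' @param channel `"BS1"` or `"BS2"`.
#' @return Invisibly, `path`.
#' @export
write_signature_table <- function(sigs, path, channel = c("BS1", "BS2")) {
  channel <- match.arg(channel)
  col <- if (channel == "BS1") "sig_bs1" else "sig_bs2"
  mat <- do.call(rbind, lapply(sigs[[col]], `[[`, "values"))
  df <- data.frame(run_id = sigs$run_id)
  tmp <- as.data.frame(mat)
  names(tmp) <- sprintf("%.3f", sigs[[col]][[1]]$temperature)
  readr::write_csv(dplyr::bind_cols(df, tmp), path)
  invisible(path)
}
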