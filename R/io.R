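# CSV interchange for the spectral and laboratory blocks, and the
# sample-id join that aligns them (with complete-case filtering).

#' Write a spectra block as wide CSV
#'
#' Columns: `sample_id`, `cultivar`, `replicate`, then one column per
#' wavenumber (header = wavenumber value at full precision).
#'
#' @param block a [spectra_block()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(block, path) {
  dt <- data.table::data.table(sample_id = block$sample_id,
                               cultivar = block$cultivar,
                               replicate = block$replicate)
  M <- data.table::as.data.table(block$X)
  data.table::setnames(M, format(block$grid, digits = 17, trim = TRUE, scientific = FALSE))
  data.table::fwrite(cbind(dt, M), path)
  invisible(path)
}

#' Read a spectra block from wide CSV
#'
#' @param path file written by [write_spectra_csv()].
#' @return a [spectra_block()]; the wavenumber header must be numeric and
#'   strictly monotone descending.
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample_id", "cultivar", "replicate")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("spectra CSV missing label column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  wn <- suppressWarnings(as.numeric(setdiff(names(dt), need)))
  if (anyNA(wn))
    stop("non-numeric wavenumber header in ", path, call. = FALSE)
  if (!all(diff(wn) < 0))
    stop("wavenumber header is not strictly monotone descending in ", path,
         call. = FALSE)
  X <- as.matrix(dt[, setdiff(names(dt), need), with = FALSE])
  if (!is.numeric(X)) stop("non-numeric absorbance cells in ", path, call. = FALSE)
  spectra_block(unname(X), wn, dt$sample_id, dt$cultivar, dt$replicate)
}

#' Write a lab panel as CSV
#' @param panel a [lab_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lab_csv <- function(panel, path) {
  data.table::fwrite(as.data.frame(panel), path)
  invisible(path)
}

#' Read a lab panel from CSV
#' @param path file with columns `sample_id`, `cultivar`, `harvest` and
#'   the five parameter columns.
#' @return a [lab_panel()].
#' @export
read_lab_csv <- function(path) {
  lab_panel(as.data.frame(data.table::fread(path)))
}

#' Align a spectra block with a lab panel by sample id
#'
#' Keeps fruits present in both blocks (fruits absent from either side are
#' dropped, with a message); with `complete_case = TRUE`, fruits with any
#' missing laboratory record are removed from both blocks.
#'
#' @param spectra a [spectra_block()].
#' @param panel a [lab_panel()].
#' @param complete_case drop fruits with masked lab values (default TRUE).
#' @return list with the aligned `spectra` (row subset, original order)
#'   and `panel` (one row per retained fruit, in spectra order).
#' @export
join_blocks <- function(spectra, panel, complete_case = TRUE) {
  common <- intersect(unique(spectra$sample_id), panel$sample_id)
  if (!length(common))
    stop("no overlapping sample ids between spectra and lab panel", call. = FALSE)
  dropped <- setdiff(unique(spectra$sample_id), common)
  if (length(dropped))
    message(length(dropped), " fruit(s) in spectra but not in panel; dropped")
  if (complete_case) {
    incomplete <- panel$sample_id[rowSums(missing_mask(panel)) > 0L]
    common <- setdiff(common, incomplete)
  }
  if (!length(common))
    stop("no complete-case fruits remain after the join", call. = FALSE)
  keep <- spectra$sample_id %in% common
  sb <- spectra_block(spectra$X[keep, , drop = FALSE], spectra$grid,
                      spectra$sample_id[keep], spectra$cultivar[keep],
                      spectra$replicate[keep])
  ord <- match(unique(sb$sample_id), panel$sample_id)
  list(spectra = sb,
       panel = lab_panel(as.data.frame(panel)[ord, , drop = FALSE]))
}
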