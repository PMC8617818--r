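## Plain-text and TIFF interchange. Channels are written as 32-bit float
## TIFF pages scaled into [0,1] (the scale is recorded in the sidecar);
## label masks as 16-bit integers / 65535, exact for labels <= 65535.

FIELD_TIFF_SCALE <- 65535

#' Write a synthetic field to disk
#'
#' Writes `<prefix>_channels.tif` (one page per channel, 32-bit float,
#' intensities divided by the recorded scale), `<prefix>_labels.tif`
#' (16-bit label mask) and `<prefix>_truth.tsv` (cell_id, tag,
#' truth_pm_fraction; scale and background in the header comment are
#' repeated as columns).
#'
#' @param field a `synthetic_field`.
#' @param prefix output path prefix.
#' @return invisibly, the three paths written.
#' @export
write_field <- function(field, prefix) {
  stopifnot(inherits(field, "synthetic_field"))
  pages <- lapply(field$channels, function(m) pmax(m, 0) / FIELD_TIFF_SCALE)
  ch_path <- paste0(prefix, "_channels.tif")
  tiff::writeTIFF(pages, ch_path, bits.per.sample = 32L)
  lab_path <- paste0(prefix, "_labels.tif")
  tiff::writeTIFF(field$truth_labels / 65535, lab_path, bits.per.sample = 16L)
  truth_path <- paste0(prefix, "_truth.tsv")
  ids <- seq_len(field$n_cells)
  truth <- data.frame(cell_id = ids,
                      tag = field$per_cell_tag,
                      truth_pm_fraction = field$truth_pm_fraction,
                      truth_background = field$truth_background,
                      channel = names(field$channels)[
                        ifelse(field$per_cell_tag == "green", 1L, 2L)],
                      intensity_scale = FIELD_TIFF_SCALE)
  utils::write.table(truth, truth_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(channels = ch_path, labels = lab_path, truth = truth_path))
}

#' Read field channels written by [write_field()]
#'
#' @param path `_channels.tif` file.
#' @param channel_names names for the pages (default green, red).
#' @param scale intensity scale recorded in the sidecar.
#' @return named list of numeric matrices.
#' @export
read_field_channels <- function(path, channel_names = c("green", "red"),
                                scale = FIELD_TIFF_SCALE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == length(channel_names))
  setNames(lapply(pages, function(p) p * scale), channel_names)
}

#' Read an integer label mask from TIFF
#'
#' @param path label TIFF written by [write_field()] or external
#'   segmentation software (16-bit, labels stored as value/65535).
#' @return integer matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read / write an expression profile as TSV
#'
#' Genes in rows (first column), mutants in columns; an optional
#' companion p-value file with the same layout.
#'
#' @param path log2FC TSV.
#' @param pvals_path optional p-value TSV.
#' @return an [expression_profile()].
#' @export
read_expression <- function(path, pvals_path = NULL) {
  read_mat <- function(p) {
    d <- utils::read.delim(p, check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  expression_profile(read_mat(path),
                     if (is.null(pvals_path)) NULL else read_mat(pvals_path))
}

#' @rdname read_expression
#' @param profile an [expression_profile()].
#' @param prefix output prefix; writes `<prefix>_log2fc.tsv` and, when
#'   present, `<prefix>_pvals.tsv`.
#' @export
write_expression <- function(profile, prefix) {
  wr <- function(m, p) {
    d <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  paths <- paste0(prefix, "_log2fc.tsv")
  wr(profile$log2fc, paths)
  if (!is.null(profile$pvals)) {
    pp <- paste0(prefix, "_pvals.tsv")
    wr(profile$pvals, pp)
    paths <- c(paths, pp)
  }
  invisible(paths)
}

#' Read / write a growth grid as CSV
#'
#' Rows are strains (first column `strain`), remaining columns are
#' dilution factors (as column names).
#'
#' @param path CSV file.
#' @param plate_id plate identifier for the returned grid.
#' @return a [growth_grid()].
#' @export
read_growth_grid <- function(path, plate_id = basename(path)) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  growth_grid(m, dilution_factors = as.numeric(colnames(m)),
              plate_id = plate_id)
}

#' @rdname read_growth_grid
#' @param grid a [growth_grid()].
#' @export
write_growth_grid <- function(grid, path) {
  d <- data.frame(strain = rownames(grid), unclass(grid),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
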