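#' Disc structuring element offsets
#'
#' Pixel offsets of a Euclidean disc of radius `width_px`: all integer
#' offsets (dy, dx) with dy^2 + dx^2 <= width_px^2. The radius-1 disc is
#' the 3x3 cross (4-neighbourhood). The same element is used both to paint
#' rim rings in the synthetic generator and to measure plasma-membrane
#' shells, so ground truth and measurement are commensurable.
#'
#' @param width_px integer radius >= 1.
#' @return two-column integer matrix of (row, col) offsets.
#' @keywords internal
disc_offsets <- function(width_px) {
  width_px <- as.integer(width_px)
  stopifnot(length(width_px) == 1L, width_px >= 1L)
  g <- expand.grid(dy = -width_px:width_px, dx = -width_px:width_px)
  g <- g[g$dy^2 + g$dx^2 <= width_px^2, , drop = FALSE]
  as.matrix(g)
}

#' Binary erosion by a disc
#'
#' Erodes a logical mask by a disc of radius `width_px`. Pixels outside the
#' image are treated as background, so regions touching the border are
#' eroded from that side too. Implemented as an intersection of shifted
#' copies of the mask, one per structuring-element offset.
#'
#' @param mask logical (or 0/1) matrix.
#' @param width_px disc radius in pixels, >= 1.
#' @return logical matrix of the same dimensions.
#' @export
#' @examples
#' m <- matrix(FALSE, 7, 7); m[2:6, 2:6] <- TRUE
#' sum(erode_binary(m, 1))  # inner 3x3 plus cross arms removed corners
erode_binary <- function(mask, width_px = 1L) {
  if (is.numeric(mask)) mask <- mask != 0
  stopifnot(is.logical(mask), is.matrix(mask))
  off <- disc_offsets(width_px)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nrow(off))) {
    dy <- off[i, 1L]; dx <- off[i, 2L]
    if (dy == 0L && dx == 0L) next
    shifted <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L - dy):min(nr, nr - dy)   # destination rows
    cs <- max(1L, 1L - dx):min(nc, nc - dx)
    shifted[rs, cs] <- mask[rs + dy, cs + dx]
    out <- out & shifted
  }
  out
}

#' Erode every label of a segmentation mask
#'
#' Applies [erode_binary()] to each labelled region independently (so
#' adjacent cells cannot bleed into one another) and reports labels whose
#' eroded interior is empty. The ring `label minus eroded label` is the
#' plasma-membrane shell used throughout the imaging module.
#'
#' @param labels integer matrix; 0 = background, positive integers = cells.
#' @param width_px erosion radius in pixels, >= 1.
#' @return list with `labels` (eroded integer matrix) and `empty`
#'   (integer vector of labels whose interior vanished).
#' @export
erode_labels <- function(labels, width_px = 3L) {
  stopifnot(is.matrix(labels), width_px >= 1L)
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  out <- matrix(0L, nrow(labels), ncol(labels))
  empty <- integer(0)
  for (id in ids) {
    er <- erode_binary(labels == id, width_px)
    if (!any(er)) {
      empty <- c(empty, id)
    } else {
      out[er] <- id
    }
  }
  list(labels = out, empty = empty)
}
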