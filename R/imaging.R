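#' Segment cells from a fluorescence or transmitted-light image
#'
#' Thresholds the image with Otsu's method on the min-max-normalised
#' intensities (so segmentation is invariant to global offset and scale),
#' fills holes (bright-rim cells have dim interiors), labels connected
#' components, and discards regions below `min_area`. Optionally splits
#' touching cells by a distance-map watershed. Intended for synthetic
#' fields and simple micrographs; externally produced label masks can be
#' supplied to the quantification functions instead.
#'
#' @param image numeric matrix, finite-valued.
#' @param min_area minimum region area in pixels.
#' @param split_touching if `TRUE`, apply a watershed on the distance map
#'   to separate touching cells.
#' @return integer label matrix (0 = background), labels `1..n` compact,
#'   with attribute `n_cells`.
#' @export
segment_cells <- function(image, min_area = 20L, split_touching = FALSE) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (rng[1] == rng[2]) return(structure(matrix(0L, nrow(image), ncol(image)),
                                         n_cells = 0L))
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- EBImage::fillHull(EBImage::Image(norm > thr))
  if (split_touching) {
    dm <- EBImage::distmap(bw)
    lab <- EBImage::watershed(dm)
  } else {
    lab <- EBImage::bwlabel(bw)
  }
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  structure(out, n_cells = length(keep))
}

#' Identify reporter-negative cells from a second marker channel
#'
#' Classifies each segmented cell as reporter-negative when its mean
#' intensity in the marker channel is high (it carries the red-only
#' marker) while its mean in the quantified channel is low. With
#' `"auto"` thresholds each channel's per-cell means are split by
#' 2-means clustering; explicit numeric thresholds can be given instead.
#'
#' @param quant_channel numeric matrix of the channel being quantified
#'   (e.g. green).
#' @param marker_channel numeric matrix of the marker channel (e.g. red).
#' @param mask integer label matrix.
#' @param marker_min,quant_max `"auto"` or numeric thresholds on per-cell
#'   mean intensities.
#' @return integer vector of negative-cell labels (possibly empty).
#' @export
find_negative_cells <- function(quant_channel, marker_channel, mask,
                                marker_min = "auto", quant_max = "auto") {
  ids <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (length(ids) == 0) return(integer(0))
  qm <- vapply(ids, function(i) mean(quant_channel[mask == i]), numeric(1))
  mm <- vapply(ids, function(i) mean(marker_channel[mask == i]), numeric(1))
  split_thr <- function(x, given) {
    if (is.numeric(given)) return(given)
    if (length(unique(x)) < 2) return(Inf)
    km <- kmeans(x, centers = range(x))
    mean(km$centers)
  }
  m_thr <- split_thr(mm, marker_min)
  q_thr <- if (is.numeric(quant_max)) quant_max else {
    if (length(unique(qm)) < 2) Inf else mean(kmeans(qm, centers = range(qm))$centers)
  }
  ids[mm > m_thr & qm < q_thr]
}

#' Estimate uniform autofluorescence background from negative cells
#'
#' Mean per-pixel intensity of the quantified channel over the pixels of
#' reporter-negative cells (the co-imaged red-only population), used as a
#' single scalar background for the whole field.
#'
#' @param channel numeric matrix of the channel being quantified.
#' @param mask integer label matrix.
#' @param negative_cells integer vector of negative-cell labels (e.g. from
#'   [find_negative_cells()]); must be non-empty.
#' @return scalar background estimate (a.u.).
#' @export
estimate_background <- function(channel, mask, negative_cells) {
  if (length(negative_cells) == 0)
    stop("no reporter-negative cells found; pass background = 0 explicitly ",
         "if the field has no autofluorescence")
  px <- mask %in% negative_cells
  if (!any(px)) stop("negative_cells labels not present in mask")
  mean(channel[px])
}

#' Per-cell plasma-membrane fraction by morphological erosion
#'
#' For each cell, the background-corrected signal is split between a
#' plasma-membrane shell (the ring between the cell boundary and its
#' erosion by a disc of radius `width_px`) and the interior. The headline
#' statistic is `pm_percent = 100 * shell / total`, clamped to \[0, 100\].
#' Total intensity is defined as shell + interior over the disjoint
#' partition, so the conservation identity is exact. Cells whose corrected
#' total is non-positive or whose eroded interior is empty are flagged;
#' flagged cells should be excluded from summaries.
#'
#' @param channel numeric matrix of the quantified channel.
#' @param mask integer label matrix (non-empty).
#' @param width_px erosion radius in pixels (default 3).
#' @param background scalar background to subtract from every pixel
#'   (>= 0), e.g. from [estimate_background()].
#' @return data.frame with one row per cell: `cell_id`, `area_px`,
#'   `shell_area_px`, `total_intensity`, `shell_intensity`,
#'   `interior_intensity`, `pm_percent`, `mean_intensity`, `flagged`,
#'   `flag`.
#' @export
quantify_pm <- function(channel, mask, width_px = 3L, background = 0) {
  stopifnot(is.matrix(channel), is.matrix(mask),
            all(dim(channel) == dim(mask)), background >= 0, width_px >= 1L)
  ids <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (length(ids) == 0) stop("mask contains no cells")
  er <- erode_labels(mask, width_px)
  corrected <- channel - background
  rows <- lapply(ids, function(id) {
    cell <- mask == id
    interior <- er$labels == id
    shell <- cell & !interior
    shell_sum <- sum(corrected[shell])
    interior_sum <- sum(corrected[interior])
    total <- shell_sum + interior_sum
    empty_int <- id %in% er$empty
    flag <- if (empty_int) "empty_interior"
            else if (total <= 0) "nonpositive_total"
            else ""
    pm <- if (flag == "") min(100, max(0, 100 * shell_sum / total)) else NA_real_
    data.frame(cell_id = id, area_px = sum(cell), shell_area_px = sum(shell),
               total_intensity = total, shell_intensity = shell_sum,
               interior_intensity = interior_sum, pm_percent = pm,
               mean_intensity = total / sum(cell),
               flagged = flag != "", flag = flag)
  })
  out <- do.call(rbind, rows)
  if (all(out$flagged))
    warning("all cells flagged (erosion width too large or signal absent)")
  out
}

#' Per-cell mean corrected intensity
#'
#' Mean background-corrected pixel intensity over each cell, for
#' whole-cell expression-level comparisons.
#'
#' @inheritParams quantify_pm
#' @return data.frame with `cell_id`, `area_px`, `mean_intensity`.
#' @export
measure_total <- function(channel, mask, background = 0) {
  stopifnot(is.matrix(channel), is.matrix(mask),
            all(dim(channel) == dim(mask)), background >= 0)
  ids <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (length(ids) == 0) stop("mask contains no cells")
  data.frame(cell_id = ids,
             area_px = vapply(ids, function(i) sum(mask == i), numeric(1)),
             mean_intensity = vapply(ids, function(i)
               mean(channel[mask == i]) - background, numeric(1)))
}

#' Strain-level summaries with Student's t-test against a reference
#'
#' Summarises a per-cell measurement by strain and compares each strain to
#' the reference with a two-sample, two-sided Student's t-test (pooled
#' variance; Welch available behind `welch = TRUE`). Flagged cells are
#' excluded. Zero pooled variance is handled as a degenerate case: t = 0 /
#' p = 1 when the means agree, |t| = Inf / p = 0 otherwise, with
#' `degenerate = TRUE`.
#'
#' @param records data.frame of per-cell records with a `strain` column
#'   and the measurement column `value_col`; a logical `flagged` column,
#'   if present, removes cells.
#' @param reference name of the reference strain (must be present).
#' @param value_col measurement column, default `"pm_percent"`.
#' @param welch use Welch's unequal-variance t-test instead of Student's.
#' @return data.frame with one row per strain: `strain`, `n`, `mean`,
#'   `sd`, `t_statistic`, `p_value`, `degenerate` (reference row has NA
#'   test fields).
#' @export
summarize_strains <- function(records, reference, value_col = "pm_percent",
                              welch = FALSE) {
  stopifnot(is.data.frame(records), "strain" %in% names(records),
            value_col %in% names(records))
  if ("flagged" %in% names(records)) records <- records[!records$flagged, ]
  if (!reference %in% records$strain) stop("reference strain not present")
  ref <- records[[value_col]][records$strain == reference]
  strains <- unique(records$strain)
  rows <- lapply(strains, function(s) {
    x <- records[[value_col]][records$strain == s]
    out <- data.frame(strain = s, n = length(x), mean = mean(x),
                      sd = if (length(x) > 1) sd(x) else NA_real_,
                      t_statistic = NA_real_, p_value = NA_real_,
                      degenerate = FALSE)
    if (s == reference) return(out)
    if (length(x) < 2 || length(ref) < 2) {
      out$degenerate <- TRUE
      return(out)
    }
    pooled0 <- isTRUE(all.equal(sd(x), 0)) && isTRUE(all.equal(sd(ref), 0))
    if (pooled0) {
      same <- isTRUE(all.equal(mean(x), mean(ref)))
      out$t_statistic <- if (same) 0 else sign(mean(x) - mean(ref)) * Inf
      out$p_value <- if (same) 1 else 0
      out$degenerate <- TRUE
    } else {
      tt <- t.test(x, ref, var.equal = !welch)
      out$t_statistic <- unname(tt$statistic)
      out$p_value <- tt$p.value
    }
    out
  })
  do.call(rbind, rows)
}
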