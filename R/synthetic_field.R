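#' Specification for a synthetic two-channel field of yeast-like cells
#'
#' Describes the geometry and intensity structure of a simulated micrograph:
#' disc-shaped cells with a bright rim (the plasma-membrane shell) holding a
#' set fraction of each cell's signal, optional endosome-like interior
#' puncta, uniform autofluorescence background, and additive Gaussian
#' detector noise. Ground truth is recorded pre-noise so downstream
#' measurements can be validated exactly.
#'
#' @param height_px,width_px image dimensions in pixels.
#' @param n_cells number of cells to place (>= 0).
#' @param cell_radius_mean,cell_radius_sd cell radius distribution (px).
#' @param rim_width_px width of the painted rim ring (px, >= 1); must be
#'   smaller than the smallest cell radius.
#' @param pm_fraction fraction of each cell's true signal painted into the
#'   rim, in \[0, 1\].
#' @param n_puncta number of endosome-like interior spots per cell; their
#'   intensity is drawn from the interior budget so `pm_fraction` holds
#'   exactly.
#' @param cell_intensity mean painted signal per cell pixel (a.u.);
#'   per-cell total = `cell_intensity * area`.
#' @param background_level uniform autofluorescence added to every pixel of
#'   every channel (a.u., >= 0).
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.),
#'   applied last.
#' @param channel_tag `"green"` (cells carry the green reporter) or
#'   `"redonly"` (cells carry only the red marker; green over them is pure
#'   background).
#' @param seed integer RNG seed.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(height_px = 256L, width_px = 256L, n_cells = 20L,
                       cell_radius_mean = 12, cell_radius_sd = 1.5,
                       rim_width_px = 3L, pm_fraction = 0.8,
                       n_puncta = 0L, cell_intensity = 100,
                       background_level = 0, noise_sd = 0,
                       channel_tag = c("green", "redonly"), seed = 1L) {
  channel_tag <- match.arg(channel_tag)
  spec <- list(height_px = as.integer(height_px), width_px = as.integer(width_px),
               n_cells = as.integer(n_cells),
               cell_radius_mean = cell_radius_mean, cell_radius_sd = cell_radius_sd,
               rim_width_px = as.integer(rim_width_px), pm_fraction = pm_fraction,
               n_puncta = as.integer(n_puncta), cell_intensity = cell_intensity,
               background_level = background_level, noise_sd = noise_sd,
               channel_tag = channel_tag, seed = as.integer(seed))
  validate_field_spec(spec)
  structure(spec, class = "field_spec")
}

validate_field_spec <- function(spec) {
  with(spec, {
    stopifnot(height_px >= 8L, width_px >= 8L, n_cells >= 0L,
              cell_radius_mean > 0, cell_radius_sd >= 0,
              rim_width_px >= 1L,
              is.finite(pm_fraction), pm_fraction >= 0, pm_fraction <= 1,
              n_puncta >= 0L,
              is.finite(cell_intensity), cell_intensity >= 0,
              is.finite(background_level), background_level >= 0,
              is.finite(noise_sd), noise_sd >= 0)
    if (rim_width_px >= cell_radius_mean - 2 * cell_radius_sd)
      stop("rim_width_px must be smaller than the smallest plausible cell radius")
  })
  invisible(spec)
}

## Non-overlapping circle placement; rejects and retries up to a bound.
place_cells <- function(n_cells, height, width, r_mean, r_sd, r_min,
                        existing = NULL, max_tries = 2000L) {
  centers <- if (is.null(existing)) matrix(numeric(0), 0, 3) else existing
  placed0 <- nrow(centers)
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- max(r_min, rnorm(1, r_mean, r_sd))
      if (r + 1 >= min(height, width) / 2) next
      cy <- runif(1, r + 1, height - r)
      cx <- runif(1, r + 1, width - r)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
              centers[, 3] + r + 2)) {
        centers <- rbind(centers, c(cy, cx, r))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("field too crowded: could not place cell ",
                  placed0 + i, " after ", max_tries, " attempts")
  }
  centers
}

disc_mask <- function(height, width, cy, cx, r) {
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

## Paints one cell's reporter signal into `channel`, splitting the per-cell
## total between rim ring and interior so that rim/total == pm_fraction
## exactly (pre-noise). Returns the updated channel.
paint_cell <- function(channel, cell, rim, interior, spec) {
  total <- spec$cell_intensity * sum(cell)
  n_rim <- sum(rim); n_int <- sum(interior)
  if (n_rim > 0) channel[rim] <- channel[rim] + spec$pm_fraction * total / n_rim
  if (n_int > 0 && spec$pm_fraction < 1) {
    int_budget <- (1 - spec$pm_fraction) * total
    punct_share <- if (spec$n_puncta > 0) 0.5 else 0
    channel[interior] <- channel[interior] +
      (1 - punct_share) * int_budget / n_int
    if (spec$n_puncta > 0) {
      idx <- which(interior)
      pts <- sample(idx, min(spec$n_puncta, length(idx)))
      channel[pts] <- channel[pts] + punct_share * int_budget / length(pts)
    }
  }
  channel
}

make_field_core <- function(specs) {
  s1 <- specs[[1]]
  h <- s1$height_px; w <- s1$width_px
  labels <- matrix(0L, h, w)
  green <- matrix(0, h, w)
  red <- matrix(0, h, w)
  tags <- character(0)
  truth_pm <- numeric(0)
  centers <- NULL
  label_id <- 0L
  for (spec in specs) {
    r_min <- spec$rim_width_px + 2
    centers_new <- place_cells(spec$n_cells, h, w, spec$cell_radius_mean,
                               spec$cell_radius_sd, r_min, existing = centers)
    new_rows <- if (is.null(centers)) seq_len(nrow(centers_new)) else
      setdiff(seq_len(nrow(centers_new)), seq_len(nrow(centers)))
    centers <- centers_new
    for (i in new_rows) {
      label_id <- label_id + 1L
      cell <- disc_mask(h, w, centers[i, 1], centers[i, 2], centers[i, 3])
      interior <- erode_binary(cell, spec$rim_width_px)
      rim <- cell & !interior
      labels[cell] <- label_id
      ch <- if (spec$channel_tag == "green") "green" else "red"
      if (ch == "green") green <- paint_cell(green, cell, rim, interior, spec)
      else red <- paint_cell(red, cell, rim, interior, spec)
      tags <- c(tags, spec$channel_tag)
      truth_pm <- c(truth_pm, spec$pm_fraction)
    }
  }
  bg <- s1$background_level
  prenoise <- list(green = green + bg, red = red + bg)
  noisy <- lapply(prenoise, function(m)
    if (s1$noise_sd > 0) m + matrix(rnorm(h * w, 0, s1$noise_sd), h, w) else m)
  structure(list(channels = noisy, prenoise = prenoise,
                 truth_labels = labels,
                 truth_pm_fraction = truth_pm,
                 per_cell_tag = tags,
                 truth_background = bg,
                 n_cells = label_id),
            class = "synthetic_field")
}

#' Generate a synthetic fluorescence field with exact ground truth
#'
#' Places non-overlapping disc cells, paints a fraction `pm_fraction` of
#' each cell's signal into a rim ring of width `rim_width_px` (the ring is
#' the set difference between the cell and its erosion by the shared disc
#' structuring element) and the remainder into the interior, then adds
#' uniform background and finally Gaussian noise. Pre-noise channels and
#' per-cell truth are kept on the returned object.
#'
#' @param spec a [field_spec()].
#' @return a `synthetic_field`: `channels` (named list of matrices,
#'   `green`/`red`), `prenoise` (same, before noise), `truth_labels`
#'   (integer label matrix, 0 = background), `truth_pm_fraction`,
#'   `per_cell_tag`, `truth_background`, `n_cells`.
#' @export
#' @examples
#' f <- make_field(field_spec(n_cells = 5, seed = 1))
#' max(f$truth_labels)
make_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  make_field_core(list(spec))
}

#' Generate a mixed field of reporter-positive and reporter-negative cells
#'
#' Emulates co-imaging a 1:1 mix of green-reporter cells with red-only
#' marker cells: the red-only population carries no green reporter signal,
#' so the green channel over those cells is background (+ noise) only —
#' the basis for cross-population autofluorescence estimation.
#'
#' @param spec_green [field_spec()] for the green-reporter population.
#' @param spec_redonly [field_spec()] for the red-only population; must
#'   share image dimensions, background and noise with `spec_green`.
#' @return a `synthetic_field` containing both populations;
#'   `per_cell_tag` distinguishes them.
#' @export
make_mixed_field <- function(spec_green, spec_redonly) {
  stopifnot(inherits(spec_green, "field_spec"),
            inherits(spec_redonly, "field_spec"))
  same <- c("height_px", "width_px", "background_level", "noise_sd")
  for (f in same)
    if (!identical(spec_green[[f]], spec_redonly[[f]]))
      stop("specs must share ", f)
  if (spec_green$channel_tag != "green") stop("spec_green must have channel_tag 'green'")
  sr <- spec_redonly; sr$channel_tag <- "redonly"
  set.seed(spec_green$seed)
  make_field_core(list(spec_green, sr))
}
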