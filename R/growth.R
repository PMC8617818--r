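#' Construct a serial-dilution growth grid
#'
#' @param density numeric matrix, strains in rows (named), dilution steps
#'   in columns, finite and >= 0.
#' @param dilution_factors numeric vector of dilution fractions (e.g.
#'   `c(1, 0.1, 0.01)`), one per column.
#' @param plate_id plate identifier.
#' @return matrix of class `growth_grid` with attributes
#'   `dilution_factors` and `plate_id`.
#' @export
growth_grid <- function(density, dilution_factors, plate_id = "plate") {
  stopifnot(is.matrix(density), !is.null(rownames(density)),
            all(is.finite(density)), all(density >= 0),
            length(dilution_factors) == ncol(density))
  structure(density, class = c("growth_grid", class(density)),
            dilution_factors = dilution_factors, plate_id = plate_id)
}

#' Growth score of one strain across its dilution series
#'
#' Sum of spot densities across the dilution series (the documented
#' default); `weighting = "trapezoid"` instead integrates density over
#' log10 dilution by the trapezoid rule.
#'
#' @param grid a [growth_grid()].
#' @param strain strain (row) name.
#' @param weighting `"sum"` (default) or `"trapezoid"`.
#' @return scalar score.
#' @export
growth_score <- function(grid, strain, weighting = c("sum", "trapezoid")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(grid, "growth_grid"))
  if (!strain %in% rownames(grid)) stop("strain '", strain, "' not on plate")
  d <- grid[strain, ]
  if (weighting == "sum") return(sum(d))
  x <- -log10(attr(grid, "dilution_factors"))
  sum(diff(x) * (d[-length(d)] + d[-1]) / 2)
}

#' Growth of a strain relative to same-plate wild-type
#'
#' Ratio of [growth_score()]s between a strain and the reference strain
#' on the same plate; invariant to any overall plate intensity scale.
#'
#' @param grid a [growth_grid()].
#' @param strain strain name.
#' @param reference reference (wild-type) strain name.
#' @param weighting passed to [growth_score()].
#' @return scalar ratio.
#' @export
relative_growth <- function(grid, strain, reference,
                            weighting = c("sum", "trapezoid")) {
  weighting <- match.arg(weighting)
  ref <- growth_score(grid, reference, weighting)
  if (ref <= 0) stop("reference strain has zero growth score")
  growth_score(grid, strain, weighting) / ref
}

#' Compare strain growth ratios across conditions and replicate plates
#'
#' For each condition (a list of replicate plates) and strain, computes
#' per-plate ratios to the same-plate reference and summarises them: mean,
#' sd, and a one-sample t-test of the ratios against 1 (the reference's
#' own ratio on every plate). A per-strain two-sample t-test between the
#' two conditions is also returned when exactly two conditions are given.
#' Zero-variance replicate sets are flagged degenerate (t = 0 / p = 1
#' when the mean equals the null, else p = 0); single-replicate
#' conditions report ratios only.
#'
#' @param grids_by_condition named list; each element is a list of
#'   [growth_grid()]s (replicate plates of one condition).
#' @param strains strain names to report (default: all non-reference
#'   strains on the first plate).
#' @param reference reference strain name, present on every plate.
#' @return list with `per_condition` (strain x condition summary table)
#'   and `condition_contrast` (per-strain between-condition t-test, or
#'   `NULL` unless exactly two conditions).
#' @export
compare_conditions <- function(grids_by_condition, strains = NULL,
                               reference = "wt") {
  stopifnot(is.list(grids_by_condition), !is.null(names(grids_by_condition)))
  first <- grids_by_condition[[1]][[1]]
  if (is.null(strains)) strains <- setdiff(rownames(first), reference)
  ratios <- lapply(grids_by_condition, function(plates)
    vapply(plates, function(pl)
      vapply(strains, relative_growth, numeric(1), grid = pl,
             reference = reference),
      numeric(length(strains))))
  ratios <- lapply(ratios, function(r)
    if (is.matrix(r)) r else matrix(r, nrow = length(strains),
                                    dimnames = list(strains, NULL)))
  rows <- list()
  for (cond in names(ratios)) {
    r <- ratios[[cond]]
    for (s in strains) {
      x <- r[s, ]
      row <- data.frame(strain = s, condition = cond, n_plates = length(x),
                        mean_ratio = mean(x),
                        sd = if (length(x) > 1) sd(x) else NA_real_,
                        t_statistic = NA_real_, p_value = NA_real_,
                        degenerate = FALSE, test_available = length(x) >= 2)
      if (length(x) >= 2) {
        if (isTRUE(all.equal(sd(x), 0))) {
          same <- isTRUE(all.equal(mean(x), 1))
          row$t_statistic <- if (same) 0 else sign(mean(x) - 1) * Inf
          row$p_value <- if (same) 1 else 0
          row$degenerate <- TRUE
        } else {
          tt <- t.test(x, mu = 1)
          row$t_statistic <- unname(tt$statistic)
          row$p_value <- tt$p.value
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  per_condition <- do.call(rbind, rows)
  contrast <- NULL
  if (length(ratios) == 2) {
    cn <- names(ratios)
    contrast <- do.call(rbind, lapply(strains, function(s) {
      x <- ratios[[1]][s, ]; y <- ratios[[2]][s, ]
      out <- data.frame(strain = s,
                        mean_ratio_1 = mean(x), mean_ratio_2 = mean(y),
                        t_statistic = NA_real_, p_value = NA_real_,
                        degenerate = FALSE)
      names(out)[2:3] <- paste0("mean_ratio_", cn)
      if (length(x) >= 2 && length(y) >= 2) {
        if (isTRUE(all.equal(sd(c(x - mean(x), y - mean(y))), 0))) {
          same <- isTRUE(all.equal(mean(x), mean(y)))
          out$t_statistic <- if (same) 0 else sign(mean(x) - mean(y)) * Inf
          out$p_value <- if (same) 1 else 0
          out$degenerate <- TRUE
        } else {
          tt <- t.test(x, y, var.equal = TRUE)
          out$t_statistic <- unname(tt$statistic)
          out$p_value <- tt$p.value
        }
      }
      out
    }))
  }
  list(per_condition = per_condition, condition_contrast = contrast)
}
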