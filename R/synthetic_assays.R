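#' Simulate a dye-efflux flow-cytometry event stream
#'
#' Emulates a kinetic acquisition of lipid-dye-loaded cells passing the
#' detector: event times are Poisson over the acquisition window and each
#' event's fluorescence decays exponentially from a per-cell initial value,
#' with multiplicative detector noise. Defaults follow a ~1500 events/s
#' acquisition over 600 s.
#'
#' @param n_cells_per_s mean event rate (events per second, > 0).
#' @param duration_s acquisition duration in seconds (> 0).
#' @param f0_mean,f0_cv mean and coefficient of variation of the per-event
#'   initial fluorescence (lognormal family; `f0_cv = 0` gives a constant).
#' @param decay_rate_per_s exponential efflux rate k (per second, >= 0).
#' @param noise_cv multiplicative noise CV applied per event (>= 0).
#' @param seed integer RNG seed.
#' @param label optional strain/condition label stored on the stream.
#' @return an `event_stream`: data.frame with columns `time_s`,
#'   `fluorescence`, sorted by time, with attributes
#'   `acquisition_duration_s` and `label`.
#' @export
simulate_efflux <- function(n_cells_per_s = 1500, duration_s = 600,
                            f0_mean = 1000, f0_cv = 0.25,
                            decay_rate_per_s = 0.004, noise_cv = 0.05,
                            seed = 1L, label = "sim") {
  stopifnot(n_cells_per_s > 0, duration_s > 0, f0_mean > 0, f0_cv >= 0,
            decay_rate_per_s >= 0, noise_cv >= 0)
  set.seed(as.integer(seed))
  n <- rpois(1, n_cells_per_s * duration_s)
  t <- sort(runif(n, 0, duration_s))
  f0 <- if (f0_cv > 0) {
    sdlog <- sqrt(log(1 + f0_cv^2))
    rlnorm(n, meanlog = log(f0_mean) - sdlog^2 / 2, sdlog = sdlog)
  } else rep(f0_mean, n)
  fl <- f0 * exp(-decay_rate_per_s * t)
  if (noise_cv > 0) fl <- fl * (1 + rnorm(n, 0, noise_cv))
  fl <- pmax(fl, 0)
  event_stream(data.frame(time_s = t, fluorescence = fl),
               acquisition_duration_s = duration_s, label = label)
}

#' Simulate a deletion-mutant expression compendium slice
#'
#' Generates a genes x mutants log2 fold-change matrix in which planted
#' gene sets are coherently repressed or induced across every mutant
#' (effect + Gaussian noise) and all other genes are pure noise — the
#' structure assumed by cross-mutant averaging. Two-sided normal p-values
#' are derived from the standardised drawn effect (a documented
#' convention, not a platform model; with `noise_sd = 0` they are 0 for
#' planted and 1 for null genes).
#'
#' @param n_genes number of genes; names are `gene_0001`, ...
#' @param mutants character vector of mutant names.
#' @param planted_down,planted_up gene names (subset of the universe) or a
#'   single integer count, in which case genes are sampled; the two sets
#'   must be disjoint.
#' @param delta_down,delta_up planted effects (log2FC), `delta_down < 0`,
#'   `delta_up > 0`.
#' @param noise_sd Gaussian noise SD on every entry (>= 0).
#' @param seed integer RNG seed.
#' @return an [expression_profile()].
#' @export
simulate_expression <- function(n_genes = 89,
                                mutants = c("stb2", "ume1", "hos2", "cti6",
                                            "pho23", "sap30", "dep1", "sin3",
                                            "rpd3"),
                                planted_down = 24, delta_down = -1.5,
                                planted_up = 0, delta_up = 1.5,
                                noise_sd = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1, length(mutants) >= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  as_set <- function(x, avoid = character(0)) {
    if (is.character(x)) {
      if (!all(x %in% genes)) stop("planted genes outside gene universe")
      x
    } else if (length(x) == 1 && x >= 0) {
      sample(setdiff(genes, avoid), x)
    } else stop("planted set must be gene names or a count")
  }
  down <- as_set(planted_down)
  up <- as_set(planted_up, avoid = down)
  if (length(intersect(down, up)) > 0) stop("planted sets must be disjoint")
  if (length(down) > 0 && delta_down >= 0) stop("delta_down must be < 0")
  if (length(up) > 0 && delta_up <= 0) stop("delta_up must be > 0")
  delta <- setNames(numeric(n_genes), genes)
  delta[down] <- delta_down
  delta[up] <- delta_up
  m <- length(mutants)
  log2fc <- matrix(delta, n_genes, m) +
    matrix(rnorm(n_genes * m, 0, noise_sd), n_genes, m)
  dimnames(log2fc) <- list(genes, mutants)
  pvals <- if (noise_sd > 0) {
    2 * pnorm(-abs(log2fc / noise_sd))
  } else {
    p <- matrix(ifelse(delta != 0, 0, 1), n_genes, m)
    dimnames(p) <- dimnames(log2fc)
    p
  }
  prof <- expression_profile(log2fc, pvals)
  attr(prof, "planted_down") <- down
  attr(prof, "planted_up") <- up
  prof
}

#' Simulate a serial-dilution spot-assay plate
#'
#' Spot density for strain s at dilution step d is
#' `plate_scale * fitness(s) * g(d) * (1 + noise)`, where
#' `g(d) = dilution_factor^-(d-1)` is a fixed decreasing dilution response
#' shared by all strains on the plate. Ratios to a same-plate reference
#' therefore recover the programmed fitness ratio exactly when noise is
#' zero, and are invariant to `plate_scale`.
#'
#' @param strain_fitness named numeric vector of fitness values in \[0, 1\].
#' @param n_dilutions number of dilution steps (>= 2).
#' @param dilution_factor fold-dilution between consecutive spots (> 1).
#' @param plate_scale overall plate intensity scale (> 0).
#' @param noise_cv multiplicative noise CV per spot (>= 0).
#' @param seed integer RNG seed.
#' @param plate_id plate identifier stored on the grid.
#' @return a [growth_grid()].
#' @export
simulate_growth <- function(strain_fitness = c(wt = 1, mut = 0.5),
                            n_dilutions = 4L, dilution_factor = 10,
                            plate_scale = 1000, noise_cv = 0,
                            seed = 1L, plate_id = "plate1") {
  stopifnot(all(strain_fitness >= 0 & strain_fitness <= 1),
            !is.null(names(strain_fitness)),
            n_dilutions >= 2L, dilution_factor > 1, plate_scale > 0,
            noise_cv >= 0)
  set.seed(as.integer(seed))
  g <- dilution_factor^(-(seq_len(n_dilutions) - 1))
  dens <- outer(strain_fitness, g) * plate_scale
  if (noise_cv > 0)
    dens <- dens * (1 + matrix(rnorm(length(dens), 0, noise_cv),
                               nrow(dens), ncol(dens)))
  dens <- pmax(dens, 0)
  colnames(dens) <- format(g, trim = TRUE)
  growth_grid(dens, dilution_factors = g, plate_id = plate_id)
}
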