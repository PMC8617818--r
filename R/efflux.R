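#' Construct a flow-cytometry event stream
#'
#' @param events data.frame with numeric columns `time_s` and
#'   `fluorescence`.
#' @param acquisition_duration_s acquisition length in seconds; defaults
#'   to the last event time.
#' @param label strain/condition label.
#' @param dropped_n number of events removed during loading.
#' @return data.frame of class `event_stream`, sorted by time.
#' @export
event_stream <- function(events, acquisition_duration_s = NULL,
                         label = "", dropped_n = 0L) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "fluorescence") %in% names(events)))
  events <- events[order(events$time_s), c("time_s", "fluorescence")]
  rownames(events) <- NULL
  if (is.null(acquisition_duration_s))
    acquisition_duration_s <- if (nrow(events)) max(events$time_s) else 0
  if (nrow(events) && max(events$time_s) > acquisition_duration_s)
    stop("event times exceed acquisition_duration_s")
  structure(events, class = c("event_stream", "data.frame"),
            acquisition_duration_s = acquisition_duration_s,
            label = label, dropped_n = as.integer(dropped_n))
}

#' Load cytometry events from file
#'
#' Reads a CSV event table, drops rows with non-finite or negative time or
#' fluorescence (the count is kept on the result), and sorts stably by
#' time. CSV with columns `time_s,fluorescence` (or the channel names
#' given) is the canonical interchange format; FCS ingestion is not
#' bundled — export events to CSV from your cytometry software.
#'
#' @param path file path.
#' @param format `"csv"` (supported) or `"fcs"` (informative error).
#' @param time_channel,fl_channel column names holding event time
#'   (seconds) and fluorescence.
#' @param label stream label; defaults to the file name.
#' @return an [event_stream()]; attribute `dropped_n` counts removed rows.
#' @export
load_events <- function(path, format = c("csv", "fcs"),
                        time_channel = "time_s",
                        fl_channel = "fluorescence",
                        label = basename(path)) {
  format <- match.arg(format)
  if (format == "fcs")
    stop("FCS ingestion is not bundled; export events as CSV with columns '",
         time_channel, "' and '", fl_channel, "'")
  d <- utils::read.csv(path, check.names = FALSE)
  missing_ch <- setdiff(c(time_channel, fl_channel), names(d))
  if (length(missing_ch))
    stop("channel(s) ", paste(missing_ch, collapse = ", "),
         " not found; available: ", paste(names(d), collapse = ", "))
  t <- d[[time_channel]]; f <- d[[fl_channel]]
  ok <- is.finite(t) & is.finite(f) & t >= 0 & f >= 0
  dropped <- sum(!ok)
  if (dropped > 0)
    message("load_events: dropped ", dropped, " non-finite or negative events")
  ev <- data.frame(time_s = t[ok], fluorescence = f[ok])
  ev <- ev[order(ev$time_s, method = "radix"), ]
  event_stream(ev, label = label, dropped_n = dropped)
}

#' Write an event stream to CSV
#'
#' @param stream an [event_stream()].
#' @param path output file.
#' @export
write_events <- function(stream, path) {
  utils::write.csv(as.data.frame(stream)[, c("time_s", "fluorescence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Bin events and normalise to the initial acquisition window
#'
#' Computes the mean raw fluorescence of all events acquired within the
#' first `initial_window_s` seconds (the unweighted mean over events) and
#' expresses each time bin's mean fluorescence as a percentage of it.
#' This anchors every trace at 100% over the initial window, making runs
#' with different dye loading or detector gain directly comparable.
#'
#' @param stream an [event_stream()].
#' @param initial_window_s length of the normalisation window (s),
#'   default 10.
#' @param bin_width_s bin width (s), default 5; the window should be a
#'   multiple of it so bins tile the window exactly.
#' @param min_count bins with fewer events are masked from decay fitting.
#' @return an `efflux_trace`: data.frame with `bin_center_s`,
#'   `percent_of_initial`, `n_events`, plus attributes
#'   `initial_mean_raw`, `initial_window_s`, `bin_width_s`, `min_count`,
#'   `label`.
#' @export
normalize_trace <- function(stream, initial_window_s = 10, bin_width_s = 5,
                            min_count = 20L) {
  stopifnot(inherits(stream, "event_stream"),
            initial_window_s > 0, bin_width_s > 0)
  t <- stream$time_s; f <- stream$fluorescence
  init <- t <= initial_window_s
  if (!any(init))
    stop("no events inside the initial window; cannot normalise")
  initial_mean <- mean(f[init])
  if (initial_mean <= 0) stop("initial-window mean fluorescence is not positive")
  duration <- attr(stream, "acquisition_duration_s")
  n_bins <- ceiling(duration / bin_width_s)
  if (n_bins < 1) n_bins <- 1
  idx <- pmin(floor(t / bin_width_s) + 1L, n_bins)
  sums <- rowsum(f, idx)
  counts <- as.integer(table(factor(idx, levels = seq_len(n_bins))))
  means <- rep(NA_real_, n_bins)
  means[as.integer(rownames(sums))] <- sums[, 1] / counts[as.integer(rownames(sums))]
  out <- data.frame(bin_center_s = (seq_len(n_bins) - 0.5) * bin_width_s,
                    percent_of_initial = 100 * means / initial_mean,
                    n_events = counts)
  structure(out, class = c("efflux_trace", "data.frame"),
            initial_mean_raw = initial_mean,
            initial_window_s = initial_window_s,
            bin_width_s = bin_width_s, min_count = as.integer(min_count),
            label = attr(stream, "label"))
}

#' Fit decay kinetics to a normalised efflux trace
#'
#' Quantifies the efflux rate from the percent-of-initial trace. The
#' plain exponential model `p(t) = A exp(-k t)` is fitted by log-linear
#' least squares on positive bins; the default exponential-with-plateau
#' model `p(t) = c + (A - c) exp(-k t)` (dye efflux saturates above zero)
#' by bounded quasi-Newton minimisation of the residual sum of squares.
#' Only bins with at least `min_count` events (recorded on the trace)
#' enter the fit.
#'
#' @param trace an `efflux_trace` from [normalize_trace()].
#' @param model `"exponential_plus_plateau"` (default) or
#'   `"exponential"`.
#' @return a `decay_fit` list: `rate_per_s`, `plateau_percent`,
#'   `amplitude_percent`, `rss` (on the percent scale), `n_bins`,
#'   `model`.
#' @export
fit_decay <- function(trace, model = c("exponential_plus_plateau",
                                       "exponential")) {
  model <- match.arg(model)
  stopifnot(inherits(trace, "efflux_trace"))
  use <- is.finite(trace$percent_of_initial) &
    trace$n_events >= attr(trace, "min_count")
  t <- trace$bin_center_s[use]; p <- trace$percent_of_initial[use]
  if (length(t) < 5) stop("need at least 5 usable bins to fit")
  if (model == "exponential") {
    if (any(p <= 0))
      stop("trace has non-positive bins; use model = 'exponential_plus_plateau'")
    fit <- lm(log(p) ~ t)
    k <- max(0, -unname(coef(fit)[2]))
    A <- exp(unname(coef(fit)[1]))
    pred <- A * exp(-k * t)
    res <- list(rate_per_s = k, plateau_percent = 0, amplitude_percent = A,
                rss = sum((p - pred)^2), n_bins = length(t), model = model)
  } else {
    ## for fixed k the model is linear in (plateau, amplitude - plateau):
    ## profile them out and search the rate in one dimension
    prof_rss <- function(k) {
      basis <- exp(-k * t)
      fit <- lm.fit(cbind(1, basis), p)
      sum(fit$residuals^2)
    }
    opt <- optimize(prof_rss, interval = c(1e-6, 1), tol = 1e-10)
    ## refine around the optimum in case of a flat valley near the bounds
    lo <- max(1e-7, opt$minimum / 5); hi <- min(1, opt$minimum * 5)
    opt2 <- optimize(prof_rss, interval = c(lo, hi), tol = 1e-12)
    if (opt2$objective < opt$objective) opt <- opt2
    k <- opt$minimum
    beta <- lm.fit(cbind(1, exp(-k * t)), p)$coefficients
    res <- list(rate_per_s = k,
                plateau_percent = unname(beta[1]),
                amplitude_percent = unname(beta[1] + beta[2]),
                rss = opt$objective, n_bins = length(t), model = model)
  }
  structure(res, class = "decay_fit")
}

#' Compare efflux traces against a reference condition
#'
#' For each trace: percent of initial fluorescence remaining at
#' `t_eval_s` (nearest bin), the fitted decay rate, and its ratio to the
#' reference trace's rate. All traces must share binning.
#'
#' @param traces named list of `efflux_trace` objects (names are
#'   condition labels; unnamed lists fall back to trace labels).
#' @param reference name of the reference trace.
#' @param t_eval_s evaluation time in seconds, default 300.
#' @param model decay model passed to [fit_decay()].
#' @return data.frame with `label`, `percent_remaining`, `rate_per_s`,
#'   `rate_ratio_vs_reference`, `is_reference`.
#' @export
compare_efflux <- function(traces, reference, t_eval_s = 300,
                           model = c("exponential_plus_plateau",
                                     "exponential")) {
  model <- match.arg(model)
  stopifnot(is.list(traces), length(traces) >= 1)
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- vapply(traces, function(x) attr(x, "label"), character(1))
  if (!reference %in% names(traces)) stop("reference trace not present")
  bc <- traces[[1]]$bin_center_s
  for (tr in traces)
    if (!isTRUE(all.equal(tr$bin_center_s, bc)))
      stop("traces do not share binning; rebin with a common bin width")
  fits <- lapply(traces, fit_decay, model = model)
  ref_rate <- fits[[reference]]$rate_per_s
  i_eval <- which.min(abs(bc - t_eval_s))
  data.frame(label = names(traces),
             percent_remaining = vapply(traces, function(tr)
               tr$percent_of_initial[i_eval], numeric(1)),
             rate_per_s = vapply(fits, `[[`, numeric(1), "rate_per_s"),
             rate_ratio_vs_reference = vapply(fits, function(f)
               f$rate_per_s / ref_rate, numeric(1)),
             is_reference = names(traces) == reference,
             row.names = NULL)
}

#' Write a normalised trace to CSV
#' @param trace an `efflux_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
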