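test_that("event loading drops bad rows, is stable, and round-trips", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,fluorescence", "0.5,100", "1.0,NaN", "2.0,90",
               "3.0,80"), p)
  expect_message(st <- load_events(p), "dropped 1")
  expect_equal(nrow(st), 3)
  expect_equal(attr(st, "dropped_n"), 1L)
  expect_equal(st$time_s, c(0.5, 2, 3))

  sim <- simulate_efflux(n_cells_per_s = 100, duration_s = 50, seed = 3)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events(sim, p2)
  back <- load_events(p2)
  expect_equal(back$time_s, sim$time_s)
  expect_equal(back$fluorescence, sim$fluorescence)

  writeLines(c("t,f", "1,2"), p)
  expect_error(load_events(p), "available: t, f")
})

test_that("normalisation anchors the initial window at 100", {
  ## constant stream: every bin is 100
  ev <- event_stream(data.frame(time_s = seq(0.05, 60, by = 0.05),
                                fluorescence = 42),
                     acquisition_duration_s = 60)
  tr <- normalize_trace(ev, initial_window_s = 10, bin_width_s = 5)
  expect_true(all(tr$percent_of_initial == 100))
  expect_equal(sum(tr$n_events), nrow(ev))

  ## step stream: early bins 100, later bins 50
  tm <- seq(0.05, 60, by = 0.05)
  fl <- ifelse(tm <= 10, 200, 100)
  tr2 <- normalize_trace(event_stream(data.frame(time_s = tm,
                                                 fluorescence = fl),
                                      acquisition_duration_s = 60))
  expect_true(all(abs(tr2$percent_of_initial[1:2] - 100) < 1e-9))
  expect_true(all(abs(tr2$percent_of_initial[4:12] - 50) < 1e-9))

  ## event-weighted anchor and scale invariance on a noisy simulation
  sim <- simulate_efflux(n_cells_per_s = 300, duration_s = 120, seed = 5)
  tr3 <- normalize_trace(sim)
  inside <- tr3$bin_center_s + attr(tr3, "bin_width_s") / 2 <=
    attr(tr3, "initial_window_s")
  expect_equal(weighted.mean(tr3$percent_of_initial[inside],
                             tr3$n_events[inside]), 100, tolerance = 1e-9)
  scaled <- sim
  scaled$fluorescence <- scaled$fluorescence * 3.7
  tr4 <- normalize_trace(event_stream(as.data.frame(scaled),
                                      attr(sim, "acquisition_duration_s")))
  expect_equal(tr4$percent_of_initial, tr3$percent_of_initial)

  ## empty initial window errors
  late <- event_stream(data.frame(time_s = 50 + 1:100,
                                  fluorescence = 10),
                       acquisition_duration_s = 200)
  expect_error(normalize_trace(late), "initial window")
})

test_that("noise-free traces match the closed-form normalised decay", {
  k <- 0.004
  sim <- simulate_efflux(n_cells_per_s = 1500, duration_s = 600,
                         decay_rate_per_s = k, f0_cv = 0, noise_cv = 0,
                         seed = 7)
  tr <- normalize_trace(sim)
  init <- sim$time_s <= 10
  C <- mean(exp(-k * sim$time_s[init]))
  expected <- 100 * exp(-k * tr$bin_center_s) / C
  ok <- tr$n_events > 0
  rel <- abs(tr$percent_of_initial[ok] - expected[ok]) / expected[ok]
  expect_lt(max(rel), 0.02)
})

test_that("decay fitting recovers rates and handles degenerate traces", {
  ## exact exponential trace: rate to >= 4 significant figures
  t <- seq(2.5, 597.5, by = 5)
  exact <- structure(data.frame(bin_center_s = t,
                                percent_of_initial = 100 * exp(-0.01 * t),
                                n_events = 1000L),
                     class = c("efflux_trace", "data.frame"),
                     min_count = 20L, initial_window_s = 10,
                     bin_width_s = 5, initial_mean_raw = 1000, label = "x")
  fit <- fit_decay(exact, model = "exponential")
  expect_equal(fit$rate_per_s, 0.01, tolerance = 1e-6)
  fitp <- fit_decay(exact)
  expect_equal(fitp$rate_per_s, 0.01, tolerance = 1e-3)

  flat <- exact
  flat$percent_of_initial <- 100
  expect_equal(fit_decay(flat, model = "exponential")$rate_per_s, 0)

  neg <- exact
  neg$percent_of_initial[5] <- 0
  expect_error(fit_decay(neg, model = "exponential"), "plateau")

  short <- exact[1:4, ]
  attr(short, "min_count") <- 20L
  class(short) <- c("efflux_trace", "data.frame")
  expect_error(fit_decay(short), "5 usable bins")

  ## simulated noisy stream: fitted rate within 5%
  sim <- simulate_efflux(n_cells_per_s = 1500, duration_s = 600,
                         decay_rate_per_s = 0.004, seed = 7)
  k_hat <- fit_decay(normalize_trace(sim), model = "exponential")$rate_per_s
  expect_lt(abs(k_hat - 0.004) / 0.004, 0.05)
})

test_that("trace comparison orders strains by rate and flags the reference", {
  sims <- list(wt = simulate_efflux(decay_rate_per_s = 0.004, seed = 1,
                                    n_cells_per_s = 400, duration_s = 300),
               mut = simulate_efflux(decay_rate_per_s = 0.002, seed = 2,
                                     n_cells_per_s = 400, duration_s = 300),
               other = simulate_efflux(decay_rate_per_s = 0.004, seed = 3,
                                       n_cells_per_s = 400, duration_s = 300))
  traces <- lapply(sims, normalize_trace)
  cmp <- compare_efflux(traces, reference = "wt", t_eval_s = 150,
                        model = "exponential")
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$rate_ratio_vs_reference[cmp$label == "wt"], 1)
  expect_true(cmp$is_reference[cmp$label == "wt"])
  expect_equal(cmp$rate_ratio_vs_reference[cmp$label == "mut"], 0.5,
               tolerance = 0.1)
  ## slower decay leaves more dye: higher remaining percentage
  expect_gt(cmp$percent_remaining[cmp$label == "mut"],
            cmp$percent_remaining[cmp$label == "wt"])

  mis <- normalize_trace(sims$wt, bin_width_s = 10)
  expect_error(compare_efflux(list(a = traces$wt, b = mis), reference = "a"),
               "binning")
})

test_that("noise-free ordering: smaller k gives a pointwise-higher trace", {
  mk <- function(k) normalize_trace(simulate_efflux(
    n_cells_per_s = 500, duration_s = 300, decay_rate_per_s = k,
    f0_cv = 0, noise_cv = 0, seed = 17))
  slow <- mk(0.002); fast <- mk(0.004)
  after <- slow$bin_center_s > 60
  expect_true(all(slow$percent_of_initial[after] >
                    fast$percent_of_initial[after]))
})

test_that("FCS ingestion points users at the CSV interchange", {
  expect_error(load_events("x.fcs", format = "fcs"), "CSV")
})
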