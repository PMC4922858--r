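ev_df <- function(mol, t0, t1, cens = 0L, channel = "U4") {
  data.frame(molecule_id = mol, channel = channel, t_bind_s = t0,
             t_release_s = t1, censored = cens)
}

test_that("coincidence matching pairs by start time within tolerance", {
  a <- ev_df(1:3, c(10, 100, 200), c(40, 130, 230))
  b <- ev_df(1:3, c(10, 100, 200), c(50, 140, 240), channel = "U5")
  mm <- match_coincident(a, b, tolerance_s = 3)
  expect_equal(nrow(mm$pairs), 3)
  expect_equal(nrow(mm$unmatched_a), 0)
  # starts offset by two frames with one-frame tolerance stay unpaired
  b2 <- ev_df(1, 16, 50, channel = "U5")
  a2 <- ev_df(1, 10, 40)
  mm2 <- match_coincident(a2, b2, tolerance_s = 3)
  expect_equal(nrow(mm2$pairs), 0)
  expect_equal(nrow(mm2$unmatched_a), 1)
  expect_equal(nrow(mm2$unmatched_b), 1)
  # role swap transposes labels only
  mm3 <- match_coincident(b, a, tolerance_s = 3)
  expect_equal(mm3$pairs$a_start, mm$pairs$b_start)
  expect_equal(mm3$pairs$b_end, mm$pairs$a_end)
  # each interval used at most once: two A near one B leaves one A unmatched
  a4 <- ev_df(c(1, 1), c(10, 13), c(40, 43))
  b4 <- ev_df(1, 11, 50, channel = "U5")
  mm4 <- match_coincident(a4, b4, tolerance_s = 3)
  expect_equal(nrow(mm4$pairs), 1)
  expect_equal(nrow(mm4$unmatched_a), 1)
})

test_that("outcome classes are exhaustive, exclusive and conserve counts", {
  ev <- make_fixture("outcomes", c(A_FIRST = 20, B_FIRST = 5,
                                   SIMULTANEOUS_LOSS = 12, PERSIST = 3))
  mm <- match_coincident(ev[ev$channel == "U4", ], ev[ev$channel == "U5", ])
  tly <- classify_outcomes(mm$pairs)
  expect_equal(tly$total, 40)
  expect_equal(sum(tly$counts), tly$total)
  expect_equal(sum(tly$percentage), 100, tolerance = 1e-9)
  expect_equal(as.numeric(tly$counts), c(20, 5, 12, 3))
  # both censored -> PERSIST regardless of end times
  p1 <- data.frame(molecule_id = 1, t_arrival_s = 0, a_start = 0,
                   a_end = 3600, a_censored = 1L, b_start = 0, b_end = 3600,
                   b_censored = 1L)
  expect_equal(as.character(classify_outcomes(p1)$pairs$outcome), "PERSIST")
})

test_that("classification on simulator ground truth with tolerance is exact", {
  sc <- scheme_preset("2mM")
  cfg <- acquisition_config()
  tr <- simulate_molecules(sc, 150, cfg, seed = 51)
  mm <- match_coincident(tr[tr$channel == "U4", ],
                         tr[tr$channel == "U5", ], tolerance_s = 3)
  tly <- classify_outcomes(mm$pairs, tolerance_s = 1e-6)
  # ground truth: U5 end strictly after U4 end is activation; equal end
  # times are discard; both censored persist
  p <- tly$pairs
  truth_outcome <- ifelse(p$a_censored == 1 & p$b_censored == 1, "PERSIST",
                   ifelse(abs(p$a_end - p$b_end) < 1e-9,
                          "SIMULTANEOUS_LOSS",
                   ifelse(p$a_end < p$b_end, "A_FIRST", "B_FIRST")))
  expect_identical(as.character(p$outcome), truth_outcome)
})

test_that("multiple-binding summary counts repeats and co-binding", {
  ev <- make_fixture("repeat_activation",
                     list(repeat_molecules = 49, total_molecules = 481))
  mm <- match_coincident(ev[ev$channel == "U4", ], ev[ev$channel == "U5", ])
  tly <- classify_outcomes(mm$pairs)
  s <- multi_binding_summary(tly, n_molecules = 481)
  expect_equal(s$n_repeat_activation, 49)
  expect_equal(round(100 * s$frac_repeat_activation), 10)
  expect_equal(s$n_cobound, 0)
  # single event per molecule: no repeats
  ev1 <- make_fixture("outcomes", c(A_FIRST = 10, B_FIRST = 0,
                                    SIMULTANEOUS_LOSS = 0, PERSIST = 0))
  mm1 <- match_coincident(ev1[ev1$channel == "U4", ],
                          ev1[ev1$channel == "U5", ])
  s1 <- multi_binding_summary(classify_outcomes(mm1$pairs), 10)
  expect_equal(s1$n_repeat_activation, 0)
  expect_equal(s1$n_multi, 0)
})

test_that("per-molecule binding event counts match a Monte-Carlo oracle", {
  # rebinding scheme: bind <-> unbind cycles; events per molecule in the
  # window follow an alternating-renewal count reproduced by direct draws
  sc <- kinetic_scheme(
    states = c("OFF", "ON"),
    transitions = data.frame(from = c("OFF", "ON"), to = c("ON", "OFF"),
                             rate = c(1 / 300, 1 / 100)),
    emission_map = list(OFF = character(), ON = c("U4", "U5")))
  cfg <- acquisition_config(t_max = 3600)
  tr <- simulate_molecules(sc, 2000, cfg, seed = 52)
  counts <- table(factor(tr$molecule_id[tr$channel == "U4"],
                         levels = 1:2000))
  # oracle: direct alternating exponential renewal simulation
  set.seed(53)
  oracle_counts <- replicate(2000, {
    t <- 0; n <- 0
    repeat {
      t <- t + rexp(1, 1 / 300)          # waiting to bind
      if (t >= 3600) break
      n <- n + 1
      t <- t + rexp(1, 1 / 100)          # bound period
      if (t >= 3600) break
    }
    n
  })
  expect_equal(mean(counts), mean(oracle_counts), tolerance = 0.05)
  expect_lt(suppressWarnings(
    stats::ks.test(as.numeric(counts), oracle_counts))$statistic, 0.05)
})

test_that("rebinding analysis reproduces fixture counts and matches an injected Poisson rate", {
  ev <- make_fixture("rebinding", list(rebind = 15, eligible = 260))
  mm <- match_coincident(ev[ev$channel == "U4", ], ev[ev$channel == "U5", ])
  tly <- classify_outcomes(mm$pairs)
  expect_warning(rb <- rebinding_analysis(tly, ev[ev$channel == "U4", ]),
                 "background")
  expect_equal(rb$n_rebind, 15)
  expect_equal(rb$n_eligible, 260)
  expect_equal(rb$fraction, 15 / 260)
  # no reappearances -> zero
  ev0 <- make_fixture("outcomes", c(A_FIRST = 30, B_FIRST = 0,
                                    SIMULTANEOUS_LOSS = 0, PERSIST = 0))
  mm0 <- match_coincident(ev0[ev0$channel == "U4", ],
                          ev0[ev0$channel == "U5", ])
  rb0 <- rebinding_analysis(classify_outcomes(mm0$pairs),
                            ev0[ev0$channel == "U4", ],
                            background_rate_per_min = 2.3e-3)
  expect_equal(rb0$n_rebind, 0)
  # injected Poisson background inside the eligible windows is recovered
  set.seed(54)
  rate <- 9.8e-3                       # events per minute
  n_mol <- 400; win0 <- 400; win1 <- 3400
  rows <- list()
  for (m in seq_len(n_mol)) {
    rows[[length(rows) + 1L]] <- ev_df(m, 100, win0)
    rows[[length(rows) + 1L]] <- ev_df(m, 100, win1, channel = "U5")
    k <- rpois(1, rate * (win1 - win0) / 60)
    if (k > 0) {
      t0 <- sort(runif(k, win0 + 1, win1 - 2))
      rows[[length(rows) + 1L]] <- ev_df(rep(m, k), t0, t0 + 1)
    }
  }
  evp <- do.call(rbind, rows)
  mmp <- match_coincident(evp[evp$channel == "U4", ],
                          evp[evp$channel == "U5", ])
  rbp <- rebinding_analysis(classify_outcomes(mmp$pairs),
                            evp[evp$channel == "U4", ],
                            background_rate_per_min = rate)
  # instances-per-window approximates the event rate when windows are short
  # relative to 1/rate; allow Poisson-scale slack
  p_hit <- 1 - exp(-rate * (win1 - win0) / 60)
  expect_lt(abs(rbp$n_rebind - n_mol * p_hit), 3.5 * sqrt(n_mol * p_hit))
})

test_that("ordering offsets follow the stated sign convention", {
  # NTC arriving 30 s after U4 release: delta = -30
  u4 <- ev_df(1, 100, 200)
  ntc <- ev_df(1, 230, 300, channel = "NTC")
  oo <- ordering_offsets(u4, ntc)
  expect_equal(oo$offsets$delta_s, -30)
  # NTC arriving 5 s before U4 release: delta = +5
  ntc2 <- ev_df(2, 195, 400, channel = "NTC")
  u42 <- ev_df(2, 100, 200)
  oo2 <- ordering_offsets(u42, ntc2)
  expect_equal(oo2$offsets$delta_s, 5)
  # molecules lacking either event are excluded and counted
  oo3 <- ordering_offsets(rbind(u4, ev_df(3, 10, 50)), ntc)
  expect_equal(oo3$n, 1)
  expect_equal(oo3$n_excluded, 1)
})

test_that("a sequential scheme gives nearly all negative offsets", {
  sc <- scheme_preset("2mM")
  tr <- simulate_molecules(sc, 250, acquisition_config(), seed = 55)
  oo <- ordering_offsets(tr[tr$channel == "U4", ],
                         tr[tr$channel == "NTC", ])
  expect_gt(oo$fraction_negative, 0.9)
})

test_that("the randomized control is seeded-deterministic and flat for exchangeable data", {
  set.seed(56)
  n <- 150
  u4 <- ev_df(1:n, 0, runif(n, 500, 3000))
  ntc <- ev_df(1:n, runif(n, 500, 3000), 3500, channel = "NTC")
  rc1 <- randomized_control(u4, ntc, n_shuffles = 50, seed = 9)
  rc2 <- randomized_control(u4, ntc, n_shuffles = 50, seed = 9)
  expect_identical(rc1$control, rc2$control)
  # for independent arrivals/releases the observed histogram matches the
  # shuffled control up to sampling noise
  expect_equal(sum(rc1$observed), sum(rc1$control), tolerance = 0.1)
  expect_lt(mean(abs(rc1$observed - rc1$control)),
            0.35 * max(rc1$control))
  # sequential kinetics put excess negative-offset mass above the control
  tr <- simulate_molecules(scheme_preset("2mM"), 250,
                           acquisition_config(), seed = 57)
  rcs <- randomized_control(tr[tr$channel == "U4", ],
                            tr[tr$channel == "NTC", ],
                            n_shuffles = 30, seed = 10)
  neg <- rcs$breaks[-length(rcs$breaks)] < 0 & rcs$breaks[-1] <= 0
  near_neg <- rcs$breaks[-length(rcs$breaks)] >= -200 &
    rcs$breaks[-1] <= 0
  expect_gt(sum(rcs$observed[near_neg]), sum(rcs$control[near_neg]))
  expect_error(randomized_control(u4[1, ], ntc[1, ]), ">= 2 molecules")
})

test_that("dwell correlation behaves on exact, null and degenerate inputs", {
  x <- c(1, 3, 7, 2, 9, 4)
  expect_equal(dwell_correlation(x, x, n_perm = 200)$rho, 1)
  expect_equal(dwell_correlation(x, -x, n_perm = 200)$rho, -1)
  set.seed(58)
  xn <- rexp(200, 1 / 100); yn <- rexp(200, 1 / 300)
  dc <- dwell_correlation(xn, yn, n_perm = 1000, seed = 3)
  expect_lt(abs(dc$rho), 0.15)
  expect_gt(dc$p_value, 0.05)
  dg <- dwell_correlation(rep(2, 10), 1:10)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
  expect_error(dwell_correlation(1:3, 1:3), "at least 5")
})

test_that("background rate arithmetic and confidence coverage", {
  expect_equal(background_rate(0, 500, 60)$rate, 0)
  expect_equal(background_rate(90, 500, 60)$rate, 3e-3)
  # ~3e-4 events/AOI/min over 2000 AOI-hours is consistent with its CI
  set.seed(59)
  covered <- mean(replicate(200, {
    n <- rpois(1, 3e-4 * 500 * 60)
    ci <- background_rate(n, 500, 60)$ci
    ci[1] <= 3e-4 && 3e-4 <= ci[2]
  }))
  expect_gte(covered, 0.90)
})
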