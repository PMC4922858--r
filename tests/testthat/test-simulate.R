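# small ad-hoc schemes used across the simulator tests
scheme_single_bind <- function(rate = 1 / 50) {
  kinetic_scheme(states = c("FREE", "BOUND"),
                 transitions = data.frame(from = "FREE", to = "BOUND",
                                          rate = rate),
                 emission_map = list(FREE = character(),
                                     BOUND = c("U4", "U5")))
}

scheme_two_exit <- function(k_act, k_disc) {
  kinetic_scheme(states = c("B", "ACT", "DISC"),
                 transitions = data.frame(from = "B", to = c("ACT", "DISC"),
                                          rate = c(k_act, k_disc)),
                 emission_map = list(B = c("U4", "U5"), ACT = "U5",
                                     DISC = character()))
}

test_that("an absorbing start state yields no intervals; invalid schemes are rejected", {
  sc <- kinetic_scheme(states = c("FREE", "BOUND"),
                       transitions = data.frame(from = "FREE", to = "BOUND",
                                                rate = 0),
                       emission_map = list(FREE = character(), BOUND = "U4"))
  tr <- simulate_molecules(sc, 50, acquisition_config(t_max = 600), seed = 1)
  expect_equal(nrow(tr), 0)
  expect_equal(attr(tr, "n_molecules"), 50)
  expect_error(kinetic_scheme("A", data.frame(from = "A", to = "B", rate = 1),
                              list(A = character())), "unknown state")
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "A", to = "B", rate = -2),
                              list(A = character(), B = "U4")), ">= 0")
  expect_error(kinetic_scheme(c("A", "B"),
                              data.frame(from = "A", to = "B", rate = 1),
                              list(A = character())), "every state")
})

test_that("exit-route flux from a two-exit state matches the rate ratio", {
  # k_act/(k_act + k_disc) = 0.62, the activation route share
  sc <- scheme_two_exit(0.62 / 20, 0.38 / 20)
  tr <- simulate_molecules(sc, 10000, acquisition_config(t_max = 600),
                           seed = 2)
  # U4 turns off on either exit; U5 survives only the activation exit, so a
  # U5 interval outlasting its U4 partner marks an activation-route exit
  m4 <- tr[tr$channel == "U4", ]; m5 <- tr[tr$channel == "U5", ]
  stopifnot(identical(m4$molecule_id, m5$molecule_id))
  act_frac <- mean(m5$t_release_s > m4$t_release_s + 1e-9)
  se <- sqrt(0.62 * 0.38 / 10000)
  expect_lt(abs(act_frac - 0.62), 3 * se)
})

test_that("arrival times from a single binding transition are exponential", {
  sc <- scheme_single_bind(rate = 1 / 50)
  tr <- simulate_molecules(sc, 4000, acquisition_config(t_max = 3600),
                           seed = 3)
  arr <- tr$t_bind_s[tr$channel == "U4"]
  oracle <- oracle_exp_arrivals(4000, 1 / 50, 3600, seed = 99)
  expect_equal(mean(arr), 50, tolerance = 0.05)
  expect_equal(mean(arr), mean(oracle), tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(arr, oracle))
  expect_gt(ks$p.value, 0.01)
  # U4 and U5 turn on at the same instant (one tri-snRNP binding transition)
  u5 <- tr$t_bind_s[tr$channel == "U5"]
  expect_equal(arr, u5)
})

test_that("bound-state lifetimes are exponential with mean 1/(sum of exit rates)", {
  sc <- scheme_two_exit(1 / 40, 1 / 60)
  tr <- simulate_molecules(sc, 5000, acquisition_config(t_max = 3600),
                           seed = 4)
  life <- with(tr[tr$channel == "U4" & tr$censored == 0, ],
               t_release_s - t_bind_s)
  rate <- 1 / 40 + 1 / 60
  expect_gt(length(life), 4900)
  ks <- suppressWarnings(stats::ks.test(life, stats::pexp, rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation is reproducible and stable under molecule count", {
  sc <- scheme_preset("2mM")
  cfg <- acquisition_config()
  strip <- function(d) {
    d <- as.data.frame(d)
    rownames(d) <- NULL
    attributes(d) <- attributes(d)[c("names", "row.names", "class")]
    d
  }
  a <- simulate_molecules(sc, 30, cfg, seed = 5)
  b <- simulate_molecules(sc, 30, cfg, seed = 5)
  expect_identical(strip(a), strip(b))
  wide <- simulate_molecules(sc, 60, cfg, seed = 5)
  expect_identical(strip(a), strip(wide[wide$molecule_id <= 30, ]))
})

test_that("noiseless rendering reproduces intervals exactly, including fractional frames", {
  cfg <- acquisition_config(frame_duration = 1, frame_spacing = 3,
                            t_max = 120, baseline = 50, noise_sd = 0,
                            amplitude = 40)
  # frame k (1-based) illuminates [3(k-1), 3(k-1)+1]
  truth <- structure(
    data.frame(molecule_id = 1L, channel = "U4",
               t_bind_s = 27, t_release_s = 57.5, censored = 0L),
    n_molecules = 1L, class = c("molecule_truth", "data.frame"))
  tt <- render_traces(truth, cfg, seed = 1)
  oracle <- oracle_trace(data.frame(t0 = 27, t1 = 57.5), 1, 3, 120, 50, 40)
  expect_equal(tt$intensity, oracle)
  # fully covered frames are exactly baseline + amplitude
  expect_true(all(tt$intensity[tt$t_mid_s > 27 & tt$t_mid_s < 57] == 90))
  # frame starting at 57 gets half the amplitude (overlap 0.5 of 1 s)
  expect_equal(tt$intensity[tt$frame_index == 20], 50 + 40 * 0.5)
  expect_true(all(tt$intensity[tt$t_mid_s < 27] == 50))
})

test_that("noiseless rendering is invertible by thresholding", {
  sc <- scheme_preset("50uM")
  cfg <- acquisition_config(noise_sd = 0, t_max = 1800)
  truth <- simulate_molecules(sc, 25, cfg, seed = 6)
  tt <- render_traces(truth, cfg, seed = 1, channels = c("U4", "U5"))
  tt$intensity <- tt$intensity + stats::rnorm(nrow(tt), 0, 1e-9)
  ev <- detect_all_events(tt, detector_config(),
                          frame_spacing = cfg$frame_spacing)
  # every truth interval spanning >= 1 full frame is recovered within 1 frame
  # (robust baseline estimation presumes mostly-dark traces, so restrict to
  # molecules bound < 40% of the window)
  bound_frac <- tapply(truth$t_release_s - truth$t_bind_s,
                       paste(truth$molecule_id, truth$channel),
                       sum) / cfg$t_max
  truth$key <- paste(truth$molecule_id, truth$channel)
  truth_long <- truth[truth$t_release_s - truth$t_bind_s >=
                        cfg$frame_spacing + cfg$frame_duration &
                        bound_frac[truth$key] < 0.4, ]
  for (i in seq_len(nrow(truth_long))) {
    cand <- ev[ev$molecule_id == truth_long$molecule_id[i] &
                 ev$channel == truth_long$channel[i] &
                 abs(ev$t_start_s - truth_long$t_bind_s[i]) <=
                   cfg$frame_spacing + 0.51, ]
    expect_gte(nrow(cand), 1)
  }
})

test_that("photobleach-driven spot loss scales with laser power", {
  # permanently bound molecules: apparent dwells are pure bleach times
  sc <- kinetic_scheme(states = c("FREE", "BOUND"),
                       transitions = data.frame(from = "FREE", to = "BOUND",
                                                rate = 5),
                       emission_map = list(FREE = character(), BOUND = "U4"))
  coef_b <- 2e-5                       # per uW s
  rates <- sapply(c(150, 450), function(P) {
    cfg <- acquisition_config(noise_sd = 0, t_max = 3600,
                              laser_power_uW = P,
                              photobleach_coeff = coef_b)
    truth <- simulate_molecules(sc, 400, cfg, seed = 7)
    tt <- render_traces(truth, cfg, seed = 8, channels = "U4")
    tt$intensity <- tt$intensity + stats::rnorm(nrow(tt), 0, 1e-9)
    ev <- detect_all_events(tt, frame_spacing = cfg$frame_spacing)
    dw <- extract_dwells(ev)
    f <- fit_dwells(dw, "exp1", t_m = 3, t_max = 3600)
    1 / unname(coef(f))
  })
  expect_equal(rates[2] / rates[1], 3, tolerance = 0.2)
  expect_equal(rates[1], coef_b * 150, tolerance = 0.2)
})

test_that("background binding is a Poisson process with the configured rate", {
  cfg <- acquisition_config(t_max = 3600)
  bg0 <- render_background(20, 0, cfg, seed = 9)
  expect_equal(nrow(bg0$events), 0)
  expect_true(all(abs(bg0$traces$intensity - cfg$baseline) <
                    6 * cfg$noise_sd))
  bg <- render_background(500, 2.3e-3, cfg, seed = 10)
  n <- nrow(bg$events)
  lambda <- 2.3e-3 * 500 * 60          # expected ~ 69 events
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))
  est <- background_rate(bg$events, 500, 60)
  expect_true(est$ci[1] <= 2.3e-3 && 2.3e-3 <= est$ci[2])
  # doubling the duration doubles the expected count
  cfg2 <- acquisition_config(t_max = 7200)
  n2 <- mean(sapply(1:4, function(s)
    nrow(render_background(500, 2.3e-3, cfg2, seed = s)$events)))
  n1 <- mean(sapply(1:4, function(s)
    nrow(render_background(500, 2.3e-3, cfg, seed = s)$events)))
  expect_equal(n2 / n1, 2, tolerance = 0.25)
})

test_that("preset schemes carry the published structure", {
  s2 <- scheme_preset("2mM")
  expect_setequal(s2$channels, c("U4", "U5", "NTC"))
  # three release classes at 2 mM, two at 50 uM
  expect_equal(sum(grepl("^B", s2$states)), 3)
  expect_equal(sum(grepl("^B", scheme_preset("50uM")$states)), 2)
  # NTC can only come on after U4 is already off
  for (st in s2$states[vapply(s2$emission_map, function(e) "NTC" %in% e,
                              logical(1))])
    expect_false("U4" %in% s2$emission_map[[st]])
})
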