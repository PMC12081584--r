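test_that("K(ATP) open probability obeys its algebraic limits and monotonicity", {
  p <- iom_params()
  expect_equal(okatp(0, 0, p), 0.08)
  expect_lt(okatp(1e9, 500, p), 1e-6)

  atp <- seq(0, 4000, by = 50)
  adp <- seq(0, 2000, by = 100)
  for (a in adp) {
    o <- okatp(atp, a, p)
    expect_true(all(o > 0 & o <= 1))
    expect_true(all(diff(o) < 0))
  }
  # higher ATP affinity (smaller Ktt) closes the channel at any ATP > 0
  p96 <- iom_params(ktt = 0.96)
  for (a in c(0, 100, 500, 1500)) {
    o1 <- okatp(atp[-1], a, p)
    o96 <- okatp(atp[-1], a, p96)
    expect_true(all(o96 < o1))
  }
  expect_equal(okatp(100, 50, p96), okatp(100, 50, p), tolerance = 0.05)
  expect_error(okatp(-1, 0, p), ">= 0")
})

test_that("compiled and reference right-hand sides agree along a trajectory", {
  p <- iom_params()
  st <- c(v = -52, n = 0.02, c = 0.18, cer = 220, f6p = 350, fbp = 3, adp = 130)
  # short horizon: spiking dynamics amplify round-off differences over long runs
  rc <- iom_integrate(p, initial_state = st, t_span = 0.02, dt_out = 10,
                      compiled = TRUE)
  rr <- iom_integrate(p, initial_state = st, t_span = 0.02, dt_out = 10,
                      compiled = FALSE)
  for (nm in c("V", "Ca_c", "FBP", "ADP"))
    expect_equal(rc[[nm]], rr[[nm]], tolerance = 1e-6)
})

test_that("dominant K(ATP) conductance silences the cell at a fixed point", {
  p <- iom_params(overrides = list(gkatpbar = 1e6))
  run <- iom_integrate(p, t_span = 60, dt_out = 100)
  expect_equal(classify_activity(run), "silent")
  tail_keep <- run$times > 48
  expect_lt(max(run$V[tail_keep]), -60)   # near V_K, hyperpolarised
  # the state it settles to approaches a fixed point of the right-hand side
  # (the nucleotide pool relaxes on a taua ~ minutes timescale)
  last <- length(run$V)
  final <- c(v = unname(run$V[last]), n = unname(run$n[last]),
             c = unname(run$Ca_c[last]), cer = unname(run$Ca_er[last]),
             f6p = unname(run$F6P[last]), fbp = unname(run$FBP[last]),
             adp = unname(run$ADP[last]))
  d <- iom_rhs(final, p)
  scales <- pmax(abs(final), 0.01)
  expect_true(all(abs(d) / scales < 1e-5))   # per-ms relative drift
})

test_that("calcium is conserved when influx and extrusion are switched off", {
  p <- iom_params(overrides = list(alpha = 0, kpmca = 0))
  run <- iom_integrate(p, t_span = 5)
  total <- run$Ca_c + run$Ca_er / p$sigmav
  expect_lt(diff(range(total)), 1e-6 * total[1])
})

test_that("integration is deterministic", {
  r1 <- iom_integrate(iom_params(), t_span = 3)
  r2 <- iom_integrate(iom_params(), t_span = 3)
  expect_identical(r1$V, r2$V)
  expect_identical(r1$Ca_c, r2$Ca_c)
})

test_that("event detection counts spikes, bursts and silent phases", {
  flat <- list(times = seq(0, 5, by = 1 / 600), V = rep(-70, 3001))
  ev <- detect_events(flat)
  expect_equal(ev$n_spikes, 0L)

  # synthetic bursting: 3 bursts of 5 spikes, 20 s between bursts
  t <- seq(0, 2, by = 1 / 6000)          # 10 ms sampling over 2 min
  V <- rep(-70, length(t))
  spike_at <- function(t0) which(abs(t - t0) < 1 / 6000 / 2 + 1e-9)[1]
  starts <- c(0.2, 0.8, 1.4)             # minutes
  spikes <- as.vector(outer(seq(0, by = 1 / 60, length.out = 5), starts, "+"))
  for (s in spikes) {
    i <- spike_at(s)
    V[i:(i + 2)] <- 0
    V[i - 1] <- -70
  }
  ev <- detect_events(list(times = t, V = V), spike_threshold = -40,
                      silent_gap = 5)
  expect_equal(ev$n_spikes, 15L)
  expect_equal(nrow(ev$bursts), 3L)
  expect_equal(ev$bursts$n_spikes, rep(5L, 3))

  # pure periodic fast spiking: one burst spanning the window
  Vp <- -70 + 50 * (sin(2 * pi * t * 120) > 0.95)
  evp <- detect_events(list(times = t, V = Vp), silent_gap = 5)
  expect_equal(nrow(evp$bursts), 1L)
})

test_that("activity classification distinguishes the three regimes", {
  t <- seq(0, 10, by = 1 / 6000)
  silent <- list(times = t, V = rep(-70, length(t)),
                 Ca_c = rep(0.05, length(t)))
  expect_equal(classify_activity(silent, window = c(2, 10)), "silent")

  # square-wave bursting: 30 s active / 30 s silent
  on <- (t %% 1) < 0.5
  Vb <- ifelse(on, -20 + 10 * sin(2 * pi * t * 300), -65)
  burst <- list(times = t, V = Vb)
  expect_equal(classify_activity(burst, window = c(2, 10)), "bursting")

  # fast periodic spikes that dip below threshold between peaks
  Vc <- ifelse(sin(2 * pi * t * 120) > 0.9, -10, -55)
  cont <- list(times = t, V = Vc)
  expect_equal(classify_activity(cont, window = c(2, 10)), "continuous_spiking")
})

test_that("calcium metrics recover amplitude and period of slow oscillations", {
  t <- seq(0, 40, by = 1 / 600)          # 0.1 s sampling, minutes
  a <- 0.12; p_min <- 5
  ca <- 0.2 + a * sin(2 * pi * t / p_min)
  m <- ca_metrics(list(times = t, Ca_c = ca), window = c(5, 40))
  expect_equal(m$amplitude, 2 * a, tolerance = 0.02 * 2 * a)
  expect_equal(m$period, p_min, tolerance = 0.02 * p_min)
  expect_false(m$abolished)
  expect_equal(m$mean_level, mean(ca[t >= 5]), tolerance = 1e-3)

  flat <- ca_metrics(list(times = t, Ca_c = rep(0.3, length(t))),
                     window = c(5, 40))
  expect_equal(flat$amplitude, 0)
  expect_true(flat$abolished)
})
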