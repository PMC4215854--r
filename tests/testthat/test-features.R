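# brute-force threshold-crossing oracle
brute_spikes <- function(t, v, thr, gap) {
  out <- numeric(0)
  for (i in 2:length(v)) {
    if (v[i] >= thr && v[i - 1] < thr &&
        (length(out) == 0 || t[i] - out[length(out)] >= gap))
      out <- c(out, t[i])
  }
  out
}

# synthetic spiking trace: baseline with triangular spikes at given times
spike_train_trace <- function(spike_times, baseline = -65, peak = 20,
                              width = 2, dt = 0.1, t_end = 3000) {
  t <- seq(0, t_end, by = dt)
  v <- rep(baseline, length(t))
  for (ts in spike_times) {
    idx <- which(t >= ts & t <= ts + width)
    half <- ceiling(length(idx) / 2)
    ramp <- c(seq(0, 1, length.out = half),
              seq(1, 0, length.out = length(idx) - half))
    v[idx] <- baseline + (peak - baseline) * ramp
  }
  fake_trace(t, v, amp = 90)
}

test_that("spike detection counts constructed spikes and tolerates silence", {
  tr <- spike_train_trace(seq(1050, 1950, by = 100))
  expect_length(detect_spikes(tr), 10)
  flat <- fake_trace(seq(0, 3000, 0.1), rep(-70, 30001))
  expect_length(detect_spikes(flat), 0)
})

test_that("spike detection equals a brute-force crossing oracle", {
  set.seed(7)
  for (rep in 1:20) {
    t <- seq(0, 500, by = 0.1)
    v <- -60 + 10 * sin(t / 5) + rnorm(length(t), 0, 8)
    thr <- runif(1, -45, -20)
    gap <- runif(1, 1, 5)
    tr <- fake_trace(t, v, pre = 100, step_dur = 300, post = 100)
    expect_identical(detect_spikes(tr, threshold = thr, refractory = gap),
                     brute_spikes(t, v, thr, gap))
  }
})

test_that("the default registry has the published cardinalities", {
  reg <- measure_registry()
  expect_identical(sum(reg$protocol == "hyp"), 11L)
  expect_identical(sum(reg$protocol == "dep"), 92L)
  expect_identical(nrow(reg), 103L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_true(all(grepl("^(Ini|Pulse|Recov)", reg$name)))
  tf <- tempfile(fileext = ".json")
  registry_to_json(reg, tf)
  expect_true(file.exists(tf))
})

test_that("pulse spike count and firing frequency follow construction", {
  tr <- spike_train_trace(seq(1050, 1950, by = 100))
  m <- extract_measures(tr, protocol = "dep")
  expect_identical(unname(m[["PulseSpikes"]]), 10)
  expect_identical(unname(m[["PulseFiringFreq"]]), 10)
  expect_identical(unname(m[["IniSpikes"]]), 0)
  # spike-shape statistics in spikeless periods are invalid, not zero
  expect_true(is.na(m[["IniSpikeAmplitudeMean"]]))
  expect_true(is.na(m[["RecovISIMode"]]))
  expect_false(is.na(m[["PulseISIMean"]]))
  expect_equal(unname(m[["PulseISIMean"]]), 100, tolerance = 1e-6)
})

test_that("sag amplitude equals steady state minus trough by definition", {
  t <- seq(0, 3000, 0.1)
  v <- rep(-74, length(t))
  pulse <- t >= 1000 & t < 2000
  tp <- t[pulse] - 1000
  v[pulse] <- -82 - 8 * exp(-tp / 120)      # trough -90, settles to -82
  tr <- fake_trace(t, v)
  m <- extract_measures(tr, protocol = "hyp")
  expect_equal(unname(m[["PulsePotSag"]]), 8, tolerance = 0.01)
  expect_equal(unname(m[["PulseVmMin"]]), -90, tolerance = 0.01)
  expect_equal(unname(m[["PulseVmSS"]]), -82, tolerance = 0.01)
})

test_that("sag tau recovery: exact, planted, and noisy cases", {
  mk <- function(tau, noise = 0, seed = 1) {
    set.seed(seed)
    t <- seq(0, 3000, 0.1)
    v <- rep(-74, length(t))
    pulse <- t >= 1000 & t < 2000
    tp <- t[pulse] - 1000
    v[pulse] <- -82 - 10 * exp(-tp / tau)
    v <- v + rnorm(length(v), 0, noise)
    fake_trace(t, v)
  }
  # exact synthetic exponential, tau = 50 ms -> within 1%
  f50 <- fit_sag_tau(mk(50))
  expect_true(f50$ok)
  expect_lt(abs(f50$tau - 50) / 50, 0.01)
  # planted tau = 120 ms -> within 5%
  f120 <- fit_sag_tau(mk(120))
  expect_lt(abs(f120$tau - 120) / 120, 0.05)
  # 0.2 mV gaussian noise, tau = 120 ms -> within 10% (several seeds)
  errs <- vapply(1:5, function(s) {
    f <- fit_sag_tau(mk(120, noise = 0.2, seed = s))
    abs(f$tau - 120) / 120
  }, 1)
  expect_true(all(errs < 0.10))
  # monotonic passive response -> no-sag verdict, not a fit failure
  t <- seq(0, 3000, 0.1)
  v <- rep(-74, length(t))
  pulse <- t >= 1000 & t < 2000
  v[pulse] <- -74 - 16 * (1 - exp(-(t[pulse] - 1000) / 57))
  mono <- fit_sag_tau(fake_trace(t, v))
  expect_false(mono$ok)
  expect_identical(mono$reason, "no sag")
})

test_that("measures are invariant to zero-current padding", {
  tr <- spike_train_trace(seq(1050, 1950, by = 100))
  m1 <- extract_measures(tr, protocol = "dep")
  # pad 500 ms of quiet baseline before and after
  dt <- 0.1
  pad <- rep(-65, 5000)
  t2 <- seq(0, 4000, by = dt)
  v2 <- c(pad, as.numeric(tr$v), pad)[seq_along(t2)]
  tr2 <- fake_trace(t2, v2, pre = 1500, step_dur = 1000, post = 1500,
                    amp = 90)
  m2 <- extract_measures(tr2, protocol = "dep")
  skip_names <- c("PulseFirstSpikeTime", "PulseLastSpikeTime",
                  "RecovFirstSpikeTime")
  for (nm in setdiff(names(m1), skip_names)) {
    if (is.na(m1[[nm]])) expect_true(is.na(m2[[nm]]))
    else expect_equal(m2[[nm]], m1[[nm]], tolerance = 1e-8,
                      label = nm)
  }
})

test_that("sag amplitude is non-negative with a trough, zero only when monotonic", {
  set.seed(21)
  for (rep in 1:10) {
    tau <- runif(1, 30, 300)
    amp <- runif(1, 0, 12)
    t <- seq(0, 3000, 0.2)
    v <- rep(-74, length(t))
    pulse <- t >= 1000 & t < 2000
    tp <- t[pulse] - 1000
    v[pulse] <- -82 - amp * exp(-tp / tau)
    m <- extract_measures(fake_trace(t, v), protocol = "hyp")
    expect_gte(m[["PulsePotSag"]], 0)
  }
})
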