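carbon_spectrum <- function(centers, heights, noise_sd = 1, width = 2,
                            seed = 1L) {
  height_unit <- 1 / (1 - exp(-pi * width / 20000))
  m <- data.frame(center = centers, pattern = "s", j = 0,
                  amplitude = heights / height_unit, width = width,
                  protons = 1L)
  spec <- spectrum_spec(m, noise_sd = noise_sd, field = 100.6,
                        points = 16384L, sweep = 20000, offset_ppm = 100,
                        nucleus = "13C", seed = seed)
  sim <- simulate_fid(spec)
  sp <- estimate_noise(fourier_transform(sim$fid))
  list(spectrum = sp, sim = sim)
}

test_that("greedy picking finds peaks of widely differing amplitude", {
  # pre-transform heights 100, 50, 10 on unit noise
  cs <- carbon_spectrum(c(30, 90, 150), c(100, 50, 10), seed = 91L)
  pk <- pick_peaks_iterative(cs$spectrum)
  hzpt <- 20000 / length(cs$spectrum$ppm)
  for (c0 in c(30, 90, 150))
    expect_lt(min(abs(pk$position - c0)) * 100.6, 2 * hzpt)
  # any surplus picks sit at the noise floor, to be down-weighted by the
  # amplitude grouping (a pointwise 3 sigma stop necessarily admits the
  # occasional ~4 sigma noise excursion)
  extras <- pk[vapply(pk$position, function(p)
    min(abs(c(30, 90, 150) - p)) * 100.6 > 2 * hzpt, logical(1)), ]
  expect_lte(nrow(extras), 3L)
  expect_true(all(extras$amplitude < 5 * cs$spectrum$noise_sigma))

  # spectrum below the stop threshold: empty list
  set.seed(4)
  spn <- new_spectrum(complex(real = rnorm(16384), imaginary = rnorm(16384)),
                      ppm = seq(200, 0, length.out = 16384), sfrq = 100.6,
                      sweep = 20000, nucleus = "13C")
  spn <- estimate_noise(spn)
  pk0 <- pick_peaks_iterative(spn)
  expect_equal(nrow(pk0), 0L)
})

test_that("weak quaternary-like peaks survive among strong ones", {
  hits <- vapply(1:5, function(s) {
    cs <- carbon_spectrum(c(25, 80, 120, 170), c(100, 100, 100, 4),
                          seed = 100L + s)
    pk <- pick_peaks_iterative(cs$spectrum)
    min(abs(pk$position - 170)) * 100.6 < 3
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("amplitude grouping reproduces the nine-carbon worked example", {
  w <- carbon_weight_worked_example(1)
  expect_length(w, 3L)
  expect_equal(unname(w), c(1, 2 / 7, 2 / 17), tolerance = 1e-12)
})

test_that("amplitude grouping degenerate and two-cluster cases", {
  # all equal amplitudes: one group, weight one everywhere
  pk <- data.frame(position = seq(10, 100, length.out = 8), amplitude = 5)
  w <- group_amplitudes_and_weight(pk, 8)
  expect_true(all(w$group == 1L))
  expect_true(all(w$weight == 1))

  # two separated clusters: exactly one interior boundary, matching a
  # brute-force valley search on the same density curve
  set.seed(5)
  amps <- c(rnorm(6, 1, 0.05), rnorm(4, 20, 1))
  pk2 <- data.frame(position = seq(10, 100, length.out = 10),
                    amplitude = amps)
  w2 <- group_amplitudes_and_weight(pk2, 10)
  expect_equal(sort(unique(w2$group)), c(1L, 2L))
  d <- density(log10(amps), bw = "SJ", n = 512L)
  valleys <- which(diff(sign(diff(d$y))) == 2) + 1L
  valleys <- valleys[d$y[valleys] < 0.9 * max(d$y)]
  expect_equal(length(valleys), 1L)
  boundary <- d$x[valleys]
  expect_true(all((log10(amps) > boundary) == (w2$group == 1L)))

  # weights lie in (0, 1] and exactly the top group carries 1
  expect_true(all(w2$weight > 0 & w2$weight <= 1))
  expect_true(all(w2$weight[w2$group == 1L] == 1))
  expect_true(all(w2$weight[w2$group != 1L] < 1))
})

test_that("picker is idempotent on its own rendered output", {
  # construct the spectrum directly so the identical noise vector can be
  # replayed under the rendered model
  n <- 16384L
  ppm <- seq(200, 200 - 20000 / 100.6 * (n - 1) / n, length.out = n)
  lor <- function(c0, a, w) a * (w^2 / 4) / ((ppm - c0)^2 + w^2 / 4)
  y0 <- lor(40, 60, 0.03) + lor(110, 30, 0.03) + lor(160, 15, 0.03)
  set.seed(112)
  noise <- rnorm(n); noise_i <- rnorm(n)
  mk <- function(signal) {
    sp <- new_spectrum(complex(real = signal + noise, imaginary = noise_i),
                       ppm = ppm, sfrq = 100.6, sweep = 20000,
                       nucleus = "13C")
    estimate_noise(sp)
  }
  pk <- pick_peaks_iterative(mk(y0))
  y1 <- numeric(n)
  for (k in seq_len(nrow(pk)))
    y1 <- y1 + lor(pk$position[k], pk$amplitude[k], pk$width[k])
  pk2 <- pick_peaks_iterative(mk(y1))
  expect_equal(nrow(pk2), nrow(pk))
  expect_equal(sort(pk2$position), sort(pk$position),
               tolerance = 2 * 20000 / n / 100.6 / 100)
})

test_that("random 13C spectra: picks recover truth with few extras", {
  n_true <- 0L; n_hit <- 0L; n_extra <- 0L
  for (s in 1:10) {
    cx <- random_carbon_spec(400 + s)
    sim <- simulate_fid(cx$spec)
    sp <- estimate_noise(fourier_transform(sim$fid))
    sp <- baseline_correct(sp)
    pk <- pick_peaks_iterative(sp)
    pk <- group_amplitudes_and_weight(pk, cx$n_carbons)
    tr <- sim$truth$lines$ppm
    n_true <- n_true + length(tr)
    n_hit <- n_hit + sum(vapply(tr, function(p)
      min(abs(pk$position - p)) * 100.6 < 2, logical(1)))
    # extras judged on the module output above its own noise group
    ngrp <- max(pk$group)
    keep <- if (ngrp > 1L) pk$group < ngrp else rep(TRUE, nrow(pk))
    d <- vapply(pk$position[keep], function(p) min(abs(tr - p)) * 100.6,
                numeric(1))
    n_extra <- n_extra + sum(d > 4)
  }
  expect_gte(n_hit / n_true, 0.95)
  expect_lte(n_extra / n_true, 0.10)
})
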