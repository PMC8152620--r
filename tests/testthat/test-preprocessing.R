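test_that("noise estimation is accurate on pure noise and ignores signal", {
  est <- vapply(1:10, function(s) {
    set.seed(s)
    sp <- new_spectrum(complex(real = rnorm(16384), imaginary = rnorm(16384)),
                       ppm = seq(10, 0, length.out = 16384), sfrq = 400,
                       sweep = 4000)
    estimate_noise(sp)$noise_sigma
  }, numeric(1))
  expect_true(all(est > 0.95 & est < 1.05))

  # five strong Lorentzians on top of unit noise: signal excluded
  set.seed(42)
  ppm <- seq(10, 0, length.out = 16384)
  y <- rnorm(16384)
  for (c0 in c(1.5, 3, 5, 7, 8.5))
    y <- y + 100 / (1 + ((ppm - c0) * 400 / 0.8)^2)
  sp <- new_spectrum(complex(real = y, imaginary = rnorm(16384)),
                     ppm = ppm, sfrq = 400, sweep = 4000)
  est <- estimate_noise(sp)$noise_sigma
  expect_true(est > 0.9 && est < 1.1)

  # zero spectrum -> zero sigma
  sp0 <- new_spectrum(complex(real = rep(0, 2048)),
                      ppm = seq(10, 0, length.out = 2048), sfrq = 400,
                      sweep = 4000)
  expect_identical(estimate_noise(sp0)$noise_sigma, 0)
})

test_that("signal classification finds the generating multiplets", {
  cp <- clean_proton_spectrum(rbind(mrow(1.5, "d", 7, 2), mrow(4.0, "s"),
                                    mrow(7.5, "t", 7, 2)),
                              noise_sd = 2, seed = 21L)
  sp <- cp$spectrum
  regions <- classify_signal_regions(sp, sp$noise_sigma)
  # exactly the three generating multiplets among the substantive regions
  # (a low threshold may admit an occasional 1-2 point noise run)
  wide <- regions[regions$end - regions$start + 1L >= 3L, , drop = FALSE]
  expect_equal(nrow(wide), 3L)
  for (c0 in c(1.5, 4.0, 7.5)) {
    i <- which.min(abs(sp$ppm - c0))
    expect_true(any(wide$start <= i & i <= wide$end))
  }

  # pure noise -> empty classification (5 sigma leaves no excursions)
  set.seed(3)
  spn <- new_spectrum(complex(real = rnorm(8192), imaginary = rnorm(8192)),
                      ppm = seq(10, 0, length.out = 8192), sfrq = 400,
                      sweep = 4000, noise_sigma = 1)
  expect_equal(nrow(classify_signal_regions(spn, 1, threshold = 5)), 0L)

  # two nearby runs merge across a small gap
  y <- rep(0, 8192)
  y[4000:4010] <- 100; y[4016:4026] <- 100
  spm <- new_spectrum(complex(real = y), ppm = seq(10, 0, length.out = 8192),
                      sfrq = 400, sweep = 4000)
  merged <- classify_signal_regions(spm, 1, merge_gap_ppm = 10 * 10 / 8192)
  expect_equal(nrow(merged), 1L)
})

test_that("phase correction inverts injected phase errors", {
  base <- rbind(mrow(1.2, "d", 7, 3), mrow(2.6, "s", 0, 2),
                mrow(4.2, "t", 7, 1), mrow(6.4, "s", 0, 1),
                mrow(7.8, "d", 9, 1))

  # zero-order only
  spec <- spectrum_spec(base, noise_sd = 2, phi0 = 30 * pi / 180,
                        seed = 31L)
  sim <- simulate_fid(spec)
  sp <- estimate_noise(fourier_transform(sim$fid))
  pc <- phase_correct(sp)
  expect_lt(abs(pc$phase$phi0 - spec$phi0) * 180 / pi, 2)
  expect_lt(abs(pc$phase$phi1) * 180 / pi, 2)

  # already phased: identity within 2 degrees
  spec0 <- spectrum_spec(base, noise_sd = 2, seed = 32L)
  sim0 <- simulate_fid(spec0)
  sp0 <- estimate_noise(fourier_transform(sim0$fid))
  pc0 <- phase_correct(sp0)
  expect_lt(abs(pc0$phase$phi0) * 180 / pi, 2)
  expect_lt(abs(pc0$phase$phi1) * 180 / pi, 2)

  # mixed-order error over eight multiplets, entropy must not increase
  spec2 <- spectrum_spec(rbind(base, mrow(3.3, "q", 7, 2), mrow(5.3, "s"),
                               mrow(8.6, "t", 8, 1)),
                         noise_sd = 2, phi0 = 20 * pi / 180,
                         phi1 = 80 * pi / 180, seed = 33L)
  sim2 <- simulate_fid(spec2)
  sp2 <- estimate_noise(fourier_transform(sim2$fid))
  pc2 <- phase_correct(sp2)
  expect_lt(abs(pc2$phase$phi0 - spec2$phi0) * 180 / pi, 5)
  expect_lt(abs(pc2$phase$phi1 - spec2$phi1) * 180 / pi, 5)
  expect_lte(attr(pc2$phase, "entropy_final"),
             attr(pc2$phase, "entropy_seed") + 1e-12)
})

test_that("baseline correction removes polynomial drift", {
  spec <- spectrum_spec(rbind(mrow(2.0, "s", 0, 2), mrow(6.0, "d", 8, 1)),
                        noise_sd = 2, baseline = c(40, -120, 160, -80),
                        seed = 41L)
  sim <- simulate_fid(spec)
  sp <- estimate_noise(fourier_transform(sim$fid))
  bc <- baseline_correct(sp)
  regions <- classify_signal_regions(sp, sp$noise_sigma, detrend = TRUE)
  mask <- rep(TRUE, length(sp$ppm))
  for (k in seq_len(nrow(regions)))
    mask[max(1, regions$start[k] - 10):min(length(mask), regions$end[k] + 10)] <- FALSE
  rms <- sqrt(mean(Re(bc$intensity[mask])^2))
  expect_lt(rms, 2 * sp$noise_sigma)
  expect_lt(abs(mean(Re(bc$intensity[mask]))), 0.2 * sp$noise_sigma)

  # flat baseline passes through essentially unchanged
  spec0 <- spectrum_spec(mrow(3.0, "s", 0, 2), noise_sd = 2, seed = 42L)
  sim0 <- simulate_fid(spec0)
  sp0 <- estimate_noise(fourier_transform(sim0$fid))
  bc0 <- baseline_correct(sp0)
  expect_lt(max(abs(Re(bc0$intensity) - Re(sp0$intensity))),
            1.5 * sp0$noise_sigma)

  # model integrals under drift survive within 5 percent of the
  # drift-free value
  fit_total_integral <- function(baseline) {
    spc <- spectrum_spec(mrow(4.5, "t", 7, 2), noise_sd = 1,
                         baseline = baseline, seed = 43L)
    simc <- simulate_fid(spc)
    spx <- estimate_noise(fourier_transform(simc$fid))
    bcx <- estimate_noise(baseline_correct(spx))
    tl <- simc$truth$lines
    model <- fit_region(bcx, data.frame(position = tl$ppm,
                                        height = tl$height))
    sum(gl_component_integral(model$params))
  }
  got <- fit_total_integral(c(30, -60, 90))
  ref <- fit_total_integral(0)
  expect_lt(abs(got - ref) / ref, 0.05)
})
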