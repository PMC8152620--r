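test_that("derivative picking finds all well-resolved lines", {
  # 12 singlet lines at SNR >= 10
  centers <- seq(1, 8.7, length.out = 12)
  cp <- clean_proton_spectrum(mrow(centers, protons = 1L), noise_sd = 8,
                              seed = 51L)
  sp <- cp$spectrum
  picks <- pick_peaks_derivative(sp)
  hzpt <- sp$sweep / length(sp$ppm)
  for (c0 in centers) {
    d <- min(abs(picks$position - c0)) * sp$sfrq
    expect_lte(d, hzpt)
  }
})

test_that("18 Hz multiplet grouping is field-aware and order-invariant", {
  p16 <- data.frame(position = c(1.000, 1.040))   # 16 Hz at 400 MHz
  expect_length(group_multiplets(p16, 400), 1L)
  p40 <- data.frame(position = c(1.000, 1.100))   # 40 Hz
  expect_length(group_multiplets(p40, 400), 2L)
  expect_length(group_multiplets(data.frame(position = 2), 400), 1L)
  # permutation invariance
  set.seed(6)
  pos <- sort(runif(9, 1, 8))
  g1 <- group_multiplets(data.frame(position = pos), 400)
  g2 <- group_multiplets(data.frame(position = sample(pos)), 400)
  expect_equal(lapply(g1, function(g) g$position),
               lapply(g2, function(g) g$position))
  # 16 Hz at 100.6 MHz (13C-like field) is 0.159 ppm: still one group
  p <- data.frame(position = c(100, 100 + 16 / 100.6))
  expect_length(group_multiplets(p, 100.6), 1L)
})

test_that("region deconvolution recovers overlapping Lorentzians", {
  sep_hz <- 6
  m <- rbind(mrow(2.000, amplitude = 1), mrow(2.000 + sep_hz / 400,
                                              amplitude = 0.7))
  cp <- clean_proton_spectrum(m, noise_sd = 0.5, seed = 61L)
  sp <- cp$spectrum
  truth <- cp$sim$truth$lines
  group <- data.frame(position = truth$ppm, height = truth$height)
  model <- fit_region(sp, group)
  expect_true(model$converged)
  for (k in 1:2) {
    j <- which.min(abs(model$params$center - truth$ppm[k]))
    expect_lt(abs(model$params$center[j] - truth$ppm[k]) * 400, 0.3)  # Hz
  }
  # amplitudes within 5 percent (apodization adds 0.3 Hz to the width, so
  # compare integrals, which the apodization preserves less than heights)
  ints <- gl_component_integral(model$params)
  expect_lt(abs(ints[1] / ints[2] - truth$amp[1] / truth$amp[2]), 0.05)

  # a single isolated peak converges immediately
  cp1 <- clean_proton_spectrum(mrow(3.5), noise_sd = 0.5, seed = 62L)
  t1 <- cp1$sim$truth$lines
  m1 <- fit_region(cp1$spectrum, data.frame(position = t1$ppm,
                                            height = t1$height))
  expect_true(m1$converged)
  expect_lte(m1$iterations, 3L)

  # shape mixing absorbs a Gaussian lineshape
  sp2 <- cp1$spectrum
  ppm <- sp2$ppm
  g <- 400 / 400   # 1 ppm wide window around 5.5 ppm
  y <- Re(sp2$intensity)
  y <- y + 80 * exp(-4 * log(2) * ((ppm - 5.5) * 400 / 2.5)^2)
  sp2$intensity <- complex(real = y, imaginary = Im(sp2$intensity))
  mg <- fit_region(sp2, data.frame(position = 5.5, height = 80))
  expect_true(mg$converged)
  expect_lt(mg$params$mixing[which.max(mg$params$amplitude)], 0.5)
})

test_that("BIC pruning deletes noise components and keeps real ones", {
  cp <- clean_proton_spectrum(rbind(mrow(2.0, amplitude = 1),
                                    mrow(2.03, amplitude = 0.7)),
                              noise_sd = 0.03, seed = 71L)
  sp <- cp$spectrum
  truth <- cp$sim$truth$lines
  spike_pos <- 2.0 - 10 / 400
  group <- data.frame(position = c(truth$ppm, spike_pos),
                      height = c(truth$height, 3 * sp$noise_sigma))
  model <- fit_region(sp, group)
  pruned <- prune_noise_bic(model, sp)
  for (p in truth$ppm)
    expect_true(any(abs(pruned$params$center - p) * 400 < 2))
  expect_false(any(abs(pruned$params$center - spike_pos) * 400 < 2 &
                     pruned$params$amplitude > 2 * sp$noise_sigma))

  # region with only true peaks at high SNR: nothing deleted
  model2 <- fit_region(sp, data.frame(position = truth$ppm,
                                      height = truth$height))
  pruned2 <- prune_noise_bic(model2, sp)
  expect_equal(nrow(pruned2$params), nrow(model2$params))

  # all-noise region: everything deleted (checked across seeds elsewhere)
  spn <- clean_proton_spectrum(mrow(7.0, amplitude = 1e-6), noise_sd = 1,
                               seed = 72L)$spectrum
  gn <- data.frame(position = c(4.0, 4.01), height = 3 * spn$noise_sigma)
  mn <- prune_noise_bic(fit_region(spn, gn), spn)
  expect_true(all(mn$params$amplitude < 3 * spn$noise_sigma) ||
                nrow(mn$params) == 0L)
})

test_that("solvent identification removes and references correctly", {
  lib <- fixture_library()
  sim <- simulate_fid(lib$h_solvent_chcl3)
  out <- process_proton(fourier_transform(sim$fid), total_protons = 5L,
                        solvent = "chloroform")
  expect_lt(abs(out$solvent_shift - (-0.03)), 0.002)
  got <- multiplet_table(out$multiplets)
  # solvent singlet removed; every solute center carries the referencing
  # shift (the axis moves so the solvent lands exactly on 7.26)
  expect_false(any(abs(got$center - 7.26) < 0.05))
  for (c0 in lib$h_solvent_chcl3$multiplets$center)
    expect_true(any(abs(got$center - (c0 + out$solvent_shift)) < 0.005))

  # no candidate in the window: nothing removed, zero shift, warning
  mult <- list(mk_mult(1, center = 2.0))
  spn <- clean_proton_spectrum(mrow(2.0), noise_sd = 0.5, seed = 81L)$spectrum
  expect_warning(
    res <- remove_solvent_and_reference(mult, "chloroform", spn),
    "window")
  expect_equal(res$shift, 0)
  expect_length(res$multiplets, 1L)

  # DMSO quintet pattern beats a nearby solute singlet on pattern score
  entry <- solvent_table()$dmso
  quintet <- list(center = 2.52,
                  peaks = data.frame(center = 2.52 + (-2:2) * 1.9 / 400,
                                     amplitude = c(1, 2, 3, 2, 1)))
  singlet <- list(center = 2.48,
                  peaks = data.frame(center = 2.48, amplitude = 3))
  s_q <- nmrdp4:::solvent_candidate_score(quintet, entry)
  s_s <- nmrdp4:::solvent_candidate_score(singlet, entry)
  expect_gt(s_q, s_s)
})

test_that("integral normalization matches the brute-force search", {
  ni <- normalize_integrals(lapply(c(1.02, 1.51, 0.49), mk_mult), 6L, 0L)
  expect_equal(vapply(ni$multiplets, `[[`, integer(1), "proton_count"),
               c(2L, 3L, 1L))
  orc <- oracle_normalize(c(1.02, 1.51, 0.49), 6L, 0L)
  expect_equal(ni$n_protons, orc$n)

  # exact integrals stay exact
  ni2 <- normalize_integrals(lapply(c(1, 2, 3), mk_mult), 6L, 0L)
  expect_equal(vapply(ni2$multiplets, `[[`, integer(1), "proton_count"),
               c(1L, 2L, 3L))

  # one labile OH: the search starts at total - labile
  ni3 <- normalize_integrals(lapply(c(2.9, 2.1, 1.05), mk_mult), 7L, 1L)
  expect_equal(vapply(ni3$multiplets, `[[`, integer(1), "proton_count"),
               c(3L, 2L, 1L))
  expect_equal(ni3$n_protons,
               oracle_normalize(c(2.9, 2.1, 1.05), 7L, 1L)$n)

  # randomized agreement with the oracle, ties resolved to the smaller n
  set.seed(9)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    counts <- sample(1:3, k, replace = TRUE)
    raw <- counts * runif(1, 0.5, 2) + rnorm(k, 0, 0.03)
    total <- sum(counts)
    ni <- normalize_integrals(lapply(raw, mk_mult), total, 0L)
    orc <- oracle_normalize(raw, total, 0L)
    expect_equal(ni$n_protons, orc$n)
  }

  # degenerate single-multiplet input warns and takes the smallest total
  expect_warning(nd <- normalize_integrals(list(mk_mult(2.2)), 4L, 1L),
                 "degenerate")
  expect_equal(nd$n_protons, 3L)
})
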