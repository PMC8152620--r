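# shared fixtures and independent oracles

# minimal multiplet list entry as built by build_multiplets()
mk_mult <- function(raw_integral, center = 1, peaks = NULL,
                    proton_count = NA_integer_) {
  list(center = center, raw_integral = raw_integral, peaks = peaks,
       proton_count = proton_count)
}

# independent brute-force oracle for the integral-normalization search:
# plain loop over candidate totals, integer-likeness scored directly
oracle_normalize <- function(raw, total, labile, floor = 0.2) {
  best_n <- NA_integer_
  best_score <- -Inf
  for (n in seq.int(max(1L, total - labile), 2L * total)) {
    scaled <- raw / sum(raw) * n
    terms <- pmax(1 - 2 * abs(scaled - round(scaled)), floor)
    score <- exp(mean(log(terms)))
    if (score > best_score + 1e-12) {
      best_score <- score
      best_n <- n
    }
  }
  scaled <- raw / sum(raw) * best_n
  list(n = best_n, counts = as.integer(round(scaled)))
}

# one clean absorption spectrum with known lines, no artifacts
clean_proton_spectrum <- function(multiplets, noise_sd = 1, seed = 1L,
                                  lb = 0.3) {
  spec <- spectrum_spec(multiplets, noise_sd = noise_sd, seed = seed)
  sim <- simulate_fid(spec)
  sp <- fourier_transform(sim$fid, line_broadening = lb)
  sp <- estimate_noise(sp)
  list(spectrum = sp, sim = sim, spec = spec)
}

# simple multiplet table row
mrow <- function(center, pattern = "s", j = 0, protons = 1L,
                 amplitude = 1, width = 1.6) {
  data.frame(center = center, pattern = pattern, j = j,
             amplitude = amplitude, width = width, protons = protons)
}
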