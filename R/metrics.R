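# Recovery and oracle-equivalence metrics on freshly generated synthetic
# data.  Shared by run_simulation_suite(), the test suite and the
# acceptance script so that every reported number is recomputed from
# scratch by the same code path.

#' Exhaustive-search linear sum assignment (reference oracle)
#'
#' Minimizes total cost over all row-to-column injections by explicit
#' permutation enumeration; exponential, for cross-checking
#' [solve_assignment()] on small instances only.
#'
#' @param cost numeric cost matrix with `nrow <= ncol`, `ncol` at most 8.
#' @return integer assignment vector with attribute `"cost"`.
#' @export
exhaustive_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 8L)
  perms <- permutations_of(m)
  perms <- perms[, seq_len(n), drop = FALSE]   # injections rows -> cols
  costs <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(n), p)]))
  best <- which.min(costs)
  structure(as.integer(perms[best, ]), cost = costs[best])
}

permutations_of <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  r <- 0L
  for (k in seq_len(m)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- k
    rest <- setdiff(seq_len(m), k)
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), m - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Hungarian vs exhaustive-search agreement rate
#'
#' Random probability matrices (2 to 7 shifts, up to 7 peaks); agreement
#' means equal total cost to within 1e-9.
#'
#' @param seed RNG seed.
#' @param n_instances number of random instances.
#' @return fraction of instances in exact agreement.
#' @export
hungarian_oracle_check <- function(seed, n_instances = 1000L) {
  set.seed(seed)
  ok <- logical(n_instances)
  for (i in seq_len(n_instances)) {
    n <- sample(2:7, 1L)
    m <- if (n == 7L) 7L else sample(n:7, 1L)
    M <- matrix(runif(n * m, 1e-6, 1), n, m)
    cost <- -log(M)
    a <- solve_assignment(cost)
    b <- exhaustive_assignment(cost)
    ok[i] <- abs(attr(a, "cost") - attr(b, "cost")) < 1e-9
  }
  mean(ok)
}

#' Phase-recovery rate over random dephased spectra
#'
#' Each replicate draws a random multiplet layout with
#' phi0 ~ U(-pi, pi) and phi1 ~ U(-90, 90) degrees, simulates the FID,
#' transforms and rephases it; success means both parameters recovered
#' within `tol_deg` degrees (phi0 compared on the circle).
#'
#' @param seed RNG seed.
#' @param n replicates.
#' @param tol_deg tolerance, degrees.
#' @return fraction recovered; attribute `"entropy_ok"` reports the
#'   fraction of replicates where the refinement stage did not increase
#'   the entropy objective.
#' @export
phase_recovery_rate <- function(seed, n = 100L, tol_deg = 5) {
  ok <- logical(n)
  ent_ok <- logical(n)
  for (i in seq_len(n)) {
    spec <- random_proton_spec(seed + i, n_multiplets = c(4L, 10L),
                               snr = 25, phase = TRUE)
    sim <- simulate_fid(spec)
    sp <- fourier_transform(sim$fid)
    sp <- estimate_noise(sp)
    pc <- phase_correct(sp)
    d0 <- abs(wrap_phase(pc$phase$phi0 - sim$truth$phi0)) * 180 / pi
    d1 <- abs(pc$phase$phi1 - sim$truth$phi1) * 180 / pi
    ok[i] <- d0 <= tol_deg && d1 <= tol_deg
    ent_ok[i] <- attr(pc$phase, "entropy_final") <=
      attr(pc$phase, "entropy_seed") + 1e-12
  }
  structure(mean(ok), entropy_ok = mean(ent_ok))
}

#' Multiplet-center and proton-count recovery on random 1H spectra
#'
#' Full pipeline (transform, phase, baseline, pick, fit, prune, normalize)
#' on random 3-15 multiplet spectra at SNR >= 8; a true multiplet is
#' recovered when some reported multiplet center lies within `tol_hz` of
#' it, and counted correct when its proton count matches exactly.
#'
#' @param seed RNG seed.
#' @param n replicates.
#' @param tol_hz center tolerance, Hz.
#' @return list with `center_rate`, `count_rate`, `false_rate` (spurious
#'   multiplets as a fraction of true ones) and the per-replicate detail.
#' @export
proton_recovery_rates <- function(seed, n = 100L, tol_hz = 1) {
  n_true <- 0L; n_center <- 0L; n_count <- 0L; n_false <- 0L
  for (i in seq_len(n)) {
    spec <- random_proton_spec(seed + i, snr = 8 + (i %% 5) * 5)
    sim <- simulate_fid(spec)
    sp <- fourier_transform(sim$fid)
    out <- process_proton(sp, total_protons = sum(spec$multiplets$protons),
                          labile_protons = 0L, solvent = NULL)
    got <- multiplet_table(out$multiplets)
    truth <- spec$multiplets
    n_true <- n_true + nrow(truth)
    used <- rep(FALSE, nrow(got))
    for (k in seq_len(nrow(truth))) {
      if (!nrow(got)) break
      d_hz <- abs(got$center - truth$center[k]) * spec$field
      j <- which.min(d_hz)
      if (d_hz[j] <= tol_hz) {
        n_center <- n_center + 1L
        if (!is.na(got$proton_count[j]) &&
            got$proton_count[j] == truth$protons[k])
          n_count <- n_count + 1L
        used[j] <- TRUE
      }
    }
    n_false <- n_false + sum(!used)
  }
  list(center_rate = n_center / n_true, count_rate = n_count / n_true,
       false_rate = n_false / n_true)
}

#' Noise-spike removal rate of the BIC pruning step
#'
#' Each trial simulates a spectrum with true peaks (SNR >= 10) and forces
#' the deconvolution to include an extra component at a signal-free
#' position (a pure-noise spike pick); success means the spike is deleted
#' while every true peak survives.
#'
#' @param seed RNG seed.
#' @param n trials.
#' @return fraction of successful trials.
#' @export
bic_prune_rate <- function(seed, n = 50L) {
  ok <- logical(n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    width <- 1.6
    mult <- data.frame(center = c(2.0, 2.03), pattern = "s", j = 0,
                       amplitude = c(1, 0.7), width = width,
                       protons = 1L)
    spec <- spectrum_spec(mult, noise_sd = 0, seed = seed + i)
    height <- (1 - exp(-pi * width / spec$sweep))^-1
    spec$noise_sd <- min(mult$amplitude) * height / 50   # SNR ~50
    sim <- simulate_fid(spec)
    sp <- fourier_transform(sim$fid)
    sp <- estimate_noise(sp)
    # true picks plus one spike on pure noise 10 Hz upfield
    group <- data.frame(position = c(2.0, 2.03, 2.0 - 10 / spec$field),
                        height = c(sim$truth$lines$height[1:2],
                                   3 * sp$noise_sigma))
    model <- fit_region(sp, group)
    pruned <- prune_noise_bic(model, sp)
    true_kept <- all(vapply(c(2.0, 2.03), function(c0)
      any(abs(pruned$params$center - c0) * spec$field < 2), logical(1)))
    spike_gone <- !any(abs(pruned$params$center - (2.0 - 10 / spec$field)) *
                         spec$field < 2 &
                         pruned$params$amplitude > 2 * sp$noise_sigma)
    ok[i] <- true_kept && spike_gone
  }
  mean(ok)
}

#' End-to-end DP4 recovery rate on the bundled fixture library
#'
#' Each fixture spectrum is processed once; per replicate a fresh
#' candidate set (the true isomer plus decoys perturbed by
#' `decoy_sd_multiple` times the error-model sd) is simulated, assigned
#' and ranked. Success means the true candidate gets the highest DP4.
#'
#' @param seed RNG seed.
#' @param n replicates (spread across the fixtures).
#' @param n_decoys decoys per replicate.
#' @param decoy_sd_multiple decoy perturbation in error-model sds.
#' @return fraction of replicates won by the true candidate.
#' @export
dp4_recovery_rate <- function(seed, n = 100L, n_decoys = 3L,
                              decoy_sd_multiple = 5) {
  lib <- fixture_library()
  cases <- list()

  # 13C fixtures: process once, true shifts = generating line positions
  for (nm in c("c_sparse", "c_degenerate", "c_quaternary")) {
    fx <- lib[[nm]]
    sim <- simulate_fid(fx$spec)
    sp <- fourier_transform(sim$fid)
    sp <- estimate_noise(sp)
    sp <- baseline_correct(sp)
    pk <- pick_peaks_iterative(sp)
    pk <- group_amplitudes_and_weight(pk, fx$n_carbons)
    true_shifts <- rep(sim$truth$multiplets$center, fx$degeneracy)
    cases[[nm]] <- list(
      nucleus = "13C", peaks = pk,
      truth = data.frame(label = paste0("C", seq_along(true_shifts)),
                         shift = true_shifts),
      model = default_error_model("13C"))
  }

  # one 1H fixture with >= 10 assignable protons
  fx <- lib$h_clean_6
  sim <- simulate_fid(fx)
  sp <- fourier_transform(sim$fid)
  out <- process_proton(sp, total_protons = sum(fx$multiplets$protons),
                        labile_protons = 0L, solvent = NULL)
  tm <- fx$multiplets
  labels <- unlist(lapply(seq_len(nrow(tm)), function(k)
    paste0("H", k, "_", seq_len(tm$protons[k]))))
  shifts <- rep(tm$center, tm$protons)
  methyls <- lapply(which(tm$pattern == "s" & tm$protons == 3L),
                    function(k) paste0("H", k, "_", 1:3))
  cases$h_clean_6 <- list(
    nucleus = "1H", multiplets = out$multiplets,
    truth = data.frame(label = labels, shift = shifts),
    methyls = methyls, model = default_error_model("1H"))

  wins <- logical(n)
  for (i in seq_len(n)) {
    case <- cases[[(i - 1L) %% length(cases) + 1L]]
    sd1 <- case$model$sds[1]
    cc <- simulate_candidates(
      case$truth, n_decoys = n_decoys,
      decoy_perturbation = decoy_sd_multiple * sd1,
      model = case$model, scaling = c(1.03, 0.02 * sd1 * 10),
      seed = seed + i, nucleus = case$nucleus,
      methyl_groups = if (case$nucleus == "1H") case$methyls else list())
    errs <- lapply(cc$candidates, function(cand) {
      a <- if (case$nucleus == "13C")
        assign_carbons(cand, case$peaks, model = case$model)
      else
        assign_protons(cand, case$multiplets, model = case$model)
      setNames(list(a$table$error), case$nucleus)
    })
    r <- dp4(errs, models = setNames(list(case$model), case$nucleus))
    wins[i] <- r$candidate[which.max(r$dp4)] == cc$truth_id
  }
  mean(wins)
}

#' Gaussian-mixture parameter recovery error
#'
#' Fits a 3-component mixture to draws from a known 3-Gaussian error model
#' and reports the largest absolute deviation of the recovered component
#' means after label alignment.
#'
#' @param seed RNG seed.
#' @param n_draws sample size.
#' @return max absolute mean error, ppm.
#' @export
mixture_mean_recovery_error <- function(seed, n_draws = 10000L) {
  true <- error_model("13C", means = c(-5, 0, 5), sds = c(1, 1.2, 1),
                      weights = c(0.25, 0.5, 0.25))
  set.seed(seed)
  draws <- sample_errors(n_draws, true)
  fit <- fit_error_model(draws, n_components = 3L, nucleus = "13C",
                         seed = seed)
  got <- sort(fit$means)
  max(abs(got - sort(true$means)))
}

#' Worked 13C amplitude-weighting example
#'
#' Builds the 17-peak instance (ten peaks near amplitude 1, five near 5,
#' two near 10) for a 9-carbon structure, runs the KDE grouping and
#' returns the normalized per-group weights (most to least intense).
#'
#' @param seed RNG seed for the small amplitude jitter.
#' @return numeric vector of group weights.
#' @export
carbon_weight_worked_example <- function(seed = 1L) {
  set.seed(seed)
  amps <- c(rnorm(10, 1, 0.03), rnorm(5, 5, 0.1), rnorm(2, 10, 0.15))
  peaks <- data.frame(position = seq(10, 170, length.out = 17),
                      amplitude = amps)
  w <- group_amplitudes_and_weight(peaks, n_carbons = 9)
  out <- unique(w[order(w$group), c("group", "weight")])
  setNames(out$weight, paste0("group", out$group))
}
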