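# Synthetic ground-truth fixtures: raw FIDs built from sums of damped
# complex sinusoids (binomial multiplet patterns), with injected phase
# error, polynomial baseline, solvent peak and Gaussian noise; plus
# calculated-shift tables corrupted by a known linear map and drawn errors.

#' Specification of a synthetic spectrum
#'
#' @param multiplets data.frame with columns `center` (ppm), `pattern`
#'   (`"s"`, `"d"`, `"t"`, `"q"`, `"quint"`), `j` (Hz), `amplitude`
#'   (relative intensity scale, default 1), `width` (FWHM, Hz), `protons`
#'   (integer; line amplitudes are scaled so the multiplet integral is
#'   proportional to `amplitude * protons`).
#' @param noise_sd frequency-domain Gaussian noise sd (per real/imaginary
#'   component), in spectrum intensity units.
#' @param phi0,phi1 injected phase error, radians (first-order across the
#'   displayed spectrum).
#' @param baseline polynomial coefficients (constant first) of an additive
#'   real baseline in the fractional display coordinate `x` in `[0, 1]`.
#' @param solvent NULL or a list `list(name=, offset_ppm=, amplitude=)`
#'   describing a residual solvent multiplet displaced by `offset_ppm`
#'   from its reference position.
#' @param field spectrometer frequency, MHz.
#' @param points acquired complex points.
#' @param sweep sweep width, Hz.
#' @param offset_ppm carrier position, ppm.
#' @param nucleus `"1H"` or `"13C"`.
#' @param group_delay digital-filter group delay, points.
#' @param seed RNG seed; a fixed seed makes the fixture bit-reproducible.
#' @return an object of class `SpectrumSpec`.
#' @export
spectrum_spec <- function(multiplets, noise_sd = 0, phi0 = 0, phi1 = 0,
                          baseline = 0, solvent = NULL, field = 400,
                          points = 8192L, sweep = 4000, offset_ppm = 5,
                          nucleus = "1H", group_delay = 0L, seed = 1L) {
  stopifnot(is.data.frame(multiplets) || is.null(multiplets))
  if (is.null(multiplets))
    multiplets <- data.frame(center = numeric(0), pattern = character(0),
                             j = numeric(0), amplitude = numeric(0),
                             width = numeric(0), protons = integer(0))
  if (!"pattern" %in% names(multiplets)) multiplets$pattern <- "s"
  if (!"j" %in% names(multiplets)) multiplets$j <- 0
  if (!"amplitude" %in% names(multiplets)) multiplets$amplitude <- 1
  if (!"width" %in% names(multiplets)) multiplets$width <- 1.5
  if (!"protons" %in% names(multiplets)) multiplets$protons <- 1L
  lo <- (offset_ppm * field - sweep / 2) / field
  hi <- (offset_ppm * field + sweep / 2) / field
  if (nrow(multiplets) &&
      any(multiplets$center <= lo | multiplets$center >= hi))
    stop("multiplet centers must lie within the sweep (",
         sprintf("%.2f..%.2f ppm", lo, hi), ")")
  structure(list(multiplets = multiplets, noise_sd = noise_sd, phi0 = phi0,
                 phi1 = phi1, baseline = baseline, solvent = solvent,
                 field = field, points = as.integer(points), sweep = sweep,
                 offset_ppm = offset_ppm, nucleus = nucleus,
                 group_delay = as.integer(group_delay),
                 seed = as.integer(seed)),
            class = "SpectrumSpec")
}

# draw one integer from an inclusive range (safe for degenerate ranges)
sample_range <- function(r) {
  if (r[1] >= r[2]) return(as.integer(r[1]))
  sample(seq.int(r[1], r[2]), 1L)
}

binomial_pattern <- function(pattern) {
  switch(pattern,
         s = 1, d = c(1, 1), t = c(1, 2, 1), q = c(1, 3, 3, 1),
         quint = c(1, 4, 6, 4, 1),
         stop("unknown multiplet pattern '", pattern, "'"))
}

# expand a multiplet table into individual lines
expand_lines <- function(multiplets, field, solvent = NULL,
                         table = solvent_table()) {
  rows <- list()
  add <- function(center, pattern, j, scale, width, id, kind) {
    rel <- binomial_pattern(pattern)
    L <- length(rel)
    offs <- (seq_len(L) - (L + 1) / 2) * j / field
    data.frame(ppm = center + offs, amp = scale * rel / sum(rel),
               width = width, multiplet = id, kind = kind)
  }
  for (k in seq_len(nrow(multiplets))) {
    m <- multiplets[k, ]
    rows[[length(rows) + 1L]] <-
      add(m$center, m$pattern, m$j, m$amplitude * m$protons, m$width,
          k, "solute")
  }
  if (!is.null(solvent)) {
    entry <- table[[solvent$name]]
    if (is.null(entry)) stop("unknown solvent '", solvent$name, "'")
    pat <- c(s = "s", d = "d", t = "t", q = "q")
    pattern <- switch(as.character(length(entry$pattern)),
                      "1" = "s", "5" = "quint",
                      stop("unsupported solvent pattern length"))
    rows[[length(rows) + 1L]] <-
      add(entry$ref + solvent$offset_ppm, pattern, entry$j_hz,
          solvent$amplitude, 1.2, 0L, "solvent")
  }
  do.call(rbind, rows)
}

#' Simulate a raw FID with ground truth
#'
#' The ideal FID is the sum of damped complex sinusoids (one per multiplet
#' line, binomial intensities); phase error, polynomial baseline and
#' complex Gaussian noise are injected in the frequency domain and the
#' result inverted back to the time domain, so that [transform()] with no
#' line broadening reproduces the corrupted spectrum exactly.
#'
#' @param spec a [spectrum_spec()].
#' @return list with `fid` (a [raw_fid()]), `truth` (list: `lines` with
#'   per-line ppm/amplitude/width/height, `multiplets`, `phi0`, `phi1`,
#'   `baseline`, `solvent`, `noise_sd`) and `spec`.
#' @export
simulate_fid <- function(spec) {
  stopifnot(inherits(spec, "SpectrumSpec"))
  set.seed(spec$seed)
  N <- spec$points
  sw <- spec$sweep
  o1 <- spec$offset_ppm * spec$field
  t <- (seq_len(N) - 1) / sw

  lines <- expand_lines(spec$multiplets, spec$field, spec$solvent)
  fid0 <- complex(real = rep(0, N))
  if (!is.null(lines) && nrow(lines)) {
    for (k in seq_len(nrow(lines))) {
      f <- lines$ppm[k] * spec$field - o1
      fid0 <- fid0 + lines$amp[k] *
        exp((2i * pi * f - pi * lines$width[k]) * t)
    }
    lines$height <- lines$amp / (1 - exp(-pi * lines$width / sw))
  }

  # to frequency domain (display order), inject artifacts, invert
  x <- fid0
  x[1] <- x[1] / 2
  X <- fft(x)
  half <- N / 2
  S_asc <- c(X[(half + 1):N], X[1:half])
  S <- rev(S_asc)                                 # descending ppm
  xs <- (seq_len(N) - 1) / (N - 1)
  S <- S * exp(1i * (spec$phi0 + spec$phi1 * xs))
  base <- numeric(N)
  for (p in seq_along(spec$baseline))
    base <- base + spec$baseline[p] * xs^(p - 1)
  S <- S + base
  if (spec$noise_sd > 0)
    S <- S + complex(real = rnorm(N, 0, spec$noise_sd),
                     imaginary = rnorm(N, 0, spec$noise_sd))
  S_asc <- rev(S)
  X <- c(S_asc[(half + 1):N], S_asc[1:half])
  xfid <- fft(X, inverse = TRUE) / N
  xfid[1] <- 2 * xfid[1]                          # undo first-point halving
  if (spec$group_delay > 0L) {
    gd <- spec$group_delay %% N
    xfid <- c(xfid[(N - gd + 1L):N], xfid[1:(N - gd)])
  }

  solvent_name <- if (is.null(spec$solvent)) "chloroform" else
    spec$solvent$name
  fid <- raw_fid(points = xfid, sfrq = spec$field, sweep = sw, offset = o1,
                 nucleus = spec$nucleus, solvent = solvent_name,
                 group_delay = spec$group_delay)
  truth <- list(lines = lines, multiplets = spec$multiplets,
                phi0 = spec$phi0, phi1 = spec$phi1,
                baseline = spec$baseline, solvent = spec$solvent,
                noise_sd = spec$noise_sd)
  list(fid = fid, truth = truth, spec = spec)
}

#' Write a simulated fixture to disk
#'
#' Bruker-dialect directory plus a JSON ground-truth file.
#'
#' @param sim result of [simulate_fid()].
#' @param directory_path output directory.
#' @return `directory_path`, invisibly.
#' @export
write_fixture <- function(sim, directory_path) {
  write_bruker(sim$fid, directory_path)
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(directory_path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory_path)
}

#' Random 1H spectrum specification
#'
#' Draws 3-15 multiplets with random singlet/doublet/triplet/quartet
#' patterns, centers at least 60 Hz apart (outside the solvent window),
#' J in 4-12 Hz, 1-3 protons each (quartet-free methyls as singlets), and
#' sets the noise so the weakest line has at least the requested
#' signal-to-noise ratio.
#'
#' @param seed RNG seed.
#' @param n_multiplets integer range to draw from.
#' @param snr minimum line signal-to-noise ratio.
#' @param phase logical: inject a random phase error
#'   (phi0 ~ U(-pi, pi), phi1 ~ U(-90, 90) degrees)?
#' @param baseline logical: inject a random cubic baseline?
#' @param solvent NULL or solvent name for an injected solvent peak.
#' @return a [spectrum_spec()].
#' @export
random_proton_spec <- function(seed, n_multiplets = c(3L, 15L), snr = 10,
                               phase = FALSE, baseline = FALSE,
                               solvent = NULL) {
  set.seed(seed)
  nm <- sample_range(n_multiplets)
  field <- 400
  # centers >= 60 Hz apart, away from the solvent window around 7.26
  repeat {
    centers <- sort(runif(nm, 0.8, 6.5))
    if (nm == 1L || min(diff(centers)) * field >= 60) break
  }
  patterns <- sample(c("s", "d", "t", "q"), nm, replace = TRUE)
  protons <- ifelse(patterns == "s", sample(c(1L, 2L, 3L), nm, replace = TRUE),
                    sample(c(1L, 2L), nm, replace = TRUE))
  mult <- data.frame(center = centers, pattern = patterns,
                     j = runif(nm, 4, 12), amplitude = 1,
                     width = runif(nm, 1.2, 2.0), protons = protons)
  lines <- expand_lines(mult, field)
  min_amp <- min(lines$amp)
  min_height <- min_amp / (1 - exp(-pi * max(mult$width) / 4000))
  noise_sd <- min_height / snr
  ph0 <- if (phase) runif(1, -pi, pi) else 0
  ph1 <- if (phase) runif(1, -pi / 2, pi / 2) else 0
  bl <- if (baseline) rnorm(4, 0, 20 * noise_sd) else 0
  sol <- if (!is.null(solvent))
    list(name = solvent, offset_ppm = runif(1, -0.05, 0.05),
         amplitude = runif(1, 0.5, 2)) else NULL
  spectrum_spec(mult, noise_sd = noise_sd, phi0 = ph0, phi1 = ph1,
                baseline = bl, solvent = sol, field = field,
                points = 8192L, sweep = 4000, offset_ppm = 5,
                nucleus = "1H", seed = seed + 1000L)
}

#' Random 13C spectrum specification
#'
#' 10-40 carbons, about 10 percent degenerate pairs (two carbons on one
#' line), peak heights spanning the requested signal-to-noise range
#' (quaternary-like weak peaks included).
#'
#' @param seed RNG seed.
#' @param n_carbons integer range.
#' @param snr range of per-peak signal-to-noise ratios.
#' @return list with `spec` (a [spectrum_spec()]) and `n_carbons`.
#' @export
random_carbon_spec <- function(seed, n_carbons = c(10L, 40L),
                               snr = c(5, 100)) {
  set.seed(seed)
  nc <- sample_range(n_carbons)
  n_degen <- max(0L, round(0.1 * nc / 2))
  n_lines <- nc - n_degen
  field <- 100.6
  repeat {
    centers <- sort(runif(n_lines, 10, 190))
    if (n_lines == 1L || min(diff(centers)) * field >= 40) break
  }
  degen <- sample(c(rep(2L, n_degen), rep(1L, n_lines - n_degen)))
  width <- 2.0
  sweep <- 20000
  height_unit <- 1 / (1 - exp(-pi * width / sweep))
  snr_per <- runif(n_lines, snr[1], snr[2])
  noise_sd <- 1
  amps <- snr_per * noise_sd / height_unit * degen
  mult <- data.frame(center = centers, pattern = "s", j = 0,
                     amplitude = amps, width = width, protons = 1L)
  spec <- spectrum_spec(mult, noise_sd = noise_sd, field = field,
                        points = 16384L, sweep = sweep, offset_ppm = 100,
                        nucleus = "13C", seed = seed + 2000L)
  list(spec = spec, n_carbons = nc, degeneracy = degen)
}

#' Simulate candidate shift tables
#'
#' The true candidate's calculated shifts are `slope * true + intercept`
#' plus draws from the error model; each decoy is additionally perturbed
#' per atom by a Gaussian of the stated sd. Candidate order is shuffled;
#' the truth label is returned for recovery scoring.
#'
#' @param true_shifts data.frame with `label` and `shift` (the true
#'   experimental shifts), or a named numeric vector.
#' @param n_decoys number of decoy candidates.
#' @param decoy_perturbation per-atom perturbation sd, ppm.
#' @param model an [error_model()] for the prediction errors.
#' @param scaling `c(slope, intercept)` systematic linear corruption.
#' @param seed RNG seed.
#' @param nucleus stored on the candidates.
#' @param methyl_groups,labile passed through to [candidate_shifts()].
#' @return list with `candidates` (list of `CandidateShifts`) and
#'   `truth_id`.
#' @export
simulate_candidates <- function(true_shifts, n_decoys = 1L,
                                decoy_perturbation = 10,
                                model = default_error_model("13C"),
                                scaling = c(1.05, 2.0), seed = 1L,
                                nucleus = "13C", methyl_groups = list(),
                                labile = NULL) {
  stopifnot(n_decoys >= 0L)
  set.seed(seed)
  if (!is.data.frame(true_shifts))
    true_shifts <- data.frame(label = names(true_shifts),
                              shift = as.numeric(true_shifts))
  na <- nrow(true_shifts)
  mk <- function(id, extra_sd) {
    shift <- scaling[1] * true_shifts$shift + scaling[2] +
      sample_errors(na, model)
    if (extra_sd > 0) shift <- shift + rnorm(na, 0, extra_sd)
    candidate_shifts(id, nucleus,
                     data.frame(label = true_shifts$label, shift = shift),
                     methyl_groups = methyl_groups, labile = labile)
  }
  cands <- c(list(mk("true", 0)),
             lapply(seq_len(n_decoys), function(k)
               mk(sprintf("decoy%02d", k), decoy_perturbation)))
  ord <- sample(length(cands))
  cands <- cands[ord]
  names(cands) <- vapply(cands, `[[`, character(1), "candidate_id")
  list(candidates = cands, truth_id = "true")
}

#' Bundled fixture library
#'
#' Twelve named synthetic specifications spanning clean, noisy, overlapped
#' and solvent-contaminated 1H cases plus sparse, degenerate and
#' quaternary-carbon 13C cases.
#'
#' @return named list; 1H entries are [spectrum_spec()] objects, 13C
#'   entries are lists as returned by [random_carbon_spec()].
#' @export
fixture_library <- function() {
  h <- function(...) spectrum_spec(...)
  m <- function(center, pattern, j, protons, width = 1.6, amplitude = 1)
    data.frame(center = center, pattern = pattern, j = j,
               amplitude = amplitude, width = width, protons = protons)
  list(
    h_clean_3 = h(rbind(m(1.2, "d", 7, 3), m(2.6, "q", 7, 1),
                        m(4.1, "s", 0, 2)),
                  noise_sd = 2, seed = 101L),
    h_clean_6 = h(rbind(m(0.9, "t", 7, 3), m(1.8, "s", 0, 2),
                        m(2.4, "d", 8, 1), m(3.6, "s", 0, 3),
                        m(4.9, "t", 6, 1), m(6.4, "d", 9, 1)),
                  noise_sd = 2, seed = 102L),
    h_noisy = h(rbind(m(1.1, "d", 7, 3), m(2.2, "s", 0, 2),
                      m(3.3, "t", 7, 2), m(5.1, "s", 0, 1)),
                noise_sd = 25, seed = 103L),
    h_overlapped = h(rbind(m(2.00, "d", 8, 1), m(2.08, "t", 7, 1),
                           m(3.5, "s", 0, 3)),
                     noise_sd = 2, seed = 104L),
    h_solvent_chcl3 = h(rbind(m(1.3, "d", 7, 3), m(3.9, "q", 7, 1),
                              m(6.8, "s", 0, 1)),
                        noise_sd = 2,
                        solvent = list(name = "chloroform",
                                       offset_ppm = 0.03, amplitude = 1),
                        seed = 105L),
    h_solvent_dmso = h(rbind(m(1.0, "t", 7, 3), m(3.4, "s", 0, 2)),
                       noise_sd = 2,
                       solvent = list(name = "dmso", offset_ppm = -0.02,
                                      amplitude = 2),
                       seed = 106L),
    h_methyl_rich = h(rbind(m(0.95, "s", 0, 3), m(1.15, "s", 0, 3),
                            m(2.3, "s", 0, 2), m(4.4, "s", 0, 1)),
                      noise_sd = 2, seed = 107L),
    h_phased = h(rbind(m(1.4, "d", 7, 3), m(2.9, "s", 0, 2),
                       m(5.6, "t", 7, 1)),
                 noise_sd = 2, phi0 = 30 * pi / 180, phi1 = 50 * pi / 180,
                 seed = 108L),
    h_baseline = h(rbind(m(1.7, "s", 0, 3), m(3.1, "d", 8, 2),
                         m(6.1, "s", 0, 1)),
                   noise_sd = 2, baseline = c(50, -120, 200, -90),
                   seed = 109L),
    c_sparse = random_carbon_spec(201L, n_carbons = c(12L, 12L),
                                  snr = c(20, 80)),
    c_degenerate = random_carbon_spec(202L, n_carbons = c(20L, 20L),
                                      snr = c(15, 60)),
    c_quaternary = random_carbon_spec(203L, n_carbons = c(15L, 15L),
                                      snr = c(5, 100))
  )
}
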