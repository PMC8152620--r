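# 1H pipeline: derivative peak picking, 18 Hz multiplet grouping,
# per-region generalized-Lorentzian deconvolution, BIC noise pruning,
# solvent removal/referencing and integer-integral normalization.

#' Derivative peak picking
#'
#' Candidate peaks are local maxima of the Savitzky-Golay smoothed real
#' part where the smoothed second derivative has a local minimum. A
#' candidate is kept iff its height is strictly above
#' `amp_multiple * noise_sigma` and its second derivative strictly below
#' `-d2_multiple` times the robust sd of the second-derivative trace. Both
#' thresholds are deliberately low; spurious picks are removed later by
#' information-criterion pruning.
#'
#' @param spectrum phased, baseline-corrected `Spectrum` with `noise_sigma`.
#' @param amp_multiple amplitude threshold, multiples of the noise sd.
#' @param d2_multiple second-derivative threshold, multiples of the robust
#'   sd of the second derivative.
#' @param sg_window Savitzky-Golay window length (odd).
#' @return data.frame with columns `position` (ppm), `height`,
#'   `second_derivative`, sorted by ascending ppm.
#' @export
pick_peaks_derivative <- function(spectrum, amp_multiple = 3,
                                  d2_multiple = 1, sg_window = 7L) {
  stopifnot(!is.na(spectrum$noise_sigma))
  y <- Re(spectrum$intensity)
  n <- length(y)
  p <- 3L
  ys <- signal::sgolayfilt(y, p = p, n = sg_window, m = 0L)
  d1 <- signal::sgolayfilt(y, p = p, n = sg_window, m = 1L)
  d2 <- signal::sgolayfilt(y, p = p, n = sg_window, m = 2L)
  sigma_d2 <- mad(d2)
  sigma <- spectrum$noise_sigma

  cross <- which(d1[-n] > 0 & d1[-1] <= 0)     # + to - zero crossings
  if (!length(cross)) {
    return(data.frame(position = numeric(0), height = numeric(0),
                      second_derivative = numeric(0)))
  }
  idx <- vapply(cross, function(i) if (ys[i] >= ys[i + 1L]) i else i + 1L,
                integer(1))
  idx <- unique(idx[idx > 1L & idx < n])
  keep <- y[idx] > amp_multiple * sigma & d2[idx] < -d2_multiple * sigma_d2
  idx <- idx[keep]
  out <- data.frame(position = spectrum$ppm[idx], height = y[idx],
                    second_derivative = d2[idx], index = idx)
  out[order(out$position), , drop = FALSE]
}

#' Group picked peaks into multiplets by the 18 Hz rule
#'
#' Single-linkage grouping: consecutive peaks (in ppm order) closer than
#' `max_j` Hz belong to one multiplet, the maximum 1H-1H scalar coupling
#' expected being about 18 Hz.
#'
#' @param peaks data.frame with a `position` column (ppm), any row order.
#' @param sfrq spectrometer frequency, MHz.
#' @param max_j grouping cutoff, Hz.
#' @return list of data.frames, one per group, each sorted by ppm.
#' @export
group_multiplets <- function(peaks, sfrq, max_j = 18) {
  if (!nrow(peaks)) return(list())
  peaks <- peaks[order(peaks$position), , drop = FALSE]
  gaps_hz <- diff(peaks$position) * sfrq
  grp <- cumsum(c(1L, as.integer(gaps_hz >= max_j)))
  lapply(split(seq_len(nrow(peaks)), grp), function(i)
    peaks[i, , drop = FALSE])
}

#' Deconvolve a spectral region with generalized Lorentzians
#'
#' Fits one generalized Lorentzian per picked peak over the group's extent
#' (padded by `margin_hz`) by Levenberg-Marquardt least squares, then
#' iterates - adding a component at the largest residual when needed -
#' until the model integral matches the region integral within
#' `integral_tol` (default 1 percent) or `max_iter` is reached.
#'
#' @param spectrum phased, baseline-corrected `Spectrum`.
#' @param group data.frame of picked peaks (one multiplet group).
#' @param margin_hz padding added each side of the group extent, Hz.
#' @param integral_tol relative integral convergence tolerance.
#' @param max_iter maximum refinement iterations.
#' @param default_width_hz initial FWHM guess, Hz.
#' @return a [lineshape_model()].
#' @export
fit_region <- function(spectrum, group, margin_hz = 8, integral_tol = 0.01,
                       max_iter = 6L, default_width_hz = 1.5) {
  stopifnot(nrow(group) >= 1L)
  ppm <- spectrum$ppm
  n <- length(ppm)
  margin_ppm <- margin_hz / spectrum$sfrq
  lo_ppm <- min(group$position) - margin_ppm
  hi_ppm <- max(group$position) + margin_ppm
  sel <- which(ppm >= lo_ppm & ppm <= hi_ppm)
  sel <- sort(sel)
  x <- ppm[sel]
  yobs <- Re(spectrum$intensity[sel])
  dppm <- abs(mean(diff(x)))
  w0 <- default_width_hz / spectrum$sfrq

  params <- data.frame(center = group$position,
                       amplitude = pmax(group$height, .Machine$double.eps),
                       width = w0, mixing = 0.9)
  target <- sum(yobs) * dppm

  refit <- function(params) {
    k <- nrow(params)
    pv <- as.numeric(t(as.matrix(params)))
    lower <- rep(c(lo_ppm, 0, dppm / 2, 0), k)
    upper <- rep(c(hi_ppm, Inf, (hi_ppm - lo_ppm), 1), k)
    resid_fn <- function(p) {
      gl_eval_mat(matrix(p, ncol = 4L, byrow = TRUE), x) - yobs
    }
    fit <- suppressWarnings(minpack.lm::nls.lm(
                              par = pv, lower = lower, upper = upper,
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 60L, ptol = 1e-9)))
    pm <- as.data.frame(matrix(fit$par, ncol = 4L, byrow = TRUE))
    names(pm) <- c("center", "amplitude", "width", "mixing")
    pm
  }

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    params <- refit(params)
    model_int <- sum(gl_model_eval(params, x)) * dppm
    if (abs(target) > 0 &&
        abs(model_int - target) / abs(target) < integral_tol) {
      converged <- TRUE
      break
    }
    # add a component at the largest residual and try again
    resid <- yobs - gl_model_eval(params, x)
    i <- which.max(abs(resid))
    if (abs(resid[i]) <= 2 * spectrum$noise_sigma) break
    params <- rbind(params,
                    data.frame(center = x[i],
                               amplitude = max(resid[i], .Machine$double.eps),
                               width = w0, mixing = 0.9))
  }
  lineshape_model(params, region = c(sel[1], sel[length(sel)]),
                  converged = converged, iterations = it)
}

# Gaussian-residual BIC of a parameter table over a region
region_bic <- function(params, x, yobs, pars_per_peak = 4L) {
  m <- if (nrow(params)) gl_model_eval(params, x) else numeric(length(x))
  rss <- sum((yobs - m)^2)
  nn <- length(yobs)
  nn * log(max(rss, .Machine$double.xmin) / nn) +
    pars_per_peak * nrow(params) * log(nn)
}

#' Prune noise components by Bayesian Information Criterion
#'
#' Each lineshape component is removed in turn and the reduced model
#' refitted; if the removal lowers the region BIC (Gaussian residual
#' likelihood, 4 parameters per component) by more than `bic_threshold`,
#' the component carried no information and is deleted permanently.
#' Components are tested in ascending amplitude order.
#'
#' @param model a [lineshape_model()].
#' @param spectrum the `Spectrum` the model was fitted to.
#' @param bic_threshold required BIC decrease for deletion.
#' @return the pruned `LineshapeModel` (possibly with zero components).
#' @export
prune_noise_bic <- function(model, spectrum, bic_threshold = 10,
                            min_window = 512L) {
  # refits stay on the original fit region (centers and widths bounded
  # there), but the criterion is evaluated over a window of at least
  # `min_window` points: on a window barely wider than the multiplet the
  # parameter penalty (4 log n) is too small to reject a component fitted
  # to the largest local noise excursion
  n_spec <- length(spectrum$ppm)
  sel_fit <- model$region[1]:model$region[2]
  x <- spectrum$ppm[sel_fit]
  yobs <- Re(spectrum$intensity[sel_fit])
  # pad the evaluation window with noise-classified points only, so that
  # unmodeled neighboring multiplets cannot dominate the residual
  pad <- max(0L, min_window - length(sel_fit))
  cand <- setdiff(max(1L, model$region[1] - 4L * pad):
                    min(n_spec, model$region[2] + 4L * pad), sel_fit)
  sig <- if (!is.na(spectrum$noise_sigma)) spectrum$noise_sigma else
    mad(Re(spectrum$intensity))
  cand <- cand[abs(Re(spectrum$intensity[cand])) <= 4 * sig]
  if (length(cand) > pad) cand <- cand[seq_len(pad)]
  sel_ext <- sort(c(sel_fit, cand))
  x_ext <- spectrum$ppm[sel_ext]
  y_ext <- Re(spectrum$intensity[sel_ext])
  params <- model$params
  if (!nrow(params)) return(model)

  refit_at <- function(params) {
    if (!nrow(params)) return(params)
    k <- nrow(params)
    lo_ppm <- min(x); hi_ppm <- max(x)
    dppm <- abs(mean(diff(x)))
    pv <- as.numeric(t(as.matrix(params)))
    lower <- rep(c(lo_ppm, 0, dppm / 2, 0), k)
    upper <- rep(c(hi_ppm, Inf, (hi_ppm - lo_ppm), 1), k)
    resid_fn <- function(p) {
      gl_eval_mat(matrix(p, ncol = 4L, byrow = TRUE), x) - yobs
    }
    fit <- suppressWarnings(minpack.lm::nls.lm(
                              par = pv, lower = lower, upper = upper,
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 40L)))
    pm <- as.data.frame(matrix(fit$par, ncol = 4L, byrow = TRUE))
    names(pm) <- c("center", "amplitude", "width", "mixing")
    pm
  }

  bic_cur <- region_bic(params, x_ext, y_ext)
  repeat {
    if (!nrow(params)) break
    ord <- order(params$amplitude)
    deleted <- FALSE
    for (j in ord) {
      reduced <- refit_at(params[-j, , drop = FALSE])
      bic_red <- region_bic(reduced, x_ext, y_ext)
      if (bic_red < bic_cur - bic_threshold) {
        params <- reduced
        bic_cur <- bic_red
        deleted <- TRUE
        break   # restart the scan on the reduced model
      }
    }
    if (!deleted) break
  }
  lineshape_model(params, region = model$region,
                  converged = model$converged, iterations = model$iterations)
}

#' Build multiplets from pruned lineshape models
#'
#' Surviving components from all regions are pooled and regrouped by the
#' 18 Hz rule; each group becomes one multiplet with an integral-weighted
#' center and a raw model integral.
#'
#' @param models list of [lineshape_model()] objects (after pruning).
#' @param sfrq spectrometer frequency, MHz.
#' @param max_j grouping cutoff, Hz.
#' @return list of multiplets; each is a list with `center`, `raw_integral`,
#'   `peaks` (component table with an `integral` column) and `proton_count`
#'   (NA until [normalize_integrals()]).
#' @export
build_multiplets <- function(models, sfrq, max_j = 18) {
  all_params <- do.call(rbind, lapply(models, function(m) m$params))
  if (is.null(all_params) || !nrow(all_params)) return(list())
  all_params$integral <- gl_component_integral(all_params)
  all_params <- all_params[order(all_params$center), , drop = FALSE]
  groups <- group_multiplets(
    data.frame(position = all_params$center,
               row = seq_len(nrow(all_params))),
    sfrq = sfrq, max_j = max_j)
  lapply(groups, function(g) {
    rows <- all_params[g$row, , drop = FALSE]
    list(center = weighted.mean(rows$center, rows$integral),
         raw_integral = sum(rows$integral),
         peaks = rows,
         proton_count = NA_integer_)
  })
}

#' Identify and remove the solvent multiplet, then reference the spectrum
#'
#' Every multiplet within the search window around the expected solvent
#' position is scored by how well its line pattern (line count and relative
#' amplitudes) matches the expected solvent multiplet, times a Gaussian
#' distance score from the expected position. The best-scoring multiplet is
#' removed and the ppm axis and all multiplet centers are shifted so that
#' it sits exactly at the solvent reference shift.
#'
#' @param multiplets list from [build_multiplets()].
#' @param solvent one of `"chloroform"`, `"methanol"`, `"benzene"`,
#'   `"dmso"` (extensible via `solvent_table`).
#' @param spectrum the `Spectrum` (its ppm axis is re-referenced too).
#' @param nucleus `"1H"` only (13C referencing is out of scope here).
#' @param window_ppm search half-window around the expected position.
#' @param min_score below this no candidate is accepted.
#' @param table solvent table; see [solvent_table()].
#' @return list with `multiplets` (solvent removed, centers shifted),
#'   `spectrum` (axis shifted), `shift` (ppm added to the axis), and
#'   `removed` (the solvent multiplet or NULL).
#' @export
remove_solvent_and_reference <- function(multiplets, solvent, spectrum,
                                         nucleus = "1H", window_ppm = 0.5,
                                         min_score = 0.01,
                                         table = solvent_table()) {
  if (!solvent %in% names(table))
    stop("unsupported solvent '", solvent, "'; known: ",
         paste(names(table), collapse = ", "))
  entry <- table[[solvent]]
  if (!length(multiplets))
    return(list(multiplets = multiplets, spectrum = spectrum, shift = 0,
                removed = NULL))
  centers <- vapply(multiplets, `[[`, numeric(1), "center")
  cand <- which(abs(centers - entry$ref) <= window_ppm)
  if (!length(cand)) {
    warning("no candidate multiplet in the ", solvent, " window; ",
            "spectrum left unreferenced")
    return(list(multiplets = multiplets, spectrum = spectrum, shift = 0,
                removed = NULL))
  }
  scores <- vapply(cand, function(i)
    solvent_candidate_score(multiplets[[i]], entry), numeric(1))
  best <- cand[which.max(scores)]
  if (max(scores) < min_score) {
    warning("no multiplet matched the ", solvent,
            " pattern well enough; spectrum left unreferenced")
    return(list(multiplets = multiplets, spectrum = spectrum, shift = 0,
                removed = NULL))
  }
  shift <- entry$ref - multiplets[[best]]$center
  removed <- multiplets[[best]]
  kept <- multiplets[-best]
  kept <- lapply(kept, function(m) {
    m$center <- m$center + shift
    m$peaks$center <- m$peaks$center + shift
    m
  })
  spectrum$ppm <- spectrum$ppm + shift
  list(multiplets = kept, spectrum = spectrum, shift = shift,
       removed = removed)
}

# score one candidate multiplet against an expected solvent pattern:
# amplitude-profile cosine similarity (best alignment), a line-count
# penalty, and a Gaussian distance term (sd 0.2 ppm)
solvent_candidate_score <- function(multiplet, entry, dist_sd = 0.2) {
  a <- multiplet$peaks$amplitude[order(multiplet$peaks$center)]
  e <- entry$pattern
  n_obs <- length(a); L <- length(e)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  if (n_obs >= L) {
    sims <- vapply(seq_len(n_obs - L + 1L), function(o)
      cosine(a[o:(o + L - 1L)], e), numeric(1))
    pattern <- max(sims) * L / n_obs
  } else {
    sims <- vapply(seq_len(L - n_obs + 1L), function(o)
      cosine(a, e[o:(o + n_obs - 1L)]), numeric(1))
    pattern <- max(sims) * n_obs / L
  }
  dist <- exp(-((multiplet$center - entry$ref) / dist_sd)^2)
  pattern * dist
}

#' Table of supported residual-solvent multiplets (1H)
#'
#' Reference shift (ppm), expected line pattern (relative amplitudes) and
#' line spacing (Hz) for the residual protio-solvent signal in common
#' deuterated solvents. User-extensible: supply a modified copy to
#' [remove_solvent_and_reference()].
#'
#' @return named list of entries with fields `ref`, `pattern`, `j_hz`.
#' @export
solvent_table <- function() {
  list(
    chloroform = list(ref = 7.26, pattern = 1, j_hz = 0),
    benzene    = list(ref = 7.16, pattern = 1, j_hz = 0),
    methanol   = list(ref = 3.31, pattern = c(1, 2, 3, 2, 1), j_hz = 1.7),
    dmso       = list(ref = 2.50, pattern = c(1, 2, 3, 2, 1), j_hz = 1.9)
  )
}

#' Normalize multiplet integrals to integer proton counts
#'
#' Searches the total proton count n from `total_protons - labile_protons`
#' to `2 * total_protons`; for each n the raw model integrals are scaled to
#' sum to n and scored by integer-likeness (geometric mean of per-multiplet
#' terms `max(1 - 2|x - round(x)|, floor)`); the best-scoring n (ties to
#' the smaller n) fixes the normalization constant. Multiplets whose scaled
#' integral rounds to zero are dropped.
#'
#' @param multiplets list from [build_multiplets()].
#' @param total_protons protons in the candidate structure.
#' @param labile_protons exchangeable (OH/NH/SH) protons.
#' @param floor lower clip for a per-multiplet score term. The floor keeps
#'   a single unexplained (e.g. spurious) multiplet from dominating the
#'   product: with a harsh floor a half-integer integral can push the
#'   search to a harmonic (doubled) total.
#' @return list with `multiplets` (with `proton_count` set, zero-count ones
#'   dropped), `n_protons` (the selected total) and `scores` (the search
#'   trace, for diagnostics).
#' @export
normalize_integrals <- function(multiplets, total_protons,
                                labile_protons = 0L, floor = 0.2) {
  stopifnot(total_protons >= labile_protons, labile_protons >= 0)
  if (!length(multiplets))
    return(list(multiplets = multiplets, n_protons = 0L, scores = NULL))
  raw <- vapply(multiplets, `[[`, numeric(1), "raw_integral")
  if (any(raw < 0)) raw <- pmax(raw, 0)
  ns <- seq.int(max(1L, total_protons - labile_protons), 2L * total_protons)
  if (length(multiplets) == 1L) {
    warning("single multiplet: integral normalization is degenerate, ",
            "using the smallest candidate proton count")
    n_best <- ns[1]
    scores <- NULL
  } else {
    score_one <- function(n) {
      scaled <- raw / sum(raw) * n
      terms <- pmax(1 - 2 * abs(scaled - round(scaled)), floor)
      exp(mean(log(terms)))
    }
    sc <- vapply(ns, score_one, numeric(1))
    n_best <- ns[which.max(sc)]   # which.max takes the first = smallest n
    scores <- data.frame(n = ns, score = sc)
  }
  scaled <- raw / sum(raw) * n_best
  counts <- as.integer(round(scaled))
  out <- multiplets
  for (k in seq_along(out)) out[[k]]$proton_count <- counts[k]
  out <- out[counts > 0L]
  list(multiplets = out, n_protons = n_best, scores = scores)
}

#' Run the full 1H processing pipeline on a spectrum
#'
#' Noise estimation, signal classification, phasing, baseline correction,
#' derivative peak picking, grouping, per-region deconvolution, BIC
#' pruning, solvent removal/referencing and integral normalization.
#'
#' @param spectrum a freshly transformed `Spectrum` (1H).
#' @param total_protons,labile_protons see [normalize_integrals()]; skip
#'   normalization when `total_protons` is NULL.
#' @param solvent solvent label; NULL skips solvent removal.
#' @param amp_multiple,d2_multiple picking thresholds.
#' @param bic_threshold see [prune_noise_bic()].
#' @return list with `multiplets`, `spectrum` (processed), `phase`,
#'   `models`, `solvent_shift`, `n_protons`.
#' @export
process_proton <- function(spectrum, total_protons = NULL,
                           labile_protons = 0L, solvent = spectrum$solvent,
                           amp_multiple = 3, d2_multiple = 1,
                           bic_threshold = 10) {
  spectrum <- estimate_noise(spectrum)
  if (spectrum$noise_sigma <= 0)
    stop("degenerate spectrum: zero noise estimate")
  ph <- phase_correct(spectrum)
  spectrum <- ph$spectrum
  spectrum <- baseline_correct(spectrum)
  spectrum <- estimate_noise(spectrum)

  peaks <- pick_peaks_derivative(spectrum, amp_multiple, d2_multiple)
  groups <- group_multiplets(peaks, spectrum$sfrq)
  models <- lapply(groups, function(g) {
    m <- fit_region(spectrum, g)
    prune_noise_bic(m, spectrum, bic_threshold)
  })
  multiplets <- build_multiplets(models, spectrum$sfrq)

  solvent_shift <- 0
  if (!is.null(solvent) && length(multiplets)) {
    sr <- remove_solvent_and_reference(multiplets, solvent, spectrum)
    multiplets <- sr$multiplets
    spectrum <- sr$spectrum
    solvent_shift <- sr$shift
  }
  n_protons <- NA_integer_
  if (!is.null(total_protons) && length(multiplets)) {
    ni <- normalize_integrals(multiplets, total_protons, labile_protons)
    multiplets <- ni$multiplets
    n_protons <- ni$n_protons
  }
  list(multiplets = multiplets, spectrum = spectrum, phase = ph$phase,
       models = models, solvent_shift = solvent_shift,
       n_protons = n_protons)
}

#' Summarize multiplets as a data.frame
#'
#' @param multiplets list of multiplets.
#' @return data.frame with one row per multiplet: `center`, `raw_integral`,
#'   `proton_count`, `n_peaks`.
#' @export
multiplet_table <- function(multiplets) {
  if (!length(multiplets))
    return(data.frame(center = numeric(0), raw_integral = numeric(0),
                      proton_count = integer(0), n_peaks = integer(0)))
  data.frame(
    center = vapply(multiplets, `[[`, numeric(1), "center"),
    raw_integral = vapply(multiplets, `[[`, numeric(1), "raw_integral"),
    proton_count = vapply(multiplets, function(m)
      as.integer(m$proton_count), integer(1)),
    n_peaks = vapply(multiplets, function(m) nrow(m$peaks), integer(1)))
}
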