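# Automatic phase correction: hybrid scheme combining signal-region
# classification, per-region scalar phase estimation, weighted linear
# regression of phase against frequency, and a global model-projection
# refinement gated on the derivative-entropy (ACME) objective.

# --- per-region scalar phase ------------------------------------------------

# phase of one region from the second moment of the (linearly detrended)
# complex trace over a symmetric window: for a symmetric multiplet,
# sum(z^2) = exp(2i*phi) * (positive real), so phi = Arg(sum(z^2))/2 up to
# pi, resolved by the sign of the rotated real sum.  The linear detrend
# removes the slowly varying dispersion background of distant peaks.
region_phase_moment <- function(S, lo, hi) {
  seg <- S[lo:hi]
  nn <- length(seg)
  ne <- min(12L, max(4L, nn %/% 6L))
  edge_i <- c(seq_len(ne), nn - seq_len(ne) + 1L)
  xi <- seq_len(nn)
  cr <- lm.fit(cbind(1, xi[edge_i]), Re(seg)[edge_i])$coefficients
  ci <- lm.fit(cbind(1, xi[edge_i]), Im(seg)[edge_i])$coefficients
  z <- seg - complex(real = cr[1] + cr[2] * xi,
                     imaginary = ci[1] + ci[2] * xi)
  th <- 0.5 * Arg(sum(z * z))
  if (sum(Re(z * exp(-1i * th))) < 0) th <- th + pi
  th
}

# merge threshold runs of the magnitude trace into phasing regions
phasing_regions <- function(magn, sig, n, gap_pts) {
  thr <- max(8 * sig, 0.02 * max(magn))
  above <- magn > thr
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
    if (iv$start[k] - merged$end[nrow(merged)] <= gap_pts)
      merged$end[nrow(merged)] <- iv$end[k]
    else merged <- rbind(merged, iv[k, ])
  }
  merged
}

# stages 1-2: per-region phases + weighted linear regression with outlier
# rejection; iterated so mod-pi ambiguities resolve as the residual shrinks
phase_seed_wlr <- function(S0, sig, n, gap_pts, npass = 3L,
                           nregions = 12L) {
  S <- S0
  tot <- c(0, 0)
  x <- (seq_len(n) - 1) / (n - 1)
  for (pass in seq_len(npass)) {
    magn <- Mod(S)
    merged <- phasing_regions(magn, sig, n, gap_pts)
    if (is.null(merged)) break
    hts <- vapply(seq_len(nrow(merged)), function(k)
      max(magn[merged$start[k]:merged$end[k]]), numeric(1))
    keep <- sort(order(hts, decreasing = TRUE)[
      seq_len(min(nregions, nrow(merged)))])
    merged <- merged[keep, , drop = FALSE]
    xs <- c(); est <- c(); wt <- c()
    for (k in seq_len(nrow(merged))) {
      idx <- merged$start[k]:merged$end[k]
      ctr <- weighted.mean(idx, magn[idx]^2)
      W <- round(max(abs(idx - ctr)) + 15)
      lo <- round(ctr - W); hi <- round(ctr + W)
      if (lo < 1 || hi > n) next
      est <- c(est, region_phase_moment(S, lo, hi))
      xs <- c(xs, (ctr - 1) / (n - 1))
      wt <- c(wt, max(magn[idx]))
    }
    if (length(est) < 2L) {
      if (length(est) == 1L) {
        tot[1] <- tot[1] + est
        S <- S0 * exp(-1i * (tot[1] + tot[2] * x))
      }
      break
    }
    o <- order(xs); eu <- est[o]; xo <- xs[o]; wo <- wt[o]
    # region phases are known modulo pi; chaining adjacent differences can
    # walk off by multiples of pi when a weak region is noisy, so anchor
    # every phase to the strongest region, fit, then re-resolve each
    # ambiguity against the current fit and refit
    ref <- eu[which.max(wo)]
    eu <- eu - pi * round((eu - ref) / pi)
    robust_fit <- function(eu) {
      fit <- lm(eu ~ xo, weights = wo)
      r2 <- abs(stats::residuals(fit)); s <- mad(r2)
      if (s > 0 && any(r2 > 3 * s) && sum(r2 <= 3 * s) >= 2L) {
        ok <- r2 <= 3 * s
        fit <- lm(eu[ok] ~ xo[ok], weights = wo[ok])
      }
      fit
    }
    fit <- robust_fit(eu)
    for (it in 1:2) {
      pred <- coef(fit)[1] + coef(fit)[2] * xo
      eu <- eu - pi * round((eu - pred) / pi)
      fit <- robust_fit(eu)
    }
    sol <- c(coef(fit)[1], coef(fit)[2])
    if (!all(is.finite(sol)) || abs(sol[2]) > 1.2 * pi) {
      # implausible first-order slope: fall back to the weighted circular
      # mean as a zero-order-only estimate
      sol <- c(Arg(sum(wo * exp(1i * eu))), 0)
    }
    Snew <- S * exp(-1i * (sol[1] + sol[2] * x))
    thr <- max(8 * sig, 0.02 * max(magn))
    if (sum(Re(Snew)[magn > thr]) < 0) {
      sol[1] <- sol[1] + pi
      Snew <- -Snew
    }
    tot <- tot + sol
    S <- Snew
  }
  tot
}

# --- stage 3: model-projection refinement -----------------------------------

# local maxima of a trace above a threshold, deduplicated
find_lines <- function(trace, n, thr) {
  locmax <- which(diff(sign(diff(trace))) == -2) + 1L
  locmax <- locmax[trace[locmax] > thr]
  if (length(locmax) > 100L)
    locmax <- sort(locmax[order(trace[locmax], decreasing = TRUE)[1:100]])
  keep <- rep(TRUE, length(locmax))
  for (j in seq_along(locmax)[-1]) {
    if (locmax[j] - locmax[j - 1] <= 2L) {
      if (trace[locmax[j]] >= trace[locmax[j - 1]]) keep[j - 1] <- FALSE
      else keep[j] <- FALSE
    }
  }
  locmax[keep]
}

subpixel_max <- function(trace, idx, n) {
  vapply(idx, function(i) {
    if (i <= 1 || i >= n) return(as.numeric(i))
    y0 <- trace[i - 1]; y1 <- trace[i]; y2 <- trace[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den >= 0) return(as.numeric(i))
    i + max(min((y0 - y2) / (2 * den), 0.5), -0.5)
  }, numeric(1))
}

halfwidth_pts <- function(trace, idx, n, scale = 1) {
  vapply(idx, function(i) {
    h <- trace[i]
    r <- i; while (r < n && trace[r] > h / 2) r <- r + 1L
    l <- i; while (l > 1 && trace[l] > h / 2) l <- l - 1L
    max(((r - l) / 2) / scale, 0.8)
  }, numeric(1))
}

# Lorentzian center/width from an inverse-quadratic fit of 7 points around
# a real-part maximum (1/y is quadratic in the offset for a Lorentzian)
invquad_line_params <- function(re, idx, n, g0) {
  cs <- numeric(length(idx)); gs <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    d <- -3:3
    ok <- i + d >= 1 & i + d <= n
    y <- re[i + d[ok]]
    if (any(y <= 0) || length(y) < 5L) { cs[j] <- i; gs[j] <- g0[j]; next }
    cf <- lm.fit(cbind(1, d[ok], d[ok]^2), 1 / y)$coefficients
    a <- cf[3]; b <- cf[2]; cc <- cf[1]
    if (!is.finite(a) || a <= 0) { cs[j] <- i; gs[j] <- g0[j]; next }
    delta <- -b / (2 * a)
    g2 <- cc / a - delta^2
    if (!is.finite(g2) || g2 <= 0.5 || abs(delta) > 1.5) {
      cs[j] <- i; gs[j] <- g0[j]
    } else {
      cs[j] <- i + delta
      gs[j] <- sqrt(g2)
    }
  }
  list(c = cs, g = gs)
}

# discrete lineshape: DTFT of a sampled damped sinusoid with the
# conventional half-weighted first point
discrete_lineshape <- function(theta, rho, nacq) {
  z <- rho * exp(1i * theta)
  (1 - z^nacq) / (1 - z) - 0.5
}

# one variable-projection pass: line centers/widths fixed, real amplitudes
# projected out by linear least squares, (phi0, phi1) by Nelder-Mead on
# the projected residual
varpro_phase_round <- function(S, cs, g_pts, n, nacq, sweep, seed_phase) {
  L <- length(cs)
  hzpt <- sweep / n
  sel <- sort(unique(unlist(lapply(seq_len(L), function(j) {
    w <- max(10L, ceiling(10 * g_pts[j]))
    max(1L, round(cs[j]) - w):min(n, round(cs[j]) + w)
  }))))
  xsel <- (sel - 1) / (n - 1)
  B <- matrix(0, 2 * length(sel), L)
  for (j in seq_len(L)) {
    theta <- 2 * pi * (sel - cs[j]) / n
    rho <- exp(-pi * (2 * g_pts[j] * hzpt) / sweep)
    z <- discrete_lineshape(theta, rho, nacq)
    B[, j] <- c(Re(z), Im(z))
  }
  Q <- qr.Q(qr(B))
  Ssel <- S[sel]
  obj <- function(p) {
    T <- Ssel * exp(-1i * (p[1] + p[2] * xsel))
    y <- c(Re(T), Im(T))
    sum(y^2) - sum((crossprod(Q, y))^2)
  }
  optim(seed_phase, obj, method = "Nelder-Mead",
        control = list(maxit = 600, reltol = 1e-13))$par
}

phase_refine_model <- function(S0, sig, n, nacq, sweep, seed_phase,
                               nrounds = 4L) {
  magn <- Mod(S0)
  idx <- find_lines(magn, n, 5 * sig)
  if (length(idx) < 2L) return(seed_phase)
  cs <- subpixel_max(magn, idx, n)
  gs <- halfwidth_pts(magn, idx, n, scale = sqrt(3))
  tot <- varpro_phase_round(S0, cs, gs, n, nacq, sweep, seed_phase)
  x <- (seq_len(n) - 1) / (n - 1)
  for (round in seq_len(nrounds - 1L)) {
    S1 <- S0 * exp(-1i * (tot[1] + tot[2] * x))
    re <- Re(S1)
    idx <- find_lines(re, n, 4 * sig)
    if (length(idx) < 2L) break
    g0 <- halfwidth_pts(re, idx, n, scale = 1)
    pq <- invquad_line_params(re, idx, n, g0)
    dp <- varpro_phase_round(S1, pq$c, pq$g, n, nacq, sweep, c(0, 0))
    tot <- tot + dp
    if (max(abs(dp)) < 5e-5) break
  }
  tot
}

#' Automatic phase correction
#'
#' Hybrid staged scheme. Stage 1: the magnitude trace is classified into
#' signal regions (merged across multiplet gaps) and each region receives a
#' scalar phase from the second moment of its detrended complex trace.
#' Stage 2: weighted linear regression of region phase against fractional
#' frequency position - weights are region peak heights, regions whose
#' residual exceeds 3 median absolute deviations are dropped - yields
#' (phi0, phi1); the estimate is iterated three times. Stage 3: global
#' refinement by variable projection - line positions and widths are read
#' off the spectrum, real line amplitudes are projected out by linear least
#' squares, and (phi0, phi1) minimize the projected residual. The refined
#' solution is accepted only if it does not increase the
#' derivative-entropy (ACME) objective over the signal regions; otherwise
#' the entropy objective itself is minimized from the regression seed.
#'
#' @param spectrum a `Spectrum` (noise sigma estimated on the fly if
#'   unset).
#' @param regions optional signal regions (from
#'   [classify_signal_regions()]); used only for the entropy gate; the
#'   stages derive their own regions from the magnitude trace.
#' @param merge_gap_hz gap (Hz) below which threshold runs merge into one
#'   phasing region; defaults to 25 Hz so whole multiplets stay together.
#' @return list with `spectrum` (phased) and `phase` (a [phase_params()]
#'   with attributes `entropy_seed` and `entropy_final`).
#' @export
phase_correct <- function(spectrum, regions = NULL, merge_gap_hz = 25) {
  if (is.na(spectrum$noise_sigma)) spectrum <- estimate_noise(spectrum)
  sig <- spectrum$noise_sigma
  n <- length(spectrum$intensity)
  if (sig <= 0 || max(Mod(spectrum$intensity)) <= 8 * sig) {
    pp <- phase_params(0, 0)
    attr(pp, "entropy_seed") <- attr(pp, "entropy_final") <- NA_real_
    return(list(spectrum = spectrum, phase = pp))
  }
  hzpt <- spectrum$sweep / n
  gap_pts <- max(1L, round(merge_gap_hz / hzpt))
  S0 <- spectrum$intensity
  x <- (seq_len(n) - 1) / (n - 1)
  nacq <- if (!is.null(spectrum$acquired)) spectrum$acquired else n %/% 2L

  seed <- phase_seed_wlr(S0, sig, n, gap_pts)
  refined <- phase_refine_model(S0, sig, n, nacq, spectrum$sweep, seed)

  # final ACME polish: entropy objective over the signal points, confined
  # to a small trust region around the model solution; accepted only if
  # the entropy does not increase
  magn <- Mod(S0)
  thr <- max(8 * sig, 0.02 * max(magn))
  sel <- which(magn > thr)
  pad <- unique(pmin(pmax(rep(sel, each = 5L) + rep(-2:2, length(sel)), 1L), n))
  sel <- sort(pad)
  ent_at <- function(p)
    acme_entropy(Re(S0[sel] * exp(-1i * (p[1] + p[2] * x[sel]))))
  e_seed <- ent_at(refined)
  box <- 0.5 * pi / 180
  op <- optim(refined, ent_at, method = "L-BFGS-B",
              lower = refined - box, upper = refined + box,
              control = list(maxit = 50L))
  if (is.finite(op$value) && op$value <= e_seed) {
    sol <- op$par
    e_final <- op$value
  } else {
    sol <- refined
    e_final <- e_seed
  }

  out <- spectrum
  out$intensity <- S0 * exp(-1i * (sol[1] + sol[2] * x))
  if (sum(Re(out$intensity[sel])) < 0) {
    sol[1] <- sol[1] + pi
    out$intensity <- -out$intensity
  }
  pp <- phase_params(sol[1], sol[2])
  attr(pp, "entropy_seed") <- e_seed
  attr(pp, "entropy_final") <- e_final
  list(spectrum = out, phase = pp)
}
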