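# Preprocessing: noise estimation, signal-region classification, hybrid
# phase correction (per-region entropy minimization + weighted linear
# regression + global refinement) and baseline correction.

#' Estimate the noise standard deviation of a spectrum
#'
#' Robust sigma of the real part over noise-classified points. An initial
#' estimate is taken as the median absolute deviation over the quietest
#' eighth of fixed-size chunks; points are then classified into
#' signal/noise and sigma recomputed over the noise complement.
#'
#' @param spectrum a [new_spectrum()] object with at least 1024 points.
#' @return the spectrum with `noise_sigma` set (use `attr(, "sigma")` or the
#'   field); returned invisibly as an updated `Spectrum`.
#' @export
estimate_noise <- function(spectrum) {
  y <- Re(spectrum$intensity)
  n <- length(y)
  if (n < 1024L) stop("spectrum must have at least 1024 points")
  if (all(y == 0)) {
    spectrum$noise_sigma <- 0
    return(spectrum)
  }
  # remove slow structure (baseline drift, broad humps) so the estimate
  # reflects the point-to-point noise only
  det <- y - stats::runmed(y, 129L)
  chunk <- 256L
  nch <- n %/% chunk
  sds <- vapply(seq_len(nch), function(i)
    mad(det[((i - 1L) * chunk + 1L):(i * chunk)]), numeric(1))
  sds <- sds[sds > 0]
  sigma0 <- if (length(sds))
    median(sort(sds)[seq_len(max(1L, length(sds) %/% 8L))]) else mad(det)
  mask <- abs(det) > 4 * sigma0
  # dilate the mask so peak flanks do not leak into the noise set
  mask <- stats::filter(as.numeric(mask), rep(1, 9L), sides = 2L)
  mask <- !is.na(mask) & mask > 0
  if (sum(!mask) < chunk) {
    warning("no noise region found; falling back to whole-spectrum MAD")
    sigma <- mad(det)
  } else {
    sigma <- sd(det[!mask])
  }
  spectrum$noise_sigma <- sigma
  spectrum
}

#' Classify signal-containing regions
#'
#' Contiguous runs where the absolute real part exceeds `threshold` times
#' the noise sigma, dilated by merging runs separated by less than a gap
#' (default 0.02 ppm for 1H, 0.2 ppm for 13C). The real part is used
#' rather than the complex magnitude: the dispersion wings in the
#' imaginary channel decay only as 1/offset and would lift the magnitude
#' trace above any low threshold across much of the spectrum.
#'
#' @param spectrum a `Spectrum`.
#' @param noise_sigma noise standard deviation (> 0).
#' @param threshold multiple of sigma defining signal.
#' @param merge_gap_ppm gap below which adjacent runs merge.
#' @param detrend subtract a running median before thresholding, so that
#'   sharp peaks are found even on top of a strong baseline drift (used
#'   when classifying for baseline estimation).
#' @return data.frame with integer columns `start`, `end` (inclusive,
#'   sorted, disjoint); zero rows when nothing exceeds the threshold.
#' @export
classify_signal_regions <- function(spectrum, noise_sigma,
                                    threshold = 4,
                                    merge_gap_ppm = NULL,
                                    detrend = FALSE) {
  stopifnot(noise_sigma > 0)
  if (is.null(merge_gap_ppm))
    merge_gap_ppm <- if (spectrum$nucleus == "1H") 0.02 else 0.2
  y <- Re(spectrum$intensity)
  if (detrend) y <- y - stats::runmed(y, 129L)
  magn <- abs(y)
  above <- magn > threshold * noise_sigma
  if (!any(above)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sig <- which(r$values)
  iv <- data.frame(start = starts[sig], end = ends[sig])
  gap_pts <- max(1L, round(merge_gap_ppm * spectrum$sfrq / hz_per_point(spectrum)))
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (k in 2:nrow(iv)) {
      if (iv$start[k] - merged$end[nrow(merged)] <= gap_pts) {
        merged$end[nrow(merged)] <- iv$end[k]
      } else {
        merged <- rbind(merged, iv[k, ])
      }
    }
  }
  rownames(merged) <- NULL
  merged
}

# Entropy objective for automatic phasing: entropy of the normalized
# absolute first derivative of the real part, plus a quadratic penalty on
# negative intensity.  Low entropy = sharp absorption lines; the penalty
# breaks the 180-degree ambiguity.
acme_entropy <- function(re_part, penalty = 1) {
  h <- abs(diff(re_part))
  s <- sum(h)
  if (s <= 0) return(0)
  h <- h / s
  h <- h[h > 0]
  ent <- -sum(h * log(h))
  neg <- re_part[re_part < 0]
  ent + penalty * sum(neg^2) / (sum(re_part^2) + .Machine$double.xmin)
}

# apply phi0/phi1 correction; x = fractional position in display order
apply_phase <- function(intensity, phi0, phi1) {
  n <- length(intensity)
  x <- (seq_len(n) - 1) / (n - 1)
  intensity * exp(-1i * (phi0 + phi1 * x))
}

#' Apply a zero/first-order phase error to a spectrum
#'
#' Multiplies by `exp(+1i (phi0 + phi1 x))` with `x` the fractional
#' position across the displayed spectrum; the inverse of the correction
#' applied by [phase_correct()]. Used by the fixture generator.
#'
#' @param spectrum a `Spectrum`.
#' @param phi0,phi1 radians.
#' @return the dephased spectrum.
#' @export
dephase <- function(spectrum, phi0, phi1) {
  spectrum$intensity <- apply_phase(spectrum$intensity, -phi0, -phi1)
  spectrum
}

#' Baseline correction
#'
#' Models the baseline as a smoothing spline through the points outside
#' signal regions and subtracts it from the real part. After correction the
#' median of the noise regions is approximately zero.
#'
#' @param spectrum phased `Spectrum`.
#' @param regions signal regions; computed from `noise_sigma` if NULL.
#' @param df_per_kpt spline flexibility, degrees of freedom per 1000 noise
#'   points (controls the knot spacing).
#' @return the corrected spectrum.
#' @export
baseline_correct <- function(spectrum, regions = NULL, df_per_kpt = 2.5) {
  y <- Re(spectrum$intensity)
  n <- length(y)
  if (is.null(regions)) {
    if (is.na(spectrum$noise_sigma)) spectrum <- estimate_noise(spectrum)
    if (spectrum$noise_sigma <= 0) return(spectrum)
    regions <- classify_signal_regions(spectrum, spectrum$noise_sigma,
                                       detrend = TRUE)
  }
  mask <- rep(TRUE, n)
  if (nrow(regions)) {
    for (k in seq_len(nrow(regions))) {
      i0 <- max(1L, regions$start[k] - 5L)
      i1 <- min(n, regions$end[k] + 5L)
      mask[i0:i1] <- FALSE
    }
  }
  if (sum(mask) < 50L) return(spectrum)
  idx <- which(mask)
  # thin for speed: the baseline is smooth, every 4th noise point suffices
  idx <- idx[seq(1L, length(idx), by = 4L)]
  dof <- max(4, min(50, df_per_kpt * length(idx) / 1000))
  fit <- smooth.spline(idx, y[idx], df = dof)
  base <- predict(fit, x = seq_len(n))$y
  spectrum$intensity <- complex(real = y - base, imaginary = Im(spectrum$intensity))
  spectrum
}
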