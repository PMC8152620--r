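#' Raw free induction decay
#'
#' Container for raw time-domain NMR data plus the acquisition metadata
#' needed to reconstruct a calibrated frequency axis.
#'
#' @param points complex vector of time-domain samples.
#' @param sfrq spectrometer (transmitter) frequency in MHz.
#' @param sweep spectral width in Hz.
#' @param offset carrier position in Hz relative to 0 ppm (Bruker O1).
#' @param nucleus `"1H"` or `"13C"`.
#' @param solvent solvent label (e.g. `"chloroform"`).
#' @param group_delay digital-filter group delay in points (0 if none).
#' @return an object of class `RawFID`.
#' @export
raw_fid <- function(points, sfrq, sweep, offset = 0, nucleus = c("1H", "13C"),
                    solvent = "chloroform", group_delay = 0L) {
  nucleus <- match.arg(nucleus)
  if (length(points) < 1L) stop("FID must contain at least one point")
  if (!is.complex(points)) points <- as.complex(points)
  if (sweep <= 0) stop("sweep width must be positive")
  if (sfrq <= 0) stop("spectrometer frequency must be positive")
  structure(list(points = points, sfrq = sfrq, sweep = sweep,
                 offset = offset, nucleus = nucleus, solvent = solvent,
                 group_delay = as.integer(group_delay)),
            class = "RawFID")
}

#' @export
print.RawFID <- function(x, ...) {
  cat(sprintf("<RawFID> %s, %d points, %.1f Hz sweep, %.2f MHz, solvent %s\n",
              x$nucleus, length(x$points), x$sweep, x$sfrq, x$solvent))
  invisible(x)
}

#' Frequency-domain NMR spectrum
#'
#' Complex spectrum over a strictly descending ppm axis (the display
#' convention: high field to the right).
#'
#' @param intensity complex vector over frequency, in descending-ppm order.
#' @param ppm numeric vector, strictly decreasing, same length as `intensity`.
#' @param sfrq spectrometer frequency, MHz.
#' @param sweep spectral width, Hz.
#' @param offset carrier position in Hz from 0 ppm.
#' @param nucleus `"1H"` or `"13C"`.
#' @param solvent solvent label.
#' @param noise_sigma noise standard deviation of the real part (filled by
#'   [estimate_noise()]).
#' @param acquired number of acquired (pre-zero-fill) complex points, used
#'   by the model-based phasing stage; defaults to half the spectrum size.
#' @return an object of class `Spectrum`.
#' @export
new_spectrum <- function(intensity, ppm, sfrq, sweep, offset = 0,
                         nucleus = c("1H", "13C"), solvent = "chloroform",
                         noise_sigma = NA_real_, acquired = NULL) {
  nucleus <- match.arg(nucleus)
  if (length(intensity) != length(ppm))
    stop("intensity and ppm axis lengths differ")
  d <- diff(ppm)
  if (any(d >= 0)) stop("ppm axis must be strictly decreasing")
  if (!is.complex(intensity)) intensity <- as.complex(intensity)
  if (is.null(acquired)) acquired <- length(intensity) %/% 2L
  structure(list(intensity = intensity, ppm = ppm, sfrq = sfrq,
                 sweep = sweep, offset = offset, nucleus = nucleus,
                 solvent = solvent, noise_sigma = noise_sigma,
                 acquired = as.integer(acquired)),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum> %s, %d points, %.3f..%.3f ppm, solvent %s%s\n",
              x$nucleus, length(x$intensity),
              max(x$ppm), min(x$ppm), x$solvent,
              if (is.na(x$noise_sigma)) ""
              else sprintf(", noise sd %.3g", x$noise_sigma)))
  invisible(x)
}

# ppm -> nearest index on the (descending) axis
ppm_to_index <- function(spectrum, ppm) {
  vapply(ppm, function(p) which.min(abs(spectrum$ppm - p)), integer(1))
}

# Hz per spectral point
hz_per_point <- function(spectrum) spectrum$sweep / length(spectrum$ppm)

#' Zero/first-order phase parameters
#'
#' First-order phase is linear in fractional position across the displayed
#' (descending-ppm) spectrum: the correction applied at fractional position
#' `x` in `[0, 1]` (0 at the first displayed point, the high-ppm edge) is
#' `exp(-1i * (phi0 + phi1 * x))`.
#'
#' @param phi0 zero-order phase, radians; wrapped to (-pi, pi].
#' @param phi1 first-order phase across the full sweep, radians.
#' @return an object of class `PhaseParams`.
#' @export
phase_params <- function(phi0 = 0, phi1 = 0) {
  structure(list(phi0 = wrap_phase(phi0), phi1 = phi1), class = "PhaseParams")
}

wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  ifelse(w <= -pi, w + 2 * pi, w)   # report in (-pi, pi]
}

#' @export
print.PhaseParams <- function(x, ...) {
  cat(sprintf("<PhaseParams> phi0 = %.2f deg, phi1 = %.2f deg\n",
              x$phi0 * 180 / pi, x$phi1 * 180 / pi))
  invisible(x)
}

#' Calculated shifts for one candidate isomer
#'
#' @param candidate_id identifier string.
#' @param nucleus `"1H"` or `"13C"`.
#' @param atoms data.frame with columns `label` (unique atom labels) and
#'   `shift` (calculated shift, ppm).
#' @param methyl_groups list of character vectors, each the three H labels of
#'   one methyl group (1H only).
#' @param labile named logical vector (or NULL), TRUE for exchangeable
#'   protons (H on O/N/S); names are atom labels.
#' @param conformers optional data.frame with columns `conformer`, `label`,
#'   `shift` (or `shielding`) and `energy` (relative, kJ/mol) for Boltzmann
#'   averaging.
#' @return an object of class `CandidateShifts`.
#' @export
candidate_shifts <- function(candidate_id, nucleus = c("1H", "13C"), atoms,
                             methyl_groups = list(), labile = NULL,
                             conformers = NULL) {
  nucleus <- match.arg(nucleus)
  stopifnot(is.data.frame(atoms), all(c("label", "shift") %in% names(atoms)))
  if (anyDuplicated(atoms$label)) stop("atom labels must be unique")
  if (length(methyl_groups)) {
    all_m <- unlist(methyl_groups)
    if (anyDuplicated(all_m)) stop("methyl groups must be disjoint")
    if (!all(vapply(methyl_groups, length, 1L) == 3L))
      stop("each methyl group must list exactly three protons")
  }
  if (is.null(labile)) labile <- setNames(rep(FALSE, nrow(atoms)), atoms$label)
  structure(list(candidate_id = candidate_id, nucleus = nucleus,
                 atoms = atoms, methyl_groups = methyl_groups,
                 labile = labile, conformers = conformers),
            class = "CandidateShifts")
}

#' @export
print.CandidateShifts <- function(x, ...) {
  cat(sprintf("<CandidateShifts> %s (%s): %d atoms, %d methyl groups\n",
              x$candidate_id, x$nucleus, nrow(x$atoms),
              length(x$methyl_groups)))
  invisible(x)
}
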