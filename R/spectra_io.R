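#' Read a Bruker-style acquisition directory
#'
#' Reads the minimal Bruker 1D dialect: a binary `fid` file of interleaved
#' real/imaginary samples plus an `acqus` key/value parameter file. Required
#' keys: `TD` (total real+imaginary point count), `SW_h` (sweep, Hz), `SFO1`
#' (spectrometer frequency, MHz), `O1` (carrier offset, Hz), `BYTORDA`
#' (0 little-endian, 1 big-endian), `DTYPA` (0 = int32, 2 = float64),
#' `NUC1`, `SOLVENT`, and optionally `GRPDLY`. Anything else is ignored;
#' unsupported data types are rejected explicitly rather than guessed.
#'
#' @param directory_path path to the acquisition directory.
#' @return a [raw_fid()] object.
#' @export
read_bruker <- function(directory_path) {
  if (!dir.exists(directory_path))
    stop("no such directory: ", directory_path)
  acqus_path <- file.path(directory_path, "acqus")
  fid_path <- file.path(directory_path, "fid")
  if (!file.exists(acqus_path))
    stop("missing acquisition parameter file 'acqus' in ", directory_path)
  if (!file.exists(fid_path))
    stop("missing binary 'fid' file in ", directory_path)

  pars <- parse_bruker_params(acqus_path)
  need <- c("TD", "SW_h", "SFO1", "O1", "BYTORDA", "DTYPA", "NUC1", "SOLVENT")
  missing_keys <- setdiff(need, names(pars))
  if (length(missing_keys))
    stop("acqus is missing required key(s): ",
         paste(missing_keys, collapse = ", "))

  td <- as.integer(pars[["TD"]])
  endian <- if (as.integer(pars[["BYTORDA"]]) == 1L) "big" else "little"
  dtypa <- as.integer(pars[["DTYPA"]])
  if (!dtypa %in% c(0L, 2L))
    stop("unsupported DTYPA ", dtypa, " (supported: 0 = int32, 2 = float64)")
  nbytes <- if (dtypa == 0L) 4L else 8L
  what <- if (dtypa == 0L) "integer" else "double"

  expected <- td * nbytes
  actual <- file.size(fid_path)
  if (actual < expected)
    stop(sprintf("truncated fid: expected %d bytes (TD = %d), found %d",
                 expected, td, actual))
  con <- file(fid_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = what, n = td, size = nbytes, endian = endian)
  if (length(raw_vals) < td) stop("truncated fid: short read")

  re <- raw_vals[seq(1L, td, by = 2L)]
  im <- raw_vals[seq(2L, td, by = 2L)]
  nuc <- gsub("[<>]", "", pars[["NUC1"]])
  if (!nuc %in% c("1H", "13C"))
    stop("unsupported nucleus '", nuc, "' (supported: 1H, 13C)")
  gd <- if ("GRPDLY" %in% names(pars)) round(as.numeric(pars[["GRPDLY"]])) else 0L

  raw_fid(points = complex(real = re, imaginary = im),
          sfrq = as.numeric(pars[["SFO1"]]),
          sweep = as.numeric(pars[["SW_h"]]),
          offset = as.numeric(pars[["O1"]]),
          nucleus = nuc,
          solvent = gsub("[<>]", "", pars[["SOLVENT"]]),
          group_delay = gd)
}

parse_bruker_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- grep("^##\\$", lines, value = TRUE)
  keys <- sub("^##\\$([^=]+)=.*$", "\\1", kv)
  vals <- trimws(sub("^##\\$[^=]+=", "", kv))
  setNames(as.list(vals), trimws(keys))
}

#' Write a Bruker-style acquisition directory
#'
#' Emits the same minimal dialect that [read_bruker()] consumes; used to
#' materialize synthetic fixtures as on-disk raw data.
#'
#' @param fid a [raw_fid()] object.
#' @param directory_path output directory (created if needed).
#' @param dtypa 0 to store int32 (values rounded), 2 for float64.
#' @param endian `"little"` or `"big"`.
#' @return `directory_path`, invisibly.
#' @export
write_bruker <- function(fid, directory_path, dtypa = 2L,
                         endian = c("little", "big")) {
  endian <- match.arg(endian)
  stopifnot(inherits(fid, "RawFID"), dtypa %in% c(0L, 2L))
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  n <- length(fid$points)
  inter <- numeric(2L * n)
  inter[seq(1L, 2L * n, by = 2L)] <- Re(fid$points)
  inter[seq(2L, 2L * n, by = 2L)] <- Im(fid$points)
  con <- file(file.path(directory_path, "fid"), "wb")
  if (dtypa == 0L) {
    writeBin(as.integer(round(inter)), con, size = 4L, endian = endian)
  } else {
    writeBin(as.double(inter), con, size = 8L, endian = endian)
  }
  close(con)
  acqus <- c(
    "##TITLE= synthetic acquisition parameters",
    "##JCAMPDX= 5.0",
    sprintf("##$TD= %d", 2L * n),
    sprintf("##$SW_h= %.10g", fid$sweep),
    sprintf("##$SFO1= %.10g", fid$sfrq),
    sprintf("##$O1= %.10g", fid$offset),
    sprintf("##$BYTORDA= %d", if (endian == "big") 1L else 0L),
    sprintf("##$DTYPA= %d", dtypa),
    sprintf("##$GRPDLY= %d", fid$group_delay),
    sprintf("##$NUC1= <%s>", fid$nucleus),
    sprintf("##$SOLVENT= <%s>", fid$solvent),
    "##END=")
  writeLines(acqus, file.path(directory_path, "acqus"))
  invisible(directory_path)
}

#' Read a 1D JCAMP-DX record
#'
#' Minimal JCAMP-DX 1D reader, AFFN (plain numeric) encoding only.
#' Frequency-domain records (`##DATATYPE= NMR SPECTRUM`, single `##XYDATA=
#' (X++(Y..Y))` block) are returned as a [new_spectrum()]; time-domain
#' records (`##DATATYPE= NMR FID`, `##NTUPLES` with R and I `##DATA TABLE`
#' pages) as a [raw_fid()]. Compressed encodings (SQZ/DIF/PAC) are rejected.
#'
#' @param file_path path to a JCAMP-DX file.
#' @return a `RawFID` or `Spectrum`, depending on the record type.
#' @export
read_jcamp <- function(file_path) {
  if (!file.exists(file_path)) stop("no such file: ", file_path)
  lines <- readLines(file_path, warn = FALSE)
  if (!length(lines) || !any(grepl("^##TITLE", lines)))
    stop("not a JCAMP-DX file (missing ##TITLE): ", file_path)
  get1 <- function(key) {
    hit <- grep(paste0("^##\\.?", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[[1]]))
  }
  dtype <- toupper(get1("DATATYPE") %||% get1("DATA TYPE") %||% "")
  freq <- as.numeric(get1("\\.OBSERVE FREQUENCY") %||% get1("OBSERVEFREQUENCY") %||% NA)
  nuc <- gsub("[\\^<>]", "", get1("\\.OBSERVE NUCLEUS") %||% "1H")
  if (grepl("H", nuc)) nuc <- "1H" else nuc <- "13C"
  solvent <- get1("\\.SOLVENT NAME") %||% "chloroform"

  check_affn <- function(datalines) {
    if (any(grepl("[A-DF-Za-df-z@%]", gsub("[Ee][+-]?[0-9]+", "", datalines))))
      stop("unsupported JCAMP-DX encoding (only AFFN is supported)")
  }

  if (grepl("FID", dtype)) {
    pages <- parse_jcamp_ntuples(lines, check_affn)
    sw <- as.numeric(get1("\\$SW_h") %||% get1("SW_h"))
    o1 <- as.numeric(get1("\\$O1") %||% "0")
    gd <- as.integer(get1("\\$GRPDLY") %||% "0")
    if (is.na(sw) || is.na(freq)) {
      # fall back to the time increment of the R page
      dt <- pages$dx
      sw <- 1 / dt
    }
    raw_fid(points = complex(real = pages$R, imaginary = pages$I),
            sfrq = freq, sweep = sw, offset = o1, nucleus = nuc,
            solvent = solvent, group_delay = gd)
  } else if (grepl("SPECTRUM", dtype) || !is.null(get1("XYDATA"))) {
    i0 <- grep("^##XYDATA=", lines)
    if (!length(i0)) stop("no ##XYDATA block found")
    iend <- grep("^##", lines)
    iend <- min(iend[iend > i0[1]], length(lines) + 1L)
    datalines <- lines[(i0[1] + 1L):(iend - 1L)]
    check_affn(datalines)
    firstx <- as.numeric(get1("FIRSTX")); lastx <- as.numeric(get1("LASTX"))
    npt <- as.integer(get1("NPOINTS"))
    yfac <- as.numeric(get1("YFACTOR") %||% "1")
    y <- unlist(lapply(datalines, function(l) {
      v <- as.numeric(strsplit(trimws(l), "[ \t,]+")[[1]])
      v[-1]   # first value on each line is the X of the line
    }))
    if (length(y) != npt)
      stop(sprintf("JCAMP data table has %d points, header says %d",
                   length(y), npt))
    ppm <- seq(firstx, lastx, length.out = npt)
    ord <- order(ppm, decreasing = TRUE)
    sw <- abs(firstx - lastx) * freq
    new_spectrum(intensity = as.complex(y[ord] * yfac), ppm = ppm[ord],
                 sfrq = freq, sweep = sw,
                 offset = mean(range(ppm)) * freq, nucleus = nuc,
                 solvent = solvent)
  } else {
    stop("unsupported JCAMP-DX data type: '", dtype, "'")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_jcamp_ntuples <- function(lines, check_affn) {
  starts <- grep("^##DATA TABLE=", lines)
  if (length(starts) < 2L)
    stop("JCAMP-DX FID requires two ##DATA TABLE pages (R and I)")
  bounds <- grep("^##", lines)
  out <- list()
  pagesym <- grep("^##PAGE=", lines, value = TRUE)
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    iend <- min(bounds[bounds > i0], length(lines) + 1L)
    datalines <- lines[(i0 + 1L):(iend - 1L)]
    check_affn(datalines)
    vals <- lapply(datalines, function(l)
      as.numeric(strsplit(trimws(l), "[ \t,]+")[[1]]))
    xs <- vapply(vals, `[`, numeric(1), 1L)
    y <- unlist(lapply(vals, `[`, -1L))
    comp <- if (grepl("\\(X\\+\\+\\(I", lines[i0])) "I" else "R"
    out[[comp]] <- y
    if (length(xs) > 1L && is.null(out$dx))
      out$dx <- (xs[2] - xs[1]) / (length(vals[[1]]) - 1L)
  }
  if (is.null(out$R) || is.null(out$I))
    stop("JCAMP-DX FID pages R and I not both found")
  out
}

#' Write a 1D JCAMP-DX record
#'
#' Counterpart of [read_jcamp()]; AFFN encoding. A `RawFID` is written as an
#' NMR FID with R/I data-table pages; a `Spectrum` as an NMR SPECTRUM with a
#' real-part `##XYDATA` block.
#'
#' @param x a `RawFID` or `Spectrum`.
#' @param file_path output path.
#' @return `file_path`, invisibly.
#' @export
write_jcamp <- function(x, file_path) {
  fmt_table <- function(y, xs) {
    per <- 6L
    idx <- seq(1L, length(y), by = per)
    vapply(idx, function(i) {
      j <- min(i + per - 1L, length(y))
      paste(c(sprintf("%.8g", xs[i]), sprintf("%.8g", y[i:j])),
            collapse = " ")
    }, character(1))
  }
  if (inherits(x, "RawFID")) {
    n <- length(x$points)
    t <- (seq_len(n) - 1) / x$sweep
    body <- c(
      "##TITLE= synthetic FID",
      "##JCAMPDX= 6.0",
      "##DATATYPE= NMR FID",
      sprintf("##.OBSERVE FREQUENCY= %.10g", x$sfrq),
      sprintf("##.OBSERVE NUCLEUS= ^%s", x$nucleus),
      sprintf("##.SOLVENT NAME= %s", x$solvent),
      sprintf("##$SW_h= %.10g", x$sweep),
      sprintf("##$O1= %.10g", x$offset),
      sprintf("##$GRPDLY= %d", x$group_delay),
      "##NTUPLES= NMR FID",
      "##PAGE= N=1",
      "##DATA TABLE= (X++(R..R)), XYDATA",
      fmt_table(Re(x$points), t),
      "##PAGE= N=2",
      "##DATA TABLE= (X++(I..I)), XYDATA",
      fmt_table(Im(x$points), t),
      "##END NTUPLES= NMR FID",
      "##END=")
  } else if (inherits(x, "Spectrum")) {
    y <- Re(x$intensity)
    body <- c(
      "##TITLE= processed spectrum",
      "##JCAMPDX= 6.0",
      "##DATATYPE= NMR SPECTRUM",
      sprintf("##.OBSERVE FREQUENCY= %.10g", x$sfrq),
      sprintf("##.OBSERVE NUCLEUS= ^%s", x$nucleus),
      sprintf("##.SOLVENT NAME= %s", x$solvent),
      "##XUNITS= PPM",
      "##YUNITS= ARBITRARY",
      "##YFACTOR= 1",
      sprintf("##FIRSTX= %.10g", x$ppm[1]),
      sprintf("##LASTX= %.10g", x$ppm[length(x$ppm)]),
      sprintf("##NPOINTS= %d", length(y)),
      "##XYDATA= (X++(Y..Y))",
      fmt_table(y, x$ppm),
      "##END=")
  } else stop("x must be a RawFID or Spectrum")
  writeLines(body, file_path)
  invisible(file_path)
}

#' Fourier transform a raw FID into a calibrated spectrum
#'
#' Applies exponential apodization, removes the digital-filter group delay
#' (circular left shift), halves the first time-domain point (standard
#' discrete-FT baseline-offset correction), zero fills to
#' `zero_fill_factor` times the next power of two, transforms, and builds a
#' descending ppm axis from the sweep width, carrier offset and
#' spectrometer frequency.
#'
#' @param fid a [raw_fid()].
#' @param line_broadening exponential line broadening, Hz (adds this amount
#'   to every linewidth). Default 0.3 Hz for 1H, 1.0 Hz for 13C.
#' @param zero_fill_factor integer >= 1.
#' @param first_point_scale scale applied to the first time-domain point
#'   before the transform; the conventional 0.5 removes the constant
#'   baseline offset of the discrete FT of a half-line signal. Set to 1 for
#'   a strictly power-preserving transform.
#' @return a [new_spectrum()].
#' @export
fourier_transform <- function(fid, line_broadening = NULL, zero_fill_factor = 2L,
                      first_point_scale = 0.5) {
  stopifnot(inherits(fid, "RawFID"))
  if (is.null(line_broadening))
    line_broadening <- if (fid$nucleus == "1H") 0.3 else 1.0
  if (line_broadening < 0) stop("line_broadening must be >= 0")
  zero_fill_factor <- as.integer(zero_fill_factor)
  if (zero_fill_factor < 1L) stop("zero_fill_factor must be >= 1")

  x <- fid$points
  n <- length(x)
  if (fid$group_delay > 0L) {
    s <- fid$group_delay %% n
    if (s > 0L) x <- c(x[(s + 1L):n], x[1:s])
  }
  t <- (seq_len(n) - 1) / fid$sweep
  if (line_broadening > 0) x <- x * exp(-pi * line_broadening * t)
  x[1] <- x[1] * first_point_scale

  nfft <- zero_fill_factor * 2^ceiling(log2(n))
  xz <- c(x, complex(real = rep(0, nfft - n)))
  X <- fft(xz)
  # reorder to ascending frequency (-sw/2 .. sw/2 - sw/N), then flip to
  # descending ppm for display
  half <- nfft / 2
  Xs <- c(X[(half + 1):nfft], X[1:half])
  f_asc <- (seq_len(nfft) - 1 - half) / nfft * fid$sweep
  ppm_asc <- (fid$offset + f_asc) / fid$sfrq
  ord <- rev(seq_len(nfft))
  new_spectrum(intensity = Xs[ord], ppm = ppm_asc[ord], sfrq = fid$sfrq,
               sweep = fid$sweep, offset = fid$offset, nucleus = fid$nucleus,
               solvent = fid$solvent, acquired = n)
}
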