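test_that("Bruker round trip preserves data and metadata", {
  spec <- spectrum_spec(mrow(2.5, protons = 2), noise_sd = 1,
                        points = 1024L, sweep = 4800, field = 400,
                        seed = 11L)
  sim <- simulate_fid(spec)
  d <- withr::local_tempdir()
  write_bruker(sim$fid, d)
  fid <- read_bruker(d)
  expect_equal(fid$points, sim$fid$points, tolerance = 1e-12)
  expect_equal(fid$sfrq, 400)
  expect_equal(fid$sweep, 4800)
  expect_equal(fid$nucleus, "1H")
  expect_equal(fid$group_delay, 0L)

  # big- and little-endian encodings of the same array read identically
  d2 <- withr::local_tempdir()
  write_bruker(sim$fid, d2, endian = "big")
  fid_be <- read_bruker(d2)
  expect_identical(fid_be$points, fid$points)
})

test_that("Bruker reader rejects broken inputs with named errors", {
  d <- withr::local_tempdir()
  expect_error(read_bruker(d), "acqus")
  spec <- spectrum_spec(mrow(2.5), points = 1024L, seed = 2L)
  sim <- simulate_fid(spec)
  write_bruker(sim$fid, d)
  file.remove(file.path(d, "fid"))
  expect_error(read_bruker(d), "fid")
  # drop a required key
  write_bruker(sim$fid, d)
  acqus <- readLines(file.path(d, "acqus"))
  writeLines(acqus[!grepl("SW_h", acqus)], file.path(d, "acqus"))
  expect_error(read_bruker(d), "SW_h")
  # truncated binary
  write_bruker(sim$fid, d)
  bin <- readBin(file.path(d, "fid"), "raw", n = 999999)
  writeBin(bin[1:100], file.path(d, "fid"))
  expect_error(read_bruker(d), "truncated")
})

test_that("JCAMP-DX round trips both record types and rejects junk", {
  spec <- spectrum_spec(mrow(3.1, "d", 7, 2), noise_sd = 1,
                        points = 1024L, seed = 3L)
  sim <- simulate_fid(spec)
  f <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(sim$fid, f)
  fid <- read_jcamp(f)
  expect_s3_class(fid, "RawFID")
  expect_lt(max(Mod(fid$points - sim$fid$points)) / max(Mod(sim$fid$points)),
            1e-6)

  sp <- fourier_transform(sim$fid)
  f2 <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(sp, f2)
  sp2 <- read_jcamp(f2)
  expect_s3_class(sp2, "Spectrum")
  expect_equal(range(sp2$ppm), range(sp$ppm), tolerance = 1e-6)

  f3 <- withr::local_tempfile(fileext = ".jdx")
  writeLines("", f3)
  expect_error(read_jcamp(f3), "TITLE")
  # SQZ-style compressed payloads are rejected, not misread
  writeLines(c("##TITLE= x", "##DATATYPE= NMR SPECTRUM",
               "##.OBSERVE FREQUENCY= 400", "##FIRSTX= 10", "##LASTX= 0",
               "##NPOINTS= 4", "##XYDATA= (X++(Y..Y))",
               "10 A123J456", "##END="), f3)
  expect_error(read_jcamp(f3), "encoding")
})

test_that("Fourier transform puts a damped sinusoid at its frequency", {
  # single decaying complex sinusoid at +200 Hz from the carrier
  sw <- 4800; sfrq <- 400; n <- 2048L
  t <- (0:(n - 1)) / sw
  fid <- raw_fid(exp((2i * pi * 200 - pi * 2) * t), sfrq = sfrq,
                 sweep = sw, offset = 5 * sfrq, nucleus = "1H")
  sp <- fourier_transform(fid, line_broadening = 0, zero_fill_factor = 1L)
  i <- which.max(Re(sp$intensity))
  expect_lt(abs(sp$ppm[i] - (5 + 200 / sfrq)), sw / n / sfrq)  # one point

  # zero FID -> zero spectrum
  fid0 <- raw_fid(complex(real = rep(0, 512)), sfrq = sfrq, sweep = sw,
                  nucleus = "1H")
  expect_true(all(Mod(fourier_transform(fid0)$intensity) == 0))
})

test_that("zero filling does not move peaks", {
  spec <- spectrum_spec(mrow(2.2, "d", 8), points = 2048L, seed = 5L)
  sim <- simulate_fid(spec)
  pk <- function(zf) {
    sp <- fourier_transform(sim$fid, line_broadening = 0,
                            zero_fill_factor = zf)
    sp$ppm[which.max(Re(sp$intensity))]
  }
  coarse_spacing <- 4000 / (2 * 2048) / 400
  expect_lt(abs(pk(2L) - pk(4L)), coarse_spacing / 2)
})

test_that("transform conserves power when not apodized", {
  set.seed(8)
  n <- 1024L
  fid <- raw_fid(complex(real = rnorm(n), imaginary = rnorm(n)),
                 sfrq = 400, sweep = 4000, nucleus = "1H")
  sp <- fourier_transform(fid, line_broadening = 0, zero_fill_factor = 1L,
                          first_point_scale = 1)
  p_time <- sum(Mod(fid$points)^2)
  p_freq <- sum(Mod(sp$intensity)^2) / length(sp$intensity)
  expect_equal(p_freq, p_time, tolerance = 1e-10)
})

test_that("fixture round trip recovers generating peak positions", {
  # reader -> transform reproduces generator line positions within a point
  n_ok <- 0L; n_tot <- 0L
  for (s in 1:6) {
    spec <- random_proton_spec(300 + s, n_multiplets = c(3L, 6L), snr = 20)
    sim <- simulate_fid(spec)
    d <- withr::local_tempdir()
    write_bruker(sim$fid, d)
    sp <- fourier_transform(read_bruker(d))
    hzpt <- sp$sweep / length(sp$ppm)
    re <- Re(sp$intensity)
    for (p in sim$truth$lines$ppm) {
      i <- which.min(abs(sp$ppm - p))
      w <- (i - 3):(i + 3)
      j <- w[which.max(re[w])]
      n_tot <- n_tot + 1L
      if (abs(sp$ppm[j] - p) * sp$sfrq <= hzpt) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.99)
})
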