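test_that("Hungarian solver equals exhaustive search", {
  # trivial diagonal case
  M <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  a <- assign_hungarian(M)
  expect_equal(as.integer(a), c(1L, 2L))

  # random 6x6 instances against the permutation oracle
  set.seed(12)
  for (r in 1:20) {
    cost <- matrix(rexp(36), 6, 6)
    a <- solve_assignment(cost)
    b <- exhaustive_assignment(cost)
    expect_equal(attr(a, "cost"), attr(b, "cost"), tolerance = 1e-10)
  }

  # rectangular: 3 rows into 5 columns
  set.seed(13)
  cost <- matrix(runif(15), 3, 5)
  a <- solve_assignment(cost)
  b <- exhaustive_assignment(cost)
  expect_equal(attr(a, "cost"), attr(b, "cost"), tolerance = 1e-10)
  expect_equal(anyDuplicated(as.integer(a)), 0L)
})

test_that("Boltzmann averaging weights conformers correctly", {
  one <- data.frame(conformer = "a", label = c("C1", "C2"),
                    shift = c(10, 20), energy = 0)
  expect_equal(boltzmann_average(one)$shift, c(10, 20))

  # equal energies: arithmetic mean
  two <- data.frame(conformer = rep(c("a", "b"), each = 2),
                    label = rep(c("C1", "C2"), 2),
                    shift = c(10, 20, 14, 24), energy = 0)
  expect_equal(boltzmann_average(two)$shift, c(12, 22))

  # dE = RT ln 3 gives 0.75/0.25 weights
  RT <- 0.00831446 * 298.15
  three <- data.frame(conformer = rep(c("a", "b"), each = 1),
                      label = "C1", shift = c(10, 20),
                      energy = c(0, RT * log(3)))
  expect_equal(boltzmann_average(three)$shift, 0.75 * 10 + 0.25 * 20,
               tolerance = 1e-9)

  # non-finite energies are dropped with a warning
  bad <- data.frame(conformer = c("a", "b"), label = "C1",
                    shift = c(10, 20), energy = c(0, NaN))
  expect_warning(out <- boltzmann_average(bad), "non-finite")
  expect_equal(out$shift, 10)
})

test_that("external and internal scaling behave per contract", {
  expect_equal(scale_external(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(scale_external(100, c(1.05, 2.0)), (100 - 2) / 1.05)
  expect_error(scale_external(1, c(0, 0)), "slope")

  # exact linear relation recovered to machine precision
  exps <- c(10, 40, 90, 140, 170)
  calc <- 1.05 * exps + 2.0
  expect_equal(scale_internal(calc, exps), c(1.05, 2.0), tolerance = 1e-10)

  # gross outlier down-weighted
  set.seed(14)
  exps2 <- seq(10, 180, length.out = 12)
  calc2 <- 1.04 * exps2 + 1.0 + rnorm(12, 0, 0.1)
  calc2[5] <- calc2[5] + 40
  f <- scale_internal(calc2, exps2)
  expect_lt(abs(f[1] - 1.04), 0.05)

  # fewer than three pairs: identity with warning
  expect_warning(f2 <- scale_internal(c(1, 2), c(1, 2)), "pairs")
  expect_equal(f2, c(1, 0))
  # degenerate x variance: identity
  expect_warning(f3 <- scale_internal(c(1, 2, 3), c(5, 5, 5)), "degenerate")
  expect_equal(f3, c(1, 0))
  # implausible slope: identity
  expect_warning(f4 <- scale_internal(c(1, 5, 9), c(1, 2, 3)), "slope")
  expect_equal(f4, c(1, 0))
})

test_that("probability matrix reflects the error model and 13C weights", {
  m <- error_model("13C", 0, 2.5)
  M <- build_matrix(10, c(10, 15), m, "13C")
  expect_equal(M[1, 1] / M[1, 2], exp(2), tolerance = 1e-9)

  # identical shifts and peaks: row maxima on the diagonal
  shifts <- c(20, 60, 120)
  M2 <- build_matrix(shifts, shifts, m, "13C")
  expect_equal(apply(M2, 1L, which.max), 1:3)

  # multiple-assignment penalty: strictly decreasing in t, faster for
  # higher group rank
  M_t0 <- build_matrix(10, 10, m, "13C", assignment_counts = 0L,
                       weights = 1, groups = 1L)
  M_t1k1 <- build_matrix(10, 10, m, "13C", assignment_counts = 1L,
                         weights = 1, groups = 1L)
  M_t1k2 <- build_matrix(10, 10, m, "13C", assignment_counts = 1L,
                         weights = 1, groups = 2L)
  expect_lt(M_t1k1[1, 1], M_t0[1, 1])
  expect_lt(M_t1k2[1, 1], M_t1k1[1, 1])

  # 1H matrix carries no weights or penalties
  Mh <- build_matrix(1.0, 1.0, error_model("1H", 0, 0.19), "1H")
  expect_equal(Mh[1, 1], error_pdf(0, error_model("1H", 0, 0.19)))
})

test_that("13C assignment recovers a known linear map and degeneracy", {
  set.seed(15)
  true <- sort(runif(10, 10, 180))
  peaks <- data.frame(position = true, amplitude = 100, group = 1L,
                      weight = 1)
  cand <- candidate_shifts("c", "13C",
                           data.frame(label = paste0("C", 1:10),
                                      shift = 1.05 * true + 2.0))
  a <- assign_carbons(cand, peaks)
  expect_equal(a$table$peak_ppm, true, tolerance = 1e-9)
  expect_equal(a$scaling$internal[1], 1.05, tolerance = 0.01)

  # degenerate pair: 10 shifts on 9 peaks, one peak used twice
  true9 <- true[-5]
  peaks9 <- data.frame(position = true9, amplitude = 100, group = 1L,
                       weight = 1)
  shifts10 <- c(1.02 * true9 + 0.5, 1.02 * true9[4] + 0.5 + 0.3)
  cand10 <- candidate_shifts("d", "13C",
                             data.frame(label = paste0("C", 1:10),
                                        shift = shifts10))
  a2 <- assign_carbons(cand10, peaks9)
  counts <- table(a2$table$peak_index)
  expect_equal(max(counts), 2L)
  expect_equal(sum(counts == 2L), 1L)

  # idempotence: a clean stage-1-optimal case is unchanged by stages 2-3
  candc <- candidate_shifts("e", "13C",
                            data.frame(label = paste0("C", 1:10),
                                       shift = true))
  a3 <- assign_carbons(candc, peaks)
  expect_equal(a3$table$peak_ppm, true, tolerance = 1e-9)
  expect_false(any(a3$table$reassigned))
})

test_that("bias reassignment rescues shifts stranded on weak peaks", {
  peaks <- data.frame(position = c(100, 103), amplitude = c(5, 500),
                      group = c(2L, 1L), weight = c(0.1, 1.0))
  tab <- data.frame(label = "C1", calc_shift = 100, scaled_shift = 100,
                    peak_index = 1L, peak_ppm = 100, error = 0)
  res <- assignment_result(tab, "13C")
  out <- bias_reassign(res, peaks)
  expect_equal(out$table$peak_index, 2L)
  expect_true(out$table$reassigned)

  # nothing unassigned: unchanged
  peaks1 <- peaks[1, ]
  res1 <- assignment_result(tab, "13C")
  out1 <- bias_reassign(res1, peaks1)
  expect_equal(out1$table$peak_index, 1L)

  # two biased shifts competing for one strong peak: higher bias wins
  peaks2 <- data.frame(position = c(100, 104, 102),
                       amplitude = c(5, 8, 800),
                       group = c(2L, 2L, 1L),
                       weight = c(0.05, 0.2, 1.0))
  tab2 <- data.frame(label = c("C1", "C2"), calc_shift = c(100, 104),
                     scaled_shift = c(100, 104), peak_index = c(1L, 2L),
                     peak_ppm = c(100, 104), error = 0)
  out2 <- bias_reassign(assignment_result(tab2, "13C"), peaks2)
  # C1 has bias 1/0.05 = 20 > C2 at 1/0.2 = 5: C1 takes the strong peak
  expect_equal(out2$table$peak_index[out2$table$label == "C1"], 3L)
})

test_that("1H assignment honors methyls and integral capacities", {
  mults <- list(list(center = 1.0, proton_count = 3L),
                list(center = 2.5, proton_count = 2L),
                list(center = 4.0, proton_count = 1L))
  cand <- candidate_shifts(
    "h", "1H",
    data.frame(label = c("Ma", "Mb", "Mc", "Xa", "Xb", "Y"),
               shift = c(1.05, 0.97, 1.02, 2.55, 2.47, 3.93)),
    methyl_groups = list(c("Ma", "Mb", "Mc")))
  a <- assign_protons(cand, mults)
  tab <- a$table
  expect_equal(tab$peak_index[tab$label %in% c("Ma", "Mb", "Mc")],
               rep(1L, 3))
  expect_equal(tab$peak_index[tab$label %in% c("Xa", "Xb")], rep(2L, 2))
  expect_equal(tab$peak_index[tab$label == "Y"], 3L)
  # capacity conservation: no multiplet over its proton count
  counts <- table(tab$peak_index)
  expect_true(all(counts <= c(3L, 2L, 1L)[as.integer(names(counts))]))

  # single multiplet, single proton: forced matching
  a1 <- suppressWarnings(
    assign_protons(candidate_shifts("s", "1H",
                                    data.frame(label = "H1", shift = 2)),
                   list(list(center = 2.1, proton_count = 1L))))
  expect_equal(a1$table$peak_index, 1L)

  # two methyls on one 6-proton singlet
  cand2 <- candidate_shifts(
    "m2", "1H",
    data.frame(label = c(paste0("A", 1:3), paste0("B", 1:3)),
               shift = c(1.21, 1.19, 1.20, 1.18, 1.22, 1.20)),
    methyl_groups = list(paste0("A", 1:3), paste0("B", 1:3)))
  a2 <- suppressWarnings(
    assign_protons(cand2, list(list(center = 1.2, proton_count = 6L))))
  expect_true(all(a2$table$peak_index == 1L))

  # labile protons are excluded from the assignable set
  cand3 <- candidate_shifts(
    "l", "1H", data.frame(label = c("H1", "OH"), shift = c(2.0, 5.0)),
    labile = c(H1 = FALSE, OH = TRUE))
  a3 <- suppressWarnings(
    assign_protons(cand3, list(list(center = 2.05, proton_count = 1L))))
  expect_equal(a3$table$label, "H1")
})

test_that("internal scaling is a fixed point on error-free linear data", {
  set.seed(16)
  true <- sort(runif(12, 10, 180))
  peaks <- data.frame(position = true, amplitude = 100, group = 1L,
                      weight = 1)
  cand <- candidate_shifts("f", "13C",
                           data.frame(label = paste0("C", 1:12),
                                      shift = 1.04 * true + 1.5))
  a <- assign_carbons(cand, peaks)
  # a further pass from the already-scaled state changes nothing
  f2 <- suppressWarnings(scale_internal(a$table$scaled_shift,
                                        a$table$peak_ppm))
  expect_equal(f2[1], 1, tolerance = 1e-6)
  expect_equal(f2[2], 0, tolerance = 1e-4)
})

test_that("assignment recovers atoms under realistic 13C noise", {
  set.seed(17)
  model <- error_model("13C", 0, 2.5)
  n_ok <- 0L; n_tot <- 0L
  for (r in 1:25) {
    true <- sort(10 + cumsum(runif(12, 7.5, 15)))   # spacing >= 3 sd
    peaks <- data.frame(position = true, amplitude = 100, group = 1L,
                        weight = 1)
    cand <- candidate_shifts("r", "13C",
                             data.frame(label = paste0("C", 1:12),
                                        shift = true + sample_errors(12, model)))
    a <- suppressWarnings(assign_carbons(cand, peaks, model = model))
    n_ok <- n_ok + sum(abs(a$table$peak_ppm - true) < 1e-9)
    n_tot <- n_tot + 12L
  }
  expect_gte(n_ok / n_tot, 0.90)
})
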