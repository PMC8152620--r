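# Assignment of calculated shifts to experimental peaks: probability
# matrix + Hungarian matching, three-stage scaling (external -> internal ->
# bias), 13C amplitude weights and multiple-assignment penalties, 1H
# methyl pre-assignment and integral-capacity constraints.

#' Boltzmann-average per-conformer shifts
#'
#' Conformer weights are proportional to `exp(-dE / RT)`; per-atom shifts
#' are the weighted means. Shieldings (column `shielding`) are converted to
#' shifts via a linear map `shift = (reference - shielding) / slope`.
#'
#' @param conformers data.frame with columns `conformer`, `label`, `energy`
#'   (relative, kJ/mol) and `shift` or `shielding`.
#' @param temperature Kelvin.
#' @param shielding_reference,shielding_slope linear map for
#'   shielding-to-shift conversion (defaults: identity slope; reference
#'   must be supplied when shieldings are given).
#' @return data.frame with columns `label`, `shift`.
#' @export
boltzmann_average <- function(conformers, temperature = 298.15,
                              shielding_reference = NULL,
                              shielding_slope = 1) {
  stopifnot(is.data.frame(conformers),
            all(c("conformer", "label", "energy") %in% names(conformers)))
  R <- 0.00831446   # kJ / (mol K)
  if (!"shift" %in% names(conformers)) {
    if (!"shielding" %in% names(conformers))
      stop("conformer table needs a 'shift' or 'shielding' column")
    if (is.null(shielding_reference))
      stop("shielding_reference required to convert shieldings to shifts")
    conformers$shift <-
      (shielding_reference - conformers$shielding) / shielding_slope
  }
  en <- tapply(conformers$energy, conformers$conformer, function(e) e[1])
  bad <- names(en)[!is.finite(en)]
  if (length(bad)) {
    warning("dropping conformer(s) with non-finite energy: ",
            paste(bad, collapse = ", "))
    conformers <- conformers[!conformers$conformer %in% bad, , drop = FALSE]
    en <- en[!names(en) %in% bad]
  }
  if (!length(en)) stop("no conformers with finite energies")
  w <- exp(-(en - min(en)) / (R * temperature))
  w <- w / sum(w)
  labs <- unique(conformers$label)
  shift <- vapply(labs, function(l) {
    rows <- conformers[conformers$label == l, , drop = FALSE]
    wi <- w[as.character(rows$conformer)]
    sum(rows$shift * wi) / sum(wi)
  }, numeric(1))
  data.frame(label = labs, shift = as.numeric(shift))
}

#' Apply external (literature) scaling factors
#'
#' Removes the systematic linear error of GIAO shift predictions:
#' `scaled = (shift - intercept) / slope`.
#'
#' @param shifts numeric vector, ppm.
#' @param factors numeric `c(slope, intercept)`; slope must be nonzero.
#' @return scaled shifts.
#' @export
scale_external <- function(shifts, factors = c(1, 0)) {
  slope <- factors[1]; intercept <- factors[2]
  if (!is.finite(slope) || slope == 0)
    stop("external scaling slope must be finite and nonzero")
  (shifts - intercept) / slope
}

#' Internal scaling factors from an assignment
#'
#' Ordinary least squares of calculated on experimental shifts with a
#' single outlier-rejection pass (points whose residual exceeds 3 median
#' absolute deviations are dropped and the fit repeated). Degenerate cases
#' (fewer than 3 pairs, zero experimental variance, slope outside
#' [0.8, 1.2]) return the identity with a warning.
#'
#' @param calc,exp paired calculated and experimental shifts, ppm.
#' @return numeric `c(slope, intercept)`.
#' @export
scale_internal <- function(calc, exp) {
  identity_f <- c(1, 0)
  if (length(calc) < 3L) {
    warning("fewer than 3 assigned pairs; internal scaling skipped")
    return(identity_f)
  }
  if (stats::var(exp) == 0) {
    warning("degenerate experimental shifts; internal scaling skipped")
    return(identity_f)
  }
  fit <- lm(calc ~ exp)
  res <- abs(stats::residuals(fit))
  s <- mad(res)
  if (s > 0 && any(res > 3 * s) && sum(res <= 3 * s) >= 3L) {
    ok <- res <= 3 * s
    fit <- lm(calc[ok] ~ exp[ok])
  }
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope < 0.8 || slope > 1.2) {
    warning(sprintf(
      "internal scaling slope %.3f outside [0.8, 1.2]; identity used", slope))
    return(identity_f)
  }
  c(slope, intercept)
}

# Multiple-assignment penalty for 13C: 1 at t = 0, strictly decreasing in
# the times-already-assigned count t, faster for less intense amplitude
# groups (rank k, 1 = most intense).
multiple_assignment_penalty <- function(t, k) {
  (1 / (1 + t))^k
}

#' Build the assignment probability matrix
#'
#' `M[i, j]` is the error-model density of `scaled_shift[i] - peak[j]`.
#' For 13C each element is additionally multiplied by the peak's amplitude
#' weight `A_j` and by the multiple-assignment penalty `(1/(1+t_j))^k_j`
#' (`t_j` = times peak j has already been assigned, `k_j` = its amplitude
#' group rank, 1 = most intense). 1H uses neither weights nor penalties:
#' its capacities come from the integrals.
#'
#' @param scaled_shifts calculated shifts after scaling, ppm.
#' @param peaks experimental peak positions, ppm.
#' @param model an [error_model()].
#' @param nucleus `"1H"` or `"13C"`.
#' @param assignment_counts per-peak t (13C), default all zero.
#' @param weights per-peak amplitude weights (13C), default 1.
#' @param groups per-peak amplitude group ranks (13C), default 1.
#' @return matrix with `length(scaled_shifts)` rows.
#' @export
build_matrix <- function(scaled_shifts, peaks, model,
                         nucleus = c("13C", "1H"),
                         assignment_counts = NULL, weights = NULL,
                         groups = NULL) {
  nucleus <- match.arg(nucleus)
  M <- outer(scaled_shifts, peaks,
             function(s, p) error_pdf(s - p, model))
  if (nucleus == "13C") {
    np <- length(peaks)
    if (is.null(weights)) weights <- rep(1, np)
    if (is.null(groups)) groups <- rep(1L, np)
    if (is.null(assignment_counts)) assignment_counts <- rep(0L, np)
    fac <- weights * multiple_assignment_penalty(assignment_counts, groups)
    M <- sweep(M, 2L, fac, `*`)
  }
  M
}

#' Most probable assignment from a probability matrix
#'
#' Maximizes the product of probabilities, i.e. minimizes the sum of
#' `-log M` (epsilon-floored at 1e-300), by the Hungarian method. Columns
#' may outnumber rows (dummy-free rectangular case); every row (shift) is
#' matched.
#'
#' @param matrix probability matrix (rows = shifts, columns = peaks or
#'   replicated peak slots).
#' @return integer vector of column indices per row, with attribute
#'   `"cost"` (total `-log` probability). Rows whose probabilities are all
#'   zero are matched arbitrarily (flat cost) with a warning.
#' @export
assign_hungarian <- function(matrix) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  zero_rows <- which(apply(matrix, 1L, max) <= 0)
  if (length(zero_rows))
    warning(length(zero_rows),
            " shift(s) had zero probability for every peak; ",
            "their assignment is by position only")
  cost <- -log(pmax(matrix, 1e-300))
  solve_assignment(cost)
}

#' An assignment of calculated shifts to experimental peaks
#'
#' @param table data.frame with one row per atom: `label`, `calc_shift`,
#'   `scaled_shift`, `peak_index`, `peak_ppm`, `error`.
#' @param nucleus nucleus of the assignment.
#' @param scaling list with `external` and `internal` factor pairs.
#' @param stages character log of the stages executed.
#' @param unassigned_peaks integer indices of peaks left unassigned.
#' @return an object of class `AssignmentResult`.
#' @export
assignment_result <- function(table, nucleus, scaling = list(),
                              stages = character(), unassigned_peaks = integer()) {
  structure(list(table = table, nucleus = nucleus, scaling = scaling,
                 stages = stages, unassigned_peaks = unassigned_peaks),
            class = "AssignmentResult")
}

#' @export
print.AssignmentResult <- function(x, ...) {
  cat(sprintf("<AssignmentResult> %s: %d atoms, %d unassigned peak(s)\n",
              x$nucleus, nrow(x$table), length(x$unassigned_peaks)))
  print.data.frame(utils::head(x$table, 10), row.names = FALSE, digits = 4)
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}

# one 13C Hungarian pass with replicated peak columns
carbon_assign_once <- function(scaled, peaks, model, replication_bound) {
  np <- nrow(peaks)
  reps <- replication_bound
  col_peak <- rep(seq_len(np), each = reps)
  col_t <- rep(seq_len(reps) - 1L, times = np)
  M <- build_matrix(scaled, peaks$position[col_peak], model, "13C",
                    assignment_counts = col_t,
                    weights = peaks$weight[col_peak],
                    groups = peaks$group[col_peak])
  a <- assign_hungarian(M)
  peak_idx <- col_peak[a]
  list(peak_index = peak_idx, peak_ppm = peaks$position[peak_idx])
}

#' Three-stage 13C assignment
#'
#' Stage 1: external scaling, probability matrix with amplitude weights and
#' multiple-assignment penalties (peak columns replicated up to
#' `ceil(n_shifts / n_peaks) + 1` times), Hungarian matching. Stage 2:
#' internal linear rescaling from the stage-1 pairs, then reassignment.
#' Stage 3: bias reassignment of shifts stranded on weak peaks
#' ([bias_reassign()]).
#'
#' @param shifts a [candidate_shifts()] (13C).
#' @param peaks data.frame from [group_amplitudes_and_weight()] (columns
#'   `position`, `amplitude`, `group`, `weight`).
#' @param model an [error_model()] for 13C.
#' @param external_factors `c(slope, intercept)` literature scaling.
#' @param bias_window ppm window for the bias stage.
#' @return an [assignment_result()].
#' @export
assign_carbons <- function(shifts, peaks, model = default_error_model("13C"),
                           external_factors = c(1, 0), bias_window = 10) {
  stopifnot(inherits(shifts, "CandidateShifts"), nrow(peaks) >= 1L)
  calc <- shifts$atoms$shift
  labels <- shifts$atoms$label
  ns <- length(calc); np <- nrow(peaks)
  bound <- ceiling(ns / np) + 1L

  scaled <- scale_external(calc, external_factors)
  a <- carbon_assign_once(scaled, peaks, model, bound)
  # two internal-scaling refinements: the first regression is computed on
  # the stage-1 pairs (which may contain systematic misassignments); after
  # reassignment the factors are re-derived from the corrected pairs, so
  # that on error-free linear data a further pass is the identity.  The
  # reported factors are the composition of both maps.
  internal <- c(1, 0)
  stages <- "external+assign"
  for (pass in 1:2) {
    f <- suppressWarnings(scale_internal(scaled, a$peak_ppm))
    scaled <- (scaled - f[2]) / f[1]
    internal <- c(internal[1] * f[1], internal[2] + internal[1] * f[2])
    a <- carbon_assign_once(scaled, peaks, model, bound)
    stages <- c(stages, "internal+reassign")
  }

  tab <- data.frame(label = labels, calc_shift = calc,
                    scaled_shift = scaled,
                    peak_index = a$peak_index, peak_ppm = a$peak_ppm,
                    error = scaled - a$peak_ppm)
  res <- assignment_result(
    tab, "13C",
    scaling = list(external = external_factors, internal = internal),
    stages = stages,
    unassigned_peaks = setdiff(seq_len(np), unique(a$peak_index)))
  bias_reassign(res, peaks, window = bias_window)
}

#' Bias reassignment of shifts stranded on weak peaks
#'
#' For each assigned shift the bias is the summed amplitude weight of the
#' unassigned peaks within `window` ppm of its assigned peak, divided by
#' the weight of the assigned peak. Shifts with bias above one are
#' reassigned in order of decreasing bias, each to the largest-amplitude
#' still-unassigned peak in its window; the vacated peak returns to the
#' unassigned pool.
#'
#' @param result an [assignment_result()] (13C).
#' @param peaks the weighted peak table used for the assignment.
#' @param window ppm half-window.
#' @return the updated `AssignmentResult` (a `reassigned` column marks
#'   moved atoms).
#' @export
bias_reassign <- function(result, peaks, window = 10) {
  tab <- result$table
  np <- nrow(peaks)
  unassigned <- setdiff(seq_len(np), unique(tab$peak_index))
  tab$reassigned <- FALSE
  if (!length(unassigned)) {
    result$table <- tab
    result$stages <- c(result$stages, "bias (no unassigned peaks)")
    return(result)
  }
  bias_of <- function(i, unassigned) {
    near <- unassigned[abs(peaks$position[unassigned] -
                             tab$peak_ppm[i]) <= window]
    if (!length(near)) return(0)
    sum(peaks$weight[near]) / peaks$weight[tab$peak_index[i]]
  }
  biases <- vapply(seq_len(nrow(tab)), bias_of, numeric(1),
                   unassigned = unassigned)
  order_i <- order(biases, decreasing = TRUE)
  order_i <- order_i[biases[order_i] > 1]
  for (i in order_i) {
    # recompute against the current pool; earlier moves may have used it up
    if (bias_of(i, unassigned) <= 1) next
    near <- unassigned[abs(peaks$position[unassigned] -
                             tab$peak_ppm[i]) <= window]
    if (!length(near)) next
    target <- near[which.max(peaks$amplitude[near])]
    vacated <- tab$peak_index[i]
    tab$peak_index[i] <- target
    tab$peak_ppm[i] <- peaks$position[target]
    tab$error[i] <- tab$scaled_shift[i] - tab$peak_ppm[i]
    tab$reassigned[i] <- TRUE
    unassigned <- setdiff(c(unassigned, vacated), tab$peak_index)
  }
  result$table <- tab
  result$stages <- c(result$stages,
                     sprintf("bias (%d reassignment(s))", sum(tab$reassigned)))
  result$unassigned_peaks <- setdiff(seq_len(np), unique(tab$peak_index))
  result
}

# one full 1H pass (methyl phase + remaining protons) at given shifts;
# capacities = per-multiplet proton counts
proton_assign_once <- function(scaled, labels, methyl_groups, capacities,
                               centers, model) {
  nm <- length(centers)
  assign_tab <- data.frame(label = labels, scaled_shift = scaled,
                           peak_index = NA_integer_)
  remaining <- capacities

  # phase A: methyl trios against multiplets with capacity >= 3
  if (length(methyl_groups)) {
    trio_shift <- vapply(methyl_groups, function(g)
      mean(scaled[match(g, labels)]), numeric(1))
    slots_per <- pmax(remaining %/% 3L, 0L)
    cols <- rep(seq_len(nm), times = slots_per)
    deficit <- length(trio_shift) - length(cols)
    if (deficit > 0L) {
      warning("insufficient multiplet capacity for methyl groups; ",
              "closest-peak fallback used")
      extra <- rep(seq_len(nm), length.out = deficit)
      cols <- c(cols, extra)
    }
    M <- build_matrix(trio_shift, centers[cols], model, "1H")
    a <- assign_hungarian(M)
    for (g in seq_along(methyl_groups)) {
      j <- cols[a[g]]
      assign_tab$peak_index[match(methyl_groups[[g]], labels)] <- j
      remaining[j] <- remaining[j] - 3L
    }
  }

  # phase B: remaining protons, one slot per unit of integral
  rest <- which(is.na(assign_tab$peak_index))
  if (length(rest)) {
    remaining <- pmax(remaining, 0L)
    cols <- rep(seq_len(nm), times = remaining)
    deficit <- length(rest) - length(cols)
    if (deficit > 0L) {
      warning("total multiplet proton capacity below the proton count; ",
              "excess protons matched to closest peaks")
      cols <- c(cols, rep(seq_len(nm), length.out = deficit))
    }
    M <- build_matrix(scaled[rest], centers[cols], model, "1H")
    a <- assign_hungarian(M)
    assign_tab$peak_index[rest] <- cols[a]
  }
  assign_tab
}

#' Two-stage 1H assignment with methyl and integral constraints
#'
#' Labile protons are excluded. Methyl trios (mean of the three calculated
#' shifts) are matched first against multiplets with integral capacity of
#' at least three protons, consuming capacity in units of three; the
#' remaining protons are then matched with each multiplet's column
#' replicated once per remaining proton of capacity. After the first pass
#' the internal scaling is computed from the assigned pairs, the shifts
#' rescaled and both phases repeated. No amplitude weighting, bias or
#' multiple-assignment penalty is used: the integrals fix the capacities.
#'
#' @param shifts a [candidate_shifts()] (1H) with methyl groups and labile
#'   flags.
#' @param multiplets list of multiplets with `proton_count` set
#'   ([normalize_integrals()]).
#' @param model an [error_model()] for 1H.
#' @param external_factors `c(slope, intercept)`.
#' @return an [assignment_result()].
#' @export
assign_protons <- function(shifts, multiplets,
                           model = default_error_model("1H"),
                           external_factors = c(1, 0)) {
  stopifnot(inherits(shifts, "CandidateShifts"), length(multiplets) >= 1L)
  centers <- vapply(multiplets, `[[`, numeric(1), "center")
  capacities <- vapply(multiplets, function(m)
    as.integer(m$proton_count), integer(1))
  if (any(is.na(capacities)))
    stop("multiplets must carry proton counts; run normalize_integrals()")

  keep <- !shifts$labile[shifts$atoms$label]
  atoms <- shifts$atoms[keep, , drop = FALSE]
  methyls <- Filter(function(g) all(g %in% atoms$label), shifts$methyl_groups)

  scaled1 <- scale_external(atoms$shift, external_factors)
  a1 <- proton_assign_once(scaled1, atoms$label, methyls, capacities,
                           centers, model)

  internal <- scale_internal(scaled1, centers[a1$peak_index])
  scaled2 <- (scaled1 - internal[2]) / internal[1]
  a2 <- proton_assign_once(scaled2, atoms$label, methyls, capacities,
                           centers, model)

  tab <- data.frame(label = atoms$label, calc_shift = atoms$shift,
                    scaled_shift = scaled2,
                    peak_index = a2$peak_index,
                    peak_ppm = centers[a2$peak_index],
                    error = scaled2 - centers[a2$peak_index])
  assignment_result(
    tab, "1H",
    scaling = list(external = external_factors, internal = internal),
    stages = c("external+assign", "internal+reassign"),
    unassigned_peaks = setdiff(seq_along(centers), unique(a2$peak_index)))
}
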