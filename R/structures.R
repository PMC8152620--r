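# Calculated-shift tables (delimited text) and candidate structure files
# (MDL MOL/SDF): methyl-group and labile-proton detection from
# connectivity.

#' Read a calculated-shift table
#'
#' Delimited text with columns `atom_label`, `shift_ppm` and optionally
#' `conformer_id`, `energy_kJmol` (triggering Boltzmann averaging).
#'
#' @param file_path path to the table.
#' @param candidate_id identifier for the candidate (defaults to the file
#'   name).
#' @param nucleus `"1H"` or `"13C"`.
#' @param sep field separator (whitespace by default).
#' @param temperature Kelvin, for Boltzmann averaging.
#' @return a [candidate_shifts()] (no methyl/labile annotation; add via
#'   [annotate_from_structure()]).
#' @export
read_shift_table <- function(file_path, candidate_id = NULL,
                             nucleus = c("13C", "1H"), sep = "",
                             temperature = 298.15) {
  nucleus <- match.arg(nucleus)
  if (!file.exists(file_path)) stop("no such file: ", file_path)
  if (is.null(candidate_id))
    candidate_id <- tools::file_path_sans_ext(basename(file_path))
  tab <- read.table(file_path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
  if (!all(c("atom_label", "shift_ppm") %in% names(tab)))
    stop("shift table needs columns atom_label and shift_ppm")
  if ("conformer_id" %in% names(tab)) {
    if (!"energy_kJmol" %in% names(tab))
      stop("per-conformer table needs an energy_kJmol column")
    conf <- data.frame(conformer = tab$conformer_id,
                       label = tab$atom_label, shift = tab$shift_ppm,
                       energy = tab$energy_kJmol)
    atoms <- boltzmann_average(conf, temperature = temperature)
    candidate_shifts(candidate_id, nucleus, atoms, conformers = conf)
  } else {
    atoms <- data.frame(label = tab$atom_label, shift = tab$shift_ppm)
    candidate_shifts(candidate_id, nucleus, atoms)
  }
}

#' Write a calculated-shift table
#'
#' @param candidate a [candidate_shifts()].
#' @param file_path output path (tab-separated).
#' @return `file_path`, invisibly.
#' @export
write_shift_table <- function(candidate, file_path) {
  tab <- data.frame(atom_label = candidate$atoms$label,
                    shift_ppm = candidate$atoms$shift)
  write.table(tab, file_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file_path)
}

#' Methyl groups and labile protons from a structure file
#'
#' Parses an MDL MOL/SDF file (via ChemmineR) and derives, from the
#' connectivity: methyl groups (carbons with exactly three attached
#' hydrogens; the three H labels form one group), labile protons (H bonded
#' to O, N or S) and the total H and C counts. Atom labels follow the
#' `<element><index>` convention (H atoms numbered by file order).
#'
#' @param file_path path to a MOL or SDF file (first molecule used).
#' @return list with `methyl_groups`, `labile` (named logical over H
#'   labels), `n_protons`, `n_labile`, `n_carbons`, `labels` (per-atom
#'   labels).
#' @export
read_structure <- function(file_path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("structure-file parsing requires the ChemmineR package")
  if (!file.exists(file_path)) stop("no such file: ", file_path)
  sdf <- ChemmineR::read.SDFset(file_path)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- gsub("_.*$", "", rownames(ab))
  labels <- paste0(elements, seq_along(elements))
  edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))

  neighbors <- function(i) {
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
  }
  h_idx <- which(elements == "H")
  labile <- setNames(rep(FALSE, length(h_idx)), labels[h_idx])
  methyl_groups <- list()
  for (i in which(elements == "C")) {
    nb <- neighbors(i)
    hs <- nb[elements[nb] == "H"]
    if (length(hs) == 3L)
      methyl_groups[[length(methyl_groups) + 1L]] <- labels[hs]
  }
  for (i in h_idx) {
    nb <- neighbors(i)
    if (any(elements[nb] %in% c("O", "N", "S")))
      labile[labels[i]] <- TRUE
  }
  list(methyl_groups = methyl_groups, labile = labile,
       n_protons = length(h_idx), n_labile = sum(labile),
       n_carbons = sum(elements == "C"), labels = labels)
}

#' Attach structure-derived annotation to a candidate
#'
#' @param candidate a [candidate_shifts()].
#' @param structure result of [read_structure()].
#' @return the candidate with methyl groups and labile flags set (1H) or
#'   unchanged (13C).
#' @export
annotate_from_structure <- function(candidate, structure) {
  if (candidate$nucleus != "1H") return(candidate)
  keep <- Filter(function(g) all(g %in% candidate$atoms$label),
                 structure$methyl_groups)
  candidate$methyl_groups <- keep
  lab <- structure$labile[candidate$atoms$label]
  lab[is.na(lab)] <- FALSE
  names(lab) <- candidate$atoms$label
  candidate$labile <- lab
  candidate
}
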