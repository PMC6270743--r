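#' Labeled dsDNA construct sequences
#'
#' The three 48-mer oligonucleotides of the dye-labeled double-stranded DNA
#' standards: two donor strands (labeling positions separated by 10 or 17
#' base pairs from the acceptor position) and the common acceptor strand.
#' `X` marks the thymine labeled at its 5' position via a C6 amino linker;
#' lowercase `g` in the acceptor strand marks the deliberate base-pair
#' mismatch opposite position 27 of the 10-bp donor strand.
#'
#' @format A named list of character strings (5' to 3').
#' @export
dsdna_sequences <- function() {
  list(
    donor_10bp = "GGACTAGTCTAGGCGAACGTTTAAGGXGATCTCTGTTTACAACTCCGA",
    donor_17bp = "GGACTAGTCTAGGCGAACGTTTAAGGCGATCTCXGTTTACAACTCCGA",
    acceptor   = "TCGGAGTTGTAAACAGAGATCgCCTTAAACGXTCGCCTAGACTAGTCC")
}

#' Labeled residue positions of the dsDNA constructs
#'
#' 1-based positions of the labeled thymines: on the top (donor) strand and
#' on the bottom (acceptor) strand in its own 5'->3' numbering.
#'
#' @param construct `"17bp"` or `"10bp"`.
#' @return List with `donor` (top-strand residue) and `acceptor`
#'   (bottom-strand residue).
#' @export
dsdna_label_positions <- function(construct = c("17bp", "10bp")) {
  construct <- match.arg(construct)
  list(donor = if (construct == "17bp") 34L else 27L, acceptor = 32L)
}

role_radii <- c(phosphate = 2.9, sugar = 2.9, base = 3.5)
role_helix_radius <- c(phosphate = 9.4, sugar = 7.4, base = 2.5)

#' Build an idealized B-DNA duplex as a pseudo-atom structure
#'
#' Canonical straight B-form geometry: helix axis along z, residue 1 of the
#' top strand at z = 0, helical rise 3.4 A and twist 36 deg per step. Each
#' nucleotide is represented by three pseudo-atoms — phosphate (r = 2.9 A,
#' helix radius 9.4 A), sugar (r = 2.9 A, 7.4 A) and base (r = 3.5 A,
#' 2.5 A) — which reproduce the ~20 A steric diameter of the duplex. The
#' bottom strand runs antiparallel; its backbone is offset azimuthally by
#' `strand_offset` degrees from the paired top-strand residue (154 deg,
#' giving distinct major and minor grooves). Sequence-dependent helical
#' parameters, bending and mismatch distortions are not modeled; mismatched
#' positions are built with standard geometry.
#'
#' @param seq_top,seq_bottom Complementary sequences, 5' to 3', equal
#'   length. `X` is treated as thymine; case is ignored; mismatches are
#'   allowed (positions noted in the returned object).
#' @param rise Helical rise per base pair in Angstrom.
#' @param twist Helical twist per base pair in degrees.
#' @param strand_offset Azimuthal offset of the bottom strand in degrees.
#' @return An object of class `pseudo_atom_structure`: data frame `atoms`
#'   with columns `x`, `y`, `z`, `radius`, `residue`, `strand`, `role`, plus
#'   sequence metadata.
#' @export
build_bdna <- function(seq_top, seq_bottom, rise = 3.4, twist = 36,
                       strand_offset = 154) {
  top <- toupper(gsub("\\s", "", seq_top))
  bot <- toupper(gsub("\\s", "", seq_bottom))
  n <- nchar(top)
  if (nchar(bot) != n) stop("strand length mismatch")
  base_top <- strsplit(chartr("X", "T", top), "")[[1]]
  base_bot <- strsplit(chartr("X", "T", bot), "")[[1]]
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  # bottom strand residue j pairs with top residue n + 1 - j
  mismatches <- unname(which(comp[base_top] != rev(base_bot)))
  deg <- pi / 180
  rows <- list()
  for (i in seq_len(n)) {
    phi <- (i - 1) * twist * deg
    z <- (i - 1) * rise
    for (role in names(role_radii)) {
      hr <- role_helix_radius[[role]]
      rows[[length(rows) + 1L]] <- data.frame(
        x = hr * cos(phi), y = hr * sin(phi), z = z,
        radius = role_radii[[role]], residue = i, strand = "top",
        role = role)
    }
    j <- n + 1L - i  # bottom-strand residue paired with top residue i
    phi_b <- phi + strand_offset * deg
    for (role in names(role_radii)) {
      hr <- role_helix_radius[[role]]
      rows[[length(rows) + 1L]] <- data.frame(
        x = hr * cos(phi_b), y = hr * sin(phi_b), z = z,
        radius = role_radii[[role]], residue = j, strand = "bottom",
        role = role)
    }
  }
  atoms <- do.call(rbind, rows)
  structure(list(atoms = atoms, seq_top = top, seq_bottom = bot,
                 rise = rise, twist = twist, strand_offset = strand_offset,
                 mismatches = mismatches),
            class = "pseudo_atom_structure")
}

#' @export
print.pseudo_atom_structure <- function(x, ...) {
  cat(sprintf("pseudo-atom structure: %d atoms", nrow(x$atoms)))
  if (!is.null(x$seq_top))
    cat(sprintf(", %d-bp duplex", nchar(x$seq_top)))
  if (length(x$mismatches))
    cat(sprintf(", mismatch at top position %s",
                paste(x$mismatches, collapse = ",")))
  cat("\n")
  invisible(x)
}

#' Dye attachment sites on a duplex
#'
#' The attachment point of a dye-linker construct is the labeled residue's
#' base pseudo-atom displaced 3 A radially outward from the helix axis
#' (toward the groove where the C6 amino linker exits the thymine).
#'
#' @param structure A [build_bdna()] result.
#' @param positions List of `list(strand =, residue =)` entries (or a single
#'   such entry).
#' @param displacement Radial displacement in Angstrom.
#' @return A list of attachment sites: each `list(position, residue,
#'   strand)` with `position` a length-3 numeric.
#' @export
attachment_sites <- function(structure, positions, displacement = 3) {
  stopifnot(inherits(structure, "pseudo_atom_structure"))
  if (!is.null(positions$strand)) positions <- list(positions)
  lapply(positions, function(p) {
    at <- structure$atoms
    row <- at[at$strand == p$strand & at$residue == p$residue &
                at$role == "base", , drop = FALSE]
    if (nrow(row) != 1L)
      stop("labeled residue not found: ", p$strand, ":", p$residue)
    seqs <- if (p$strand == "top") structure$seq_top else structure$seq_bottom
    if (!is.null(seqs) && !substr(seqs, p$residue, p$residue) %in% c("T", "X"))
      warning("labeled residue ", p$strand, ":", p$residue,
              " is not a thymine")
    radial <- c(row$x, row$y, 0)
    nr <- sqrt(sum(radial^2))
    u <- if (nr > 1e-9) radial / nr else c(1, 0, 0)
    list(position = c(row$x, row$y, row$z) + displacement * u,
         residue = p$residue, strand = p$strand)
  })
}

element_vdw <- c(C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8, H = 1.2)
role_element <- c(phosphate = "P", sugar = "C", base = "N")

#' Write a pseudo-atom structure as PDB
#'
#' Pseudo-atoms are written as HETATM records, one residue per nucleotide,
#' with the element chosen by role (phosphate P, sugar C, base N), chain A/B
#' for top/bottom strand, and the pseudo-atom radius stored in the B-factor
#' column (a documented convention of this package).
#'
#' @param structure A [build_bdna()]-style structure.
#' @param path Output file.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   pseudo-atom duplex; radius stored in B-factor", con)
  for (i in seq_len(nrow(at))) {
    el <- role_element[[at$role[i]]]
    chain <- if (at$strand[i] == "top") "A" else "B"
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, el, "DNA", chain, at$residue[i], at$x[i], at$y[i], at$z[i],
      1.0, at$radius[i], el), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file as a pseudo-atom structure
#'
#' Reads standard PDB (protein, DNA or pseudo-atom files written by
#' [write_pdb()]). For files carrying this package's radius-in-B-factor
#' convention (`remark` flag) radii are taken from the B-factor column;
#' otherwise default van der Waals radii are assigned by element (C 1.7,
#' N 1.55, O 1.52, P/S 1.8, H 1.2 A; unknown elements get 1.7 A with a
#' warning).
#'
#' @param path PDB file path.
#' @param radius_from_b Read radii from the B-factor column (default: auto,
#'   TRUE when the package's REMARK marker is present).
#' @return A `pseudo_atom_structure` (roles `"atom"` for generic input).
#' @export
read_pdb <- function(path, radius_from_b = NULL) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  if (is.null(radius_from_b)) {
    hdr <- readLines(path, n = 5)
    radius_from_b <- any(grepl("radius stored in B-factor", hdr))
  }
  el <- toupper(trimws(a$elesy))
  el[el == "" | is.na(el)] <- substr(trimws(a$elety)[el == "" | is.na(el)], 1, 1)
  if (radius_from_b) {
    radius <- a$b
  } else {
    radius <- unname(element_vdw[el])
    if (anyNA(radius)) {
      warning("unknown element(s) ",
              paste(unique(el[is.na(radius)]), collapse = ","),
              "; using default radius 1.7 A")
      radius[is.na(radius)] <- 1.7
    }
  }
  role <- rep("atom", nrow(a))
  known <- setNames(names(role_element), role_element)
  if (radius_from_b) role <- unname(known[el])
  atoms <- data.frame(x = a$x, y = a$y, z = a$z, radius = radius,
                      residue = a$resno,
                      strand = ifelse(a$chain %in% c(NA, "A"), "top",
                                      "bottom"),
                      role = ifelse(is.na(role), "atom", role))
  structure(list(atoms = atoms, seq_top = NULL, seq_bottom = NULL,
                 mismatches = integer(0)),
            class = "pseudo_atom_structure")
}

#' Rigidly transform a pseudo-atom structure
#'
#' Applies a rotation matrix and translation to all atom positions (used to
#' check frame independence of downstream distance results).
#'
#' @param structure A `pseudo_atom_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric.
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Transform an attachment site with the same rigid motion
#' @inheritParams transform_structure
#' @param site An attachment site from [attachment_sites()].
#' @return The transformed site.
#' @export
transform_site <- function(site, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  site$position <- as.numeric(rotation %*% site$position) + translation
  site
}
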