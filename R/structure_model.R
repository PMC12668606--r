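# Atomic data model for binder-target complexes.
#
# A complex_model is a list(atoms = data.frame, binder_chain, target_chains)
# where `atoms` holds one row per heavy atom in file order with columns:
#   chain   single-character chain id
#   resno   author residue number (integer)
#   ins     insertion code ("" when absent)
#   resid   3-letter residue name
#   aa      1-letter amino acid (X for unknown)
#   atom    atom name (N/CA/C/O/CB/...)
#   element element symbol
#   x,y,z   coordinates, Angstrom
#   o       occupancy
#   b       B-factor (repurposed as per-residue pLDDT on extraction output)
# This mirrors the flat atom table used by bio3d, with the binder/target
# chain roles of a design campaign attached.

ATOM_COLS <- c("chain", "resno", "ins", "resid", "aa", "atom", "element",
               "x", "y", "z", "o", "b")

new_complex_model <- function(atoms, binder_chain, target_chains) {
  stopifnot(is.data.frame(atoms), all(ATOM_COLS %in% names(atoms)))
  m <- list(atoms = atoms[, ATOM_COLS],
            binder_chain = binder_chain,
            target_chains = sort(unique(target_chains)))
  class(m) <- "complex_model"
  validate_complex_model(m)
}

validate_complex_model <- function(m) {
  present <- unique(m$atoms$chain)
  if (!m$binder_chain %in% present) {
    stop("binder chain '", m$binder_chain, "' not present in structure",
         call. = FALSE)
  }
  missing_t <- setdiff(m$target_chains, present)
  if (length(missing_t)) {
    stop("target chain(s) missing from structure: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }
  if (m$binder_chain %in% m$target_chains) {
    stop("binder and target chain sets must be disjoint", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(m$atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  m
}

#' @export
print.complex_model <- function(x, ...) {
  cat("<complex_model> ", nrow(x$atoms), " atoms; binder chain ",
      x$binder_chain, "; target chain(s) ",
      paste(x$target_chains, collapse = ","), "\n", sep = "")
  for (ch in chain_ids(x)) {
    cat("  chain ", ch, ": ", n_residues(x, ch), " residues\n", sep = "")
  }
  invisible(x)
}

#' Chain identifiers of a complex, file order
#' @param model a `complex_model`
#' @return character vector of chain ids
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Atom table of one chain
#' @param model a `complex_model`
#' @param chain_id single-character chain id
#' @return data.frame of atoms in file order
#' @export
chain_atoms <- function(model, chain_id) {
  if (!chain_id %in% model$atoms$chain) {
    stop("chain '", chain_id, "' not found", call. = FALSE)
  }
  model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
}

# unique (resno, ins) keys of a chain, file order
residue_keys <- function(atoms) {
  key <- paste(atoms$resno, atoms$ins, sep = "|")
  unique(key)
}

#' Residue count of a chain
#' @inheritParams chain_atoms
#' @return integer
#' @export
n_residues <- function(model, chain_id) {
  length(residue_keys(chain_atoms(model, chain_id)))
}

# three-letter -> one-letter, X for anything unknown
aa3to1 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

#' Read a binder-target complex from PDB text
#'
#' Fixed-column ATOM/HETATM records are parsed (via bio3d) preserving chain,
#' residue and atom file order. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered). HETATM records and
#' hydrogens are dropped by default, matching the heavy-atom, protein-only
#' outputs of design pipelines; set `keep_hetatm = TRUE` for grafting
#' templates carrying ligands.
#'
#' @param text PDB-format string (or character vector of lines)
#' @param binder_chain chain id of the designed binder
#' @param target_chains chain id(s) of the target
#' @param keep_hetatm keep HETATM records (waters always dropped)
#' @return a `complex_model`
#' @export
read_pdb <- function(text, binder_chain = "A", target_chains = "B",
                     keep_hetatm = FALSE) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_rec)) stop("no ATOM records in input", call. = FALSE)
  # validate coordinate fields up front so errors carry a line number
  for (i in which(is_rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM record at line ", i, ": too short", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop("malformed ATOM record at line ", i,
           ": unparseable coordinates", call. = FALSE)
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  # element: take the PDB element column, fall back to the atom-name letter
  elesy <- trimws(at$elesy)
  fromname <- toupper(substr(gsub("^[0-9]*", "", trimws(at$elety)), 1, 1))
  elesy[is.na(elesy) | elesy == ""] <- fromname[is.na(elesy) | elesy == ""]
  at$element <- elesy
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms left after filtering", call. = FALSE)

  # altloc: within (chain, resno, ins, atom name) keep highest occupancy,
  # ties resolved to the first encountered record
  at$ins[is.na(at$ins)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  key <- paste(at$chain, at$resno, at$ins, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(idx) idx[which.max(at$o[idx])]),
                 use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  atoms <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                      ins = at$ins, resid = trimws(at$resid),
                      aa = aa3to1(trimws(at$resid)),
                      atom = trimws(at$elety), element = at$element,
                      x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
                      stringsAsFactors = FALSE)
  new_complex_model(atoms, binder_chain, target_chains)
}

#' Write a complex to PDB-format text
#'
#' Fixed-column ATOM records, a TER after each chain, END terminator,
#' coordinates to three decimals. Residue numbers land in columns 23-26.
#'
#' @param model a `complex_model`
#' @return a single PDB-format string
#' @export
write_pdb <- function(model) {
  at <- model$atoms
  if (any(abs(at[, c("x", "y", "z")]) >= 10000)) {
    stop("coordinate overflows the 8-column PDB field", call. = FALSE)
  }
  if (any(at$resno > 9999 | at$resno < -999)) {
    stop("residue number overflows the 4-column PDB field", call. = FALSE)
  }
  lines <- character(0)
  serial <- 0L
  for (ch in chain_ids(model)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1L
      nm <- ca$atom[i]
      nm4 <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm4, ca$resid[i], ch, ca$resno[i],
        ifelse(ca$ins[i] == "", " ", ca$ins[i]),
        ca$x[i], ca$y[i], ca$z[i], ca$o[i], ca$b[i], ca$element[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial %% 100000L, ca$resid[nrow(ca)], ch,
                              ca$resno[nrow(ca)]))
  }
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

#' Renumber one chain consecutively
#'
#' Residues of `chain_id` are renumbered consecutively from `start`,
#' preserving order; all other fields are untouched. Insertion codes are
#' stripped (with a warning) since consecutive numbering subsumes them.
#' This implements the campaign convention of renumbering a trimmed target
#' to a high offset (e.g. 1018) to avoid residue-index collisions in
#' downstream prediction tools.
#'
#' @param model a `complex_model`
#' @param chain_id chain to renumber
#' @param start first residue number after renumbering
#' @return a `complex_model`
#' @export
renumber_chain <- function(model, chain_id, start) {
  ca <- chain_atoms(model, chain_id)   # errors if absent
  keys <- residue_keys(ca)
  newno <- setNames(seq.int(start, length.out = length(keys)), keys)
  sel <- model$atoms$chain == chain_id
  k <- paste(model$atoms$resno[sel], model$atoms$ins[sel], sep = "|")
  if (any(ca$ins != "")) {
    warning("insertion codes stripped while renumbering chain ", chain_id)
  }
  model$atoms$resno[sel] <- as.integer(newno[k])
  model$atoms$ins[sel] <- ""
  model
}

#' One-letter sequence of a chain
#' @inheritParams chain_atoms
#' @return amino-acid string, length = residue count, X for unknown residues
#' @export
sequence_of <- function(model, chain_id) {
  ca <- chain_atoms(model, chain_id)
  key <- paste(ca$resno, ca$ins, sep = "|")
  first <- !duplicated(key)
  paste(ca$aa[first], collapse = "")
}

#' Coordinates of a set of atoms as an n x 3 matrix
#' @param atoms an atom data.frame (rows of `model$atoms`)
#' @return numeric matrix with columns x, y, z
#' @export
atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# extract a single-chain model (used by SASA components and extraction)
subset_chains <- function(model, chains) {
  atoms <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  m <- model
  m$atoms <- atoms
  m
}
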