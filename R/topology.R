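#' Construct a topology
#'
#' A topology is the atom table every other object refers to: one row per
#' atom with its name, residue number (author/PDB numbering, preserved
#' exactly — e.g. 243-338 for the hDVL3 PDZ construct), 3-letter residue
#' name (including `"SEP"` for phosphoserine), chain id and element.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_number`,
#'   `residue_name`, `chain_id`, `element`; `atom_index` (0-based,
#'   contiguous) is added if absent.
#' @return An object of class `topology`.
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_name", "residue_number", "residue_name", "chain_id", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("topology: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("topology: zero atoms")
  atoms$atom_name <- toupper(as.character(atoms$atom_name))
  atoms$residue_name <- toupper(as.character(atoms$residue_name))
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  if (is.null(atoms$atom_index)) {
    atoms$atom_index <- seq_len(nrow(atoms)) - 1L
  } else if (!identical(as.integer(atoms$atom_index), seq_len(nrow(atoms)) - 1L)) {
    stop("topology: atom_index must be contiguous from 0")
  }
  key <- paste(atoms$residue_number, atoms$atom_name, atoms$chain_id)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("topology: duplicate (residue, atom, chain) record: ", d)
  }
  for (ch in unique(atoms$chain_id)) {
    rn <- atoms$residue_number[atoms$chain_id == ch]
    if (is.unsorted(rn)) {
      stop("topology: residue numbers not nondecreasing within chain ", ch)
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  res <- unique(x$atoms[, c("residue_number", "chain_id")])
  cat(sprintf("<topology> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nrow(res),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Residue numbers present in a topology
#' @param top a [topology].
#' @return Sorted unique integer residue numbers.
#' @export
residue_numbers <- function(top) sort(unique(top$atoms$residue_number))

guess_element <- function(atom_name) {
  # PDB convention: element usually the first letter; handle phosphorus and
  # sodium pseudo-atoms explicitly
  nm <- toupper(atom_name)
  ifelse(nm == "P" | substr(nm, 1, 1) == "P" & nchar(nm) == 1, "P",
    ifelse(nm %in% c("NA", "SOD"), "Na", substr(gsub("[0-9]", "", nm), 1, 1)))
}

#' Read a topology from a PDB file
#'
#' All ATOM/HETATM records of the first MODEL are kept (so SEP
#' phosphoserine and ion records survive). Insertion codes are rejected;
#' alternate locations other than blank/"A" are dropped with a warning.
#'
#' @param path PDB file path.
#' @return A [topology].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("read_topology: no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("read_topology: zero atoms in ", path)
  if (any(nzchar(trimws(as.character(at$insert))) & !is.na(at$insert))) {
    bad <- which(nzchar(trimws(as.character(at$insert))) & !is.na(at$insert))[1]
    stop(sprintf("read_topology: insertion code on record %d (residue %s%s)",
                 bad, at$resid[bad], at$resno[bad]))
  }
  alt <- trimws(as.character(at$alt))
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A")
  if (!all(keep)) {
    warning(sprintf("read_topology: dropping %d altloc records (kept blank/'A')",
                    sum(!keep)))
    at <- at[keep, , drop = FALSE]
  }
  chain <- as.character(at$chain)
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  elesy <- trimws(as.character(at$elesy))
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess_element(at$elety[is.na(elesy) | !nzchar(elesy)])
  topology(data.frame(
    atom_name = at$elety,
    residue_number = at$resno,
    residue_name = at$resid,
    chain_id = chain,
    element = elesy,
    stringsAsFactors = FALSE
  ))
}

#' Write a topology (+ reference coordinates) as a PDB file
#'
#' @param top a [topology].
#' @param coords_nm n_atoms x 3 matrix of coordinates in nm (written in
#'   Angstrom, the PDB unit).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, coords_nm, path) {
  stopifnot(inherits(top, "topology"), is.matrix(coords_nm),
            nrow(coords_nm) == n_atoms(top), ncol(coords_nm) == 3L)
  a <- top$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords_nm)) * 10,
    type = ifelse(a$residue_name %in% c("NA", "SEP"), "HETATM", "ATOM"),
    resno = a$residue_number,
    resid = a$residue_name,
    eleno = a$atom_index + 1L,
    elety = a$atom_name,
    chain = a$chain_id,
    elesy = a$element
  )
  invisible(path)
}

#' Global sequence identity between two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) with identity
#' reported over aligned positions, as used when quoting the identity of a
#' homology-model template.
#'
#' @param seq_a,seq_b character(1) one-letter amino-acid sequences.
#' @return Percent identity (0-100).
#' @export
sequence_identity <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  Biostrings::pid(al, type = "PID1")
}

#' One-letter sequence of a topology chain
#' @param top a [topology].
#' @param chain chain id (default first chain).
#' @return character(1) sequence; SEP is read as S.
#' @export
topology_sequence <- function(top, chain = NULL) {
  a <- top$atoms
  if (is.null(chain)) chain <- a$chain_id[1]
  a <- a[a$chain_id == chain, , drop = FALSE]
  res <- a[!duplicated(a$residue_number), c("residue_number", "residue_name")]
  res <- res[order(res$residue_number), ]
  three <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
             GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
             MET = "M", PHE = "F", PRO = "P", SER = "S", SEP = "S", THR = "T",
             TRP = "W", TYR = "Y", VAL = "V")
  one <- three[res$residue_name]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}
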