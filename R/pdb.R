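# PDB v3.3 structure model: a flat atom table with a thin S3 class,
# in the style of the field's structure packages.

#' Three-letter codes of the 20 standard residues
#' @keywords internal
AA3_CODES <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Default three-letter code used for DOPA residues
#' @keywords internal
DOPA_CODE <- "DAH"

# Residue names treated as amino acids by residue-level logic.
amino_resnames <- function(dopa_code = DOPA_CODE) c(AA3_CODES, dopa_code)

#' Construct a structure object from an atom table
#'
#' The coordinate model is a single data frame of atoms (one row per
#' atom) carrying the PDB hierarchy in its columns, plus a title.  This
#' flat layout keeps vectorised geometry cheap while `residue_key`
#' (`chain:resseq:icode`) provides the residue-level grouping used by
#' the SASA and classification code.
#'
#' @param atoms Data frame with columns `record` ("ATOM"/"HETATM"),
#'   `serial`, `name`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`,
#'   `z`, `occupancy`, `bfactor`, `element`.
#' @param title Structure title.
#' @return Object of class `pdb_structure`.
#' @export
pdb_structure <- function(atoms, title = "") {
  needed <- c("record", "serial", "name", "resname", "chain", "resseq",
              "icode", "x", "y", "z", "occupancy", "bfactor", "element")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure contains zero atoms")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = ":")
  dup <- duplicated(paste(key, atoms$name))
  if (any(dup)) {
    stop("duplicate atom name within residue: ",
         paste(unique(paste(key[dup], atoms$name[dup])), collapse = ", "))
  }
  rownames(atoms) <- NULL
  structure(list(title = title, atoms = atoms), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat("<pdb_structure>", if (nzchar(x$title)) x$title else "(untitled)", "\n")
  cat("  ", nrow(a), " atoms (", sum(!a$hydrogen), " heavy), ",
      length(unique(residue_keys(x))), " residues, chains: ",
      paste(unique(a$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-atom residue keys (`chain:resseq:icode`)
#' @param structure A [pdb_structure()].
#' @return Character vector, one entry per atom.
#' @export
residue_keys <- function(structure) {
  a <- structure$atoms
  paste(a$chain, a$resseq, a$icode, sep = ":")
}

#' Per-atom unique atom keys (`chain:resseq:icode:name`)
#' @param structure A [pdb_structure()].
#' @return Character vector, one entry per atom.
#' @export
atom_keys <- function(structure) {
  paste(residue_keys(structure), structure$atoms$name, sep = ":")
}

#' Residue-level summary table
#'
#' One row per residue in atom order: key, chain, resseq, icode,
#' resname, record type, and whether the residue name is a standard
#' amino acid (or DOPA).
#' @param structure A [pdb_structure()].
#' @param dopa_code Residue name treated as DOPA.
#' @return Data frame.
#' @export
residue_table <- function(structure, dopa_code = DOPA_CODE) {
  a <- structure$atoms
  key <- residue_keys(structure)
  first <- !duplicated(key)
  data.frame(
    key = key[first], chain = a$chain[first], resseq = a$resseq[first],
    icode = a$icode[first], resname = a$resname[first],
    record = a$record[first],
    is_amino = a$resname[first] %in% amino_resnames(dopa_code),
    stringsAsFactors = FALSE
  )
}

# Element inference from a PDB atom name when the element column is
# blank.  Handles leading digits (e.g. "1HB") and two-letter elements.
infer_element <- function(name) {
  two_letter <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE", "CA")
  stripped <- gsub("[0-9']", "", name)
  if (!nzchar(stripped)) return(NA_character_)
  # names like "CA " in amino acids are carbon; two-letter metals only
  # matter for HETATM names that exactly match the element
  if (nchar(stripped) >= 2L && toupper(name) %in% two_letter) {
    return(toupper(name))
  }
  substr(stripped, 1L, 1L)
}

parse_num <- function(s, what, lineno) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    stop("unreadable ", what, " on line ", lineno, ": '", trimws(s), "'")
  }
  v
}

#' Read a structure from a PDB file
#'
#' Parses `ATOM`/`HETATM` records of a PDB v3.3 fixed-width file into a
#' [pdb_structure()].  Only the first `MODEL` block of a multi-model
#' file is read (with a warning).  When several altLoc conformers are
#' present, the highest-occupancy one is kept (ties: first seen).
#' Hydrogens are retained in the model and flagged; they are excluded
#' from SASA by default downstream.  The element is inferred from the
#' atom name when the element column is blank.
#'
#' @param path Path to a PDB file.
#' @return A [pdb_structure()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec6 <- substr(lines, 1L, 6L)
  model_idx <- which(substr(rec6, 1L, 5L) == "MODEL")
  if (length(model_idx) > 1L) {
    warning("file contains ", length(model_idx),
            " MODEL blocks; reading the first model only")
    endmdl <- which(trimws(rec6) == "ENDMDL")
    stop_at <- endmdl[endmdl > model_idx[1L]][1L]
    if (is.na(stop_at)) stop_at <- model_idx[2L]
    keep <- seq_len(length(lines)) < stop_at
  } else {
    keep <- rep(TRUE, length(lines))
  }
  is_atom <- keep & (rec6 == "ATOM  " | rec6 == "HETATM")
  title <- trimws(paste(substr(lines[rec6 == "TITLE "], 11L, 80L),
                        collapse = " "))
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("no ATOM/HETATM records in '", path, "'")
  ln <- lines[idx]
  n <- length(ln)
  x <- y <- z <- occ <- bf <- numeric(n)
  for (i in seq_len(n)) {
    x[i] <- parse_num(substr(ln[i], 31L, 38L), "x-coordinate", idx[i])
    y[i] <- parse_num(substr(ln[i], 39L, 46L), "y-coordinate", idx[i])
    z[i] <- parse_num(substr(ln[i], 47L, 54L), "z-coordinate", idx[i])
    o <- suppressWarnings(as.numeric(substr(ln[i], 55L, 60L)))
    occ[i] <- if (is.na(o)) 1 else o
    b <- suppressWarnings(as.numeric(substr(ln[i], 61L, 66L)))
    bf[i] <- if (is.na(b)) 0 else b
  }
  name <- trimws(substr(ln, 13L, 16L))
  altloc <- substr(ln, 17L, 17L)
  element <- trimws(substr(ln, 77L, 78L))
  blank <- !nzchar(element)
  if (any(blank)) {
    element[blank] <- vapply(name[blank], infer_element, character(1L))
  }
  atoms <- data.frame(
    record = trimws(substr(ln, 1L, 6L)),
    serial = suppressWarnings(as.integer(trimws(substr(ln, 7L, 11L)))),
    name = name,
    altloc = altloc,
    resname = trimws(substr(ln, 18L, 20L)),
    chain = substr(ln, 22L, 22L),
    resseq = suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L)))),
    icode = substr(ln, 27L, 27L),
    x = x, y = y, z = z, occupancy = occ, bfactor = bf,
    element = toupper(element),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resseq)) {
    stop("unreadable residue number on line ",
         idx[which(is.na(atoms$resseq))[1L]])
  }
  # altLoc policy: keep the highest-occupancy conformer per atom slot
  has_alt <- atoms$altloc != " "
  if (any(has_alt)) {
    slot <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
    ord <- order(slot, -atoms$occupancy, seq_len(nrow(atoms)))
    atoms <- atoms[ord, ]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resseq,
                                     atoms$icode, atoms$name)), ]
    atoms <- atoms[order(atoms$serial), ]
  }
  atoms$altloc <- NULL
  pdb_structure(atoms, title = title)
}

#' Write a structure to a PDB file
#'
#' Emits PDB v3.3 fixed-width `ATOM`/`HETATM` records.  Round trip
#' through [read_structure()] preserves names, numbering, and
#' coordinates to three decimals.
#'
#' @param structure A [pdb_structure()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  if (any(nchar(a$name) > 4L)) {
    stop("atom name longer than 4 characters: ",
         paste(unique(a$name[nchar(a$name) > 4L]), collapse = ", "))
  }
  # PDB name column convention: 1-3 character names start in column 14
  # unless the element symbol has two letters.
  fmt_name <- ifelse(nchar(a$name) == 4L | nchar(a$element) == 2L,
                     formatC(a$name, width = -4L),
                     formatC(paste0(" ", a$name), width = -4L))
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, a$serial %% 100000L, fmt_name, " ", a$resname, a$chain,
    a$resseq %% 10000L, a$icode, a$x, a$y, a$z, a$occupancy, a$bfactor,
    a$element
  )
  header <- character(0L)
  if (nzchar(structure$title)) {
    header <- sprintf("TITLE     %-70s", structure$title)
  }
  writeLines(c(header, lines, "END"), path)
  invisible(path)
}
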