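# Shared constructors for hand-built toy structures.

# Minimal atom table row; coordinates as a length-3 vector.
toy_atom <- function(name, xyz, resname = "BLK", chain = "X", resseq = 1L,
                     record = "HETATM", element = NULL) {
  if (is.null(element)) element <- substr(name, 1L, 1L)
  data.frame(record = record, serial = 0L, name = name, resname = resname,
             chain = chain, resseq = as.integer(resseq), icode = " ",
             x = xyz[1L], y = xyz[2L], z = xyz[3L],
             occupancy = 1, bfactor = 0, element = element,
             stringsAsFactors = FALSE)
}

# Structure from a list of toy_atom() rows (serials assigned).
toy_structure <- function(rows, title = "toy") {
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  pdb_structure(atoms, title = title)
}

# n carbon pseudo-atoms, one residue each, from a coordinate matrix.
carbon_cloud <- function(coords) {
  toy_structure(lapply(seq_len(nrow(coords)), function(i) {
    toy_atom("C", coords[i, ], resseq = i)
  }))
}

# Rigidly rotate + translate a structure (for invariance tests).
transform_structure <- function(structure, angle = 0.7, axis = c(1, 2, 3),
                                shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  rot <- diag(3L) + s_ * k + (1 - c_) * (k %*% k)
  coords <- as.matrix(structure$atoms[, c("x", "y", "z")])
  coords <- sweep(coords %*% t(rot), 2L, shift, "+")
  atoms <- structure$atoms
  atoms$x <- coords[, 1L]; atoms$y <- coords[, 2L]; atoms$z <- coords[, 3L]
  pdb_structure(atoms[setdiff(names(atoms), "hydrogen")],
                title = structure$title)
}
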