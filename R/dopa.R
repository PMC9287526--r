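# Tyrosinase-accessibility classification of tyrosines and in-structure
# conversion of selected tyrosines to L-DOPA.

#' Accessibility classification parameters
#'
#' Two classification schemes are supported.  `whole_residue`: a
#' tyrosine is modifiable when its relative accessibility strictly
#' exceeds `threshold` (default 0.55, i.e. "more than 55%").
#' `ring_carbon`: a tyrosine is modifiable when every named ring carbon
#' (default CE1/CE2, the ortho positions flanking the phenolic OH at
#' CZ, where tyrosinase installs the second hydroxyl) has at least
#' `ring_atom_min_area` of exposed surface.  The ring-atom cut-off is
#' an operational default for what the eye judges as "facing the
#' enzyme"; it is echoed in every report.
#'
#' @param threshold Relative-accessibility threshold in (0, 1).
#' @param mode `"whole_residue"` or `"ring_carbon"`.
#' @param ring_atoms Atom names checked in `ring_carbon` mode.
#' @param ring_atom_min_area Minimum per-atom exposed area (Angstrom^2).
#' @return Object of class `accessibility_params`.
#' @export
accessibility_params <- function(threshold = 0.55,
                                 mode = c("whole_residue", "ring_carbon"),
                                 ring_atoms = c("CE1", "CE2"),
                                 ring_atom_min_area = 5.0) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  if (mode == "ring_carbon" && length(ring_atoms) == 0L) {
    stop("ring_atoms must be non-empty in ring_carbon mode")
  }
  structure(list(threshold = threshold, mode = mode,
                 ring_atoms = ring_atoms,
                 ring_atom_min_area = ring_atom_min_area),
            class = "accessibility_params")
}

#' Classify tyrosines as tyrosinase-modifiable
#'
#' Applies the scheme selected in `params` to every tyrosine of the
#' structure, using a SASA result computed on the same structure.  Both
#' the relative accessibility and the ring-carbon exposure flag are
#' reported for every tyrosine regardless of mode, so disagreements
#' between the two schemes are visible rather than hidden.
#'
#' @param structure A [pdb_structure()].
#' @param sasa A [compute_sasa()] result on the same structure, with
#'   relative accessibility filled in by [relative_sasa()].
#' @param params An [accessibility_params()].
#' @return Object of class `modification_report`: per-tyrosine table
#'   (ordered by chain then residue number), totals, the modifiable
#'   fraction, and per-chain counts.
#' @export
classify_tyrosines <- function(structure, sasa,
                               params = accessibility_params()) {
  stopifnot(inherits(structure, "pdb_structure"),
            inherits(sasa, "sasa_result"))
  sel <- if (sasa$params$include_hydrogens) {
    rep(TRUE, nrow(structure$atoms))
  } else !structure$atoms$hydrogen
  if (!identical(unname(names(sasa$per_atom)),
                 unname(atom_keys(structure)[sel]))) {
    stop("SASA result does not match structure (atom keys differ); ",
         "recompute SASA on this structure")
  }
  if (is.null(sasa$relative_per_residue)) {
    stop("relative accessibility missing; run relative_sasa() first")
  }
  res <- residue_table(structure)
  tyr <- res[res$resname == "TYR", , drop = FALSE]
  if (nrow(tyr) == 0L) {
    warning("structure contains no tyrosines; empty report")
  }
  tyr <- tyr[order(tyr$chain, tyr$resseq, tyr$icode), , drop = FALSE]
  ring_exposed <- logical(nrow(tyr))
  rel <- numeric(nrow(tyr))
  for (i in seq_len(nrow(tyr))) {
    key <- tyr$key[i]
    rel[i] <- sasa$relative_per_residue[[key]]
    ring_keys <- paste(key, params$ring_atoms, sep = ":")
    ring_area <- sasa$per_atom[ring_keys]
    ring_exposed[i] <- !anyNA(ring_area) &&
      all(ring_area >= params$ring_atom_min_area)
  }
  modifiable <- switch(params$mode,
    whole_residue = rel > params$threshold,  # strict: "more than 55%"
    ring_carbon = ring_exposed
  )
  per_tyr <- data.frame(
    key = tyr$key, chain = tyr$chain, resseq = tyr$resseq,
    relative_sa = rel, ring_exposed = ring_exposed,
    modifiable = modifiable, stringsAsFactors = FALSE
  )
  rownames(per_tyr) <- NULL
  per_chain <- do.call(rbind, lapply(split(per_tyr, per_tyr$chain),
    function(d) data.frame(chain = d$chain[1L], total = nrow(d),
                           modifiable = sum(d$modifiable),
                           stringsAsFactors = FALSE)))
  n_total <- nrow(per_tyr)
  n_mod <- sum(per_tyr$modifiable)
  structure(list(per_tyrosine = per_tyr,
                 n_total = n_total,
                 n_modifiable = n_mod,
                 fraction = if (n_total > 0L) n_mod / n_total else NA_real_,
                 per_chain_counts = per_chain,
                 params = params),
            class = "modification_report")
}

#' @export
print.modification_report <- function(x, ...) {
  cat("<modification_report> ", x$n_modifiable, " of ", x$n_total,
      " tyrosine(s) modifiable", sep = "")
  if (x$n_total > 0L) cat(sprintf(" (%.0f%%)", 100 * x$fraction))
  cat("\n  mode: ", x$params$mode,
      ", threshold: ", x$params$threshold,
      ", ring cut-off: ", x$params$ring_atom_min_area, " A^2\n", sep = "")
  if (x$n_total > 0L) print(x$per_tyrosine, row.names = FALSE)
  invisible(x)
}

# Unit normal of the least-squares plane through a set of points.
ls_plane_normal <- function(pts) {
  centered <- sweep(pts, 2L, colMeans(pts), "-")
  svd(centered)$v[, 3L]
}

#' Convert selected tyrosines to DOPA in a structure
#'
#' For each selected tyrosine the residue is renamed to the DOPA
#' three-letter code and one oxygen atom (name `OH3`) is added bonded
#' to CE1 at `bond_length`, lying in the aromatic-ring plane along the
#' bisector of the external angle at CE1 — the geometry of the second
#' catechol hydroxyl installed ortho to the phenolic OH.  All
#' pre-existing coordinates are untouched; the heavy-atom model adds no
#' hydrogen.  Re-applying to an already converted residue is rejected.
#'
#' @param structure A [pdb_structure()].
#' @param residue_keys Character vector of residue keys
#'   (`chain:resseq:icode`) naming tyrosines.
#' @param dopa_code Three-letter code for the modified residue.
#' @param bond_length C-O bond length in Angstrom.
#' @return A new [pdb_structure()] with `length(residue_keys)` extra
#'   atoms.
#' @export
apply_dopa <- function(structure, residue_keys, dopa_code = DOPA_CODE,
                       bond_length = 1.36) {
  stopifnot(inherits(structure, "pdb_structure"))
  residue_keys <- unique(as.character(residue_keys))
  if (length(residue_keys) == 0L) return(structure)
  res <- residue_table(structure, dopa_code = dopa_code)
  bad <- residue_keys[!(residue_keys %in% res$key)]
  already <- residue_keys[residue_keys %in% res$key[res$resname == dopa_code]]
  not_tyr <- setdiff(
    residue_keys[residue_keys %in% res$key[res$resname != "TYR"]], already)
  if (length(bad) > 0L || length(not_tyr) > 0L || length(already) > 0L) {
    msg <- c(
      if (length(bad) > 0L) paste("not found:", paste(bad, collapse = ", ")),
      if (length(not_tyr) > 0L) paste("not tyrosine:",
                                      paste(not_tyr, collapse = ", ")),
      if (length(already) > 0L) paste("already DOPA:",
                                      paste(already, collapse = ", "))
    )
    stop("cannot apply DOPA conversion - ", paste(msg, collapse = "; "))
  }
  atoms <- structure$atoms
  rkeys <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = ":")
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  for (key in residue_keys) {
    in_res <- which(rkeys == key)
    ra <- atoms[in_res, , drop = FALSE]
    need <- c("CE1", "CD1", "CZ")
    if (!all(need %in% ra$name)) {
      stop("tyrosine ", key, " lacks ring atoms ",
           paste(setdiff(need, ra$name), collapse = ", "))
    }
    ring <- as.matrix(ra[ra$name %in% ring_names, c("x", "y", "z")])
    nrm <- ls_plane_normal(ring)
    ce1 <- as.numeric(ra[ra$name == "CE1", c("x", "y", "z")])
    cd1 <- as.numeric(ra[ra$name == "CD1", c("x", "y", "z")])
    cz <- as.numeric(ra[ra$name == "CZ", c("x", "y", "z")])
    u1 <- (cd1 - ce1) / sqrt(sum((cd1 - ce1)^2))
    u2 <- (cz - ce1) / sqrt(sum((cz - ce1)^2))
    dir <- -(u1 + u2)
    dir <- dir - sum(dir * nrm) * nrm  # keep the new O in the ring plane
    dir <- dir / sqrt(sum(dir^2))
    new_xyz <- ce1 + bond_length * dir
    new_atom <- ra[ra$name == "CE1", , drop = FALSE]
    new_atom$resname <- dopa_code
    new_atom$name <- "OH3"
    new_atom$element <- "O"
    new_atom$hydrogen <- FALSE
    new_atom$x <- new_xyz[1L]
    new_atom$y <- new_xyz[2L]
    new_atom$z <- new_xyz[3L]
    atoms$resname[in_res] <- dopa_code
    insert_after <- max(in_res)
    atoms <- rbind(atoms[seq_len(insert_after), , drop = FALSE],
                   new_atom,
                   if (insert_after < nrow(atoms)) {
                     atoms[(insert_after + 1L):nrow(atoms), , drop = FALSE]
                   })
    rkeys <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = ":")
  }
  atoms$serial <- seq_len(nrow(atoms))
  pdb_structure(atoms, title = structure$title)
}

#' Full modification pipeline
#'
#' Runs [compute_sasa()], [relative_sasa()], [classify_tyrosines()],
#' and [apply_dopa()] on the modifiable set, mirroring the in-silico
#' workflow of predicting tyrosinase-accessible tyrosines and editing
#' them to DOPA.
#'
#' @param structure A [pdb_structure()].
#' @param sasa_parameters A [sasa_params()].
#' @param acc_params An [accessibility_params()].
#' @param reference_table Passed to [relative_sasa()].
#' @param dopa_code Residue code for converted tyrosines.
#' @return List with elements `structure` (modified), `report`
#'   (the [classify_tyrosines()] report), and `sasa`.
#' @export
modification_pipeline <- function(structure,
                                  sasa_parameters = sasa_params(),
                                  acc_params = accessibility_params(),
                                  reference_table = max_asa_reference(),
                                  dopa_code = DOPA_CODE) {
  sasa <- compute_sasa(structure, sasa_parameters)
  sasa <- relative_sasa(sasa, reference_table)
  report <- suppressWarnings(
    classify_tyrosines(structure, sasa, acc_params))
  modified <- if (report$n_modifiable > 0L) {
    apply_dopa(structure,
               report$per_tyrosine$key[report$per_tyrosine$modifiable],
               dopa_code = dopa_code)
  } else {
    structure
  }
  list(structure = modified, report = report, sasa = sasa)
}
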