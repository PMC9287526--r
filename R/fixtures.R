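# Deterministic generator of toy structures with known, controllable
# properties: isolated atoms for closed-form SASA checks, ideal-geometry
# peptides for dihedral checks, and tyrosine hosts with controlled
# burial for classification tests.  Generation is a pure function of
# the spec; no randomness.

# Ideal backbone internal coordinates (Angstrom / degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

# Place atom d bonded to c, given the chain a-b-c, with |cd| = bond,
# angle(b,c,d) and dihedral(a,b,c,d) (natural extension reference
# frame).
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  tor <- -dihedral_deg * pi / 180  # sign fixed against the IUPAC measure
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2L] * bc[3L] - ab[3L] * bc[2L],
         ab[3L] * bc[1L] - ab[1L] * bc[3L],
         ab[1L] * bc[2L] - ab[2L] * bc[1L])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2L] * bc[3L] - n[3L] * bc[2L],
         n[3L] * bc[1L] - n[1L] * bc[3L],
         n[1L] * bc[2L] - n[2L] * bc[1L])
  frame <- cbind(bc, m, n)
  c + as.numeric(frame %*% d_local)
}

# Drop the derived hydrogen flag so fresh atom rows can be rbind-ed.
strip_derived <- function(atoms) {
  atoms[setdiff(names(atoms), "hydrogen")]
}

atom_row <- function(record, name, resname, chain, resseq, xyz, element) {
  data.frame(record = record, serial = 0L, name = name, resname = resname,
             chain = chain, resseq = resseq, icode = " ",
             x = xyz[1L], y = xyz[2L], z = xyz[3L],
             occupancy = 1, bfactor = 0, element = element,
             stringsAsFactors = FALSE)
}

# Tyrosine sidechain atoms from backbone N/CA/C with given rotamer.
tyr_sidechain <- function(n, ca, c, chi1 = 180, chi2 = 90) {
  cb <- place_atom(n, c, ca, 1.530, 110.6, -122.6)
  cg <- place_atom(n, ca, cb, 1.512, 113.9, chi1)
  cd1 <- place_atom(ca, cb, cg, 1.389, 120.9, chi2)
  cd2 <- place_atom(ca, cb, cg, 1.389, 120.9, chi2 - 180)
  ce1 <- place_atom(cb, cg, cd1, 1.389, 121.2, 180)
  ce2 <- place_atom(cb, cg, cd2, 1.389, 121.2, 180)
  cz <- place_atom(cg, cd1, ce1, 1.389, 119.6, 0)
  oh <- place_atom(cd1, ce1, cz, 1.376, 119.9, 180)
  list(CB = cb, CG = cg, CD1 = cd1, CD2 = cd2, CE1 = ce1, CE2 = ce2,
       CZ = cz, OH = oh)
}

#' Build an ideal-geometry peptide
#'
#' Constructs a peptide from ideal internal coordinates (N-CA 1.458,
#' CA-C 1.525, C-N 1.329 Angstrom; standard angles; omega = 180) with
#' the requested per-residue phi/psi.  Supported residues: G, A
#' (backbone + CB), and Y (full aromatic sidechain).
#'
#' @param sequence One-letter sequence (G/A/Y only).
#' @param phi,psi Backbone dihedrals in degrees; scalars are recycled.
#' @param chain Chain identifier.
#' @param chi1,chi2 Tyrosine rotamer (degrees).
#' @return A [pdb_structure()].
#' @export
build_peptide <- function(sequence, phi = -140, psi = 135, chain = "A",
                          chi1 = 180, chi2 = 90) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("G", "A", "Y"))) {
    stop("build_peptide supports only G, A, and Y residues")
  }
  nres <- length(chars)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  rows <- list()
  n_prev <- ca_prev <- c_prev <- NULL
  for (i in seq_len(nres)) {
    if (i == 1L) {
      n_i <- c(0, 0, 0)
      ca_i <- c(BOND_N_CA, 0, 0)
      ang <- ANGLE_N_CA_C * pi / 180
      c_i <- ca_i + BOND_CA_C * c(-cos(ang), sin(ang), 0)
    } else {
      n_i <- place_atom(n_prev, ca_prev, c_prev, BOND_C_N,
                        ANGLE_CA_C_N, psi[i - 1L])
      ca_i <- place_atom(ca_prev, c_prev, n_i, BOND_N_CA,
                         ANGLE_C_N_CA, 180)
      c_i <- place_atom(c_prev, n_i, ca_i, BOND_CA_C,
                        ANGLE_N_CA_C, phi[i])
    }
    o_i <- place_atom(n_i, ca_i, c_i, BOND_C_O, 120.5, psi[i] + 180)
    resname <- AA3_CODES[[chars[i]]]
    rows[[length(rows) + 1L]] <- atom_row("ATOM", "N", resname, chain, i,
                                          n_i, "N")
    rows[[length(rows) + 1L]] <- atom_row("ATOM", "CA", resname, chain, i,
                                          ca_i, "C")
    rows[[length(rows) + 1L]] <- atom_row("ATOM", "C", resname, chain, i,
                                          c_i, "C")
    rows[[length(rows) + 1L]] <- atom_row("ATOM", "O", resname, chain, i,
                                          o_i, "O")
    if (chars[i] == "A") {
      cb <- place_atom(n_i, c_i, ca_i, 1.530, 110.6, -122.6)
      rows[[length(rows) + 1L]] <- atom_row("ATOM", "CB", resname, chain,
                                            i, cb, "C")
    } else if (chars[i] == "Y") {
      sc <- tyr_sidechain(n_i, ca_i, c_i, chi1 = chi1, chi2 = chi2)
      for (nm in names(sc)) {
        rows[[length(rows) + 1L]] <- atom_row(
          "ATOM", nm, resname, chain, i, sc[[nm]],
          if (startsWith(nm, "O")) "O" else "C")
      }
    }
    n_prev <- n_i
    ca_prev <- ca_i
    c_prev <- c_i
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  pdb_structure(atoms, title = paste0("ideal peptide ", sequence))
}

# Shell of carbon blocker pseudo-atoms on one sphere, emitted as
# HETATM records in their own chain so residue-level logic ignores
# them while SASA occlusion includes them.
blocker_shell <- function(center, radius, spacing = 3.0, chain = "X",
                          start_resseq = 1L) {
  n <- max(12L, as.integer(ceiling(4 * pi * radius^2 / spacing^2 * 1.3)))
  pts <- sweep(sphere_points(n) * radius, 2L, center, "+")
  rows <- lapply(seq_len(n), function(i) {
    atom_row("HETATM", "C", "BLK", chain, start_resseq + i - 1L,
             pts[i, ], "C")
  })
  do.call(rbind, rows)
}

# Double blocker shell around a set of atom coordinates: tight enough
# that no probe-sized channel reaches the enclosed atoms.
burial_shells <- function(atom_coords, clearance = 3.0, spacing = 3.0,
                          chain = "X", start_resseq = 1L) {
  center <- colMeans(atom_coords)
  r_in <- max(sqrt(rowSums(sweep(atom_coords, 2L, center, "-")^2))) +
    clearance
  inner <- blocker_shell(center, r_in, spacing, chain, start_resseq)
  outer <- blocker_shell(center, r_in + 1.8, spacing, chain,
                         start_resseq + nrow(inner))
  rbind(inner, outer)
}

#' Fixture specification
#'
#' @param kind One of `isolated_atom`, `atom_pair`, `buried_atom`,
#'   `extended_peptide`, `helix`, `strand`, `exposed_tyr`,
#'   `buried_tyr`, `toy_chimera`.
#' @param parameters Named list of kind-specific parameters (distances
#'   in Angstrom, counts, phi/psi targets).
#' @param seed Integer carried for provenance; generation itself is
#'   deterministic and does not consume randomness.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, parameters = list(), seed = 1L) {
  kinds <- c("isolated_atom", "atom_pair", "buried_atom",
             "extended_peptide", "helix", "strand", "exposed_tyr",
             "buried_tyr", "toy_chimera")
  if (!(kind %in% kinds)) {
    stop("unknown fixture kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  }
  structure(list(kind = kind, parameters = parameters,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build a synthetic test fixture
#'
#' Deterministically constructs the toy structure described by a
#' [fixture_spec()].  Peptide kinds also return the corresponding
#' sequence record.  `toy_chimera` concatenates a strand-like segment
#' (curli-flavoured, no tyrosines) with an extended tyrosine-rich
#' segment holding `k` exposed and `m` shell-buried tyrosines; burial
#' is enforced by HETATM carbon blocker shells in a separate chain.
#'
#' @param spec A [fixture_spec()] (or a kind name, for defaults).
#' @return List with elements `structure` ([pdb_structure()]) and
#'   `record` ([seq_record()] or `NULL`).
#' @export
build_fixture <- function(spec) {
  if (is.character(spec)) spec <- fixture_spec(spec)
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$parameters
  getp <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  record <- NULL
  st <- switch(spec$kind,
    isolated_atom = {
      atoms <- atom_row("HETATM", "C", "BLK", "X", 1L, c(0, 0, 0), "C")
      atoms$serial <- 1L
      pdb_structure(atoms, title = "isolated carbon atom")
    },
    atom_pair = {
      d <- getp("distance", 3.1)
      atoms <- rbind(
        atom_row("HETATM", "C", "BLK", "X", 1L, c(0, 0, 0), "C"),
        atom_row("HETATM", "C", "BLK", "X", 2L, c(d, 0, 0), "C"))
      atoms$serial <- seq_len(2L)
      pdb_structure(atoms, title = sprintf("carbon pair at %.2f A", d))
    },
    buried_atom = {
      s <- getp("spacing", 2.0)
      grid <- as.matrix(expand.grid(x = c(-s, 0, s), y = c(-s, 0, s),
                                    z = c(-s, 0, s)))
      center_row <- which(rowSums(grid^2) == 0)
      grid <- rbind(grid[center_row, , drop = FALSE],
                    grid[-center_row, , drop = FALSE])
      rows <- lapply(seq_len(nrow(grid)), function(i) {
        atom_row("HETATM", "C", "BLK", "X", i, grid[i, ], "C")
      })
      atoms <- do.call(rbind, rows)
      atoms$serial <- seq_len(nrow(atoms))
      pdb_structure(atoms, title = "buried central atom in 3x3x3 lattice")
    },
    extended_peptide = {
      seq_str <- getp("sequence", "GGGGG")
      record <- seq_record("extended_peptide", seq_str)
      build_peptide(seq_str, phi = getp("phi", -140), psi = getp("psi", 135))
    },
    helix = {
      seq_str <- getp("sequence", "AAAAAAAAAA")
      record <- seq_record("helix", seq_str)
      build_peptide(seq_str, phi = getp("phi", -57), psi = getp("psi", -47))
    },
    strand = {
      seq_str <- getp("sequence", "AAAAAAAA")
      record <- seq_record("strand", seq_str)
      build_peptide(seq_str, phi = getp("phi", -120), psi = getp("psi", 120))
    },
    exposed_tyr = {
      record <- seq_record("exposed_tyr", "GYG")
      build_peptide("GYG", phi = -150, psi = 150, chi1 = -60)
    },
    buried_tyr = {
      pep <- build_peptide("GYG", phi = -150, psi = 150, chi1 = -60)
      record <- seq_record("buried_tyr", "GYG")
      res <- residue_keys(pep)
      tyr_atoms <- pep$atoms[res == "A:2: " &
                               !(pep$atoms$name %in% c("N", "CA", "C", "O")), ]
      shells <- burial_shells(as.matrix(tyr_atoms[, c("x", "y", "z")]),
                              clearance = getp("clearance", 3.0),
                              spacing = getp("spacing", 3.0))
      atoms <- rbind(strip_derived(pep$atoms), shells)
      atoms$serial <- seq_len(nrow(atoms))
      pdb_structure(atoms, title = "buried tyrosine in blocker shell")
    },
    toy_chimera = {
      k <- getp("k", 4L)
      m <- getp("m", 3L)
      n_tyr <- k + m
      strand_seq <- "AGAGAG"
      tyr_seq <- if (n_tyr > 0L) {
        paste0(strrep("GGGY", n_tyr), "GG")
      } else "GG"
      seq_str <- paste0(strand_seq, tyr_seq)
      record <- seq_record("toy_chimera", seq_str)
      nres <- nchar(seq_str)
      phi <- c(rep(-120, 6L), rep(-140, nres - 6L))
      psi <- c(rep(120, 6L), rep(135, nres - 6L))
      pep <- build_peptide(seq_str, phi = phi, psi = psi)
      chars <- strsplit(seq_str, "", fixed = TRUE)[[1L]]
      tyr_pos <- which(chars == "Y")
      buried_pos <- if (m > 0L) tail(tyr_pos, m) else integer(0L)
      atoms <- strip_derived(pep$atoms)
      next_blk <- 1L
      for (pos in buried_pos) {
        keys <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = ":")
        sel <- keys == paste("A", pos, " ", sep = ":") &
          !(atoms$name %in% c("N", "CA", "C", "O"))
        shells <- burial_shells(as.matrix(atoms[sel, c("x", "y", "z")]),
                                start_resseq = next_blk)
        next_blk <- next_blk + nrow(shells)
        atoms <- rbind(atoms, shells)
      }
      atoms$serial <- seq_len(nrow(atoms))
      pdb_structure(atoms, title = sprintf(
        "toy chimera: %d exposed + %d buried tyrosines", k, m))
    }
  )
  list(structure = st, record = record)
}
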