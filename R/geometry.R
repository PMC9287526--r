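# Structure-quality and comparison metrics: phi/psi dihedrals with a
# coarse Ramachandran classification, radius of gyration, and RMSD
# with optional Kabsch superposition.

# Signed dihedral angle (degrees, IUPAC convention) defined by four
# points; NA when any bonded triplet is collinear.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  n2 <- c(b2[2L] * b3[3L] - b2[3L] * b3[2L],
          b2[3L] * b3[1L] - b2[1L] * b3[3L],
          b2[1L] * b3[2L] - b2[2L] * b3[1L])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2L] * b2[3L] - n1[3L] * b2[2L],
          n1[3L] * b2[1L] - n1[1L] * b2[3L],
          n1[1L] * b2[2L] - n1[2L] * b2[1L]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Coarse Ramachandran rectangles (phi_min, phi_max, psi_min, psi_max).
rama_core_boxes <- list(
  c(-180, -30, -90, 180),    # beta / polyproline / alpha-L sheet region
  c(-180, -30, -180, -150),  # psi wrap-around of the same region
  c(30, 90, -20, 60)         # right-handed (left-side) helical box
)

in_boxes <- function(phi, psi, boxes, margin = 0) {
  for (b in boxes) {
    if (phi >= max(-180, b[1L] - margin) && phi <= min(180, b[2L] + margin) &&
        psi >= max(-180, b[3L] - margin) && psi <= min(180, b[4L] + margin)) {
      return(TRUE)
    }
  }
  FALSE
}

classify_rama <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("incomplete")
  if (in_boxes(phi, psi, rama_core_boxes)) return("core")
  if (in_boxes(phi, psi, rama_core_boxes, margin = 20)) return("allowed")
  "outlier"
}

#' Backbone phi/psi dihedrals with coarse Ramachandran regions
#'
#' Computes phi and psi for every residue with complete backbone
#' context and classifies each pair into coarse rectangular regions
#' (`core`, `allowed` = 20 degree margin, `outlier`).  Terminal
#' residues, residues with missing backbone atoms, and degenerate
#' (collinear) geometry are marked `incomplete`.  The rectangles are a
#' deliberately simple stand-in for empirical density maps and are
#' meant for sanity checks, not for publication-grade validation.
#'
#' @param structure A [pdb_structure()].
#' @return Data frame: `key`, `chain`, `resseq`, `resname`, `phi`,
#'   `psi` (degrees in (-180, 180]), `region`.
#' @export
backbone_dihedrals <- function(structure) {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms
  rkeys <- residue_keys(structure)
  res <- residue_table(structure)
  res <- res[res$is_amino, , drop = FALSE]
  get_atom <- function(key, name) {
    i <- which(rkeys == key & a$name == name)
    if (length(i) != 1L) return(NULL)
    as.numeric(a[i, c("x", "y", "z")])
  }
  out <- vector("list", nrow(res))
  collinear_seen <- FALSE
  for (chain in unique(res$chain)) {
    rc <- res[res$chain == chain, , drop = FALSE]
    rc <- rc[order(rc$resseq, rc$icode), , drop = FALSE]
    n <- nrow(rc)
    for (i in seq_len(n)) {
      phi <- psi <- NA_real_
      bb <- list(N = get_atom(rc$key[i], "N"),
                 CA = get_atom(rc$key[i], "CA"),
                 C = get_atom(rc$key[i], "C"))
      if (!any(vapply(bb, is.null, logical(1L))) && n >= 3L) {
        if (i > 1L) {
          c_prev <- get_atom(rc$key[i - 1L], "C")
          if (!is.null(c_prev)) {
            phi <- dihedral_angle(c_prev, bb$N, bb$CA, bb$C)
          }
        }
        if (i < n) {
          n_next <- get_atom(rc$key[i + 1L], "N")
          if (!is.null(n_next)) {
            psi <- dihedral_angle(bb$N, bb$CA, bb$C, n_next)
          }
        }
        if ((i > 1L && i < n) && (is.na(phi) || is.na(psi)) &&
            !is.null(bb$N)) {
          collinear_seen <- TRUE
        }
      }
      region <- if (is.na(phi) || is.na(psi)) "incomplete"
                else classify_rama(phi, psi)
      out[[which(res$key == rc$key[i])]] <- data.frame(
        key = rc$key[i], chain = chain, resseq = rc$resseq[i],
        resname = rc$resname[i], phi = phi, psi = psi, region = region,
        stringsAsFactors = FALSE)
    }
  }
  if (collinear_seen) {
    warning("degenerate (collinear) backbone geometry: ",
            "dihedral undefined for at least one interior residue")
  }
  do.call(rbind, out)
}

#' Radius of gyration
#'
#' Root-mean-square distance of heavy atoms from their centroid.
#' Mass-unweighted by default (MD packages differ on this); set
#' `mass_weighted = TRUE` to weight by atomic mass.
#'
#' @param structure A [pdb_structure()].
#' @param mass_weighted Weight atoms by atomic mass.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(structure, mass_weighted = FALSE) {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms[!structure$atoms$hydrogen, , drop = FALSE]
  if (nrow(a) == 0L) stop("structure has no heavy atoms")
  coords <- as.matrix(a[, c("x", "y", "z")])
  w <- if (mass_weighted) {
    masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                P = 30.974, H = 1.008)
    m <- masses[a$element]
    if (anyNA(m)) stop("no atomic mass for element ",
                       a$element[which(is.na(m))[1L]])
    m
  } else {
    rep(1, nrow(coords))
  }
  centroid <- colSums(coords * w) / sum(w)
  d2 <- rowSums(sweep(coords, 2L, centroid, "-")^2)
  sqrt(sum(w * d2) / sum(w))
}

# Kabsch optimal rotation of b onto a (both centered).
kabsch_rotation <- function(a, b) {
  h <- t(b) %*% a
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' RMSD between two conformers
#'
#' Root-mean-square deviation over corresponding atoms, matched by
#' atom key (`chain:resseq:icode:name`).  With `superpose = TRUE`
#' (default) the optimal rigid-body superposition (Kabsch) is applied
#' first.
#'
#' @param a,b [pdb_structure()] objects with identical atom sets.
#' @param superpose Superpose before measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = TRUE) {
  stopifnot(inherits(a, "pdb_structure"), inherits(b, "pdb_structure"))
  ka <- atom_keys(a)
  kb <- atom_keys(b)
  if (!setequal(ka, kb) || length(ka) != length(kb)) {
    first <- c(setdiff(ka, kb), setdiff(kb, ka))[1L]
    stop("mismatched atom sets between structures; first mismatch: ",
         first)
  }
  ca <- as.matrix(a$atoms[, c("x", "y", "z")])
  cb <- as.matrix(b$atoms[match(ka, kb), c("x", "y", "z")])
  if (superpose) {
    ca_c <- sweep(ca, 2L, colMeans(ca), "-")
    cb_c <- sweep(cb, 2L, colMeans(cb), "-")
    rot <- kabsch_rotation(ca_c, cb_c)
    cb_c <- cb_c %*% rot
    sqrt(mean(rowSums((ca_c - cb_c)^2)))
  } else {
    sqrt(mean(rowSums((ca - cb)^2)))
  }
}
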