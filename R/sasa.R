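# Shrake-Rupley solvent-accessible surface area, with a seeded
# Monte-Carlo rejection-sampling oracle used for cross-checks.

#' Default van der Waals radii (Angstrom)
#'
#' Bondi-style heavy-atom radii conventionally used for SASA.
#' @keywords internal
DEFAULT_VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                       H = 1.20, D = 1.20, P = 1.80)

#' SASA calculation parameters
#'
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Number of deterministic test points per atom
#'   sphere; at least 12.
#' @param radii_table Named vector mapping element symbol to van der
#'   Waals radius (Angstrom).
#' @param include_hydrogens If `TRUE`, hydrogens contribute surface and
#'   occlusion; default `FALSE` (heavy-atom model).
#' @return Object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L,
                        radii_table = DEFAULT_VDW_RADII,
                        include_hydrogens = FALSE) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  n_sphere_points <- as.integer(n_sphere_points)
  if (n_sphere_points < 12L) stop("n_sphere_points must be >= 12")
  if (any(radii_table <= 0)) stop("all van der Waals radii must be > 0")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 radii_table = radii_table,
                 include_hydrogens = include_hydrogens),
            class = "sasa_params")
}

#' Deterministic near-uniform points on the unit sphere
#'
#' Golden-section spiral: no randomness, points on the unit sphere to
#' machine precision.  Used as the test-point set of the Shrake-Rupley
#' sampler so that results are bit-reproducible.
#'
#' @param n Number of points (>= 12).
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 12L) stop("n must be >= 12")
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Assign per-atom radii; error names the offending atom.
atom_radii <- function(atoms, keys, radii_table) {
  r <- unname(radii_table[atoms$element])
  if (anyNA(r)) {
    bad <- which(is.na(r))[1L]
    stop("no van der Waals radius for element '", atoms$element[bad],
         "' (atom ", keys[bad], ")")
  }
  r
}

# Neighbor candidate lists via a uniform spatial grid with cell size
# 2*(max radius + probe), so occlusion tests are complete and the
# result does not depend on atom order.
grid_neighbors <- function(coords, cell) {
  ix <- floor(coords / cell)
  key <- paste(ix[, 1L], ix[, 2L], ix[, 3L])
  cells <- split(seq_len(nrow(coords)), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lookup <- function(i) {
    ci <- ix[i, ]
    nb <- integer(0L)
    for (k in seq_len(nrow(offsets))) {
      kk <- paste(ci[1L] + offsets[k, 1L], ci[2L] + offsets[k, 2L],
                  ci[3L] + offsets[k, 3L])
      hit <- cells[[kk]]
      if (!is.null(hit)) nb <- c(nb, hit)
    }
    nb[nb != i]
  }
  lapply(seq_len(nrow(coords)), lookup)
}

#' Compute solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius `r_vdw + probe` is sampled at
#' `n_sphere_points` deterministic spiral points; a point is accessible
#' when it lies outside every neighboring atom's augmented sphere.  The
#' atom's area is the accessible fraction times `4*pi*(r + probe)^2`.
#'
#' @param structure A [pdb_structure()].
#' @param params A [sasa_params()].
#' @return Object of class `sasa_result` with per-atom and per-residue
#'   absolute areas (Angstrom^2); relative areas are filled in by
#'   [relative_sasa()].
#' @export
compute_sasa <- function(structure, params = sasa_params()) {
  stopifnot(inherits(structure, "pdb_structure"),
            inherits(params, "sasa_params"))
  a <- structure$atoms
  sel <- if (params$include_hydrogens) rep(TRUE, nrow(a)) else !a$hydrogen
  if (!any(sel)) stop("structure has no heavy atoms")
  a <- a[sel, , drop = FALSE]
  akeys <- atom_keys(structure)[sel]
  rkeys <- residue_keys(structure)[sel]
  coords <- as.matrix(a[, c("x", "y", "z")])
  radii <- atom_radii(a, akeys, params$radii_table)
  aug <- radii + params$probe_radius
  pts <- sphere_points(params$n_sphere_points)
  nb <- grid_neighbors(coords, cell = 2 * max(aug))
  counts <- sasa_exposed_counts(coords, aug, pts, nb)
  area <- counts / params$n_sphere_points * 4 * pi * aug^2
  names(area) <- akeys
  per_res <- vapply(split(area, factor(rkeys, levels = unique(rkeys))),
                    sum, numeric(1L))
  res_tab <- residue_table(structure)
  res_tab <- res_tab[res_tab$key %in% names(per_res), , drop = FALSE]
  structure(list(per_atom = area,
                 per_residue = per_res,
                 relative_per_residue = NULL,
                 residues = res_tab,
                 params = params),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> ", length(x$per_atom), " atoms, ",
      length(x$per_residue), " residues, total ",
      round(sum(x$per_atom), 1), " A^2\n", sep = "")
  if (!is.null(x$relative_per_residue)) {
    cat("  relative accessibility computed for ",
        length(x$relative_per_residue), " residues\n", sep = "")
  }
  invisible(x)
}

#' Reference maximum accessible areas per residue type
#'
#' Theoretical maximum accessible surface areas (Angstrom^2) for the 20
#' standard residues (Tien et al. 2013, theoretical column), shipped as
#' a plain-text table.  The DOPA entry is the tyrosine reference plus a
#' hydroxyl increment, since no published maximum exists for DOPA.
#'
#' @param path Optional path to an alternative two-column table
#'   (residue name, area).
#' @param dopa_code Residue name under which DOPA is listed.
#' @param dopa_oh_increment Area increment (Angstrom^2) added to the
#'   tyrosine maximum for the DOPA entry when the table lacks one.
#' @return Named numeric vector, three-letter residue name -> area.
#' @export
max_asa_reference <- function(path = NULL, dopa_code = DOPA_CODE,
                              dopa_oh_increment = 30) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_asa_tien2013.tsv",
                        package = "dopasight", mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ref <- stats::setNames(tab[[2L]], tab[[1L]])
  if (!(dopa_code %in% names(ref)) && "TYR" %in% names(ref)) {
    ref[dopa_code] <- ref[["TYR"]] + dopa_oh_increment
  }
  ref
}

#' Relative (fractional) accessibility per residue
#'
#' Divides each amino-acid residue's absolute area by the reference
#' maximum for its residue type.  Values can exceed 1 in extended
#' conformations; values above 1.5 are capped at 1.5 with a warning.
#' Non-amino residues (e.g. HETATM blocker dummies in synthetic
#' fixtures) are skipped; a missing reference entry for an amino-acid
#' residue is an error.
#'
#' @param result A [compute_sasa()] result.
#' @param reference_table Named vector residue-name -> maximum area.
#' @return The `sasa_result` with `relative_per_residue` filled in.
#' @export
relative_sasa <- function(result, reference_table = max_asa_reference()) {
  stopifnot(inherits(result, "sasa_result"))
  res <- result$residues
  amino <- res[res$is_amino, , drop = FALSE]
  missing_ref <- setdiff(unique(amino$resname), names(reference_table))
  if (length(missing_ref) > 0L) {
    stop("no reference maximum area for residue type(s): ",
         paste(missing_ref, collapse = ", "))
  }
  rel <- result$per_residue[amino$key] / reference_table[amino$resname]
  names(rel) <- amino$key
  if (any(rel > 1.5)) {
    warning(sum(rel > 1.5), " residue(s) exceed 150% of the reference ",
            "maximum; capped at 1.5")
    rel[rel > 1.5] <- 1.5
  }
  result$relative_per_residue <- rel
  result
}

#' Monte-Carlo SASA oracle
#'
#' Independent rejection-sampling estimate of the same accessible-area
#' quantity as [compute_sasa()]: for each atom, `n_samples` random
#' directions are drawn, and the accessible fraction of the augmented
#' sphere is estimated, with a binomial standard error per atom.  Used
#' as a cross-check in the test suite; seeded and reproducible.
#'
#' @param structure A [pdb_structure()].
#' @param params A [sasa_params()].
#' @param n_samples Samples per atom (>= 1000).
#' @param seed Integer seed.
#' @return List with named vectors `per_atom` (Angstrom^2) and `se`
#'   (standard errors, Angstrom^2).
#' @export
mc_sasa_oracle <- function(structure, params = sasa_params(),
                           n_samples = 10000L, seed = 1L) {
  stopifnot(inherits(structure, "pdb_structure"),
            inherits(params, "sasa_params"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1000L) {
    stop("n_samples must be >= 1000")
  }
  a <- structure$atoms
  sel <- if (params$include_hydrogens) rep(TRUE, nrow(a)) else !a$hydrogen
  if (!any(sel)) stop("structure has no heavy atoms")
  a <- a[sel, , drop = FALSE]
  akeys <- atom_keys(structure)[sel]
  coords <- as.matrix(a[, c("x", "y", "z")])
  radii <- atom_radii(a, akeys, params$radii_table)
  aug <- radii + params$probe_radius
  n_at <- nrow(coords)
  area <- se <- numeric(n_at)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (i in seq_len(n_at)) {
    u <- matrix(stats::rnorm(3L * n_samples), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * aug[i], 2L, coords[i, ], "+")
    d2 <- colSums((t(coords) - coords[i, ])^2)
    cand <- which(d2 < (aug[i] + aug)^2 & seq_len(n_at) != i)
    exposed <- rep(TRUE, n_samples)
    for (j in cand) {
      dx <- p[, 1L] - coords[j, 1L]
      dy <- p[, 2L] - coords[j, 2L]
      dz <- p[, 3L] - coords[j, 3L]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz >= aug[j]^2)
    }
    frac <- mean(exposed)
    full <- 4 * pi * aug[i]^2
    area[i] <- frac * full
    se[i] <- sqrt(frac * (1 - frac) / n_samples) * full
  }
  names(area) <- names(se) <- akeys
  list(per_atom = area, se = se)
}
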