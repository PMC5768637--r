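# Structural analysis: active-site detection by ligand/metal contacts,
# Shrake-Rupley solvent-accessible surface area, active-site accessibility,
# homologous-position mapping and rigid (Kabsch) superposition.

#' Read a PDB structure into an atom tibble
#'
#' @param path Path to a PDB file (or PDB text containing newlines).
#' @param chain Optional chain identifier to select.
#' @return Tibble with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `residue_number`, `chain`, `x`, `y`, `z`, `is_hetero`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (length(path) == 1 && grepl("\n", path)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(path, tmp)
    on.exit(unlink(tmp))
    path <- tmp
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  out <- tibble(
    serial = a$eleno,
    atom_name = trimws(a$elety),
    element = toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                                    substr(trimws(a$elety), 1, 1), a$elesy))),
    residue_name = trimws(a$resid),
    residue_number = a$resno,
    chain = a$chain,
    x = a$x, y = a$y, z = a$z,
    is_hetero = a$type == "HETATM"
  )
  if (!is.null(chain)) out <- out[out$chain %in% chain, ]
  out
}

#' Strip hetero records (ligand, co-factors, waters) from a structure
#'
#' @param atoms Atom tibble.
#' @return Atom tibble without HETATM records.
#' @export
strip_hetero <- function(atoms) atoms[!atoms$is_hetero, ]

#' Detect active-site residues by ligand/metal contacts
#'
#' Residues with at least one heavy atom within `cutoff` of any atom of the
#' phosphate ligand or of a metal ion are considered active-site residues
#' (noncovalent contact criterion); the ligand residues themselves are
#' excluded.
#'
#' @param atoms Atom tibble (see [read_structure()]).
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0).
#' @param ligand_resnames Residue names treated as the phosphate ligand.
#' @param metal_elements Elements treated as metal-ion co-factors.
#' @return Object of class `active_site`: tibble of residues (`chain`,
#'   `residue_number`, `residue_name`, `min_distance`) with the cutoff and
#'   ligand selection as attributes.  Empty (with a warning) when no ligand
#'   is present.
#' @export
detect_active_site <- function(atoms, cutoff = 4.0,
                               ligand_resnames = c("PO4", "PI", "IPS", "2HP"),
                               metal_elements = c("CA", "FE", "ZN", "MG",
                                                  "MN")) {
  lig <- atoms[atoms$is_hetero &
                 (atoms$residue_name %in% ligand_resnames |
                    atoms$element %in% metal_elements), ]
  empty <- structure(
    tibble(chain = character(), residue_number = integer(),
           residue_name = character(), min_distance = numeric()),
    class = c("active_site", "tbl_df", "tbl", "data.frame"),
    cutoff = cutoff
  )
  if (nrow(lig) == 0) {
    warn("no phosphate ligand or metal ion found: empty active site")
    return(empty)
  }
  prot <- atoms[!atoms$is_hetero & atoms$element != "H", ]
  if (nrow(prot) == 0) return(empty)
  pm <- as.matrix(prot[, c("x", "y", "z")])
  lm <- as.matrix(lig[, c("x", "y", "z")])
  # min distance from each protein atom to any ligand atom
  d2 <- outer(rowSums(pm^2), rep(1, nrow(lm))) +
    outer(rep(1, nrow(pm)), rowSums(lm^2)) - 2 * pm %*% t(lm)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  prot$min_distance <- mind
  res <- dplyr::summarise(
    dplyr::group_by(prot, .data$chain, .data$residue_number,
                    .data$residue_name),
    min_distance = min(.data$min_distance), .groups = "drop"
  )
  res <- res[res$min_distance <= cutoff, ]
  res <- res[order(res$chain, res$residue_number), ]
  structure(res, class = c("active_site", class(tibble())), cutoff = cutoff)
}

# Molecule-attached orthonormal frame: principal axes of the coordinate
# cloud, axis signs fixed by the third moment, determinant forced to +1.
principal_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  X0 <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(X0), symmetric = TRUE)
  axes <- ev$vectors
  for (k in 1:3) {
    s <- sum((X0 %*% axes[, k])^3)
    if (s < 0) axes[, k] <- -axes[, k]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  axes
}

# Deterministic, near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places `n_points` test points on each atom's solvent-expanded sphere
#' (radius `r + probe`); points falling inside any neighbouring atom's
#' expanded sphere are buried.  The accessible fraction times the sphere
#' area gives the per-atom SASA, summed per residue.  Hydrogens are ignored.
#'
#' @param atoms Atom tibble; hetero atoms should usually be stripped first
#'   with [strip_hetero()].
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Test points per atom (default 960).
#' @param radii Named van der Waals radii by element.
#' @return Object of class `residue_sasa`: tibble (`chain`, `residue_number`,
#'   `residue_name`, `sasa`) with `probe` and `n_points` attributes.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960,
                               radii = VDW_RADII) {
  atoms <- atoms[atoms$element != "H", ]
  r <- radii[atoms$element]
  if (anyNA(r)) {
    abort(sprintf("no van der Waals radius for element '%s'",
                  atoms$element[which(is.na(r))[1]]))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  # Anchor the test-point sphere to the molecule's principal axes (signs
  # fixed by the third moment) so the computed area is invariant under
  # rigid motion of the whole structure.
  pts <- sphere_points(n_points) %*% t(principal_frame(xyz))
  rexp <- unname(r) + probe
  atom_sasa <- numeric(n)
  maxr <- max(rexp)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rexp[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < rexp[i] + rexp[nb]]
    test <- sweep(pts * rexp[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        dj2 <- rowSums(sweep(test, 2, xyz[j, ])^2)
        buried <- buried | dj2 < rexp[j]^2
      }
      acc <- sum(!buried)
    }
    atom_sasa[i] <- 4 * pi * rexp[i]^2 * acc / n_points
  }
  atoms$sasa <- atom_sasa
  out <- dplyr::summarise(
    dplyr::group_by(atoms, .data$chain, .data$residue_number,
                    .data$residue_name),
    sasa = sum(.data$sasa), .groups = "drop"
  )
  structure(out, class = c("residue_sasa", class(tibble())),
            probe = probe, n_points = n_points)
}

#' Active-site accessibility
#'
#' The sum of per-residue solvent-accessible surface areas over the
#' active-site residues.  The SASA should be computed on the structure with
#' ligand, co-factors (and any signal peptide) removed, so the site surface
#' is not masked by its own ligand.
#'
#' @param sasa A `residue_sasa` tibble.
#' @param site An `active_site` tibble (or any tibble with `chain` and
#'   `residue_number`).
#' @return Accessibility in square Angstrom.
#' @export
active_site_accessibility <- function(sasa, site) {
  if (nrow(site) == 0) return(0)
  key_sasa <- paste(sasa$chain, sasa$residue_number)
  key_site <- paste(site$chain, site$residue_number)
  missing <- setdiff(key_site, key_sasa)
  if (length(missing) > 0) {
    abort(paste("site residues absent from the SASA table:",
                paste(missing, collapse = ", ")))
  }
  sum(sasa$sasa[key_sasa %in% key_site])
}

#' Map active-site positions onto a homolog through an alignment
#'
#' Given a pairwise alignment (two equal-length gapped strings) and residue
#' positions on the reference, returns the aligned residue positions on the
#' homolog; positions aligned to a gap are reported as absent (`NA`).
#'
#' @param ref_aln,hom_aln Aligned (gapped) sequence strings.
#' @param site_positions Integer residue positions on the ungapped reference.
#' @return Tibble with `ref_pos`, `hom_pos` (NA when the position has no
#'   equivalent in the homolog).
#' @export
map_site_to_homolog <- function(ref_aln, hom_aln, site_positions) {
  rc <- strsplit(ref_aln, "")[[1]]
  hc <- strsplit(hom_aln, "")[[1]]
  if (length(rc) != length(hc)) abort("aligned strings differ in length")
  ref_num <- cumsum(rc != "-")
  hom_num <- cumsum(hc != "-")
  out <- purrr::map_dfr(site_positions, function(p) {
    col <- which(ref_num == p & rc != "-")
    if (length(col) == 0) {
      abort(sprintf("site position %d lies outside the alignment", p))
    }
    tibble(ref_pos = p,
           hom_pos = if (hc[col] == "-") NA_integer_
                     else as.integer(hom_num[col]))
  })
  out
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Least-squares rotation/translation superposing paired coordinates (e.g.
#' C-alpha atoms) via singular value decomposition, with the determinant
#' correction that guarantees a proper rotation.
#'
#' @param coordsA,coordsB n x 3 matrices of paired coordinates; `coordsB` is
#'   moved onto `coordsA`.
#' @return Object of class `superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3) {
    abort("coordinate sets must be paired n x 3 matrices")
  }
  if (nrow(A) < 3) abort("at least 3 paired points are required")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2) {
    abort("points are collinear: superposition is not unique")
  }
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Brot <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Brot - A0)^2)))
  translation <- ca - as.numeric(R %*% cb)
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD = %.3f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition (or any rigid transform) to coordinates
#'
#' @param coords n x 3 matrix.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector.
#' @return Transformed n x 3 matrix.
#' @export
transform_coords <- function(coords, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(coords) %*% t(rotation), 2, -translation)
}

#' Per-residue formal charge summary near a site
#'
#' A simple sequence-based summary of charged residues (D/E negative, K/R
#' positive, H half-positive) among and around the active-site residues.
#' This is a coarse descriptor of the site's electrostatic character, not an
#' electrostatic potential map.
#'
#' @param atoms Atom tibble.
#' @param site Active-site tibble.
#' @param radius Residues with any atom within `radius` Angstrom of a site
#'   residue atom are included (default 8).
#' @return Tibble with `n_positive`, `n_negative`, `net_formal_charge`.
#' @export
site_charge_summary <- function(atoms, site, radius = 8) {
  prot <- strip_hetero(atoms)
  site_atoms <- prot[paste(prot$chain, prot$residue_number) %in%
                       paste(site$chain, site$residue_number), ]
  if (nrow(site_atoms) == 0) {
    return(tibble(n_positive = 0L, n_negative = 0L, net_formal_charge = 0))
  }
  pm <- as.matrix(prot[, c("x", "y", "z")])
  sm <- as.matrix(site_atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rep(1, nrow(sm))) +
    outer(rep(1, nrow(pm)), rowSums(sm^2)) - 2 * pm %*% t(sm)
  near <- apply(d2, 1, min) <= radius^2
  res <- unique(prot[near, c("residue_number", "residue_name")])
  npos <- sum(res$residue_name %in% c("LYS", "ARG"))
  nneg <- sum(res$residue_name %in% c("ASP", "GLU"))
  nhis <- sum(res$residue_name == "HIS")
  tibble(n_positive = npos, n_negative = nneg,
         net_formal_charge = npos + 0.5 * nhis - nneg)
}
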