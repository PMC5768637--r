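# Seeded synthetic-data generators.  Each generator derives its own
# substream from the global seed so adding one generator does not perturb
# the others; given a seed, outputs are byte-identical across runs.

# Per-generator substream offsets.
SUBSTREAM_OFFSETS <- c(proteome = 11L, promoters = 23L, structure = 37L,
                       kinetics = 53L, survey = 71L, families = 97L)

substream_seed <- function(seed, what) {
  off <- SUBSTREAM_OFFSETS[[what]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% (2^31 - 1))
}

#' Generate synthetic phosphatase family reference sets
#'
#' Builds, for each requested family, sharply peaked random count matrices
#' (one dominant residue per column) and the matching consensus reference
#' sequence, then assembles calibrated `family_set` objects.  These emulate
#' curated profile sets at desk scale.
#'
#' @param families Named integer vector: number of PSSMs per family, e.g.
#'   `c(PhoD = 2, PhoX = 1)`.
#' @param pssm_length Columns per PSSM.
#' @param peak Probability mass of the dominant residue per column (0-1).
#' @param n_counts Pseudo-observations per column.
#' @param seed Integer seed.
#' @param calibration_samples,calibration_length Passed to
#'   [calibrate_pssm()].
#' @return List with `family_sets` (named list of `family_set`),
#'   `calibrations` (named by accession), `pssms`.
#' @export
gen_reference_families <- function(families = c(PhoD = 2, PhoX = 1),
                                   pssm_length = 60, peak = 0.85,
                                   n_counts = 100, seed = 1,
                                   calibration_samples = 500,
                                   calibration_length = 200) {
  sseed <- substream_seed(seed, "families")
  pssms <- list()
  refs <- list()
  with_seed(sseed, {
    for (fam in names(families)) {
      consensus <- sample(AA_ALPHABET, pssm_length, replace = TRUE,
                          prob = AA_BACKGROUND)
      for (k in seq_len(families[[fam]])) {
        # PSSMs of one family describe overlapping stretches of the same
        # consensus, so one implanted domain carries hits for all of them.
        if (k == 1) {
          cols <- seq_len(pssm_length)
        } else {
          span <- max(10, round(pssm_length / 2))
          start <- sample(seq_len(pssm_length - span + 1), 1)
          cols <- start:(start + span - 1)
        }
        counts <- matrix(0, length(cols), 20,
                         dimnames = list(NULL, AA_ALPHABET))
        for (i in seq_along(cols)) {
          rest <- n_counts * (1 - peak) * AA_BACKGROUND
          counts[i, ] <- rest
          counts[i, consensus[cols[i]]] <-
            counts[i, consensus[cols[i]]] + n_counts * peak
        }
        acc <- sprintf("SYN_%s_%d", fam, k)
        pssms[[acc]] <- counts_to_logodds(counts, accession = acc)
      }
      refs[[fam]] <- tibble(
        id = sprintf("%s_ref", fam), description = "synthetic consensus",
        residues = paste(consensus, collapse = ""), moltype = "protein"
      )
    }
  })
  calibrations <- lapply(pssms, function(p) {
    calibrate_pssm(p, n_samples = calibration_samples,
                   sample_length = calibration_length,
                   seed = substream_seed(seed, "families") + match(
                     p$accession, names(pssms)))
  })
  names(calibrations) <- names(pssms)
  family_sets <- list()
  for (fam in names(families)) {
    fam_pssms <- pssms[grepl(sprintf("^SYN_%s_", fam), names(pssms))]
    family_sets[[fam]] <- build_family_set(fam, refs[[fam]],
                                           unname(fam_pssms), calibrations)
  }
  list(family_sets = family_sets, calibrations = calibrations, pssms = pssms)
}

#' Generate a synthetic proteome with implanted phosphatase domains
#'
#' Decoy proteins are drawn i.i.d. from background amino-acid frequencies;
#' implant proteins carry a domain sampled from a family PSSM's per-column
#' emission probabilities (optionally sharpened), embedded at a random
#' position in a decoy host.  The truth table records every implant.
#'
#' @param families Output of [gen_reference_families()] (its PSSMs define
#'   the implantable domains).
#' @param implants Named integer vector of implant copies per family, e.g.
#'   `c(PhoD = 1, PhoX = 4)`.
#' @param n_decoys Number of decoy proteins.
#' @param length_range Range of protein lengths (aa).
#' @param sharpness Exponent applied to the emission probabilities when
#'   sampling implant residues; 1 samples the matrix as-is, 0 samples the
#'   background (signal-free negative control), larger values approach the
#'   consensus.
#' @param seed Integer seed.
#' @return List with `proteome` (sequence tibble) and `truth` (tibble
#'   `protein_id`, `family`, `insert_begin`, `insert_end`).
#' @export
gen_proteome <- function(families, implants = c(PhoD = 1, PhoX = 4),
                         n_decoys = 200, length_range = c(200, 600),
                         sharpness = 1, seed = 1) {
  sseed <- substream_seed(seed, "proteome")
  with_seed(sseed, {
    lens <- sample(length_range[1]:length_range[2],
                   n_decoys + sum(implants), replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = AA_BACKGROUND),
            collapse = "")
    }, character(1))
    ids <- sprintf("prot_%04d", seq_along(seqs))
    truth <- list()
    slot <- n_decoys
    for (fam in names(implants)) {
      # implants are sampled from the family's longest retained PSSM
      fam_pssms <- families$family_sets[[fam]]$pssms
      if (length(fam_pssms) == 0) {
        abort(sprintf(
          "family '%s' retained no PSSMs (profiles too short to reach the significance threshold on their own reference?)",
          fam))
      }
      p <- fam_pssms[[which.max(vapply(fam_pssms, `[[`, 0, "length"))]]
      emis <- exp(log(2) / 2 * p$weights) *
        matrix(p$background, p$length, 20, byrow = TRUE)  # back to probs
      emis <- emis / rowSums(emis)
      for (k in seq_len(implants[[fam]])) {
        slot <- slot + 1
        host <- seqs[slot]
        if (p$length > nchar(host)) {
          abort("implant longer than host protein")
        }
        domain <- vapply(seq_len(p$length), function(i) {
          pr <- if (sharpness == 0) AA_BACKGROUND else
            emis[i, ]^sharpness / sum(emis[i, ]^sharpness)
          sample(AA_ALPHABET, 1, prob = pr)
        }, character(1))
        pos <- sample(seq_len(nchar(host) - p$length + 1), 1)
        substr(host, pos, pos + p$length - 1) <-
          paste(domain, collapse = "")
        seqs[slot] <- host
        truth[[length(truth) + 1]] <- tibble(
          protein_id = ids[slot], family = fam,
          insert_begin = pos, insert_end = pos + p$length - 1
        )
      }
    }
    list(
      proteome = tibble(id = ids, description = "", residues = seqs,
                        moltype = "protein"),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Generate synthetic promoter regions with implanted motifs
#'
#' Background sequence follows an order-1 Markov chain (AT-rich by default,
#' as is typical of prokaryotic regulatory regions); motif instances are
#' sampled from a DNA PSSM's probabilities and implanted at stated positions
#' relative to the gene start (negative upstream).
#'
#' @param pssm A `dna_pssm` whose instances are implanted.
#' @param n_regions Number of upstream regions.
#' @param region_length Region length (nt).
#' @param implant_at Position of the implant 5' end relative to the gene
#'   start (e.g. -96), or `NULL` for no implant.
#' @param strand Strand of the implants, `"+"` or `"-"`.
#' @param at_richness Stationary A+T fraction of the background chain.
#' @param persistence Probability boost for staying within the AT (or GC)
#'   pool between adjacent bases, giving mild order-1 structure.
#' @param seed Integer seed.
#' @return List with `regions` (sequence tibble), `truth` (tibble
#'   `region_id`, `tf_name`, `rel_begin`, `rel_end`, `strand`) and
#'   `background` (the generating `markov_background`).
#' @export
gen_promoters <- function(pssm = NULL, n_regions = 100, region_length = 400,
                          implant_at = -96, strand = "+",
                          at_richness = 0.70, persistence = 0.1, seed = 1) {
  sseed <- substream_seed(seed, "promoters")
  at <- at_richness / 2
  gc <- (1 - at_richness) / 2
  initial <- c(A = at, C = gc, G = gc, T = at)
  trans <- matrix(rep(initial, each = 4), 4, 4,
                  dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  # mild first-order structure: AT-pool and GC-pool self-persistence
  for (a in DNA_ALPHABET) {
    pool <- if (a %in% c("A", "T")) c("A", "T") else c("C", "G")
    trans[a, pool] <- trans[a, pool] + persistence / 2
    trans[a, ] <- trans[a, ] / sum(trans[a, ])
  }
  bg <- structure(list(order = 1, initial = initial, transition = trans,
                       trained_on = "synthetic generator parameters"),
                  class = "markov_background")
  if (!is.null(pssm) && !is.null(implant_at)) {
    L <- pssm$length
    start_in_region <- region_length + 1 + implant_at
    if (start_in_region < 1 || start_in_region + L - 1 > region_length) {
      abort("implant does not fit inside the region")
    }
  }
  with_seed(sseed, {
    regions <- character(n_regions)
    truth <- list()
    for (r in seq_len(n_regions)) {
      s <- character(region_length)
      s[1] <- sample(DNA_ALPHABET, 1, prob = initial)
      for (i in seq_len(region_length)[-1]) {
        s[i] <- sample(DNA_ALPHABET, 1, prob = trans[s[i - 1], ])
      }
      if (!is.null(pssm) && !is.null(implant_at)) {
        inst <- vapply(seq_len(pssm$length), function(i) {
          sample(DNA_ALPHABET, 1, prob = exp(pssm$logp[i, ]))
        }, character(1))
        if (strand == "-") inst <- strsplit(
          reverse_complement(paste(inst, collapse = "")), "")[[1]]
        s[start_in_region:(start_in_region + pssm$length - 1)] <- inst
        truth[[length(truth) + 1]] <- tibble(
          region_id = sprintf("region_%03d", r), tf_name = pssm$accession,
          rel_begin = implant_at, rel_end = implant_at + pssm$length - 1,
          strand = strand
        )
      }
      regions[r] <- paste(s, collapse = "")
    }
    list(
      regions = tibble(id = sprintf("region_%03d", seq_len(n_regions)),
                       description = "", residues = regions,
                       moltype = "dna"),
      truth = if (length(truth) > 0) dplyr::bind_rows(truth) else
        tibble(region_id = character(), tf_name = character(),
               rel_begin = integer(), rel_end = integer(),
               strand = character()),
      background = bg
    )
  })
}

#' Generate a toy protein structure with a phosphate ligand
#'
#' Residues are laid out as C-alpha pseudo-atoms along a coarse helix; the
#' designated site residues are relocated to sit at a stated distance from a
#' phosphate ligand (P plus four O), optionally accompanied by metal ions.
#' Atom clashes (< 1 Angstrom) raise an error.
#'
#' @param n_residues Number of residues.
#' @param site_residues Residue numbers forming the active site.
#' @param ligand_distance Distance (Angstrom) from each site residue's
#'   C-alpha to the nearest ligand atom.
#' @param ions Character vector of ion element names placed near the ligand
#'   (e.g. `c("CA", "FE")`), or `NULL`.
#' @param seed Integer seed.
#' @return List with `pdb` (PDB text), `atoms` (atom tibble) and `truth`
#'   (tibble of site residue numbers).
#' @export
gen_toy_structure <- function(n_residues = 60, site_residues = c(5, 12, 40),
                              ligand_distance = 3.0, ions = "CA", seed = 1) {
  if (!all(site_residues %in% seq_len(n_residues))) {
    abort("site_residues must be a subset of the residues")
  }
  sseed <- substream_seed(seed, "structure")
  with_seed(sseed, {
    t <- seq_len(n_residues)
    helix <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t)
    # ligand centre well off the helix axis
    centre <- c(25, 0, mean(helix[, 3]))
    # phosphate: P at the centre, 4 O tetrahedral at 1.54 A
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                 c(-1, -1, 1)) / sqrt(3) * 1.54
    lig <- rbind(P = centre, O1 = centre + tet[1, ], O2 = centre + tet[2, ],
                 O3 = centre + tet[3, ], O4 = centre + tet[4, ])
    # relocate site residues onto a sphere around the ligand, along
    # well-separated (deterministic) directions
    dirs <- sphere_points(max(length(site_residues), 4))
    dirs <- dirs[seq_along(site_residues), , drop = FALSE]
    for (k in seq_along(site_residues)) {
      # radius along the chosen direction at which the distance to the
      # nearest ligand atom equals ligand_distance exactly
      mind <- function(r) {
        p <- centre + dirs[k, ] * r
        sqrt(min(rowSums(sweep(lig, 2, p)^2))) - ligand_distance
      }
      r <- uniroot(mind, c(ligand_distance / 4,
                           ligand_distance + 4), tol = 1e-10)$root
      helix[site_residues[k], ] <- centre + dirs[k, ] * r
    }
    atoms_xyz <- rbind(helix, lig)
    ion_xyz <- NULL
    if (!is.null(ions) && length(ions) > 0) {
      ion_xyz <- t(vapply(seq_along(ions), function(i) {
        centre + c(0, 0, 3.0 + 2.5 * (i - 1))
      }, numeric(3)))
      atoms_xyz <- rbind(atoms_xyz, ion_xyz)
    }
    dd <- as.matrix(stats::dist(atoms_xyz))
    diag(dd) <- Inf
    if (min(dd) < 1) abort("atom clash (< 1 Angstrom) in generated structure")

    res_names <- sample(c("ALA", "GLY", "SER", "ASP", "LYS", "HIS"),
                        n_residues, replace = TRUE)
    atoms <- tibble(
      serial = seq_len(n_residues),
      atom_name = "CA", element = "C",
      residue_name = res_names,
      residue_number = seq_len(n_residues), chain = "A",
      x = helix[, 1], y = helix[, 2], z = helix[, 3], is_hetero = FALSE
    )
    lig_tbl <- tibble(
      serial = n_residues + 1:5,
      atom_name = c("P", "O1", "O2", "O3", "O4"),
      element = c("P", "O", "O", "O", "O"),
      residue_name = "PO4", residue_number = n_residues + 1L, chain = "A",
      x = unname(lig[, 1]), y = unname(lig[, 2]), z = unname(lig[, 3]),
      is_hetero = TRUE
    )
    atoms <- dplyr::bind_rows(atoms, lig_tbl)
    if (!is.null(ion_xyz)) {
      atoms <- dplyr::bind_rows(atoms, tibble(
        serial = max(atoms$serial) + seq_along(ions),
        atom_name = ions, element = ions,
        residue_name = ifelse(ions == "CA", "CA", ions),
        residue_number = n_residues + 1L + seq_along(ions), chain = "A",
        x = ion_xyz[, 1], y = ion_xyz[, 2], z = ion_xyz[, 3],
        is_hetero = TRUE
      ))
    }
    list(pdb = atoms_to_pdb(atoms), atoms = atoms,
         truth = tibble(residue_number = sort(site_residues)))
  })
}

# Minimal fixed-width PDB writer for generated toy structures.
atoms_to_pdb <- function(atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (a$is_hetero) "HETATM" else "ATOM", a$serial,
            substr(a$atom_name, 1, 4), a$residue_name, a$chain,
            a$residue_number, a$x, a$y, a$z, 1.0, 0.0, a$element)
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a synthetic hydrolysis kinetics series
#'
#' `value(t) = slope * t + N(0, noise_sd)`, optionally saturating (constant)
#' after `t_sat`, emulating the initial linear phase of an enzymatic
#' absorbance assay.
#'
#' @param times Strictly increasing sampling times (s).
#' @param rate_pmol_s True release rate (pmol/s).
#' @param volume_l Reaction volume (L) converting the rate to a
#'   concentration slope.
#' @param noise_sd Gaussian noise, as a fraction of the final (pre-plateau)
#'   concentration.
#' @param t_sat Saturation time (s) after which the mean plateaus, or
#'   `NULL`.
#' @param seed Integer seed.
#' @return Tibble with `time`, `concentration`; the true rate is attached as
#'   attribute `"truth"`.
#' @export
gen_kinetics <- function(times = seq(0, 300, by = 20), rate_pmol_s = 1.7,
                         volume_l = 1e-3, noise_sd = 0.02, t_sat = NULL,
                         seed = 1) {
  if (is.unsorted(times, strictly = TRUE)) {
    abort("times must be strictly increasing")
  }
  sseed <- substream_seed(seed, "kinetics")
  slope <- rate_pmol_s * 1e-12 / volume_l  # M/s
  teff <- if (is.null(t_sat)) times else pmin(times, t_sat)
  mean_conc <- slope * teff
  scale <- max(mean_conc)
  with_seed(sseed, {
    conc <- mean_conc + rnorm(length(times), 0, noise_sd * scale)
  })
  structure(tibble(time = times, concentration = conc),
            truth = list(rate_pmol_s = rate_pmol_s, slope_m_per_s = slope,
                         t_sat = t_sat))
}

#' Generate a synthetic genome survey table
#'
#' Genome sizes are lognormal; per-family gene counts are Poisson with mean
#' proportional to genome size (or exactly linear with `noise = "none"`),
#' and phylum labels are assigned round-robin.
#'
#' @param n_genomes Number of genomes (>= 3).
#' @param slope_per_mb Named numeric: mean genes per Mb for each family
#'   present; families not named get 0.
#' @param mean_size_mb,sdlog Lognormal size distribution parameters.
#' @param phyla Phylum labels recycled over genomes.
#' @param noise `"poisson"` (default) or `"none"` (deterministic rounding-
#'   free linear counts, for noiseless checks).
#' @param seed Integer seed.
#' @return Survey tibble in the layout of [build_survey()].
#' @export
gen_survey <- function(n_genomes = 200,
                       slope_per_mb = c(PhoA = 0.108, PhoK = 0.010,
                                        PhoD = 0.047, PhoX = 0.062,
                                        AcpA = 0.040, PhoN = 0.040,
                                        AphA = 0.040, NSAPc = 0.040),
                       mean_size_mb = 4, sdlog = 0.35,
                       phyla = c("Proteobacteria", "Firmicutes",
                                 "Actinobacteria", "Bacteroidetes"),
                       noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  if (n_genomes < 3) abort("n_genomes must be >= 3")
  sseed <- substream_seed(seed, "survey")
  with_seed(sseed, {
    sizes <- stats::rlnorm(n_genomes, log(mean_size_mb * 1e6), sdlog)
    out <- tibble(
      genome_id = sprintf("genome_%04d", seq_len(n_genomes)),
      phylum = rep(phyla, length.out = n_genomes),
      genome_length = sizes
    )
    for (f in PHOSPHATASE_FAMILIES) {
      mu <- (slope_per_mb[f] %||% 0) * sizes / 1e6
      mu[is.na(mu)] <- 0
      out[[f]] <- if (noise == "poisson") rpois(n_genomes, mu) else mu
    }
    out$total <- rowSums(out[, PHOSPHATASE_FAMILIES])
    out$alkaline <- rowSums(out[, ALKALINE_FAMILIES])
    if (noise == "poisson") {
      out$total <- as.integer(out$total)
      out$alkaline <- as.integer(out$alkaline)
    }
    out
  })
}
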