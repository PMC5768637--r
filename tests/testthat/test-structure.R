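test_that("isolated and distant atoms reach the closed-form sphere area", {
  a1 <- ca_atom(1, 1, 0, 0, 0)
  s1 <- shrake_rupley_sasa(a1)
  expect_equal(s1$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)

  pair <- dplyr::bind_rows(a1, ca_atom(2, 2, 100, 0, 0))
  s2 <- shrake_rupley_sasa(pair)
  expect_equal(s2$sasa, rep(4 * pi * (1.7 + 1.4)^2, 2), tolerance = 1e-6)

  expect_error(shrake_rupley_sasa(ca_atom(1, 1, 0, 0, 0, element = "QQ")),
               "QQ")
})

test_that("dimer SASA matches a Monte-Carlo surface integration within 2%", {
  pair <- dplyr::bind_rows(ca_atom(1, 1, 0, 0, 0), ca_atom(2, 2, 2, 0, 0))
  sr <- shrake_rupley_sasa(pair)
  r <- 1.7 + 1.4
  mc <- withr::with_seed(9, {
    n <- 1e5
    pts <- matrix(rnorm(3 * n), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * r
    # accessible fraction of atom 1's expanded sphere vs neighbour at (2,0,0)
    mean(rowSums(sweep(pts, 2, c(2, 0, 0))^2) >= r^2) * 4 * pi * r^2
  })
  expect_lt(abs(sr$sasa[1] - mc) / mc, 0.02)
  expect_lt(abs(sr$sasa[2] - mc) / mc, 0.02)
})

test_that("per-atom SASA is bounded and shrinks as neighbours are added", {
  iso <- shrake_rupley_sasa(ca_atom(1, 1, 0, 0, 0))$sasa
  two <- shrake_rupley_sasa(dplyr::bind_rows(
    ca_atom(1, 1, 0, 0, 0), ca_atom(2, 2, 2.5, 0, 0)))$sasa
  three <- shrake_rupley_sasa(dplyr::bind_rows(
    ca_atom(1, 1, 0, 0, 0), ca_atom(2, 2, 2.5, 0, 0),
    ca_atom(3, 3, -2.5, 0, 0)))$sasa
  expect_lte(two[1], iso)
  expect_lte(three[1], two[1])
})

test_that("SASA is invariant under rigid motion of the structure", {
  ts <- gen_toy_structure(seed = 11)
  prot <- strip_hetero(ts$atoms)
  s0 <- shrake_rupley_sasa(prot)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  xyz <- as.matrix(prot[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, c(5, -3, 2), `+`)
  moved <- prot
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  s1 <- shrake_rupley_sasa(moved)
  expect_lt(max(abs(s1$sasa - s0$sasa) / pmax(s0$sasa, 1)), 0.001)
})

test_that("active sites are detected from ligand and metal contacts", {
  ts <- gen_toy_structure(site_residues = c(5, 12, 40), seed = 11)
  site <- detect_active_site(ts$atoms)
  expect_equal(site$residue_number, c(5L, 12L, 40L))

  # removing the ligand and ions empties the site, with a warning
  bare <- strip_hetero(ts$atoms)
  expect_warning(empty <- detect_active_site(bare), "no phosphate ligand")
  expect_equal(nrow(empty), 0)
})

test_that("accessibility sums per-residue SASA over the site", {
  ts <- gen_toy_structure(seed = 13)
  site <- detect_active_site(ts$atoms)
  sas <- shrake_rupley_sasa(strip_hetero(ts$atoms))
  acc <- active_site_accessibility(sas, site)
  manual <- sum(sas$sasa[sas$residue_number %in% site$residue_number])
  expect_equal(acc, manual)
  expect_equal(active_site_accessibility(sas, site[0, ]), 0)
  ghost <- tibble::tibble(chain = "A", residue_number = 999L)
  expect_error(active_site_accessibility(sas, ghost), "999")
})

test_that("toy PDB text round-trips through the PDB reader", {
  ts <- gen_toy_structure(seed = 17)
  atoms <- read_structure(ts$pdb)
  expect_equal(nrow(atoms), nrow(ts$atoms))
  expect_equal(sum(atoms$is_hetero), sum(ts$atoms$is_hetero))
  expect_equal(atoms$x, ts$atoms$x, tolerance = 1e-3)
  site <- detect_active_site(atoms)
  expect_equal(site$residue_number, ts$truth$residue_number)
})

test_that("site positions map through alignments, gaps become absences", {
  # identity alignment maps identically
  ident <- map_site_to_homolog("MKVLWA", "MKVLWA", c(2, 5))
  expect_equal(ident$hom_pos, c(2L, 5L))

  # C-terminal extension absent from the homolog: capped positions map to NA
  ref <- paste0(paste(rep("A", 10), collapse = ""),
                paste(rep("C", 28), collapse = ""))
  hom <- paste0(paste(rep("A", 10), collapse = ""),
                paste(rep("-", 28), collapse = ""))
  capped <- map_site_to_homolog(ref, hom, c(3, 20, 35))
  expect_equal(capped$hom_pos, c(3L, NA, NA))

  # hand-built alignment with one insertion in the homolog
  m <- map_site_to_homolog("MK-VLW", "MKAVLW", c(3, 4))
  expect_equal(m$hom_pos, c(4L, 5L))

  expect_error(map_site_to_homolog("MKV", "MKV", 7), "outside")
  expect_error(map_site_to_homolog("MKV", "MKVA", 1), "length")
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  withr::with_seed(19, {
    A <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)

    th <- 1.1
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                3, 3, byrow = TRUE)
    B <- sweep(A %*% t(R), 2, c(4, -2, 7), `+`)
    fit <- kabsch_superpose(A, B)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  })
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches a rotation-grid search on a toy pair", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.2, 0), c(0.3, 0.4, 1.5))
  B <- withr::with_seed(23, A + matrix(rnorm(12, sd = 0.3), 4, 3))
  ours <- kabsch_superpose(A, B)$rmsd
  # independent oracle: coarse grid over Euler angles, then local refinement
  rmsd_at <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
    B0 <- sweep(B, 2, colMeans(B))
    A0 <- sweep(A, 2, colMeans(A))
    sqrt(mean(rowSums((B0 %*% t(R) - A0)^2)))
  }
  grid <- as.matrix(expand.grid(seq(-pi, pi, length.out = 12),
                                seq(-pi / 2, pi / 2, length.out = 7),
                                seq(-pi, pi, length.out = 12)))
  vals <- apply(grid, 1, rmsd_at)
  refined <- optim(grid[which.min(vals), ], rmsd_at)$value
  expect_equal(ours, refined, tolerance = 1e-3)
})

test_that("site charge summary counts formal charges near the site", {
  atoms <- dplyr::bind_rows(
    ca_atom(1, 1, 0, 0, 0, residue_name = "ASP"),
    ca_atom(2, 2, 3, 0, 0, residue_name = "LYS"),
    ca_atom(3, 3, 50, 0, 0, residue_name = "ARG"),
    ca_atom(4, 10, 1.5, 1.5, 0, element = "P", residue_name = "PO4",
            hetero = TRUE, atom_name = "P")
  )
  site <- detect_active_site(atoms)
  cs <- site_charge_summary(atoms, site)
  expect_equal(cs$n_negative, 1L)
  expect_equal(cs$n_positive, 1L)  # the distant ARG is excluded
  expect_equal(cs$net_formal_charge, 0)
})
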