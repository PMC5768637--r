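test_that("log-odds weights follow the pseudocounted formula", {
  # uniform counts against a uniform background give all-zero weights
  ucounts <- matrix(1, 3, 20, dimnames = list(NULL, aa20))
  ubg <- setNames(rep(1 / 20, 20), aa20)
  expect_equal(max(abs(counts_to_logodds(ucounts, ubg)$weights)), 0)

  # hand arithmetic: column (4, 0, ..., 0), uniform bg, pseudocount 1
  counts <- matrix(0, 1, 20, dimnames = list(NULL, aa20))
  counts[1, "A"] <- 4
  p <- counts_to_logodds(counts, ubg, pseudocount = 1)
  expect_equal(unname(p$weights[1, "A"]),
               2 * (log2((4 + 1 / 20) / (4 + 1)) - log2(1 / 20)))
  expect_equal(unname(p$weights[1, "C"]),
               2 * (log2((0 + 1 / 20) / (4 + 1)) - log2(1 / 20)))

  # doubling all counts leaves weights unchanged in the zero-pseudocount
  # limit (all cells positive so the limit is finite)
  cnt <- matrix(withr::with_seed(2, sample(1:9, 40, replace = TRUE)), 2, 20,
                dimnames = list(NULL, aa20))
  w1 <- counts_to_logodds(cnt, pseudocount = 1e-9)$weights
  w2 <- counts_to_logodds(2 * cnt, pseudocount = 1e-9)$weights
  expect_equal(w1, w2, tolerance = 1e-6)

  expect_error(counts_to_logodds(cnt, setNames(rep(0, 20), aa20)),
               "> 0")
})

test_that("best ungapped hit equals exhaustive segment enumeration", {
  cal1 <- structure(list(lambda = 1, K = 1, method = "none"),
                    class = "scan_calibration")
  withr::with_seed(7, {
    for (rep in 1:5) {
      m <- sample(4:15, 1)
      n <- sample(10:30, 1)
      toy <- toy_protein_pssm(length = m, seed = rep + 100)
      q <- random_protein(n)
      best <- best_ungapped_hits(toy$pssm, q, cal1, max_hits = 1)
      W <- toy$pssm$weights
      qi <- match(strsplit(q, "")[[1]], aa20)
      brute <- -Inf
      for (off in -(m - 1):(n - 1)) for (i in 1:m) for (j in i:m) {
        qs <- (i:j) + off
        if (all(qs >= 1 & qs <= n)) {
          s <- sum(W[cbind(i:j, qi[qs])])
          if (s > brute) brute <- s
        }
      }
      expect_equal(best$score, brute, tolerance = 1e-10)
    }
  })
})

test_that("a consensus query yields a full-profile maximal hit", {
  toy <- toy_protein_pssm(length = 20, seed = 5)
  cal <- structure(list(lambda = 0.3, K = 0.1, method = "none"),
                   class = "scan_calibration")
  h <- best_ungapped_hits(toy$pssm, toy$consensus, cal, max_hits = 1)
  expect_equal(c(h$p_begin, h$p_end), c(1L, 20L))
  expect_equal(c(h$q_begin, h$q_end), c(1L, 20L))
  expect_equal(h$score, sum(apply(toy$pssm$weights, 1, max)))
})

test_that("E-values decrease strictly with score at fixed calibration", {
  cal <- structure(list(lambda = 0.3, K = 0.1, method = "none"),
                   class = "scan_calibration")
  scores <- c(10, 20, 40, 80)
  ev <- cal$K * 100 * 200 * exp(-cal$lambda * scores)
  expect_true(all(diff(ev) < 0))
})

test_that("calibration is deterministic and rejects degenerate scores", {
  toy <- toy_protein_pssm(length = 15, seed = 9)
  c1 <- calibrate_pssm(toy$pssm, n_samples = 120, sample_length = 80,
                       seed = 3)
  c2 <- calibrate_pssm(toy$pssm, n_samples = 120, sample_length = 80,
                       seed = 3)
  expect_identical(c1$lambda, c2$lambda)
  expect_identical(c1$K, c2$K)

  zero <- counts_to_logodds(matrix(1, 5, 20, dimnames = list(NULL, aa20)),
                            setNames(rep(1 / 20, 20), aa20), pseudocount = 0)
  expect_error(calibrate_pssm(zero, n_samples = 50, sample_length = 40),
               "degenerate")
})

test_that("empirical lambda matches the analytic Karlin root for a lattice score", {
  # +1/-1 column scores: lambda solves sum_a p_a exp(lambda s_a) = 1
  ord <- order(-bg20)
  sel <- character(0); tot <- 0
  for (i in ord) {
    if (tot < 0.25) { sel <- c(sel, aa20[i]); tot <- tot + bg20[i] }
  }
  w <- ifelse(aa20 %in% sel, 1, -1)
  lam_analytic <- uniroot(function(l) sum(bg20 * exp(l * w)) - 1,
                          c(1e-6, 5))$root
  W <- matrix(rep(w, each = 200), nrow = 200, dimnames = list(NULL, aa20))
  pm <- structure(list(accession = "pm1", alphabet = aa20, weights = W,
                       length = 200, source_counts = NULL,
                       background = bg20), class = "protein_pssm")
  cal <- calibrate_pssm(pm, n_samples = 1000, sample_length = 200, seed = 5)
  expect_lt(abs(cal$lambda - lam_analytic) / lam_analytic, 0.10)
})

test_that("null best-hit scores follow the calibrated Gumbel law", {
  toy <- toy_protein_pssm(length = 40, seed = 21)
  cal <- calibrate_pssm(toy$pssm, n_samples = 600, sample_length = 150,
                        seed = 11)
  null_cal <- structure(list(lambda = 1, K = 1, method = "none"),
                        class = "scan_calibration")
  scores <- withr::with_seed(12, vapply(1:400, function(i) {
    q <- random_protein(150)
    best_ungapped_hits(toy$pssm, q, null_cal, max_hits = 1)$score
  }, numeric(1)))
  # distributional agreement: Kolmogorov distance to the calibrated Gumbel
  # stays small (scores are lattice-valued, so the law is only approximately
  # Gumbel at this size)
  mu <- log(cal$K * toy$pssm$length * 150) / cal$lambda
  pg <- exp(-exp(-cal$lambda * (scores - mu)))  # Gumbel CDF transform
  ks <- suppressWarnings(stats::ks.test(pg, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
  # and the calibrated tail is accurate where E-value decisions are made
  for (q in c(0.9, 0.95, 0.99)) {
    s <- quantile(scores, q)
    pred <- 1 - exp(-cal$K * toy$pssm$length * 150 * exp(-cal$lambda * s))
    emp <- mean(scores >= s)
    expect_gt(emp / pred, 0.5)
    expect_lt(emp / pred, 2.0)
  }
})

test_that("the 70% mutual-coverage rule reproduces the published retentions", {
  # PhoD reference: COG3540 [22-539] and cd07389 [174-468] are both kept
  phod <- tibble::tibble(
    pssm_accession = c("COG3540", "cd07389"),
    q_begin = c(22L, 174L), q_end = c(539L, 468L),
    evalue = c(1e-100, 1e-60)
  )
  expect_setequal(deduplicate_profiles(phod), c("COG3540", "cd07389"))
  # overlap 295 / longer 518 = 0.57 <= 0.70
  expect_lt((468 - 174 + 1) / (539 - 22 + 1), 0.70)

  # PhoK reference: pfam01663 [44-494] and COG1524 [41-114] are both kept
  phok <- tibble::tibble(
    pssm_accession = c("pfam01663", "COG1524"),
    q_begin = c(44L, 41L), q_end = c(494L, 114L),
    evalue = c(1e-120, 1e-20)
  )
  expect_setequal(deduplicate_profiles(phok), c("pfam01663", "COG1524"))

  # 86% coverage: only the lower-E profile survives
  redundant <- tibble::tibble(
    pssm_accession = c("strong", "weak"),
    q_begin = c(1L, 10L), q_end = c(100L, 95L),
    evalue = c(1e-50, 1e-20)
  )
  expect_equal(deduplicate_profiles(redundant), "strong")

  expect_equal(deduplicate_profiles(phod[0, ]), character(0))
})

test_that("deduplication is idempotent and never keeps a violating pair", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(2:12, 1)
      b <- sample(1:400, n, replace = TRUE)
      hits <- tibble::tibble(
        pssm_accession = sprintf("p%02d", 1:n),
        q_begin = b, q_end = b + sample(20:300, n, replace = TRUE),
        evalue = 10^-runif(n, 5, 80)
      )
      kept <- deduplicate_profiles(hits)
      sub <- hits[hits$pssm_accession %in% kept, ]
      expect_identical(deduplicate_profiles(sub), kept)
      if (length(kept) >= 2) {
        for (i in 1:(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
          ov <- min(sub$q_end[i], sub$q_end[j]) -
            max(sub$q_begin[i], sub$q_begin[j]) + 1
          longer <- max(sub$q_end[i] - sub$q_begin[i] + 1,
                        sub$q_end[j] - sub$q_begin[j] + 1)
          expect_lte(ov / longer, 0.70)
        }
      }
    }
  })
})

test_that("family membership requires every PSSM at threshold, monotonically", {
  fs <- structure(list(
    family = "PhoD", reference = NULL,
    pssms = list(list(accession = "p1"), list(accession = "p2"))
  ), class = "family_set")
  hits <- function(e1, e2) tibble::tibble(
    pssm_accession = c("p1", "p2"), evalue = c(e1, e2))
  expect_true(assign_family(hits(1e-12, 1e-15), fs))
  expect_false(assign_family(hits(1e-12, 1e-8), fs))
  # relaxing the threshold can only grow the annotated set
  expect_true(assign_family(hits(1e-12, 1e-8), fs, e_threshold = 1e-8))
})

test_that("local-alignment validation separates self from random sequences", {
  ref <- random_protein(400, seed = 51)
  self <- validate_member(ref, ref)
  expect_true(self[1])
  withr::with_seed(52, {
    for (i in 1:20) {
      rnd <- random_protein(300)
      expect_false(validate_member(rnd, ref)[1])
    }
  })
})

test_that("Smith-Waterman scores match an exhaustive affine-gap DP", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sw_brute <- function(a, b, go = 11, ge = 1) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    M <- Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
    M[1, ] <- 0; M[, 1] <- 0
    best <- 0
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      s <- BLOSUM62[A[i - 1], B[j - 1]]
      Ix[i, j] <- max(M[i - 1, j] - go - ge, Ix[i - 1, j] - ge)
      Iy[i, j] <- max(M[i, j - 1] - go - ge, Iy[i, j - 1] - ge)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      best <- max(best, M[i, j])
    }
    best
  }
  withr::with_seed(61, {
    for (rep in 1:5) {
      a <- random_protein(10)
      b <- random_protein(10)
      ours <- attr(validate_member(a, b), "score")
      expect_equal(ours, sw_brute(a, b))
    }
  })
})

test_that("an empty proteome annotates to an empty table", {
  empty <- tibble::tibble(id = character(), description = character(),
                          residues = character(), moltype = character())
  out <- annotate_proteome(empty, list(), list())
  expect_equal(nrow(out), 0)
  expect_named(out, c("protein_id", "family", "worst_evalue", "validated"))
})

test_that("RPS-Blast tabular output imports into the membership logic", {
  txt <- paste("prot1\tCOG3540\t45.2\t510\t20\t530\t1\t511\t1e-120\t380",
               "prot1\tcd07389\t40.1\t290\t170\t460\t1\t291\t1e-80\t250",
               sep = "\n")
  hits <- read_rpsblast_tabular(txt)
  fs <- structure(list(
    family = "PhoD", reference = NULL,
    pssms = list(list(accession = "COG3540"), list(accession = "cd07389"))
  ), class = "family_set")
  expect_true(assign_family(hits, fs))
})
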