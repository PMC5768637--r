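test_that("Markov training reproduces simple closed-form cases", {
  m <- train_markov("AAAA", order = 1, pseudocount = 0)
  expect_equal(unname(m$transition["A", "A"]), 1)

  m0 <- train_markov(c("ACGT", "AATT"), order = 0, pseudocount = 0)
  expect_equal(unname(m0$initial),
               as.numeric(table(factor(strsplit("ACGTAATT", "")[[1]],
                                       levels = dna4))) / 8)

  expect_error(train_markov(character(0)), "empty corpus")
})

test_that("transitions of a uniform i.i.d. corpus are near 0.25", {
  corpus <- random_dna(100000, seed = 8)
  m <- train_markov(corpus, order = 1)
  expect_true(all(abs(m$transition - 0.25) < 0.01))
  expect_true(all(abs(rowSums(m$transition) - 1) < 1e-9))
})

test_that("window scores follow the log-likelihood-ratio definition", {
  # matrix equal to the background: every window scores 0
  ubg <- uniform_markov0()
  flat <- dna_pssm(matrix(1, 4, 4, dimnames = list(NULL, dna4)),
                   pseudocount = 0)
  withr::with_seed(3, {
    for (i in 1:10) {
      expect_equal(window_score(flat, random_dna(4), ubg), 0,
                   tolerance = 1e-12)
    }
  })

  # 2-bp hand case under a hand-set order-1 chain
  bg <- hand_markov()
  cnt <- matrix(c(8, 1, 1, 0,
                  1, 1, 1, 7), 2, 4, byrow = TRUE,
                dimnames = list(NULL, dna4))
  pm <- dna_pssm(cnt, pseudocount = 0)
  hand <- (log(8 / 10) - log(bg$initial[["A"]])) +
    (log(7 / 10) - log(bg$transition["A", "T"]))
  expect_equal(window_score(pm, "AT", bg), hand)
  # left context switches the first-base background to the transition
  hand_ctx <- (log(8 / 10) - log(bg$transition["C", "A"])) +
    (log(7 / 10) - log(bg$transition["A", "T"]))
  expect_equal(window_score(pm, "AT", bg, left_context = "C"), hand_ctx)

  expect_error(window_score(pm, "AU", bg), "illegal symbol")
  # N contributes zero
  expect_equal(window_score(pm, "AN", bg),
               log(8 / 10) - log(bg$initial[["A"]]))
})

test_that("exact p-value table matches closed forms and brute enumeration", {
  ubg <- uniform_markov0()
  # 1-column matrix scoring A = 1, others 0 (log-prob crafted directly)
  pm1 <- structure(list(
    accession = "a1",
    logp = matrix(log(0.25) + c(1, 0, 0, 0), 1, 4,
                  dimnames = list(NULL, dna4)),
    length = 1L), class = "dna_pssm")
  tab1 <- exact_pvalue_table(pm1, ubg)
  expect_equal(score_pvalue(tab1, 1), 0.25)
  expect_equal(score_pvalue(tab1, min(tab1$scores)), 1)

  # arbitrary 5-column matrix vs brute force under a hand-set order-1 chain
  bg <- hand_markov()
  toy <- toy_dna_pssm(length = 5, seed = 13)
  tab <- exact_pvalue_table(toy$pssm, bg)
  expect_true(all(diff(tab$tail) <= 1e-12))  # non-increasing in score
  words <- expand.grid(rep(list(dna4), 5), stringsAsFactors = FALSE)
  sc <- apply(words, 1, function(w)
    window_score(toy$pssm, paste(w, collapse = ""), bg))
  pr <- apply(words, 1, function(w) {
    p <- bg$initial[[w[1]]]
    for (i in 2:5) p <- p * bg$transition[w[i - 1], w[i]]
    p
  })
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  for (s in quantile(sc, c(0.05, 0.25, 0.5, 0.9, 0.99))) {
    dp <- score_pvalue(tab, s)
    # agreement within the accumulated discretisation (L bins on
    # continuous scores; per-position increments are bin-rounded)
    lo <- sum(pr[sc >= s + 5 * tab$bin_width])
    hi <- sum(pr[sc >= s - 5 * tab$bin_width])
    expect_gte(dp, lo - 1e-12)
    expect_lte(dp, hi + 1e-12)
  }

  expect_error(exact_pvalue_table(toy$pssm, bg, bin_width = 0),
               "bin_width")
})

test_that("upstream scanning is calibrated on background sequence", {
  # ~1 false positive expected per 10 kb at p <= 1e-4 (both strands)
  toy <- toy_dna_pssm(length = 16, dominant = 20, seed = 4)
  sim <- gen_promoters(pssm = NULL, n_regions = 1, region_length = 50000,
                       implant_at = NULL, seed = 3)
  tab <- exact_pvalue_table(toy$pssm, sim$background)
  hits <- scan_upstream(toy$pssm, sim$regions$residues[1], sim$background,
                        p_threshold = 1e-4, table = tab)
  n_windows <- 2 * (50000 - 16 + 1)
  expected <- 1e-4 * n_windows
  # 99% Poisson interval around the expected count
  expect_gte(nrow(hits), qpois(0.005, expected))
  expect_lte(nrow(hits), qpois(0.995, expected))
})

test_that("a planted strong motif is recovered at its position", {
  toy <- toy_dna_pssm(length = 16, dominant = 50, seed = 6)
  sim <- gen_promoters(pssm = toy$pssm, n_regions = 10,
                       region_length = 400, implant_at = -96, seed = 7)
  tab <- exact_pvalue_table(toy$pssm, sim$background)
  found <- vapply(1:10, function(i) {
    h <- scan_upstream(toy$pssm, sim$regions$residues[i], sim$background,
                       table = tab)
    any(h$rel_begin == -96 & h$strand == "+")
  }, logical(1))
  expect_gte(mean(found), 0.9)
  # the hit label follows the [-96, -81] convention
  h <- scan_upstream(toy$pssm, sim$regions$residues[1], sim$background,
                     table = tab)
  expect_true("[-96, -81]" %in% h$positions)
})

test_that("scanning respects strand symmetry and short-region edge cases", {
  toy <- toy_dna_pssm(length = 8, dominant = 30, seed = 9)
  bg <- uniform_markov0()
  tab <- exact_pvalue_table(toy$pssm, bg)
  region <- random_dna(300, seed = 10)
  fwd <- scan_upstream(toy$pssm, region, bg, p_threshold = 0.05,
                       table = tab)
  rev <- scan_upstream(toy$pssm, phorep:::reverse_complement(region), bg,
                       p_threshold = 0.05, table = tab)
  # scanning the reverse complement swaps strands, same score multiset
  expect_equal(sort(fwd$score[fwd$strand == "+"]),
               sort(rev$score[rev$strand == "-"]), tolerance = 1e-9)
  expect_equal(sort(fwd$score[fwd$strand == "-"]),
               sort(rev$score[rev$strand == "+"]), tolerance = 1e-9)

  expect_equal(nrow(scan_upstream(toy$pssm, "ACGT", bg, table = tab)), 0)
  expect_equal(nrow(scan_upstream(toy$pssm, "", bg, table = tab)), 0)
})

test_that("upstream regions are extracted strand-aware", {
  genes <- parse_gene_table(paste(
    "locus_tag\tstrand\tstart\tend",
    "A\tD\t1\t300", "B\tD\t401\t700", "C\tR\t1000\t801",
    sep = "\n"))
  genome <- random_dna(1100, seed = 12)
  up_b <- extract_upstream(genes, "B", genome)
  expect_equal(up_b$upstream_length, 100)
  expect_equal(up_b$residues, substr(genome, 301, 400))

  # reverse-strand target: region 3' of the numeric end, reverse-complemented
  # (gene C has no annotated neighbour on that side, so the region is
  # truncated at the contig edge, with a warning)
  expect_warning(up_c <- extract_upstream(genes, "C", genome),
                 "contig edge")
  expect_equal(up_c$upstream_length, 100)
  expect_equal(up_c$residues,
               phorep:::reverse_complement(substr(genome, 1001, 1100)))

  # adjacent genes leave an empty region
  tight <- parse_gene_table(paste(
    "locus_tag\tstrand\tstart\tend", "A\tD\t1\t300", "B\tD\t301\t600",
    sep = "\n"))
  expect_equal(extract_upstream(tight, "B", genome)$upstream_length, 0)

  expect_warning(extract_upstream(genes, "A", genome), "contig edge")
})

test_that("operon heuristic merges same-strand neighbours within the gap", {
  # three same-strand genes with gaps 74 and 50 form one unit
  genes <- parse_gene_table(paste(
    "locus_tag\tstrand\tstart\tend",
    "g1\tR\t700\t500", "g2\tR\t925\t775", "g3\tR\t1100\t976",
    sep = "\n"))
  tu <- predict_transcription_units(genes)
  expect_equal(length(unique(tu$tu_id)), 1)
  expect_equal(tu$n_genes, rep(3L, 3))
  # on the reverse strand the 5'-most gene is the numeric rightmost
  expect_equal(tu$first_gene[1], "g3")
  expect_equal(tu$locus_tag[tu$position_in_unit == 3], "g1")

  # strand switch splits
  mixed <- parse_gene_table(paste(
    "locus_tag\tstrand\tstart\tend", "g1\tD\t1\t300", "g2\tR\t500\t350",
    sep = "\n"))
  expect_equal(length(unique(predict_transcription_units(mixed)$tu_id)), 2)

  # boundary: gap == max_gap is merged (inclusive rule)
  edge <- parse_gene_table(paste(
    "locus_tag\tstrand\tstart\tend", "g1\tD\t1\t300", "g2\tD\t451\t600",
    sep = "\n"))
  expect_equal(length(unique(predict_transcription_units(edge)$tu_id)), 1)
  wide <- parse_gene_table(paste(
    "locus_tag\tstrand\tstart\tend", "g1\tD\t1\t300", "g2\tD\t452\t600",
    sep = "\n"))
  expect_equal(length(unique(predict_transcription_units(wide)$tu_id)), 2)
})
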