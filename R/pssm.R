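# Profile-based phosphatase family annotation.
#
# Families are described by sets of PSSMs hit on a reference sequence; a
# protein is annotated into a family when every PSSM of the family set hits
# it at E <= 1e-10, then validated by local alignment against the family
# reference at E <= 1e-3.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not perturb the
#' caller's RNG stream.
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Convert a count matrix to a log-odds protein PSSM
#'
#' Weights are `log2((count + pseudocount * bg_a) / (total + pseudocount)) -
#' log2(bg_a)`, expressed in half-bit units (i.e. multiplied by 2), the
#' customary scale of protein scoring matrices.
#'
#' @param counts A `matrix_file` object or a plain positions-by-symbols count
#'   matrix with column names.
#' @param background Named background frequencies summing to 1; defaults to
#'   Robinson-Robinson amino-acid frequencies.
#' @param pseudocount Non-negative pseudocount mass, spread in proportion to
#'   the background.
#' @param accession Identifier for the resulting PSSM.
#' @return An object of class `protein_pssm`: list with `accession`,
#'   `alphabet`, `weights` (positions x symbols, half-bits), `length`,
#'   `source_counts`.
#' @export
counts_to_logodds <- function(counts, background = AA_BACKGROUND,
                              pseudocount = 1, accession = NULL) {
  if (inherits(counts, "matrix_file")) {
    accession <- accession %||% counts$accession
    counts <- counts$counts
  }
  accession <- accession %||% "pssm"
  if (is.null(colnames(counts))) {
    abort("count matrix must have symbol column names")
  }
  if (any(background <= 0)) abort("background frequencies must be > 0")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  bg <- background[colnames(counts)]
  if (anyNA(bg)) abort("background frequencies missing for some symbols")
  totals <- rowSums(counts)
  p <- (counts + pseudocount * matrix(bg, nrow(counts), ncol(counts),
                                      byrow = TRUE)) /
    (totals + pseudocount)
  w <- 2 * (log2(p) - matrix(log2(bg), nrow(counts), ncol(counts),
                             byrow = TRUE))
  structure(
    list(accession = accession, alphabet = colnames(counts), weights = w,
         length = nrow(counts), source_counts = counts,
         background = bg),
    class = "protein_pssm"
  )
}

#' @export
print.protein_pssm <- function(x, ...) {
  cat(sprintf("<protein_pssm> %s: %d positions (half-bit log-odds)\n",
              x$accession, x$length))
  invisible(x)
}

# Maximal-scoring contiguous segment (Kadane via cumulative sums).
# Returns c(start, end, score); segments have length >= 1.
max_segment <- function(v) {
  cs <- cumsum(v)
  prefix <- c(0, cs)                    # prefix[i] = sum of the first i-1 terms
  pm <- cummin(prefix)
  gain <- cs - pm[seq_along(cs)]
  j <- which.max(gain)
  i <- which(prefix[seq_len(j)] == pm[j])[1]
  c(start = i, end = j, score = gain[j])
}

#' Best ungapped profile-sequence hits
#'
#' Slides a protein PSSM along a query: for each diagonal offset the
#' maximal-scoring contiguous segment of per-position weights is found
#' (Kadane's algorithm), mirroring ungapped profile search.  E-values follow
#' the Karlin-Altschul form `E = K * m * n * exp(-lambda * score)` with
#' `m` the profile length and `n` the query length.  Unknown residues (`X`)
#' score 0.
#'
#' @param pssm A `protein_pssm`.
#' @param query A single-row sequence tibble (see [parse_sequences()]) or a
#'   protein string.
#' @param calibration A `scan_calibration` from [calibrate_pssm()].
#' @param max_hits Maximum number of non-overlapping hits returned.
#' @param query_id Identifier used when `query` is a bare string.
#' @return Tibble of hits sorted by ascending E-value, with columns
#'   `query_id`, `pssm_accession`, `q_begin`, `q_end`, `p_begin`, `p_end`,
#'   `score`, `evalue`.
#' @export
best_ungapped_hits <- function(pssm, query, calibration, max_hits = 5,
                               query_id = "query") {
  if (is.data.frame(query)) {
    query_id <- query$id[1]
    query <- query$residues[1]
  }
  n <- nchar(query)
  if (n < 1) abort("query must have length >= 1")
  m <- pssm$length
  W <- cbind(pssm$weights, X = 0)
  qidx <- match(strsplit(query, "")[[1]], c(pssm$alphabet, "X"))
  if (anyNA(qidx)) abort("query contains residues outside the PSSM alphabet")
  # S[i, j] = weight of aligning profile position i to query position j
  S <- matrix(W[, qidx], nrow = m, ncol = n, byrow = FALSE)
  # Diagonals: constant j - i; split() respects column-major order, so each
  # diagonal comes out ordered by increasing profile position.
  d <- col(S) - row(S)
  diags <- split(S, d)
  offs <- as.integer(names(diags))
  segs <- vapply(diags, max_segment, numeric(3))
  # map segment indices back to profile/query coordinates
  i0 <- pmax(1L, 1L - offs)           # first profile position on the diagonal
  p_begin <- i0 + as.integer(segs["start", ]) - 1L
  p_end <- i0 + as.integer(segs["end", ]) - 1L
  hits <- tibble(
    query_id = query_id,
    pssm_accession = pssm$accession,
    q_begin = p_begin + offs,
    q_end = p_end + offs,
    p_begin = p_begin,
    p_end = p_end,
    score = unname(segs["score", ])
  )
  hits$evalue <- calibration$K * m * n * exp(-calibration$lambda * hits$score)
  hits <- hits[order(hits$evalue, hits$q_begin), ]
  # greedy non-overlap selection on the query
  keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(keep) >= max_hits) break
    ov <- any(hits$q_begin[i] <= hits$q_end[keep] &
                hits$q_end[i] >= hits$q_begin[keep])
    if (!ov) keep <- c(keep, i)
  }
  hits[keep, ]
}

# Fit a Gumbel (type-I extreme value) law by maximum likelihood.
fit_gumbel <- function(x) {
  if (sd(x) < .Machine$double.eps^0.5) {
    abort("degenerate score distribution: all calibration scores are equal")
  }
  xbar <- mean(x)
  f <- function(beta) {
    w <- exp(-(x - max(x)) / beta)
    beta - xbar + sum(x * w) / sum(w)
  }
  s <- sd(x)
  beta <- uniroot(f, c(s / 20, s * 20), extendInt = "yes")$root
  mu <- -beta * (log(mean(exp(-(x - max(x)) / beta))) - max(x) / beta)
  list(mu = mu, beta = beta)
}

#' Calibrate Karlin-Altschul parameters for a PSSM
#'
#' Scans `n_samples` i.i.d. background sequences, records the best segment
#' score of each, and fits a Gumbel law by maximum likelihood.  The fitted
#' location/scale translate into `lambda = 1/beta` and
#' `K = exp(mu/beta) / (m * n)`.
#'
#' @param pssm A `protein_pssm`.
#' @param background Named residue frequencies for the random sequences.
#' @param n_samples Number of random sequences (>= 500 recommended for
#'   stable fits; smaller values are accepted for quick checks).
#' @param sample_length Length of each random sequence.
#' @param seed Integer seed; calibration is deterministic given the seed.
#' @return An object of class `scan_calibration`: list with `lambda`, `K`,
#'   `method`, `n_samples`, `seed`.
#' @export
calibrate_pssm <- function(pssm, background = AA_BACKGROUND, n_samples = 500,
                           sample_length = 200, seed = 1) {
  m <- pssm$length
  null_cal <- structure(list(lambda = 1, K = 1, method = "none"),
                        class = "scan_calibration")
  scores <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      s <- paste(sample(names(background), sample_length, replace = TRUE,
                        prob = background), collapse = "")
      max(best_ungapped_hits(pssm, s, null_cal, max_hits = 1)$score)
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  structure(
    list(lambda = 1 / fit$beta,
         K = exp(fit$mu / fit$beta) / (m * sample_length),
         method = "empirical", n_samples = n_samples, seed = seed),
    class = "scan_calibration"
  )
}

#' @export
print.scan_calibration <- function(x, ...) {
  cat(sprintf("<scan_calibration> lambda = %.4f, K = %.4g (%s, n = %s)\n",
              x$lambda, x$K, x$method, x$n_samples %||% NA))
  invisible(x)
}

#' Remove redundant profiles by the 70% mutual-coverage rule
#'
#' Among hits on a family reference sequence, profiles whose hit intervals
#' overlap with mutual coverage exceeding 70% of the longer hit are redundant:
#' only the one with the lowest E-value is retained.  Selection is greedy by
#' ascending E-value (ties broken by accession).
#'
#' @param hits Tibble of hits on one reference sequence (columns
#'   `pssm_accession`, `q_begin`, `q_end`, `evalue`).
#' @param max_coverage Coverage threshold (default 0.70).
#' @return Character vector of retained accessions, in retention order.
#' @export
deduplicate_profiles <- function(hits, max_coverage = 0.70) {
  if (nrow(hits) == 0) return(character(0))
  hits <- hits[order(hits$evalue, hits$pssm_accession), ]
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    redundant <- FALSE
    for (k in kept) {
      ov <- min(hits$q_end[i], hits$q_end[k]) -
        max(hits$q_begin[i], hits$q_begin[k]) + 1
      if (ov <= 0) next
      longer <- max(hits$q_end[i] - hits$q_begin[i] + 1,
                    hits$q_end[k] - hits$q_begin[k] + 1)
      if (ov / longer > max_coverage) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  hits$pssm_accession[kept]
}

#' Build a phosphatase family reference set
#'
#' Scans each candidate PSSM against the family reference sequence, keeps
#' significant hits (default E <= 1e-10), and removes profile redundancy by
#' the 70% mutual-coverage rule.
#'
#' @param family Family name (e.g. `"PhoD"`).
#' @param reference Single-row sequence tibble: the family reference protein.
#' @param pssms List of `protein_pssm` objects.
#' @param calibrations Named list of `scan_calibration`, keyed by PSSM
#'   accession.
#' @param e_significant Significance threshold for reference hits.
#' @return An object of class `family_set`: list with `family`, `reference`,
#'   `pssms` (retained), `reference_hits`.
#' @export
build_family_set <- function(family, reference, pssms, calibrations,
                             e_significant = 1e-10) {
  hits <- purrr::map_dfr(pssms, function(p) {
    h <- best_ungapped_hits(p, reference, calibrations[[p$accession]],
                            max_hits = 1)
    head(h, 1)
  })
  hits <- hits[hits$evalue <= e_significant, ]
  kept <- deduplicate_profiles(hits)
  structure(
    list(family = family, reference = reference,
         pssms = pssms[match(kept, vapply(pssms, `[[`, "", "accession"))],
         reference_hits = hits[match(kept, hits$pssm_accession), ]),
    class = "family_set"
  )
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("<family_set> %s: %d PSSM(s) [%s], reference %s\n",
              x$family, length(x$pssms),
              paste(vapply(x$pssms, `[[`, "", "accession"), collapse = ", "),
              x$reference$id[1]))
  invisible(x)
}

#' Family membership by the all-profiles rule
#'
#' A protein belongs to a family when, for every PSSM of the family set,
#' at least one hit reaches the membership E-value threshold.
#'
#' @param protein_hits Tibble of hits of one protein against the family's
#'   PSSMs (columns `pssm_accession`, `evalue`).
#' @param family_set A `family_set`.
#' @param e_threshold Membership threshold (default 1e-10).
#' @return Logical scalar.
#' @export
assign_family <- function(protein_hits, family_set, e_threshold = 1e-10) {
  accs <- vapply(family_set$pssms, `[[`, "", "accession")
  all(vapply(accs, function(a) {
    any(protein_hits$evalue[protein_hits$pssm_accession == a] <= e_threshold)
  }, logical(1)))
}

#' Validate a candidate by local alignment against the family reference
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gap open 11 / extend 1)
#' with a Karlin-Altschul E-value using the standard gapped BLOSUM62
#' parameters; the candidate is validated when E <= `e_threshold` (default
#' 1e-3, a deliberately low-stringency filter against remote superfamily
#' homology only).
#'
#' @param protein,reference Single-row sequence tibbles or protein strings.
#' @param e_threshold Validation E-value threshold.
#' @param lambda,K Karlin-Altschul parameters for the score-to-E conversion.
#' @return Logical scalar; the E-value is attached as attribute `"evalue"`.
#' @export
validate_member <- function(protein, reference, e_threshold = 1e-3,
                            lambda = BLAST_GAPPED_LAMBDA,
                            K = BLAST_GAPPED_K) {
  p <- if (is.data.frame(protein)) protein$residues[1] else protein
  r <- if (is.data.frame(reference)) reference$residues[1] else reference
  score <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(r),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
  )
  evalue <- K * nchar(p) * nchar(r) * exp(-lambda * score)
  structure(evalue <= e_threshold, evalue = evalue, score = score)
}

#' Annotate a proteome into phosphatase families
#'
#' Applies the all-profiles membership rule (E <= `e_member` for every PSSM
#' of a family set) followed by local-alignment validation against the family
#' reference (E <= `e_validate`) to every protein.
#'
#' @param proteome Sequence tibble of proteins.
#' @param family_sets Named list of `family_set` objects.
#' @param calibrations Named list of `scan_calibration` keyed by PSSM
#'   accession.
#' @param e_member Membership threshold (default 1e-10).
#' @param e_validate Validation threshold (default 1e-3).
#' @param validate Run the validation step (default TRUE).
#' @return Tibble with one row per annotated (protein, family) pair:
#'   `protein_id`, `family`, `worst_evalue` (the largest per-PSSM best
#'   E-value), `validated`.
#' @export
annotate_proteome <- function(proteome, family_sets, calibrations,
                              e_member = 1e-10, e_validate = 1e-3,
                              validate = TRUE) {
  out <- list()
  for (i in seq_len(nrow(proteome))) {
    prot <- proteome[i, ]
    for (fs in family_sets) {
      hits <- purrr::map_dfr(fs$pssms, function(p) {
        best_ungapped_hits(p, prot, calibrations[[p$accession]], max_hits = 3)
      })
      if (nrow(hits) == 0) next
      if (assign_family(hits, fs, e_member)) {
        ok <- if (validate) {
          isTRUE(validate_member(prot, fs$reference, e_validate)[1])
        } else TRUE
        worst <- max(vapply(fs$pssms, function(p) {
          min(hits$evalue[hits$pssm_accession == p$accession])
        }, numeric(1)))
        if (ok) {
          out[[length(out) + 1]] <- tibble(
            protein_id = prot$id, family = fs$family,
            worst_evalue = worst, validated = ok
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(protein_id = character(), family = character(),
                  worst_evalue = numeric(), validated = logical()))
  }
  dplyr::bind_rows(out)
}

#' Six-frame profile scan of intergenic regions
#'
#' Translates every intergenic span (>= `min_span` bp) of a genome in all six
#' reading frames and scans the translations with each family's PSSMs,
#' reporting hits with their frame and genomic interval.  This searches for
#' phosphatase genes or pseudogenes missed by the structural annotation.
#'
#' @param genome Single-row DNA sequence tibble or DNA string.
#' @param genes Gene tibble from [parse_gene_table()], any order.
#' @param family_sets Named list of `family_set` objects.
#' @param calibrations Named list of calibrations keyed by accession.
#' @param min_span Minimum intergenic span scanned (bp).
#' @param e_threshold Report threshold.
#' @return Tibble with `family`, `pssm_accession`, `frame` (+1..+3, -1..-3),
#'   `genomic_begin`, `genomic_end`, `score`, `evalue`.
#' @export
scan_noncoding_sixframe <- function(genome, genes, family_sets, calibrations,
                                    min_span = 60, e_threshold = 1e-10) {
  g <- if (is.data.frame(genome)) genome$residues[1] else genome
  glen <- nchar(g)
  spans <- intergenic_spans(genes, glen)
  spans <- spans[spans$end - spans$start + 1 >= min_span, , drop = FALSE]
  out <- list()
  for (si in seq_len(nrow(spans))) {
    a <- spans$start[si]; b <- spans$end[si]
    dna_fwd <- substr(g, a, b)
    dna_rev <- reverse_complement(dna_fwd)
    for (fr in 1:3) {
      for (strand in c(1, -1)) {
        dna <- if (strand == 1) dna_fwd else dna_rev
        sub <- substr(dna, fr, nchar(dna))
        sub <- substr(sub, 1, 3 * (nchar(sub) %/% 3))
        if (nchar(sub) < 3) next
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAString(sub), if.fuzzy.codon = "X"
        ))
        aa <- chartr("*", "X", aa)
        for (fs in family_sets) {
          for (p in fs$pssms) {
            h <- best_ungapped_hits(p, aa, calibrations[[p$accession]],
                                    max_hits = 3,
                                    query_id = sprintf("span_%d", si))
            h <- h[h$evalue <= e_threshold, ]
            if (nrow(h) == 0) next
            if (strand == 1) {
              gb <- a + (fr - 1) + 3 * (h$q_begin - 1)
              ge <- a + (fr - 1) + 3 * h$q_end - 1
            } else {
              ge <- b - (fr - 1) - 3 * (h$q_begin - 1)
              gb <- b - (fr - 1) - 3 * h$q_end + 1
            }
            out[[length(out) + 1]] <- tibble(
              family = fs$family, pssm_accession = p$accession,
              frame = strand * fr, genomic_begin = gb, genomic_end = ge,
              score = h$score, evalue = h$evalue
            )
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(family = character(), pssm_accession = character(),
                  frame = integer(), genomic_begin = integer(),
                  genomic_end = integer(), score = numeric(),
                  evalue = numeric()))
  }
  dplyr::bind_rows(out)
}

# Intergenic spans (1-based inclusive) of a genome given gene models.
intergenic_spans <- function(genes, genome_length) {
  if (nrow(genes) == 0) {
    return(tibble(start = 1L, end = as.integer(genome_length)))
  }
  iv <- genes[order(genes$left), c("left", "right")]
  # merge overlapping gene intervals
  merged <- list(c(iv$left[1], iv$right[1]))
  for (i in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv$left[i] <= last[2] + 1) {
      merged[[length(merged)]][2] <- max(last[2], iv$right[i])
    } else {
      merged[[length(merged) + 1]] <- c(iv$left[i], iv$right[i])
    }
  }
  m <- do.call(rbind, merged)
  starts <- c(1L, m[, 2] + 1L)
  ends <- c(m[, 1] - 1L, as.integer(genome_length))
  ok <- starts <= ends
  tibble(start = as.integer(starts[ok]), end = as.integer(ends[ok]))
}

#' Import RPS-Blast tabular output as profile hits
#'
#' Adapter for externally computed profile searches (outfmt 6 columns
#' `qseqid sseqid pident length qstart qend sstart send evalue bitscore`),
#' so real CDD runs can feed the same family-membership logic.
#'
#' @param text Tabular text or file path.
#' @return Hit tibble compatible with [assign_family()].
#' @export
read_rpsblast_tabular <- function(text) {
  cols <- c("query_id", "pssm_accession", "pident", "length", "q_begin",
            "q_end", "p_begin", "p_end", "evalue", "bitscore")
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    raw <- readr::read_tsv(text, col_names = cols, show_col_types = FALSE)
  } else {
    raw <- readr::read_tsv(I(paste(text, collapse = "\n")), col_names = cols,
                           show_col_types = FALSE)
  }
  raw$score <- raw$bitscore
  raw[, c("query_id", "pssm_accession", "q_begin", "q_end", "p_begin",
          "p_end", "score", "evalue")]
}
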