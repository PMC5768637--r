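# Cis-regulatory element detection: PSSM scanning of upstream noncoding
# regions with exact p-values under an order-0/1 Markov background trained
# on the organism's own upstream sequences.

#' Train a Markov background model on a sequence corpus
#'
#' Counts (order+1)-mers within each sequence (never across sequence
#' boundaries), adds a Laplace pseudocount, and normalises.  The initial
#' distribution is the marginal base composition of the corpus.
#'
#' @param sequences Character vector of DNA sequences, or a sequence tibble.
#' @param order Markov order, 0 or 1.
#' @param pseudocount Laplace pseudocount added to every count cell.
#' @return An object of class `markov_background`: list with `order`,
#'   `initial` (named probabilities), `transition` (4x4 row-stochastic matrix,
#'   `NULL` for order 0), `trained_on`.
#' @export
train_markov <- function(sequences, order = 1, pseudocount = 1) {
  if (is.data.frame(sequences)) sequences <- sequences$residues
  sequences <- toupper(sequences)
  if (length(sequences) == 0 || sum(nchar(sequences)) == 0) {
    abort("empty corpus: cannot train a background model")
  }
  if (!order %in% c(0, 1)) abort("order must be 0 or 1")
  chars <- lapply(strsplit(sequences, ""), function(x) x[x %in% DNA_ALPHABET])
  base_counts <- table(factor(unlist(chars), levels = DNA_ALPHABET))
  initial <- (as.numeric(base_counts) + pseudocount) /
    (sum(base_counts) + 4 * pseudocount)
  names(initial) <- DNA_ALPHABET
  transition <- NULL
  if (order == 1) {
    tc <- matrix(0, 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
    for (cv in chars) {
      if (length(cv) < 2) next
      a <- factor(cv[-length(cv)], levels = DNA_ALPHABET)
      b <- factor(cv[-1], levels = DNA_ALPHABET)
      tc <- tc + table(a, b)
    }
    tc <- tc + pseudocount
    transition <- tc / rowSums(tc)
  }
  structure(
    list(order = order, initial = initial, transition = transition,
         trained_on = sprintf("%d sequence(s), %d nt", length(sequences),
                              sum(nchar(sequences)))),
    class = "markov_background"
  )
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("<markov_background> order %d, trained on %s\n",
              x$order, x$trained_on))
  invisible(x)
}

#' Build a DNA PSSM from a count matrix
#'
#' Stores per-position log probabilities `log P(base | position)` with a
#' background-weighted pseudocount; the background term of the scan score is
#' applied at scan time because it depends on the preceding base.
#'
#' @param counts A `matrix_file` or a positions-by-ACGT count matrix.
#' @param pseudocount Pseudocount mass spread by `bg0`.
#' @param bg0 Base frequencies used to spread the pseudocount (default
#'   uniform).
#' @param accession Motif / transcription-factor name.
#' @return Object of class `dna_pssm`: list with `accession`, `logp`
#'   (positions x 4), `length`.
#' @export
dna_pssm <- function(counts, pseudocount = 1, bg0 = rep(0.25, 4),
                     accession = NULL) {
  if (inherits(counts, "matrix_file")) {
    accession <- accession %||% counts$accession
    counts <- counts$counts
  }
  accession <- accession %||% "motif"
  counts <- counts[, DNA_ALPHABET, drop = FALSE]
  p <- (counts + pseudocount * matrix(bg0, nrow(counts), 4, byrow = TRUE)) /
    (rowSums(counts) + pseudocount)
  structure(list(accession = accession, logp = log(p), length = nrow(counts)),
            class = "dna_pssm")
}

#' @export
print.dna_pssm <- function(x, ...) {
  cat(sprintf("<dna_pssm> %s: %d bp\n", x$accession, x$length))
  invisible(x)
}

#' Score one window against a DNA PSSM under a Markov background
#'
#' `score = sum_i [log P_matrix(w_i | i) - log P_bg(w_i | w_(i-1))]`; the
#' background initial distribution is used for the first base when no left
#' context is supplied.  `N` bases contribute 0 to the score.
#'
#' @param pssm A `dna_pssm`.
#' @param window DNA string of length equal to the PSSM.
#' @param background A `markov_background`.
#' @param left_context Single base 5' of the window, or `NULL`.
#' @return Numeric log-likelihood-ratio score (natural log units).
#' @export
window_score <- function(pssm, window, background, left_context = NULL) {
  w <- strsplit(toupper(window), "")[[1]]
  if (length(w) != pssm$length) abort("window length must equal PSSM length")
  bad <- setdiff(w, c(DNA_ALPHABET, "N"))
  if (length(bad) > 0) abort(sprintf("illegal symbol '%s' in window", bad[1]))
  score <- 0
  prev <- if (!is.null(left_context) && left_context %in% DNA_ALPHABET)
    left_context else NULL
  for (i in seq_along(w)) {
    b <- w[i]
    if (b != "N") {
      lp_bg <- if (background$order == 1 && !is.null(prev)) {
        log(background$transition[prev, b])
      } else {
        log(background$initial[[b]])
      }
      score <- score + pssm$logp[i, b] - lp_bg
    }
    prev <- if (b %in% DNA_ALPHABET) b else NULL
  }
  unname(score)
}

#' Exact score p-value table by dynamic programming
#'
#' Computes the full distribution of [window_score()] for random windows
#' drawn from the background model (first base from the initial distribution,
#' subsequent bases from the order-1 transitions), by dynamic programming over
#' (position, previous base, discretised score).  Returns the right-tail
#' function P(S >= s).
#'
#' @param pssm A `dna_pssm`.
#' @param background A `markov_background` of order <= 1.
#' @param bin_width Score discretisation bin (default 0.01).
#' @return Object of class `pvalue_table`: list with `scores` (bin lower
#'   edges), `tail` (P(S >= score)), `bin_width`.
#' @export
exact_pvalue_table <- function(pssm, background, bin_width = 0.01) {
  if (bin_width <= 0) abort("bin_width must be > 0")
  L <- pssm$length
  # integer score increments for every (position, prev base, base)
  inc0 <- round((pssm$logp[1, ] - log(background$initial)) / bin_width)
  use_trans <- background$order == 1
  incs <- array(0L, c(L, 4, 4))  # position, prev, base (positions >= 2)
  if (L >= 2) {
    for (i in 2:L) {
      for (p in 1:4) {
        lp_bg <- if (use_trans) log(background$transition[p, ]) else
          log(background$initial)
        incs[i, p, ] <- round((pssm$logp[i, ] - lp_bg) / bin_width)
      }
    }
  }
  # bounds on the accumulated integer score
  per_min <- c(min(inc0), if (L >= 2) vapply(2:L, function(i) min(incs[i, , ]), numeric(1)))
  per_max <- c(max(inc0), if (L >= 2) vapply(2:L, function(i) max(incs[i, , ]), numeric(1)))
  lo <- sum(per_min); hi <- sum(per_max)
  nb <- hi - lo + 1
  off <- 1 - lo  # integer score k maps to index k + off
  # mass[prev, k]
  mass <- matrix(0, 4, nb, dimnames = list(DNA_ALPHABET, NULL))
  for (b in 1:4) {
    k <- inc0[b]
    mass[b, k + off] <- mass[b, k + off] + background$initial[b]
  }
  if (L >= 2) {
    for (i in 2:L) {
      new <- matrix(0, 4, nb, dimnames = list(DNA_ALPHABET, NULL))
      for (p in 1:4) {
        row <- mass[p, ]
        if (all(row == 0)) next
        pb <- if (use_trans) background$transition[p, ] else background$initial
        nz <- which(row > 0)
        for (b in 1:4) {
          sh <- incs[i, p, b]
          idx <- nz + sh
          new[b, idx] <- new[b, idx] + row[nz] * pb[b]
        }
      }
      mass <- new
    }
  }
  dist <- colSums(mass)
  total <- sum(dist)
  if (abs(total - 1) > 1e-9) {
    warn(sprintf("p-value table mass deviates from 1 by %.2e", total - 1))
  }
  tail <- rev(cumsum(rev(dist)))
  scores <- (seq_len(nb) + lo - 1) * bin_width
  structure(list(scores = scores, tail = tail, bin_width = bin_width),
            class = "pvalue_table")
}

#' Look up the right-tail p-value of a score
#'
#' Conservative: the score is mapped to the lower edge of its bin.
#'
#' @param table A `pvalue_table`.
#' @param score Numeric score(s).
#' @return P(S >= score) under the background.
#' @export
score_pvalue <- function(table, score) {
  pos <- findInterval(score + table$bin_width / 2, table$scores)
  p <- rep(1, length(score))
  ok <- pos >= 1
  p[ok] <- table$tail[pos[ok]]
  p
}

#' Scan an upstream region for motif occurrences
#'
#' Scans both strands (by default) of an upstream region with a DNA PSSM and
#' reports windows whose exact background p-value is at or below the
#' threshold.  Coordinates are reported relative to the gene start: position
#' -1 is the base immediately 5' of the start codon, so a hit occupying the
#' last 16 bases of a 100-nt region is reported as `[-16, -1]`.
#'
#' @param pssm A `dna_pssm`.
#' @param region Upstream DNA string (5' to 3', ending just before the gene
#'   start) or a single-row sequence tibble.
#' @param background A `markov_background`.
#' @param p_threshold Raw per-window p-value threshold (default 1e-4, about
#'   one false positive expected per 10 kb scanned).
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @param table Optional precomputed [exact_pvalue_table()].
#' @return Tibble of hits: `tf_name`, `rel_begin`, `rel_end`, `positions`
#'   (formatted `"[-96, -81]"`), `strand`, `score`, `pvalue`.
#' @export
scan_upstream <- function(pssm, region, background, p_threshold = 1e-4,
                          both_strands = TRUE, table = NULL) {
  r <- if (is.data.frame(region)) region$residues[1] else region
  L <- pssm$length
  U <- nchar(r)
  empty <- tibble(tf_name = character(), rel_begin = integer(),
                  rel_end = integer(), positions = character(),
                  strand = character(), score = numeric(),
                  pvalue = numeric())
  if (U < L) return(empty)
  if (is.null(table)) table <- exact_pvalue_table(pssm, background)
  # vectorised equivalent of window_score() over all windows: matrix term by
  # L shifted adds, background term by a cumulative sum of per-position
  # background log probabilities (initial distribution at the sequence start
  # or after an N, transition given the preceding base elsewhere)
  scan_one <- function(seqstr) {
    chars <- strsplit(toupper(seqstr), "")[[1]]
    n <- length(chars)
    idx <- match(chars, DNA_ALPHABET)      # NA for N
    nw <- n - L + 1
    bgv <- numeric(n)
    if (!is.na(idx[1])) bgv[1] <- log(background$initial[idx[1]])
    if (n >= 2) {
      prev <- idx[-n]; cur <- idx[-1]
      v <- numeric(n - 1)
      both <- !is.na(prev) & !is.na(cur)
      if (background$order == 1) {
        v[both] <- log(background$transition[cbind(prev[both], cur[both])])
      } else {
        v[both] <- log(background$initial[cur[both]])
      }
      onlycur <- is.na(prev) & !is.na(cur)
      v[onlycur] <- log(background$initial[cur[onlycur]])
      bgv[-1] <- v
    }
    matv <- numeric(nw)
    for (j in seq_len(L)) {
      cj <- idx[j:(j + nw - 1)]
      contrib <- pssm$logp[j, ][cj]
      contrib[is.na(cj)] <- 0
      matv <- matv + contrib
    }
    cs <- cumsum(c(0, bgv))
    matv - (cs[seq_len(nw) + L] - cs[seq_len(nw)])
  }
  res <- list()
  fwd <- scan_one(r)
  pf <- score_pvalue(table, fwd)
  hit <- which(pf <= p_threshold)
  if (length(hit) > 0) {
    res[[1]] <- tibble(tf_name = pssm$accession,
                       rel_begin = hit - U - 1L,
                       rel_end = hit + L - 1L - U - 1L,
                       strand = "+", score = fwd[hit], pvalue = pf[hit])
  }
  if (both_strands) {
    rc <- reverse_complement(r)
    rev_scores <- scan_one(rc)
    pr <- score_pvalue(table, rev_scores)
    hit <- which(pr <= p_threshold)
    if (length(hit) > 0) {
      # position i on the reverse complement covers forward positions
      # (U - i - L + 2) .. (U - i + 1)
      fb <- U - hit - L + 2L
      res[[length(res) + 1]] <- tibble(tf_name = pssm$accession,
                                       rel_begin = fb - U - 1L,
                                       rel_end = fb + L - 1L - U - 1L,
                                       strand = "-",
                                       score = rev_scores[hit],
                                       pvalue = pr[hit])
    }
  }
  if (length(res) == 0) return(empty)
  out <- dplyr::bind_rows(res)
  out$positions <- sprintf("[%d, %d]", out$rel_begin, out$rel_end)
  out[order(out$pvalue), c("tf_name", "rel_begin", "rel_end", "positions",
                           "strand", "score", "pvalue")]
}

#' Extract the noncoding region upstream of a gene or transcription unit
#'
#' Returns the noncoding span between the target's 5' end and the nearest
#' annotated feature boundary, strand-aware: for a reverse-strand gene the
#' region lies 3' of the numeric `right` coordinate and is
#' reverse-complemented so that it reads 5' to 3' toward the start codon.
#'
#' @param genes Gene tibble (see [parse_gene_table()]).
#' @param target `locus_tag` of the target gene (for an operon, pass the
#'   first gene of the unit).
#' @param genome Genome DNA string or single-row sequence tibble.
#' @return Tibble with one row: `locus_tag`, `strand`, `upstream_length`,
#'   `residues` (the region, oriented toward the start codon), `truncated`.
#' @export
extract_upstream <- function(genes, target, genome) {
  g <- if (is.data.frame(genome)) genome$residues[1] else genome
  glen <- nchar(g)
  i <- match(target, genes$locus_tag)
  if (is.na(i)) abort(sprintf("target '%s' not found in gene table", target))
  strand <- genes$strand[i]
  others <- genes[-i, , drop = FALSE]
  truncated <- FALSE
  if (strand == "D") {
    five <- genes$left[i]
    bound <- suppressWarnings(max(others$right[others$right < five]))
    if (!is.finite(bound)) {
      bound <- 0L
      truncated <- TRUE
      warn(sprintf("'%s' has no upstream neighbour; region truncated at the contig edge", target))
    }
    a <- bound + 1L; b <- five - 1L
    region <- if (a <= b) substr(g, a, b) else ""
  } else {
    five <- genes$right[i]
    bound <- suppressWarnings(min(others$left[others$left > five]))
    if (!is.finite(bound)) {
      bound <- glen + 1L
      truncated <- TRUE
      warn(sprintf("'%s' has no upstream neighbour; region truncated at the contig edge", target))
    }
    a <- five + 1L; b <- bound - 1L
    region <- if (a <= b) reverse_complement(substr(g, a, b)) else ""
  }
  tibble(locus_tag = target, strand = strand,
         upstream_length = nchar(region), residues = region,
         truncated = truncated)
}

#' Predict transcription units by a distance/strand heuristic
#'
#' Consecutive same-strand genes whose intergenic gap is at most `max_gap`
#' bp (inclusive) are merged into one unit; all other genes are singleton
#' units.  This simple heuristic stands in for database-backed operon
#' predictions; only the choice of upstream region depends on it.
#'
#' @param genes Gene tibble, any order.
#' @param max_gap Maximum intergenic gap within a unit (bp, default 150).
#' @return Tibble with `tu_id`, `locus_tag`, `strand`, `position_in_unit`
#'   (1 = 5'-most gene), `n_genes`, `first_gene`.
#' @export
predict_transcription_units <- function(genes, max_gap = 150) {
  if (nrow(genes) == 0) {
    return(tibble(tu_id = integer(), locus_tag = character(),
                  strand = character(), position_in_unit = integer(),
                  n_genes = integer(), first_gene = character()))
  }
  o <- order(genes$left)
  gs <- genes[o, ]
  tu <- integer(nrow(gs))
  tu[1] <- 1L
  for (i in seq_len(nrow(gs))[-1]) {
    gap <- gs$left[i] - gs$right[i - 1] - 1L
    same <- gs$strand[i] == gs$strand[i - 1] && gap <= max_gap
    tu[i] <- if (same) tu[i - 1] else tu[i - 1] + 1L
  }
  out <- tibble(tu_id = tu, locus_tag = gs$locus_tag, strand = gs$strand,
                left = gs$left)
  out <- dplyr::group_by(out, .data$tu_id)
  out <- dplyr::mutate(
    out,
    n_genes = dplyr::n(),
    # 5'-most gene: leftmost on D, rightmost (numeric) on R
    position_in_unit = if (.data$strand[1] == "D")
      rank(.data$left) else rank(-.data$left),
    first_gene = .data$locus_tag[.data$position_in_unit == 1][1]
  )
  out <- dplyr::ungroup(out)
  out$position_in_unit <- as.integer(out$position_in_unit)
  out[, c("tu_id", "locus_tag", "strand", "position_in_unit", "n_genes",
          "first_gene")]
}
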