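# Sequence-derived physicochemical features of precursor and mature
# phosphatases: molecular weight, theoretical pI, signal-peptide handling,
# Tat export motif detection.

#' Molecular weight of a protein
#'
#' Sum of average (isotope-weighted) residue masses plus one water, the
#' convention of standard proteomics calculators.
#'
#' @param sequence Protein string or single-row sequence tibble.
#' @return Mass in Da.
#' @examples
#' molecular_weight("G") # 75.07
#' @export
molecular_weight <- function(sequence) {
  s <- if (is.data.frame(sequence)) sequence$residues[1] else sequence
  chars <- strsplit(s, "")[[1]]
  if (any(chars == "X")) {
    abort("sequence contains 'X': molecular weight is undefined")
  }
  masses <- AA_AVERAGE_MASS[chars]
  if (anyNA(masses)) {
    abort(sprintf("unknown residue '%s'", chars[which(is.na(masses))[1]]))
  }
  sum(masses) + WATER_MASS
}

# Net protein charge at a given pH (Henderson-Hasselbalch over the termini
# and ionizable side chains).
net_charge <- function(chars, pH, pka) {
  nt_pka <- pka$nterm[chars[1]]
  if (is.na(nt_pka) || is.null(nt_pka)) nt_pka <- pka$nterm_default
  pos <- 1 / (1 + 10^(pH - nt_pka))
  for (res in c("H", "K", "R")) {
    k <- pka$side[res]
    if (!is.na(k)) pos <- pos + sum(chars == res) / (1 + 10^(pH - k))
  }
  neg <- 1 / (1 + 10^(pka$cterm - pH))
  for (res in c("D", "E", "C", "Y")) {
    k <- pka$side[res]
    if (!is.na(k)) neg <- neg + sum(chars == res) / (1 + 10^(k - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Finds the unique pH at which the net charge (termini plus D, E, C, Y, H,
#' K, R side chains under Henderson-Hasselbalch) is zero, by bisection.  The
#' net-charge function is strictly decreasing in pH, so the root is unique.
#'
#' @param sequence Protein string or single-row sequence tibble.
#' @param pKa_set `"bjellqvist"` (the ProtParam set, default) or `"emboss"`.
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pKa_set = c("bjellqvist", "emboss"),
                              tol = 1e-4) {
  pKa_set <- match.arg(pKa_set)
  pka <- if (pKa_set == "bjellqvist") PKA_BJELLQVIST else PKA_EMBOSS
  s <- if (is.data.frame(sequence)) sequence$residues[1] else sequence
  chars <- strsplit(s, "")[[1]]
  if (length(chars) == 0) abort("empty sequence has no isoelectric point")
  lo <- 0; hi <- 14
  if (net_charge(chars, lo, pka) < 0 || net_charge(chars, hi, pka) > 0) {
    abort("net charge does not bracket zero on (0, 14)")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(chars, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Remove a signal peptide
#'
#' @param sequence Protein string or single-row sequence tibble (precursor).
#' @param signal_length Number of N-terminal residues to remove.
#' @return Mature sequence string.
#' @export
cleave_signal <- function(sequence, signal_length) {
  s <- if (is.data.frame(sequence)) sequence$residues[1] else sequence
  n <- nchar(s)
  if (signal_length <= 0 || signal_length >= n) {
    abort(sprintf("signal_length must be in (0, %d)", n))
  }
  substr(s, signal_length + 1, n)
}

#' Detect a twin-arginine (Tat) export motif
#'
#' Looks within the N-terminal window for the Tat consensus
#' `[ST]-R-R-x-[FGAVML]-[LITMVF]`; failing that, a bare `R-R` pair in the
#' window is reported as a low-confidence match.  This is a lightweight
#' heuristic for the twin-arginine translocase signal, which exports folded
#' proteins across the inner membrane.
#'
#' @param sequence Protein string or single-row sequence tibble.
#' @param window Number of N-terminal residues searched (default 45).
#' @return Tibble with zero or one row: `match`, `begin`, `end`,
#'   `confidence` (`"high"` or `"low"`).
#' @export
find_tat_motif <- function(sequence, window = 45) {
  s <- if (is.data.frame(sequence)) sequence$residues[1] else sequence
  head_seq <- substr(s, 1, window)
  m <- regexpr("[ST]RR.[FGAVML][LITMVF]", head_seq)
  if (m > 0) {
    return(tibble(match = regmatches(head_seq, m), begin = as.integer(m),
                  end = as.integer(m + attr(m, "match.length") - 1),
                  confidence = "high"))
  }
  m <- regexpr("RR", head_seq)
  if (m > 0) {
    return(tibble(match = "RR", begin = as.integer(m),
                  end = as.integer(m + 1), confidence = "low"))
  }
  tibble(match = character(), begin = integer(), end = integer(),
         confidence = character())
}

#' Precursor/mature feature table for a set of proteins
#'
#' Computes, for each protein, length, molecular weight and theoretical pI of
#' the precursor and (when a signal length is supplied) of the mature form,
#' plus the Tat motif call.
#'
#' @param proteome Sequence tibble of precursors.
#' @param signal_lengths Optional tibble (`id`, `signal_length`) of
#'   signal-peptide lengths consumed as annotations (e.g. from an external
#'   signal-peptide predictor).
#' @param pKa_set Passed to [isoelectric_point()].
#' @return Tibble with one row per protein: `id`, `length`, `signal_length`,
#'   `mw_precursor_kda`, `mw_mature_kda`, `pi_precursor`, `pi_mature`,
#'   `tat_motif`, `tat_confidence`.
#' @export
protein_features <- function(proteome, signal_lengths = NULL,
                             pKa_set = "bjellqvist") {
  purrr::map_dfr(seq_len(nrow(proteome)), function(i) {
    s <- proteome$residues[i]
    id <- proteome$id[i]
    sl <- NA_integer_
    if (!is.null(signal_lengths)) {
      j <- match(id, signal_lengths$id)
      if (!is.na(j)) sl <- as.integer(signal_lengths$signal_length[j])
    }
    mature <- if (!is.na(sl)) cleave_signal(s, sl) else NA_character_
    tat <- find_tat_motif(s)
    tibble(
      id = id,
      length = nchar(s),
      signal_length = sl,
      mw_precursor_kda = molecular_weight(s) / 1000,
      mw_mature_kda = if (!is.na(sl)) molecular_weight(mature) / 1000
                      else NA_real_,
      pi_precursor = isoelectric_point(s, pKa_set),
      pi_mature = if (!is.na(sl)) isoelectric_point(mature, pKa_set)
                  else NA_real_,
      tat_motif = if (nrow(tat) > 0) tat$match[1] else NA_character_,
      tat_confidence = if (nrow(tat) > 0) tat$confidence[1] else NA_character_
    )
  })
}
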