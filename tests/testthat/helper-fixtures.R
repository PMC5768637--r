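# Shared in-code fixtures for the test suite.  Everything is generated
# programmatically; no binary data.

aa20 <- phorep:::AA_ALPHABET
bg20 <- phorep:::AA_BACKGROUND
dna4 <- c("A", "C", "G", "T")

# A peaked random protein count matrix and its PSSM.
toy_protein_pssm <- function(length = 12, peak = 0.85, seed = 1,
                             accession = "toy") {
  withr::with_seed(seed, {
    cons <- sample(aa20, length, replace = TRUE)
    counts <- matrix(0, length, 20, dimnames = list(NULL, aa20))
    for (i in seq_len(length)) {
      counts[i, ] <- 100 * (1 - peak) * bg20
      counts[i, cons[i]] <- counts[i, cons[i]] + 100 * peak
    }
    list(pssm = counts_to_logodds(counts, accession = accession),
         consensus = paste(cons, collapse = ""), counts = counts)
  })
}

# A peaked random DNA count matrix.
toy_dna_pssm <- function(length = 16, dominant = 20, seed = 1,
                         accession = "TF") {
  withr::with_seed(seed, {
    counts <- matrix(1, length, 4, dimnames = list(NULL, dna4))
    cons <- integer(length)
    for (i in seq_len(length)) {
      cons[i] <- sample(4, 1)
      counts[i, cons[i]] <- dominant
    }
    list(pssm = dna_pssm(counts, accession = accession),
         consensus = paste(dna4[cons], collapse = ""), counts = counts)
  })
}

# Hand-set order-1 Markov background.
hand_markov <- function(seed = 2) {
  withr::with_seed(seed, {
    init <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
    tr <- matrix(runif(16, 0.05, 0.5), 4, 4,
                 dimnames = list(dna4, dna4))
    tr <- tr / rowSums(tr)
    structure(list(order = 1, initial = init, transition = tr,
                   trained_on = "hand-set"), class = "markov_background")
  })
}

uniform_markov0 <- function() {
  structure(list(order = 0,
                 initial = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 transition = NULL, trained_on = "uniform"),
            class = "markov_background")
}

random_protein <- function(n, seed = NULL) {
  gen <- function() paste(sample(aa20, n, replace = TRUE, prob = bg20),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(dna4, n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Reverse-translate a peptide with one fixed codon per amino acid.
reverse_translate <- function(aa_string) {
  code <- Biostrings::getGeneticCode()
  map <- vapply(aa20, function(a) names(code)[match(a, code)], character(1))
  paste(map[strsplit(aa_string, "")[[1]]], collapse = "")
}

# Single C-alpha pseudo-atom row.
ca_atom <- function(serial, resno, x, y, z, element = "C",
                    residue_name = "ALA", hetero = FALSE,
                    atom_name = "CA") {
  tibble::tibble(serial = as.integer(serial), atom_name = atom_name,
                 element = element, residue_name = residue_name,
                 residue_number = as.integer(resno), chain = "A",
                 x = x, y = y, z = z, is_hetero = hetero)
}

# Table of gene coordinates and published protein lengths for the five
# Rta phosphatase genes (coordinates 5'->3' on the coding strand).
rta_gene_table <- function() {
  parse_gene_table(paste(
    "locus_tag\tstrand\tstart\tend",
    "Rta_17200\tD\t1805367\t1806959",  # PhoD
    "Rta_14460\tR\t1514607\t1512676",  # PhoX1
    "Rta_37610\tR\t4006412\t4004532",  # PhoX2
    "Rta_37000\tR\t3936191\t3933921",  # PhoX3
    "Rta_01350\tR\t134200\t132824",    # PhoX4
    sep = "\n"
  ))
}
rta_protein_lengths <- c(PhoD = 530L, PhoX1 = 643L, PhoX2 = 626L,
                         PhoX3 = 756L, PhoX4 = 458L)
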