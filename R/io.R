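#' Parse FASTA text into a sequence tibble
#'
#' Reads FASTA-formatted text (or a file path) and returns one row per record.
#' Residues are validated against the molecule alphabet: the 20 standard amino
#' acids plus `X` for proteins, `ACGT` plus `N` for DNA.
#'
#' @param text FASTA text (single string or character vector of lines), or the
#'   path to an existing FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @return A tibble with columns `id`, `description`, `residues`, `moltype`.
#'   Empty input yields a zero-row tibble.
#' @examples
#' parse_sequences(">a\nMKV", "protein")
#' @export
parse_sequences <- function(text, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (length(text) == 1 && !grepl("[>\n]", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(id = character(), description = character(),
                  residues = character(), moltype = character()))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) abort("FASTA input must start with a '>' header line")
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- vapply(split(lines[!hdr], rec[!hdr]), function(x) {
    toupper(gsub("\\s", "", paste(x, collapse = "")))
  }, character(1))
  # records with a header but no sequence lines
  all_ids <- as.character(seq_along(headers))
  residues <- residues[all_ids]
  residues[is.na(residues)] <- ""
  names(residues) <- NULL

  legal <- if (moltype == "protein") c(AA_ALPHABET, "X") else c(DNA_ALPHABET, "N")
  for (i in seq_along(residues)) {
    if (!nzchar(residues[i])) {
      abort(sprintf("record '%s' has an empty sequence", id[i]))
    }
    chars <- strsplit(residues[i], "")[[1]]
    bad <- which(!chars %in% legal)
    if (length(bad) > 0) {
      abort(sprintf(
        "illegal %s residue '%s' in record '%s' at position %d",
        moltype, chars[bad[1]], id[i], bad[1]
      ))
    }
  }
  tibble(id = id, description = description, residues = residues,
         moltype = moltype)
}

#' Write a sequence tibble to FASTA
#'
#' @param sequences Tibble as returned by [parse_sequences()].
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sequences))) {
    desc <- sequences$description[i]
    header <- if (nzchar(desc)) paste(sequences$id[i], desc) else sequences$id[i]
    writeLines(paste0(">", header), con)
    s <- sequences$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a gene coordinate table
#'
#' Reads a tab-separated table of protein-coding gene models with columns
#' `locus_tag`, `strand` (`D` direct / `R` reverse), `start`, `end` (1-based,
#' inclusive).  Reverse-strand rows conventionally list `start > end`
#' (coordinates read 5' to 3' on the coding strand); both orders are accepted
#' and normalised into `left`/`right` columns.
#'
#' @param text TSV text or a file path.
#' @return A tibble with columns `locus_tag`, `strand`, `start`, `end`,
#'   `left`, `right`, plus any extra columns present (e.g. `product_id`).
#' @seealso [derive_protein_length()]
#' @export
parse_gene_table <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    raw <- readr::read_tsv(text, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  } else {
    raw <- readr::read_tsv(I(paste(text, collapse = "\n")),
                           show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  }
  need <- c("locus_tag", "strand", "start", "end")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste("gene table is missing column(s):",
                paste(missing, collapse = ", ")))
  }
  for (col in c("start", "end")) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))) |
                   grepl("[^0-9]", raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-integer %s coordinate in row %d: '%s'",
                    col, bad[1], raw[[col]][bad[1]]))
    }
  }
  out <- raw
  out$start <- as.integer(raw$start)
  out$end <- as.integer(raw$end)
  if (any(!out$strand %in% c("D", "R"))) {
    abort("strand must be 'D' (direct) or 'R' (reverse)")
  }
  if (any(pmin(out$start, out$end) < 1)) abort("coordinates must be >= 1")
  out$left <- pmin(out$start, out$end)
  out$right <- pmax(out$start, out$end)
  as_tibble(out)
}

#' Protein length implied by CDS coordinates
#'
#' The coding span covers the protein plus the stop codon, so the encoded
#' protein length is `(|end - start| + 1) / 3 - 1`.
#'
#' @param genes Gene tibble from [parse_gene_table()], or a numeric vector of
#'   spans in bp.
#' @return Integer vector of protein lengths (aa).
#' @examples
#' g <- parse_gene_table("locus_tag\tstrand\tstart\tend\nx\tD\t1\t9")
#' derive_protein_length(g) # 2 aa
#' @export
derive_protein_length <- function(genes) {
  span <- if (is.data.frame(genes)) abs(genes$end - genes$start) + 1 else genes
  if (any(span %% 3 != 0)) {
    warn("CDS span not divisible by 3 for some entries")
  }
  as.integer(span / 3 - 1)
}

#' Parse a count/probability matrix file
#'
#' Supports three dialects:
#' * `"plain"`: one row per symbol, `A 1 0 4 ...` or `A: 1 0 4`, columns are
#'   motif positions;
#' * `"transfac"`: TRANSFAC-style blocks (`P0  A C G T` header, numbered
#'   position rows, optional `AC`/`ID` lines);
#' * `"meme"`: MEME minimal format (`MOTIF`, `letter-probability matrix`
#'   header with `nsites`); probabilities are converted back to counts via
#'   the stated `nsites`.
#'
#' @param text Matrix file text or path.
#' @param dialect One of `"plain"`, `"transfac"`, `"meme"`.
#' @param alphabet Symbol set; defaults to `ACGT`, use [AA_ALPHABET] via
#'   `alphabet = "protein"` for 20-residue matrices.
#' @return An object of class `matrix_file`: list with `accession`,
#'   `alphabet`, `counts` (positions x symbols matrix), `dialect`.
#' @export
parse_matrix <- function(text, dialect = c("plain", "transfac", "meme"),
                         alphabet = "dna") {
  dialect <- match.arg(dialect)
  if (identical(alphabet, "dna")) alphabet <- DNA_ALPHABET
  if (identical(alphabet, "protein")) alphabet <- AA_ALPHABET
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  out <- switch(dialect,
    plain = parse_matrix_plain(lines, alphabet),
    transfac = parse_matrix_transfac(lines),
    meme = parse_matrix_meme(lines)
  )
  if (any(out$counts < 0)) abort("matrix counts must be non-negative")
  # normalise column order
  out$counts <- out$counts[, match(alphabet, colnames(out$counts)),
                           drop = FALSE]
  colnames(out$counts) <- alphabet
  out$alphabet <- alphabet
  out$dialect <- dialect
  structure(out, class = "matrix_file")
}

parse_matrix_plain <- function(lines, alphabet) {
  rows <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(gsub(":", " ", ln)), "\\s+")[[1]]
    if (length(parts) < 2) abort(sprintf("cannot parse plain matrix line '%s'", ln))
    sym <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) abort(sprintf("non-numeric value in line '%s'", ln))
    rows[[sym]] <- vals
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) abort("ragged matrix: rows differ in length")
  if (!setequal(names(rows), alphabet)) {
    abort(sprintf("plain matrix symbols (%s) do not match alphabet",
                  paste(names(rows), collapse = ",")))
  }
  counts <- t(do.call(rbind, rows))  # positions x symbols
  colnames(counts) <- names(rows)
  list(accession = "plain_matrix", counts = counts)
}

parse_matrix_transfac <- function(lines) {
  acc <- "transfac_matrix"
  header <- NULL
  body <- list()
  for (ln in lines) {
    tag <- substr(trimws(ln), 1, 2)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tag %in% c("AC", "ID", "NA")) {
      if (length(parts) > 1) acc <- parts[2]
    } else if (tag == "P0" || tag == "PO") {
      header <- parts[-1]
    } else if (grepl("^[0-9]+$", parts[1])) {
      vals <- suppressWarnings(as.numeric(parts[2:(length(header) + 1)]))
      if (anyNA(vals)) abort(sprintf("ragged matrix row '%s'", ln))
      body[[length(body) + 1]] <- vals
    }
  }
  if (is.null(header) || length(body) == 0) {
    abort("not a TRANSFAC matrix: no P0 header or position rows found")
  }
  counts <- do.call(rbind, body)
  colnames(counts) <- toupper(header)
  list(accession = acc, counts = counts)
}

parse_matrix_meme <- function(lines) {
  acc <- "meme_matrix"
  i_motif <- grep("^MOTIF", lines)
  if (length(i_motif) > 0) {
    acc <- strsplit(trimws(lines[i_motif[1]]), "\\s+")[[1]][2]
  }
  i_hdr <- grep("letter-probability matrix", lines)
  if (length(i_hdr) == 0) abort("not a MEME matrix: missing probability header")
  hdr <- lines[i_hdr[1]]
  nsites <- if (grepl("nsites=", hdr)) {
    as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
  } else 20
  w <- if (grepl("w=", hdr)) {
    as.integer(sub(".*\\bw=\\s*([0-9]+).*", "\\1", hdr))
  } else NA_integer_
  body <- lines[(i_hdr[1] + 1):length(lines)]
  body <- body[grepl("^\\s*[0-9.eE+-]", body)]
  probs <- lapply(body, function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  })
  if (length(unique(lengths(probs))) != 1) abort("ragged MEME matrix")
  probs <- do.call(rbind, probs)
  if (!is.na(w) && nrow(probs) > w) probs <- probs[seq_len(w), , drop = FALSE]
  counts <- round(probs * nsites)
  colnames(counts) <- DNA_ALPHABET[seq_len(ncol(counts))]
  list(accession = acc, counts = counts, nsites = nsites)
}

#' @export
print.matrix_file <- function(x, ...) {
  cat(sprintf("<matrix_file> %s: %d positions x %d symbols (%s)\n",
              x$accession, nrow(x$counts), ncol(x$counts), x$dialect))
  invisible(x)
}

#' Write a matrix in the plain dialect
#'
#' @param mat A `matrix_file` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_plain <- function(mat, path) {
  lines <- vapply(seq_along(mat$alphabet), function(j) {
    paste(mat$alphabet[j], paste(mat$counts[, j], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
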