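#' Canonical amino-acid ordering
#'
#' The 20 canonical amino acids in the fixed column order used by every
#' composition matrix and profile in the package: alphabetical by
#' one-letter code.
#'
#' @format Character vector of length 20.
#' @export
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguous/non-standard residues tolerated in sequences: counted in the
# protein length but excluded from amino-acid count vectors.
AA_AMBIGUOUS <- c("B", "Z", "U", "X")

#' Average residue masses (Da)
#'
#' Average (isotope-abundance-weighted) residue masses after peptide-bond
#' water loss, used to convert residue counts into mass fractions
#' (g AA / g protein). Named by one-letter code in [AA_ORDER].
#'
#' @format Named numeric vector of length 20.
#' @export
AA_RESIDUE_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)

#' Essential and conditionally essential amino acids
#'
#' One-letter codes of the 15 amino acids that are essential or
#' conditionally essential for humans (Arg, Cys, Gln, Gly, His, Ile, Leu,
#' Lys, Met, Phe, Pro, Thr, Trp, Tyr, Val) — the nutritional focus set for
#' profile restriction.
#'
#' @format Character vector of length 15.
#' @export
AA_ESSENTIAL <- c("R", "C", "Q", "G", "H", "I", "L", "K",
                  "M", "F", "P", "T", "W", "Y", "V")

#' Construct a protein database
#'
#' Builds a `protein_db` object from named sequences. Sequences are
#' upper-cased and validated against the 20-letter amino-acid alphabet
#' (the ambiguity codes B, Z, U, X are tolerated; they count towards the
#' protein length but not towards any amino-acid count).
#'
#' @param sequences named character vector of amino-acid sequences; names
#'   are the protein ids.
#' @param source label recording where the database came from.
#' @return A `protein_db`: list with `protein_id`, `sequence`, `length`
#'   (residues) and `source`.
#' @export
protein_db <- function(sequences, source = "in-memory") {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must be named by a protein id")
  if (anyDuplicated(ids))
    stop("duplicate protein id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(sequences))
  if (any(!nzchar(seqs)))
    stop("empty sequence for protein: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  allowed <- c(AA_ORDER, AA_AMBIGUOUS)
  bad <- setdiff(unique(unlist(strsplit(seqs, ""), use.names = FALSE)), allowed)
  if (length(bad) > 0)
    stop("sequence contains non-amino-acid residue(s): ",
         paste(bad, collapse = ", "))
  structure(
    list(protein_id = ids,
         sequence = stats::setNames(seqs, ids),
         length = stats::setNames(nchar(seqs), ids),
         source = source),
    class = "protein_db"
  )
}

#' Read a protein FASTA database
#'
#' Parses a FASTA file into a [protein_db()]. The header token before the
#' first whitespace is taken as the protein id. Duplicate ids, empty
#' sequences and residues outside the tolerated alphabet are errors.
#'
#' @param path path to a FASTA file.
#' @return A `protein_db`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(aas))
  protein_db(stats::setNames(as.character(aas), ids), source = path)
}

#' Write a protein database as FASTA
#'
#' @param db a `protein_db`.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  stopifnot(inherits(db, "protein_db"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in db$protein_id) {
    s <- db$sequence[[id]]
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", id), chunks), con)
  }
  invisible(path)
}

#' Amino-acid count matrix
#'
#' Tallies residue counts per protein into a proteins x 20 integer matrix
#' with columns in the canonical [AA_ORDER]. Ambiguous residues (B, Z, U,
#' X) are not counted, so row sums equal protein lengths only for
#' ambiguity-free sequences.
#'
#' @param db a `protein_db`.
#' @return Integer matrix, rownames protein ids, colnames `AA_ORDER`.
#' @export
aa_count_matrix <- function(db) {
  stopifnot(inherits(db, "protein_db"))
  if (length(db$protein_id) == 0) stop("empty protein database")
  chars <- strsplit(db$sequence, "")
  m <- t(vapply(chars, function(ch) {
    tabulate(factor(ch, levels = AA_ORDER), nbins = length(AA_ORDER))
  }, integer(length(AA_ORDER))))
  dimnames(m) <- list(db$protein_id, AA_ORDER)
  m
}

#' @export
print.protein_db <- function(x, ...) {
  cat("protein_db:", length(x$protein_id), "proteins",
      sprintf("(lengths %d-%d, source: %s)\n",
              min(x$length), max(x$length), x$source))
  invisible(x)
}

#' @export
length.protein_db <- function(x) length(x$protein_id)
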