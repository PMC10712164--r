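#' Construct a PSM table
#'
#' A PSM (peptide-spectrum match) table records, per sample, the spectral
#' evidence for each peptide together with the candidate proteins the
#' peptide maps to. This is the downstream format of a search-engine +
#' protein-inference chain after FDR control.
#'
#' @param sample_id sample label.
#' @param peptide character vector of peptide sequences (or surrogate ids).
#' @param protein_ids list of character vectors, candidate proteins per
#'   peptide row; or a character vector of semicolon-separated ids.
#' @param psm_count numeric vector of PSM counts per row; strictly
#'   positive. Integer for observed data; fractional values are accepted
#'   so noise-free expected counts can be propagated exactly.
#' @return A `psm_table` data frame with columns `sample_id`, `peptide`,
#'   `protein_ids` (list column), `psm_count`.
#' @export
psm_table <- function(sample_id, peptide, protein_ids, psm_count) {
  if (is.character(protein_ids)) protein_ids <- strsplit(protein_ids, ";", fixed = TRUE)
  stopifnot(length(peptide) == length(protein_ids),
            length(peptide) == length(psm_count))
  if (any(psm_count <= 0)) stop("psm_count must be strictly positive")
  if (any(lengths(protein_ids) == 0)) stop("every PSM row needs >= 1 candidate protein")
  out <- data.frame(sample_id = rep_len(sample_id, length(peptide)),
                    peptide = peptide, stringsAsFactors = FALSE)
  out$protein_ids <- protein_ids
  out$psm_count <- psm_count
  class(out) <- c("psm_table", "data.frame")
  out
}

#' Read a PSM table from CSV
#'
#' Expects columns `sample_id`, `peptide`, `protein_ids`
#' (semicolon-separated candidate ids) and `psm_count`.
#'
#' @param path CSV path.
#' @return A [psm_table()].
#' @export
read_psm_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "peptide", "protein_ids", "psm_count")
  if (!all(need %in% names(df)))
    stop("PSM CSV must have columns: ", paste(need, collapse = ", "))
  psm_table(df$sample_id[1], df$peptide, df$protein_ids, df$psm_count)
}

#' Write a PSM table to CSV
#'
#' @param psms a `psm_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  df <- data.frame(sample_id = psms$sample_id,
                   peptide = psms$peptide,
                   protein_ids = vapply(psms$protein_ids, paste,
                                        character(1), collapse = ";"),
                   psm_count = psms$psm_count)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Razor assignment of shared-peptide evidence
#'
#' Assigns each PSM row's count to exactly one of its candidate proteins
#' (the "razor" protein), using a greedy majority-evidence rule in two
#' passes: first all unique (single-candidate) rows are credited, then
#' shared rows are processed in table order, each assigned to the
#' candidate with the largest accumulated evidence (unique +
#' already-assigned); ties break to the lexicographically smallest
#' protein id. Total PSM counts are conserved exactly.
#'
#' Contaminant entries (ids prefixed `contam_`) are removed from candidate
#' sets before assignment; rows whose candidates are all contaminants are
#' dropped.
#'
#' @param psms a [psm_table()].
#' @param db a [protein_db()] containing every candidate id.
#' @return Named numeric vector of razor PSM counts per protein. Proteins
#'   with zero assigned evidence are absent, not zero-filled.
#' @export
assign_razor <- function(psms, db) {
  stopifnot(inherits(psms, "psm_table"), inherits(db, "protein_db"))
  cand <- lapply(psms$protein_ids, function(ids) ids[!startsWith(ids, "contam_")])
  keep <- lengths(cand) > 0
  cand <- cand[keep]
  counts <- psms$psm_count[keep]
  unknown <- setdiff(unique(unlist(cand, use.names = FALSE)), db$protein_id)
  if (length(unknown) > 0)
    stop("candidate protein id(s) not in database: ",
         paste(unknown, collapse = ", "))

  tally <- new.env(parent = emptyenv())
  add <- function(id, x) {
    cur <- if (is.null(tally[[id]])) 0 else tally[[id]]
    tally[[id]] <- cur + x
  }
  get0_ <- function(id) if (is.null(tally[[id]])) 0 else tally[[id]]

  shared <- lengths(cand) > 1
  mapply(function(ids, n) add(ids[1], n), cand[!shared], counts[!shared])
  for (i in which(shared)) {
    ids <- sort(cand[[i]])
    ev <- vapply(ids, get0_, numeric(1))
    add(ids[which.max(ev)], counts[i])  # which.max takes first max: lexicographic tie-break
  }
  out <- unlist(as.list(tally))
  out[order(names(out))]
}

#' Length-normalize razor PSM counts into quantification values
#'
#' Converts per-protein razor PSM counts to the quantification value used
#' throughout the pipeline: PSM count divided by protein length
#' (PSM per residue). Proteins without assigned PSMs are omitted.
#'
#' @param razor named numeric vector from [assign_razor()].
#' @param db a [protein_db()].
#' @param sample_id sample label carried into the result.
#' @return A `sample_quant`: data frame with columns `protein_id`,
#'   `razor_psm`, `length`, `quant`, and a `sample_id` attribute.
#' @export
length_normalize <- function(razor, db, sample_id = "sample") {
  stopifnot(inherits(db, "protein_db"))
  unknown <- setdiff(names(razor), db$protein_id)
  if (length(unknown) > 0)
    stop("protein id(s) not in database: ", paste(unknown, collapse = ", "))
  L <- db$length[names(razor)]
  out <- data.frame(protein_id = names(razor),
                    razor_psm = unname(razor),
                    length = unname(L),
                    quant = unname(razor / L),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("sample_quant", "data.frame")
  out
}

#' Quantify a PSM table
#'
#' Convenience wrapper: razor assignment followed by length
#' normalization.
#'
#' @inheritParams assign_razor
#' @return A `sample_quant` (see [length_normalize()]).
#' @export
quantify <- function(psms, db) {
  length_normalize(assign_razor(psms, db), db,
                   sample_id = as.character(psms$sample_id[1]))
}

#' Quantification share of a protein subset
#'
#' Fraction of total quantification (PSM per residue, summed) carried by
#' a subset of proteins.
#'
#' @param quant a `sample_quant`.
#' @param subset character vector of protein ids.
#' @return Fraction in \[0, 1\].
#' @export
quant_share <- function(quant, subset) {
  stopifnot(inherits(quant, "sample_quant"))
  tot <- sum(quant$quant)
  if (tot <= 0) stop("total quantification is zero")
  sum(quant$quant[quant$protein_id %in% subset]) / tot
}

#' Write a sample quantification table as TSV
#'
#' @param quant a `sample_quant`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_quant <- function(quant, path) {
  df <- cbind(sample_id = attr(quant, "sample_id"), as.data.frame(quant))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sample_quant <- function(x, ...) {
  cat("sample_quant:", attr(x, "sample_id"), "-", nrow(x), "proteins,",
      sum(x$razor_psm), "razor PSMs\n")
  invisible(x)
}
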