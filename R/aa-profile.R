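#' Amino-acid profile of a protein subset
#'
#' Computes the amino-acid composition of a quantified protein subset as
#' the product of protein quantification values with their residue
#' counts: `raw_a = sum_p quant_p * count_{p,a}`. In `count` mode the
#' profile is the molar fraction `raw_a / sum(raw)`; in `mass` mode
#' (default, g AA / g protein) raw tallies are weighted by average
#' residue masses [AA_RESIDUE_MASS] before normalization.
#'
#' @param quant a `sample_quant`.
#' @param db a [protein_db()].
#' @param subset character vector of protein ids defining the context
#'   (e.g. all quantified proteins for the whole cell, or the proteins of
#'   one cellular component); default all quantified proteins.
#' @param mode `"mass"` or `"count"`.
#' @param context label stored with the profile.
#' @return An `aa_profile`: named numeric vector of 20 fractions summing
#'   to 1, with attributes `mode` and `context`.
#' @export
aa_profile <- function(quant, db, subset = quant$protein_id,
                       mode = c("mass", "count"), context = "whole_cell") {
  stopifnot(inherits(quant, "sample_quant"), inherits(db, "protein_db"))
  mode <- match.arg(mode)
  ids <- intersect(quant$protein_id, subset)
  if (length(ids) == 0) stop("no quantified protein in subset")
  q <- stats::setNames(quant$quant, quant$protein_id)[ids]
  counts <- aa_count_matrix(db)[ids, , drop = FALSE]
  raw <- as.numeric(crossprod(counts, q))
  names(raw) <- AA_ORDER
  if (mode == "mass") raw <- raw * AA_RESIDUE_MASS[AA_ORDER]
  f <- raw / sum(raw)
  structure(f, mode = mode, context = context, class = "aa_profile")
}

#' Relative amino-acid difference versus ribosomal proteins
#'
#' Per amino acid, the percent difference of a component's profile from
#' the ribosomal profile:
#' `delta_a = (f_{a,c} - f_{a,ribo}) / f_{a,ribo} * 100`.
#' Amino acids with zero ribosomal fraction are reported as `NA`
#' (undefined), never infinite.
#'
#' @param profile_c component (or whole-cell) `aa_profile`.
#' @param profile_ribo ribosomal `aa_profile`, same mode.
#' @return An `aa_rel_diff`: named numeric vector of percent differences
#'   with a `context` attribute.
#' @export
aa_rel_diff <- function(profile_c, profile_ribo) {
  stopifnot(inherits(profile_c, "aa_profile"), inherits(profile_ribo, "aa_profile"))
  if (!identical(attr(profile_c, "mode"), attr(profile_ribo, "mode")))
    stop("profiles computed in different modes (",
         attr(profile_c, "mode"), " vs ", attr(profile_ribo, "mode"), ")")
  ribo <- unclass(profile_ribo)
  d <- (unclass(profile_c) - ribo) / ribo * 100
  d[ribo == 0] <- NA_real_
  structure(d, context = attr(profile_c, "context"), class = "aa_rel_diff")
}

#' Restrict a profile to essential and conditionally essential amino acids
#'
#' Keeps the 15 amino acids in [AA_ESSENTIAL]. By default the restricted
#' vector is not renormalized (entries keep their whole-profile values);
#' `renormalize = TRUE` rescales the restriction to sum to 1.
#'
#' @param profile an `aa_profile` (or `aa_rel_diff`).
#' @param renormalize rescale the restriction to sum to 1 (profiles
#'   only).
#' @return Object of the same class restricted to the essential set, in
#'   [AA_ORDER] order.
#' @export
essential_subset <- function(profile, renormalize = FALSE) {
  keep <- intersect(AA_ORDER, AA_ESSENTIAL)
  out <- profile[names(profile) %in% keep]
  if (renormalize && inherits(profile, "aa_profile")) out <- out / sum(out)
  attributes(out) <- c(attributes(out),
                       attributes(profile)[c("mode", "context")])
  class(out) <- class(profile)
  out
}

#' @export
print.aa_profile <- function(x, digits = 4, ...) {
  cat(sprintf("aa_profile (%s, %s mode):\n",
              attr(x, "context"), attr(x, "mode")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
print.aa_rel_diff <- function(x, digits = 1, ...) {
  cat(sprintf("aa_rel_diff (%% vs ribosomal, context %s):\n",
              attr(x, "context")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write profiles or relative differences as a long TSV
#'
#' @param profiles named list of `aa_profile`/`aa_rel_diff` objects.
#' @param path output TSV path (columns context, aa_code, value).
#' @return `path`, invisibly.
#' @export
write_aa_table <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    data.frame(context = nm, aa_code = names(p), value = as.numeric(p))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
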