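# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, fixpoints, textbook formulas) and never call
# the implementation paths they check.

# Transitive closure by iterated boolean matrix fixpoint.
# direction = "down": follow parent -> child; "up": child -> parent.
closure_oracle <- function(terms, edges, start, direction = c("down", "up")) {
  direction <- match.arg(direction)
  n <- length(terms)
  adj <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  for (i in seq_len(nrow(edges))) {
    if (direction == "down") adj[edges$parent[i], edges$child[i]] <- TRUE
    else adj[edges$child[i], edges$parent[i]] <- TRUE
  }
  reach <- terms == start
  names(reach) <- terms
  repeat {
    nxt <- reach | (as.vector(reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sort(terms[reach])
}

# Random DAG: node i may only point to earlier nodes, guaranteeing
# acyclicity. Some names contain "membrane" to exercise the grouping.
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  nm <- paste("term", seq_len(n_terms))
  is_mem <- runif(n_terms) < 0.15
  nm[is_mem] <- paste("membrane part", seq_len(n_terms))[is_mem]
  child <- character(0); parent <- character(0); rel <- character(0)
  for (i in 2:n_terms) {
    k <- sample(1:min(3, i - 1), 1)
    pa <- sample(seq_len(i - 1), k)
    child <- c(child, rep(ids[i], k))
    parent <- c(parent, ids[pa])
    rel <- c(rel, sample(c("is_a", "part_of"), k, replace = TRUE))
  }
  list(terms = data.frame(id = ids, name = nm,
                          namespace = "cellular_component",
                          stringsAsFactors = FALSE),
       edges = data.frame(child = child, parent = parent, relation = rel,
                          stringsAsFactors = FALSE))
}

# Independent re-implementation of the annotation collapse on top of the
# matrix-closure oracle.
map_oracle <- function(annotations, terms, edges, roots) {
  term_ids <- terms$id
  name_of <- setNames(terms$name, terms$id)
  known <- annotations[annotations %in% term_ids]
  up <- function(t) closure_oracle(term_ids, edges, t, "up")
  down <- function(t) closure_oracle(term_ids, edges, t, "down")
  expanded <- unique(unlist(lapply(known, up)))
  desc <- lapply(roots, down)
  names(desc) <- roots
  refset <- unique(unlist(desc))
  matched <- intersect(expanded, refset)
  if (length(matched) == 0) {
    nm <- name_of[known]
    return(sort(unique(unname(
      ifelse(grepl("membrane", nm, ignore.case = TRUE), "membrane", nm)))))
  }
  if (length(matched) > 1) {
    drop <- vapply(matched, function(t)
      any(vapply(setdiff(matched, t), function(o) t %in% up(o), logical(1))),
      logical(1))
    if (!all(drop)) matched <- matched[!drop]
  }
  lab <- vapply(matched, function(t) {
    if ("GO:0005840" %in% roots && t %in% desc[["GO:0005840"]]) "ribosome"
    else if ("GO:0032991" %in% roots && t %in% desc[["GO:0032991"]])
      "protein containing complexes"
    else unname(name_of[t])
  }, character(1))
  sort(unique(unname(lab)))
}

# Spearman via hand-computed mid-ranks and the textbook Pearson sum
# formula.
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(rx)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Exhaustive two-pass razor oracle: unique counts first, then shared rows
# in order, recomputing evidence from scratch at every row.
razor_oracle <- function(candidates, counts) {
  assigned <- setNames(numeric(0), character(0))
  credit <- function(tab, id, x) {
    if (is.na(tab[id])) tab[id] <- 0
    tab[id] <- tab[id] + x
    tab
  }
  for (i in seq_along(candidates))
    if (length(candidates[[i]]) == 1)
      assigned <- credit(assigned, candidates[[i]], counts[i])
  for (i in seq_along(candidates)) {
    ids <- sort(candidates[[i]])
    if (length(ids) < 2) next
    ev <- vapply(ids, function(id) if (is.na(assigned[id])) 0 else assigned[id],
                 numeric(1))
    assigned <- credit(assigned, ids[which.max(ev)], counts[i])
  }
  assigned[order(names(assigned))]
}

# Per-residue tally of a quantification-weighted amino-acid profile.
profile_oracle <- function(quant, sequences, mode, masses, aa_order) {
  raw <- setNames(rep(0, length(aa_order)), aa_order)
  for (id in names(quant)) {
    for (ch in strsplit(sequences[[id]], "")[[1]])
      if (ch %in% aa_order) raw[ch] <- raw[ch] + quant[[id]]
  }
  if (mode == "mass") raw <- raw * masses[aa_order]
  raw / sum(raw)
}

# Small random proteome for round-trip tests.
random_protein_db <- function(n, seed, len_range = c(20, 80)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(microcomp::AA_ORDER, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = ""), character(1))
  microcomp::protein_db(setNames(seqs, sprintf("P%04d", seq_len(n))))
}

# Random PSM table over a db, with shared peptides.
random_psm_table <- function(db, n_rows, seed, shared_prob = 0.4) {
  set.seed(seed)
  ids <- db$protein_id
  cand <- lapply(seq_len(n_rows), function(i) {
    k <- if (runif(1) < shared_prob) sample(2:3, 1) else 1
    sample(ids, min(k, length(ids)))
  })
  microcomp::psm_table("s1", sprintf("pep%04d", seq_len(n_rows)), cand,
                       sample(1:20, n_rows, replace = TRUE))
}
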