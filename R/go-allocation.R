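#' Default cellular-component reference roots
#'
#' GO ids of "cellular anatomical entity", "protein-containing complex"
#' and "ribosome": the three roots whose descendant closures form the
#' reference against which protein annotations are collapsed.
#'
#' @format Named character vector of length 3.
#' @export
GO_CC_ROOTS <- c(cellular_anatomical_entity = "GO:0110165",
                 protein_containing_complex = "GO:0032991",
                 ribosome = "GO:0005840")

#' Construct a GO graph
#'
#' Directed acyclic graph of GO terms with typed edges. Only `is_a` and
#' `part_of` edges are represented (regulates-type relations are out of
#' scope); edges point child -> parent.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`).
#' @return A `go_graph`.
#' @export
go_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$id)) stop("duplicate term id")
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing) > 0)
    stop("edge endpoint(s) not in term list: ", paste(missing, collapse = ", "))
  if (!all(edges$relation %in% c("is_a", "part_of")))
    stop("edge relation must be is_a or part_of")
  g <- structure(list(terms = terms, edges = edges,
                      parents = split(edges$parent, factor(edges$child, levels = terms$id)),
                      children = split(edges$child, factor(edges$parent, levels = terms$id))),
                 class = "go_graph")
  cyc <- .find_cycle_member(g)
  if (!is.null(cyc)) stop("cycle detected in ontology graph involving ", cyc)
  g
}

# Kahn-style peel; returns NULL if acyclic, else one id on a cycle.
.find_cycle_member <- function(g) {
  indeg <- lengths(g$children)  # number of children (incoming in child->parent direction)
  names(indeg) <- g$terms$id
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in g$parents[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < nrow(g$terms)) names(indeg)[indeg > 0][1] else NULL
}

#' Read an OBO 1.2 ontology subset
#'
#' Parses `[Term]` stanzas (fields: `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `is_obsolete`). Obsolete terms are skipped.
#' Cross-references to terms outside the file are dropped with the edge.
#'
#' @param path OBO file path.
#' @return A [go_graph()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]\\s*$", lines)
  bounds <- c(grep("^\\[", lines), length(lines) + 1L)
  ids <- character(0); nm <- character(0); ns <- character(0)
  child <- character(0); parent <- character(0); rel <- character(0)
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[seq(s + 1L, e)]
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE)[1])
    if (is.na(id)) next
    name <- sub("^name:\\s*", "", grep("^name:", block, value = TRUE)[1])
    nspace <- sub("^namespace:\\s*", "", grep("^namespace:", block, value = TRUE)[1])
    ids <- c(ids, id)
    nm <- c(nm, if (is.na(name)) id else name)
    ns <- c(ns, if (is.na(nspace)) "cellular_component" else nspace)
    isa <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE)))
    po <- sub("\\s*!.*$", "",
              sub("^relationship:\\s*part_of\\s*", "",
                  grep("^relationship:\\s*part_of\\s", block, value = TRUE)))
    child <- c(child, rep(id, length(isa) + length(po)))
    parent <- c(parent, isa, po)
    rel <- c(rel, rep("is_a", length(isa)), rep("part_of", length(po)))
  }
  keep <- parent %in% ids
  go_graph(data.frame(id = ids, name = nm, namespace = ns,
                      stringsAsFactors = FALSE),
           data.frame(child = child[keep], parent = parent[keep],
                      relation = rel[keep], stringsAsFactors = FALSE))
}

#' Write a GO graph as an OBO 1.2 subset
#'
#' @param graph a `go_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "go_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", graph$terms$name[i]),
                 paste0("namespace: ", graph$terms$namespace[i])), con)
    ed <- graph$edges[graph$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(ed))) {
      if (ed$relation[j] == "is_a")
        writeLines(paste0("is_a: ", ed$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", ed$parent[j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# BFS transitive closure from `start` following `adj` (child or parent map).
.closure <- function(adj, start) {
  out <- character(0)
  frontier <- start
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, out)
  }
  unique(out)
}

#' Descendants of a GO term
#'
#' Transitive closure over the child direction of `is_a` and `part_of`
#' edges, the term itself included.
#'
#' @param graph a `go_graph`.
#' @param term_id GO id present in the graph.
#' @return Character vector of term ids.
#' @export
go_descendants <- function(graph, term_id) {
  stopifnot(inherits(graph, "go_graph"))
  if (!term_id %in% graph$terms$id) stop("unknown term: ", term_id)
  .closure(graph$children, term_id)
}

#' Ancestors of a GO term
#'
#' Transitive closure over the parent direction of `is_a` and `part_of`
#' edges, the term itself included (annotations are always joined with
#' their own id before mapping).
#'
#' @inheritParams go_descendants
#' @return Character vector of term ids.
#' @export
go_ancestors <- function(graph, term_id) {
  stopifnot(inherits(graph, "go_graph"))
  if (!term_id %in% graph$terms$id) stop("unknown term: ", term_id)
  .closure(graph$parents, term_id)
}

#' Build the cellular-component reference set
#'
#' For each root term, collects its descendant closure (or direct
#' children only, when `direct_children = TRUE`), root included.
#'
#' @param graph a `go_graph`.
#' @param roots character vector of root GO ids; defaults to
#'   [GO_CC_ROOTS].
#' @param direct_children if `TRUE`, use only one level below each root
#'   instead of the full closure.
#' @return A `go_reference`: list with `roots` and `descendants` (named
#'   list root id -> id set).
#' @export
build_reference <- function(graph, roots = GO_CC_ROOTS, direct_children = FALSE) {
  stopifnot(inherits(graph, "go_graph"))
  roots <- unname(roots)
  missing <- setdiff(roots, graph$terms$id)
  if (length(missing) > 0) stop("root(s) not in graph: ", paste(missing, collapse = ", "))
  desc <- lapply(roots, function(r) {
    if (direct_children) unique(c(r, graph$children[[r]])) else go_descendants(graph, r)
  })
  names(desc) <- roots
  structure(list(roots = roots, descendants = desc), class = "go_reference")
}

#' Collapse protein annotations to simplified component labels
#'
#' Implements the cellular-component collapse: (1) each annotated GO id
#' is expanded to its ancestors plus itself; (2) the expanded set is
#' intersected with each reference root's descendant closure; (3) among
#' matched terms, any term that is an ancestor of another matched term is
#' dropped (the most specific term per lineage is kept); (4) matches are
#' simplified — descendants of ribosome label "ribosome", remaining
#' descendants of protein-containing complex label
#' "protein containing complexes", other matches keep their own term
#' name; if nothing matched, terms whose name contains "membrane"
#' (case-insensitive) collapse to "membrane" and other unmatched terms
#' keep their names.
#'
#' @param annotations character vector of cellular-component GO ids
#'   assigned to one protein (non-empty; unannotated proteins are
#'   filtered out upstream).
#' @param graph a `go_graph`.
#' @param ref a [build_reference()] result.
#' @return Character vector of unique simplified labels.
#' @export
map_protein_terms <- function(annotations, graph, ref) {
  stopifnot(inherits(graph, "go_graph"), inherits(ref, "go_reference"))
  if (length(annotations) == 0) stop("empty annotation set")
  known <- annotations %in% graph$terms$id
  if (!any(known))
    stop("no annotation id present in the graph: ",
         paste(annotations, collapse = ", "))
  if (any(!known))
    warning("skipping annotation id(s) absent from graph: ",
            paste(annotations[!known], collapse = ", "))
  expanded <- unique(unlist(lapply(annotations[known],
                                   function(a) go_ancestors(graph, a)),
                            use.names = FALSE))
  refset <- unique(unlist(ref$descendants, use.names = FALSE))
  matched <- intersect(expanded, refset)
  term_name <- stats::setNames(graph$terms$name, graph$terms$id)

  if (length(matched) == 0) {
    nm <- term_name[annotations[known]]
    labels <- ifelse(grepl("membrane", nm, ignore.case = TRUE), "membrane", nm)
    return(sort(unique(unname(labels))))
  }
  if (length(matched) > 1) {
    # keep the most specific term of each lineage: drop any matched term
    # that is a proper ancestor of another matched term
    anc_of_other <- vapply(matched, function(t) {
      any(vapply(setdiff(matched, t),
                 function(o) t %in% go_ancestors(graph, o), logical(1)))
    }, logical(1))
    if (!all(anc_of_other)) matched <- matched[!anc_of_other]
  }
  ribo <- ref$descendants[["GO:0005840"]]
  complex <- ref$descendants[["GO:0032991"]]
  labels <- vapply(matched, function(t) {
    if (!is.null(ribo) && t %in% ribo) "ribosome"
    else if (!is.null(complex) && t %in% complex) "protein containing complexes"
    else unname(term_name[t])
  }, character(1))
  sort(unique(unname(labels)))
}

#' Read a protein-to-GO annotation TSV
#'
#' Two columns (`protein_id`, `go_id`), one pair per line.
#'
#' @param path TSV path.
#' @return Named list: protein id -> character vector of GO ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("protein_id", "go_id") %in% names(df)))
    stop("annotation TSV must have columns protein_id, go_id")
  split(df$go_id, df$protein_id)
}

#' Allocate quantification to simplified cellular components
#'
#' Sums quantification values per simplified label (a multi-label protein
#' contributes its full quantification to each of its labels), computes
#' the annotated fraction (quantification of proteins with at least one
#' label over total), and reports the top-k labels by summed
#' quantification with a lexicographic tie-break.
#'
#' @param quant a `sample_quant`.
#' @param labels named list: protein id -> character vector of simplified
#'   labels (from [map_protein_terms()]); proteins absent from `labels`
#'   are treated as unannotated.
#' @param top_k number of top components to report (default 3).
#' @return A `component_allocation`: list with `sample_id`, `table`
#'   (label, quant, share), `annotated_fraction`, `top_k`.
#' @export
allocate_components <- function(quant, labels, top_k = 3L) {
  stopifnot(inherits(quant, "sample_quant"))
  if (nrow(quant) == 0) stop("empty quantification")
  total <- sum(quant$quant)
  lab_of <- labels[quant$protein_id]
  has <- !vapply(lab_of, is.null, logical(1)) & lengths(lab_of) > 0
  annotated <- sum(quant$quant[has]) / total
  if (any(has)) {
    long_lab <- unlist(lab_of[has], use.names = FALSE)
    long_q <- rep(quant$quant[has], lengths(lab_of[has]))
    sums <- tapply(long_q, long_lab, sum)
    tab <- data.frame(label = names(sums), quant = as.numeric(sums),
                      share = as.numeric(sums) / total,
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$quant, tab$label), , drop = FALSE]
    rownames(tab) <- NULL
    top <- utils::head(tab$label, top_k)
  } else {
    tab <- data.frame(label = character(0), quant = numeric(0),
                      share = numeric(0))
    top <- character(0)
  }
  structure(list(sample_id = attr(quant, "sample_id"), table = tab,
                 annotated_fraction = annotated, top_k = top),
            class = "component_allocation")
}

#' @export
print.component_allocation <- function(x, ...) {
  cat("component_allocation:", x$sample_id,
      sprintf("(annotated fraction %.3f)\n", x$annotated_fraction))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Write a component allocation as TSV
#'
#' @param alloc a `component_allocation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_allocation <- function(alloc, path) {
  df <- cbind(sample_id = alloc$sample_id, alloc$table)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
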