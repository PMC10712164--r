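# 6-term toy DAG with a diamond (D -> B -> A, D -> C -> A) and a
# membrane-named orphan.
toy_graph <- function() {
  go_graph(
    data.frame(id = c("A", "B", "C", "D", "E", "M"),
               name = c("root entity", "left arm", "right arm", "leaf",
                        "other", "outer membrane thing"),
               namespace = "cellular_component"),
    data.frame(child = c("B", "C", "D", "D"),
               parent = c("A", "A", "B", "C"),
               relation = c("is_a", "is_a", "is_a", "part_of")))
}

test_that("read_obo parses term stanzas with typed edges", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: c", "namespace: cellular_component", "",
               "[Term]", "id: GO:2", "name: b", "is_a: GO:1 ! c", "",
               "[Term]", "id: GO:3", "name: a",
               "relationship: part_of GO:2 ! b", "",
               "[Term]", "id: GO:9", "name: gone", "is_obsolete: true", ""), f)
  g <- read_obo(f)
  expect_equal(nrow(g$terms), 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$relation[g$edges$child == "GO:3"], "part_of")
  expect_false("GO:9" %in% g$terms$id)
})

test_that("cyclic ontologies are rejected naming a member", {
  expect_error(
    go_graph(data.frame(id = c("A", "B"), name = c("a", "b"),
                        namespace = "cc"),
             data.frame(child = c("A", "B"), parent = c("B", "A"),
                        relation = "is_a")),
    "cycle.*[AB]")
})

test_that("write_obo / read_obo round trip preserves the graph", {
  g <- toy_graph()
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(g, f)
  g2 <- read_obo(f)
  expect_equal(g2$terms[order(g2$terms$id), ],
               g$terms[order(g$terms$id), ], ignore_attr = TRUE)
  key <- function(e) sort(paste(e$child, e$parent, e$relation))
  expect_equal(key(g2$edges), key(g$edges))
})

test_that("descendants and ancestors handle leaves and diamonds", {
  g <- toy_graph()
  expect_equal(go_descendants(g, "D"), "D")
  expect_setequal(go_descendants(g, "A"), c("A", "B", "C", "D"))
  expect_equal(go_ancestors(g, "A"), "A")
  expect_setequal(go_ancestors(g, "D"), c("D", "B", "C", "A"))
  expect_error(go_descendants(g, "ZZ"), "unknown")
})

test_that("closures match the fixpoint oracle and are mutually consistent", {
  for (seed in 1:6) {
    d <- random_dag(n_terms = 60, seed = seed)
    g <- go_graph(d$terms, d$edges)
    ids <- sample(d$terms$id, 8)
    for (t in ids) {
      expect_equal(sort(go_descendants(g, t)),
                   closure_oracle(d$terms$id, d$edges, t, "down"))
      expect_equal(sort(go_ancestors(g, t)),
                   closure_oracle(d$terms$id, d$edges, t, "up"))
    }
    a <- ids[1]; b <- ids[2]
    expect_equal(b %in% go_descendants(g, a), a %in% go_ancestors(g, b))
  }
})

test_that("reference sets support full-closure and direct-children modes", {
  g <- toy_graph()
  ref <- build_reference(g, roots = "A")
  expect_setequal(ref$descendants[["A"]], c("A", "B", "C", "D"))
  ref1 <- build_reference(g, roots = "A", direct_children = TRUE)
  expect_setequal(ref1$descendants[["A"]], c("A", "B", "C"))
})

test_that("annotation collapse keeps the most specific lineage term", {
  g <- toy_graph()
  ref <- build_reference(g, roots = "A")
  # both a subterm and its ancestor annotated -> one label, the deeper term
  expect_equal(map_protein_terms(c("D", "B"), g, ref), "leaf")
  # no match -> membrane-named terms group under "membrane"
  expect_equal(map_protein_terms("M", g, ref), "membrane")
  expect_equal(map_protein_terms("E", g, ref), "other")
  expect_warning(out <- map_protein_terms(c("D", "GO:404"), g, ref), "GO:404")
  expect_equal(out, "leaf")
  expect_error(suppressWarnings(map_protein_terms("GO:404", g, ref)),
               "no annotation")
})

test_that("ribosome children collapse to 'ribosome', complexes to their group", {
  pr <- simulate_proteome(sim_config(seed = 2, n_proteins_per_component = 4L))
  ref <- build_reference(pr$graph)
  expect_equal(map_protein_terms("GO:0015935", pr$graph, ref), "ribosome")
  expect_equal(map_protein_terms("GO:1990234", pr$graph, ref),
               "protein containing complexes")
  expect_equal(map_protein_terms(c("GO:1990234", "GO:0032991"), pr$graph, ref),
               "protein containing complexes")
  expect_equal(map_protein_terms("GO:0016021", pr$graph, ref), "membrane")
  # idempotence: terms already mapping to a single label keep mapping there
  expect_equal(map_protein_terms("GO:0005737", pr$graph, ref), "cytoplasm")
  expect_equal(map_protein_terms("GO:0005737", pr$graph, ref),
               map_protein_terms("GO:0005737", pr$graph, ref))
})

test_that("allocation sums, annotated fraction and top-k behave", {
  db <- random_protein_db(6, seed = 4)
  q <- length_normalize(setNames(rep(6, 6), db$protein_id), db)
  all_cyto <- setNames(rep(list("cytoplasm"), 6), db$protein_id)
  a <- allocate_components(q, all_cyto)
  expect_equal(a$table$quant, sum(q$quant))
  expect_equal(a$annotated_fraction, 1.0)
  a0 <- allocate_components(q, list())
  expect_equal(a0$annotated_fraction, 0)
  expect_length(a0$top_k, 0)
  # multi-label proteins contribute full quant to each label; ties in the
  # top-k order break lexicographically
  two <- setNames(rep(list(c("alpha", "beta")), 6), db$protein_id)
  a2 <- allocate_components(q, two)
  expect_equal(a2$table$quant, rep(sum(q$quant), 2))
  expect_equal(a2$table$label, c("alpha", "beta"))
})

test_that("collapse on random DAGs matches the independent oracle", {
  for (seed in 1:5) {
    d <- random_dag(n_terms = 40, seed = seed)
    g <- go_graph(d$terms, d$edges)
    roots <- sample(d$terms$id, 2)
    ref <- build_reference(g, roots = roots)
    for (i in 1:10) {
      ann <- sample(d$terms$id, sample(1:3, 1))
      expect_equal(map_protein_terms(ann, g, ref),
                   map_oracle(ann, d$terms, d$edges, roots))
    }
  }
})

test_that("noise-free allocation recovers generator component fractions", {
  cfg <- sim_config(seed = 8, n_proteins_per_component = 15L)
  pr <- simulate_proteome(cfg)
  ref <- build_reference(pr$graph)
  labels <- lapply(pr$annotations, map_protein_terms, graph = pr$graph,
                   ref = ref)
  mus <- c(0.1, 0.2, 0.3)
  tabs <- simulate_psm_tables(cfg, mus, proteome = pr, counts = "expected",
                              shared_fraction = 0)
  ribo_shares <- numeric(0)
  for (i in seq_along(mus)) {
    q <- quantify(tabs[[i]], pr$db)
    alloc <- allocate_components(q, labels)
    truth <- component_shares(cfg, mus[i])
    for (comp in names(pr$component_label)) {
      got <- alloc$table$quant[alloc$table$label == pr$component_label[comp]] /
        sum(q$quant)
      expect_equal(got, unname(truth[comp]), tolerance = 1e-12)
    }
    ribo_shares <- c(ribo_shares,
                     alloc$table$share[alloc$table$label == "ribosome"])
  }
  # ribosomal share strictly increasing with growth rate
  expect_true(all(diff(ribo_shares) > 0))
  expect_equal(cor(rank(mus), rank(ribo_shares)), 1)
})
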