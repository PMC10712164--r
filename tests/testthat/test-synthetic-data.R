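test_that("configuration invariants are enforced", {
  expect_error(sim_config(components = c("ribosome", "mystery"),
                          aa_bias = default_aa_bias("ribosome")),
               "mystery")
  expect_error(sim_config(Ks_C = 0), "positive")
  expect_error(sim_config(X0 = -1), "positive")
  expect_error(sim_config(alloc_intercept = 0.9, alloc_slope = 0.45),
               "phi_ribo")
  expect_error(sim_config(component_weights = c(cytoplasm = 1)),
               "component_weights")
  expect_error(sim_config(total_psms = 0), "positive")
})

test_that("identical seed and config give identical outputs", {
  cfg <- sim_config(seed = 99, n_proteins_per_component = 6L, n_events = 300)
  a <- simulate_proteome(cfg); b <- simulate_proteome(cfg)
  expect_identical(a$db$sequence, b$db$sequence)
  expect_identical(a$annotations, b$annotations)
  expect_identical(simulate_batch(cfg, "carbon"),
                   simulate_batch(cfg, "carbon"))
  expect_identical(simulate_psm_tables(cfg, 0.2),
                   simulate_psm_tables(cfg, 0.2))
  expect_identical(as.data.frame(simulate_events(cfg, "SGPI")),
                   as.data.frame(simulate_events(cfg, "SGPI")))
  cfg2 <- sim_config(seed = 100, n_proteins_per_component = 6L)
  expect_false(identical(simulate_proteome(cfg2)$db$sequence, a$db$sequence))
})

test_that("degenerate and biased residue samplers behave as configured", {
  comps <- c("ribosome", "cytoplasm")
  ala_only <- stats::setNames(rep(0, 20), AA_ORDER); ala_only["A"] <- 1
  bias <- list(ribosome = ala_only, cytoplasm = ala_only)
  cfg <- sim_config(seed = 5, components = comps, aa_bias = bias,
                    component_weights = c(cytoplasm = 1),
                    n_proteins_per_component = 5L)
  pr <- simulate_proteome(cfg)
  expect_true(all(grepl("^A+$", pr$db$sequence)))

  lys <- stats::setNames(rep(1, 20), AA_ORDER); lys["K"] <- 1.5
  cfg2 <- sim_config(seed = 6, components = comps,
                     aa_bias = list(ribosome = lys,
                                    cytoplasm = stats::setNames(rep(1, 20), AA_ORDER)),
                     component_weights = c(cytoplasm = 1),
                     n_proteins_per_component = 80L,
                     protein_length = c(ribosome = 140, cytoplasm = 140))
  pr2 <- simulate_proteome(cfg2)
  ribo_seq <- pr2$db$sequence[pr2$truth$protein_id[pr2$truth$component == "ribosome"]]
  residues <- unlist(strsplit(ribo_seq, ""), use.names = FALSE)
  n <- length(residues)
  expect_gt(n, 10000)
  p <- 1.5 / 20.5
  expect_lt(abs(mean(residues == "K") - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("generated proteome ships the reference roots and annotations", {
  cfg <- sim_config(seed = 1, n_proteins_per_component = 4L)
  pr <- simulate_proteome(cfg)
  expect_true(all(GO_CC_ROOTS %in% pr$graph$terms$id))
  # >= 2 levels below a root
  expect_gte(length(go_descendants(pr$graph, "GO:0032991")), 4)
  unann <- pr$truth$protein_id[pr$truth$component == "unannotated"]
  expect_false(any(unann %in% names(pr$annotations)))
  ann <- pr$truth$protein_id[pr$truth$component != "unannotated"]
  expect_true(all(ann %in% names(pr$annotations)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(pr$annotations, f)
  back <- read_annotations(f)
  expect_equal(back[order(names(back))],
               pr$annotations[order(names(pr$annotations))])
})

test_that("batch simulation reproduces Monod limits and limitation order", {
  cfg <- sim_config(seed = 21)
  s <- simulate_batch(cfg, "carbon", noise = FALSE)
  pre <- s$COD > 50 * cfg$Ks_C & s$NH4 > 50 * cfg$Ks_N
  expect_true(all(s$mu[pre] > 0.95 * cfg$mu_max))
  expect_true(all(s$phase[pre] == "abundant"))
  expect_true(all(s$COD >= 0 & s$NH4 >= 0 & s$CDW > 0))
  sn <- simulate_batch(cfg, "nitrogen", noise = FALSE)
  expect_lt(sn$NH4[nrow(sn)], 1e-3)
  expect_gt(sn$COD[nrow(sn)], 0.5)
  expect_error(sim_config(Ks_N = -1), "positive")
})

test_that("trajectory endpoint converges under step halving", {
  cfg <- sim_config(seed = 22)
  s1 <- simulate_batch(cfg, "carbon", dt = 0.01, noise = FALSE)
  s2 <- simulate_batch(cfg, "carbon", dt = 0.001, noise = FALSE)
  x1 <- s1$CDW[nrow(s1)]; x2 <- s2$CDW[nrow(s2)]
  expect_lt(abs(x1 - x2) / x2, 0.001)
})

test_that("PSM generator inverts exactly and responds monotonically to mu", {
  cfg <- sim_config(seed = 23, n_proteins_per_component = 10L)
  pr <- simulate_proteome(cfg)
  ribo <- pr$truth$protein_id[pr$truth$component == "ribosome"]
  tabs <- simulate_psm_tables(cfg, c(0.1, 0.3), proteome = pr,
                              counts = "expected", shared_fraction = 0)
  s1 <- quant_share(quantify(tabs[[1]], pr$db), ribo)
  s2 <- quant_share(quantify(tabs[[2]], pr$db), ribo)
  expect_equal(s1, phi_ribo(cfg, 0.1), tolerance = 1e-12)
  expect_equal(s2, phi_ribo(cfg, 0.3), tolerance = 1e-12)
  expect_gt(s2, s1)
  cfg$total_psms <- -5
  expect_error(simulate_psm_tables(cfg, 0.2, proteome = pr), "positive")
  expect_error(simulate_psm_tables(sim_config(seed = 1), 3), "phi_ribo")
})

test_that("shared peptides are generated and razor conserves their counts", {
  cfg <- sim_config(seed = 29, n_proteins_per_component = 8L,
                    shared_peptide_fraction = 0.3, total_psms = 2000)
  pr <- simulate_proteome(cfg)
  tabs <- simulate_psm_tables(cfg, 0.2, proteome = pr)
  psms <- tabs[[1]]
  expect_gt(sum(lengths(psms$protein_ids) > 1), 0)
  razor <- assign_razor(psms, pr$db)
  expect_equal(sum(razor), sum(psms$psm_count))
})

test_that("event tables carry metadata and mixture fractions", {
  cfg <- sim_config(seed = 31, n_events = 2000, doublet_fraction = 0)
  ev <- simulate_events(cfg, "SGPI")
  expect_equal(attr(ev, "volume_mL"), 0.075)
  expect_equal(attr(ev, "panel"), "SGPI")
  truth <- attr(ev, "truth")
  p <- cfg$intact_fraction
  expect_lt(abs(mean(truth == "cell") - p), 3 * sqrt(p * (1 - p) / 2000))
  expect_true(all(as.matrix(as.data.frame(ev)) >= 0))
  expect_error(simulate_events(cfg, "XYZ"), "arg")
})
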