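#' Simulation configuration with known ground truth
#'
#' Bundles every parameter of the synthetic-data generator: the proteome
#' layout (components, protein counts, per-component amino-acid sampling
#' biases), the ribosomal allocation law `phi_ribo(mu) = phi0 + k * mu`,
#' dual-Monod batch growth parameters, growth-rate-dependent composition
#' rules, cytometry mixture parameters, and per-observable noise levels.
#' All randomness derives from `seed`; identical seed and configuration
#' give byte-identical outputs.
#'
#' Defaults emulate a fructose-grown batch culture sampled over a
#' 0.05-0.35 1/h growth-rate range: the ribosomal proteome share rises
#' linearly with growth rate (0.12 + 0.45 mu, spanning roughly 14-28%),
#' ribosomal proteins are enriched in Arg/Lys/Met/Val, nucleic-acid stain
#' intensity rises and protein content falls with growth rate, and
#' storage-compound intensity rises under nitrogen-limited deceleration.
#'
#' @param seed integer seed governing all generator randomness.
#' @param n_proteins_per_component proteins per cellular component.
#' @param components component labels; each needs an `aa_bias` entry.
#' @param aa_bias named list: component -> 20-dim non-negative sampling
#'   weights over [AA_ORDER].
#' @param protein_length named vector of mean protein lengths (residues)
#'   per component.
#' @param alloc_intercept,alloc_slope ribosomal allocation law
#'   `phi_ribo(mu) = alloc_intercept + alloc_slope * mu` (slope per 1/h).
#' @param component_weights fixed split of the non-ribosomal share among
#'   the remaining components (sums to 1).
#' @param mu_max maximum specific growth rate (1/h).
#' @param Ks_C,Ks_N Monod half-saturation constants (gCOD/L, gNH4/L).
#' @param yield_C,yield_N biomass yields (gCDW/gCOD, gCDW/gNH4).
#' @param C0,X0 initial substrate (gCOD/L) and biomass (gCDW/L).
#' @param N0 named initial ammonium (gNH4/L) per limitation scenario.
#' @param od_per_cdw OD600 units per gCDW/L.
#' @param na_intercept,na_slope nucleic-acid intensity rule
#'   `a + b * mu` (A.U.).
#' @param prot_intercept,prot_slope protein content rule `a - b * mu`
#'   (g protein/gCDW).
#' @param carb_intercept,carb_slope carbohydrate content rule `a + b *
#'   mu` (g/gCDW).
#' @param pha_base,pha_gain,lipid_base,lipid_gain storage-compound
#'   intensity (A.U.): base everywhere, plus gain during
#'   nitrogen/dual-limited deceleration.
#' @param size_intercept,size_slope cell size rule `a + b * mu` (um).
#' @param noise_cv named multiplicative lognormal noise CVs per
#'   observable (0 disables noise).
#' @param total_psms expected total PSM budget per sample.
#' @param peptides_per_protein peptide rows per protein.
#' @param shared_peptide_fraction fraction of peptide rows given a second
#'   candidate protein (exercises razor assignment).
#' @param n_events cytometry events per acquisition.
#' @param volume_mL,dilution_factor acquisition metadata (75 uL recorded
#'   volume by default).
#' @param intact_fraction,pha_positive_fraction,debris_fraction,
#'   doublet_fraction cytometry mixture composition.
#' @param cyto_meanlog,cyto_sdlog lognormal location/scale of the main
#'   cell population per channel.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins_per_component = 40L,
                       components = c("ribosome", "cytoplasm", "membrane",
                                      "protein_complex", "unannotated"),
                       aa_bias = default_aa_bias(components),
                       protein_length = c(ribosome = 130, cytoplasm = 300,
                                          membrane = 280, protein_complex = 320,
                                          unannotated = 250),
                       alloc_intercept = 0.12, alloc_slope = 0.45,
                       component_weights = c(cytoplasm = 0.24, membrane = 0.18,
                                             protein_complex = 0.10,
                                             unannotated = 0.48),
                       mu_max = 0.35, Ks_C = 0.02, Ks_N = 0.002,
                       yield_C = 0.5, yield_N = 6.5,
                       C0 = 2.13, X0 = 0.064,
                       N0 = c(carbon = 0.5, nitrogen = 0.08, dual = 0.164),
                       od_per_cdw = 2.5,
                       na_intercept = 40, na_slope = 300,
                       prot_intercept = 0.68, prot_slope = 0.6,
                       carb_intercept = 0.08, carb_slope = 0.15,
                       pha_base = 20, pha_gain = 150,
                       lipid_base = 15, lipid_gain = 60,
                       size_intercept = 0.9, size_slope = 1.0,
                       noise_cv = c(od = 0.05, cod = 0.05, nh4 = 0.05,
                                    cdw = 0.05, protein = 0.05,
                                    carbohydrate = 0.05, na = 0.05,
                                    pha = 0.05, lipid = 0.05, size = 0.05),
                       total_psms = 50000, peptides_per_protein = 3L,
                       shared_peptide_fraction = 0.1,
                       n_events = 5000, volume_mL = 0.075,
                       dilution_factor = 10,
                       intact_fraction = 0.75,
                       pha_positive_fraction = 0.4,
                       debris_fraction = 0.2,
                       doublet_fraction = 0.05,
                       cyto_meanlog = c(`FSC-H` = 4.0, `SSC-H` = 3.5,
                                        `BL1-H` = 5.0, `BL3-H` = 2.0,
                                        `RL1-H` = 5.0),
                       cyto_sdlog = 0.3) {
  cfg <- as.list(environment())
  missing_bias <- setdiff(components, names(aa_bias))
  if (length(missing_bias) > 0)
    stop("component(s) without aa_bias: ", paste(missing_bias, collapse = ", "))
  for (comp in components) {
    w <- aa_bias[[comp]]
    if (length(w) != 20 || any(w < 0) || sum(w) <= 0)
      stop("aa_bias for ", comp,
           " must be a non-negative 20-dim vector with positive sum")
  }
  if (Ks_C <= 0 || Ks_N <= 0) stop("half-saturation constants must be positive")
  if (C0 <= 0 || X0 <= 0 || any(N0 <= 0))
    stop("initial substrate and biomass must be positive")
  phi <- alloc_intercept + alloc_slope * c(0, mu_max)
  if (any(phi <= 0) || any(phi >= 1))
    stop("phi_ribo(mu) must stay inside (0, 1) over [0, mu_max]")
  prot <- prot_intercept - prot_slope * c(0, mu_max)
  if (any(prot < 0) || any(prot > 1))
    stop("protein fraction rule leaves [0, 1] over the mu range")
  others <- setdiff(components, "ribosome")
  if (!setequal(names(component_weights), others) ||
      abs(sum(component_weights) - 1) > 1e-9)
    stop("component_weights must cover the non-ribosomal components and sum to 1")
  if (total_psms <= 0) stop("total PSM budget must be positive")
  structure(cfg, class = "sim_config")
}

#' Default per-component amino-acid sampling biases
#'
#' Uniform weights over the 20 amino acids, with ribosomal proteins
#' enriched in Arg, Lys, Met and Val, and cytoplasmic/membrane proteins
#' enriched in Cys, Leu, Phe, Thr, Trp and Tyr — the enrichment
#' directions reported for microbial proteomes.
#'
#' @param components component labels.
#' @return Named list of 20-dim weight vectors over [AA_ORDER].
#' @export
default_aa_bias <- function(components) {
  base <- stats::setNames(rep(1, 20), AA_ORDER)
  out <- lapply(components, function(comp) {
    w <- base
    if (comp == "ribosome") w[c("R", "K", "M", "V")] <- 1.8
    if (comp == "cytoplasm") w[c("C", "L", "F", "T", "W", "Y")] <- 1.4
    if (comp == "membrane") w[c("C", "L", "F", "W", "Y", "I")] <- 1.5
    w
  })
  stats::setNames(out, components)
}

#' Ribosomal allocation law
#'
#' The generating growth law for the ribosomal proteome share:
#' `phi_ribo(mu) = alloc_intercept + alloc_slope * mu`.
#'
#' @param config a [sim_config()].
#' @param mu growth rate(s), 1/h.
#' @return Ribosomal mass share(s) in (0, 1).
#' @export
phi_ribo <- function(config, mu) {
  stopifnot(inherits(config, "sim_config"))
  config$alloc_intercept + config$alloc_slope * mu
}

#' Ground-truth component mass shares at a growth rate
#'
#' @param config a [sim_config()].
#' @param mu growth rate, 1/h.
#' @return Named share vector over the configured components (sums to 1).
#' @export
component_shares <- function(config, mu) {
  phi <- phi_ribo(config, mu)
  if (phi <= 0 || phi >= 1) stop("phi_ribo(mu) outside (0, 1) at mu = ", mu)
  shares <- c(ribosome = phi, (1 - phi) * config$component_weights)
  shares[config$components]
}

# The fixed toy cellular-component ontology shipped with the generator:
# the three reference roots with >= 2 levels of is_a/part_of descendants,
# plus one orphan membrane-named term to exercise the no-match grouping.
.toy_go_terms <- function() {
  data.frame(
    id = c("GO:0110165", "GO:0005737", "GO:0005829", "GO:0016020",
           "GO:0005886", "GO:0032991", "GO:0005840", "GO:0015934",
           "GO:0015935", "GO:1902494", "GO:1990234", "GO:0016021"),
    name = c("cellular anatomical entity", "cytoplasm", "cytosol",
             "membrane", "plasma membrane", "protein-containing complex",
             "ribosome", "large ribosomal subunit",
             "small ribosomal subunit", "catalytic complex",
             "transferase complex", "integral component of membrane"),
    namespace = "cellular_component", stringsAsFactors = FALSE)
}

.toy_go_edges <- function() {
  data.frame(
    child = c("GO:0005737", "GO:0005829", "GO:0016020", "GO:0005886",
              "GO:0005840", "GO:0015934", "GO:0015935", "GO:1902494",
              "GO:1990234"),
    parent = c("GO:0110165", "GO:0005737", "GO:0110165", "GO:0016020",
               "GO:0032991", "GO:0005840", "GO:0005840", "GO:0032991",
               "GO:1902494"),
    relation = c("is_a", "part_of", "is_a", "is_a", "is_a", "part_of",
                 "part_of", "is_a", "is_a"),
    stringsAsFactors = FALSE)
}

#' Simulate a proteome with component ground truth
#'
#' Generates a protein FASTA-style database whose residues are drawn from
#' each component's amino-acid bias, a toy GO cellular-component DAG
#' containing the three reference roots with at least two levels of
#' is_a/part_of descendants, and protein-to-GO annotations mapping each
#' annotated protein to a leaf term of its component ("unannotated"
#' proteins receive none; half the membrane proteins are annotated to an
#' orphan membrane-named term to exercise the no-match grouping branch).
#'
#' @param config a [sim_config()].
#' @return List with `db` ([protein_db()]), `truth` (data frame
#'   protein_id, component, length), `graph` ([go_graph()]),
#'   `annotations` (named list protein_id -> GO ids), and
#'   `component_label` (the simplified label each component maps to).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    ids <- character(0); comps <- character(0); seqs <- character(0)
    for (comp in config$components) {
      n <- config$n_proteins_per_component
      mean_len <- config$protein_length[[comp]]
      lens <- pmax(50L, stats::rpois(n, mean_len))
      w <- config$aa_bias[[comp]]
      pid <- sprintf("%s_%03d", comp, seq_len(n))
      sq <- vapply(lens, function(L)
        paste(sample(AA_ORDER, L, replace = TRUE, prob = w), collapse = ""),
        character(1))
      ids <- c(ids, pid); comps <- c(comps, rep(comp, n)); seqs <- c(seqs, sq)
    }
    db <- protein_db(stats::setNames(seqs, ids), source = "synthetic")
    graph <- go_graph(.toy_go_terms(), .toy_go_edges())
    ann <- list()
    for (i in seq_along(ids)) {
      comp <- comps[i]
      ann[[ids[i]]] <- switch(
        comp,
        ribosome = if (i %% 2 == 0) "GO:0015934" else "GO:0015935",
        cytoplasm = "GO:0005737",
        membrane = if (i %% 2 == 0) "GO:0016020" else "GO:0016021",
        protein_complex = "GO:1990234",
        unannotated = NULL)
    }
    list(db = db,
         truth = data.frame(protein_id = ids, component = comps,
                            length = unname(db$length[ids]),
                            stringsAsFactors = FALSE),
         graph = graph,
         annotations = ann,
         component_label = c(ribosome = "ribosome", cytoplasm = "cytoplasm",
                             membrane = "membrane",
                             protein_complex = "protein containing complexes"))
  })
}

#' Write protein-to-GO annotations as TSV
#'
#' @param annotations named list protein_id -> GO id vector.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(protein_id = rep(names(annotations), lengths(annotations)),
                   go_id = unlist(annotations, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Dual-Monod instantaneous growth rate.
.monod_mu <- function(C, N, config) {
  config$mu_max * min(max(C, 0) / (config$Ks_C + max(C, 0)),
                      max(N, 0) / (config$Ks_N + max(N, 0)))
}

#' Simulate a batch bioreactor run
#'
#' Integrates the dual-Monod batch model
#' `dX/dt = mu X`, `dC/dt = -mu X / Y_C`, `dN/dt = -mu X / Y_N` with
#' `mu = mu_max * min(C/(Ks_C+C), N/(Ks_N+N))`
#' by fixed-step 4th-order Runge-Kutta, then samples observables on a
#' regular grid with multiplicative lognormal noise: OD, residual COD and
#' ammonium, cell dry weight, the composition rules of the configuration
#' (protein falling and nucleic-acid intensity rising with growth rate,
#' storage intensity rising under nitrogen/dual-limited deceleration) and
#' cell size. Ground-truth phase labels mark a point `abundant` while the
#' residual limiting substrate exceeds 10 half-saturation constants,
#' `limiting` otherwise.
#'
#' @param config a [sim_config()].
#' @param limitation `"carbon"`, `"nitrogen"` or `"dual"`: which
#'   substrate runs out (sets the initial ammonium level).
#' @param t_end simulated duration (h).
#' @param dt integration step (h).
#' @param sample_every observation interval (h).
#' @param noise use the configured noise CVs (`FALSE` forces noise off).
#' @return A `sample_series` data frame (time, OD, COD, NH4, CDW, mu,
#'   protein, carbohydrate, na_intensity, pha_intensity, lipid_intensity,
#'   cell_size, phase, limitation) with the fine-grid ODE solution in
#'   attribute `solution`.
#' @export
simulate_batch <- function(config, limitation = c("carbon", "nitrogen", "dual"),
                           t_end = 16, dt = 0.01, sample_every = 0.5,
                           noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  limitation <- match.arg(limitation)
  N0 <- config$N0[[limitation]]
  rhs <- function(t, y, parms) {
    mu <- .monod_mu(y[2], y[3], config)
    list(c(mu * y[1], -mu * y[1] / config$yield_C, -mu * y[1] / config$yield_N))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(X = config$X0, C = config$C0, N = N0),
                      times = times, func = rhs, parms = NULL,
                      method = "rk4")
  sol <- as.data.frame(sol)
  sol$C <- pmax(sol$C, 0); sol$N <- pmax(sol$N, 0)
  sol$mu <- mapply(function(C, N) .monod_mu(C, N, config), sol$C, sol$N)

  obs_t <- seq(0, t_end, by = sample_every)
  idx <- vapply(obs_t, function(tt) which.min(abs(sol$time - tt)), integer(1))
  pt <- sol[idx, ]
  abundant <- switch(limitation,
                     carbon = pt$C > 10 * config$Ks_C,
                     nitrogen = pt$N > 10 * config$Ks_N,
                     dual = pt$C > 10 * config$Ks_C & pt$N > 10 * config$Ks_N)
  storage_on <- limitation %in% c("nitrogen", "dual") & !abundant
  series <- data.frame(
    time = pt$time,
    OD = pt$X * config$od_per_cdw,
    COD = pt$C,
    NH4 = pt$N,
    CDW = pt$X,
    mu = pt$mu,
    protein = config$prot_intercept - config$prot_slope * pt$mu,
    carbohydrate = config$carb_intercept + config$carb_slope * pt$mu,
    na_intensity = config$na_intercept + config$na_slope * pt$mu,
    pha_intensity = config$pha_base + config$pha_gain * storage_on,
    lipid_intensity = config$lipid_base + config$lipid_gain * storage_on,
    cell_size = config$size_intercept + config$size_slope * pt$mu,
    phase = ifelse(abundant, "abundant", "limiting"),
    limitation = limitation,
    stringsAsFactors = FALSE)
  if (noise && any(config$noise_cv > 0)) {
    cv <- config$noise_cv
    noisy <- c(OD = "od", COD = "cod", NH4 = "nh4", CDW = "cdw",
               protein = "protein", carbohydrate = "carbohydrate",
               na_intensity = "na", pha_intensity = "pha",
               lipid_intensity = "lipid", cell_size = "size")
    off <- match(limitation, c("carbon", "nitrogen", "dual"))
    withr::with_seed(config$seed + 100L * off, {
      for (col in names(noisy)) {
        s <- cv[[noisy[[col]]]]
        if (s > 0)
          series[[col]] <- series[[col]] *
            exp(stats::rnorm(nrow(series), 0, s))
      }
    })
  }
  attr(series, "solution") <- sol
  attr(series, "limitation") <- limitation
  class(series) <- c("sample_series", "data.frame")
  series
}

#' Simulate PSM tables across growth rates
#'
#' For each growth rate, expected per-protein PSM counts are set
#' proportional to component mass share x within-component weight x
#' protein length, so that length-normalized razor counts recover the
#' component mass shares exactly. Counts are split over peptide rows and
#' either used as expectations directly (`counts = "expected"`,
#' fractional, noise-free) or drawn Poisson. A configurable fraction of
#' peptide rows receives a second candidate protein to exercise razor
#' assignment.
#'
#' @param config a [sim_config()].
#' @param mus growth rates (1/h); `phi_ribo` must stay inside (0, 1).
#' @param proteome result of [simulate_proteome()] (regenerated from
#'   `config` when omitted).
#' @param counts `"poisson"` (default) or `"expected"`.
#' @param shared_fraction fraction of peptide rows with a second
#'   candidate; defaults to the configured value.
#' @return Named list of [psm_table()]s, one per growth rate
#'   (`mu_<value>`).
#' @export
simulate_psm_tables <- function(config, mus,
                                proteome = simulate_proteome(config),
                                counts = c("poisson", "expected"),
                                shared_fraction = config$shared_peptide_fraction) {
  stopifnot(inherits(config, "sim_config"))
  counts <- match.arg(counts)
  if (config$total_psms <= 0) stop("total PSM budget must be positive")
  phis <- phi_ribo(config, mus)
  if (any(phis <= 0 | phis >= 1))
    stop("phi_ribo(mu) outside (0, 1) for some requested mu")
  truth <- proteome$truth
  npep <- config$peptides_per_protein
  out <- list()
  for (s in seq_along(mus)) {
    mu <- mus[s]
    shares <- component_shares(config, mu)
    w <- shares[truth$component] / config$n_proteins_per_component
    e_p <- w * truth$length
    e_p <- e_p / sum(e_p) * config$total_psms
    pep_expect <- rep(e_p / npep, each = npep)
    pep_protein <- rep(truth$protein_id, each = npep)
    pep_id <- paste0("PEP_", pep_protein, "_", seq_len(npep))
    withr::with_seed(config$seed + 1000L + s, {
      cnt <- if (counts == "poisson") stats::rpois(length(pep_expect), pep_expect)
             else pep_expect
      cand <- as.list(pep_protein)
      if (shared_fraction > 0) {
        shared <- stats::runif(length(cand)) < shared_fraction
        partners <- sample(truth$protein_id, sum(shared), replace = TRUE)
        k <- 1L
        for (i in which(shared)) {
          if (partners[k] != pep_protein[i])
            cand[[i]] <- c(pep_protein[i], partners[k])
          k <- k + 1L
        }
      }
    })
    keep <- cnt > 0
    out[[paste0("mu_", format(mu))]] <-
      psm_table(sample_id = paste0("mu_", format(mu)),
                peptide = pep_id[keep], protein_ids = cand[keep],
                psm_count = cnt[keep])
  }
  out
}

#' Simulate a stained cytometry acquisition
#'
#' Draws per-event scatter and fluorescence from per-population
#' lognormal mixtures for one of three staining panels: `SG` (SYBR Green
#' total-cell stain), `SGPI` (SYBR Green + propidium iodide; an
#' `intact_fraction` of cells is PI-negative, the rest carry high BL3
#' fluorescence), or `BODIPY_SYTO62` (storage-compound stain on BL1 with
#' SYTO 62 counterstain on RL1 and a low-scatter debris population).
#' Doublets are simulated as event pairs with summed area and
#' 1.1x-the-larger height on the primary channel. Acquisition metadata
#' (recorded volume, dilution factor, panel) is attached.
#'
#' @param config a [sim_config()].
#' @param panel `"SG"`, `"SGPI"` or `"BODIPY_SYTO62"`.
#' @return An [event_table()] with a `truth` attribute recording the
#'   generating population of each event.
#' @export
simulate_events <- function(config, panel = c("SG", "SGPI", "BODIPY_SYTO62")) {
  stopifnot(inherits(config, "sim_config"))
  panel <- match.arg(panel)
  n <- config$n_events
  ml <- config$cyto_meanlog
  sd <- config$cyto_sdlog
  off <- match(panel, c("SG", "SGPI", "BODIPY_SYTO62"))
  withr::with_seed(config$seed + 5000L + off, {
    draw <- function(k, meanlog) stats::rlnorm(k, meanlog, sd)
    ev <- data.frame(`FSC-H` = draw(n, ml[["FSC-H"]]),
                     `SSC-H` = draw(n, ml[["SSC-H"]]),
                     `BL1-H` = draw(n, ml[["BL1-H"]]),
                     `BL3-H` = draw(n, ml[["BL3-H"]]),
                     `RL1-H` = draw(n, ml[["RL1-H"]]),
                     check.names = FALSE)
    truth <- rep("cell", n)
    if (panel == "SGPI") {
      damaged <- stats::runif(n) >= config$intact_fraction
      ev[["BL3-H"]][damaged] <- draw(sum(damaged), ml[["BL3-H"]] + 3)
      truth[damaged] <- "damaged"
    }
    if (panel == "BODIPY_SYTO62") {
      positive <- stats::runif(n) < config$pha_positive_fraction
      ev[["BL1-H"]] <- draw(n, 3.0)
      ev[["BL1-H"]][positive] <- draw(sum(positive), 6.0)
      truth[positive] <- "pha_positive"
      n_debris <- round(config$debris_fraction * n)
      if (n_debris > 0) {
        debris <- data.frame(`FSC-H` = draw(n_debris, 1.5),
                             `SSC-H` = draw(n_debris, 1.0),
                             `BL1-H` = draw(n_debris, 1.0),
                             `BL3-H` = draw(n_debris, 1.0),
                             `RL1-H` = draw(n_debris, 1.5),
                             check.names = FALSE)
        ev <- rbind(ev, debris)
        truth <- c(truth, rep("debris", n_debris))
      }
    }
    # singlet area tracks height; doublets sum areas at near-single height
    ev[["BL1-A"]] <- ev[["BL1-H"]] * exp(stats::rnorm(nrow(ev), 0, 0.02))
    if (config$doublet_fraction > 0) {
      n_dbl <- round(config$doublet_fraction * n)
      if (n_dbl > 0) {
        i1 <- sample(seq_len(n), n_dbl, replace = TRUE)
        i2 <- sample(seq_len(n), n_dbl, replace = TRUE)
        dbl <- ev[i1, ]
        for (ch in c("FSC-H", "SSC-H", "BL1-H", "BL3-H", "RL1-H"))
          dbl[[ch]] <- pmax(ev[[ch]][i1], ev[[ch]][i2]) * 1.1
        dbl[["BL1-A"]] <- ev[["BL1-A"]][i1] + ev[["BL1-A"]][i2]
        ev <- rbind(ev, dbl)
        truth <- c(truth, rep("doublet", n_dbl))
      }
    }
    out <- event_table(ev, volume_mL = config$volume_mL,
                       dilution_factor = config$dilution_factor,
                       panel = panel)
    attr(out, "truth") <- truth
    out
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed", x$seed, "):",
      length(x$components), "components x",
      x$n_proteins_per_component, "proteins;",
      sprintf("phi_ribo(mu) = %.3g + %.3g mu; mu_max = %.3g 1/h\n",
              x$alloc_intercept, x$alloc_slope, x$mu_max))
  invisible(x)
}

#' @export
print.sample_series <- function(x, ...) {
  cat("sample_series (", attr(x, "limitation"), "limitation ):",
      nrow(x), "time points over", max(x$time), "h\n")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
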