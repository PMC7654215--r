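# Seeded generators for every input the screening pipeline consumes:
# replicated expression intensities, a scale-free interactome with a planted
# high-centrality module, chemical-protein links, disease-association
# tables, survival cohorts and nuclear morphometry tables.  Planted truth is
# always attached to the output so recovery can be tested.
#
# One global seed fans out to per-generator substreams through fixed offsets,
# so adding or re-running one generator never perturbs the others.
.seed_offset <- c(expression = 11L, interactome = 23L, chemicals = 37L,
                  disease = 41L, survival = 53L, morphometry = 67L)

# Beta(a, b) truncated to [lo, 1]: used for planted-truth edges so that the
# planted wiring survives the medium-confidence (0.400) filter by
# construction, keeping recovery well-defined.
rbeta_trunc <- function(n, a, b, lo) {
  stats::qbeta(stats::runif(n, stats::pbeta(lo, a, b), 1), a, b)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable the generators use.  The defaults are the study
#' conditions of the package's own end-to-end experiments; see the methods
#' vignette for the rationale behind each value.
#'
#' @param seed Integer master seed; identical configurations produce
#'   byte-identical outputs.
#' @param n_genes Number of genes on the expression arrays.
#' @param n_replicates Number of replicate arrays.
#' @param frac_expressed Fraction of genes drawn from the high-intensity
#'   ("constitutively expressed") component.
#' @param expression_separation Separation between the expressed and noise
#'   components, in units of the log-intensity SD.
#' @param n_proteins Number of protein nodes in the interactome.
#' @param attachment_parameter Edges added per new node by the
#'   preferential-attachment process (>= 1).
#' @param planted_module_size Size of the planted high-centrality module.
#' @param module_spokes Extra random edges wired from each module node into
#'   the rest of the interactome.
#' @param chemicals Character vector of chemical identifiers.
#' @param targets_per_chemical Protein targets assigned to each chemical.
#' @param n_patients Cohort size for the survival generator.
#' @param planted_log_hazard Additive log-hazard for above-median expression
#'   of a planted gene.
#' @param censoring_rate Independent censoring probability per patient.
#' @param n_nuclei Nuclei generated per morphometry group.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 1000L,
                         n_replicates = 3L,
                         frac_expressed = 0.05,
                         expression_separation = 6,
                         n_proteins = 1000L,
                         attachment_parameter = 2L,
                         planted_module_size = 10L,
                         module_spokes = 12L,
                         chemicals = c("RSV", "DOXO"),
                         targets_per_chemical = 6L,
                         n_patients = 500L,
                         planted_log_hazard = 1.0,
                         censoring_rate = 0.2,
                         n_nuclei = 200L) {
  assert_count(seed + 1L, "seed")  # allow seed = 0
  for (nm in c("n_genes", "n_replicates", "n_proteins", "attachment_parameter",
               "planted_module_size", "module_spokes", "targets_per_chemical",
               "n_patients", "n_nuclei"))
    assert_count(get(nm), nm)
  assert_fraction(frac_expressed, "frac_expressed")
  assert_fraction(censoring_rate, "censoring_rate")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates), frac_expressed = frac_expressed,
    expression_separation = expression_separation,
    n_proteins = as.integer(n_proteins),
    attachment_parameter = as.integer(attachment_parameter),
    planted_module_size = as.integer(planted_module_size),
    module_spokes = as.integer(module_spokes),
    chemicals = as.character(chemicals),
    targets_per_chemical = as.integer(targets_per_chemical),
    n_patients = as.integer(n_patients),
    planted_log_hazard = planted_log_hazard,
    censoring_rate = censoring_rate, n_nuclei = as.integer(n_nuclei)
  ), class = "synth_config")
}

synth_seed <- function(cfg, stream) {
  (cfg$seed * 97L + .seed_offset[[stream]]) %% 2147483629L
}

#' Generate a replicated expression intensity matrix
#'
#' Intensities are log-normal with two components: a baseline noise
#' component and a high-intensity component `expression_separation` SDs
#' above it on the log scale, emulating present/absent transcript calls on
#' replicated arrays.  Component membership is per gene and shared across
#' replicates; replicate values are otherwise independent.  The planted
#' expressed genes are recorded in the `planted` attribute.
#'
#' @param cfg A [synth_config()].
#' @param gene_ids Optional gene identifiers (default `G0001`, ...).
#' @param planted_genes Optional explicit set of expressed genes; overrides
#'   `frac_expressed`-based sampling (must be a subset of `gene_ids`).
#' @return Numeric matrix (genes x replicates, positive intensities) with a
#'   `planted` attribute naming the expressed genes.
#' @export
gen_expression_dataset <- function(cfg, gene_ids = NULL, planted_genes = NULL) {
  n <- cfg$n_genes
  gene_ids <- gene_ids %||% sprintf("G%04d", seq_len(n))
  if (length(gene_ids) != n)
    stop_hb("hb_bad_argument", "gene_ids must have length n_genes (%d)", n)
  with_seed(synth_seed(cfg, "expression"), {
    if (is.null(planted_genes)) {
      n_planted <- floor(cfg$frac_expressed * n)
      if (n_planted < 1)
        warning("no expressed genes planted", call. = FALSE)
      planted_genes <- sort(sample(gene_ids, n_planted))
    } else {
      if (!all(planted_genes %in% gene_ids))
        stop_hb("hb_bad_argument", "planted_genes must be a subset of gene_ids")
      planted_genes <- sort(unique(planted_genes))
    }
    meanlog <- 6; sdlog <- 0.5
    shift <- cfg$expression_separation * sdlog
    mu <- ifelse(gene_ids %in% planted_genes, meanlog + shift, meanlog)
    m <- matrix(stats::rlnorm(n * cfg$n_replicates, meanlog = mu, sdlog = sdlog),
                nrow = n, ncol = cfg$n_replicates,
                dimnames = list(gene_ids, sprintf("R%d", seq_len(cfg$n_replicates))))
    attr(m, "planted") <- planted_genes
    m
  })
}

#' Generate a scale-free interactome with a planted central module
#'
#' The backbone is a preferential-attachment graph (heavy-tailed degrees,
#' as hub-bottleneck analysis presumes).  A module of
#' `planted_module_size` nodes is then densified into a clique and wired
#' outward with `module_spokes` random edges per member, so module members
#' have above-average degree and betweenness.  Two spoke endpoints per
#' member are designated "anchors" (recorded in metadata): downstream
#' fixtures include them alongside the module so that the module remains a
#' hub and a bottleneck in induced subnetworks.  Edge confidences are
#' Beta(5, 2), so a 0.400 cutoff removes a nontrivial minority of edges.
#'
#' @param cfg A [synth_config()].
#' @return An [interaction_table()] with attributes `module` (planted node
#'   ids) and `anchors` (designated non-module neighbours of the module).
#' @export
gen_interactome <- function(cfg) {
  n <- cfg$n_proteins
  m <- cfg$attachment_parameter
  if (m >= n)
    stop_hb("hb_degenerate_generator",
            "degenerate generator: attachment_parameter >= n_proteins")
  if (n <= cfg$planted_module_size)
    stop_hb("hb_bad_argument", "n_proteins must exceed planted_module_size")
  ids <- sprintf("P%04d", seq_len(n))
  with_seed(synth_seed(cfg, "interactome"), {
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    module <- sort(sample(n, cfg$planted_module_size))
    # densify the module into a clique
    cl <- t(utils::combn(module, 2L))
    # spokes: random edges from each module node into the periphery
    spokes <- do.call(rbind, lapply(module, function(v) {
      nb <- sample(setdiff(seq_len(n), module), cfg$module_spokes)
      cbind(v, nb)
    }))
    anchors <- sort(unique(as.vector(t(
      do.call(rbind, lapply(seq_along(module), function(i) {
        rows <- spokes[spokes[, 1] == module[i], 2]
        rows[1:2]
      }))))))
    all_e <- rbind(el, cl, spokes)
    conf <- stats::rbeta(nrow(all_e), 5, 2)
    # anchor spokes are part of the planted truth: confidence above the
    # medium cutoff by construction
    anchor_rows <- nrow(el) + nrow(cl) + which(spokes[, 2] %in% anchors)
    conf[anchor_rows] <- rbeta_trunc(length(anchor_rows), 5, 2, 0.4)
    tab <- interaction_table(ids[all_e[, 1]], ids[all_e[, 2]], conf)
    attr(tab, "module") <- ids[module]
    attr(tab, "anchors") <- ids[anchors]
    tab
  })
}

#' Add chemical-protein edges to an interaction table
#'
#' Emulates a chemical-protein interaction resource: each chemical receives
#' `targets_per_chemical` protein targets.  By default targets are sampled
#' so that every chemical hits the planted module (when module metadata is
#' present): `module_targets` per chemical come from the module and the
#' rest from other proteins.  Explicit targets can be supplied instead.
#'
#' @param table An [interaction_table()] of protein-protein edges.
#' @param chemicals Character vector of chemical identifiers.
#' @param targets_per_chemical Number of protein targets per chemical.
#' @param cfg A [synth_config()] (supplies the RNG substream).
#' @param module_targets How many of each chemical's targets are drawn from
#'   the planted module (ignored when `targets` is given or no module
#'   metadata exists).
#' @param targets Optional named list, one character vector of protein ids
#'   per chemical; unknown protein identifiers are an error.
#' @return The input table augmented with chemical-protein edges
#'   (`kind = "chemical"` endpoints); attribute `chemical_targets` records
#'   the target map, module/anchors metadata is preserved.
#' @export
gen_chemical_links <- function(table, chemicals, targets_per_chemical, cfg,
                               module_targets = 4L, targets = NULL) {
  proteins <- unique(c(table$node_a[table$kind_a == "protein"],
                       table$node_b[table$kind_b == "protein"]))
  module <- attr(table, "module")
  with_seed(synth_seed(cfg, "chemicals"), {
    if (is.null(targets)) {
      targets <- lapply(seq_along(chemicals), function(i) {
        n_mod <- if (is.null(module)) 0L else min(module_targets, targets_per_chemical,
                                                  length(module))
        from_mod <- if (n_mod > 0) sample(module, n_mod) else character(0)
        pool <- setdiff(proteins, c(from_mod, module))
        c(from_mod, sample(pool, targets_per_chemical - n_mod))
      })
      names(targets) <- chemicals
    } else {
      if (!all(chemicals %in% names(targets)))
        stop_hb("hb_bad_argument", "targets must be named by chemical")
      bad <- setdiff(unique(unlist(targets[chemicals])), proteins)
      if (length(bad))
        stop_hb("hb_unknown_target",
                "unknown protein identifier(s) among targets: %s",
                paste(bad, collapse = ", "))
      targets <- lapply(targets[chemicals], unique)
    }
    chem_a <- rep(chemicals, lengths(targets[chemicals]))
    prot_b <- unlist(targets[chemicals], use.names = FALSE)
    conf <- stats::rbeta(length(chem_a), 5, 2)
    # planted drug-target links (chemical -> module) pass the medium cutoff
    # by construction
    if (!is.null(module)) {
      in_mod <- prot_b %in% module
      conf[in_mod] <- rbeta_trunc(sum(in_mod), 5, 2, 0.4)
    }
    add <- data.frame(node_a = chem_a, node_b = prot_b, confidence = conf,
                      kind_a = "chemical", kind_b = "protein",
                      stringsAsFactors = FALSE)
    out <- clean_interactions(rbind(as.data.frame(table), add))
    attr(out, "module") <- module
    attr(out, "anchors") <- attr(table, "anchors")
    attr(out, "chemical_targets") <- targets[chemicals]
    out
  })
}

#' Generate a gene-disease association table
#'
#' Rows of (gene, confidence) on a configurable scale (default \[0, 1\]).
#' Planted genes receive maximal confidence; the remainder draw from a
#' Beta(2, 2) stretched to the scale.
#'
#' @param genes Character vector of gene identifiers.
#' @param cfg A [synth_config()].
#' @param planted Genes assigned maximal confidence (default none).
#' @param scale_max Top of the confidence scale (default 1).
#' @return Data.frame with columns `gene`, `confidence`.
#' @export
gen_disease_table <- function(genes, cfg, planted = character(0), scale_max = 1) {
  if (length(genes) == 0L)
    stop_hb("hb_bad_argument", "genes must be nonempty")
  with_seed(synth_seed(cfg, "disease"), {
    conf <- stats::rbeta(length(genes), 2, 2) * scale_max
    conf[genes %in% planted] <- scale_max
    data.frame(gene = genes, confidence = conf, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic patient survival cohort
#'
#' Per-gene expression is standard normal across patients.  Survival times
#' are exponential with baseline hazard `log(2)/60` per month (median 60
#' months); each planted gene adds `planted_log_hazard` to the log hazard
#' of patients whose expression of that gene is above the cohort median.
#' Censoring is independent: with probability `censoring_rate` a patient is
#' censored at a uniform fraction of their event time.
#'
#' @param genes Character vector of gene columns to simulate.
#' @param planted Subset of `genes` whose expression is hazard-linked.
#' @param cfg A [synth_config()].
#' @return A `survival_table` data.frame (`patient_id`, `time_months`,
#'   `event`, one column per gene) with attribute `planted`.
#' @export
gen_survival_cohort <- function(genes, planted, cfg) {
  if (!all(planted %in% genes))
    stop_hb("hb_bad_argument", "planted must be a subset of genes")
  if (cfg$censoring_rate >= 1)
    stop_hb("hb_bad_argument", "censoring_rate must be < 1")
  n <- cfg$n_patients
  with_seed(synth_seed(cfg, "survival"), {
    expr <- matrix(stats::rnorm(n * length(genes)), nrow = n,
                   dimnames = list(NULL, genes))
    loghaz <- rep(log(log(2) / 60), n)
    for (g in planted) {
      high <- expr[, g] >= stats::median(expr[, g])
      loghaz <- loghaz + cfg$planted_log_hazard * high
    }
    time <- stats::rexp(n, rate = exp(loghaz))
    event <- stats::rbinom(n, 1L, 1 - cfg$censoring_rate)
    time[event == 0L] <- time[event == 0L] * stats::runif(sum(event == 0L))
    df <- data.frame(patient_id = sprintf("PT%04d", seq_len(n)),
                     time_months = time, event = event,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(expr))
    out <- as_survival_table(df)
    attr(out, "planted") <- planted
    out
  })
}

# per-class generative shifts (units of the control SD); within-class
# dispersion is 0.8x the control SD -- see the methods vignette.
.nma_shift <- list(
  N   = c(area = 0,  nii = 0),
  SR  = c(area = -4.5, nii = 0),
  SI  = c(area = -4.5, nii = 4),
  LR  = c(area = 7,  nii = 0),
  LIr = c(area = 7,  nii = 4)
)

# control-reference distribution of the four shape metrics + area
.nma_ref <- list(
  area = c(mean = 100, sd = 10),
  aspect = c(mean = 1.3, sd = 0.08),
  areabox = c(mean = 0.78, sd = 0.04),
  radius_ratio = c(mean = 1.5, sd = 0.12),
  roundness = c(mean = 1.1, sd = 0.08)
)

#' Generate nuclear morphometry records
#'
#' Samples `n_nuclei` nucleus records per group from per-class
#' distributions: area and shape metrics are shifted relative to a control
#' reference according to the class (small/large in area, irregular in the
#' shape metrics feeding the nuclear irregularity index).  The true class is
#' recorded in the `true_class` column.
#'
#' @param cfg A [synth_config()].
#' @param group_fractions Named numeric vector over classes
#'   (`N`, `SR`, `SI`, `LR`, `LIr`) summing to 1.
#' @return Data.frame with columns `area`, `aspect`, `areabox`,
#'   `radius_ratio`, `roundness`, `true_class`.
#' @export
gen_morphometry <- function(cfg, group_fractions = c(N = 1)) {
  classes <- names(.nma_shift)
  if (!all(names(group_fractions) %in% classes))
    stop_hb("hb_bad_argument", "unknown class in group_fractions")
  if (abs(sum(group_fractions) - 1) > 1e-9)
    stop_hb("hb_bad_argument", "group_fractions must sum to 1")
  n <- cfg$n_nuclei
  # largest-remainder apportionment so counts sum exactly to n
  raw <- group_fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  with_seed(synth_seed(cfg, "morphometry"), {
    rows <- lapply(names(cnt)[cnt > 0], function(cl) {
      k <- cnt[[cl]]
      sh <- .nma_shift[[cl]]
      area <- stats::rnorm(k,
        mean = .nma_ref$area["mean"] + sh["area"] * .nma_ref$area["sd"],
        sd = 0.8 * .nma_ref$area["sd"])
      # irregularity shift is split between the two positively-entering
      # shape terms (aspect and radius ratio)
      nii_sd <- sqrt(sum(vapply(.nma_ref[-1], `[[`, 0, "sd")^2))
      asp <- stats::rnorm(k, .nma_ref$aspect["mean"] +
                            sh["nii"] / 2 * nii_sd * 0.5,
                          0.8 * .nma_ref$aspect["sd"])
      arbx <- stats::rnorm(k, .nma_ref$areabox["mean"],
                           0.8 * .nma_ref$areabox["sd"])
      rr <- stats::rnorm(k, .nma_ref$radius_ratio["mean"] +
                           sh["nii"] / 2 * nii_sd * 1.5,
                         0.8 * .nma_ref$radius_ratio["sd"])
      rou <- stats::rnorm(k, .nma_ref$roundness["mean"],
                          0.8 * .nma_ref$roundness["sd"])
      data.frame(area = pmax(area, 1),
                 aspect = pmax(asp, 1),
                 areabox = pmin(pmax(arbx, 0.01), 1),
                 radius_ratio = pmax(rr, 1),
                 roundness = pmax(rou, 0.01),
                 true_class = cl, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a control morphometry reference sample
#'
#' Control nuclei drawn from the untreated reference distribution, used to
#' derive classification thresholds.
#'
#' @param cfg A [synth_config()].
#' @return Data.frame of nucleus records (no class column).
#' @export
gen_morphometry_control <- function(cfg) {
  with_seed(synth_seed(cfg, "morphometry") + 1L, {
    n <- cfg$n_nuclei
    data.frame(
      area = stats::rnorm(n, .nma_ref$area["mean"], .nma_ref$area["sd"]),
      aspect = pmax(stats::rnorm(n, .nma_ref$aspect["mean"], .nma_ref$aspect["sd"]), 1),
      areabox = pmin(pmax(stats::rnorm(n, .nma_ref$areabox["mean"], .nma_ref$areabox["sd"]), 0.01), 1),
      radius_ratio = pmax(stats::rnorm(n, .nma_ref$radius_ratio["mean"], .nma_ref$radius_ratio["sd"]), 1),
      roundness = pmax(stats::rnorm(n, .nma_ref$roundness["mean"], .nma_ref$roundness["sd"]), 0.01),
      stringsAsFactors = FALSE
    )
  })
}
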