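# End-to-end orchestration of the screening workflow: expression calling ->
# cell-line network -> chemical attachment -> disease network ->
# intersection -> centrality/H-B on all three -> consensus core ->
# drug-adjacency -> regulation overlay -> survival screen ->
# pathway-interface -> final candidates.

#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration with every threshold the
#' workflow applies.  The defaults are the thresholds of the screening
#' procedure itself: interaction confidence 0.400 (medium), rank-product
#' significance 0.01, disease-association maximal confidence 1 with a
#' top-1000 cap, enrichment FDR 0.0001 and survival screen alpha 0.05.
#'
#' @param seed Master seed; forwarded to [synth_config()] unless `synth`
#'   is supplied.
#' @param synth A [synth_config()] describing the synthetic inputs.
#' @param confidence_cutoff Edge-confidence cutoff for every network build.
#' @param rp_alpha,rp_n_perm,rp_call_on Rank-product calling parameters.
#' @param disease_cutoff,disease_top_n Disease-gene selection parameters.
#' @param km_alpha Survival screen significance level.
#' @param enrich_alpha Enrichment FDR threshold.
#' @param out_dir Optional directory; when set, every stage's artifact is
#'   persisted as TSV.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synth = synth_config(seed = seed),
                            confidence_cutoff = 0.400,
                            rp_alpha = 0.01,
                            rp_n_perm = 200L,
                            rp_call_on = "p",
                            disease_cutoff = 1,
                            disease_top_n = 1000L,
                            km_alpha = 0.05,
                            enrich_alpha = 1e-4,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), synth = synth,
                 confidence_cutoff = confidence_cutoff,
                 rp_alpha = rp_alpha, rp_n_perm = as.integer(rp_n_perm),
                 rp_call_on = rp_call_on,
                 disease_cutoff = disease_cutoff,
                 disease_top_n = as.integer(disease_top_n),
                 km_alpha = km_alpha, enrich_alpha = enrich_alpha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Generate the full set of synthetic pipeline inputs
#'
#' Produces every table the workflow consumes, wired so the planted module
#' is recoverable: the constitutively-expressed gene set and the
#' maximal-confidence disease genes both contain the module and its anchor
#' neighbours (co-expression and disease clustering of a functional
#' module), and each chemical targets part of the module plus decoy
#' proteins.
#'
#' @param cfg A [synth_config()].
#' @return List with `expression`, `interactome` (protein-protein
#'   [interaction_table()]), `cp_links` (the same table plus
#'   chemical-protein edges), `disease_table`, `pathways` (gene-set list),
#'   `de_table` (named regulation vector) and `truth` (planted metadata:
#'   `module`, `anchors`, `expressed`, `chemical_targets`,
#'   `planted_candidates`, `decoys`).
#' @export
synthesize_pipeline_inputs <- function(cfg) {
  if (cfg$n_genes != cfg$n_proteins)
    stop_hb("hb_bad_argument",
            "pipeline synthesis assumes n_genes == n_proteins (gene ids are protein ids)")
  interactome <- gen_interactome(cfg)
  module <- attr(interactome, "module")
  anchors <- attr(interactome, "anchors")
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))

  n_expressed <- max(floor(cfg$frac_expressed * cfg$n_genes),
                     length(module) + length(anchors))
  with_seed(synth_seed(cfg, "expression") + 7L, {
    fill <- sample(setdiff(proteins, c(module, anchors)),
                   max(n_expressed - length(module) - length(anchors), 0L))
  })
  expressed <- sort(c(module, anchors, fill))
  expression <- gen_expression_dataset(cfg, gene_ids = proteins,
                                       planted_genes = expressed)

  cp_links <- gen_chemical_links(interactome, cfg$chemicals,
                                 cfg$targets_per_chemical, cfg)
  targets <- attr(cp_links, "chemical_targets")

  disease_table <- gen_disease_table(proteins, cfg,
                                     planted = c(module, anchors))

  # three overlapping cellular-process gene sets anchored on the module
  with_seed(synth_seed(cfg, "disease") + 13L, {
    k <- length(module)
    blocks <- list(seq_len(ceiling(k / 2)),
                   seq(floor(k / 3), min(floor(k / 3) + ceiling(k / 2), k)),
                   unique(c(1L, seq(max(k - ceiling(k / 2), 1L), k))))
    pathways <- lapply(blocks, function(b) {
      sort(unique(c(module[b], anchors,
                    sample(setdiff(proteins, module), 40L))))
    })
    names(pathways) <- c("process_apoptosis", "process_senescence",
                         "process_autophagy")
    de_pool <- sample(c("up", "down", "none"), cfg$n_proteins,
                      replace = TRUE, prob = c(0.25, 0.25, 0.5))
    de_table <- stats::setNames(de_pool, proteins)
    de_table[module] <- "up"
  })

  planted_candidates <- sort(base::intersect(module, unlist(targets)))
  decoys <- sort(unique(c(setdiff(expressed, module),
                          setdiff(unlist(targets), module))))
  list(expression = expression, interactome = interactome,
       cp_links = cp_links, disease_table = disease_table,
       pathways = pathways, de_table = de_table,
       truth = list(module = module, anchors = anchors,
                    expressed = expressed, chemical_targets = targets,
                    planted_candidates = planted_candidates,
                    decoys = decoys))
}

empty_report <- function(config, log, warnings) {
  structure(list(config = config, stage_log = log, degraded = TRUE,
                 warnings = warnings, final_candidates = character(0)),
            class = "pipeline_report")
}

#' Run the screening pipeline end to end
#'
#' Executes, in order: rank-product expression calling; cell-line network
#' build at the confidence cutoff; chemical attachment; disease-gene
#' selection and disease network build; chemical attachment there too;
#' network intersection; centrality and hub-bottleneck classification on
#' all three networks; consensus H-B core; drug-adjacency partition;
#' regulation annotation; enrichment of the intersection network;
#' median-split Kaplan-Meier screening of the drug-adjacent consensus H-B
#' genes; pathway-interface ranking of the survivors; and the final
#' candidate list (KM-significant drug-adjacent consensus H-B genes that
#' are H-B in the merged pathway network).  Every stage's parameters and
#' row counts are logged in the report.
#'
#' @param config A [pipeline_config()] (or an integer seed, taken as
#'   `pipeline_config(seed)`).
#' @param inputs Optional pre-built inputs as returned by
#'   [synthesize_pipeline_inputs()]; generated from the configuration when
#'   omitted.
#' @return A `pipeline_report` object; see [print.pipeline_report()].
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL) {
  if (is.numeric(config)) config <- pipeline_config(seed = config)
  cfg <- config$synth
  log <- list()
  note <- function(stage, ...) {
    entry <- list(...)
    log[[stage]] <<- entry
    message(sprintf("[%s] %s", stage,
                    paste(names(entry), unlist(entry), sep = "=",
                          collapse = " ")))
  }

  inputs <- inputs %||% synthesize_pipeline_inputs(cfg)
  truth <- inputs$truth

  ## 1. rank-product expression calling
  rp <- rp_significance(inputs$expression, n_perm = config$rp_n_perm,
                        seed = synth_seed(cfg, "expression") + 1L,
                        alpha = config$rp_alpha, call_on = config$rp_call_on)
  called <- rp$gene[rp$called]
  note("rankprod", alpha = config$rp_alpha, n_perm = config$rp_n_perm,
       called = length(called))

  ## 2. cell-line PPI: interactome induced on called genes
  pp <- inputs$interactome
  sub <- pp[pp$node_a %in% called & pp$node_b %in% called, , drop = FALSE]
  class(sub) <- class(pp)
  if (nrow(sub) == 0L)
    return(empty_report(config, log, "no interactions among called genes"))
  cell_ppi <- build_network(sub, config$confidence_cutoff)
  note("cell_line_ppi", cutoff = config$confidence_cutoff,
       nodes = igraph::vcount(cell_ppi), edges = igraph::ecount(cell_ppi))

  ## 3. chemical attachment (cell line)
  chem_tab <- inputs$cp_links
  cell_cp <- attach_chemicals(cell_ppi, chem_tab, config$confidence_cutoff)
  chems_present <- base::intersect(cfg$chemicals, igraph::V(cell_cp)$name)
  if (length(chems_present) == 0L)
    stop_hb("hb_attach_failed",
            "no chemical could be attached to the cell-line network")
  note("cell_line_cp", nodes = igraph::vcount(cell_cp),
       edges = igraph::ecount(cell_cp))

  ## 4. disease-gene selection and disease network
  disease_genes <- select_disease_genes(inputs$disease_table,
                                        config$disease_cutoff,
                                        config$disease_top_n)
  note("disease_genes", cutoff = config$disease_cutoff,
       top_n = config$disease_top_n, selected = length(disease_genes))
  sub_d <- pp[pp$node_a %in% disease_genes & pp$node_b %in% disease_genes, ,
              drop = FALSE]
  class(sub_d) <- class(pp)
  if (nrow(sub_d) == 0L)
    return(empty_report(config, log, "no interactions among disease genes"))
  disease_ppi <- build_network(sub_d, config$confidence_cutoff)
  disease_cp <- attach_chemicals(disease_ppi, chem_tab,
                                 config$confidence_cutoff)
  note("disease_cp", nodes = igraph::vcount(disease_cp),
       edges = igraph::ecount(disease_cp))

  ## 5. intersection
  inter <- intersect_networks(cell_cp, disease_cp)
  note("intersection", nodes = igraph::vcount(inter),
       edges = igraph::ecount(inter))
  if (igraph::vcount(inter) == 0L)
    return(empty_report(config, log, "empty network intersection"))

  ## 6. centralities + H-B on all three networks, consensus core
  reports <- list(cell_line = centrality_report(cell_cp),
                  disease = centrality_report(disease_cp),
                  intersection = centrality_report(inter))
  hb_sets <- lapply(reports, function(r) r$node[r$hb_class == "H-B"])
  consensus <- consensus_hb(hb_sets)
  note("consensus_hb", cell_line = length(hb_sets$cell_line),
       disease = length(hb_sets$disease),
       intersection = length(hb_sets$intersection),
       consensus = length(consensus$consensus))

  ## 7. drug adjacency (in the intersection network) + regulation overlay
  chems_in_inter <- base::intersect(cfg$chemicals, igraph::V(inter)$name)
  adjacency <- if (length(chems_in_inter)) drug_adjacent(inter, chems_in_inter)
               else list()
  inter <- annotate_regulation(inter, inputs$de_table)
  candidate_pool <- sort(base::intersect(
    consensus$consensus, names(adjacency)))
  note("drug_adjacent", adjacent = length(adjacency),
       pool = length(candidate_pool))

  ## 8. enrichment of the intersection network (reporting)
  inter_prot <- igraph::V(inter)$name[igraph::V(inter)$kind == "protein"]
  enrich <- hypergeometric_enrichment(
    inter_prot, inputs$pathways,
    universe = unique(c(inputs$interactome$node_a, inputs$interactome$node_b,
                        inter_prot)),
    alpha = config$enrich_alpha)
  note("enrichment", significant = sum(enrich$significant))

  if (length(candidate_pool) == 0L)
    return(empty_report(config, log, "no drug-adjacent consensus H-B genes"))

  ## 9. survival screen of the candidate pool
  cohort <- gen_survival_cohort(candidate_pool,
                                base::intersect(candidate_pool, truth$module),
                                cfg)
  km <- km_screen(cohort, candidate_pool, alpha = config$km_alpha)
  km_sig <- km$gene[km$significant]
  note("km_screen", alpha = config$km_alpha, screened = nrow(km),
       significant = length(km_sig))

  ## 10. pathway-interface ranking of the survivors
  if (length(km_sig)) {
    pi_res <- pathway_interface(km_sig, inputs$pathways, inputs$interactome,
                                config$confidence_cutoff)
    pw_hb <- pi_res$candidate_report$gene[
      !is.na(pi_res$candidate_report$hb_class) &
        pi_res$candidate_report$hb_class == "H-B"]
  } else {
    pi_res <- NULL
    pw_hb <- character(0)
  }
  final <- sort(pw_hb)
  note("final", candidates = length(final))

  ## funnel invariant: final <= pathway H-B <= KM-significant <= pool
  stopifnot(all(final %in% km_sig), all(km_sig %in% candidate_pool),
            all(candidate_pool %in% consensus$consensus))

  report <- structure(list(
    config = config, stage_log = log, degraded = FALSE, warnings = character(0),
    rp = rp, called_genes = called,
    networks = list(cell_line = cell_cp, disease = disease_cp,
                    intersection = inter),
    centrality = reports, hb_sets = hb_sets, consensus = consensus,
    drug_adjacency = adjacency, regulation = inputs$de_table,
    enrichment = enrich, candidate_pool = candidate_pool,
    km = km, km_significant = km_sig,
    pathway_interface = pi_res, pathway_hb = pw_hb,
    final_candidates = final, truth = truth
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

persist_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(report$rp), file.path(dir, "rankprod.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$networks))
    write_network(report$networks[[nm]],
                  file.path(dir, paste0(nm, "_edges.tsv")),
                  file.path(dir, paste0(nm, "_nodes.tsv")))
  for (nm in names(report$centrality))
    utils::write.table(report$centrality[[nm]],
                       file.path(dir, paste0(nm, "_centrality.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$consensus$venn, file.path(dir, "consensus_venn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$km), file.path(dir, "km_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$pathway_interface))
    utils::write.table(report$pathway_interface$candidate_report,
                       file.path(dir, "pathway_interface.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$final_candidates, file.path(dir, "final_candidates.txt"))
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Hub-bottleneck screening pipeline report\n")
  if (isTRUE(x$degraded)) {
    cat("  DEGRADED:", paste(x$warnings, collapse = "; "), "\n")
    return(invisible(x))
  }
  sizes <- vapply(x$networks, function(g)
    sprintf("%d nodes / %d edges", igraph::vcount(g), igraph::ecount(g)), "")
  cat(sprintf("  expressed genes called: %d\n", length(x$called_genes)))
  for (nm in names(sizes)) cat(sprintf("  %-12s %s\n", nm, sizes[[nm]]))
  cat(sprintf("  H-B: cell_line %d, disease %d, intersection %d; consensus core %d\n",
              length(x$hb_sets$cell_line), length(x$hb_sets$disease),
              length(x$hb_sets$intersection), length(x$consensus$consensus)))
  cat(sprintf("  drug-adjacent consensus H-B pool: %d\n",
              length(x$candidate_pool)))
  cat(sprintf("  KM-significant: %d; H-B in pathway network: %d\n",
              length(x$km_significant), length(x$pathway_hb)))
  cat("  final candidates:",
      if (length(x$final_candidates)) paste(x$final_candidates, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
summary.pipeline_report <- function(object, ...) {
  print(object)
  if (!isTRUE(object$degraded)) {
    cat("\nSurvival screen:\n")
    print.data.frame(as.data.frame(object$km), digits = 3)
    if (!is.null(object$pathway_interface)) {
      cat("\nPathway-interface report:\n")
      print.data.frame(object$pathway_interface$candidate_report, digits = 3)
    }
  }
  invisible(object)
}
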