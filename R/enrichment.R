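# Hypergeometric gene-set over-representation with Benjamini-Hochberg FDR,
# and the pathway-interface procedure that re-ranks candidate genes inside
# a merged pathway network.

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap: population `universe`, successes the set's
#' genes (intersected with the universe first), draws the query.  FDR by
#' Benjamini-Hochberg across the collection; a set is significant when
#' `fdr <= alpha` (default 0.0001).
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector, the gene universe.
#' @param alpha FDR significance threshold (default 1e-4).
#' @return Data.frame with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `fdr`, `significant`.
#' @export
hypergeometric_enrichment <- function(query, collection, universe,
                                      alpha = 1e-4) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L || length(query) == 0L)
    stop_hb("hb_bad_argument", "query and universe must be nonempty")
  if (!all(query %in% universe))
    stop_hb("hb_bad_argument", "query genes must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- base::intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(base::intersect(set, query))
    # P(X >= k), inclusive of the observed overlap
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr <= alpha
  out
}

#' Pathway-interface ranking of candidate genes
#'
#' Places candidate genes in the context of a set of cellular-process
#' pathways: (1) Venn membership of each candidate across the pathway sets;
#' (2) a merged network induced from the interactome over the union of all
#' pathway genes and the candidates, at the confidence cutoff; (3)
#' centralities, hub-bottleneck classification and quarters on that
#' network; (4) a per-candidate report of H-B status and quarter.
#' Candidates absent from the built network are kept in the Venn step and
#' flagged unconnected.
#'
#' @param candidates Character vector of candidate genes.
#' @param pathways Named list of pathway gene sets.
#' @param interactome An [interaction_table()] of protein-protein edges.
#' @param confidence_cutoff Minimum edge confidence (default 0.400).
#' @return List with `candidate_report` (gene, venn_membership, connected,
#'   degree, betweenness, hb_class, quarter), `records` (full centrality
#'   table of the merged network) and `network` (the merged `igraph`).
#' @export
pathway_interface <- function(candidates, pathways, interactome,
                              confidence_cutoff = 0.400) {
  if (length(candidates) == 0L)
    stop_hb("hb_bad_argument", "candidates must be nonempty")
  if (length(pathways) == 0L)
    stop_hb("hb_bad_argument", "pathways must be nonempty")
  membership <- vapply(candidates, function(g) {
    inset <- names(pathways)[vapply(pathways, function(s) g %in% s, TRUE)]
    paste(inset, collapse = "+")
  }, "")
  keep_nodes <- unique(c(unlist(pathways, use.names = FALSE), candidates))
  sub <- interactome[interactome$node_a %in% keep_nodes &
                       interactome$node_b %in% keep_nodes, , drop = FALSE]
  class(sub) <- class(interactome)
  net <- build_network(sub, confidence_cutoff)
  records <- centrality_report(net)
  idx <- match(candidates, records$node)
  rep_df <- data.frame(
    gene = candidates,
    venn_membership = unname(membership),
    connected = !is.na(idx),
    degree = records$degree[idx],
    betweenness = records$betweenness[idx],
    hb_class = records$hb_class[idx],
    quarter = records$quarter[idx],
    stringsAsFactors = FALSE)
  rownames(rep_df) <- NULL
  list(candidate_report = rep_df, records = records, network = net)
}
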