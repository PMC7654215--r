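# Degree and betweenness centrality, hub-bottleneck classification against
# network-average thresholds, median-based quarters over the H-B set, and
# consensus H-B cores across networks.

#' Compute degree and betweenness centrality
#'
#' Degree is the adjacency count.  Betweenness is the pair-fraction form:
#' for every unordered pair of distinct nodes s, t the node v (not an
#' endpoint) accrues sigma_st(v)/sigma_st, the fraction of shortest s-t
#' paths passing through v; unnormalized, unweighted (edge confidences are
#' ignored for paths), disconnected pairs contribute zero.
#'
#' @param net An `igraph` network.
#' @param include_chemicals Keep chemical nodes in the records (default
#'   TRUE; they participate in paths either way).
#' @return Data.frame with columns `node`, `kind`, `degree`, `betweenness`.
#' @export
compute_centralities <- function(net, include_chemicals = TRUE) {
  if (igraph::vcount(net) < 2L)
    stop_hb("hb_bad_argument", "centrality needs >= 2 nodes")
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, weights = NA,
                             normalized = FALSE)
  out <- data.frame(node = igraph::V(net)$name,
                    kind = igraph::V(net)$kind %||%
                      rep("protein", igraph::vcount(net)),
                    degree = unname(deg), betweenness = unname(btw),
                    stringsAsFactors = FALSE)
  if (!include_chemicals) out <- out[out$kind != "chemical", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify nodes as hubs and/or bottlenecks
#'
#' A node is a hub when its degree strictly exceeds the network mean degree
#' and a bottleneck when its betweenness strictly exceeds the network mean
#' betweenness (means over all analyzed nodes).  The two flags assemble the
#' class: `H-B`, `H-NB`, `NH-B` or `NH-NB`.
#'
#' @param records Centrality records from [compute_centralities()].
#' @return The records with an `hb_class` column; the thresholds are
#'   attached as attribute `thresholds` (`degree_mean`, `betweenness_mean`).
#' @export
classify_hb <- function(records) {
  dm <- mean(records$degree)
  bm <- mean(records$betweenness)
  hub <- records$degree > dm
  bot <- records$betweenness > bm
  records$hb_class <- paste0(ifelse(hub, "H", "NH"), "-",
                             ifelse(bot, "B", "NB"))
  attr(records, "thresholds") <- list(degree_mean = dm, betweenness_mean = bm)
  records
}

#' Induced subnetwork on the hub-bottleneck nodes
#'
#' @param net The analyzed `igraph` network.
#' @param records Classified records from [classify_hb()].
#' @return The induced subgraph on nodes with `hb_class == "H-B"` (every
#'   edge of `net` between retained nodes is kept); empty with a warning if
#'   there are none.
#' @export
hb_subnetwork <- function(net, records) {
  hb <- records$node[records$hb_class == "H-B"]
  if (length(hb) == 0L)
    warning("no H-B nodes; empty subnetwork", call. = FALSE)
  igraph::induced_subgraph(net, hb)
}

#' Assign quarters to hub-bottleneck nodes
#'
#' Quarters rank the H-B nodes against the medians of degree and
#' betweenness computed over the H-B nodes only: Q4 exceeds both medians
#' (strictly), Q3 only the degree median, Q2 only the betweenness median,
#' Q1 neither.  Non-H-B nodes get `NA`.
#'
#' @param records Classified records from [classify_hb()].
#' @return The records with a `quarter` column; the H-B medians are
#'   attached as attribute `hb_medians`.
#' @export
assign_quarters <- function(records) {
  hb <- records$hb_class == "H-B"
  if (!any(hb))
    stop_hb("hb_no_hb_nodes", "no H-B nodes to assign quarters to")
  dmed <- stats::median(records$degree[hb])
  bmed <- stats::median(records$betweenness[hb])
  hi_d <- records$degree > dmed
  hi_b <- records$betweenness > bmed
  q <- ifelse(hi_d & hi_b, 4L, ifelse(hi_d, 3L, ifelse(hi_b, 2L, 1L)))
  records$quarter <- ifelse(hb, q, NA_integer_)
  attr(records, "hb_medians") <- list(degree_median = dmed,
                                      betweenness_median = bmed)
  records
}

#' Consensus of hub-bottleneck node sets across networks
#'
#' @param classifications List (>= 2) of character vectors of node ids
#'   (e.g. the H-B sets of several networks).
#' @return List with `consensus` (the intersection, sorted) and `venn`
#'   (data.frame: node, one logical column per input set, and the
#'   membership `pattern` string) covering the union of all sets.
#' @export
consensus_hb <- function(classifications) {
  if (length(classifications) < 2L)
    stop_hb("hb_bad_argument", "consensus needs >= 2 node sets")
  nms <- names(classifications) %||% paste0("set", seq_along(classifications))
  nms[nms == ""] <- paste0("set", which(nms == ""))
  all_nodes <- sort(unique(unlist(classifications)))
  member <- vapply(classifications, function(s) all_nodes %in% s,
                   logical(length(all_nodes)))
  member <- matrix(member, nrow = length(all_nodes),
                   dimnames = list(all_nodes, nms))
  venn <- data.frame(node = all_nodes, member,
                     pattern = apply(member, 1L, function(r)
                       paste(as.integer(r), collapse = "")),
                     stringsAsFactors = FALSE, row.names = NULL)
  consensus <- all_nodes[rowSums(member) == length(classifications)]
  list(consensus = consensus, venn = venn)
}

#' Full centrality report for a network
#'
#' Convenience wrapper: centralities, H-B classification and quarters in
#' one table.
#'
#' @param net An `igraph` network.
#' @param include_chemicals Passed to [compute_centralities()].
#' @return Classified records with quarters (where H-B nodes exist).
#' @export
centrality_report <- function(net, include_chemicals = TRUE) {
  rec <- classify_hb(compute_centralities(net, include_chemicals))
  if (any(rec$hb_class == "H-B")) rec <- assign_quarters(rec)
  else rec$quarter <- NA_integer_
  rec
}
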