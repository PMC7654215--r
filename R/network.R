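# Network construction, filtering, combination and annotation.  Networks
# are simple undirected igraph objects with a vertex attribute `kind`
# ("protein"/"chemical") and an edge attribute `confidence` in [0, 1].

#' Build a network from an interaction table
#'
#' Retains edges with confidence at or above the cutoff (inclusive, the
#' convention of the medium-confidence 0.400 filter of interaction
#' databases); nodes are the endpoints of retained edges, so inputs that
#' become isolated are dropped (with a logged count).
#'
#' @param table An [interaction_table()].
#' @param confidence_cutoff Minimum edge confidence in \[0, 1\]
#'   (default 0.400).
#' @return An `igraph` network (simple, undirected) with vertex attribute
#'   `kind` and edge attribute `confidence`.
#' @export
build_network <- function(table, confidence_cutoff = 0.400) {
  if (confidence_cutoff < 0 || confidence_cutoff > 1)
    stop_hb("hb_bad_argument", "confidence_cutoff must be in [0, 1]")
  keep <- table$confidence >= confidence_cutoff
  if (!any(keep))
    stop_hb("hb_empty_network",
            "no edges at confidence >= %g (max observed %g)",
            confidence_cutoff, max(table$confidence))
  dropped_nodes <- setdiff(
    unique(c(table$node_a, table$node_b)),
    unique(c(table$node_a[keep], table$node_b[keep])))
  if (length(dropped_nodes))
    message(length(dropped_nodes), " node(s) isolated after filtering; dropped")
  df <- as.data.frame(table)[keep, , drop = FALSE]
  kinds <- c(stats::setNames(df$kind_a, df$node_a),
             stats::setNames(df$kind_b, df$node_b))
  kinds <- kinds[!duplicated(names(kinds))]
  vertices <- data.frame(name = names(kinds), kind = unname(kinds),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    df[, c("node_a", "node_b", "confidence")],
    directed = FALSE, vertices = vertices)
  igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
}

#' Select disease-associated genes by confidence cutoff and top-n
#'
#' Rows at or above the confidence cutoff, sorted by confidence descending
#' then identifier ascending (a deterministic tiebreak), truncated to
#' `top_n`.
#'
#' @param table Data.frame with columns `gene`, `confidence`.
#' @param confidence_cutoff Minimum association confidence (default 1, the
#'   maximal-confidence filter).
#' @param top_n Maximum number of genes returned (default 1000).
#' @return Character vector of selected gene ids.
#' @export
select_disease_genes <- function(table, confidence_cutoff = 1, top_n = 1000L) {
  assert_count(top_n, "top_n")
  pass <- table[table$confidence >= confidence_cutoff, , drop = FALSE]
  if (nrow(pass) == 0L) {
    warning("no disease associations pass the confidence cutoff", call. = FALSE)
    return(character(0))
  }
  ord <- order(-pass$confidence, pass$gene)
  utils::head(pass$gene[ord], top_n)
}

#' Attach chemical nodes and chemical-protein edges to a network
#'
#' Chemical-protein edges passing the cutoff whose protein endpoint exists
#' in the network are added, together with their chemical nodes
#' (`kind = "chemical"`).  Edges to absent proteins are dropped with a
#' logged count; protein-protein edges in `chem_table` are ignored.
#'
#' @param net An `igraph` network from [build_network()].
#' @param chem_table An [interaction_table()] containing chemical edges.
#' @param confidence_cutoff Minimum edge confidence (default 0.400).
#' @return The augmented network; unchanged (with a warning) if no
#'   chemical edge survives.
#' @export
attach_chemicals <- function(net, chem_table, confidence_cutoff = 0.400) {
  df <- as.data.frame(chem_table)
  is_chem_edge <- xor(df$kind_a == "chemical", df$kind_b == "chemical")
  df <- df[is_chem_edge, , drop = FALSE]
  # orient: chemical first
  swap <- df$kind_b == "chemical"
  if (any(swap)) {
    tmp <- df$node_a[swap]; df$node_a[swap] <- df$node_b[swap]; df$node_b[swap] <- tmp
  }
  df <- df[df$confidence >= confidence_cutoff, , drop = FALSE]
  present <- df$node_b %in% igraph::V(net)$name
  if (any(!present))
    message(sum(!present), " chemical edge(s) to proteins absent from the network dropped")
  df <- df[present, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no chemical edge survives; network returned unchanged", call. = FALSE)
    return(net)
  }
  new_chems <- setdiff(unique(df$node_a), igraph::V(net)$name)
  g <- igraph::add_vertices(net, length(new_chems), name = new_chems,
                            kind = "chemical")
  g <- igraph::add_edges(g, rbind(df$node_a, df$node_b),
                         confidence = df$confidence)
  igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
}

#' Intersect two networks
#'
#' The common network: nodes present in both inputs, edges whose node pair
#' is present in both (matched by identifier only), each keeping the
#' smaller of the two confidences.  An empty intersection is a warning, not
#' an error.
#'
#' @param a,b `igraph` networks.
#' @return The intersection network (simple, undirected).
#' @export
intersect_networks <- function(a, b) {
  ea <- network_edges(a); eb <- network_edges(b)
  key <- function(e) paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b),
                           sep = "\r")
  ka <- key(ea); kb <- key(eb)
  common <- base::intersect(ka, kb)
  nodes <- base::intersect(igraph::V(a)$name, igraph::V(b)$name)
  if (length(nodes) == 0L)
    warning("empty network intersection", call. = FALSE)
  ia <- match(common, ka); ib <- match(common, kb)
  conf <- pmin(ea$confidence[ia], eb$confidence[ib])
  kinds <- stats::setNames(igraph::V(a)$kind, igraph::V(a)$name)[nodes]
  # edges whose endpoints are common but that are present in only one
  # network are excluded; node set keeps all common nodes
  edf <- data.frame(node_a = ea$node_a[ia], node_b = ea$node_b[ia],
                    confidence = conf, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = data.frame(name = nodes, kind = unname(kinds),
                          stringsAsFactors = FALSE))
  igraph::simplify(g, edge.attr.comb = list(confidence = "min"))
}

#' Map protein nodes to the chemicals they are adjacent to
#'
#' "Directly modulated" nodes in the drug-target sense: each protein node
#' sharing an edge with at least one of the named chemical nodes is mapped
#' to the subset of chemicals it touches; proteins with no chemical
#' neighbour are omitted.
#'
#' @param net An `igraph` network containing the chemicals.
#' @param chemicals Character vector of chemical node names.
#' @return Named list: protein id -> character vector of adjacent chemicals.
#' @export
drug_adjacent <- function(net, chemicals) {
  missing <- setdiff(chemicals, igraph::V(net)$name[igraph::V(net)$kind == "chemical"])
  if (length(missing))
    stop_hb("hb_missing_chemical", "chemical(s) absent from network: %s",
            paste(missing, collapse = ", "))
  out <- list()
  for (chem in chemicals) {
    nb <- igraph::neighbors(net, chem)
    prots <- nb$name[nb$kind == "protein"]
    for (p in prots) out[[p]] <- c(out[[p]], chem)
  }
  lapply(out, unique)
}

#' Annotate nodes with differential-regulation status
#'
#' Sets a `regulation` vertex attribute (`"up"`, `"down"` or `"none"`) from
#' a gene-level table; genes absent from the table get `"none"`.
#'
#' @param net An `igraph` network.
#' @param de_table Named character vector gene -> `"up"|"down"|"none"`.
#' @return The annotated network.
#' @export
annotate_regulation <- function(net, de_table) {
  reg <- unname(de_table[igraph::V(net)$name])
  reg[is.na(reg)] <- "none"
  igraph::set_vertex_attr(net, "regulation", value = reg)
}

#' Edge table of a network
#'
#' @param net An `igraph` network.
#' @return Data.frame with columns `node_a`, `node_b`, `confidence`.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  data.frame(node_a = el[, 1], node_b = el[, 2],
             confidence = igraph::E(net)$confidence %||%
               rep(1, igraph::ecount(net)),
             stringsAsFactors = FALSE)
}

#' Node table of a network
#'
#' @param net An `igraph` network.
#' @return Data.frame with columns `node`, `kind` plus any extra vertex
#'   attributes (e.g. `regulation`).
#' @export
network_nodes <- function(net) {
  out <- data.frame(node = igraph::V(net)$name,
                    kind = igraph::V(net)$kind %||%
                      rep("protein", igraph::vcount(net)),
                    stringsAsFactors = FALSE)
  for (a in setdiff(igraph::vertex_attr_names(net), c("name", "kind")))
    out[[a]] <- igraph::vertex_attr(net, a)
  out
}

#' Serialize a network as a TSV edge table plus node-attribute table
#'
#' @param net An `igraph` network.
#' @param edge_path,node_path Output paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  e <- network_edges(net)
  kinds <- stats::setNames(igraph::V(net)$kind, igraph::V(net)$name)
  tab <- interaction_table(e$node_a, e$node_b, e$confidence,
                           kind_a = unname(kinds[e$node_a]),
                           kind_b = unname(kinds[e$node_b]))
  write_edge_table(tab, edge_path)
  nd <- network_nodes(net)
  long <- do.call(rbind, lapply(setdiff(names(nd), "node"), function(a)
    data.frame(node = nd$node, key = a, value = as.character(nd[[a]]),
               stringsAsFactors = FALSE)))
  write_node_attributes(long, node_path)
  invisible(net)
}

#' Read a network serialized by [write_network()]
#'
#' @param edge_path,node_path Input paths.
#' @return An `igraph` network.
#' @export
read_network <- function(edge_path, node_path) {
  tab <- read_edge_table(edge_path, dialect = "unit")
  net <- build_network(tab, confidence_cutoff = 0)
  attrs <- read_node_attributes(node_path)
  for (k in setdiff(unique(attrs$key), "kind")) {
    sub <- attrs[attrs$key == k, ]
    val <- stats::setNames(sub$value, sub$node)[igraph::V(net)$name]
    net <- igraph::set_vertex_attr(net, k, value = unname(val))
  }
  net
}
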