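# Network construction, filtering, intersection algebra, drug adjacency
# and annotation.

simple_tab <- function(a, b, conf, ...) {
  suppressMessages(interaction_table(a, b, conf, ...))
}

test_that("confidence filtering is boundary-inclusive", {
  tab <- simple_tab(c("A", "B", "C"), c("B", "C", "D"), c(0.39, 0.40, 0.95))
  net <- suppressMessages(build_network(tab, 0.400))
  expect_equal(igraph::ecount(net), 2)
  expect_false("A" %in% igraph::V(net)$name)  # isolated input dropped
  expect_equal(igraph::ecount(build_network(tab, 0)), 3)
  expect_error(build_network(tab, 0.99), class = "hb_empty_network")
  # counting oracle on a random table + cutoff monotonicity
  set.seed(12)
  rt <- random_graph_table(15, 0.5)
  rt$confidence <- runif(nrow(rt))
  for (cut in c(0.2, 0.5, 0.8)) {
    n1 <- suppressMessages(build_network(rt, cut))
    expect_equal(igraph::ecount(n1), sum(rt$confidence >= cut))
  }
  lo <- suppressMessages(build_network(rt, 0.2))
  hi <- suppressMessages(build_network(rt, 0.6))
  expect_true(all(igraph::V(hi)$name %in% igraph::V(lo)$name))
  expect_lte(igraph::ecount(hi), igraph::ecount(lo))
})

test_that("disease-gene selection sorts, tie-breaks and truncates", {
  tab <- data.frame(gene = c("Z", "A", "M", "B"),
                    confidence = c(1, 1, 1, 0.5))
  expect_equal(select_disease_genes(tab, 1, 2), c("A", "M"))
  expect_equal(select_disease_genes(tab, 1, 10), c("A", "M", "Z"))
  expect_warning(out <- select_disease_genes(tab, 2, 5), "no disease")
  expect_length(out, 0)
  # 1000-row fixture vs sort-and-slice oracle
  set.seed(21)
  big <- data.frame(gene = sprintf("g%04d", sample(1000)),
                    confidence = round(runif(1000), 3))
  got <- select_disease_genes(big, 0.5, 100)
  keep <- big[big$confidence >= 0.5, ]
  want <- head(keep$gene[order(-keep$confidence, keep$gene)], 100)
  expect_equal(got, want)
})

test_that("chemical attachment adds chemicals and drops dangling edges", {
  tab <- simple_tab(c("A", "B", "C"), c("B", "C", "A"), c(0.9, 0.9, 0.9))
  net <- build_network(tab, 0.4)
  chem <- simple_tab(c("RSV", "RSV", "DOXO", "DOXO"),
                     c("A", "ZZZ", "B", "C"), c(0.8, 0.9, 0.7, 0.2),
                     kind_a = "chemical", kind_b = "protein")
  out <- suppressMessages(attach_chemicals(net, chem, 0.4))
  # two chemicals added; edge to absent protein ZZZ and low-confidence
  # DOXO-C edge dropped
  expect_equal(igraph::vcount(out), igraph::vcount(net) + 2)
  expect_equal(sort(igraph::V(out)$name[igraph::V(out)$kind == "chemical"]),
               c("DOXO", "RSV"))
  expect_equal(igraph::ecount(out), igraph::ecount(net) + 2)
  # chemical with no passing edge is not added
  chem2 <- simple_tab("X17", "A", 0.1, kind_a = "chemical")
  expect_warning(out2 <- attach_chemicals(net, chem2, 0.4), "no chemical edge")
  expect_equal(igraph::vcount(out2), igraph::vcount(net))
})

test_that("network intersection matches the common-nodes/common-edges rule", {
  a <- build_network(simple_tab(c("A", "B"), c("B", "C"), c(0.8, 0.6)), 0)
  b <- build_network(simple_tab(c("A", "B"), c("B", "D"), c(0.5, 0.9)), 0)
  i <- intersect_networks(a, b)
  expect_setequal(igraph::V(i)$name, c("A", "B"))
  expect_equal(igraph::ecount(i), 1)
  expect_equal(igraph::E(i)$confidence, 0.5)  # min of the two
  # idempotence
  ii <- intersect_networks(a, a)
  expect_setequal(igraph::V(ii)$name, igraph::V(a)$name)
  expect_equal(igraph::ecount(ii), igraph::ecount(a))
  # empty intersection warns, does not error
  c_net <- build_network(simple_tab("X", "Y", 0.7), 0)
  expect_warning(e <- intersect_networks(a, c_net), "empty")
  expect_equal(igraph::vcount(e), 0)
})

edge_key_set <- function(net) {
  e <- network_edges(net)
  sort(paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b)))
}

test_that("intersection is commutative, associative and a subgraph", {
  set.seed(33)
  for (rep in 1:20) {
    a <- suppressMessages(build_network(random_graph_table(10, 0.35, "A"), 0))
    bt <- random_graph_table(10, 0.35, "A")
    b <- suppressMessages(build_network(bt, 0))
    ab <- suppressWarnings(intersect_networks(a, b))
    ba <- suppressWarnings(intersect_networks(b, a))
    expect_setequal(igraph::V(ab)$name, igraph::V(ba)$name)
    expect_equal(edge_key_set(ab), edge_key_set(ba))
    # subgraph containment in both inputs
    expect_true(all(igraph::V(ab)$name %in% igraph::V(a)$name))
    expect_true(all(igraph::V(ab)$name %in% igraph::V(b)$name))
    expect_true(all(edge_key_set(ab) %in% edge_key_set(a)))
    expect_true(all(edge_key_set(ab) %in% edge_key_set(b)))
    # associativity with a third random network
    cc <- suppressMessages(build_network(random_graph_table(10, 0.35, "A"), 0))
    l <- suppressWarnings(intersect_networks(intersect_networks(a, b), cc))
    r <- suppressWarnings(intersect_networks(a, intersect_networks(b, cc)))
    expect_setequal(igraph::V(l)$name, igraph::V(r)$name)
    expect_equal(edge_key_set(l), edge_key_set(r))
  }
})

test_that("drug adjacency maps proteins to their chemical neighbours", {
  tab <- simple_tab(c("A", "B"), c("B", "C"), c(0.9, 0.9))
  net <- build_network(tab, 0.4)
  chem <- simple_tab(c("DOXO", "DOXO", "RSV"), c("A", "B", "B"),
                     c(0.8, 0.8, 0.8), kind_a = "chemical")
  cp <- attach_chemicals(net, chem, 0.4)
  adj <- drug_adjacent(cp, c("DOXO", "RSV"))
  expect_equal(adj$A, "DOXO")
  expect_setequal(adj$B, c("DOXO", "RSV"))
  expect_false("C" %in% names(adj))
  expect_error(drug_adjacent(cp, "TAMOX"), class = "hb_missing_chemical")
})

test_that("regulation annotation sets attributes and round-trips", {
  net <- build_network(simple_tab(c("A", "B"), c("B", "C"), c(0.9, 0.9)), 0.4)
  net <- annotate_regulation(net, c(A = "up", B = "down"))
  expect_equal(igraph::V(net)$regulation[igraph::V(net)$name == "A"], "up")
  expect_equal(igraph::V(net)$regulation[igraph::V(net)$name == "C"], "none")
  ef <- withr::local_tempfile(fileext = ".tsv")
  nf <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, ef, nf)
  back <- read_network(ef, nf)
  idx <- match(igraph::V(net)$name, igraph::V(back)$name)
  expect_equal(igraph::V(back)$regulation[idx], igraph::V(net)$regulation)
  expect_equal(edge_key_set(back), edge_key_set(net))
})
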