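# Centrality, hub-bottleneck classification, quarters and consensus cores.

path_net <- function(nodes) {
  n <- length(nodes)
  suppressMessages(build_network(
    interaction_table(nodes[-n], nodes[-1], rep(1, n - 1)), 0))
}

star_net <- function(center, leaves) {
  suppressMessages(build_network(
    interaction_table(rep(center, length(leaves)), leaves,
                      rep(1, length(leaves))), 0))
}

cycle_net <- function(nodes) {
  n <- length(nodes)
  suppressMessages(build_network(
    interaction_table(nodes, nodes[c(2:n, 1)], rep(1, n)), 0))
}

test_that("betweenness and degree match textbook cases", {
  rec <- compute_centralities(path_net(c("a", "b", "c")))
  expect_equal(rec$betweenness[rec$node == "b"], 1)
  expect_equal(rec$betweenness[rec$node %in% c("a", "c")], c(0, 0))
  st <- compute_centralities(star_net("c0", paste0("l", 1:4)))
  expect_equal(st$degree[st$node == "c0"], 4)
  expect_equal(st$betweenness[st$node == "c0"], choose(4, 2))
  expect_true(all(st$betweenness[st$node != "c0"] == 0))
})

test_that("centralities agree exactly with the brute-force enumerator", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    tab <- random_graph_table(n, runif(1, 0.1, 0.5))
    net <- suppressMessages(build_network(tab, 0))
    got <- compute_centralities(net)
    want <- oracle_centrality(as.matrix(as.data.frame(tab)[, 1:2]))
    idx <- match(got$node, want$node)
    expect_equal(got$degree, want$degree[idx])
    expect_equal(got$betweenness, want$betweenness[idx], tolerance = 1e-10)
  }
})

test_that("tree betweenness equals the crossing-pairs closed form", {
  set.seed(19)
  for (rep in 1:5) {
    edges <- random_tree_edges(sample(6:15, 1))
    net <- suppressMessages(build_network(
      interaction_table(edges[, 1], edges[, 2], rep(1, nrow(edges))), 0))
    got <- compute_centralities(net)
    n <- igraph::vcount(net)
    # in a tree, betweenness(v) = #pairs whose unique path crosses v
    # = C(n-1, 2) - sum over components of net - v of C(size, 2)
    for (v in got$node) {
      sub <- igraph::delete_vertices(net, v)
      comp <- igraph::components(sub)$csize
      expect_equal(got$betweenness[got$node == v],
                   choose(n - 1, 2) - sum(choose(comp, 2)))
    }
  }
})

test_that("hub-bottleneck classification uses strict mean thresholds", {
  # cycle: every degree and betweenness equal -> nothing exceeds the mean
  rec <- classify_hb(compute_centralities(cycle_net(paste0("n", 1:6))))
  expect_true(all(rec$hb_class == "NH-NB"))
  # star: only the center is H-B
  st <- classify_hb(compute_centralities(star_net("c0", paste0("l", 1:4))))
  expect_equal(st$hb_class[st$node == "c0"], "H-B")
  expect_true(all(st$hb_class[st$node != "c0"] == "NH-NB"))
  th <- attr(st, "thresholds")
  expect_equal(th$degree_mean, mean(st$degree))
})

test_that("a hand-worked 10-node graph classifies against its means", {
  edges <- rbind(
    c("h", "a"), c("h", "b"), c("h", "c"), c("h", "d"), c("h", "e"),
    c("a", "b"), c("c", "d"), c("e", "f"), c("f", "g"), c("g", "i"),
    c("i", "j"))
  net <- suppressMessages(build_network(
    interaction_table(edges[, 1], edges[, 2], rep(1, nrow(edges))), 0))
  rec <- classify_hb(compute_centralities(net))
  # manual means
  dm <- mean(rec$degree); bm <- mean(rec$betweenness)
  for (i in seq_len(nrow(rec))) {
    want <- paste0(if (rec$degree[i] > dm) "H" else "NH", "-",
                   if (rec$betweenness[i] > bm) "B" else "NB")
    expect_equal(rec$hb_class[i], want)
  }
  expect_setequal(unique(rec$hb_class[rec$node %in% c("h")]), "H-B")
})

test_that("the four H-B classes partition every graph", {
  set.seed(23)
  for (rep in 1:10) {
    tab <- random_graph_table(sample(6:20, 1), 0.3)
    rec <- classify_hb(compute_centralities(
      suppressMessages(build_network(tab, 0))))
    expect_true(all(rec$hb_class %in% c("H-B", "H-NB", "NH-B", "NH-NB")))
    expect_equal(sum(table(rec$hb_class)), nrow(rec))
  }
})

test_that("the H-B subnetwork is the induced subgraph on H-B nodes", {
  st <- star_net("c0", paste0("l", 1:4))
  rec <- classify_hb(compute_centralities(st))
  sub <- hb_subnetwork(st, rec)
  expect_equal(igraph::V(sub)$name, "c0")
  expect_equal(igraph::ecount(sub), 0)
  # induced property on random graphs
  set.seed(29)
  for (rep in 1:5) {
    net <- suppressMessages(build_network(random_graph_table(15, 0.35), 0))
    rec <- classify_hb(compute_centralities(net))
    hb <- rec$node[rec$hb_class == "H-B"]
    if (length(hb) == 0) next
    sub <- hb_subnetwork(net, rec)
    e_all <- network_edges(net)
    both_hb <- e_all$node_a %in% hb & e_all$node_b %in% hb
    expect_equal(igraph::ecount(sub), sum(both_hb))
  }
  empty <- classify_hb(compute_centralities(cycle_net(paste0("n", 1:5))))
  expect_warning(hb_subnetwork(cycle_net(paste0("n", 1:5)), empty), "no H-B")
})

test_that("quarters split H-B nodes at the H-B medians, strictly", {
  rec <- data.frame(node = c("p", "q"), kind = "protein",
                    degree = c(1, 3), betweenness = c(1, 3),
                    hb_class = "H-B", stringsAsFactors = FALSE)
  out <- assign_quarters(rec)
  expect_equal(out$quarter, c(1L, 4L))
  med <- attr(out, "hb_medians")
  expect_equal(med$degree_median, 2)
  # identical H-B nodes: all Q1 (nothing strictly exceeds the median)
  rec2 <- data.frame(node = c("a", "b"), kind = "protein", degree = 5,
                     betweenness = 5, hb_class = "H-B",
                     stringsAsFactors = FALSE)
  expect_true(all(assign_quarters(rec2)$quarter == 1L))
  # 12-node fixture vs hand-computed medians
  set.seed(31)
  rec3 <- data.frame(node = sprintf("n%02d", 1:12), kind = "protein",
                     degree = sample(1:40, 12),
                     betweenness = round(runif(12, 0, 50), 1),
                     hb_class = sample(c("H-B", "NH-NB"), 12, replace = TRUE),
                     stringsAsFactors = FALSE)
  rec3$hb_class[1:2] <- "H-B"   # ensure H-B nodes exist
  out3 <- assign_quarters(rec3)
  hb <- rec3$hb_class == "H-B"
  dmed <- median(rec3$degree[hb]); bmed <- median(rec3$betweenness[hb])
  for (i in which(hb)) {
    want <- if (rec3$degree[i] > dmed && rec3$betweenness[i] > bmed) 4L
            else if (rec3$degree[i] > dmed) 3L
            else if (rec3$betweenness[i] > bmed) 2L else 1L
    expect_equal(out3$quarter[i], want)
  }
  expect_true(all(is.na(out3$quarter[!hb])))
})

test_that("consensus cores are set intersections with a Venn partition", {
  sets <- list(x = c("A", "B", "C"), y = c("B", "C", "D"), z = c("C", "B"))
  cons <- consensus_hb(sets)
  expect_setequal(cons$consensus, c("B", "C"))
  expect_equal(cons$venn$pattern[cons$venn$node == "A"], "100")
  expect_equal(cons$venn$pattern[cons$venn$node == "C"], "111")
  expect_setequal(consensus_hb(list(1:3, 1:3, 1:3))$consensus, 1:3)
  expect_length(consensus_hb(list(c("A"), c("B")))$consensus, 0)
  expect_error(consensus_hb(list("A")), class = "hb_bad_argument")
})
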