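test_that("miRNA names are normalized preserving arm suffixes", {
  expect_equal(normalize_mirna(c("hsa-miR-145-5p", "miR-22-3p", "mmu-let-7a")),
               c("miR-145-5p", "miR-22-3p", "let-7a"))
  expect_equal(normalize_mirna("hsa-mir-132-3p"), "miR-132-3p")
})

test_that("candidate intersection keeps screen order and reports the venn", {
  out <- intersect_candidates(c("m1-5p", "m2-5p", "m3-5p"),
                              c("m2-5p", "m3-5p", "m4-5p"))
  expect_equal(as.character(out), c("m2-5p", "m3-5p"))
  expect_equal(attr(out, "venn"),
               c(n_screen = 3L, n_de = 3L, n_overlap = 2L))
  expect_warning(empty <- intersect_candidates(c("a-5p"), c("b-5p")),
                 "no overlap")
  expect_length(empty, 0)
  # arm-annotation mismatch must error, never silently part-match
  expect_error(intersect_candidates(c("miR-145-5p", "miR-22-3p"),
                                    c("miR-145", "miR-22")),
               "arm")
})

test_that("shared targets group genes by exact k and account for all genes", {
  tab <- data.frame(mirna = c("A", "A", "B", "B", "C"),
                    gene = c("g1", "g2", "g1", "g3", "g1"))
  out <- shared_targets(tab, k_min = 3)
  expect_equal(out$gene, "g1")
  expect_equal(out$k, 3L)
  full <- shared_targets(tab)
  expect_equal(sum(attr(full, "k_counts")), length(unique(tab$gene)))
  expect_equal(nrow(shared_targets(tab, k_min = 4)), 0L)
  expect_error(shared_targets(tab, k_min = 0), ">= 1")
})

test_that("MCC matches hand-derived values on canonical graphs", {
  triangle <- data.frame(a = c("x", "y", "x"), b = c("y", "z", "z"))
  expect_equal(sort(mcc_scores(triangle)), c(x = 2, y = 2, z = 2))
  star <- data.frame(a = c("c", "c", "c"), b = c("l1", "l2", "l3"))
  expect_equal(mcc_scores(star)[["c"]], 3)
  expect_equal(unname(mcc_scores(star)[c("l1", "l2", "l3")]), rep(1, 3))
  path <- data.frame(a = c("a", "b"), b = c("b", "c"))
  expect_equal(mcc_scores(path)[["b"]], 2)
  expect_equal(mcc_scores(path)[["a"]], 1)
  expect_equal(mcc_scores(path, nodes = "iso")[["iso"]], 0)
})

test_that("MCC agrees with a brute-force oracle and igraph clique counts", {
  set.seed(55)
  for (i in 1:40) {
    g <- random_graph(sample(4:10, 1))
    if (!nrow(g$edges)) next
    mcc <- mcc_scores(g$edges, nodes = g$nodes)
    oracle <- mcc_bruteforce_oracle(g$adj)
    expect_equal(mcc[g$nodes], oracle[g$nodes])
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$nodes)
    n_bk <- length(vsmcscreen:::bron_kerbosch(
      lapply(g$nodes, function(v) match(g$adj[[v]], g$nodes))))
    expect_equal(n_bk, length(igraph::max_cliques(ig, min = 2)))
  }
})

test_that("MCC is invariant under edge order permutation and rejects non-simple graphs", {
  set.seed(56)
  g <- random_graph(8)
  mcc1 <- mcc_scores(g$edges, nodes = g$nodes)
  perm <- g$edges[sample(nrow(g$edges)), ]
  expect_equal(mcc_scores(perm, nodes = g$nodes)[names(mcc1)], mcc1)
  expect_error(mcc_scores(data.frame(a = "x", b = "x")), "simple")
  expect_error(mcc_scores(data.frame(a = c("x", "y"), b = c("y", "x"))),
               "simple")
})

test_that("clique enumeration stops at the configured budget", {
  g <- random_graph(9, p_edge = 0.8)
  expect_error(mcc_scores(g$edges, clique_budget = 1), "budget")
})

test_that("hub selection recovers a planted clique and deduplicates the hub set", {
  plan <- fixture_plan(
    mirnas = paste0("m", 1:6),
    gene_universe = sprintf("G%03d", 1:400),
    planted_hub_cliques = list(list(mirna = "m1", genes = paste0("q", 1:4))),
    n_filler_targets = 12)
  fx <- generate_fixtures(plan, seed = 10)
  hubs <- select_hubs(fx$targets, fx$ppi)
  expect_true(all(hubs$per_mirna$m1 %in% paste0("q", 1:4)))
  expect_length(hubs$per_mirna$m1, 3L)

  # six miRNAs with disjoint top-3 lists -> 18 hubs; one shared gene -> 17
  targets <- data.frame(
    mirna = rep(paste0("m", 1:6), each = 3),
    gene = c(paste0("h", 1:17), "h1"))   # m6 shares h1 with m1
  edges <- do.call(rbind, lapply(split(targets$gene, targets$mirna),
                                 function(gs) {
    p <- utils::combn(sort(unique(gs)), 2)
    data.frame(gene_a = p[1, ], gene_b = p[2, ])
  }))
  edges <- edges[!duplicated(edges), ]
  hubs17 <- select_hubs(targets, edges)
  expect_length(hubs17$hub_set, 17L)
  disjoint <- data.frame(mirna = rep(paste0("m", 1:6), each = 3),
                         gene = paste0("h", 1:18))
  iso_hubs <- select_hubs(disjoint,
                          data.frame(gene_a = character(),
                                     gene_b = character()))
  expect_length(iso_hubs$hub_set, 18L)
})

test_that("a miRNA with fewer targets than the cutoff warns and keeps all", {
  targets <- data.frame(mirna = "m1", gene = c("g1", "g2"))
  expect_warning(hubs <- select_hubs(targets,
                                     data.frame(gene_a = "g1",
                                                gene_b = "g2")),
                 "only 2")
  expect_setequal(hubs$per_mirna$m1, c("g1", "g2"))
})

test_that("the merged network deduplicates shared/hub roles", {
  shared <- data.frame(gene = c("s1", "s2", "h1"), k = c(5L, 4L, 4L),
                       mirnas = "")
  hubs <- structure(list(per_mirna = list(mA = c("h1", "h2", "h3")),
                         hub_set = c("h1", "h2", "h3"),
                         scores = data.frame(mirna = "mA",
                                             gene = c("h1", "h2", "h3"),
                                             mcc = c(2, 2, 2),
                                             degree = 1L, rank = 1:3,
                                             hub = TRUE)),
                    class = "hub_network")
  g <- data.frame(gene_a = c("s1", "h1"), gene_b = c("h1", "h2"))
  net <- build_network(shared, hubs, g, k_min = 4)
  expect_equal(nrow(net$nodes), 5L)  # s1 s2 h1 h2 h3, h1 deduplicated
  expect_equal(net$nodes$role[net$nodes$gene == "h1"], "both")
  expect_equal(nrow(net$edges), 2L)
  # empty shared + 3 hubs -> 3 nodes
  net0 <- build_network(shared[0, ], hubs, g)
  expect_equal(nrow(net0$nodes), 3L)
})

test_that("drug mapping expands miRNA x drug combinations and reports coverage", {
  targets <- data.frame(mirna = c("mA", "mB"), gene = "g1")
  drugs <- data.frame(drug = c("d1", "d2"), gene = "g1")
  out <- map_drugs("g1", drugs, targets)
  expect_equal(nrow(out$triples), 4L)  # 2 miRNAs x 2 drugs
  expect_equal(out$coverage, 1)
  none <- map_drugs(c("g2", "g3"), drugs, targets)
  expect_equal(nrow(none$triples), 0L)
  expect_equal(none$coverage, 0)
})

test_that("network export writes GraphML and an edge list", {
  shared <- data.frame(gene = "s1", k = 4L, mirnas = "mA")
  hubs <- structure(list(per_mirna = list(mA = "h1"), hub_set = "h1",
                         scores = data.frame(mirna = "mA", gene = "h1",
                                             mcc = 0, degree = 0L,
                                             rank = 1L, hub = TRUE)),
                    class = "hub_network")
  net <- build_network(shared, hubs,
                       data.frame(gene_a = "s1", gene_b = "h1"))
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, gml, tsv)
  expect_true(file.exists(gml) && file.exists(tsv))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
})
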