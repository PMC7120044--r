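test_that("shared-target p-value matches enumeration on worked cases", {
  u10 <- paste0("m", 1:10)
  # N=10, K=4, M=5, x=3: C(4,3)C(6,2) + C(4,4)C(6,1) over C(10,5) = 66/252
  st <- shared_target_pvalue(u10[1:4], u10[c(2, 3, 4, 5, 6)], u10)
  expect_identical(st$x, 3L + 0L)
  expect_equal(st$p_value, 66 / 252, tolerance = 1e-14)
  expect_equal(st$p_value, hyper_tail_oracle(3, 10, 4, 5),
               tolerance = 1e-14)
  # disjoint sets: empty upper sum, p = 1
  expect_equal(shared_target_pvalue(u10[1:3], u10[4:6], u10)$p_value, 1)
  # both target everything: forced overlap, p = 1
  full <- shared_target_pvalue(u10, u10, u10)
  expect_identical(full$x, 10L)
  expect_equal(full$p_value, 1)
  expect_error(shared_target_pvalue(character(0), u10[1:2], u10),
               "non-empty")
  expect_error(shared_target_pvalue(c("zz"), u10[1:2], u10), "universe")
})

test_that("shared-target p is symmetric and non-increasing in overlap", {
  u <- paste0("m", 1:30)
  set.seed(4)
  for (i in 1:20) {
    a <- sample(u, sample(3:12, 1)); b <- sample(u, sample(3:12, 1))
    expect_identical(shared_target_pvalue(a, b, u)$p_value,
                     shared_target_pvalue(b, a, u)$p_value)
  }
  # fixed N, K, M: p(x) decreases as overlap grows
  ps <- vapply(0:8, function(x)
    shared_target_pvalue(u[1:8], u[c(seq_len(x), 8 + seq_len(8 - x))],
                         u)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-14))
})

test_that("pearson_r matches the textbook formula and its edge cases", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  expect_equal(pearson_r(a, b), pearson_oracle(a, b), tolerance = 1e-14)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_warning(r <- pearson_r(a, rep(2, 4)), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(a, b[1:3]), "equal length")
  expect_error(pearson_r(a[1:2], b[1:2]), "at least 3")
})

test_that("pair inference gates on both the test and the correlation", {
  # L1, G1, G2 share the same 6 targets; G1 correlates with L1 while G2
  # anti-correlates; G3 shares no target with anyone
  u <- paste0("m", 1:40)
  tm <- target_map(list(L1 = u[1:6], G1 = u[1:6], G2 = u[1:6],
                        G3 = u[30:35]),
                   universe = u)
  set.seed(1)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  em <- tiny_expr(rbind(x, x + rnorm(8, 0, 0.1), -x + rnorm(8, 0, 0.1),
                        rnorm(8)),
                  rep(c("tumor", "normal"), each = 4),
                  features = c("L1", "G1", "G2", "G3"))
  pairs <- infer_cerna_pairs(em, tm)
  # only the positively correlated pair passes the signed-r filter
  expect_identical(pair_key(pairs$rna_a, pairs$rna_b), "G1 L1")
  expect_true(all(pairs$rna_a < pairs$rna_b))
  # |r| switch admits the anti-correlated combinations too
  pairs_abs <- infer_cerna_pairs(em, tm, use_abs_r = TRUE)
  expect_setequal(pair_key(pairs_abs$rna_a, pairs_abs$rna_b),
                  c("G1 L1", "G2 L1", "G1 G2"))
  # pairs sharing zero miRNAs are never candidates even with open gates
  open <- infer_cerna_pairs(em, tm, p_cut = 1.01, r_cut = -1.01,
                            use_abs_r = FALSE)
  expect_false(any(grepl("G3", pair_key(open$rna_a, open$rna_b))))
  expect_identical(attr(open, "n_candidates"), 3L)
})

test_that("inverted-index candidate generation equals naive enumeration", {
  set.seed(12)
  u <- paste0("m", 1:25)
  ids <- sprintf("R%02d", 1:12)
  tsets <- lapply(setNames(ids, ids), function(i) sample(u, 6))
  em <- tiny_expr(matrix(rnorm(12 * 10, 8), 12, 10),
                  rep(c("tumor", "normal"), each = 5), features = ids)
  tm <- target_map(tsets, universe = u)
  got <- suppressWarnings(infer_cerna_pairs(em, tm, p_cut = 0.5,
                                            r_cut = -1.01))
  naive <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    a <- ids[i]; b <- ids[j]
    x <- length(intersect(tsets[[a]], tsets[[b]]))
    if (x < 1) next
    p <- hyper_tail_oracle(x, 25, 6, 6)
    r <- pearson_oracle(em$values[a, ], em$values[b, ])
    if (p < 0.5 && r > -1.01)
      naive[[pair_key(a, b)]] <- c(p = p, r = r, x = x)
  }
  expect_setequal(pair_key(got$rna_a, got$rna_b), names(naive))
  for (k in seq_len(nrow(got))) {
    key <- pair_key(got$rna_a[k], got$rna_b[k])
    expect_equal(got$p_value[k], unname(naive[[key]]["p"]),
                 tolerance = 1e-12)
    expect_equal(got$r[k], unname(naive[[key]]["r"]), tolerance = 1e-12)
    expect_equal(got$x[k], as.integer(naive[[key]]["x"]))
  }
})

test_that("pair inference is invariant to input row order", {
  co <- generate_cohort(simulation_config(seed = 44, n_lncrna = 15,
                                          n_mrna = 30,
                                          n_planted_pairs = 5,
                                          n_de_lncrna = 2,
                                          n_prognostic = 1,
                                          n_de_mirna = 4))
  p1 <- infer_cerna_pairs(co$rna, co$targets)
  set.seed(1)
  perm <- sample(nrow(co$rna$values))
  shuffled <- expression_matrix(co$rna$values[perm, ], co$rna$groups)
  p2 <- infer_cerna_pairs(shuffled, co$targets)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("shared_mirnas column is consistent with the counted overlap", {
  co <- generate_cohort(simulation_config(seed = 2))
  pr <- infer_cerna_pairs(co$rna, co$targets)
  expect_true(nrow(pr) > 0)
  n_listed <- lengths(strsplit(pr$shared_mirnas, ",", fixed = TRUE))
  expect_equal(n_listed, pr$x, ignore_attr = TRUE)
  expect_true(all(pr$x <= pmin(pr$K, pr$M)))
  expect_true(all(pr$p_value > 0 & pr$p_value <= 1))
})

test_that("network assembly types nodes, counts degrees, obeys handshake", {
  u <- paste0("m", 1:20)
  tm <- target_map(list(L1 = u[1:5], G1 = u[1:5]), universe = u)
  em <- tiny_expr(rbind(1:6 + rnorm(6, 0, 0.05), 1:6),
                  rep(c("tumor", "normal"), each = 3),
                  features = c("L1", "G1"))
  pairs <- infer_cerna_pairs(em, tm)
  types <- c(L1 = "lncRNA", G1 = "mRNA")
  net <- build_network(pairs, rna_types = types)
  nodes <- network_nodes(net)
  expect_identical(nrow(nodes), 2L)
  expect_identical(nrow(network_edges(net)), 1L)
  expect_identical(sort(nodes$degree), c(1L, 1L))
  # shared miRNA edges: 1 pair edge + 2 members x 5 shared targets
  net2 <- build_network(pairs, rna_types = types,
                        include_mirna_edges = TRUE)
  nodes2 <- network_nodes(net2)
  expect_identical(nrow(nodes2), 7L)
  expect_identical(nrow(network_edges(net2)), 11L)
  expect_identical(sort(unique(nodes2$type)),
                   c("lncRNA", "mRNA", "miRNA"))
  # handshake lemma
  expect_identical(sum(nodes2$degree), 2L * nrow(network_edges(net2)))
})

test_that("methylation overlay partitions network genes correctly", {
  pairs <- data.frame(rna_a = c("G1", "G2", "L1"),
                      rna_b = c("L1", "G3", "L2"),
                      N = 10L, K = 3L, M = 3L, x = 2L, p_value = 0.01,
                      r = 0.9, shared_mirnas = "m1,m2",
                      stringsAsFactors = FALSE)
  class(pairs) <- c("cerna_pairs", "data.frame")
  types <- c(L1 = "lncRNA", L2 = "lncRNA", G1 = "mRNA", G2 = "mRNA",
             G3 = "mRNA")
  net <- build_network(pairs, rna_types = types)
  ov <- overlay_methylation(net, c("G1", "G3", "L2", "ZZ"))
  expect_identical(ov$lncrna_meth, "L2")
  expect_identical(ov$mrna_meth, c("G1", "G3"))
  # G1 pairs with lncRNA L1; G3 pairs only with mRNA G2
  expect_identical(ov$mrna_paired_with_lncrna, "G1")
  # disjoint methylation set leaves everything empty
  ov2 <- overlay_methylation(net, "ZZ")
  expect_identical(lengths(ov2), c(lncrna_meth = 0L, mrna_meth = 0L,
                                   mrna_paired_with_lncrna = 0L))
})

test_that("candidate lncRNAs are a plain intersection", {
  expect_identical(candidate_lncrnas(c("a", "b", "c"), c("b", "c", "d")),
                   c("b", "c"))
  expect_identical(candidate_lncrnas(character(0), c("a")), character(0))
})

test_that("subnetwork extraction closes over first neighbors", {
  pairs <- data.frame(rna_a = c("A", "B", "C"), rna_b = c("B", "C", "D"),
                      N = 10L, K = 3L, M = 3L, x = 1L, p_value = 0.01,
                      r = 0.9, shared_mirnas = "m1",
                      stringsAsFactors = FALSE)
  class(pairs) <- c("cerna_pairs", "data.frame")
  net <- build_network(pairs)
  sub <- extract_subnetwork(net, "B")
  nodes <- network_nodes(sub)
  expect_setequal(nodes$node, c("A", "B", "C"))
  # degrees recomputed within the subgraph: C loses its D edge
  expect_identical(nodes$degree[nodes$node == "C"], 1L)
  edge_keys <- pair_key(network_edges(sub)$source,
                        network_edges(sub)$target)
  all_keys <- pair_key(network_edges(net)$source,
                       network_edges(net)$target)
  expect_true(all(edge_keys %in% all_keys))
  # empty focus gives an empty network; unknown ids are ignored
  expect_identical(nrow(network_nodes(extract_subnetwork(net,
                                                         character(0)))),
                   0L)
  expect_warning(sub2 <- extract_subnetwork(net, c("B", "nope")),
                 "nope")
  expect_setequal(network_nodes(sub2)$node, c("A", "B", "C"))
})
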