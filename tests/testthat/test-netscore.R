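# Largest-cluster isolation and degree-weighted network efficacy.

test_that("largest cluster returns the biggest induced component deterministically", {
  edges <- tibble::tibble(
    from = c("a", "a", "b", "c", "x", "y", "z"),
    to   = c("b", "c", "c", "d", "y", "z", "w")
  )
  # component {a,b,c,d} (size 4) beats {w,x,y,z} when e is excluded
  cl <- largest_cluster(c("a", "b", "c", "d", "x", "y", "z"), edges)
  expect_equal(cl$nodes, c("a", "b", "c", "d"))
  expect_false(cl$degenerate)
  # size tie: the component holding the smallest gene id wins
  cl_tie <- largest_cluster(c("a", "b", "c", "x", "y", "z"), edges)
  expect_equal(cl_tie$nodes, c("a", "b", "c"))
  # all queries isolated: single-node component, flagged degenerate
  expect_warning(
    cl_iso <- largest_cluster(c("a", "w"), edges),
    "single node"
  )
  expect_length(cl_iso$nodes, 1)
  expect_true(cl_iso$degenerate)
  # no query in the network
  expect_warning(cl_none <- largest_cluster("nope", edges), "no query")
  expect_length(cl_none$nodes, 0)
})

test_that("a planted clique among noise genes is recovered exactly", {
  cfg <- synth_config(n_genes = 200, n_disease_genes = 40,
                      module_sizes = c(8, 8), p_within = 1, p_between = 0,
                      n_background_nodes = 20, n_drugs = 2, seed = 13)
  es <- generate_expression_study(cfg)
  net <- generate_interaction_network(cfg, es$truth)
  planted <- names(net$partition)[net$partition == 1]
  # query = planted clique plus disease genes that are not network nodes
  query <- union(planted, setdiff(es$truth$up_genes, names(net$partition)))
  cl <- largest_cluster(query, net$edges)
  expect_setequal(cl$nodes, planted)
})

test_that("weighted ratio equals the definitional degree-weighted sum", {
  edges <- tibble::tibble(from = c("a", "a", "a", "b"),
                          to = c("b", "c", "d", "e"))
  lrm <- wide_tbl(matrix(c(1, -1, 0, 0.5, 2), 5, 1,
                         dimnames = list(c("a", "b", "c", "d", "e"),
                                         "cond")))
  # degrees: a=3, b=2, c=1, d=1, e=1
  W <- weighted_ratio(c("a", "b"), lrm, "cond", edges)
  expect_equal(W, 3 * 1 + 2 * (-1))  # 1
  # simple two-node example: degrees {3,1}, ratios {+1,-1} -> W = 2
  W2 <- weighted_ratio(c("a", "c"), lrm, "cond", edges)
  expect_equal(W2, 3 * 1 + 1 * 0)
  # zero ratios give zero
  lrm0 <- wide_tbl(matrix(0, 5, 1,
                          dimnames = list(c("a", "b", "c", "d", "e"),
                                          "cond")))
  expect_equal(weighted_ratio(c("a", "b", "c"), lrm0, "cond", edges), 0)
  # linearity: doubling ratios doubles W
  lrm2 <- lrm
  lrm2$cond <- lrm$cond * 2
  expect_equal(weighted_ratio(c("a", "b"), lrm2, "cond", edges), 2 * W)
  # normalization divides by cluster size
  expect_equal(weighted_ratio(c("a", "b"), lrm, "cond", edges,
                              normalize = TRUE), W / 2)
  # within-cluster degrees differ from network degrees
  cl <- largest_cluster(c("a", "b", "e"), edges)
  W_net <- weighted_ratio(cl, lrm, "cond", edges)
  W_cl <- weighted_ratio(cl, lrm, "cond", edges,
                         degree_source = "cluster")
  expect_equal(W_net, 3 * 1 + 2 * (-1) + 1 * 2)
  expect_equal(W_cl, 1 * 1 + 2 * (-1) + 1 * 2)
})

test_that("vectorized W matches a brute-force loop on fuzzed inputs", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    genes <- sprintf("g%02d", seq_len(n))
    pr <- utils::combn(genes, 2)
    keep <- runif(ncol(pr)) < 0.2
    if (sum(keep) < 2) next
    edges <- tibble::tibble(from = pr[1, keep], to = pr[2, keep])
    lrm <- wide_tbl(matrix(rnorm(n), n, 1,
                           dimnames = list(genes, "cond")))
    cluster <- sample(genes, sample(3:n, 1))
    W <- suppressMessages(weighted_ratio(cluster, lrm, "cond", edges))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    deg <- igraph::degree(g)
    r <- setNames(lrm$cond, genes)
    W_brute <- 0
    for (gene in cluster) {
      d <- if (gene %in% names(deg)) deg[[gene]] else 0
      W_brute <- W_brute + d * r[[gene]]
    }
    expect_equal(W, W_brute)
  }
})

test_that("W is additive over disjoint clusters and order-invariant", {
  set.seed(15)
  genes <- sprintf("g%02d", 1:20)
  pr <- utils::combn(genes, 2)
  keep <- runif(ncol(pr)) < 0.3
  edges <- tibble::tibble(from = pr[1, keep], to = pr[2, keep])
  lrm <- wide_tbl(matrix(rnorm(20), 20, 1,
                         dimnames = list(genes, "cond")))
  a <- genes[1:7]
  b <- genes[11:16]
  expect_equal(
    weighted_ratio(c(a, b), lrm, "cond", edges),
    weighted_ratio(a, lrm, "cond", edges) +
      weighted_ratio(b, lrm, "cond", edges)
  )
  expect_equal(weighted_ratio(rev(a), lrm, "cond", edges),
               weighted_ratio(a, lrm, "cond", edges))
})

test_that("W shrinks monotonically toward 0 across restoring dose steps in noise-free data", {
  cfg <- synth_config(n_genes = 300, n_disease_genes = 60, noise_sd = 0,
                      module_sizes = c(8, 8), p_within = 1,
                      p_between = 0, n_drugs = 2, seed = 16,
                      restore_fraction_per_step = 0.5)
  b <- synth_bundle(cfg)
  lrm <- log_ratio(b$study, pseudo = 0)  # exact ratios in noise-free mode
  cl <- largest_cluster(c(b$truth$up_genes, b$truth$down_genes),
                        b$network)
  conds <- names(lrm)[-1]
  Ws <- vapply(conds, function(cc) weighted_ratio(cl, lrm, cc, b$network),
               numeric(1))
  expect_true(all(diff(abs(Ws)) < 0))
  expect_gt(abs(Ws[1]), abs(Ws[length(Ws)]))
  # exact geometric shrinkage at zero noise
  expect_equal(unname(Ws[-1] / Ws[1]), c(0.5, 0.25, 0.125))
})

test_that("planted disease cluster is significant; per-gene terms self-correlate", {
  cfg <- synth_config(n_genes = 300, n_disease_genes = 60,
                      module_sizes = c(8, 8), p_within = 0.9,
                      p_between = 0.02, n_drugs = 2, seed = 17)
  b <- synth_bundle(cfg)
  lrm <- log_ratio(b$study)
  planted <- names(b$truth$module_partition)[b$truth$module_partition == 1]
  res <- weighted_ratio_significance(planted, lrm, b$network,
                                     conditions = c("disease_1",
                                                    "treated_dose10"),
                                     n_permutations = 1000, seed = 18)
  expect_lte(res$w$p[1], 0.01)
  expect_true(all(res$w$p > 0 & res$w$p <= 1))
  # per-gene weighted terms of a condition against itself correlate at 1
  terms_d <- res$terms$term[res$terms$condition == "disease_1"]
  expect_equal(stats::cor(terms_d, terms_d), 1)
  # over the up- and down-module union the per-gene terms of the disease
  # and a dose condition correlate strongly (shared sign structure)
  both <- names(b$truth$module_partition)
  res_pair <- weighted_ratio_significance(both, lrm, b$network,
                                          conditions = c("disease_1",
                                                         "treated_dose10"),
                                          n_permutations = 1000, seed = 20)
  expect_gt(res_pair$pair_cor$r, 0.9)
  expect_lte(res_pair$pair_cor$p_perm, 0.01)
  # determinism
  res2 <- weighted_ratio_significance(planted, lrm, b$network,
                                      conditions = c("disease_1",
                                                     "treated_dose10"),
                                      n_permutations = 1000, seed = 18)
  expect_identical(res$w, res2$w)
})

test_that("weighted-ratio permutation p is calibrated under a random null", {
  set.seed(19)
  genes <- sprintf("g%03d", 1:60)
  pr <- utils::combn(genes, 2)
  keep <- runif(ncol(pr)) < 0.15
  edges <- tibble::tibble(from = pr[1, keep], to = pr[2, keep])
  ps <- vapply(seq_len(200), function(i) {
    lrm <- wide_tbl(matrix(rnorm(60), 60, 1,
                           dimnames = list(genes, "cond")))
    cluster <- sample(genes, 10)
    res <- weighted_ratio_significance(cluster, lrm, edges,
                                       conditions = "cond",
                                       n_permutations = 200, seed = i)
    res$w$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
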