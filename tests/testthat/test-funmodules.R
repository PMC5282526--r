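# Correlation graph construction, Markov clustering, module overlap,
# enrichment-map edges.

test_that("functional graph links co-trajectory genes at the signed threshold", {
  m <- rbind(
    g1 = c(0, 1, 2, 3),
    g2 = c(1, 2, 3, 4),      # identical trajectory shape: r = 1
    g3 = c(3, 2, 1, 0),      # anti-correlated: r = -1
    g4 = c(0, 0, 0, 0)       # flat: excluded
  )
  colnames(m) <- paste0("t", 1:4)
  fg <- build_functional_graph(wide_tbl(m), r_threshold = 0.8)
  key <- paste(pmin(fg$from, fg$to), pmax(fg$from, fg$to))
  expect_true("g1 g2" %in% key)
  expect_false(any(grepl("g3", key)))     # signed threshold: no edge
  expect_false(any(grepl("g4", key)))
  expect_equal(attr(fg, "n_excluded"), 1)
  # absolute-value mode admits anti-correlated pairs
  fg_abs <- build_functional_graph(wide_tbl(m), r_threshold = 0.8,
                                   use_abs = TRUE)
  key_abs <- paste(pmin(fg_abs$from, fg_abs$to),
                   pmax(fg_abs$from, fg_abs$to))
  expect_true("g1 g3" %in% key_abs)
  expect_error(build_functional_graph(wide_tbl(m[, 1:2])), "3 conditions")
})

test_that("a backbone restricts functional edges to interaction pairs", {
  set.seed(21)
  m <- matrix(rep(c(0, 1, 2, 3), 3), 3, 4, byrow = TRUE) +
    matrix(rnorm(12, 0, 1e-9), 3)
  rownames(m) <- c("a", "b", "c")
  colnames(m) <- paste0("t", 1:4)
  backbone <- tibble::tibble(from = "a", to = "b")
  fg <- build_functional_graph(wide_tbl(m), backbone = backbone)
  expect_equal(nrow(fg), 1)
  expect_setequal(c(fg$from, fg$to), c("a", "b"))
})

test_that("a planted co-expressed block forms a complete subgraph at zero noise", {
  block <- matrix(rep(c(0, 1, 2, 0.5), each = 10), 10, 4)
  noise <- matrix(rnorm(40), 10, 4)
  m <- rbind(block, noise)
  rownames(m) <- sprintf("g%02d", 1:20)
  colnames(m) <- paste0("t", 1:4)
  set.seed(22)
  fg <- build_functional_graph(wide_tbl(m), r_threshold = 0.8)
  key <- paste(pmin(fg$from, fg$to), pmax(fg$from, fg$to))
  blk <- sprintf("g%02d", 1:10)
  expected <- utils::combn(blk, 2)
  expect_true(all(paste(expected[1, ], expected[2, ]) %in% key))
})

test_that("MCL splits two cliques joined by a bridge and respects components", {
  cl1 <- utils::combn(paste0("a", 1:8), 2)
  cl2 <- utils::combn(paste0("b", 1:8), 2)
  edges <- tibble::tibble(
    from = c(cl1[1, ], cl2[1, ], "a1"),
    to = c(cl1[2, ], cl2[2, ], "b1")
  )
  ms <- mcl_cluster(edges)
  expect_true(ms$converged)
  lab <- setNames(ms$modules$module, ms$modules$gene)
  expect_length(unique(lab), 2)
  expect_length(unique(lab[paste0("a", 1:8)]), 1)
  expect_length(unique(lab[paste0("b", 1:8)]), 1)
  expect_false(lab[["a1"]] == lab[["b1"]])
  # disjoint components never share a module
  edges_dis <- tibble::tibble(from = c(cl1[1, ], cl2[1, ]),
                              to = c(cl1[2, ], cl2[2, ]))
  ms_dis <- mcl_cluster(edges_dis)
  lab_dis <- setNames(ms_dis$modules$module, ms_dis$modules$gene)
  expect_length(intersect(lab_dis[paste0("a", 1:8)],
                          lab_dis[paste0("b", 1:8)]), 0)
  # a single clique is one module
  ms_one <- mcl_cluster(tibble::tibble(from = cl1[1, ], to = cl1[2, ]))
  expect_equal(length(unique(ms_one$modules$module)), 1)
  expect_equal(nrow(ms_one$modules), 8)
  # determinism: no RNG in the loop
  expect_identical(mcl_cluster(edges)$modules, ms$modules)
})

test_that("MCL recovers planted two-block partitions (mean ARI >= 0.95 over 20 seeds)", {
  aris <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    g <- two_block_graph(8, 0.9, 0.02)
    ms <- suppressMessages(mcl_cluster(g$edges, min_size = 1))
    lab <- setNames(ms$modules$module, ms$modules$gene)[g$nodes]
    rand_index_adj(lab, g$block)
  }, numeric(1))
  expect_gte(mean(aris), 0.95)
})

test_that("sub-minimum modules are discarded and counted", {
  cl1 <- utils::combn(paste0("a", 1:5), 2)
  edges <- tibble::tibble(from = c(cl1[1, ], "x"),
                          to = c(cl1[2, ], "y"))
  ms <- mcl_cluster(edges, min_size = 3)
  expect_equal(sort(unique(ms$modules$gene)), paste0("a", 1:5))
  expect_equal(ms$n_discarded, 2)
})

test_that("module overlap significance equals exhaustive enumeration", {
  universe <- sprintf("u%03d", 1:100)
  a <- universe[1:10]
  b <- c(universe[1:5], universe[20:24])
  p <- module_overlap_significance(a, b, universe)
  expect_equal(p, hyper_oracle(5, 10, 10, 100), tolerance = 1e-12)
  # zero overlap: p = 1
  expect_equal(module_overlap_significance(universe[1:5],
                                           universe[50:54], universe), 1)
  # both modules equal to the universe: the only table, p = 1
  expect_equal(module_overlap_significance(universe, universe, universe),
               1)
})

test_that("overlap-coefficient edges follow the inclusive cutoff", {
  sets <- list(A = letters[1:4], B = letters[1:8], C = letters[10:12])
  # OC(A, B) = 4/4 = 1; OC(A, C) = 0; OC(B, C) = 0
  em <- enrichment_map_edges(sets, similarity_cutoff = 0.5)
  expect_equal(nrow(em$edges), 1)
  expect_equal(em$edges$oc, 1)
  # |A| = 4, |B| = 8, overlap 2 -> OC = 0.5, kept at the inclusive cutoff
  sets2 <- list(A = letters[1:4], B = c(letters[3:4], letters[11:16]))
  em2 <- enrichment_map_edges(sets2, similarity_cutoff = 0.5)
  expect_equal(em2$edges$oc, 0.5)
  # OC is symmetric and OC(A, A) = 1
  em_self <- enrichment_map_edges(list(A = letters[1:4],
                                       A2 = letters[1:4]))
  expect_equal(em_self$edges$oc, 1)
})

test_that("post-analysis weights flag terms overlapping an external gene list", {
  universe <- sprintf("u%03d", 1:100)
  sets <- list(hit = universe[1:10], miss = universe[60:69])
  em <- enrichment_map_edges(sets, post_gene_list = universe[1:10],
                             post_universe = universe)
  post <- em$post
  expect_true(post$significant[post$term == "hit"])
  expect_false(post$significant[post$term == "miss"])
  expect_equal(post$p[post$term == "hit"],
               hyper_oracle(10, 10, 10, 100), tolerance = 1e-12)
})

test_that("shared functions emerge from modules with few common genes", {
  # two datasets annotated with the same terms; gene memberships disjoint
  universe_a <- sprintf("a%02d", 1:40)
  universe_b <- sprintf("b%02d", 1:40)
  terms <- list(
    shared_fn = c(universe_a[1:8], universe_b[1:8]),
    other_fn = c(universe_a[30:35], universe_b[30:35])
  )
  mods_a <- tibble::tibble(gene = universe_a[1:8], module = 1L)
  mods_b <- tibble::tibble(gene = universe_b[1:8], module = 1L)
  res <- shared_function_count(mods_a, mods_b, terms,
                               universe_a, universe_b)
  expect_equal(res$common_terms, "shared_fn")
  expect_length(intersect(mods_a$gene, mods_b$gene), 0)
  # identical module sets intersect to the full enriched-term set
  res_same <- shared_function_count(mods_a, mods_a, terms,
                                    universe_a, universe_a)
  expect_setequal(res_same$common_terms, res_same$enriched_a)
  # no enriched terms on one side: empty intersection, p = 1
  mods_null <- tibble::tibble(gene = universe_b[33:35], module = 1L)
  res_null <- shared_function_count(mods_a, mods_null, terms,
                                    universe_a, universe_b,
                                    q_cutoff = 1e-6)
  expect_length(res_null$common_terms, 0)
  expect_equal(res_null$p, 1)
})
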