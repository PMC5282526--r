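# Filtering, normalization, log ratios, signature selection, profile
# assignment, two-class statistic.

make_study <- function(intens, bg = NULL, roles = NULL) {
  genes <- rownames(intens)
  if (is.null(roles)) roles <- tibble::tibble(
    sample = colnames(intens),
    role = ifelse(grepl("^c", colnames(intens)), "control", "disease")
  )
  structure(list(intensities = wide_tbl(intens),
                 background = if (!is.null(bg)) wide_tbl(bg),
                 roles = roles),
            class = "expr_study")
}

test_that("background filter keeps genes at or above the fold threshold in any sample", {
  intens <- matrix(c(150, 130, 90, 500), 4, 1,
                   dimnames = list(paste0("g", 1:4), "c1"))
  bg <- matrix(100, 4, 1, dimnames = dimnames(intens))
  st <- make_study(intens, bg)
  kept <- suppressMessages(filter_above_background(st, 1.4))
  expect_setequal(as.data.frame(kept$intensities)$gene, c("g1", "g4"))
  # factor 0 keeps everything
  all_kept <- suppressMessages(filter_above_background(st, 0))
  expect_equal(nrow(all_kept$intensities), 4)
  # scope = "all" demands the threshold in every sample
  intens2 <- cbind(intens, c2 = c(150, 150, 150, 90))
  bg2 <- matrix(100, 4, 2, dimnames = dimnames(intens2))
  st2 <- make_study(intens2, bg2)
  kept2 <- suppressMessages(filter_above_background(st2, 1.4, scope = "all"))
  expect_setequal(as.data.frame(kept2$intensities)$gene, "g1")
  # background is required
  expect_error(filter_above_background(make_study(intens)), "background")
})

test_that("quantile normalization equalizes column distributions and is idempotent", {
  x <- wide_tbl(matrix(c(1, 3, 2, 4), 2, 2,
                       dimnames = list(c("a", "b"), c("s1", "s2"))))
  qn <- quantile_normalize(x)
  expect_equal(qn$s1, c(1.5, 3.5))
  expect_equal(qn$s2, c(1.5, 3.5))
  # identical columns are a fixed point
  same <- wide_tbl(matrix(c(5, 1, 5, 1), 2, 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(quantile_normalize(same), same)
  # idempotence and exact sorted-column agreement on random input
  set.seed(1)
  m <- matrix(rnorm(600), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  q1 <- quantile_normalize(wide_tbl(m))
  q2 <- quantile_normalize(q1)
  expect_equal(q1, q2)
  mm <- tbl_to_matrix_test(q1)
  sorted <- apply(mm, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # rank order within each column is preserved for tie-free input
  expect_equal(apply(mm, 2, rank), apply(m, 2, rank))
  # missing values are rejected
  m[1, 1] <- NA
  expect_error(quantile_normalize(wide_tbl(m)), "missing")
})

test_that("log ratios are log2 of intensity over the reference", {
  intens <- matrix(c(100, 100, 100, 200, 100, 50), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("c1", "d1")))
  st <- make_study(intens)
  r <- log_ratio(st, pseudo = 0)
  expect_equal(r$d1, c(1, 0, -1))
  st$intensities$c1[1] <- 0
  expect_error(log_ratio(st, pseudo = 0), "zero reference")
  expect_silent(log_ratio(st, pseudo = 1))
})

test_that("fold-change selection is inclusive, direction-exclusive, and monotone in fold", {
  r <- wide_tbl(matrix(c(1.0, 0.9, 1.2, -2, 1.0, 0.9, -1.2, -2), 4, 2,
                       dimnames = list(c("up_exact", "below", "conflict",
                                         "down"),
                                       c("condA", "condB"))))
  sig <- suppressMessages(select_fold_change(r, fold = 2))
  expect_true("up_exact" %in% sig$up)        # boundary inclusive
  expect_false("below" %in% c(sig$up, sig$down))
  expect_equal(attr(sig, "conflicting"), "conflict")
  expect_false("conflict" %in% c(sig$up, sig$down))
  expect_true("down" %in% sig$down)
  # monotone: raising the fold never adds a tag
  sig4 <- suppressMessages(select_fold_change(r, fold = 4))
  expect_true(all(sig4$up %in% sig$up))
  expect_true(all(sig4$down %in% sig$down))
  expect_error(select_fold_change(r, fold = 1), "greater than 1")
  # invariant to gene order
  r2 <- r[c(3, 1, 4, 2), ]
  sig_r2 <- suppressMessages(select_fold_change(r2, fold = 2))
  expect_setequal(sig_r2$up, sig$up)
  expect_setequal(sig_r2$down, sig$down)
})

test_that("the tag cap keeps the strongest tags", {
  m <- matrix(seq(1, 3, length.out = 10), 10, 1,
              dimnames = list(sprintf("g%02d", 1:10), "d"))
  sig <- suppressMessages(select_fold_change(wide_tbl(m), fold = 2,
                                             max_tags = 3))
  expect_setequal(sig$up, c("g10", "g09", "g08"))
})

test_that("signature construction enforces disjointness and non-emptiness", {
  expect_error(new_signature(character(0), character(0)), "non-empty")
  expect_error(new_signature(c("a", "b"), c("b")), "disjoint")
  s <- new_signature("a", character(0))
  expect_equal(s$up, "a")
})

test_that("signature mapping drops unmapped genes and resolves collisions", {
  sig <- new_signature(c("m1", "m2", "m3"), c("m4"))
  map <- tibble::tibble(from_id = c("m1", "m2", "m4"),
                        to_id = c("H1", "H2", "H4"))
  out <- suppressMessages(map_signature(sig, map))
  expect_setequal(out$up, c("H1", "H2"))
  expect_equal(out$down, "H4")
})

test_that("genes matching a template exactly are assigned to it and flat genes are not assigned", {
  # conditions: 4 ordered; templates include the monotone-up ramp
  set.seed(2)
  n <- 60
  ramp <- c(0, 1, 2, 3)
  m <- rbind(
    t(replicate(n / 2, ramp + rnorm(4, 0, 1e-6))),
    matrix(rnorm(n / 2 * 4, 0, 1), n / 2, 4)
  )
  m <- rbind(m, matrix(0, 3, 4))   # flat genes
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- paste0("t", 1:4)
  pa <- assign_model_profiles(wide_tbl(m), n_profiles = 8,
                              n_permutations = 1000, seed = 1)
  expect_equal(pa$n_unassigned, 3)
  ramp_genes <- sprintf("g%02d", 1:(n / 2))
  asg <- pa$assignment
  ramp_profile <- asg$profile[asg$gene == "g01"]
  expect_true(all(asg$profile[asg$gene %in% ramp_genes] == ramp_profile))
  expect_true(all(asg$cor[asg$gene %in% ramp_genes] > 0.999))
  # the over-occupied ramp profile is significant
  expect_lt(pa$counts$q[pa$counts$profile == ramp_profile], 0.01)
  expect_error(assign_model_profiles(wide_tbl(m[, 1:2])), "3 ordered")
})

test_that("profile counts under a permuted input match the assignment null", {
  # scrambling the conditions per gene should give unremarkable q-values
  set.seed(3)
  m <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("t", 1:4)))
  pa <- assign_model_profiles(wide_tbl(m), n_permutations = 200, seed = 4)
  expect_true(all(pa$counts$q > 0.01))
})

test_that("two-class statistic matches the hand-computed regularized difference", {
  m <- matrix(c(1, 1, 3, 3), 1, 4,
              dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  # add a second gene so the s0 quantile is not degenerate at this gene
  m <- rbind(m, g2 = c(0, 2, 1, 3))
  groups <- setNames(c("grp1", "grp1", "grp2", "grp2"), colnames(m))
  res <- two_class_statistic(wide_tbl(m), groups, threshold = 2,
                             s0_quantile = 1)  # s0 = max(s) here
  # for g1: s = 0, numerator 2; with s0 = s(g2) = sqrt(1/2 + 1/2) * ... compute
  s_g2 <- sqrt((1 / 2 + 1 / 2) * ((2 + 2) / 2))
  expect_equal(res$scores$d[1], 2 / (0 + s_g2))
  # identical group means give d = 0
  m0 <- matrix(c(1, 5, 3, 7, 3, 7, 1, 5), 2, 4,
               dimnames = list(c("x", "y"), c("a1", "a2", "b1", "b2")))
  groups0 <- setNames(c("grp1", "grp1", "grp2", "grp2"), colnames(m0))
  res0 <- two_class_statistic(wide_tbl(m0), groups0)
  expect_true(all(res0$scores$d == 0))
  # negating all values negates d; |d| invariant to label swap
  res_neg <- two_class_statistic(wide_tbl(-m), groups, s0_quantile = 1)
  expect_equal(res_neg$scores$d, -res$scores$d)
  groups_sw <- setNames(c("grp2", "grp2", "grp1", "grp1"), colnames(m))
  res_sw <- two_class_statistic(wide_tbl(m), groups_sw, s0_quantile = 1)
  expect_equal(abs(res_sw$scores$d), abs(res$scores$d))
  expect_error(
    two_class_statistic(wide_tbl(m[, 1:3]),
                        setNames(c("grp1", "grp1", "grp2"),
                                 colnames(m)[1:3])),
    "at least 2"
  )
})

test_that("two-class selection splits by sign at the threshold", {
  set.seed(5)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  m[1, 4:6] <- m[1, 4:6] + 10
  m[2, 4:6] <- m[2, 4:6] - 10
  groups <- setNames(rep(c("n", "t"), each = 3), colnames(m))
  res <- two_class_statistic(wide_tbl(m), groups, threshold = 4)
  expect_true("g01" %in% res$selected_up)
  expect_true("g02" %in% res$selected_down)
  expect_length(intersect(res$selected_up, res$selected_down), 0)
  td <- tidy(res)
  expect_true(all(td$selected[match(res$selected_up, td$gene)] == "up"))
})
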