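# Shared fixtures and independent oracles, all built in code.

# A small planted study configuration used across module tests.
small_config <- function(seed = 1, ...) {
  synth_config(n_genes = 300, n_drugs = 12, instances_per_drug = 2,
               n_disease_genes = 60, n_pathways = 8, pathway_size = 10,
               n_background_nodes = 30, seed = seed, ...)
}

# Build a ref_library from an explicit rank matrix.
make_library <- function(ranks, drugs) {
  stopifnot(ncol(ranks) == length(drugs))
  colnames(ranks) <- sprintf("inst%03d", seq_len(ncol(ranks)))
  structure(
    list(ranks = ranks,
         meta = tibble::tibble(instance_id = colnames(ranks),
                               drug = drugs)),
    class = "ref_library"
  )
}

# Random library of uniform rankings (a null library).
random_library <- function(n_genes, n_drugs, k_per_drug) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  ranks <- vapply(seq_len(n_drugs * k_per_drug),
                  function(j) sample.int(n_genes), integer(n_genes))
  rownames(ranks) <- genes
  make_library(ranks, rep(sprintf("d%03d", seq_len(n_drugs)),
                          each = k_per_drug))
}

# Definitional KS a/b oracle: direct loop over j, independent of ks_es.
ks_oracle <- function(V, n) {
  V <- sort(V)
  t <- length(V)
  a_best <- -Inf
  b_best <- -Inf
  for (j in seq_len(t)) {
    a_best <- max(a_best, j / t - V[j] / n)
    b_best <- max(b_best, V[j] / n - (j - 1) / t)
  }
  if (a_best >= b_best) a_best else -b_best
}

# Exhaustive upper-tail hypergeometric oracle via binomial coefficients,
# independent of phyper.
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  i <- i[i >= max(0, n + K - N)]
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Wide tibble -> matrix (test-local mirror of the package internal).
tbl_to_matrix_test <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -1])
  rownames(m) <- as.data.frame(x)[[1]]
  m
}

# A tiny wide expression tibble.
wide_tbl <- function(m, id = "gene") {
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, !!id := rownames(m), .before = 1)
}

# Two-block random graph with planted membership.
two_block_graph <- function(n_per_block = 8, p_in = 0.9, p_out = 0.02) {
  nodes <- c(sprintf("a%02d", seq_len(n_per_block)),
             sprintf("b%02d", seq_len(n_per_block)))
  block <- rep(1:2, each = n_per_block)
  pr <- utils::combn(length(nodes), 2)
  p <- ifelse(block[pr[1, ]] == block[pr[2, ]], p_in, p_out)
  keep <- runif(ncol(pr)) < p
  list(edges = tibble::tibble(from = nodes[pr[1, keep]],
                              to = nodes[pr[2, keep]]),
       nodes = nodes, block = block)
}

# Adjusted Rand index between two labelings (contingency-table formula).
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
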