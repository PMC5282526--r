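# Degree-weighted network efficacy on a protein-interaction backbone.

edges_to_igraph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Largest connected cluster of a gene set in an interaction network
#'
#' Induces the subgraph of the network on the query genes and returns its
#' largest connected component; size ties are broken by the component
#' containing the lexicographically smallest gene id, so the result is
#' deterministic.
#'
#' @param genes character vector of query genes (e.g. a differential set).
#' @param edges interaction edge list: data frame with two character
#'   columns (undirected, simple).
#' @return object of class `net_cluster`: list with `nodes` (sorted
#'   character), `edges` (tibble of induced edges), `degenerate` (TRUE
#'   when the component is a single node), `n_query_in_network`.
#' @export
largest_cluster <- function(genes, edges) {
  g <- edges_to_igraph(edges)
  present <- intersect(unique(genes), igraph::V(g)$name)
  if (length(present) == 0) {
    rlang::warn("no query gene is present in the network")
    return(structure(list(nodes = character(0),
                          edges = tibble::tibble(from = character(0),
                                                 to = character(0)),
                          degenerate = TRUE,
                          n_query_in_network = 0L),
                     class = "net_cluster"))
  }
  sub <- igraph::induced_subgraph(g, present)
  comp <- igraph::components(sub)
  max_size <- max(comp$csize)
  cand <- which(comp$csize == max_size)
  if (length(cand) > 1) {
    # tie: pick the component holding the smallest gene id
    firsts <- vapply(cand, function(ci) {
      min(igraph::V(sub)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[order(firsts)][1]
  }
  nodes <- sort(igraph::V(sub)$name[comp$membership == cand[1]])
  cl <- igraph::induced_subgraph(sub, nodes)
  el <- igraph::as_data_frame(cl, what = "edges")
  degenerate <- length(nodes) == 1
  if (degenerate) rlang::warn("largest cluster is a single node")
  structure(
    list(nodes = nodes,
         edges = tibble::as_tibble(el[c("from", "to")]),
         degenerate = degenerate,
         n_query_in_network = length(present)),
    class = "net_cluster"
  )
}

#' @export
print.net_cluster <- function(x, ...) {
  cat("<net_cluster> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

cluster_nodes <- function(cluster) {
  if (inherits(cluster, "net_cluster")) cluster$nodes else
    as.character(cluster)
}

node_degrees <- function(edges, nodes = NULL) {
  g <- edges_to_igraph(edges)
  d <- igraph::degree(g)
  if (!is.null(nodes)) d <- d[intersect(nodes, names(d))]
  d
}

#' Degree-weighted expression ratio of a network cluster
#'
#' The network efficacy statistic: `W = sum_g d_g * r_g` over the cluster,
#' each gene's log2 ratio weighted by its node degree so that positionally
#' important (hub) genes dominate. Degrees come from the full network by
#' default (`degree_source = "network"`) or can be recomputed inside the
#' cluster. Cluster genes missing from the ratio matrix contribute 0 and
#' are counted in a message.
#'
#' @param cluster a `net_cluster` or character vector of genes.
#' @param lrm log-ratio tibble.
#' @param condition condition column to score.
#' @param edges full-network edge list (needed for network degrees).
#' @param degree_source `"network"` (default) or `"cluster"`.
#' @param normalize divide by the cluster size (default FALSE).
#' @return a single number `W`.
#' @export
weighted_ratio <- function(cluster, lrm, condition, edges,
                           degree_source = c("network", "cluster"),
                           normalize = FALSE) {
  degree_source <- match.arg(degree_source)
  nodes <- cluster_nodes(cluster)
  d <- if (degree_source == "network") {
    node_degrees(edges, nodes)
  } else {
    node_degrees(if (inherits(cluster, "net_cluster")) cluster$edges else
      edges, nodes)
  }
  r <- tbl_to_matrix(lrm)[, condition]
  measured <- intersect(nodes, names(r))
  missing_n <- length(nodes) - length(measured)
  if (missing_n > 0) {
    rlang::inform(sprintf(
      "%d cluster genes missing from the ratio matrix contribute 0",
      missing_n
    ))
  }
  d <- d[measured]
  d[is.na(d)] <- 0
  W <- sum(d * r[measured])
  if (normalize) W <- W / length(nodes)
  W
}

#' Permutation significance of degree-weighted ratios
#'
#' Recomputes `W` for random gene sets of cluster size drawn from the
#' measured network genes (degrees taken from the network for the drawn
#' genes) and reports the two-sided add-one p-value per condition.
#' When two or more conditions are scored, the per-gene weighted terms
#' (`d_g * r_g`) of each condition pair are also correlated, with a
#' gene-relabelling permutation p for the correlation.
#'
#' @inheritParams weighted_ratio
#' @param conditions condition columns to score (default: all).
#' @param n_permutations random gene sets (default 1000).
#' @param seed RNG seed.
#' @return object of class `weighted_ratio_result`: list with `w`
#'   (tibble: condition, W, p), `terms` (tibble: gene, condition, term),
#'   `pair_cor` (tibble: cond_a, cond_b, r, p_perm), `cluster`,
#'   `provenance`.
#' @export
weighted_ratio_significance <- function(cluster, lrm, edges,
                                        conditions = NULL,
                                        n_permutations = 1000, seed = 1,
                                        degree_source = c("network",
                                                          "cluster")) {
  degree_source <- match.arg(degree_source)
  nodes <- cluster_nodes(cluster)
  r <- tbl_to_matrix(lrm)
  if (is.null(conditions)) conditions <- colnames(r)
  d_all <- node_degrees(edges)
  universe <- intersect(names(d_all), rownames(r))
  m <- length(intersect(nodes, universe))
  if (m == 0 || length(universe) < m) {
    rlang::abort("measured network universe too small for the cluster")
  }
  d_cl <- if (degree_source == "network") {
    d_all[intersect(nodes, universe)]
  } else {
    node_degrees(if (inherits(cluster, "net_cluster")) cluster$edges else
      edges, intersect(nodes, universe))
  }
  measured <- names(d_cl)

  obs <- vapply(conditions, function(cond) {
    sum(d_cl * r[measured, cond])
  }, numeric(1))

  null_w <- with_seed(seed, {
    draws <- matrix(0L, nrow = n_permutations, ncol = m)
    for (i in seq_len(n_permutations)) {
      draws[i, ] <- sample.int(length(universe), m)
    }
    vapply(conditions, function(cond) {
      rv <- r[universe, cond]
      dv <- unname(d_all[universe])
      apply(draws, 1, function(ix) sum(dv[ix] * rv[ix]))
    }, numeric(n_permutations))
  })
  p <- vapply(seq_along(conditions), function(i) {
    perm_pvalue(abs(null_w[, i]), abs(obs[i]))
  }, numeric(1))
  w_tbl <- tibble::tibble(condition = conditions, W = unname(obs),
                          p = p)

  terms <- tidyr::expand_grid(gene = measured, condition = conditions)
  terms$term <- unname(d_cl[terms$gene]) *
    r[cbind(terms$gene, terms$condition)]

  pair_cor <- NULL
  if (length(conditions) >= 2) {
    pairs <- utils::combn(conditions, 2)
    pair_cor <- with_seed(seed + 1L, {
      dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
        va <- d_cl * r[measured, pairs[1, j]]
        vb <- d_cl * r[measured, pairs[2, j]]
        robs <- stats::cor(va, vb)
        rnull <- vapply(seq_len(n_permutations), function(i) {
          abs(stats::cor(va, sample(vb)))
        }, numeric(1))
        tibble::tibble(cond_a = pairs[1, j], cond_b = pairs[2, j],
                       r = robs, p_perm = perm_pvalue(rnull, abs(robs)))
      }))
    })
  }
  structure(
    list(w = w_tbl, terms = terms, pair_cor = pair_cor,
         cluster = sort(measured),
         provenance = list(seed = seed, n_permutations = n_permutations,
                           degree_source = degree_source)),
    class = "weighted_ratio_result"
  )
}

#' @export
print.weighted_ratio_result <- function(x, ...) {
  cat("<weighted_ratio_result> cluster of ", length(x$cluster),
      " genes\n", sep = "")
  print(x$w)
  invisible(x)
}
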