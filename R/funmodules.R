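# Functional-module detection: correlation-filtered graph, Markov
# clustering, module overlap and term-overlap (enrichment-map) edges.

#' Build a correlation-filtered functional graph
#'
#' Connects two genes when their log-ratio trajectories over the ordered
#' conditions have a Pearson correlation at least `r_threshold`
#' (default 0.8; the threshold applies to the signed correlation — set
#' `use_abs = TRUE` to connect strong anti-correlation too) and, when a
#' backbone interaction network is supplied, when the pair is also a
#' backbone edge. Zero-variance genes cannot be correlated and are
#' excluded (counted in the `n_excluded` attribute).
#'
#' @param lrm log-ratio tibble over >= 3 conditions.
#' @param backbone optional interaction edge list restricting candidate
#'   pairs; `NULL` considers every gene pair.
#' @param r_threshold correlation threshold, inclusive (default 0.8).
#' @param use_abs threshold `|r|` instead of signed `r`.
#' @return object of class `functional_graph`: tibble (from, to, weight)
#'   with attributes `r_threshold`, `n_excluded`, `nodes`.
#' @export
build_functional_graph <- function(lrm, backbone = NULL, r_threshold = 0.8,
                                   use_abs = FALSE) {
  r <- tbl_to_matrix(lrm)
  if (ncol(r) < 3) rlang::abort("need >= 3 conditions for correlation")
  keep <- apply(r, 1, function(z) stats::var(z) > 0)
  n_excluded <- sum(!keep)
  r <- r[keep, , drop = FALSE]
  cc <- stats::cor(t(r))
  crit <- if (use_abs) abs(cc) else cc
  hit <- which(upper.tri(crit) & crit >= r_threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(cc)[hit[, 1]],
    to = rownames(cc)[hit[, 2]],
    weight = cc[hit]
  )
  if (!is.null(backbone)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    bb <- key(as.character(backbone[[1]]), as.character(backbone[[2]]))
    edges <- edges[key(edges$from, edges$to) %in% bb, ]
  }
  structure(edges, class = c("functional_graph", class(edges)),
            r_threshold = r_threshold, n_excluded = n_excluded,
            nodes = rownames(r))
}

#' Markov Cluster Algorithm on a weighted graph
#'
#' Classic MCL: a column-stochastic transition matrix is built from the
#' non-negative edge weights with unit self-loops, then expansion (matrix
#' power) and inflation (entrywise power followed by column
#' re-normalization) alternate, pruning entries below `prune_threshold`,
#' until the matrix changes by less than 1e-8 or `max_iter` is reached.
#' Clusters are read off the limit matrix's attractor structure: rows with
#' a surviving diagonal are attractors, attractors linked through nonzero
#' entries form attractor systems, and every node joins the system(s) it
#' flows into. A node attracted to several systems is assigned to the
#' lowest-labelled one. Modules smaller than `min_size` are discarded and
#' counted. Deterministic (no randomness in the loop).
#'
#' @param graph a `functional_graph` or any edge tibble with columns
#'   `from`, `to`, and optionally `weight` (default 1).
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter iteration cap (default 100); non-convergence returns
#'   the current clustering with `converged = FALSE` and a warning.
#' @param min_size minimum module size (default 3).
#' @return object of class `module_set`: list with `modules` (tibble:
#'   gene, module), `n_discarded` (genes in sub-minimum groups),
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2,
                        prune_threshold = 1e-5, max_iter = 100,
                        min_size = 3) {
  edges <- tibble::as_tibble(graph)
  if (nrow(edges) == 0) rlang::abort("empty graph")
  w <- if ("weight" %in% names(edges)) edges$weight else
    rep(1, nrow(edges))
  if (any(w < 0)) rlang::abort("edge weights must be non-negative")
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  M[cbind(edges$from, edges$to)] <- w
  M[cbind(edges$to, edges$from)] <- w
  diag(M) <- 1
  normalize_cols <- function(A) sweep(A, 2, colSums(A), "/")
  M <- normalize_cols(M)

  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    E <- M
    for (i in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E[E < prune_threshold] <- 0
    E <- normalize_cols(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn(sprintf("MCL did not converge within %d iterations",
                        max_iter))
  }

  # attractors: rows that retain mass on their own diagonal
  attractors <- which(diag(M) > prune_threshold)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # attractor systems: components of the attractor-attractor structure
  A <- (M[attractors, attractors, drop = FALSE] > 0) |
    t(M[attractors, attractors, drop = FALSE] > 0)
  ag <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            diag = FALSE)
  sys <- igraph::components(ag)$membership
  # every node joins the system of the attractors it flows into
  member <- rep(NA_integer_, n)
  flows <- M[attractors, , drop = FALSE] > 0
  for (j in seq_len(n)) {
    hit <- sys[flows[, j]]
    if (length(hit) > 0) {
      if (length(unique(hit)) > 1) {
        rlang::inform(sprintf(
          "node %s attracted to %d systems; assigned to the lowest label",
          nodes[j], length(unique(hit))
        ))
      }
      member[j] <- min(hit)
    }
  }
  member[is.na(member)] <- max(sys, 0) + seq_len(sum(is.na(member)))

  groups <- split(nodes, member)
  sizes <- lengths(groups)
  kept <- groups[sizes >= min_size]
  n_discarded <- sum(sizes[sizes < min_size])
  # stable labels: decreasing size, then smallest member id
  if (length(kept) > 0) {
    ord <- order(-lengths(kept), vapply(kept, min, character(1)))
    kept <- kept[ord]
    modules <- tibble::tibble(
      gene = unlist(kept, use.names = FALSE),
      module = rep(seq_along(kept), lengths(kept))
    )
  } else {
    modules <- tibble::tibble(gene = character(0), module = integer(0))
  }
  structure(
    list(modules = modules, n_discarded = n_discarded,
         converged = converged, iterations = iter),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- table(x$modules$module)
  cat("<module_set> ", length(sizes), " modules (sizes: ",
      paste(as.integer(sizes), collapse = ", "), "); ",
      x$n_discarded, " genes discarded; converged in ",
      x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Hypergeometric significance of the overlap of two gene modules
#'
#' Upper-tail probability `P(X >= |A intersect B|)` for a hypergeometric
#' draw of `|B|` genes from a universe of `N` containing `|A|` marked
#' genes.
#'
#' @param module_a,module_b character gene sets.
#' @param universe background gene set.
#' @return the p-value.
#' @export
module_overlap_significance <- function(module_a, module_b, universe) {
  a <- intersect(unique(module_a), universe)
  b <- intersect(unique(module_b), universe)
  k <- length(intersect(a, b))
  hyper_upper_tail(k, length(a), length(b), length(unique(universe)))
}

#' Overlap-coefficient edges between annotated term sets
#'
#' Enrichment-map construction: terms are linked when their overlap
#' coefficient `OC(A, B) = |A intersect B| / min(|A|, |B|)` reaches the
#' cutoff (inclusive, default 0.5). When a post-analysis gene list is
#' supplied, each term also receives the upper-tail hypergeometric p of
#' its overlap with that list over `post_universe`, and terms with
#' `p <= post_cutoff` are flagged.
#'
#' @param term_sets named list of gene sets.
#' @param similarity_cutoff OC threshold (default 0.5).
#' @param post_gene_list optional external gene list for post-analysis
#'   edge weights.
#' @param post_universe gene universe for the post-analysis test.
#' @param post_cutoff significance cutoff for flagged terms
#'   (default 0.01).
#' @return list with `edges` (tibble: term_a, term_b, oc) and, when a
#'   post list is given, `post` (tibble: term, k, p, significant).
#' @export
enrichment_map_edges <- function(term_sets, similarity_cutoff = 0.5,
                                 post_gene_list = NULL,
                                 post_universe = NULL,
                                 post_cutoff = 0.01) {
  ids <- names(term_sets)
  stopifnot(!is.null(ids))
  edges <- tibble::tibble(term_a = character(0), term_b = character(0),
                          oc = numeric(0))
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    oc <- vapply(seq_len(ncol(pairs)), function(j) {
      a <- unique(term_sets[[pairs[1, j]]])
      b <- unique(term_sets[[pairs[2, j]]])
      length(intersect(a, b)) / min(length(a), length(b))
    }, numeric(1))
    keep <- oc >= similarity_cutoff
    edges <- tibble::tibble(term_a = pairs[1, keep],
                            term_b = pairs[2, keep],
                            oc = oc[keep])
  }
  post <- NULL
  if (!is.null(post_gene_list)) {
    stopifnot(!is.null(post_universe))
    gl <- intersect(unique(post_gene_list), post_universe)
    N <- length(unique(post_universe))
    post <- dplyr::bind_rows(purrr::imap(term_sets, function(members, id) {
      members <- intersect(unique(members), post_universe)
      k <- length(intersect(gl, members))
      p <- hyper_upper_tail(k, length(members), length(gl), N)
      tibble::tibble(term = id, k = k, p = p,
                     significant = p <= post_cutoff)
    }))
  }
  list(edges = edges, post = post)
}

#' Functions enriched in modules of both datasets
#'
#' For each dataset, runs [term_enrichment()] of every module against the
#' annotated terms and collects the terms significant (q below
#' `q_cutoff`) in at least one module; the shared-function set is the
#' intersection across the two datasets, with an upper-tail
#' hypergeometric significance of the intersection size over the term
#' universe.
#'
#' @param modules_a,modules_b `module_set` objects (or tibbles with
#'   columns gene, module).
#' @param terms named list of term gene sets (shared annotation space).
#' @param universe_a,universe_b gene universes of the two datasets.
#' @param q_cutoff per-module enrichment cutoff (default 0.01).
#' @return list with `common_terms`, `enriched_a`, `enriched_b`, `p`
#'   (significance of the intersection size), `n_terms`.
#' @export
shared_function_count <- function(modules_a, modules_b, terms,
                                  universe_a, universe_b,
                                  q_cutoff = 0.01) {
  enriched_terms <- function(ms, universe) {
    tbl <- if (inherits(ms, "module_set")) ms$modules else ms
    hits <- character(0)
    for (m in unique(tbl$module)) {
      genes <- tbl$gene[tbl$module == m]
      res <- term_enrichment(genes, terms, universe)
      hits <- union(hits, res$term[res$q < q_cutoff])
    }
    hits
  }
  ea <- enriched_terms(modules_a, universe_a)
  eb <- enriched_terms(modules_b, universe_b)
  common <- intersect(ea, eb)
  n_terms <- length(terms)
  p <- if (length(ea) == 0 || length(eb) == 0) 1 else
    hyper_upper_tail(length(common), length(ea), length(eb), n_terms)
  list(common_terms = sort(common), enriched_a = sort(ea),
       enriched_b = sort(eb), p = p, n_terms = n_terms)
}
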