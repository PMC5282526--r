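#' Kolmogorov-Smirnov-type enrichment score of a tag set in a ranking
#'
#' The classic connectivity-map statistic. With `V(1) < ... < V(t)` the
#' sorted ranks of the `t` tag genes inside a ranking of `n` genes
#' (rank 1 = most up-regulated by the treatment),
#' `a = max_j (j/t - V(j)/n)` and `b = max_j (V(j)/n - (j-1)/t)`;
#' the score is `a` when `a >= b`, otherwise `-b`. Positive scores mean
#' the tags crowd the top of the ranking, negative the bottom; the score
#' lies in `[-1, 1]`.
#'
#' @param tags character vector of tag gene ids (non-empty).
#' @param ranking named integer vector mapping every gene of the instance
#'   universe to its rank (a permutation of `1..n`).
#' @param missing how to treat tags absent from the universe: drop them
#'   with a message (default) or raise an error.
#' @return the enrichment score, a single number in `[-1, 1]`.
#' @export
#' @examples
#' ranking <- stats::setNames(1:10, paste0("g", 1:10))
#' ks_enrichment(c("g1", "g2"), ranking)   #  0.8
#' ks_enrichment(c("g9", "g10"), ranking)  # -0.9
ks_enrichment <- function(tags, ranking, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  if (length(tags) == 0) rlang::abort("empty tag set")
  absent <- setdiff(tags, names(ranking))
  if (length(absent) > 0) {
    if (missing == "error") {
      rlang::abort(sprintf("%d tags missing from the ranking universe",
                           length(absent)))
    }
    rlang::inform(sprintf("dropped %d tags missing from the universe",
                          length(absent)))
    tags <- setdiff(tags, absent)
    if (length(tags) == 0) rlang::abort("no tags left after dropping")
  }
  ks_es(sort(unname(ranking[tags])), length(ranking))
}

# Core a/b statistic on sorted positions V within 1..n.
ks_es <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Connectivity of an up/down signature with one reference instance
#'
#' Scores the up and the down tag set separately and combines them: when
#' the two enrichment scores share a sign the query and the instance are
#' discordant and the combined score `c` is 0; otherwise
#' `c = ES_up - ES_down`, positive when the instance mimics the query
#' (up tags at the top, down tags at the bottom) and negative when it
#' inverts it. With a single tag direction, `c = ES_up` or `c = -ES_down`.
#'
#' @param sig a `sig_signature`.
#' @param ranking named rank vector of one instance.
#' @inheritParams ks_enrichment
#' @return tibble with columns `es_up`, `es_down`, `c`.
#' @export
instance_connectivity <- function(sig, ranking, missing = "drop") {
  if (length(sig$up) == 0 && length(sig$down) == 0) {
    rlang::abort("both tag sets empty")
  }
  es_up <- if (length(sig$up) > 0) {
    ks_enrichment(sig$up, ranking, missing)
  } else {
    NA_real_
  }
  es_down <- if (length(sig$down) > 0) {
    ks_enrichment(sig$down, ranking, missing)
  } else {
    NA_real_
  }
  c_val <- combine_es(es_up, es_down)
  tibble::tibble(es_up = es_up, es_down = es_down, c = c_val)
}

combine_es <- function(es_up, es_down) {
  if (is.na(es_up)) return(-es_down)
  if (is.na(es_down)) return(es_up)
  if (sign(es_up) == sign(es_down)) 0 else es_up - es_down
}

#' Scale combined connectivity scores to \[-1, 1\]
#'
#' Divides positive scores by the largest positive score and negative
#' scores by the magnitude of the most negative score; zeros stay zero.
#' Idempotent.
#'
#' @param c_values numeric vector of combined scores.
#' @return numeric vector in `[-1, 1]`.
#' @export
#' @examples
#' scale_scores(c(2, 1, -1))  # 1, 0.5, -1
scale_scores <- function(c_values) {
  out <- c_values
  pos <- c_values > 0
  neg <- c_values < 0
  if (any(pos)) out[pos] <- c_values[pos] / max(c_values[pos])
  if (any(neg)) out[neg] <- c_values[neg] / abs(min(c_values[neg]))
  out
}

#' Query a signature against a reference library with drug-level statistics
#'
#' Computes the per-instance combined connectivity score of the signature
#' with every instance, scales the scores, orders all `N` instances by
#' descending score, and summarizes each drug's `k` instance positions by
#' the same KS-type a/b statistic. Drug significance comes from random
#' position sets: `p = (1 + #\{|ES*| >= |ES|\}) / (1 + n_permutations)`,
#' where the null `ES*` are scores of `k` positions drawn uniformly from
#' `1..N` (one shared null per distinct `k`).
#'
#' @param sig a `sig_signature`.
#' @param library a `ref_library` (see [generate_reference_library()] and
#'   [read_rank_matrix()]).
#' @param n_permutations position permutations per drug size
#'   (default 1000).
#' @param seed RNG seed for the permutations.
#' @inheritParams ks_enrichment
#' @return object of class `connectivity_result`: list with `instances`
#'   (tibble: instance_id, drug, es_up, es_down, c, scaled, position),
#'   `drugs` (tibble: drug, es, p, n_instances), `provenance`.
#' @export
drug_enrichment <- function(sig, library, n_permutations = 1000, seed = 1,
                            missing = "drop") {
  ranks <- library$ranks
  meta <- library$meta
  stopifnot(identical(colnames(ranks), meta$instance_id))
  per_inst <- lapply(seq_len(ncol(ranks)), function(j) {
    ranking <- setNames(ranks[, j], rownames(ranks))
    instance_connectivity(sig, ranking, missing)
  })
  instances <- dplyr::bind_cols(meta, dplyr::bind_rows(per_inst))
  instances$scaled <- scale_scores(instances$c)
  # Descending combined score. Ties (notably the zero scores of
  # discordant instances) are broken uniformly at random under the run's
  # seed: a fixed tie order would park one drug's instances at fixed
  # positions inside the tied block and bias its position statistic.
  tie_key <- with_seed(seed, runif(nrow(instances)))
  ord <- order(-instances$c, tie_key)
  instances <- instances[ord, ]
  instances$position <- seq_len(nrow(instances))

  N <- nrow(instances)
  drug_tbl <- instances |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      es = ks_es(sort(.data$position), N),
      n_instances = dplyr::n(),
      .groups = "drop"
    )
  nulls <- with_seed(seed + 1L, {
    ks <- sort(unique(drug_tbl$n_instances))
    setNames(lapply(ks, function(k) {
      if (k > N) rlang::abort("drug has more instances than the library")
      vapply(seq_len(n_permutations), function(i) {
        abs(ks_es(sort(sample.int(N, k)), N))
      }, numeric(1))
    }), as.character(ks))
  })
  drug_tbl$p <- vapply(seq_len(nrow(drug_tbl)), function(i) {
    null <- nulls[[as.character(drug_tbl$n_instances[i])]]
    perm_pvalue(null, abs(drug_tbl$es[i]))
  }, numeric(1))
  drug_tbl <- dplyr::arrange(drug_tbl, dplyr::desc(.data$es))
  structure(
    list(
      instances = instances,
      drugs = dplyr::select(drug_tbl, "drug", "es", "p", "n_instances"),
      provenance = list(label = sig$label, seed = seed,
                        n_permutations = n_permutations,
                        n_instances = N)
    ),
    class = "connectivity_result"
  )
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("<connectivity_result '", x$provenance$label, "'> ",
      nrow(x$drugs), " drugs, ", x$provenance$n_instances,
      " instances, ", x$provenance$n_permutations,
      " permutations (seed ", x$provenance$seed, ")\n", sep = "")
  print(utils::head(x$drugs, 5))
  invisible(x)
}

#' Correlate the drug enrichment-score profiles of two queries
#'
#' The central reversal statistic: Pearson correlation between the
#' drug-level enrichment scores of two queries over the drugs passing a
#' permutation-p filter. A strongly negative coefficient means the two
#' queries are inversely connected through the reference library.
#'
#' @param result_a,result_b `connectivity_result` objects over a shared
#'   library.
#' @param p_threshold permutation-p filter on drugs (default 0.05).
#' @param rule keep drugs significant in `"either"` query (default) or in
#'   `"both"`.
#' @return tibble with `r`, `p`, `n_drugs`, and the drug list as a
#'   list-column.
#' @export
profile_correlation <- function(result_a, result_b, p_threshold = 0.05,
                                rule = c("either", "both")) {
  rule <- match.arg(rule)
  a <- result_a$drugs
  b <- result_b$drugs
  shared <- intersect(a$drug, b$drug)
  sig_a <- a$drug[a$p < p_threshold]
  sig_b <- b$drug[b$p < p_threshold]
  kept <- if (rule == "either") union(sig_a, sig_b) else
    intersect(sig_a, sig_b)
  kept <- intersect(kept, shared)
  if (length(kept) < 3) {
    rlang::abort(sprintf(
      "only %d drugs pass the filter; at least 3 required", length(kept)
    ))
  }
  ea <- setNames(a$es, a$drug)[kept]
  eb <- setNames(b$es, b$drug)[kept]
  ct <- stats::cor.test(ea, eb, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    p = ct$p.value,
    n_drugs = length(kept),
    drugs = list(sort(kept))
  )
}
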