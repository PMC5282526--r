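#' Repressor-weighted pathway activity
#'
#' Activity of a pathway in a condition is the mean signed log2 ratio of
#' its members: `A = (1/|members|) * sum(w_g * r_g)` over the measured
#' members, with role weight `w_g = -1` for repressors and `+1` for
#' activators. By default the divisor is the full membership size even
#' when some members are unmeasured (missing members contribute 0); set
#' `divisor = "measured"` to normalize by the measured count instead.
#'
#' @param lrm log-ratio tibble from [log_ratio()].
#' @param pathways long tibble with columns `pathway`, `gene`, `weight`
#'   (+1 activator / -1 repressor); every pathway needs >= 2 members.
#' @param conditions condition columns to score (default: all).
#' @param divisor `"membership"` (default) or `"measured"`.
#' @return tibble: pathway, condition, activity, n_members, n_genes_used.
#'   Pathways with no measured member get `NA` activity.
#' @export
pathway_activity <- function(lrm, pathways,
                             conditions = NULL,
                             divisor = c("membership", "measured")) {
  divisor <- match.arg(divisor)
  check_pathways(pathways)
  r <- tbl_to_matrix(lrm)
  if (is.null(conditions)) conditions <- colnames(r)
  r <- r[, conditions, drop = FALSE]
  by_pw <- split(pathways[c("gene", "weight")], pathways$pathway)
  rows <- lapply(names(by_pw), function(id) {
    pw <- by_pw[[id]]
    measured <- pw$gene %in% rownames(r)
    denom <- if (divisor == "membership") nrow(pw) else sum(measured)
    acts <- if (sum(measured) == 0) {
      rep(NA_real_, length(conditions))
    } else {
      colSums(pw$weight[measured] *
                r[pw$gene[measured], , drop = FALSE]) / denom
    }
    tibble::tibble(
      pathway = id, condition = conditions, activity = unname(acts),
      n_members = nrow(pw), n_genes_used = sum(measured)
    )
  })
  dplyr::bind_rows(rows)
}

check_pathways <- function(pathways) {
  err <- list()
  if (!all(c("pathway", "gene", "weight") %in% names(pathways))) {
    err <- c(err, "pathways need columns pathway, gene, weight")
  } else {
    if (!all(pathways$weight %in% c(-1, 1))) {
      err <- c(err, "role weights must be +1 or -1")
    }
    sizes <- table(pathways$pathway)
    if (any(sizes < 2)) {
      err <- c(err, sprintf("pathways with < 2 members rejected: %s",
                            paste(names(sizes)[sizes < 2], collapse = ", ")))
    }
  }
  check_all(err, "pathway table")
}

#' Permutation significance of pathway activities
#'
#' For each pathway, the null redraws a random gene set of the same size
#' from the measured genes and randomly reassigns the pathway's
#' role-weight multiset, recomputing the activity; the two-sided p-value
#' is `(1 + #\{|A*| >= |A|\}) / (1 + n_permutations)` and q-values are
#' Benjamini-Hochberg adjusted across all pathways tested in the run.
#'
#' @inheritParams pathway_activity
#' @param condition single condition column to test.
#' @param n_permutations random gene sets per pathway (default 1000).
#' @param seed RNG seed.
#' @return object of class `pathway_activity_result`: tibble (pathway,
#'   activity, n_members, n_genes_used, p, q) plus provenance attributes.
#' @export
activity_significance <- function(lrm, pathways, condition,
                                  n_permutations = 1000, seed = 1,
                                  divisor = c("membership", "measured")) {
  divisor <- match.arg(divisor)
  act <- pathway_activity(lrm, pathways, conditions = condition,
                          divisor = divisor)
  r <- tbl_to_matrix(lrm)[, condition]
  n_meas <- length(r)
  by_pw <- split(pathways[c("gene", "weight")], pathways$pathway)
  sizes <- vapply(by_pw, nrow, integer(1))
  if (any(sizes > n_meas)) {
    rlang::abort("measured gene universe smaller than a pathway")
  }
  p <- with_seed(seed, {
    vapply(names(by_pw), function(id) {
      w <- by_pw[[id]]$weight
      m <- length(w)
      denom <- if (divisor == "membership") m else m
      null <- vapply(seq_len(n_permutations), function(i) {
        abs(sum(sample(w) * r[sample.int(n_meas, m)]) / denom)
      }, numeric(1))
      obs <- abs(act$activity[act$pathway == id])
      if (is.na(obs)) return(NA_real_)
      perm_pvalue(null, obs)
    }, numeric(1))
  })
  out <- dplyr::select(act, "pathway", "activity", "n_members",
                       "n_genes_used")
  out$p <- unname(p[out$pathway])
  out$q <- bh_adjust(out$p)
  structure(
    out,
    class = c("pathway_activity_result", class(out)),
    condition = condition,
    provenance = list(seed = seed, n_permutations = n_permutations,
                      divisor = divisor)
  )
}

#' Over-representation test of a gene set against annotated terms
#'
#' One-sided Fisher's exact test (upper hypergeometric tail) per term from
#' the 2x2 table of query membership vs term membership over a gene
#' universe, with Benjamini-Hochberg adjustment across terms. The
#' conservative EASE variant (one query hit removed before the tail) is
#' available behind `ease = TRUE`.
#'
#' @param query character vector of query genes (non-empty, within the
#'   universe).
#' @param terms named list of gene sets, or a long tibble with columns
#'   `term` and `gene`.
#' @param universe character vector of background genes.
#' @param ease apply the EASE correction (default FALSE).
#' @return tibble sorted by p: term, k (query hits), K (term size),
#'   n (query size), N (universe size), p, q.
#' @export
term_enrichment <- function(query, terms, universe, ease = FALSE) {
  if (length(query) == 0) rlang::abort("empty query gene set")
  if (is.data.frame(terms)) {
    terms <- split(terms$gene, terms$term)
  }
  query <- intersect(unique(query), universe)
  N <- length(unique(universe))
  n <- length(query)
  rows <- purrr::imap(terms, function(members, id) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    k_eff <- if (ease) max(k - 1, 0) else k
    tibble::tibble(term = id, k = k, K = K, n = n, N = N,
                   p = hyper_upper_tail(k_eff, K, n, N))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p, .data$term)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values: `q_(i) = min_(j >= i) (m/j) p_(j)`, capped at 1,
#' returned in the input order. `NA` entries are passed through.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
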