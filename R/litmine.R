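# Keyword literature-association statistics (offline).

#' Binarize a literature count matrix
#'
#' Replaces every positive count with 1, removing the bias a few heavily
#' referred items would otherwise exert on set-level sums. Idempotent.
#'
#' @param lit wide tibble: `item` column plus one count column per
#'   keyword.
#' @return tibble of the same shape with entries in \{0, 1\}.
#' @export
binarize <- function(lit) {
  m <- tbl_to_matrix(lit)
  if (any(m < 0)) rlang::abort("counts must be non-negative")
  out <- matrix_to_tbl((m > 0) * 1L, id_name = names(lit)[1])
  names(out)[1] <- names(lit)[1]
  out
}

#' Randomized-set association test of an item set with keyword literature
#'
#' Binarizes the matrix, sums the query items' presence across all
#' keywords, and compares the sum with those of `n_random` same-sized
#' item sets drawn uniformly without replacement from all matrix items:
#' `p = (1 + #\{null >= observed\}) / (1 + n_random)` (one-sided, add-one
#' corrected, never 0).
#'
#' @param query_items character vector of item ids (must be rows of the
#'   matrix).
#' @param lit literature count tibble (`item` column + keyword columns).
#' @param n_random randomized sets (default 1000).
#' @param seed RNG seed.
#' @return object of class `set_association`: list with `observed`,
#'   `null_sums`, `p`, `n_random`, `seed`, `n_items`.
#' @export
set_association_test <- function(query_items, lit, n_random = 1000,
                                 seed = 1) {
  if (n_random < 1) rlang::abort("`n_random` must be at least 1")
  b <- tbl_to_matrix(binarize(lit))
  b <- b[order(rownames(b)), , drop = FALSE]  # canonical item order: the
  # seeded null draws must not depend on input row order
  items <- rownames(b)
  query_items <- unique(as.character(query_items))
  if (!all(query_items %in% items)) {
    rlang::abort("query items missing from the literature matrix")
  }
  if (length(query_items) > length(items)) {
    rlang::abort("query larger than the item universe")
  }
  row_sums <- rowSums(b)
  observed <- sum(row_sums[query_items])
  k <- length(query_items)
  null_sums <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      sum(row_sums[sample.int(length(items), k)])
    }, numeric(1))
  })
  structure(
    list(observed = observed, null_sums = null_sums,
         p = perm_pvalue(null_sums, observed),
         n_random = n_random, seed = seed, n_items = k),
    class = "set_association"
  )
}

#' @export
print.set_association <- function(x, ...) {
  cat("<set_association> ", x$n_items, " items: observed sum ",
      x$observed, ", null mean ", signif(mean(x$null_sums), 4),
      ", p = ", signif(x$p, 4), " (", x$n_random, " random sets)\n",
      sep = "")
  invisible(x)
}

#' Incremental literature-association curve
#'
#' Orders items by total reference count (descending; ties broken by item
#' id) — or uses a caller-supplied ranking — and applies the
#' randomized-set test to every prefix, starting from the single most
#' referred item.
#'
#' @param lit literature count tibble.
#' @param ranked_items optional explicit item ordering; default ranks by
#'   total raw count.
#' @param n_random randomized sets per prefix (default 1000).
#' @param seed RNG seed; prefix `i` uses `seed + i` so each prefix test is
#'   reproducible in isolation.
#' @return tibble: prefix_size, item_added, observed, p.
#' @export
incremental_curve <- function(lit, ranked_items = NULL, n_random = 1000,
                              seed = 1) {
  m <- tbl_to_matrix(lit)
  if (is.null(ranked_items)) {
    totals <- rowSums(m)
    ranked_items <- rownames(m)[order(-totals, rownames(m))]
  }
  rows <- lapply(seq_along(ranked_items), function(i) {
    res <- set_association_test(ranked_items[seq_len(i)], lit,
                                n_random = n_random, seed = seed + i)
    tibble::tibble(prefix_size = i, item_added = ranked_items[i],
                   observed = res$observed, p = res$p)
  })
  dplyr::bind_rows(rows)
}
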