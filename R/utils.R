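# Internal helpers shared across modules.

# Wide tibble (id column + numeric columns) -> numeric matrix with rownames.
tbl_to_matrix <- function(x, id_col = 1L) {
  x <- as.data.frame(x)
  ids <- as.character(x[[id_col]])
  m <- as.matrix(x[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_name = "gene") {
  out <- tibble::as_tibble(as.data.frame(m))
  out <- tibble::add_column(out, !!id_name := rownames(m), .before = 1)
  out
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Collect validation messages and raise them all at once.
check_all <- function(errors, what) {
  errors <- errors[!vapply(errors, is.null, logical(1))]
  if (length(errors) > 0) {
    rlang::abort(c(paste0("invalid ", what, ":"), unlist(errors)))
  }
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}

# Row-wise Pearson correlation of each row of `x` against each row of `y`
# (both n x k over the same k conditions). Returns nrow(x) x nrow(y).
row_cor <- function(x, y) {
  k <- ncol(x)
  stopifnot(ncol(y) == k)
  xs <- x - rowMeans(x)
  ys <- y - rowMeans(y)
  xn <- sqrt(rowSums(xs^2))
  yn <- sqrt(rowSums(ys^2))
  (xs %*% t(ys)) / outer(xn, yn)
}

# Add-one permutation p-value: share of null statistics at least as extreme.
perm_pvalue <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}

# Upper-tail hypergeometric P(X >= k) drawing n from an urn with K successes
# out of N. Shared by Fisher-style enrichment and module overlap.
hyper_upper_tail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
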