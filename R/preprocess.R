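#' Filter genes above local background
#'
#' Keeps a gene when its intensity is at least `factor` times the local
#' background (default 1.4-fold) in at least one sample (`scope = "any"`,
#' the default) or in every sample (`scope = "all"`).
#'
#' @param study an `expr_study` with a `background` component.
#' @param factor background ratio threshold (default 1.4).
#' @param scope `"any"` (expressed in any condition) or `"all"`.
#' @return the filtered `expr_study`; the number of genes dropped is
#'   reported via a message.
#' @export
filter_above_background <- function(study, factor = 1.4,
                                    scope = c("any", "all")) {
  scope <- match.arg(scope)
  if (is.null(study$background)) {
    rlang::abort(paste(
      "study has no background matrix;",
      "skip background filtering for pre-filtered data"
    ))
  }
  x <- tbl_to_matrix(study$intensities)
  b <- tbl_to_matrix(study$background)
  stopifnot(identical(dim(x), dim(b)))
  ok <- x >= factor * b
  keep <- if (scope == "any") rowSums(ok) >= 1 else rowSums(ok) == ncol(ok)
  rlang::inform(sprintf(
    "background filter (%.3g-fold, scope=%s): kept %d of %d genes",
    factor, scope, sum(keep), length(keep)
  ))
  study$intensities <- study$intensities[keep, , drop = FALSE]
  study$background <- study$background[keep, , drop = FALSE]
  study
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the identical distribution (the
#' row-wise mean of the sorted columns); ties within a column receive the
#' mean of the values at their tied ranks. Idempotent.
#'
#' @param x wide tibble/data frame: gene id column first, one numeric
#'   column per sample.
#' @return tibble of the same shape.
#' @export
#' @examples
#' m <- tibble::tibble(gene = c("a", "b"), s1 = c(1, 3), s2 = c(2, 4))
#' quantile_normalize(m)
quantile_normalize <- function(x) {
  m <- tbl_to_matrix(x)
  if (anyNA(m)) rlang::abort("missing values are not allowed")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  matrix_to_tbl(out, id_name = names(x)[1])
}

#' Log2 expression ratios relative to a reference condition
#'
#' Computes `r_g = log2((x_g + pseudo) / (x_ref,g + pseudo))` for every
#' non-reference sample; when several samples carry the reference role the
#' reference is their row-wise mean intensity.
#'
#' @param study an `expr_study`.
#' @param reference_role role label of the reference condition (default
#'   `"control"`).
#' @param pseudo pseudo-count added to intensities before the ratio
#'   (default 1); guard against near-zero intensities.
#' @return wide tibble: `gene` plus one log2-ratio column per
#'   non-reference sample.
#' @export
log_ratio <- function(study, reference_role = "control", pseudo = 1) {
  x <- tbl_to_matrix(study$intensities)
  ref_samples <- study$roles$sample[study$roles$role == reference_role]
  if (length(ref_samples) == 0) {
    rlang::abort(sprintf("no sample has role '%s'", reference_role))
  }
  ref <- rowMeans(x[, ref_samples, drop = FALSE])
  if (pseudo == 0 && any(ref == 0)) {
    rlang::abort("zero reference intensity with pseudo = 0")
  }
  other <- setdiff(colnames(x), ref_samples)
  r <- log2((x[, other, drop = FALSE] + pseudo) / (ref + pseudo))
  matrix_to_tbl(r)
}

#' Construct an up/down tag signature
#'
#' @param up,down disjoint character vectors of gene ids (at least one
#'   non-empty).
#' @param label free-text label.
#' @param max_tags tag cap per direction (default 1000).
#' @return object of class `sig_signature`.
#' @export
new_signature <- function(up, down, label = "query", max_tags = 1000) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  err <- list()
  if (length(up) == 0 && length(down) == 0) {
    err <- c(err, "at least one of up/down must be non-empty")
  }
  if (length(intersect(up, down)) > 0) {
    err <- c(err, "up and down tags must be disjoint")
  }
  if (length(up) > max_tags || length(down) > max_tags) {
    err <- c(err, sprintf("tag sets exceed the cap of %d", max_tags))
  }
  check_all(err, "signature")
  structure(list(up = up, down = down, label = label),
            class = "sig_signature")
}

#' @export
print.sig_signature <- function(x, ...) {
  cat("<signature '", x$label, "'> ", length(x$up), " up tags, ",
      length(x$down), " down tags\n", sep = "")
  invisible(x)
}

#' Select fold-changed genes into an up/down signature
#'
#' A gene becomes an up tag when its log2 ratio reaches `log2(fold)` in at
#' least one condition (`scope = "any"`) or in all conditions
#' (`scope = "all"`); down tags analogously at `-log2(fold)`. Boundaries
#' are inclusive. A gene qualifying up in one condition and down in
#' another is excluded from both directions and reported in the
#' `conflicting` attribute. When a direction exceeds `max_tags`, tags are
#' kept in decreasing order of the maximum absolute log2 ratio.
#'
#' @param lrm log-ratio tibble from [log_ratio()].
#' @param fold fold-change threshold, must be > 1 (default 2).
#' @param scope `"any"` or `"all"` conditions.
#' @param conditions optional subset of condition columns to use.
#' @param label signature label.
#' @param max_tags per-direction tag cap (default 1000).
#' @return a `sig_signature`; attribute `conflicting` lists excluded genes.
#' @export
select_fold_change <- function(lrm, fold = 2, scope = c("any", "all"),
                               conditions = NULL, label = "query",
                               max_tags = 1000) {
  scope <- match.arg(scope)
  if (!is.numeric(fold) || fold <= 1) {
    rlang::abort("`fold` must be greater than 1")
  }
  r <- tbl_to_matrix(lrm)
  if (!is.null(conditions)) r <- r[, conditions, drop = FALSE]
  thr <- log2(fold)
  up_hit <- r >= thr
  down_hit <- r <= -thr
  agg <- function(hit) {
    if (scope == "any") rowSums(hit) >= 1 else rowSums(hit) == ncol(hit)
  }
  up <- agg(up_hit)
  down <- agg(down_hit)
  conflicting <- rownames(r)[up & down]
  up_genes <- rownames(r)[up & !down]
  down_genes <- rownames(r)[down & !up]
  if (length(conflicting) > 0) {
    rlang::inform(sprintf(
      "%d genes qualified in both directions and were excluded",
      length(conflicting)
    ))
  }
  cap <- function(g) {
    if (length(g) <= max_tags) return(g)
    strength <- apply(abs(r[g, , drop = FALSE]), 1, max)
    g[order(-strength, g)][seq_len(max_tags)]
  }
  sig <- new_signature(cap(up_genes), cap(down_genes), label = label,
                       max_tags = max_tags)
  attr(sig, "conflicting") <- conflicting
  sig
}

#' Translate signature gene ids through a mapping table
#'
#' Applies a two-column orthology/platform mapping (`from_id`, `to_id`) to
#' both tag sets; unmapped genes are dropped with a message and duplicate
#' targets collapse ("first mapping wins").
#'
#' @param sig a `sig_signature`.
#' @param mapping data frame with columns `from_id` and `to_id`.
#' @return the mapped `sig_signature`.
#' @export
map_signature <- function(sig, mapping) {
  stopifnot(all(c("from_id", "to_id") %in% names(mapping)))
  mapping <- mapping[!duplicated(mapping$from_id), ]
  lut <- setNames(as.character(mapping$to_id), as.character(mapping$from_id))
  remap <- function(g) {
    hit <- g %in% names(lut)
    if (any(!hit)) {
      rlang::inform(sprintf("%d unmapped genes dropped", sum(!hit)))
    }
    unique(unname(lut[g[hit]]))
  }
  up <- remap(sig$up)
  down <- remap(sig$down)
  both <- intersect(up, down)
  new_signature(setdiff(up, both), setdiff(down, both), label = sig$label)
}

# All cumulative unit-change templates over `k` conditions: per-step
# changes in {-1, 0, +1}, anchored at 0, flat template removed.
unit_profiles <- function(n_cond) {
  steps <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n_cond - 1)))
  prof <- cbind(0, t(apply(steps, 1, cumsum)))
  prof[rowSums(abs(steps)) > 0, , drop = FALSE]
}

# Greedy farthest-point selection of `n_keep` rows, seeded with the row of
# largest norm (ties: lowest index). Deterministic.
select_distinct_profiles <- function(prof, n_keep) {
  if (nrow(prof) <= n_keep) return(prof)
  norms <- sqrt(rowSums(prof^2))
  chosen <- which.max(norms)
  d2 <- colSums((t(prof) - prof[chosen, ])^2)
  while (length(chosen) < n_keep) {
    nxt <- which.max(d2)
    chosen <- c(chosen, nxt)
    d2 <- pmin(d2, colSums((t(prof) - prof[nxt, ])^2))
  }
  prof[sort(chosen), , drop = FALSE]
}

#' Assign genes to model expression profiles with permutation FDR
#'
#' A desk-scale analogue of short-time-series profile mining: candidate
#' templates are all cumulative unit-change sequences over the ordered
#' conditions (per-step change in -1/0/+1), capped at `n_profiles` by
#' greedy farthest-point selection; each gene is assigned to the template
#' with the highest Pearson correlation (ties to the lower template
#' index). Zero-variance genes are unassignable and counted. Per-profile
#' significance comes from permuting condition labels independently per
#' gene: the permutation tail probability of the observed profile count,
#' Benjamini-Hochberg adjusted across profiles.
#'
#' @param lrm log-ratio tibble over ordered conditions (>= 3).
#' @param n_profiles maximum number of templates retained (default 8).
#' @param n_permutations label permutations for the count null
#'   (default 1000).
#' @param seed RNG seed for the permutations.
#' @return object of class `profile_assignment`: list with `profiles`
#'   (template matrix), `assignment` (tibble: gene, profile, cor),
#'   `counts` (tibble: profile, n, p, q), `n_unassigned`.
#' @export
assign_model_profiles <- function(lrm, n_profiles = 8,
                                  n_permutations = 1000, seed = 1) {
  r <- tbl_to_matrix(lrm)
  k <- ncol(r)
  if (k < 3) rlang::abort("at least 3 ordered conditions are required")
  prof <- select_distinct_profiles(unit_profiles(k), n_profiles)
  rownames(prof) <- sprintf("profile%02d", seq_len(nrow(prof)))

  flat <- apply(r, 1, function(z) stats::var(z) == 0)
  usable <- r[!flat, , drop = FALSE]

  assign_once <- function(mat) {
    cc <- row_cor(mat, prof)
    max.col(cc, ties.method = "first")
  }
  idx <- assign_once(usable)
  cc <- row_cor(usable, prof)
  assignment <- tibble::tibble(
    gene = rownames(usable),
    profile = rownames(prof)[idx],
    cor = cc[cbind(seq_len(nrow(usable)), idx)]
  )
  obs_counts <- tabulate(idx, nbins = nrow(prof))

  v <- as.vector(usable)              # column-major: row ids cycle 1..n
  row_id <- rep(seq_len(nrow(usable)), times = k)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      ord <- order(row_id, runif(length(v)))
      perm <- matrix(v[ord], nrow = nrow(usable), byrow = TRUE)
      tabulate(assign_once(perm), nbins = nrow(prof))
    }, integer(nrow(prof)))
  })
  p <- vapply(seq_len(nrow(prof)), function(i) {
    perm_pvalue(null_counts[i, ], obs_counts[i])
  }, numeric(1))
  counts <- tibble::tibble(
    profile = rownames(prof),
    n = obs_counts,
    p = p,
    q = bh_adjust(p)
  )
  structure(
    list(profiles = prof, assignment = assignment, counts = counts,
         n_unassigned = sum(flat),
         provenance = list(seed = seed, n_permutations = n_permutations)),
    class = "profile_assignment"
  )
}

#' @export
print.profile_assignment <- function(x, ...) {
  cat("<profile_assignment> ", nrow(x$assignment), " genes over ",
      nrow(x$profiles), " templates (", x$n_unassigned,
      " flat genes unassigned)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Two-class regularized difference statistic
#'
#' A regularized mean-difference score for a two-group contrast:
#' `d_g = (mean2 - mean1) / (s_g + s0)` with `s_g` the pooled standard
#' error of the mean difference and the fudge factor `s0` a quantile
#' (default the median) of the `s_g` distribution. Genes with
#' `|d| >= threshold` are selected, split by sign.
#'
#' @param x wide tibble: gene column plus one column per sample.
#' @param groups named character vector mapping sample column names to one
#'   of exactly two group labels; each group needs >= 2 samples.
#' @param threshold selection cutoff on `|d|` (the conventional values are
#'   2.0 and 4.0).
#' @param s0_quantile quantile of `{s_g}` used as the fudge factor.
#' @return object of class `two_class_selection`: tibble of per-gene
#'   scores plus the selected up/down gene sets.
#' @export
two_class_statistic <- function(x, groups, threshold = 2,
                                s0_quantile = 0.5) {
  m <- tbl_to_matrix(x)
  groups <- groups[colnames(m)]
  lev <- sort(unique(unname(groups)))
  if (length(lev) != 2) rlang::abort("exactly two group labels required")
  g1 <- colnames(m)[groups == lev[1]]
  g2 <- colnames(m)[groups == lev[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    rlang::abort("each group needs at least 2 samples")
  }
  m1 <- m[, g1, drop = FALSE]
  m2 <- m[, g2, drop = FALSE]
  n1 <- length(g1)
  n2 <- length(g2)
  ss <- rowSums((m1 - rowMeans(m1))^2) + rowSums((m2 - rowMeans(m2))^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  s0 <- stats::quantile(s, s0_quantile, names = FALSE)
  d <- (rowMeans(m2) - rowMeans(m1)) / (s + s0)
  scores <- tibble::tibble(gene = rownames(m), d = unname(d), s = unname(s))
  structure(
    list(scores = scores, s0 = s0, threshold = threshold,
         groups = list(reference = lev[1], test = lev[2]),
         selected_up = scores$gene[scores$d >= threshold],
         selected_down = scores$gene[scores$d <= -threshold]),
    class = "two_class_selection"
  )
}

#' @export
print.two_class_selection <- function(x, ...) {
  cat("<two_class_selection> ", nrow(x$scores), " genes; |d| >= ",
      x$threshold, ": ", length(x$selected_up), " up, ",
      length(x$selected_down), " down (s0 = ",
      signif(x$s0, 3), ")\n", sep = "")
  invisible(x)
}
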