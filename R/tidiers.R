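# broom-style tidy()/glance() methods for the fitted result objects.

#' @rdname sigrev_tidiers
#' @method tidy connectivity_result
#' @export
tidy.connectivity_result <- function(x, level = c("drug", "instance"),
                                     ...) {
  level <- match.arg(level)
  if (level == "drug") x$drugs else tibble::as_tibble(x$instances)
}

#' @rdname sigrev_tidiers
#' @method glance connectivity_result
#' @export
glance.connectivity_result <- function(x, ...) {
  tibble::tibble(
    label = x$provenance$label,
    n_drugs = nrow(x$drugs),
    n_instances = x$provenance$n_instances,
    n_significant = sum(x$drugs$p < 0.05),
    n_permutations = x$provenance$n_permutations,
    seed = x$provenance$seed
  )
}

#' @rdname sigrev_tidiers
#' @method tidy pathway_activity_result
#' @export
tidy.pathway_activity_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname sigrev_tidiers
#' @method glance pathway_activity_result
#' @export
glance.pathway_activity_result <- function(x, ...) {
  tibble::tibble(
    condition = attr(x, "condition"),
    n_pathways = nrow(x),
    n_significant = sum(x$q < 0.01, na.rm = TRUE),
    n_permutations = attr(x, "provenance")$n_permutations,
    seed = attr(x, "provenance")$seed
  )
}

#' @rdname sigrev_tidiers
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  x$modules
}

#' @rdname sigrev_tidiers
#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(
    n_modules = length(unique(x$modules$module)),
    n_genes = nrow(x$modules),
    n_discarded = x$n_discarded,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' @rdname sigrev_tidiers
#' @method tidy weighted_ratio_result
#' @export
tidy.weighted_ratio_result <- function(x, ...) {
  x$w
}

#' @rdname sigrev_tidiers
#' @method glance weighted_ratio_result
#' @export
glance.weighted_ratio_result <- function(x, ...) {
  tibble::tibble(
    n_cluster_genes = length(x$cluster),
    n_conditions = nrow(x$w),
    n_permutations = x$provenance$n_permutations,
    seed = x$provenance$seed
  )
}

#' @rdname sigrev_tidiers
#' @method tidy set_association
#' @export
tidy.set_association <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = mean(x$null_sums),
                 null_sd = stats::sd(x$null_sums), p = x$p)
}

#' @rdname sigrev_tidiers
#' @method glance set_association
#' @export
glance.set_association <- function(x, ...) {
  tibble::tibble(n_items = x$n_items, n_random = x$n_random,
                 seed = x$seed, p = x$p)
}

#' @rdname sigrev_tidiers
#' @method tidy two_class_selection
#' @export
tidy.two_class_selection <- function(x, ...) {
  dplyr::mutate(x$scores, selected = dplyr::case_when(
    .data$d >= x$threshold ~ "up",
    .data$d <= -x$threshold ~ "down",
    TRUE ~ "no"
  ))
}

#' @rdname sigrev_tidiers
#' @method glance two_class_selection
#' @export
glance.two_class_selection <- function(x, ...) {
  tibble::tibble(
    s0 = x$s0, threshold = x$threshold,
    n_up = length(x$selected_up), n_down = length(x$selected_down),
    n_genes = nrow(x$scores)
  )
}

#' @rdname sigrev_tidiers
#' @method tidy profile_assignment
#' @export
tidy.profile_assignment <- function(x, ...) {
  x$assignment
}

#' @rdname sigrev_tidiers
#' @method glance profile_assignment
#' @export
glance.profile_assignment <- function(x, ...) {
  tibble::tibble(
    n_profiles = nrow(x$profiles),
    n_assigned = nrow(x$assignment),
    n_unassigned = x$n_unassigned,
    n_significant = sum(x$counts$q < 0.05),
    n_permutations = x$provenance$n_permutations
  )
}

#' Tidiers for sigrev result objects
#'
#' `tidy()` returns the per-element result table of a fitted object
#' (per-drug scores, per-pathway activities, per-gene module labels, ...);
#' `glance()` returns a one-row summary with sizes, counts of significant
#' calls, and provenance.
#'
#' @param x a sigrev result object.
#' @param level for connectivity results, `"drug"` (default) or
#'   `"instance"`.
#' @param ... unused.
#' @return a tibble.
#' @name sigrev_tidiers
NULL
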