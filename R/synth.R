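#' Configuration for the synthetic study generator
#'
#' Defines the planted structure of a synthetic disease/treatment study:
#' a control vs disease contrast with a block of fold-changed genes, a dose
#' (or time) series in which the planted effect is progressively restored
#' toward control, a reference library of drug-instance rankings in which
#' some drugs mimic and some invert the disease signature, pathways with
#' known direction (including a role-flipped duplicate), an interaction
#' network realizing a planted module partition, and an item-by-keyword
#' literature count matrix with one planted enriched item set.
#'
#' @param n_genes number of genes in the universe.
#' @param n_drugs number of drugs in the reference library; drugs are
#'   labelled `drug01`, `drug02`, ...
#' @param instances_per_drug treatment instances (full rankings) per drug.
#' @param n_disease_genes number of genes shifted in the disease state.
#' @param frac_disease_up fraction of disease genes shifted up (the rest
#'   are shifted down).
#' @param effect_log2 planted log2 fold-change magnitude. Default 2 (a
#'   4-fold shift), so that partially restored treatment responses still
#'   clear a 2-fold selection threshold.
#' @param noise_sd standard deviation of additive log2-scale noise.
#' @param reversal_drugs labels of drugs planted to invert the disease
#'   signature (disease-up genes at the bottom of their rankings).
#' @param mimic_drugs labels of drugs planted to copy the disease signature.
#'   Must be disjoint from `reversal_drugs`.
#' @param doses_or_times ordered labels of the treatment series conditions.
#' @param restore_fraction_per_step fraction of the remaining planted effect
#'   removed at each successive dose/time step, so the residual log2 effect
#'   after step s is `effect_log2 * (1 - restore_fraction_per_step)^s`.
#' @param rank_noise rankings in the reference library are perturbed by
#'   `round(rank_noise * n_genes)` random adjacent transpositions; 0 gives
#'   noise-free planted rankings.
#' @param n_control,n_disease number of control / disease replicate columns.
#' @param n_pathways,pathway_size number and typical size of generated
#'   pathways (three of them are planted: one up, one down, and a
#'   role-flipped duplicate of the up pathway).
#' @param module_sizes sizes of the planted network modules; the first is
#'   drawn from disease-up genes, the second from disease-down genes.
#' @param p_within,p_between edge probabilities inside and between planted
#'   modules (and for background nodes).
#' @param n_background_nodes extra non-module genes added to the network.
#' @param lit_enriched_prob,lit_background_prob probability that a planted
#'   enriched item (resp. any other item) has a nonzero count for a keyword.
#' @param seed master RNG seed; each generator derives its own stream from
#'   it by a fixed offset, so stages are reproducible in isolation.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 200, n_drugs = 10, seed = 7)
#' cfg$reversal_drugs
synth_config <- function(n_genes = 2000,
                         n_drugs = 50,
                         instances_per_drug = 2,
                         n_disease_genes = 200,
                         frac_disease_up = 0.5,
                         effect_log2 = 2,
                         noise_sd = 0.1,
                         reversal_drugs = NULL,
                         mimic_drugs = NULL,
                         doses_or_times = c("dose10", "dose50", "dose100"),
                         restore_fraction_per_step = 0.5,
                         rank_noise = 0.5,
                         n_control = 1,
                         n_disease = 1,
                         n_pathways = 20,
                         pathway_size = 15,
                         module_sizes = c(8, 8),
                         p_within = 0.9,
                         p_between = 0.02,
                         n_background_nodes = 100,
                         lit_enriched_prob = 0.9,
                         lit_background_prob = 0.15,
                         seed = 1) {
  drugs <- sprintf("drug%02d", seq_len(max(n_drugs, 1)))
  if (is.null(reversal_drugs)) {
    reversal_drugs <- drugs[seq_len(min(5, n_drugs))]
  }
  if (is.null(mimic_drugs)) {
    remaining <- setdiff(drugs, reversal_drugs)
    mimic_drugs <- remaining[seq_len(min(5, length(remaining)))]
  }
  cfg <- list(
    n_genes = n_genes, n_drugs = n_drugs,
    instances_per_drug = instances_per_drug,
    n_disease_genes = n_disease_genes, frac_disease_up = frac_disease_up,
    effect_log2 = effect_log2, noise_sd = noise_sd,
    reversal_drugs = reversal_drugs, mimic_drugs = mimic_drugs,
    doses_or_times = doses_or_times,
    restore_fraction_per_step = restore_fraction_per_step,
    rank_noise = rank_noise,
    n_control = n_control, n_disease = n_disease,
    n_pathways = n_pathways, pathway_size = pathway_size,
    module_sizes = module_sizes,
    p_within = p_within, p_between = p_between,
    n_background_nodes = n_background_nodes,
    lit_enriched_prob = lit_enriched_prob,
    lit_background_prob = lit_background_prob,
    seed = seed
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  err <- list()
  for (f in c("n_genes", "n_drugs", "instances_per_drug", "n_disease_genes",
              "n_control", "n_disease", "n_pathways", "pathway_size",
              "n_background_nodes")) {
    if (!is_count(cfg[[f]])) {
      err <- c(err, sprintf("`%s` must be a positive integer", f))
    }
  }
  for (f in c("frac_disease_up", "restore_fraction_per_step", "p_within",
              "p_between", "lit_enriched_prob", "lit_background_prob")) {
    if (!is_fraction(cfg[[f]])) {
      err <- c(err, sprintf("`%s` must lie in [0, 1]", f))
    }
  }
  if (!is.numeric(cfg$effect_log2) || cfg$effect_log2 < 0) {
    err <- c(err, "`effect_log2` must be non-negative")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    err <- c(err, "`noise_sd` must be non-negative")
  }
  if (!is.numeric(cfg$rank_noise) || cfg$rank_noise < 0) {
    err <- c(err, "`rank_noise` must be non-negative")
  }
  if (length(intersect(cfg$reversal_drugs, cfg$mimic_drugs)) > 0) {
    err <- c(err, "`reversal_drugs` and `mimic_drugs` must be disjoint")
  }
  if (is_count(cfg$n_genes) && is_count(cfg$n_disease_genes) &&
      cfg$n_disease_genes > cfg$n_genes) {
    err <- c(err, "`n_disease_genes` cannot exceed `n_genes`")
  }
  if (length(cfg$doses_or_times) < 1) {
    err <- c(err, "`doses_or_times` must name at least one condition")
  }
  check_all(err, "synth_config")
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a synthetic expression study with planted disease structure
#'
#' Intensities follow a log-normal model `2^(baseline + effect + noise)`:
#' a per-gene baseline drawn once, a planted log2 effect (`+effect_log2`
#' for disease-up genes, `-effect_log2` for disease-down genes in disease
#' columns, geometrically shrunk across the dose/time series), and iid
#' Gaussian log2 noise. A small fraction of genes is generated dim (near
#' the local background) to exercise background filtering.
#'
#' @param config a [synth_config()].
#' @return a list with components `study` (class `expr_study`: tibbles
#'   `intensities` and `background` of genes x samples, plus a `roles`
#'   tibble mapping sample to role) and `truth` (planted up/down gene sets
#'   and per-dose residual effects).
#' @export
generate_expression_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 101L, {
    n <- config$n_genes
    genes <- gene_ids(n)

    n_dim <- floor(0.05 * n)
    bright <- setNames(rep(TRUE, n), genes)
    if (n_dim > 0) {
      dim_genes <- sample(genes, n_dim)
      bright[dim_genes] <- FALSE
    }
    baseline <- ifelse(bright, rnorm(n, mean = 9, sd = 1), rnorm(n, 6, 0.3))
    names(baseline) <- genes

    n_dis <- config$n_disease_genes
    pool <- genes[bright]
    if (length(pool) < n_dis) pool <- genes
    disease_genes <- sort(sample(pool, n_dis))
    n_up <- round(config$frac_disease_up * n_dis)
    up_genes <- disease_genes[seq_len(n_up)]
    down_genes <- setdiff(disease_genes, up_genes)

    effect <- setNames(numeric(n), genes)
    effect[up_genes] <- config$effect_log2
    effect[down_genes] <- -config$effect_log2

    keep_frac <- 1 - config$restore_fraction_per_step
    steps <- seq_along(config$doses_or_times)
    residual <- config$effect_log2 * keep_frac^steps

    samples <- c(
      paste0("control_", seq_len(config$n_control)),
      paste0("disease_", seq_len(config$n_disease)),
      paste0("treated_", config$doses_or_times)
    )
    roles <- tibble::tibble(
      sample = samples,
      role = c(rep("control", config$n_control),
               rep("disease", config$n_disease),
               paste0("dose:", config$doses_or_times))
    )

    log2_mat <- matrix(baseline, nrow = n, ncol = length(samples),
                       dimnames = list(genes, samples))
    dis_cols <- which(roles$role == "disease")
    log2_mat[, dis_cols] <- log2_mat[, dis_cols] + effect
    for (s in steps) {
      col <- which(roles$sample == paste0("treated_", config$doses_or_times[s]))
      log2_mat[, col] <- log2_mat[, col] + sign(effect) * residual[s]
    }
    if (config$noise_sd > 0) {
      log2_mat <- log2_mat + matrix(rnorm(length(log2_mat), 0, config$noise_sd),
                                    nrow = n)
    }
    intensities <- 2^log2_mat

    background <- matrix(runif(length(intensities), 80, 120),
                         nrow = n, dimnames = dimnames(intensities))

    study <- structure(
      list(intensities = matrix_to_tbl(intensities),
           background = matrix_to_tbl(background),
           roles = roles),
      class = "expr_study"
    )
    truth <- list(
      up_genes = up_genes,
      down_genes = down_genes,
      residual_effect = setNames(residual, config$doses_or_times),
      pathway_direction = NULL,
      module_partition = NULL,
      enriched_literature_items = NULL
    )
    list(study = study, truth = truth)
  })
}

#' @export
print.expr_study <- function(x, ...) {
  cat("<expr_study> ", nrow(x$intensities), " genes x ",
      nrow(x$roles), " samples\n", sep = "")
  cat("roles:", paste(unique(x$roles$role), collapse = ", "), "\n")
  invisible(x)
}

# Perturb a ranking vector (values = ranks) by n_swaps random adjacent
# transpositions of the underlying ordered gene list.
perturb_ranking <- function(ord, n_swaps) {
  n <- length(ord)
  if (n_swaps <= 0 || n < 2) return(ord)
  pos <- sample.int(n - 1, n_swaps, replace = TRUE)
  for (i in pos) {
    tmp <- ord[i]
    ord[i] <- ord[i + 1]
    ord[i + 1] <- tmp
  }
  ord
}

#' Generate a synthetic reference library of drug-instance rankings
#'
#' Each instance is a full permutation of the gene universe with rank 1 the
#' gene most up-regulated by the treatment. Mimic drugs place the planted
#' disease-up genes at the top and disease-down genes at the bottom;
#' reversal drugs do the opposite; all other drugs are uniform random
#' permutations. Planted rankings are then perturbed by random adjacent
#' transpositions (`rank_noise`).
#'
#' @param config a [synth_config()].
#' @param truth planted truth from [generate_expression_study()].
#' @return an object of class `ref_library`: list with `ranks` (integer
#'   genes x instances matrix) and `meta` (tibble: instance_id, drug).
#' @export
generate_reference_library <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config$n_genes)
  if (length(genes) == 0) rlang::abort("empty gene universe")
  stopifnot(all(truth$up_genes %in% genes), all(truth$down_genes %in% genes))
  with_seed(config$seed + 202L, {
    drugs <- sprintf("drug%02d", seq_len(config$n_drugs))
    meta <- tidyr::expand_grid(drug = drugs,
                               rep = seq_len(config$instances_per_drug))
    meta <- dplyr::mutate(meta,
      instance_id = sprintf("%s_i%d", .data$drug, .data$rep))
    meta <- dplyr::select(meta, "instance_id", "drug")

    n <- length(genes)
    n_swaps <- round(config$rank_noise * n)
    up <- truth$up_genes
    down <- truth$down_genes
    middle <- setdiff(genes, c(up, down))

    ranks <- matrix(NA_integer_, nrow = n, ncol = nrow(meta),
                    dimnames = list(genes, meta$instance_id))
    for (j in seq_len(nrow(meta))) {
      drug <- meta$drug[j]
      if (drug %in% config$mimic_drugs) {
        ord <- c(sample(up), sample(middle), sample(down))
      } else if (drug %in% config$reversal_drugs) {
        ord <- c(sample(down), sample(middle), sample(up))
      } else {
        ord <- sample(genes)
      }
      ord <- perturb_ranking(ord, if (drug %in% c(config$mimic_drugs,
                                                  config$reversal_drugs))
        n_swaps else 0L)
      ranks[ord, j] <- seq_len(n)
    }
    structure(list(ranks = ranks, meta = meta), class = "ref_library")
  })
}

#' @export
print.ref_library <- function(x, ...) {
  cat("<ref_library> ", nrow(x$ranks), " genes x ", ncol(x$ranks),
      " instances (", length(unique(x$meta$drug)), " drugs)\n", sep = "")
  invisible(x)
}

#' Generate a synthetic pathway database with activator/repressor roles
#'
#' Pathways are gene sets over the universe with a per-gene role weight
#' (+1 activator, -1 repressor). Three pathways are planted: `path_up`
#' (activators drawn from disease-up genes, direction +1), `path_down`
#' (activators from disease-down genes, direction -1), and
#' `path_up_flipped`, a duplicate of `path_up` with every role flipped to
#' repressor (direction -1) — its activity is exactly the negation of
#' `path_up`'s. Remaining pathways are random gene sets (direction 0) with
#' roughly 10% repressors.
#'
#' @inheritParams generate_reference_library
#' @return list with `pathways` (long tibble: pathway, gene, weight) and
#'   `direction` (named vector of planted pathway directions).
#' @export
generate_pathway_db <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config$n_genes)
  if (config$pathway_size < 2) rlang::abort("pathway size must be >= 2")
  with_seed(config$seed + 303L, {
    sz <- config$pathway_size
    up_members <- sample(truth$up_genes, min(sz, length(truth$up_genes)))
    down_members <- sample(truth$down_genes, min(sz, length(truth$down_genes)))
    planted <- list(
      path_up = tibble::tibble(pathway = "path_up", gene = up_members,
                               weight = 1),
      path_down = tibble::tibble(pathway = "path_down", gene = down_members,
                                 weight = 1),
      path_up_flipped = tibble::tibble(pathway = "path_up_flipped",
                                       gene = up_members, weight = -1)
    )
    n_rand <- max(config$n_pathways - length(planted), 0)
    rand <- lapply(seq_len(n_rand), function(i) {
      size <- max(2, sz + sample(-5:5, 1))
      members <- sample(genes, size)
      tibble::tibble(
        pathway = sprintf("path_rand%02d", i),
        gene = members,
        weight = ifelse(runif(size) < 0.1, -1, 1)
      )
    })
    pathways <- dplyr::bind_rows(c(planted, rand))
    direction <- setNames(
      c(1, -1, -1, rep(0, n_rand)),
      c("path_up", "path_down", "path_up_flipped",
        if (n_rand > 0) sprintf("path_rand%02d", seq_len(n_rand)))
    )
    list(pathways = pathways, direction = direction)
  })
}

#' Generate a synthetic interaction network realizing a module partition
#'
#' Planted modules are dense near-cliques (edge probability `p_within`);
#' all other node pairs, including background nodes, are connected with
#' probability `p_between`. The first module is drawn from disease-up
#' genes, the second (if any) from disease-down genes, further modules from
#' the remaining universe. The graph is simple and undirected.
#'
#' @inheritParams generate_reference_library
#' @return list with `edges` (tibble: from, to), `nodes` (character), and
#'   `partition` (named vector gene -> module label for planted modules).
#' @export
generate_interaction_network <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config$n_genes)
  with_seed(config$seed + 404L, {
    sizes <- config$module_sizes
    pools <- list(truth$up_genes, truth$down_genes)
    used <- character(0)
    members <- vector("list", length(sizes))
    for (m in seq_along(sizes)) {
      pool <- if (m <= length(pools)) setdiff(pools[[m]], used) else
        setdiff(genes, c(used, truth$up_genes, truth$down_genes))
      if (length(pool) < sizes[m]) pool <- setdiff(genes, used)
      members[[m]] <- sort(sample(pool, sizes[m]))
      used <- c(used, members[[m]])
    }
    partition <- setNames(
      rep(seq_along(members), lengths(members)),
      unlist(members)
    )
    background <- sample(setdiff(genes, used),
                         min(config$n_background_nodes,
                             length(setdiff(genes, used))))
    nodes <- c(unlist(members), background)

    pairs <- utils::combn(nodes, 2)
    same_module <- !is.na(partition[pairs[1, ]]) &
      !is.na(partition[pairs[2, ]]) &
      partition[pairs[1, ]] == partition[pairs[2, ]]
    same_module[is.na(same_module)] <- FALSE
    p_edge <- ifelse(same_module, config$p_within, config$p_between)
    keep <- runif(ncol(pairs)) < p_edge
    edges <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep])
    list(edges = edges, nodes = nodes, partition = partition)
  })
}

#' Generate a synthetic item-by-keyword literature count matrix
#'
#' Emulates a literature co-citation matrix: non-negative integer counts of
#' papers mentioning each item (drug or gene) together with each keyword.
#' Planted enriched items (by default the reversal drugs) have an elevated
#' probability of a nonzero count per keyword; a few entries are inflated
#' to emulate heavily referred items.
#'
#' @inheritParams generate_reference_library
#' @param enriched_items items planted as enriched; default the config's
#'   `reversal_drugs`.
#' @return list with `counts` (wide tibble: item, one column per keyword)
#'   and `enriched_items` (character).
#' @export
generate_literature_counts <- function(config, truth,
                                       enriched_items = NULL) {
  stopifnot(inherits(config, "synth_config"))
  keywords <- c("diabetes", "lipidemia", "glycemia", "hyperglycemia",
                "hyperlipidemia", "obesity", "triglyceride", "insulin",
                "adipocyte", "adipose")
  items <- sprintf("drug%02d", seq_len(config$n_drugs))
  enriched_items <- enriched_items %||% config$reversal_drugs
  with_seed(config$seed + 505L, {
    p <- ifelse(items %in% enriched_items,
                config$lit_enriched_prob, config$lit_background_prob)
    counts <- matrix(0L, nrow = length(items), ncol = length(keywords),
                     dimnames = list(items, keywords))
    for (i in seq_along(items)) {
      nz <- runif(length(keywords)) < p[i]
      counts[i, nz] <- rpois(sum(nz), 4) + 1L
    }
    # a few heavily referred entries, the bias binarization must remove
    if (length(items) >= 2) {
      hot <- sample(which(counts > 0), min(3, sum(counts > 0)))
      counts[hot] <- counts[hot] * 500L
    }
    out <- tibble::as_tibble(as.data.frame(counts))
    out <- tibble::add_column(out, item = items, .before = 1)
    list(counts = out, enriched_items = enriched_items)
  })
}

#' Generate every synthetic input for the full pipeline
#'
#' Runs all five generators from one configuration and assembles the
#' complete planted truth.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_bundle` with `study`, `library`,
#'   `pathways`, `network`, `literature`, `truth`, and `config`.
#' @export
#' @examples
#' sb <- synth_bundle(synth_config(n_genes = 300, n_drugs = 12, seed = 3))
#' names(sb)
synth_bundle <- function(config) {
  es <- generate_expression_study(config)
  truth <- es$truth
  lib <- generate_reference_library(config, truth)
  pw <- generate_pathway_db(config, truth)
  truth$pathway_direction <- pw$direction
  net <- generate_interaction_network(config, truth)
  truth$module_partition <- net$partition
  lit <- generate_literature_counts(config, truth)
  truth$enriched_literature_items <- lit$enriched_items
  structure(
    list(study = es$study, library = lib, pathways = pw$pathways,
         network = net$edges, literature = lit$counts,
         truth = truth, config = config),
    class = "synth_bundle"
  )
}
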