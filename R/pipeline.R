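# End-to-end orchestration: simulate -> preprocess -> signatures ->
# connectivity (two queries) -> pathway activity -> network efficacy ->
# modules -> literature association.

#' Configuration for a full pipeline run
#'
#' Collects the synthetic-study block and all stage thresholds in one
#' declarative object. Validation enumerates every problem at once.
#'
#' @param synth a [synth_config()] describing the synthetic inputs, or
#'   `NULL` when `inputs` provides file paths.
#' @param inputs optional named list of file paths (`expression`,
#'   `background`, `ranks`, `meta`, `gmt`, `roles`, `edges`,
#'   `literature`) used instead of the synth block.
#' @param background_factor background filter threshold (default 1.4).
#' @param fold fold-change threshold for signatures (default 2).
#' @param r_threshold functional-graph correlation threshold
#'   (default 0.8).
#' @param oc_cutoff enrichment-map overlap-coefficient cutoff
#'   (default 0.5).
#' @param p_cutoff drug filter for the profile correlation
#'   (default 0.05).
#' @param q_cutoff FDR cutoff for pathway/module calls (default 0.01).
#' @param n_permutations permutations for every permutation test
#'   (default 1000).
#' @param seed master seed.
#' @param output_dir optional directory; when set, [run_pipeline()]
#'   writes every stage table there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            inputs = NULL,
                            background_factor = 1.4,
                            fold = 2,
                            r_threshold = 0.8,
                            oc_cutoff = 0.5,
                            p_cutoff = 0.05,
                            q_cutoff = 0.01,
                            n_permutations = 1000,
                            seed = 1,
                            output_dir = NULL) {
  cfg <- list(synth = synth, inputs = inputs,
              background_factor = background_factor, fold = fold,
              r_threshold = r_threshold, oc_cutoff = oc_cutoff,
              p_cutoff = p_cutoff, q_cutoff = q_cutoff,
              n_permutations = n_permutations, seed = seed,
              output_dir = output_dir)
  err <- list()
  if (is.null(synth) && is.null(inputs)) {
    err <- c(err, "either a synth block or an inputs list is required")
  }
  if (!is.null(synth) && !inherits(synth, "synth_config")) {
    err <- c(err, "`synth` must be a synth_config object")
  }
  if (!is.null(inputs)) {
    needed <- c("expression", "roles", "ranks", "meta", "gmt", "edges",
                "literature")
    missing_in <- setdiff(needed, names(inputs))
    if (length(missing_in) > 0) {
      err <- c(err, sprintf("missing input paths: %s",
                            paste(missing_in, collapse = ", ")))
    }
    gone <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(gone) > 0) {
      err <- c(err, sprintf("input files not found: %s",
                            paste(gone, collapse = ", ")))
    }
  }
  if (!is.numeric(fold) || fold <= 1) {
    err <- c(err, "`fold` must exceed 1")
  }
  for (f in c("background_factor", "n_permutations")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      err <- c(err, sprintf("`%s` must be non-negative", f))
    }
  }
  for (f in c("p_cutoff", "q_cutoff", "oc_cutoff")) {
    if (!is_fraction(cfg[[f]])) {
      err <- c(err, sprintf("`%s` must lie in [0, 1]", f))
    }
  }
  if (!is.numeric(r_threshold) || abs(r_threshold) > 1) {
    err <- c(err, "`r_threshold` must lie in [-1, 1]")
  }
  check_all(err, "pipeline_config")
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(bundle, stage, ...) {
  msg <- sprintf(...)
  rlang::inform(sprintf("[%s] %s", stage, msg))
  bundle$log <- c(bundle$log, setNames(msg, stage))
  bundle
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on synthetic (or file-based)
#' inputs: background filtering, quantile normalization, log ratios,
#' fold-change signatures for the disease contrast and for the treatment
#' response, connectivity scoring of both queries against the reference
#' library, their profile correlation, repressor-weighted pathway
#' activities with permutation q-values, degree-weighted network efficacy
#' across the dose series, correlation-graph Markov modules, and the
#' randomized literature-association test of the significantly reversing
#' drugs. Reruns with the same config are identical (all randomness is
#' seeded); per-stage runtimes are recorded but excluded from the
#' provenance hash.
#'
#' @param config a [pipeline_config()].
#' @return object of class `result_bundle`; see the individual stage
#'   functions for the component types. When `config$output_dir` is set
#'   the tables are also written there as TSV/JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  nperm <- config$n_permutations
  bundle <- list(log = character(0), runtimes = numeric(0))
  tic <- function() proc.time()[["elapsed"]]
  mark <- function(bundle, stage, t0) {
    bundle$runtimes[stage] <- round(tic() - t0, 3)
    bundle
  }

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)))
    })
  }

  # --- inputs -----------------------------------------------------------
  t0 <- tic()
  sb <- run_stage("inputs", function() {
    if (!is.null(config$synth)) {
      synth_bundle(config$synth)
    } else {
      load_inputs(config$inputs)
    }
  })
  bundle$truth <- sb$truth
  bundle <- mark(bundle, "inputs", t0)

  # --- preprocess -------------------------------------------------------
  t0 <- tic()
  pre <- run_stage("preprocess", function() {
    study <- sb$study
    if (!is.null(study$background)) {
      study <- suppressMessages(
        filter_above_background(study, config$background_factor)
      )
    }
    study$intensities <- quantile_normalize(study$intensities)
    lrm_control <- log_ratio(study, reference_role = "control")
    list(study = study, lrm = lrm_control)
  })
  bundle <- stage_log(bundle, "preprocess", "%d genes retained",
                      nrow(pre$lrm))
  bundle$lrm <- pre$lrm
  bundle <- mark(bundle, "preprocess", t0)

  # --- signatures -------------------------------------------------------
  t0 <- tic()
  sigs <- run_stage("signatures", function() {
    roles <- pre$study$roles
    disease_cols <- roles$sample[roles$role == "disease"]
    dose_cols <- roles$sample[grepl("^(dose|time):", roles$role)]
    disease_sig <- suppressMessages(select_fold_change(
      pre$lrm, fold = config$fold, conditions = disease_cols,
      label = "disease"
    ))
    # treatment response: ratios of treated conditions to the disease state
    study_t <- pre$study
    study_t$roles$role[study_t$roles$role == "disease"] <- "reference"
    lrm_treat <- log_ratio(study_t, reference_role = "reference")
    treat_sig <- suppressMessages(select_fold_change(
      lrm_treat[, c(1, match(dose_cols, names(lrm_treat))), drop = FALSE],
      fold = config$fold, label = "treatment"
    ))
    list(disease = disease_sig, treatment = treat_sig,
         disease_cols = disease_cols, dose_cols = dose_cols)
  })
  bundle$signatures <- sigs[c("disease", "treatment")]
  bundle <- stage_log(bundle, "signatures",
                      "disease %du/%dd, treatment %du/%dd tags",
                      length(sigs$disease$up), length(sigs$disease$down),
                      length(sigs$treatment$up),
                      length(sigs$treatment$down))
  bundle <- mark(bundle, "signatures", t0)

  # --- connectivity -----------------------------------------------------
  t0 <- tic()
  conn <- run_stage("connectivity", function() {
    qa <- suppressMessages(drug_enrichment(
      sigs$disease, sb$library, n_permutations = nperm, seed = seed + 11
    ))
    qb <- suppressMessages(drug_enrichment(
      sigs$treatment, sb$library, n_permutations = nperm, seed = seed + 12
    ))
    pc <- profile_correlation(qa, qb, p_threshold = config$p_cutoff)
    list(disease = qa, treatment = qb, correlation = pc)
  })
  bundle$connectivity <- conn
  bundle <- stage_log(bundle, "connectivity",
                      "profile correlation r = %.3f over %d drugs",
                      conn$correlation$r, conn$correlation$n_drugs)
  bundle <- mark(bundle, "connectivity", t0)

  # --- pathway activity -------------------------------------------------
  t0 <- tic()
  pw <- run_stage("pathways", function() {
    cond <- sigs$disease_cols[1]
    keep <- sb$pathways$gene %in% pre$lrm[[1]]
    sizes <- table(sb$pathways$pathway[keep])
    usable <- names(sizes)[sizes >= 2]
    activity_significance(
      pre$lrm, sb$pathways[keep & sb$pathways$pathway %in% usable, ],
      condition = cond, n_permutations = nperm, seed = seed + 21
    )
  })
  bundle$pathway_activity <- pw
  bundle <- stage_log(bundle, "pathways", "%d pathways, %d at q < %g",
                      nrow(pw), sum(pw$q < config$q_cutoff, na.rm = TRUE),
                      config$q_cutoff)
  bundle <- mark(bundle, "pathways", t0)

  # --- network efficacy -------------------------------------------------
  t0 <- tic()
  net <- run_stage("netscore", function() {
    de_genes <- c(sigs$disease$up, sigs$disease$down)
    cl <- suppressWarnings(largest_cluster(de_genes, sb$network))
    conds <- c(sigs$disease_cols, sigs$dose_cols)
    conds <- intersect(conds, names(pre$lrm))
    wr <- weighted_ratio_significance(
      cl, pre$lrm, sb$network, conditions = conds,
      n_permutations = nperm, seed = seed + 31
    )
    list(cluster = cl, result = wr)
  })
  bundle$netscore <- net
  bundle <- stage_log(bundle, "netscore",
                      "largest cluster %d nodes; W(disease) = %.1f",
                      length(net$cluster$nodes), net$result$w$W[1])
  bundle <- mark(bundle, "netscore", t0)

  # --- functional modules -----------------------------------------------
  t0 <- tic()
  mods <- run_stage("modules", function() {
    de_genes <- c(sigs$disease$up, sigs$disease$down)
    lrm_de <- pre$lrm[pre$lrm[[1]] %in% de_genes, , drop = FALSE]
    fg <- build_functional_graph(lrm_de, backbone = sb$network,
                                 r_threshold = config$r_threshold)
    ms <- suppressMessages(mcl_cluster(fg))
    list(graph = fg, modules = ms)
  })
  bundle$modules <- mods$modules
  bundle <- stage_log(bundle, "modules", "%d modules over %d genes",
                      length(unique(mods$modules$modules$module)),
                      nrow(mods$modules$modules))
  bundle <- mark(bundle, "modules", t0)

  # --- literature -------------------------------------------------------
  t0 <- tic()
  lit <- run_stage("literature", function() {
    drugs <- bundle$connectivity$disease$drugs
    hits <- drugs$drug[drugs$p < config$p_cutoff & drugs$es < 0]
    if (length(hits) == 0) {
      hits <- drugs$drug[order(drugs$es)][1:3]
    }
    hits <- intersect(hits, sb$literature$item)
    sa <- set_association_test(hits, sb$literature, n_random = nperm,
                               seed = seed + 41)
    curve <- incremental_curve(
      sb$literature[sb$literature$item %in% hits, ],
      n_random = nperm, seed = seed + 42
    )
    list(query_items = sort(hits), association = sa, curve = curve)
  })
  bundle$literature <- lit
  bundle <- stage_log(bundle, "literature",
                      "%d reversing drugs, association p = %.4g",
                      length(lit$query_items), lit$association$p)
  bundle <- mark(bundle, "literature", t0)

  bundle$config <- config
  hash_input <- bundle[setdiff(names(bundle), c("runtimes", "log"))]
  bundle$provenance <- list(
    seed = seed, n_permutations = nperm,
    config_hash = rlang::hash(config),
    bundle_hash = rlang::hash(hash_input)
  )
  bundle <- structure(bundle, class = "result_bundle")
  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config$output_dir)
  }
  bundle
}

load_inputs <- function(inputs) {
  study <- structure(
    list(intensities = read_expression_tsv(inputs$expression),
         background = if (!is.null(inputs$background)) {
           read_expression_tsv(inputs$background)
         },
         roles = read_tsv_plain(inputs$roles)),
    class = "expr_study"
  )
  list(
    study = study,
    library = read_rank_matrix(inputs$ranks, inputs$meta),
    pathways = read_gmt(inputs$gmt, inputs$roles_sidecar %||%
                          inputs$roles_gmt %||% NULL),
    network = read_edge_list(inputs$edges),
    literature = read_literature_tsv(inputs$literature),
    truth = NULL
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle> seed ", x$provenance$seed, ", hash ",
      x$provenance$bundle_hash, "\n", sep = "")
  for (s in names(x$log)) cat("  ", s, ": ", x$log[[s]], "\n", sep = "")
  invisible(x)
}

#' Write a result bundle to a directory of TSV/JSON files
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov_header <- sprintf("# config_hash: %s",
                         bundle$provenance$config_hash)
  write_with_header <- function(x, path) {
    con <- file(path, "w")
    writeLines(prov_header, con)
    utils::write.table(x, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  write_with_header(bundle$connectivity$disease$drugs,
                    file.path(dir, "connectivity_disease.tsv"))
  write_with_header(bundle$connectivity$treatment$drugs,
                    file.path(dir, "connectivity_treatment.tsv"))
  write_with_header(
    dplyr::select(bundle$connectivity$correlation, -"drugs"),
    file.path(dir, "profile_correlation.tsv")
  )
  write_with_header(as.data.frame(bundle$pathway_activity),
                    file.path(dir, "pathway_activity.tsv"))
  write_with_header(bundle$netscore$result$w,
                    file.path(dir, "network_efficacy.tsv"))
  write_with_header(bundle$modules$modules,
                    file.path(dir, "modules.tsv"))
  write_with_header(bundle$literature$curve,
                    file.path(dir, "literature_curve.tsv"))
  # runtimes stay in the in-memory bundle only: written artifacts must be
  # bit-identical across reruns of the same config + seed
  jsonlite::write_json(
    list(provenance = bundle$provenance, log = as.list(bundle$log)),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  summary_lines <- c(
    "pipeline summary",
    sprintf("seed: %d", bundle$provenance$seed),
    sprintf("bundle hash: %s", bundle$provenance$bundle_hash),
    sprintf("%s: %s", names(bundle$log), bundle$log)
  )
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Pairwise profile correlations and shared functions of three analyses
#'
#' Tabulates all pairwise drug enrichment-score correlations between
#' three connectivity analyses (e.g. two disease studies and one
#' drug-treated study) and, when module sets and term annotations are
#' available in the bundles, the three-way intersection of module-enriched
#' terms.
#'
#' @param bundle_a,bundle_b,bundle_c `result_bundle` or
#'   `connectivity_result` objects.
#' @param p_threshold drug filter for each pairwise correlation.
#' @return list with `pairwise` (tibble: pair, r, p, n_drugs) and
#'   `skipped` (character vector of pairs without shared drugs).
#' @export
compare_three_way <- function(bundle_a, bundle_b, bundle_c,
                              p_threshold = 0.05) {
  get_conn <- function(x) {
    if (inherits(x, "result_bundle")) x$connectivity$disease else x
  }
  conns <- list(A = get_conn(bundle_a), B = get_conn(bundle_b),
                C = get_conn(bundle_c))
  pairs <- utils::combn(names(conns), 2)
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    shared <- intersect(conns[[a]]$drugs$drug, conns[[b]]$drugs$drug)
    if (length(shared) == 0) {
      rlang::inform(sprintf(
        "pair %s-%s skipped: no shared drugs", a, b
      ))
      skipped <- c(skipped, paste0(a, "-", b))
      next
    }
    pc <- profile_correlation(conns[[a]], conns[[b]],
                              p_threshold = p_threshold)
    rows[[length(rows) + 1]] <- tibble::tibble(
      pair = paste0(a, "-", b), r = pc$r, p = pc$p, n_drugs = pc$n_drugs
    )
  }
  list(pairwise = dplyr::bind_rows(rows), skipped = skipped)
}
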