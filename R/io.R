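# Plain-text readers and writers for the pipeline's interchange formats.

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Read/write an expression matrix TSV
#'
#' Genes by samples; first column the gene id, header row the sample ids.
#'
#' @param x wide tibble (gene column first).
#' @param path file path.
#' @return `read_expression_tsv` returns a tibble; the writer returns the
#'   path invisibly.
#' @export
write_expression_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) read_tsv_plain(path)

#' Read/write a rank-matrix reference library
#'
#' The rank matrix is a TSV of genes by instances holding integer ranks
#' with the convention rank 1 = most up-regulated by the treatment; this
#' convention is declared in a comment header line written by the writer
#' and checked by the reader. Instance metadata (instance_id, drug, and
#' optional columns) travels in a companion TSV. The reader breaks any
#' rank ties deterministically by gene-id lexical order, with a warning.
#'
#' @param library a `ref_library`.
#' @param ranks_path,meta_path file paths for the rank matrix and the
#'   instance metadata.
#' @return the reader returns a `ref_library`; the writer the paths,
#'   invisibly.
#' @export
write_rank_matrix <- function(library, ranks_path, meta_path) {
  con <- file(ranks_path, "w")
  writeLines("# rank_direction: 1 = most up-regulated by treatment", con)
  tbl <- matrix_to_tbl(library$ranks)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  write_tsv_plain(library$meta, meta_path)
  invisible(c(ranks_path, meta_path))
}

#' @rdname write_rank_matrix
#' @export
read_rank_matrix <- function(ranks_path, meta_path) {
  first <- readLines(ranks_path, n = 1)
  if (!grepl("rank_direction", first)) {
    rlang::warn(paste(
      "rank matrix does not declare its rank direction;",
      "assuming 1 = most up-regulated"
    ))
  }
  raw <- utils::read.delim(ranks_path, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  m <- tbl_to_matrix(tibble::as_tibble(raw))
  # enforce tie-free integer permutations per instance
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (anyDuplicated(col)) {
      rlang::warn(sprintf(
        "ties in instance %s broken by gene-id order", colnames(m)[j]
      ))
    }
    m[, j] <- rank(col, ties.method = "first")
  }
  storage.mode(m) <- "integer"
  meta <- read_tsv_plain(meta_path)
  meta <- meta[match(colnames(m), meta$instance_id), ]
  structure(list(ranks = m, meta = tibble::as_tibble(meta)),
            class = "ref_library")
}

#' Read/write signature tag lists (.grp convention)
#'
#' One gene id per line, one file per direction.
#'
#' @param sig a `sig_signature`.
#' @param up_path,down_path file paths.
#' @param label label for the signature read back.
#' @return the reader returns a `sig_signature`.
#' @export
write_signature_grp <- function(sig, up_path, down_path) {
  writeLines(sig$up, up_path)
  writeLines(sig$down, down_path)
  invisible(c(up_path, down_path))
}

#' @rdname write_signature_grp
#' @export
read_signature_grp <- function(up_path, down_path, label = "query") {
  up <- readLines(up_path)
  down <- readLines(down_path)
  new_signature(up[nzchar(up)], down[nzchar(down)], label = label)
}

#' Read/write pathway gene sets as GMT plus a role sidecar
#'
#' The GMT is the standard tab format (id, description, member genes...);
#' activator/repressor roles travel in a sidecar TSV with columns
#' pathway_id, gene_id, weight (+1/-1). Reading joins both into the long
#' (pathway, gene, weight) tibble the activity functions consume; genes
#' absent from the sidecar default to activators.
#'
#' @param pathways long tibble (pathway, gene, weight).
#' @param gmt_path,roles_path file paths.
#' @return the reader returns the long tibble.
#' @export
write_gmt <- function(pathways, gmt_path, roles_path) {
  by_pw <- split(pathways$gene, pathways$pathway)
  lines <- vapply(names(by_pw), function(id) {
    paste(c(id, "na", by_pw[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  roles <- tibble::tibble(pathway_id = pathways$pathway,
                          gene_id = pathways$gene,
                          weight = pathways$weight)
  write_tsv_plain(roles, roles_path)
  invisible(c(gmt_path, roles_path))
}

#' @rdname write_gmt
#' @export
read_gmt <- function(gmt_path, roles_path = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    tibble::tibble(pathway = parts[1], gene = parts[-(1:2)])
  })
  out <- dplyr::bind_rows(rows)
  out$weight <- 1
  if (!is.null(roles_path)) {
    roles <- read_tsv_plain(roles_path)
    lut <- setNames(roles$weight,
                    paste(roles$pathway_id, roles$gene_id))
    key <- paste(out$pathway, out$gene)
    hit <- key %in% names(lut)
    out$weight[hit] <- unname(lut[key[hit]])
  }
  out
}

#' Read/write an undirected edge list TSV
#'
#' Two columns (`from`, `to`); the graph is simple and undirected.
#'
#' @param edges tibble with columns from, to.
#' @param path file path.
#' @return the reader returns the edges tibble.
#' @export
write_edge_list <- function(edges, path) {
  write_tsv_plain(edges[c("from", "to")], path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  out <- read_tsv_plain(path)
  names(out)[1:2] <- c("from", "to")
  out$from <- as.character(out$from)
  out$to <- as.character(out$to)
  out
}

#' Read/write an item-by-keyword literature count TSV
#'
#' @param lit wide tibble (`item` column + keyword columns).
#' @param path file path.
#' @return the reader returns the tibble.
#' @export
write_literature_tsv <- function(lit, path) write_tsv_plain(lit, path)

#' @rdname write_literature_tsv
#' @export
read_literature_tsv <- function(path) {
  out <- read_tsv_plain(path)
  names(out)[1] <- "item"
  out$item <- as.character(out$item)
  out
}

#' Write planted truth as JSON
#'
#' @param truth planted truth list from [synth_bundle()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
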