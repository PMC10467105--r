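# Readers and writers for the external artifacts the pipeline consumes:
# tab-separated tables (counts, metadata, regulons, TF-disease links),
# GMT gene-set files, and JSON signatures. Dialect: UTF-8, tab separated,
# '#' comment lines skipped, gene/sample order preserved from file.

read_tsv_strict <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", ...)
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Load a count matrix and its sample metadata from TSV files
#'
#' @param counts_path TSV with gene ids in the first column and one column
#'   per sample.
#' @param meta_path TSV keyed by a `sample` column, with columns
#'   `perturbagen`, `time_point`, `replicate`, `is_control`, `control_kind`.
#' @return A [count_matrix()] object; gene and sample order as in the file.
#' @export
load_count_matrix <- function(counts_path, meta_path) {
  tab <- read_tsv_strict(counts_path)
  if (ncol(tab) < 2) stop("counts file needs a gene column plus samples")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count value in ", counts_path)
  rownames(m) <- genes
  meta <- read_tsv_strict(meta_path)
  if (!"sample" %in% names(meta)) stop("metadata needs a 'sample' column")
  meta$is_control <- as.logical(meta$is_control)
  count_matrix(m, meta)
}

#' Write a count matrix and its metadata to TSV files
#' @param cm a [count_matrix()].
#' @param counts_path,meta_path output paths.
#' @export
write_count_matrix <- function(cm, counts_path, meta_path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv_strict(df, counts_path)
  write_tsv_strict(cm$sample_meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' Read a GMT gene-set file
#'
#' Standard 3+ column convention: set id, description, then member ids.
#' @param path GMT file path.
#' @return Named list of character vectors (description dropped).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GMT line: ", substr(ln, 1, 40))
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  sets
}

#' Write a named list of sets as a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a reference signature database
#'
#' @param matrix_path TSV: gene ids in the first column, one column per
#'   reference profile (z-scores).
#' @param meta_path TSV keyed by `reference` with columns `cell_line`,
#'   `perturbagen_type`, `perturbagen`.
#' @param gmt_path optional GMT of PCL memberships (member ids are
#'   reference ids); members absent from the matrix are dropped with a
#'   warning.
#' @return A [reference_db()].
#' @export
load_reference_db <- function(matrix_path, meta_path, gmt_path = NULL) {
  tab <- read_tsv_strict(matrix_path)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  if (any(is.na(m))) stop("reference profile with missing gene value")
  meta <- read_tsv_strict(meta_path)
  pcls <- if (!is.null(gmt_path)) read_gmt(gmt_path) else list()
  reference_db(m, meta, pcls)
}

#' Write a reference database to TSV + GMT files
#' @param db a [reference_db()].
#' @param matrix_path,meta_path,gmt_path output paths (`gmt_path` optional).
#' @export
write_reference_db <- function(db, matrix_path, meta_path, gmt_path = NULL) {
  df <- data.frame(gene = rownames(db$zscores), db$zscores,
                   check.names = FALSE)
  write_tsv_strict(df, matrix_path)
  write_tsv_strict(db$ref_meta, meta_path)
  if (!is.null(gmt_path)) write_gmt(db$pcls, gmt_path)
  invisible(matrix_path)
}

#' Load regulons from a 4-column TSV
#'
#' Columns: tf, target, mode (one of `+`, `-`, `+1`, `-1`), weight in
#' (0, 1].
#' @param path TSV path.
#' @return A [regulon_set()].
#' @export
load_regulons <- function(path) {
  tab <- read_tsv_strict(path)
  required <- c("tf", "target", "mode", "weight")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("regulon file must have columns tf, target, mode, weight; missing: ",
         paste(missing_cols, collapse = ", "))
  mode_map <- c("+" = 1, "-" = -1, "+1" = 1, "-1" = -1, "1" = 1)
  mode <- mode_map[as.character(tab$mode)]
  if (any(is.na(mode))) stop("regulon mode must be one of +, -, +1, -1")
  if (anyDuplicated(tab[, c("tf", "target")]))
    stop("duplicate (tf, target) pair in regulon file")
  regs <- split(data.frame(target = as.character(tab$target),
                           mode = as.numeric(mode),
                           weight = as.numeric(tab$weight)),
                tab$tf)
  regs <- lapply(regs, function(d) { rownames(d) <- NULL; d })
  regulon_set(regs)
}

#' Write a regulon set to TSV
#' @param rs a [regulon_set()].
#' @param path output path.
#' @export
write_regulons <- function(rs, path) {
  rows <- do.call(rbind, lapply(names(rs$regulons), function(tf) {
    d <- rs$regulons[[tf]]
    data.frame(tf = tf, target = d$target,
               mode = ifelse(d$mode > 0, "+1", "-1"), weight = d$weight)
  }))
  write_tsv_strict(rows, path)
  invisible(path)
}

#' Load a TF-to-disease association table
#'
#' TSV with columns tf, cui, disease_name, icd9 (comma-separated codes,
#' may be empty).
#' @param path TSV path.
#' @return A [tf_disease_map()].
#' @export
load_tf_disease_map <- function(path) {
  tab <- read_tsv_strict(path, colClasses = "character")
  if (!"icd9" %in% names(tab)) tab$icd9 <- ""
  tab$icd9[is.na(tab$icd9)] <- ""
  tf_disease_map(tab)
}

#' Write a TF-to-disease map to TSV
#' @param map a [tf_disease_map()].
#' @param path output path.
#' @export
write_tf_disease_map <- function(map, path) {
  write_tsv_strict(map$map, path)
  invisible(path)
}

#' Write a differential-expression signature (per-gene table + JSON lists)
#'
#' The TSV carries the per-gene statistics for the signature genes in the
#' column order Gene, Base Mean, log2-FC, Wald Statistic, p-Adj, direction;
#' the JSON sidecar carries the bare up/down lists for downstream scoring.
#'
#' @param sig a [query_signature()].
#' @param table data.frame of per-gene statistics with columns `gene`,
#'   `base_mean`, `log2fc`, `wald`, `p_adj` covering at least the signature
#'   genes.
#' @param path output TSV path; a `.json` sidecar is written next to it.
#' @return Invisibly, the two paths written.
#' @export
write_signature <- function(sig, table, path) {
  stopifnot(inherits(sig, "query_signature"))
  genes <- c(sig$up, sig$down)
  direction <- c(rep("up", length(sig$up)), rep("down", length(sig$down)))
  if (length(genes)) {
    idx <- match(genes, table$gene)
    if (any(is.na(idx)))
      stop("signature gene missing from statistics table: ",
           paste(genes[is.na(idx)], collapse = ", "))
    out <- data.frame(Gene = genes,
                      `Base Mean` = table$base_mean[idx],
                      `log2-FC` = table$log2fc[idx],
                      `Wald Statistic` = table$wald[idx],
                      `p-Adj` = table$p_adj[idx],
                      direction = direction,
                      check.names = FALSE)
  } else {
    out <- data.frame(Gene = character(), `Base Mean` = numeric(),
                      `log2-FC` = numeric(), `Wald Statistic` = numeric(),
                      `p-Adj` = numeric(), direction = character(),
                      check.names = FALSE)
  }
  write_tsv_strict(out, path)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(query_id = sig$query_id,
                            up = as.list(sig$up), down = as.list(sig$down)),
                       json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, json_path))
}

#' Read a signature JSON written by [write_signature()]
#' @param json_path path to the JSON sidecar.
#' @return A [query_signature()].
#' @export
read_signature <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  query_signature(x$query_id,
                  up = if (length(x$up)) unlist(x$up) else character(),
                  down = if (length(x$down)) unlist(x$down) else character())
}
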