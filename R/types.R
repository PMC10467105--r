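# Domain containers. Lightweight S3: each constructor validates its
# invariants once, downstream code can then assume them.

#' Construct a count matrix with per-sample metadata
#'
#' The central expression container: an integer gene x sample matrix plus a
#' metadata table describing each sample (which perturbagen, time point,
#' replicate, and whether it is a control).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All entries must be
#'   non-negative integers.
#' @param sample_meta data.frame with one row per sample; must contain a
#'   `sample` column matching `colnames(counts)` plus `perturbagen`,
#'   `time_point`, `replicate`, `is_control`, `control_kind`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers with no missing values")
  storage.mode(counts) <- "integer"
  sample_meta <- as.data.frame(sample_meta)
  required <- c("sample", "perturbagen", "time_point", "replicate",
                "is_control", "control_kind")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    stop("sample metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  absent <- setdiff(colnames(counts), sample_meta$sample)
  if (length(absent))
    stop("samples without metadata: ", paste(absent, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d control)\n",
              nrow(x$counts), ncol(x$counts), sum(x$sample_meta$is_control)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a query signature (disjoint up/down gene lists)
#'
#' @param query_id identifier for the perturbagen the signature describes.
#' @param up,down character vectors of gene ids; either may be empty, they
#'   must not overlap.
#' @return A `query_signature` object.
#' @export
query_signature <- function(query_id, up = character(), down = character()) {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down))
    stop("duplicate genes within a signature list")
  overlap <- intersect(up, down)
  if (length(overlap))
    stop("up and down lists overlap: ", paste(overlap, collapse = ", "))
  structure(list(query_id = as.character(query_id), up = up, down = down),
            class = "query_signature")
}

#' @export
print.query_signature <- function(x, ...) {
  cat(sprintf("<query_signature> %s: %d up / %d down\n",
              x$query_id, length(x$up), length(x$down)))
  invisible(x)
}

#' Construct a reference signature database
#'
#' Holds N perturbational profiles over a fixed gene universe (gene-wise
#' z-scores) with per-profile metadata and perturbagen-class (PCL)
#' memberships.
#'
#' @param zscores numeric matrix, genes x references; no missing values.
#' @param ref_meta data.frame with columns `reference`, `cell_line`,
#'   `perturbagen_type`, `perturbagen` matching `colnames(zscores)`.
#' @param pcls named list mapping PCL id to character vector of member
#'   reference ids.
#' @return A `reference_db` object.
#' @export
reference_db <- function(zscores, ref_meta, pcls = list()) {
  zscores <- as.matrix(zscores)
  if (is.null(rownames(zscores)) || is.null(colnames(zscores)))
    stop("zscores must have gene rownames and reference colnames")
  if (anyDuplicated(rownames(zscores)) || anyDuplicated(colnames(zscores)))
    stop("duplicate gene or reference identifiers")
  if (any(!is.finite(zscores)))
    stop("reference profiles contain missing or non-finite values")
  if (ncol(zscores) < 1) stop("reference database needs at least one profile")
  ref_meta <- as.data.frame(ref_meta)
  required <- c("reference", "cell_line", "perturbagen_type", "perturbagen")
  missing_cols <- setdiff(required, names(ref_meta))
  if (length(missing_cols))
    stop("reference metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  absent <- setdiff(colnames(zscores), ref_meta$reference)
  if (length(absent))
    stop("references without metadata: ", paste(absent, collapse = ", "))
  ref_meta <- ref_meta[match(colnames(zscores), ref_meta$reference), ,
                       drop = FALSE]
  rownames(ref_meta) <- NULL
  pcls <- lapply(pcls, as.character)
  known <- colnames(zscores)
  n_dropped <- 0L
  for (id in names(pcls)) {
    keep <- pcls[[id]] %in% known
    n_dropped <- n_dropped + sum(!keep)
    pcls[[id]] <- pcls[[id]][keep]
  }
  pcls <- pcls[vapply(pcls, length, 1L) > 0L]
  if (n_dropped > 0L)
    warning(sprintf("dropped %d PCL member(s) absent from the profile matrix",
                    n_dropped))
  structure(list(zscores = zscores, ref_meta = ref_meta, pcls = pcls),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d genes x %d profiles, %d PCLs\n",
              nrow(x$zscores), ncol(x$zscores), length(x$pcls)))
  invisible(x)
}

#' Construct a regulon set
#'
#' @param regulons named list: TF id -> data.frame with columns `target`
#'   (unique within the regulon), `mode` (+1 activated / -1 repressed) and
#'   `weight` in (0, 1].
#' @return A `regulon_set` object.
#' @export
regulon_set <- function(regulons) {
  for (tf in names(regulons)) {
    r <- as.data.frame(regulons[[tf]])
    if (!all(c("target", "mode", "weight") %in% names(r)))
      stop("each regulon needs columns target, mode, weight")
    if (anyDuplicated(r$target))
      stop("duplicate target in regulon ", tf)
    if (!all(r$mode %in% c(-1, 1)))
      stop("regulon modes must be +1 or -1")
    if (any(r$weight <= 0 | r$weight > 1))
      stop("regulon weights must lie in (0, 1]")
    regulons[[tf]] <- r
  }
  structure(list(regulons = regulons), class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  sizes <- vapply(x$regulons, nrow, 1L)
  cat(sprintf("<regulon_set> %d regulons, %d-%d targets\n",
              length(sizes), if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Construct a TF-to-disease association map
#'
#' @param df data.frame with columns `tf`, `cui`, `disease_name`, `icd9`
#'   (comma-separated ICD-9 codes, possibly empty). (tf, cui) pairs must be
#'   unique.
#' @return A `tf_disease_map` object.
#' @export
tf_disease_map <- function(df) {
  df <- as.data.frame(df)
  required <- c("tf", "cui", "disease_name", "icd9")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("TF-disease map is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df[, c("tf", "cui")]))
    stop("duplicate (tf, cui) pairs in TF-disease map")
  rownames(df) <- NULL
  structure(list(map = df), class = "tf_disease_map")
}

#' @export
print.tf_disease_map <- function(x, ...) {
  cat(sprintf("<tf_disease_map> %d associations, %d TFs, %d diseases\n",
              nrow(x$map), length(unique(x$map$tf)),
              length(unique(x$map$cui))))
  invisible(x)
}
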