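# End-to-end orchestration: differential-expression signatures feed two
# parallel analyses (connectivity and master-regulator), with optional
# technical validation, all recorded in a JSON run manifest.

#' Validate a pipeline run configuration
#'
#' @param config named list (or path to a YAML file) with fields:
#'   `counts`, `meta` (required paths); `reference`, `reference_meta`,
#'   `pcl_gmt` for connectivity; `regulons`, `tf_disease` for
#'   master-regulator analysis; `annotations` for validation; thresholds
#'   `alpha`, `fdr`, `min_tfs`, `q`, `n_perms`; `seed`; `out_dir`.
#' @param require_mra,require_connectivity which stages must be runnable.
#' @return The normalised config list; errors name the missing field.
#' @export
validate_config <- function(config, require_mra = FALSE,
                            require_connectivity = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- list(alpha = 0.05, fdr = 0.05, min_tfs = 2L, q = 67,
                   n_perms = 100L, seed = 1L, out_dir = "sigconnect_out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  need <- c("counts", "meta")
  if (require_connectivity) need <- c(need, "reference", "reference_meta")
  if (require_mra) need <- c(need, "regulons", "tf_disease")
  missing_fields <- need[vapply(need, function(f) is.null(config[[f]]),
                                TRUE)]
  if (length(missing_fields))
    stop("config error: missing field(s): ",
         paste(missing_fields, collapse = ", "))
  for (f in intersect(c("counts", "meta", "reference", "reference_meta",
                        "pcl_gmt", "regulons", "tf_disease",
                        "annotations"), names(config))) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config error: path for '", f, "' does not exist: ",
           config[[f]])
  }
  config
}

stage_wrap <- function(stage, code) {
  t0 <- Sys.time()
  res <- tryCatch(force(code), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full pipeline from a configuration
#'
#' Stages: per-perturbagen differential-expression signatures, then in
#' parallel connectivity scoring (when a reference database is
#' configured) and master-regulator analysis (when regulons are
#' configured), then within-PCL validation when annotations are given.
#' All outputs are written under `out_dir`; a JSON manifest records
#' package version, seed, input digests and per-output row counts. The
#' run is deterministic for a fixed config.
#'
#' @param config list or YAML path; see [validate_config()].
#' @return The manifest list, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  do_connect <- !is.null(config$reference)
  do_mra <- !is.null(config$regulons)
  config <- validate_config(config, require_mra = do_mra,
                            require_connectivity = do_connect)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cm <- stage_wrap("load", load_count_matrix(config$counts, config$meta))
  meta <- cm$sample_meta
  controls <- meta$sample[meta$is_control]
  perturbagens <- unique(meta$perturbagen[!meta$is_control])

  outputs <- list()
  sigs <- list()
  for (p in perturbagens) {
    treated <- meta$sample[!meta$is_control & meta$perturbagen == p]
    res <- stage_wrap(paste0("signature:", p),
                      build_signature(cm, treated, controls,
                                      alpha = config$alpha, query_id = p))
    path <- file.path(out_dir, paste0("signature_", p, ".tsv"))
    write_signature(res$signature, res$stats, path)
    write_tsv_strict(res$stats,
                     file.path(out_dir, paste0("stats_", p, ".tsv")))
    sigs[[p]] <- res$signature
    outputs[[paste0("signature_", p)]] <- path
  }

  if (do_connect) {
    db <- stage_wrap("load_reference",
                     load_reference_db(config$reference,
                                       config$reference_meta,
                                       config$pcl_gmt))
    conn <- stage_wrap("connect", connect_all(sigs, db, q = config$q))
    if (!is.null(conn$scores)) {
      tau_wide <- stats::reshape(
        conn$scores[, c("query", "reference", "tau")],
        idvar = "query", timevar = "reference", direction = "wide")
      names(tau_wide) <- sub("^tau\\.", "", names(tau_wide))
      write_tsv_strict(tau_wide, file.path(out_dir, "tau.tsv"))
      write_tsv_strict(conn$pcl_scores,
                       file.path(out_dir, "pcl_scores.tsv"))
      write_tsv_strict(conn$summary,
                       file.path(out_dir, "ncs_summary.tsv"))
      outputs$tau <- file.path(out_dir, "tau.tsv")
      outputs$pcl_scores <- file.path(out_dir, "pcl_scores.tsv")
      outputs$ncs_summary <- file.path(out_dir, "ncs_summary.tsv")
    }
    if (!is.null(config$annotations) && !is.null(conn$scores)) {
      ann <- read_tsv_strict(config$annotations)
      val <- stage_wrap("validate",
                        within_pcl_test(conn$scores, ann, db))
      write_tsv_strict(val, file.path(out_dir, "pcl_validation.tsv"))
      outputs$pcl_validation <- file.path(out_dir, "pcl_validation.tsv")
    }
  }

  if (do_mra) {
    regs <- stage_wrap("load_regulons", load_regulons(config$regulons))
    tdm <- stage_wrap("load_tf_disease",
                      load_tf_disease_map(config$tf_disease))
    for (p in perturbagens) {
      treated <- meta$sample[!meta$is_control & meta$perturbagen == p]
      z <- gene_zscores(cm, treated, controls)
      null <- permutation_null(cm, treated, controls,
                               n_perms = config$n_perms,
                               seed = config$seed)
      enr <- stage_wrap(paste0("mra:", p),
                        regulon_enrichment(z, regs, null))
      dis <- map_to_diseases(enr, tdm, fdr_threshold = config$fdr,
                             min_tfs = config$min_tfs)
      write_tsv_strict(enr, file.path(out_dir,
                                      paste0("regulon_enrichment_", p,
                                             ".tsv")))
      write_tsv_strict(dis, file.path(out_dir,
                                      paste0("disease_associations_", p,
                                             ".tsv")))
      outputs[[paste0("regulon_enrichment_", p)]] <-
        file.path(out_dir, paste0("regulon_enrichment_", p, ".tsv"))
      outputs[[paste0("disease_associations_", p)]] <-
        file.path(out_dir, paste0("disease_associations_", p, ".tsv"))
    }
  }

  input_paths <- unlist(config[intersect(
    c("counts", "meta", "reference", "reference_meta", "pcl_gmt",
      "regulons", "tf_disease", "annotations"), names(config))])
  manifest <- list(
    package = "sigconnect",
    version = as.character(utils::packageVersion("sigconnect")),
    seed = config$seed,
    thresholds = config[c("alpha", "fdr", "min_tfs", "q", "n_perms")],
    inputs = as.list(tools::md5sum(input_paths)),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)),
           rows = length(readLines(p)) - 1L)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
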