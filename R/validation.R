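# Technical-validation statistics: within-PCL vs null connectivity tests
# with effect sizes, and expected-PCL rank-percentile analysis grouped by
# cell line or by drug.

#' Within-PCL vs null connectivity test per annotated drug
#'
#' For each drug annotated to a PCL: "within" is the drug's tau scores to
#' the members of its own PCL; "null" is its tau scores to every reference
#' belonging to any PCL. Effect size = mean(within) - mean(null);
#' significance from an independent two-sample Student's t-test (equal
#' variances); BH adjustment across rows.
#'
#' @param scores connectivity data.frame with columns `query`,
#'   `reference`, `tau` (from [connect_all()]).
#' @param annotations data.frame with columns `query`, `pcl`: the expected
#'   ("true") PCL of each query drug.
#' @param db a [reference_db()] providing PCL memberships.
#' @return data.frame: query, pcl, effect_size, p, p_adj, n_within,
#'   n_null. PCLs with fewer than 2 reference members are skipped with a
#'   message.
#' @export
within_pcl_test <- function(scores, annotations, db) {
  stopifnot(inherits(db, "reference_db"))
  pcl_refs <- unique(unlist(db$pcls))
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    qid <- annotations$query[i]; pcl <- annotations$pcl[i]
    members <- db$pcls[[pcl]]
    if (is.null(members) || length(members) < 2) {
      message(sprintf("skipping %s: PCL %s has < 2 reference members",
                      qid, pcl))
      next
    }
    sub <- scores[scores$query == qid, , drop = FALSE]
    if (!nrow(sub)) next
    within <- sub$tau[sub$reference %in% members]
    null <- sub$tau[sub$reference %in% pcl_refs]
    tt <- tryCatch(
      stats::t.test(within, null, var.equal = TRUE),
      error = function(e) list(p.value = NA_real_))
    rows[[length(rows) + 1L]] <- data.frame(
      query = qid, pcl = pcl,
      effect_size = mean(within) - mean(null),
      p = tt$p.value, n_within = length(within), n_null = length(null),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(query = character(), pcl = character(),
                      effect_size = numeric(), p = numeric(),
                      p_adj = numeric(), n_within = integer(),
                      n_null = integer()))
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out <- out[, c("query", "pcl", "effect_size", "p", "p_adj",
                 "n_within", "n_null")]
  rownames(out) <- NULL
  out
}

#' Expected-PCL rank percentiles by cell line or by drug
#'
#' For each (group, query): PCLs are ranked by their mean tau within the
#' group, descending (rank 1 = strongest connectivity; ties get the mean
#' rank); the rank of the query's expected ("true") PCL divided by the
#' number of PCLs is its rank percentile. Per group, the statistic is the
#' mean percentile and the p-value tests the percentiles against the
#' uniform-null centre 0.5 (one-sample t-test by default, one-sample KS
#' against U(0,1) optionally); BH across groups.
#'
#' @param scores data.frame with columns `query`, `group`, `pcl`, `tau`
#'   (tau values, one or more rows per (query, group, pcl); averaged).
#' @param truth data.frame with columns `query`, `pcl`: expected PCL per
#'   query. Queries without a truth annotation are excluded with a
#'   message.
#' @param test `"t"` (default) or `"ks"`.
#' @return data.frame: group, n, mean_rank_pct, p, p_adj.
#' @export
rank_percentiles <- function(scores, truth, test = c("t", "ks")) {
  test <- match.arg(test)
  known <- unique(truth$query)
  drop <- setdiff(unique(scores$query), known)
  if (length(drop))
    message(sprintf("excluding %d query(ies) without a true-PCL annotation",
                    length(drop)))
  scores <- scores[scores$query %in% known, , drop = FALSE]
  pct_rows <- list()
  for (g in unique(scores$group)) {
    sg <- scores[scores$group == g, , drop = FALSE]
    for (qid in unique(sg$query)) {
      sq <- sg[sg$query == qid, , drop = FALSE]
      mean_tau <- tapply(sq$tau, sq$pcl, mean)
      rk <- rank(-mean_tau, ties.method = "average")
      true_pcl <- truth$pcl[match(qid, truth$query)]
      if (!true_pcl %in% names(rk)) next
      pct_rows[[length(pct_rows) + 1L]] <- data.frame(
        group = g, query = qid,
        rank_pct = unname(rk[true_pcl]) / length(rk),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pct_rows))
    return(data.frame(group = character(), n = integer(),
                      mean_rank_pct = numeric(), p = numeric(),
                      p_adj = numeric()))
  pct <- do.call(rbind, pct_rows)
  out <- do.call(rbind, lapply(split(pct, pct$group), function(d) {
    p <- if (nrow(d) < 2) NA_real_
    else if (test == "t")
      tryCatch(stats::t.test(d$rank_pct, mu = 0.5)$p.value,
               error = function(e) NA_real_)  # constant percentiles
    else
      suppressWarnings(stats::ks.test(d$rank_pct, "punif")$p.value)
    data.frame(group = d$group[1], n = nrow(d),
               mean_rank_pct = mean(d$rank_pct), p = p,
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  attr(out, "percentiles") <- pct
  out
}
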