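# Connectivity scoring chain: signed KS-like enrichment score (ES),
# weighted connectivity score (WCS), group-normalised connectivity score
# (NCS), signed quantile tau on the +/-100 scale, and perturbagen-class
# (PCL) aggregation by a maximum-quantile rule.

#' Rank one reference profile
#'
#' Genes are ordered by reference z-score descending (largest first), ties
#' broken by gene id lexicographic order so the ranking is deterministic.
#'
#' @param zscores named numeric vector of gene-wise scores.
#' @return A `ranked_reference`: `order` (gene ids, position 1..n) and
#'   `rank` (named integer lookup gene -> 1-based position).
#' @export
rank_reference <- function(zscores) {
  genes <- names(zscores)
  if (is.null(genes)) stop("zscores must be named by gene")
  o <- order(-zscores, genes, method = "radix")
  rank <- seq_along(o)
  names(rank) <- genes[o]
  structure(list(order = genes[o], rank = rank, n = length(o)),
            class = "ranked_reference")
}

#' Signed KS-like enrichment score of a gene set in a ranked reference
#'
#' With V the ascending positions of the t query genes in the n-gene
#' ranking: a = max_j (j/t - V(j)/n), b = max_j (V(j)/n - (j-1)/t);
#' ES = a if a > b, -b if a < b, 0 on a tie. An empty gene set scores 0 by
#' convention. Positive ES means the set concentrates early (top of the
#' ranking).
#'
#' @param gene_set character vector of gene ids (assumed inside the
#'   universe; filter beforehand).
#' @param ranked a [rank_reference()] result.
#' @return List with `a`, `b`, `es`.
#' @export
enrichment_score <- function(gene_set, ranked) {
  t <- length(gene_set)
  if (t == 0) return(list(a = 0, b = 0, es = 0))
  v <- ranked$rank[gene_set]
  if (any(is.na(v)))
    stop("gene set contains genes outside the reference universe: ",
         paste(gene_set[is.na(v)], collapse = ", "))
  v <- sort(as.numeric(v))
  n <- ranked$n
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  es <- if (a > b) a else if (a < b) -b else 0
  list(a = a, b = b, es = es)
}

#' Weighted connectivity score from up/down enrichment scores
#'
#' w = (ES_up - ES_down) / 2 when the two scores have strictly opposite
#' signs (one positive, the other negative); otherwise 0. The zero branch
#' is what makes connectivity score distributions sparse.
#'
#' @param es_up,es_down enrichment scores in \[-1, 1\].
#' @return The weighted connectivity score.
#' @export
weighted_connectivity <- function(es_up, es_down) {
  opposite <- (es_up > 0 & es_down < 0) | (es_up < 0 & es_down > 0)
  ifelse(opposite, (es_up - es_down) / 2, 0)
}

#' Normalise connectivity scores within cell line x perturbagen type
#'
#' Positive scores are divided by the mean positive score of their
#' (cell line, perturbagen type) group; negative scores by the absolute
#' value of the group's mean negative score (sign preserved); zeros stay
#' zero. A group lacking positive (or negative) scores falls back to the
#' corresponding global mean, logged via `message()`.
#'
#' @param tab data.frame with columns `w`, `cell_line`, `perturbagen_type`.
#' @return `tab` with an `ncs` column added.
#' @export
normalize_connectivity <- function(tab) {
  stopifnot(all(c("w", "cell_line", "perturbagen_type") %in% names(tab)))
  w <- tab$w
  if (all(w == 0)) {
    warning("all weighted connectivity scores are zero; NCS set to zero")
    tab$ncs <- 0
    return(tab)
  }
  grp <- interaction(tab$cell_line, tab$perturbagen_type, drop = TRUE)
  mu_pos_global <- mean(w[w > 0])
  mu_neg_global <- mean(w[w < 0])  # NaN if no negatives anywhere
  ncs <- numeric(length(w))
  n_fallback <- 0L
  for (g in levels(grp)) {
    i <- which(grp == g)
    wi <- w[i]
    pos <- wi > 0; neg <- wi < 0
    # a group with no positive (negative) scores has nothing to scale by
    # that mean; the global fallback is kept for robustness against
    # degenerate group means
    mp <- if (any(pos)) mean(wi[pos]) else mu_pos_global
    mn <- if (any(neg)) mean(wi[neg]) else mu_neg_global
    if (any(pos) && !is.finite(mp)) { mp <- mu_pos_global; n_fallback <- n_fallback + 1L }
    if (any(neg) && !is.finite(mn)) { mn <- mu_neg_global; n_fallback <- n_fallback + 1L }
    ncs[i[pos]] <- wi[pos] / mp
    ncs[i[neg]] <- wi[neg] / abs(mn)
  }
  if (n_fallback > 0L)
    message(sprintf("NCS: %d group(s) fell back to the global mean",
                    n_fallback))
  tab$ncs <- ncs
  tab
}

#' Signed quantile score tau for one query's NCS row
#'
#' tau_r = sgn(NCS_r) * (100 / N) * #\{i : |NCS_i| < |NCS_r|\}, the strict
#' count taken over the query's scores against all N references. Range
#' is within \[-100, 100\].
#'
#' @param ncs_row numeric vector of NCS values for one query across all
#'   references.
#' @return Numeric vector of tau values, same order.
#' @export
tau_quantile <- function(ncs_row) {
  n <- length(ncs_row)
  if (n == 0) return(numeric())
  below <- rank(abs(ncs_row), ties.method = "min") - 1
  sign(ncs_row) * 100 / n * below
}

#' Aggregate member tau values for one PCL by the maximum-quantile rule
#'
#' s_hi is the nearest-rank q-th percentile of the member scores, s_lo the
#' (100-q)-th; the one with the larger absolute value is returned (tie ->
#' s_hi). With q = 67 this rewards a class whose members score strongly in
#' either direction while being robust to stragglers.
#'
#' @param taus numeric vector of member tau values (length >= 1).
#' @param q upper percentile, default 67.
#' @return The aggregated score.
#' @export
aggregate_pcl <- function(taus, q = 67) {
  m <- length(taus)
  if (m == 0) stop("aggregate_pcl needs at least one member score")
  s <- sort(taus)
  idx_hi <- max(1L, ceiling(q / 100 * m))
  idx_lo <- max(1L, ceiling((100 - q) / 100 * m))
  s_hi <- s[idx_hi]; s_lo <- s[idx_lo]
  if (abs(s_lo) > abs(s_hi)) s_lo else s_hi
}

#' Score queries against a reference database (full connectivity chain)
#'
#' Runs ES -> WCS -> NCS -> tau for every (query, reference) pair, then
#' aggregates tau within each PCL by [aggregate_pcl()] and ranks the PCLs
#' per query. Query genes absent from the reference gene universe are
#' dropped with a logged count; a query with no genes left is skipped with
#' a warning.
#'
#' @param queries list of [query_signature()] objects.
#' @param db a [reference_db()].
#' @param q aggregation percentile passed to [aggregate_pcl()].
#' @return List with `scores` (data.frame: query, reference, cell_line,
#'   perturbagen_type, es_up, es_down, w, ncs, tau), `pcl_scores`
#'   (data.frame: query, pcl, score, rank, rank_pct) and `summary`
#'   (per-query fractions of negative/zero/positive NCS).
#' @export
connect_all <- function(queries, db, q = 67) {
  stopifnot(inherits(db, "reference_db"))
  universe <- rownames(db$zscores)
  refs <- colnames(db$zscores)
  ranked <- lapply(refs, function(r) rank_reference(db$zscores[, r]))
  names(ranked) <- refs

  rows <- list()
  for (qu in queries) {
    stopifnot(inherits(qu, "query_signature"))
    up <- intersect(qu$up, universe)
    down <- intersect(qu$down, universe)
    n_lost <- (length(qu$up) - length(up)) + (length(qu$down) - length(down))
    if (n_lost > 0)
      message(sprintf("query %s: dropped %d gene(s) outside the universe",
                      qu$query_id, n_lost))
    if (length(up) == 0 && length(down) == 0) {
      warning(sprintf("query %s has no genes in the universe; skipped",
                      qu$query_id))
      next
    }
    es_up <- vapply(ranked, function(rk) enrichment_score(up, rk)$es, 0)
    es_down <- vapply(ranked, function(rk) enrichment_score(down, rk)$es, 0)
    w <- weighted_connectivity(es_up, es_down)
    rows[[qu$query_id]] <- data.frame(
      query = qu$query_id, reference = refs,
      cell_line = db$ref_meta$cell_line,
      perturbagen_type = db$ref_meta$perturbagen_type,
      es_up = unname(es_up), es_down = unname(es_down), w = unname(w),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(scores = NULL, pcl_scores = NULL, summary = NULL))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- normalize_connectivity(tab)
  tab$tau <- NA_real_
  for (qid in unique(tab$query)) {
    i <- tab$query == qid
    tab$tau[i] <- tau_quantile(tab$ncs[i])
  }

  pcl_rows <- list()
  if (length(db$pcls)) {
    for (qid in unique(tab$query)) {
      sub <- tab[tab$query == qid, ]
      scores <- vapply(db$pcls, function(members) {
        aggregate_pcl(sub$tau[match(members, sub$reference)], q = q)
      }, 0)
      rk <- rank(-scores, ties.method = "average")
      pcl_rows[[qid]] <- data.frame(
        query = qid, pcl = names(db$pcls), score = unname(scores),
        rank = unname(rk), rank_pct = unname(rk) / length(scores),
        stringsAsFactors = FALSE)
    }
  }
  pcl_scores <- if (length(pcl_rows)) do.call(rbind, pcl_rows) else
    data.frame(query = character(), pcl = character(), score = numeric(),
               rank = numeric(), rank_pct = numeric())
  rownames(pcl_scores) <- NULL

  summary <- do.call(rbind, lapply(unique(tab$query), function(qid) {
    v <- tab$ncs[tab$query == qid]
    data.frame(query = qid,
               frac_negative = mean(v < 0), frac_zero = mean(v == 0),
               frac_positive = mean(v > 0), stringsAsFactors = FALSE)
  }))

  list(scores = tab, pcl_scores = pcl_scores, summary = summary)
}
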