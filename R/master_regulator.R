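# Master-regulator analysis: per-gene Welch-t z-scores on log2(CPM+1)
# expression, label-permutation null scores, regulon enrichment as a
# weighted mean of target z-scores normalised against the permutation
# null, TF -> disease mapping with a >= 2-regulon evidence filter, and
# ICD-9 chapter rollup.

log2_cpm <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  log2(sweep(m, 2, cs, "/") * 1e6 + 1)
}

row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

welch_z <- function(e, ti, ci, cap = 8) {
  nT <- length(ti); nC <- length(ci)
  mt <- rowMeans(e[, ti, drop = FALSE])
  mc <- rowMeans(e[, ci, drop = FALSE])
  vt <- pmax(row_var(e[, ti, drop = FALSE]), 0)
  vc <- pmax(row_var(e[, ci, drop = FALSE]), 0)
  se2 <- vt / nT + vc / nC
  tt <- ifelse(se2 > 0, (mt - mc) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vt / nT)^2 / (nT - 1) + (vc / nC)^2 / (nC - 1)),
               1)
  p <- 2 * stats::pt(-abs(tt), df)
  z <- sign(tt) * stats::qnorm(pmin(1 - p / 2, stats::pnorm(cap)))
  # zero variance in both groups: equal means -> z = 0 (handled by tt = 0);
  # unequal means cannot occur with se2 = 0 unless variance is exactly zero
  # in both groups, in which case the mean difference decides the sign
  degen <- se2 == 0 & (mt != mc)
  z[degen] <- sign(mt - mc)[degen] * cap
  pmin(pmax(z, -cap), cap)
}

#' Per-gene signed z-scores from a two-group comparison
#'
#' Counts are transformed to log2(CPM + 1), each gene is tested with a
#' Welch two-sample t-test, and the two-sided p-value is mapped to a
#' signed z-score z = sign(t) * qnorm(1 - p/2), capped at +/- 8. Positive
#' z means higher expression in the treated group.
#'
#' @param cm a [count_matrix()].
#' @param treated,controls sample id vectors (>= 2 each, disjoint).
#' @return Named numeric vector of z-scores (one per gene).
#' @export
gene_zscores <- function(cm, treated, controls) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(treated) < 2 || length(controls) < 2)
    stop("need at least 2 samples per group")
  if (length(intersect(treated, controls)))
    stop("treated and control sample sets overlap")
  e <- log2_cpm(cm$counts[, c(treated, controls), drop = FALSE])
  z <- welch_z(e, seq_along(treated),
               length(treated) + seq_along(controls))
  names(z) <- rownames(cm$counts)
  z
}

#' Null z-scores from permuted sample labels
#'
#' Draws `n_perms` distinct reassignments of the treated/control labels
#' (the original labelling excluded) and scores each with the same
#' statistic as [gene_zscores()]. Reproducible for a fixed seed.
#'
#' @param cm a [count_matrix()].
#' @param treated,controls original sample id vectors.
#' @param n_perms number of permutations; must not exceed the number of
#'   distinct relabellings minus one.
#' @param seed integer seed.
#' @return A `null_scores` list: `z` (genes x n_perms matrix) and `seed`.
#' @export
permutation_null <- function(cm, treated, controls, n_perms = 100,
                             seed = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  samples <- c(treated, controls)
  n <- length(samples); k <- length(treated)
  n_avail <- choose(n, k) - 1
  if (n_perms > n_avail)
    stop(sprintf(
      "n_perms = %d exceeds the %d distinct label permutations available",
      n_perms, n_avail))
  e <- log2_cpm(cm$counts[, samples, drop = FALSE])
  orig <- sort(seq_len(k))

  combos <- new.env(hash = TRUE)
  picks <- vector("list", n_perms)
  got <- 0L
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  while (got < n_perms) {
    cand <- sort(sample.int(n, k))
    key <- paste(cand, collapse = ",")
    if (identical(cand, orig) || !is.null(combos[[key]])) next
    combos[[key]] <- TRUE
    got <- got + 1L
    picks[[got]] <- cand
  }
  zmat <- vapply(picks, function(ti) {
    welch_z(e, ti, setdiff(seq_len(n), ti))
  }, numeric(nrow(e)))
  rownames(zmat) <- rownames(cm$counts)
  structure(list(z = zmat, seed = seed), class = "null_scores")
}

regulon_score <- function(reg, z) {
  present <- reg$target %in% names(z)
  d <- reg[present, , drop = FALSE]
  sum(d$weight * d$mode * z[d$target]) / sum(d$weight)
}

#' Regulon enrichment against a permutation null
#'
#' Raw score S(TF) = sum(weight * mode * z\[target\]) / sum(weight) over
#' the regulon's targets present in the gene universe. NES = (S - mean of
#' null S) / sd of null S, where the null scores apply the same regulon to
#' each permutation column. The two-sided p-value is empirical with
#' add-one smoothing, computed on null scores centred at their own mean;
#' FDR by [bh_adjust()] across TFs. Regulons with fewer than `min_targets`
#' usable targets are skipped with a message; a degenerate null sd
#' (< 1e-12) flags the TF with NES = NA.
#'
#' @param z named z-score vector from [gene_zscores()].
#' @param regulons a [regulon_set()].
#' @param null a [permutation_null()] result.
#' @param min_targets minimum usable targets per regulon (default 5).
#' @return data.frame: tf, n_targets, score, nes, p, fdr, flagged.
#' @export
regulon_enrichment <- function(z, regulons, null, min_targets = 5) {
  stopifnot(inherits(regulons, "regulon_set"),
            inherits(null, "null_scores"))
  tfs <- names(regulons$regulons)
  usable <- vapply(tfs, function(tf) {
    sum(regulons$regulons[[tf]]$target %in% names(z))
  }, 1L)
  skipped <- tfs[usable < min_targets]
  if (length(skipped))
    message(sprintf("skipped %d regulon(s) with < %d usable targets",
                    length(skipped), min_targets))
  tfs <- tfs[usable >= min_targets]
  if (!length(tfs))
    return(data.frame(tf = character(), n_targets = integer(),
                      score = numeric(), nes = numeric(), p = numeric(),
                      fdr = numeric(), flagged = logical()))
  P <- ncol(null$z)
  rows <- lapply(tfs, function(tf) {
    reg <- regulons$regulons[[tf]]
    s <- regulon_score(reg, z)
    d <- reg[reg$target %in% rownames(null$z), , drop = FALSE]
    s_null <- as.numeric(
      crossprod(null$z[d$target, , drop = FALSE], d$weight * d$mode)) /
      sum(d$weight)
    mu <- mean(s_null); sdv <- stats::sd(s_null)
    if (sdv < 1e-12) {
      return(data.frame(tf = tf, n_targets = sum(reg$target %in% names(z)),
                        score = s, nes = NA_real_, p = NA_real_,
                        fdr = NA_real_, flagged = TRUE))
    }
    nes <- (s - mu) / sdv
    p <- (1 + sum(abs(s_null - mu) >= abs(s - mu))) / (P + 1)
    data.frame(tf = tf, n_targets = sum(reg$target %in% names(z)),
               score = s, nes = nes, p = p, fdr = NA_real_, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !out$flagged
  out$fdr[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Map significant master regulators to diseases
#'
#' Joins TFs passing the FDR threshold to their diseases and keeps only
#' diseases supported by at least `min_tfs` significant regulons, sorted
#' by support count descending.
#'
#' @param enr data.frame from [regulon_enrichment()].
#' @param map a [tf_disease_map()].
#' @param fdr_threshold significance cutoff on the regulon FDR.
#' @param min_tfs minimum supporting TFs per disease (default 2).
#' @param direction which regulons to map: `"both"` (default), `"up"`
#'   (NES > 0) or `"down"` (NES < 0).
#' @return data.frame: cui, disease_name, support, tfs (comma-joined),
#'   icd9_chapter.
#' @export
map_to_diseases <- function(enr, map, fdr_threshold = 0.05, min_tfs = 2,
                            direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "tf_disease_map"))
  sig <- enr[!is.na(enr$fdr) & enr$fdr < fdr_threshold, , drop = FALSE]
  sig <- switch(direction,
                both = sig,
                up = sig[sig$nes > 0, , drop = FALSE],
                down = sig[sig$nes < 0, , drop = FALSE])
  if (!nrow(sig))
    return(data.frame(cui = character(), disease_name = character(),
                      support = integer(), tfs = character(),
                      icd9_chapter = character()))
  joined <- map$map[map$map$tf %in% sig$tf, , drop = FALSE]
  if (!nrow(joined))
    return(data.frame(cui = character(), disease_name = character(),
                      support = integer(), tfs = character(),
                      icd9_chapter = character()))
  split_d <- split(joined, joined$cui)
  rows <- lapply(split_d, function(d) {
    tfs <- sort(unique(d$tf))
    codes <- unlist(strsplit(d$icd9[1], ",", fixed = TRUE))
    data.frame(cui = d$cui[1], disease_name = d$disease_name[1],
               support = length(tfs), tfs = paste(tfs, collapse = ","),
               icd9_chapter = icd9_rollup(codes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$support >= min_tfs, , drop = FALSE]
  out <- out[order(-out$support, out$cui), , drop = FALSE]
  rownames(out) <- NULL
  out
}
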