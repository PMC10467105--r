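test_that("gene z-scores follow the sign and quantile conventions", {
  set.seed(41)
  m <- matrix(rpois(8 * 20, 50), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:8)))
  m["g01", 1:4] <- m["g01", 1:4] + 500L  # strongly up in treated
  meta <- data.frame(sample = colnames(m), perturbagen = "v",
                     time_point = 6, replicate = 1:8,
                     is_control = rep(c(FALSE, TRUE), each = 4),
                     control_kind = "")
  cm <- count_matrix(m, meta)
  z <- gene_zscores(cm, paste0("s", 1:4), paste0("s", 5:8))
  expect_gt(z[["g01"]], 0)
  expect_true(all(abs(z) <= 8))

  # identical groups -> z = 0
  m2 <- cbind(m[, 1:4], m[, 1:4])
  colnames(m2) <- paste0("s", 1:8)
  cm2 <- count_matrix(m2, meta)
  z2 <- gene_zscores(cm2, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(unname(z2), rep(0, 20))

  # two-sided p = 0.05 with positive shift maps to z = +1.959964
  expect_equal(sign(1) * qnorm(1 - 0.05 / 2), 1.959964, tolerance = 1e-6)
})

test_that("permutation null is seeded, distinct, and bounded", {
  spec <- sim_spec(23, n_genes = 50L, n_treated = 3L, n_control = 5L,
                   n_de = 5L)
  sim <- sim_counts(spec)
  meta <- sim$counts$sample_meta
  tr <- meta$sample[!meta$is_control]; ct <- meta$sample[meta$is_control]
  n1 <- permutation_null(sim$counts, tr, ct, n_perms = 20, seed = 5)
  n2 <- permutation_null(sim$counts, tr, ct, n_perms = 20, seed = 5)
  expect_identical(n1$z, n2$z)
  n3 <- permutation_null(sim$counts, tr, ct, n_perms = 20, seed = 6)
  expect_false(identical(n1$z, n3$z))

  # choose(8,3) - 1 = 55 available
  expect_error(permutation_null(sim$counts, tr, ct, n_perms = 56),
               "55 distinct")
  expect_silent(permutation_null(sim$counts, tr, ct, n_perms = 55,
                                 seed = 2))

  # per-gene mean of null z stays near 0 on balanced null data (with
  # heavily unbalanced arms the per-gene permutation distribution is
  # skewed and this band does not hold gene-wise)
  spec0 <- sim_spec(29, n_genes = 200L, n_de = 0L, n_treated = 10L,
                    n_control = 10L)
  sim0 <- sim_counts(spec0)
  m0 <- sim0$counts$sample_meta
  null <- permutation_null(sim0$counts, m0$sample[!m0$is_control],
                           m0$sample[m0$is_control], n_perms = 200,
                           seed = 3)
  expect_true(all(abs(rowMeans(null$z)) <= 0.2))
})

test_that("regulon enrichment recovers a planted TF and is antisymmetric", {
  spec <- sim_spec(31)
  regs <- sim_regulons(spec)
  rc <- sim_regulon_counts(spec, regs)
  meta <- rc$counts$sample_meta
  tr <- meta$sample[!meta$is_control]; ct <- meta$sample[meta$is_control]
  z <- gene_zscores(rc$counts, tr, ct)
  null <- permutation_null(rc$counts, tr, ct, n_perms = 100, seed = 31)
  enr <- regulon_enrichment(z, regs$regulons, null)
  expect_equal(enr$tf[which.max(abs(enr$nes))], rc$planted_tf)
  expect_true(all(enr$fdr >= enr$p - 1e-15, na.rm = TRUE))

  # mode flip negates raw score and NES exactly
  flipped <- regs$regulons
  flipped$regulons <- lapply(flipped$regulons, function(d) {
    d$mode <- -d$mode; d
  })
  enr_f <- regulon_enrichment(z, flipped, null)
  expect_equal(enr_f$score, -enr$score, tolerance = 1e-12)
  expect_equal(enr_f$nes, -enr$nes, tolerance = 1e-12)

  # all-zero z -> raw score 0
  z0 <- setNames(rep(0, length(z)), names(z))
  null0 <- null; null0$z <- null$z  # same null, any
  enr0 <- regulon_enrichment(z0, regs$regulons, null)
  expect_equal(enr0$score, rep(0, nrow(enr0)))
})

test_that("small regulons are skipped and degenerate nulls flagged", {
  z <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  small <- regulon_set(list(
    TFS = data.frame(target = c("g01", "g02"), mode = 1, weight = 1),
    TFB = data.frame(target = sprintf("g%02d", 1:10), mode = 1,
                     weight = 1)))
  null <- structure(list(z = matrix(rnorm(30 * 20),
                                    dimnames = list(names(z), NULL),
                                    nrow = 30), seed = 1),
                    class = "null_scores")
  expect_message(enr <- regulon_enrichment(z, small, null), "skipped 1")
  expect_equal(enr$tf, "TFB")

  null$z[] <- 0  # degenerate null sd
  enr2 <- suppressMessages(regulon_enrichment(z, small, null))
  expect_true(enr2$flagged)
  expect_true(is.na(enr2$nes))
})

test_that("disease mapping enforces the >= 2 supporting TF rule", {
  enr <- data.frame(tf = c("A", "B", "C"), n_targets = 10,
                    score = 1, nes = c(3, -2.5, 0.1),
                    p = c(0.001, 0.002, 0.9),
                    fdr = c(0.003, 0.004, 0.9), flagged = FALSE)
  map <- tf_disease_map(data.frame(
    tf = c("A", "B", "A", "C"),
    cui = c("C1", "C1", "C2", "C2"),
    disease_name = c("dz1", "dz1", "dz2", "dz2"),
    icd9 = c("401", "401", "290.0", "290.0")))
  out <- map_to_diseases(enr, map)
  expect_equal(out$cui, "C1")      # dz2 has only one significant TF
  expect_equal(out$support, 2L)
  expect_true(all(out$support >= 2))
  expect_equal(out$icd9_chapter, "DISEASES OF THE CIRCULATORY SYSTEM")

  # direction filter: only up-regulated regulons
  out_up <- map_to_diseases(enr, map, direction = "up")
  expect_equal(nrow(out_up), 0)  # B is down, so C1 loses its 2nd TF

  # no significant TFs -> empty
  enr0 <- enr; enr0$fdr <- 0.9
  expect_equal(nrow(map_to_diseases(enr0, map)), 0)
})

test_that("ICD-9 rollup picks specific chapters over residual buckets", {
  expect_equal(icd9_rollup("401"), "DISEASES OF THE CIRCULATORY SYSTEM")
  expect_equal(icd9_rollup(c("401", "997.91")),
               "DISEASES OF THE CIRCULATORY SYSTEM")
  expect_message(ch <- icd9_rollup("X99"), "unmappable")
  expect_equal(ch, "UNCLASSIFIED")
  expect_equal(icd9_rollup("162.9"), "NEOPLASMS")
  expect_equal(icd9_rollup("290.0"), "MENTAL DISORDERS")
  expect_equal(icd9_rollup("487"), "DISEASES OF THE RESPIRATORY SYSTEM")
  expect_equal(icd9_rollup(character()), "UNCLASSIFIED")
})
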