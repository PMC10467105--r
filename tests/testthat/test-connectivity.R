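test_that("enrichment score matches hand-evaluated examples", {
  rk <- rank_reference(setNames(10:1, paste0("g", 1:10)))
  e <- enrichment_score(c("g1", "g2"), rk)
  expect_equal(e$a, 0.8); expect_equal(e$b, 0.1); expect_equal(e$es, 0.8)
  e <- enrichment_score(c("g9", "g10"), rk)
  expect_equal(e$a, 0.0); expect_equal(e$b, 0.9); expect_equal(e$es, -0.9)
  expect_equal(enrichment_score(character(), rk)$es, 0)
})

test_that("reference ranking is descending with lexicographic tie-break", {
  z <- c(b = 1, a = 1, c = 3)
  rk <- rank_reference(z)
  expect_identical(rk$order, c("c", "a", "b"))
  expect_equal(unname(rk$rank[c("c", "a", "b")]), 1:3)
})

test_that("ES equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(5:50, 1)
    t <- sample(1:min(10, n), 1)
    z <- rnorm(n); names(z) <- paste0("g", seq_len(n))
    rk <- rank_reference(z)
    gene_set <- sample(names(z), t)
    got <- enrichment_score(gene_set, rk)$es
    want <- es_oracle(unname(rk$rank[gene_set]), n)
    expect_equal(got, want, tolerance = 1e-12)
    expect_lte(abs(got), 1)
  }
})

test_that("WCS arithmetic and the same-sign zero branch", {
  expect_equal(weighted_connectivity(0.8, -0.9), 0.85)
  expect_equal(weighted_connectivity(-0.4, 0.6), -0.5)
  expect_equal(weighted_connectivity(0.3, 0.2), 0)
  expect_equal(weighted_connectivity(-0.3, -0.2), 0)
  expect_equal(weighted_connectivity(0, -0.5), 0)
  expect_equal(weighted_connectivity(0, 0), 0)
})

test_that("NCS normalisation: unit group means, sign preserved, zeros fixed", {
  tab <- data.frame(
    w = c(0.2, 0.4, -0.3, -0.6, 0, 0.5),
    cell_line = c("A", "A", "A", "A", "A", "B"),
    perturbagen_type = "t")
  out <- normalize_connectivity(tab)
  expect_equal(out$ncs[1:2], c(2 / 3, 4 / 3))
  expect_equal(out$ncs[3:4], c(-2 / 3, -4 / 3))
  expect_equal(out$ncs[5], 0)
  expect_equal(out$ncs[6], 1)  # single positive score in its group

  # property: per-group mean of positive NCS is 1, of |negative| is 1
  set.seed(33)
  tab2 <- data.frame(w = round(runif(200, -1, 1), 2),
                     cell_line = sample(c("A", "B", "C"), 200, TRUE),
                     perturbagen_type = sample(c("x", "y"), 200, TRUE))
  out2 <- normalize_connectivity(tab2)
  grp <- interaction(out2$cell_line, out2$perturbagen_type, drop = TRUE)
  for (g in levels(grp)) {
    v <- out2$ncs[grp == g]
    if (any(v > 0)) expect_equal(mean(v[v > 0]), 1, tolerance = 1e-12)
    if (any(v < 0)) expect_equal(mean(abs(v[v < 0])), 1, tolerance = 1e-12)
  }

  tab3 <- data.frame(w = c(0, 0), cell_line = "A", perturbagen_type = "t")
  expect_warning(out3 <- normalize_connectivity(tab3), "zero")
  expect_equal(out3$ncs, c(0, 0))
})

test_that("tau is the strict signed quantile on the +/-100 scale", {
  expect_equal(tau_quantile(c(0.1, 0.2, 0.3, 0.4)), c(0, 25, 50, 75))
  expect_equal(tau_quantile(c(0.1, 0.2, 0.3, -0.4)), c(0, 25, 50, -75))
  expect_equal(tau_quantile(rep(0.5, 6)), rep(0, 6))
  # bounds and monotonicity in |NCS|
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(sample(2:100, 1))
    tau <- tau_quantile(x)
    n <- length(x)
    expect_true(all(abs(tau) <= 100 * (n - 1) / n + 1e-12))
    o <- order(abs(x))
    expect_true(all(diff(abs(tau)[o]) >= -1e-12))
  }
})

test_that("PCL aggregation follows the nearest-rank max-quantile rule", {
  expect_equal(aggregate_pcl(rep(40, 5)), 40)
  expect_equal(aggregate_pcl(c(-80, 60)), -80)
  expect_equal(aggregate_pcl(c(10, 20, 90)), 90)
  expect_error(aggregate_pcl(numeric()), "at least one")
  # identity on constant member scores, any q
  set.seed(3)
  for (i in 1:20) {
    v <- rep(runif(1, -100, 100), sample(1:10, 1))
    expect_equal(aggregate_pcl(v, q = sample(50:99, 1)), v[1])
  }
})

test_that("connect_all: self-query tops its own reference, determinism, drops", {
  db <- tiny_reference_db(n_genes = 60, n_refs = 10, seed = 77)
  # query built from reference r3's extremes
  z3 <- sort(db$zscores[, "r3"], decreasing = TRUE)
  q_self <- query_signature("self", up = names(z3)[1:10],
                            down = rev(names(z3))[1:10])
  res <- connect_all(list(q_self), db)
  row <- res$scores[res$scores$query == "self", ]
  expect_equal(row$reference[which.max(row$tau)], "r3")

  # identical queries give identical rows
  q1 <- query_signature("q1", up = c("g1", "g2"), down = c("g5", "g6"))
  q2 <- query_signature("q2", up = c("g1", "g2"), down = c("g5", "g6"))
  res2 <- connect_all(list(q1, q2), db)
  r1 <- res2$scores[res2$scores$query == "q1",
                    c("es_up", "es_down", "w", "ncs", "tau")]
  r2 <- res2$scores[res2$scores$query == "q2",
                    c("es_up", "es_down", "w", "ncs", "tau")]
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)

  # genes outside the universe are dropped with a message (the one-sided
  # single query also triggers the all-zero-WCS warning)
  q3 <- query_signature("q3", up = c("g1", "NOT_A_GENE"))
  expect_message(suppressWarnings(connect_all(list(q3), db)), "dropped 1")
  # query with no genes in the universe is skipped with a warning
  q4 <- query_signature("q4", up = "NOPE")
  expect_warning(res4 <- connect_all(list(q4), db), "skipped")
  expect_null(res4$scores)

  # sparsity summary fractions sum to 1
  expect_equal(res$summary$frac_negative + res$summary$frac_zero +
                 res$summary$frac_positive, 1)
})
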