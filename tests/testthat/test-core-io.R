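test_that("count matrix TSV round-trips and validates invariants", {
  cm <- tiny_count_matrix()
  d <- withr::local_tempdir()
  cp <- file.path(d, "counts.tsv"); mp <- file.path(d, "meta.tsv")
  write_count_matrix(cm, cp, mp)
  cm2 <- load_count_matrix(cp, mp)
  expect_identical(cm2$counts, cm$counts)
  expect_identical(dim(cm2), c(4L, 3L))
  expect_equal(cm2$sample_meta$sample, cm$sample_meta$sample)

  # duplicate gene id
  lines <- readLines(cp)
  writeLines(c(lines, lines[2]), cp)
  expect_error(load_count_matrix(cp, mp), "duplicate gene")

  # negative and non-integer counts
  m <- cm$counts; m[1, 1] <- -1L
  expect_error(count_matrix(m, cm$sample_meta), "non-negative")
  m <- cm$counts; storage.mode(m) <- "double"; m[1, 1] <- 1.5
  expect_error(count_matrix(m, cm$sample_meta), "integer")

  # sample without metadata
  expect_error(count_matrix(cm$counts, cm$sample_meta[-1, ]),
               "without metadata")
})

test_that("replicate/time-point metadata parses into the expected design", {
  # 3 replicates at each of 6/24/36 h for one venom
  meta <- expand.grid(replicate = 1:3, time_point = c(6, 24, 36))
  meta$sample <- sprintf("v1_t%d_r%d", meta$time_point, meta$replicate)
  meta$perturbagen <- "venom_1"
  meta$is_control <- FALSE
  meta$control_kind <- ""
  m <- matrix(1L, nrow = 2, ncol = 9,
              dimnames = list(c("g1", "g2"), meta$sample))
  cm <- count_matrix(m, meta)
  treated <- cm$sample_meta[!cm$sample_meta$is_control, ]
  expect_equal(nrow(treated), 9)
  expect_equal(as.vector(table(treated$time_point)), c(3, 3, 3))
})

test_that("reference database loads with PCL handling", {
  db <- tiny_reference_db()
  d <- withr::local_tempdir()
  mp <- file.path(d, "ref.tsv"); me <- file.path(d, "ref_meta.tsv")
  gp <- file.path(d, "pcls.gmt")
  write_reference_db(db, mp, me, gp)
  db2 <- load_reference_db(mp, me, gp)
  expect_equal(db2$zscores, db$zscores)
  expect_equal(ncol(db2$zscores), 4)
  expect_equal(lengths(db2$pcls), c(PCL1 = 2L))
  expect_equal(rownames(db2$zscores), rownames(db$zscores))  # order kept

  # GMT member absent from matrix -> warning + dropped
  writeLines("PCL2\tna\tr1\tr_missing", gp)
  expect_warning(db3 <- load_reference_db(mp, me, gp), "dropped 1")
  expect_equal(db3$pcls$PCL2, "r1")

  # empty GMT -> zero PCLs, connectivity still runs
  writeLines(character(), gp)
  db4 <- load_reference_db(mp, me, gp)
  expect_length(db4$pcls, 0)
  res <- suppressWarnings(connect_all(list(query_signature("q", up = "g1")),
                                      db4))
  expect_equal(nrow(res$pcl_scores), 0)

  # missing gene value -> error
  tab <- read.delim(mp, check.names = FALSE)
  tab[2, 3] <- NA
  write.table(tab, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_reference_db(mp, me), "missing")
})

test_that("regulon TSV loads, validates, and round-trips", {
  d <- withr::local_tempdir()
  p <- file.path(d, "reg.tsv")
  writeLines(c("tf\ttarget\tmode\tweight",
               "TF1\tg1\t+\t1.0", "TF1\tg2\t-\t0.5"), p)
  rs <- load_regulons(p)
  expect_length(rs$regulons, 1)
  expect_equal(nrow(rs$regulons$TF1), 2)
  expect_equal(rs$regulons$TF1$mode, c(1, -1))

  p2 <- file.path(d, "reg2.tsv")
  write_regulons(rs, p2)
  rs2 <- load_regulons(p2)
  expect_equal(rs2$regulons, rs$regulons)

  writeLines(c("tf\ttarget\tmode\tweight", "TF1\tg1\t+\t0"), p)
  expect_error(load_regulons(p), "\\(0, 1\\]")
  writeLines(c("tf\ttarget\tweight", "TF1\tg1\t1"), p)
  expect_error(load_regulons(p), "mode")
  writeLines(c("tf\ttarget\tmode\tweight",
               "TF1\tg1\t+\t1", "TF1\tg1\t-\t1"), p)
  expect_error(load_regulons(p), "duplicate")
})

test_that("TF-disease map round-trips and enforces unique pairs", {
  d <- withr::local_tempdir()
  p <- file.path(d, "tfd.tsv")
  df <- data.frame(tf = c("A", "B"), cui = c("C01", "C01"),
                   disease_name = "dz", icd9 = c("401", "401"))
  write_tf_disease_map(tf_disease_map(df), p)
  m2 <- load_tf_disease_map(p)
  expect_equal(m2$map$tf, df$tf)
  df2 <- rbind(df, df[1, ])
  expect_error(tf_disease_map(df2), "duplicate")
})

test_that("signature TSV+JSON round-trip matches the expected schema", {
  sig <- query_signature("omacropus", up = "BAZ1B", down = "REPIN1")
  stats <- data.frame(gene = c("BAZ1B", "REPIN1"),
                      base_mean = c(120.05, 38.30),
                      log2fc = c(1.69463, -0.95256),
                      wald = c(5.0846, -4.3326),
                      p_adj = c(0.0003, 0.0061))
  d <- withr::local_tempdir()
  p <- file.path(d, "sig.tsv")
  paths <- write_signature(sig, stats, p)
  tab <- read.delim(p, check.names = FALSE)
  expect_identical(names(tab),
                   c("Gene", "Base Mean", "log2-FC", "Wald Statistic",
                     "p-Adj", "direction"))
  expect_equal(nrow(tab), 2)
  sig2 <- read_signature(paths[2])
  expect_equal(sig2$up, sig$up)
  expect_equal(sig2$down, sig$down)

  # empty signature -> header-only TSV, empty JSON lists
  empty <- query_signature("none")
  paths <- write_signature(empty, stats[0, ], file.path(d, "empty.tsv"))
  expect_equal(nrow(read.delim(paths[1], check.names = FALSE)), 0)
  e2 <- read_signature(paths[2])
  expect_length(e2$up, 0)
  expect_length(e2$down, 0)

  # overlap forbidden at construction
  expect_error(query_signature("bad", up = "g1", down = "g1"), "overlap")
})

test_that("GMT parsing ignores comments and preserves set order", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sets.gmt")
  writeLines(c("# comment", "S1\tdesc\ta\tb", "S2\tdesc\tc"), p)
  sets <- read_gmt(p)
  expect_identical(names(sets), c("S1", "S2"))
  expect_equal(sets$S1, c("a", "b"))
})
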