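# Small fixtures built in code, shared across test files.

tiny_count_matrix <- function() {
  m <- matrix(c(10L, 20L, 0L,
                5L, 8L, 3L,
                100L, 90L, 80L,
                7L, 7L, 7L), nrow = 4, byrow = TRUE,
              dimnames = list(c("BAZ1B", "REPIN1", "BRD3", "SPRY4"),
                              c("s1", "s2", "s3")))
  meta <- data.frame(sample = c("s1", "s2", "s3"),
                     perturbagen = c("venomA", "venomA", "none"),
                     time_point = c(6, 24, 0),
                     replicate = c(1, 2, 1),
                     is_control = c(FALSE, FALSE, TRUE),
                     control_kind = c("", "", "vehicle"))
  count_matrix(m, meta)
}

tiny_reference_db <- function(n_genes = 5, n_refs = 4, seed = 42) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  refs <- paste0("r", seq_len(n_refs))
  z <- matrix(rnorm(n_genes * n_refs), nrow = n_genes,
              dimnames = list(genes, refs))
  meta <- data.frame(reference = refs,
                     cell_line = rep(c("A375", "MCF7"),
                                     length.out = n_refs),
                     perturbagen_type = "trt_cp",
                     perturbagen = paste0("drug", seq_len(n_refs)))
  reference_db(z, meta, list(PCL1 = refs[1:2]))
}

# Brute-force ES oracle: scan all j for both maxima, no shared code with
# enrichment_score().
es_oracle <- function(positions, n) {
  t <- length(positions)
  if (t == 0) return(0)
  v <- sort(positions)
  a_best <- -Inf; b_best <- -Inf
  for (j in seq_len(t)) {
    a_best <- max(a_best, j / t - v[j] / n)
    b_best <- max(b_best, v[j] / n - (j - 1) / t)
  }
  if (a_best > b_best) a_best else if (a_best < b_best) -b_best else 0
}
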