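# Seeded generators for every pipeline input, with planted ground truth.
# Each generator derives its own random stream from (seed, generator
# name), so adding one generator never perturbs the draws of another.

#' Simulation specification with the package's stated-world defaults
#'
#' Defaults mirror the experimental design the pipeline targets: 3 treated
#' replicates versus 21 controls (12 solvent + 9 untreated), negative
#' binomial counts with dispersion 0.1 and 100 genes planted at
#' |log2FC| = 2 among 2000; a reference compendium of 20 classes x 10
#' members over 978 genes at signal-to-noise ratio 2 across 9 cell lines;
#' 20 disjoint 20-target regulons with one planted dysregulated TF; and an
#' 12-point 2-fold dilution dose grid from 2.0 ug/uL with sigma = 2
#' percentage points of response noise.
#'
#' @param seed integer seed (mandatory).
#' @param ... overrides for any default field.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed, ...) {
  if (missing(seed)) stop("sim_spec requires a seed")
  spec <- list(
    seed = as.integer(seed),
    # counts
    n_genes = 2000L, n_treated = 3L, n_control = 21L,
    dispersion = 0.1, n_de = 100L, lfc = 2,
    baseline_meanlog = log(100), baseline_sdlog = 1,
    # reference compendium
    n_classes = 20L, members_per_class = 10L, ref_genes = 978L, snr = 2,
    cell_lines = c("A375", "A549", "HA1E", "HCC515", "HEPG2", "HT29",
                   "MCF7", "PC3", "VCAP"),
    # regulons
    n_tfs = 20L, targets_per_tf = 20L, regulon_genes = 1000L,
    planted_tf_lfc = 1,
    disease_density = 2L,
    # dose-response
    hill = c(bottom = 0, top = 100, loggi50 = -1, h = -2),
    dose_top = 2.0, n_doses = 12L, noise_sd = 2)
  override <- list(...)
  unknown <- setdiff(names(override), names(spec))
  if (length(unknown))
    stop("unknown sim_spec field(s): ", paste(unknown, collapse = ", "))
  spec[names(override)] <- override
  structure(spec, class = "sim_spec")
}

# deterministic 32-bit stream seed from (seed, generator name)
derive_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (v in utf8ToInt(name)) {
    h <- (h * 131 + v) %% 2147483647  # doubles hold exact ints < 2^53
  }
  as.integer(h)
}

with_stream <- function(seed, name, code) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv))
  set.seed(derive_seed(seed, name))
  force(code)
}

#' Simulate a count matrix with planted differential expression
#'
#' Gene baselines are log-normal; counts are negative binomial with the
#' spec's dispersion; `n_de` planted genes get a multiplicative 2^lfc
#' fold change in the treated arm (half up, half down).
#'
#' @param spec a [sim_spec()].
#' @return List with `counts` (a [count_matrix()]) and `truth`
#'   (data.frame: gene, lfc; empty when nothing is planted).
#' @export
sim_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_stream(spec$seed, "counts", {
    g <- spec$n_genes
    genes <- sprintf("G%04d", seq_len(g))
    base_mu <- stats::rlnorm(g, spec$baseline_meanlog, spec$baseline_sdlog)
    lfc <- numeric(g)
    if (spec$n_de > 0) {
      de_idx <- sample.int(g, spec$n_de)
      signs <- rep(c(1, -1), length.out = spec$n_de)
      lfc[de_idx] <- signs * spec$lfc
    }
    nT <- spec$n_treated; nC <- spec$n_control
    size <- 1 / spec$dispersion
    mu_treat <- base_mu * 2^lfc
    draw <- function(mu, ncol) {
      matrix(stats::rnbinom(length(mu) * ncol, mu = rep(mu, ncol),
                            size = size), nrow = length(mu))
    }
    m <- cbind(draw(mu_treat, nT), draw(base_mu, nC))
    rownames(m) <- genes
    samples <- c(sprintf("T%02d", seq_len(nT)), sprintf("C%02d", seq_len(nC)))
    colnames(m) <- samples
    meta <- data.frame(
      sample = samples,
      perturbagen = c(rep("venom_1", nT), rep("none", nC)),
      time_point = c(rep(c(6, 24, 36), length.out = nT), rep(0, nC)),
      replicate = c(seq_len(nT), seq_len(nC)),
      is_control = c(rep(FALSE, nT), rep(TRUE, nC)),
      control_kind = c(rep("", nT),
                       rep(c("vehicle", "untreated"), length.out = nC)),
      stringsAsFactors = FALSE)
    truth <- data.frame(gene = genes[lfc != 0], lfc = lfc[lfc != 0],
                        stringsAsFactors = FALSE)
    list(counts = count_matrix(m, meta), truth = truth)
  })
}

#' Simulate a reference database with planted perturbagen classes
#'
#' Each class has a latent standard-normal gene template; members are
#' template * SNR + standard normal noise. Cell lines are assigned
#' round-robin and each class forms one PCL.
#'
#' @param spec a [sim_spec()].
#' @return List with `db` (a [reference_db()]) and `truth` (data.frame:
#'   reference, class) plus `templates` (genes x classes matrix).
#' @export
sim_reference_db <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_stream(spec$seed, "reference_db", {
    g <- spec$ref_genes
    genes <- sprintf("G%04d", seq_len(g))
    k <- spec$n_classes; m <- spec$members_per_class
    templates <- matrix(stats::rnorm(g * k), nrow = g,
                        dimnames = list(genes, sprintf("class_%02d",
                                                       seq_len(k))))
    n <- k * m
    refs <- sprintf("REF%03d", seq_len(n))
    class_of <- rep(colnames(templates), each = m)
    z <- templates[, class_of] * spec$snr +
      matrix(stats::rnorm(g * n), nrow = g)
    colnames(z) <- refs
    meta <- data.frame(
      reference = refs,
      cell_line = rep(spec$cell_lines, length.out = n),
      perturbagen_type = "trt_cp",
      perturbagen = sprintf("drug_%03d", seq_len(n)),
      stringsAsFactors = FALSE)
    pcls <- split(refs, class_of)
    truth <- data.frame(reference = refs, class = class_of,
                        stringsAsFactors = FALSE)
    list(db = reference_db(z, meta, pcls), truth = truth,
         templates = templates)
  })
}

#' Draw a query signature from one planted reference class
#'
#' A fresh profile is drawn from the class model (template * SNR + noise)
#' and its top/bottom `n_tail` genes become the up/down lists — the same
#' construction a differential-expression signature of a class member
#' would approximate.
#'
#' @param spec a [sim_spec()].
#' @param ref a [sim_reference_db()] result.
#' @param class_id class column name (e.g. `"class_03"`).
#' @param n_tail genes per list (default 50).
#' @param draw_seed seed for this query's noise draw.
#' @return A [query_signature()].
#' @export
sim_class_query <- function(spec, ref, class_id, n_tail = 50,
                            draw_seed = 1) {
  tmpl <- ref$templates[, class_id]
  with_stream(draw_seed, paste0("query_", class_id), {
    profile <- tmpl * spec$snr + stats::rnorm(length(tmpl))
    o <- order(-profile)
    query_signature(paste0("q_", class_id, "_", draw_seed),
                    up = names(profile)[utils::head(o, n_tail)],
                    down = names(profile)[utils::tail(o, n_tail)])
  })
}

#' Simulate regulons, a TF-disease fixture map, and a planted TF
#'
#' Disjoint-target regulons with random modes and weights in \[0.2, 1\].
#' The first TF is planted: [sim_regulon_counts()] shifts its targets in
#' the treated arm by `planted_tf_lfc` (sign following the regulation
#' mode). The disease map links every disease to `disease_density` TFs so
#' the >= 2-regulon evidence filter is exercised.
#'
#' @param spec a [sim_spec()].
#' @return List with `regulons` (a [regulon_set()]), `tf_disease` (a
#'   [tf_disease_map()]) and `planted_tf`.
#' @export
sim_regulons <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_stream(spec$seed, "regulons", {
    g <- spec$regulon_genes
    genes <- sprintf("G%04d", seq_len(g))
    k <- spec$n_tfs; tpr <- spec$targets_per_tf
    if (k * tpr > g) stop("not enough genes for disjoint regulons")
    pool <- sample(genes, k * tpr)
    regs <- list()
    for (i in seq_len(k)) {
      targets <- pool[((i - 1) * tpr + 1):(i * tpr)]
      regs[[sprintf("TF%02d", i)]] <- data.frame(
        target = targets,
        mode = sample(c(1, -1), tpr, replace = TRUE),
        weight = stats::runif(tpr, 0.2, 1),
        stringsAsFactors = FALSE)
    }
    tfs <- names(regs)
    n_dis <- max(2L, k %/% 2L)
    dis_rows <- do.call(rbind, lapply(seq_len(n_dis), function(d) {
      linked <- sample(tfs, min(spec$disease_density, k))
      data.frame(tf = linked,
                 cui = sprintf("C%07d", d),
                 disease_name = sprintf("disease_%02d", d),
                 icd9 = sample(c("401", "250", "290.0", "162.9", "493"), 1),
                 stringsAsFactors = FALSE)
    }))
    list(regulons = regulon_set(regs),
         tf_disease = tf_disease_map(dis_rows),
         planted_tf = tfs[1])
  })
}

#' Simulate counts with one planted dysregulated regulon
#'
#' Wraps [sim_counts()] on the regulon gene universe with no freely
#' planted DE genes, then shifts the planted TF's targets in the treated
#' arm by `planted_tf_lfc`, signed by each target's regulation mode (an
#' activated target goes up when the TF activity goes up).
#'
#' @param spec a [sim_spec()].
#' @param reg_sim a [sim_regulons()] result.
#' @return List with `counts` and `planted_tf`.
#' @export
sim_regulon_counts <- function(spec, reg_sim) {
  spec2 <- spec
  spec2$n_genes <- spec$regulon_genes
  spec2$n_de <- 0L
  base <- sim_counts(spec2)
  cm <- base$counts
  reg <- reg_sim$regulons$regulons[[reg_sim$planted_tf]]
  with_stream(spec$seed, "regulon_counts", {
    treated <- cm$sample_meta$sample[!cm$sample_meta$is_control]
    fold <- 2^(spec$planted_tf_lfc * reg$mode)
    for (i in seq_len(nrow(reg))) {
      gidx <- reg$target[i]
      old <- cm$counts[gidx, treated]
      cm$counts[gidx, treated] <-
        as.integer(stats::rnbinom(length(old),
                                  mu = pmax(mean(old), 1) * fold[i],
                                  size = 1 / spec$dispersion))
    }
  })
  list(counts = count_matrix(cm$counts, cm$sample_meta),
       planted_tf = reg_sim$planted_tf)
}

#' Simulate a dose-response curve from the spec's Hill parameters
#'
#' A 2-fold dilution grid from `dose_top` downward (log10 scale, `n_doses`
#' points, spanning > 3 log10 units at the default 12 points) with
#' Gaussian response noise `noise_sd` (percentage points).
#'
#' @param spec a [sim_spec()].
#' @return List with `curve` (a [dose_response_curve()]) and `truth`
#'   (named Hill parameter vector).
#' @export
sim_dose_response <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_stream(spec$seed, "dose_response", {
    conc <- spec$dose_top / 2^(seq_len(spec$n_doses) - 1)
    x <- log10(conc)
    h <- spec$hill
    y <- hill_eq(x, h["bottom"], h["top"], h["loggi50"], h["h"]) +
      stats::rnorm(length(x), 0, spec$noise_sd)
    list(curve = dose_response_curve(x, y), truth = h)
  })
}
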