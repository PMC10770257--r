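#' Configuration for the bulk count simulator
#'
#' Describes a three-arm bulk RNA-seq experiment (non-metastatic,
#' metastatic without bone metastasis, metastatic with bone metastasis)
#' with negative-binomial counts and planted upregulation in the two
#' contrasts of interest: Meta vs nonMeta and, within the metastatic
#' arms, BoM vs nonBoM. A declared number of genes is planted in both
#' contrasts; the overlap is the ground-truth gene panel downstream.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples per phenotype arm.
#' @param baseline_mean expected baseline counts per gene (all genes share
#'   this mean; library-size factors add sample-level variation).
#' @param dispersion NB dispersion; variance = mu + dispersion * mu^2.
#' @param n_meta_up genes planted up in all Meta samples vs nonMeta.
#' @param n_bom_up genes planted up in BoM samples vs nonBoM Meta samples.
#' @param n_overlap genes planted in both contrasts (must not exceed
#'   either planted count).
#' @param log2fc planted log2 fold change (> 0).
#' @param libsize_sigma SD of log-normal library-size factors (>= 0).
#' @param seed integer seed; identical configs give bit-identical data.
#' @return object of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_genes = 2000L, n_samples_per_group = 20L,
                            baseline_mean = 50, dispersion = 0.1,
                            n_meta_up = 100L, n_bom_up = 60L, n_overlap = 30L,
                            log2fc = 2, libsize_sigma = 0.15, seed = 42L) {
  if (!is.finite(baseline_mean) || baseline_mean <= 0)
    .stopf("baseline_mean must be finite and positive")
  if (!is.finite(dispersion) || dispersion <= 0)
    .stopf("dispersion must be finite and positive")
  if (libsize_sigma < 0) .stopf("libsize_sigma must be nonnegative")
  if (n_overlap > min(n_meta_up, n_bom_up))
    .stopf("n_overlap exceeds min(n_meta_up, n_bom_up)")
  if (n_meta_up + n_bom_up - n_overlap > n_genes)
    .stopf("planted gene sets do not fit in n_genes")
  if (log2fc < 0) .stopf("log2fc must be nonnegative")
  if (n_genes < 1L || n_samples_per_group < 1L)
    .stopf("n_genes and n_samples_per_group must be positive")
  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    baseline_mean = baseline_mean, dispersion = dispersion,
    n_meta_up = as.integer(n_meta_up), n_bom_up = as.integer(n_bom_up),
    n_overlap = as.integer(n_overlap), log2fc = log2fc,
    libsize_sigma = libsize_sigma, seed = as.integer(seed)
  ), class = "bulk_sim_config")
}

#' Simulate a bulk count matrix with planted two-tier upregulation
#'
#' Draws gene x sample NB counts for the three phenotype arms described
#' by the config. Planted Meta genes have their mean multiplied by
#' `2^log2fc` in every metastatic sample; planted BoM genes likewise in
#' BoM samples (a gene planted in both carries both multipliers in BoM
#' samples). Genes planted only in the BoM contrast additionally have
#' their nonMeta mean raised to the Meta-arm average, so each planted
#' set is upregulated exactly in its own contrast and invisible to the
#' other (at desk scale BoM samples are half the Meta arm and would
#' otherwise bleed into the Meta comparison). Per-sample library factors
#' are log-normal.
#'
#' @param cfg a [bulk_sim_config()].
#' @return list with `counts` (integer matrix, genes x samples),
#'   `samples` (data.frame: sample_id, meta_status, bom_status) and
#'   `truth` (class `sim_truth`: planted_meta_up, planted_bom_up,
#'   planted_overlap gene-id vectors, lexicographically sorted).
#' @export
simulate_bulk <- function(cfg) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  .with_seed(cfg$seed, {
    G <- cfg$n_genes; n <- cfg$n_samples_per_group
    genes <- sprintf("G%05d", seq_len(G))
    meta_idx <- sort(sample.int(G, cfg$n_meta_up))
    ov_idx <- sort(sample(meta_idx, cfg$n_overlap))
    pool <- setdiff(seq_len(G), meta_idx)
    bom_only_idx <- sort(sample(pool, cfg$n_bom_up - cfg$n_overlap))
    bom_idx <- sort(c(ov_idx, bom_only_idx))

    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(3L * n)),
      meta_status = rep(c("nonMeta", "Meta", "Meta"), each = n),
      bom_status = rep(c(NA_character_, "nonBoM", "BoM"), each = n),
      stringsAsFactors = FALSE
    )
    sfac <- exp(stats::rnorm(3L * n, 0, cfg$libsize_sigma))
    mult <- matrix(1, nrow = G, ncol = 3L * n)
    is_meta <- samples$meta_status == "Meta"
    is_bom <- !is.na(samples$bom_status) & samples$bom_status == "BoM"
    is_nonmeta <- !is_meta
    mult[meta_idx, is_meta] <- mult[meta_idx, is_meta] * 2^cfg$log2fc
    mult[bom_idx, is_bom] <- mult[bom_idx, is_bom] * 2^cfg$log2fc
    # BoM-only genes would otherwise leak into the Meta contrast (BoM
    # samples are half the Meta arm at desk scale, unlike cohort-scale
    # data where they are a sliver): balance the Meta-vs-nonMeta means
    # for them by raising the nonMeta arm to the Meta-arm average
    mult[bom_only_idx, is_nonmeta] <-
      mult[bom_only_idx, is_nonmeta] * (1 + 2^cfg$log2fc) / 2
    mu <- cfg$baseline_mean * mult * rep(sfac, each = G)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     nrow = G, dimnames = list(genes, samples$sample_id))
    truth <- structure(list(
      planted_meta_up = genes[meta_idx],
      planted_bom_up = genes[bom_idx],
      planted_overlap = genes[ov_idx]
    ), class = "sim_truth")
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Configuration for the single-cell count simulator
#'
#' Describes a multi-sample, multi-subgroup single-cell experiment:
#' samples carry a condition label (at least two levels; `"BoM"` marks
#' the bone-metastasis arm) and an optional multi-level sample type;
#' subgroups carry planted marker genes. Optional condition effects
#' elevate chosen genes only in BoM-derived cells of a chosen subgroup,
#' and ligand-receptor programs elevate a ligand in subgroup A and a
#' receptor in subgroup B (BoM cells only) while coupling the two genes
#' through a shared per-cell latent factor that induces a target Pearson
#' correlation on log-normalized values.
#'
#' Gene baseline means are drawn (log-normal across genes) inside this
#' constructor under the given seed and rescaled so the expected zero
#' fraction of the count matrix matches `sparsity`; they are stored in
#' the config so callers can place planted effects on expressed genes.
#'
#' @param n_genes number of genes.
#' @param subgroups list of lists with fields `label`,
#'   `n_cells_per_sample`, and optional `markers` (character gene ids).
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (two or more levels; `"BoM"` is the metastatic arm) and optional
#'   `sample_type` (defaults to `condition`).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-gene baseline means (before sparsity rescaling).
#' @param dispersion NB dispersion shared by all genes.
#' @param marker_log2fc planted log2 fold change of subgroup markers.
#' @param condition_effects data.frame (`subgroup`, `gene`, `log2fc`)
#'   applied only to BoM cells of that subgroup.
#' @param lr_programs data.frame (`ligand`, `subgroup_a`, `receptor`,
#'   `subgroup_b`, `log2fc`, `rho`) with `rho` in \[0, 1).
#' @param sparsity target fraction of zero entries (`NULL` to skip
#'   calibration and use the raw log-normal means).
#' @param seed integer seed.
#' @return object of class `sc_sim_config` (includes the calibrated
#'   `gene_means` vector and `genes` ids).
#' @export
sc_sim_config <- function(n_genes, subgroups, samples,
                          baseline_log_mean = log(0.5), baseline_log_sd = 1,
                          dispersion = 0.8, marker_log2fc = 2,
                          condition_effects = NULL, lr_programs = NULL,
                          sparsity = 0.9, seed = 42L) {
  if (length(subgroups) == 0L) .stopf("subgroup list must be non-empty")
  if (!is.data.frame(samples) || !all(c("sample_id", "condition") %in% names(samples)))
    .stopf("samples must be a data.frame with sample_id and condition columns")
  if (anyDuplicated(samples$sample_id)) .stopf("duplicate sample ids")
  if (length(unique(samples$condition)) < 2L)
    .stopf("condition labels must cover at least 2 levels")
  if (is.null(samples$sample_type)) samples$sample_type <- samples$condition
  if (!is.finite(dispersion) || dispersion <= 0)
    .stopf("dispersion must be finite and positive")
  labels <- vapply(subgroups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) .stopf("duplicate subgroup labels")
  genes <- sprintf("G%05d", seq_len(n_genes))

  chk_genes <- function(g, ctx) {
    bad <- setdiff(g, genes)
    if (length(bad)) .stopf("%s references unknown genes: %s", ctx,
                            paste(utils::head(bad, 5), collapse = ", "))
  }
  chk_sub <- function(s, ctx) {
    bad <- setdiff(s, labels)
    if (length(bad)) .stopf("%s references undeclared subgroups: %s", ctx,
                            paste(unique(bad), collapse = ", "))
  }
  for (sg in subgroups) {
    if (!is.null(sg$markers)) chk_genes(sg$markers, sprintf("subgroup %s markers", sg$label))
    if (sg$n_cells_per_sample < 1L) .stopf("n_cells_per_sample must be positive")
  }
  if (!is.null(condition_effects)) {
    stopifnot(all(c("subgroup", "gene", "log2fc") %in% names(condition_effects)))
    chk_genes(condition_effects$gene, "condition_effects")
    chk_sub(condition_effects$subgroup, "condition_effects")
  }
  if (!is.null(lr_programs)) {
    stopifnot(all(c("ligand", "subgroup_a", "receptor", "subgroup_b",
                    "log2fc", "rho") %in% names(lr_programs)))
    chk_genes(c(lr_programs$ligand, lr_programs$receptor), "lr_programs")
    chk_sub(c(lr_programs$subgroup_a, lr_programs$subgroup_b), "lr_programs")
    if (any(lr_programs$rho < 0 | lr_programs$rho >= 1))
      .stopf("co-expression rho must lie in [0, 1)")
  }

  gene_means <- .with_seed(seed, {
    mu0 <- stats::rlnorm(n_genes, baseline_log_mean, baseline_log_sd)
    if (!is.null(sparsity)) {
      p0 <- function(mu) (1 + mu * dispersion)^(-1 / dispersion)
      f <- function(lc) mean(p0(exp(lc) * mu0)) - sparsity
      # mean zero-probability is monotone decreasing in the scale
      sc <- exp(stats::uniroot(f, c(-25, 25), tol = 1e-10)$root)
      mu0 * sc
    } else mu0
  })
  names(gene_means) <- genes

  structure(list(
    n_genes = as.integer(n_genes), genes = genes, gene_means = gene_means,
    subgroups = subgroups, samples = samples,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion, marker_log2fc = marker_log2fc,
    condition_effects = condition_effects, lr_programs = lr_programs,
    sparsity = sparsity, seed = as.integer(seed)
  ), class = "sc_sim_config")
}

# Moments of the log-normalized value y = log1p(cconst * count) of an NB
# gene whose log-mean carries a latent bump a*z, z ~ N(0,1): returns the
# conditional mean curve m(z) over a fixed z grid plus the z-averaged
# within-cell variance. Used to calibrate the latent amplitude exactly
# against the observation model (NB noise + log1p compression + zeros).
.latent_moments <- function(mu, dispersion, a, cconst, zgrid, wz) {
  kmax <- max(20, stats::qnbinom(1 - 1e-7, mu = mu * exp(a * max(zgrid)),
                                 size = 1 / dispersion))
  kmax <- min(kmax, 20000)
  k <- 0:kmax
  yk <- log1p(cconst * k)
  muz <- mu * exp(a * zgrid)
  P <- vapply(muz, function(m) stats::dnbinom(k, mu = m, size = 1 / dispersion),
              numeric(length(k)))
  m <- colSums(yk * P)
  m2 <- colSums(yk^2 * P)
  list(m = m, vbar = sum(wz * (m2 - m^2)))
}

# Latent amplitude (natural-log units) such that two NB genes sharing the
# factor a*z in their log-means reach Pearson correlation ~= rho on
# log-normalized values. Monotone in a; solved by bisection on a grid of
# Gaussian quadrature nodes.
.latent_amplitude <- function(muL, muR, dispersion, rho, cconst) {
  if (rho <= 0) return(0)
  zgrid <- seq(-4.5, 4.5, length.out = 37)
  wz <- stats::dnorm(zgrid); wz <- wz / sum(wz)
  corr_at <- function(a) {
    L <- .latent_moments(muL, dispersion, a, cconst, zgrid, wz)
    R <- .latent_moments(muR, dispersion, a, cconst, zgrid, wz)
    mbarL <- sum(wz * L$m); mbarR <- sum(wz * R$m)
    covz <- sum(wz * (L$m - mbarL) * (R$m - mbarR))
    vL <- sum(wz * (L$m - mbarL)^2) + L$vbar
    vR <- sum(wz * (R$m - mbarR)^2) + R$vbar
    covz / sqrt(vL * vR)
  }
  upper <- 4
  if (corr_at(upper) < rho) {
    .warnf("target co-expression rho %.2f unreachable; using amplitude %.1f",
           rho, upper)
    return(upper)
  }
  stats::uniroot(function(a) corr_at(a) - rho, c(1e-3, upper), tol = 1e-3)$root
}

#' Simulate a single-cell count matrix with planted structure
#'
#' Draws gene x cell NB counts per (sample, subgroup) block. Marker
#' genes are elevated `2^marker_log2fc` in their subgroup everywhere;
#' condition effects and ligand-receptor elevations apply only in cells
#' from BoM samples. Each L-R program adds a shared standard-normal
#' latent factor to the log-means of its two genes within BoM cells of
#' both endpoint subgroups, scaled so the Pearson correlation of the two
#' genes' log-normalized values approximates the configured `rho`.
#'
#' @param cfg an [sc_sim_config()].
#' @return list with `counts` (sparse dgCMatrix, genes x cells), `cells`
#'   (data.frame: cell_id, sample_id, sample_type, condition, subgroup;
#'   rows align with matrix columns) and `truth` (class `sim_truth`:
#'   `planted_markers` and `planted_condition_up` as label -> gene-set
#'   lists, `planted_lr_pairs` and `planted_correlated_pairs` as
#'   data.frames).
#' @export
simulate_sc <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  .with_seed(cfg$seed, {
    G <- cfg$n_genes
    genes <- cfg$genes
    base_l2 <- log2(cfg$gene_means)
    size <- 1 / cfg$dispersion
    blocks <- list()
    cells <- list()
    k <- 0L
    for (si in seq_len(nrow(cfg$samples))) {
      smp <- cfg$samples[si, ]
      is_bom <- identical(smp$condition, "BoM")
      for (sg in cfg$subgroups) {
        k <- k + 1L
        nc <- sg$n_cells_per_sample
        l2 <- matrix(base_l2, nrow = G, ncol = nc)
        if (!is.null(sg$markers)) {
          mi <- match(sg$markers, genes)
          l2[mi, ] <- l2[mi, ] + cfg$marker_log2fc
        }
        if (is_bom && !is.null(cfg$condition_effects)) {
          ce <- cfg$condition_effects[cfg$condition_effects$subgroup == sg$label, ]
          if (nrow(ce)) {
            ci <- match(ce$gene, genes)
            l2[ci, ] <- l2[ci, ] + ce$log2fc
          }
        }
        if (is_bom && !is.null(cfg$lr_programs)) {
          for (pi in seq_len(nrow(cfg$lr_programs))) {
            pr <- cfg$lr_programs[pi, ]
            if (!(sg$label %in% c(pr$subgroup_a, pr$subgroup_b))) next
            li <- match(pr$ligand, genes); ri <- match(pr$receptor, genes)
            l2[li, ] <- l2[li, ] + pr$log2fc
            l2[ri, ] <- l2[ri, ] + pr$log2fc
            if (pr$rho > 0) {
              # shared latent factor; amplitude from the target correlation
              # and the two genes' approximate log-scale noise variances
              cconst <- 1e4 / sum(2^l2[, 1L])   # lognormalize default scale
              a_ln <- .latent_amplitude(2^l2[li, 1L], 2^l2[ri, 1L],
                                        cfg$dispersion, pr$rho, cconst)
              z <- stats::rnorm(nc)
              bump <- (a_ln / log(2)) * z
              l2[li, ] <- l2[li, ] + bump
              l2[ri, ] <- l2[ri, ] + bump
            }
          }
        }
        cnt <- matrix(stats::rnbinom(G * nc, mu = 2^l2, size = size), nrow = G)
        ids <- sprintf("%s_%s_%03d", smp$sample_id, sg$label, seq_len(nc))
        blocks[[k]] <- cnt
        cells[[k]] <- data.frame(
          cell_id = ids, sample_id = smp$sample_id,
          sample_type = smp$sample_type, condition = smp$condition,
          subgroup = sg$label, stringsAsFactors = FALSE
        )
      }
    }
    counts <- do.call(cbind, blocks)
    cell_table <- do.call(rbind, cells)
    if (anyDuplicated(cell_table$cell_id)) .stopf("duplicate cell ids generated")
    dimnames(counts) <- list(genes, cell_table$cell_id)
    counts <- Matrix::Matrix(counts, sparse = TRUE)

    markers <- lapply(cfg$subgroups, function(sg) .lex_sort(unique(sg$markers %||% character(0))))
    names(markers) <- vapply(cfg$subgroups, `[[`, character(1), "label")
    # condition-upregulated truth: explicit condition effects plus the
    # L-R program genes, which are elevated in BoM cells of both
    # endpoint subgroups and hence genuine positives for the screen
    cond_df <- data.frame(subgroup = character(0), gene = character(0))
    if (!is.null(cfg$condition_effects)) {
      ce <- cfg$condition_effects[cfg$condition_effects$log2fc > 0, ]
      cond_df <- rbind(cond_df, ce[, c("subgroup", "gene")])
    }
    if (!is.null(cfg$lr_programs)) {
      pp <- cfg$lr_programs[cfg$lr_programs$log2fc > 0, ]
      if (nrow(pp))
        cond_df <- rbind(cond_df,
                         data.frame(subgroup = rep(c(pp$subgroup_a, pp$subgroup_b), 2L),
                                    gene = c(pp$ligand, pp$ligand,
                                             pp$receptor, pp$receptor)))
    }
    cond_up <- if (nrow(cond_df))
      lapply(split(cond_df$gene, cond_df$subgroup),
             function(g) .lex_sort(unique(g)))
    else list()
    lr_pairs <- corr_pairs <- NULL
    if (!is.null(cfg$lr_programs)) {
      lr_pairs <- cfg$lr_programs[, c("ligand", "subgroup_a", "receptor", "subgroup_b")]
      cp <- cfg$lr_programs[cfg$lr_programs$rho > 0, ]
      if (nrow(cp)) {
        corr_pairs <- unique(rbind(
          data.frame(gene_a = cp$ligand, gene_b = cp$receptor,
                     subgroup = cp$subgroup_a, rho = cp$rho, stringsAsFactors = FALSE),
          data.frame(gene_a = cp$ligand, gene_b = cp$receptor,
                     subgroup = cp$subgroup_b, rho = cp$rho, stringsAsFactors = FALSE)
        ))
        rownames(corr_pairs) <- NULL
      }
    }
    truth <- structure(list(
      planted_markers = markers,
      planted_condition_up = cond_up,
      planted_lr_pairs = lr_pairs,
      planted_correlated_pairs = corr_pairs
    ), class = "sim_truth")
    list(counts = counts, cells = cell_table, truth = truth)
  })
}

#' Simulate a ligand-receptor pair database with decoys
#'
#' Builds a pair database containing the supplied true pairs plus
#' `n_decoys` decoy pairs sampled uniformly without replacement from all
#' ordered non-self gene pairs of the universe, excluding the true pairs.
#'
#' @param true_pairs data.frame with columns `ligand` and `receptor`
#'   (may have zero rows).
#' @param n_decoys number of decoy pairs.
#' @param gene_universe character vector of gene ids to draw decoys from.
#' @param seed integer seed.
#' @param decoy_universe optional subset of `gene_universe` to restrict
#'   decoy genes to (default: the whole universe); useful when some
#'   universe genes carry planted effects and must not appear in decoy
#'   rows.
#' @return data.frame (`ligand`, `receptor`, `true_pair`) of class
#'   `lr_database`, true pairs first.
#' @export
simulate_lr_db <- function(true_pairs, n_decoys, gene_universe, seed = 42L,
                           decoy_universe = gene_universe) {
  stopifnot(is.data.frame(true_pairs),
            all(c("ligand", "receptor") %in% names(true_pairs)))
  bad <- setdiff(c(true_pairs$ligand, true_pairs$receptor), gene_universe)
  if (length(bad)) .stopf("true pairs reference genes outside the universe: %s",
                          paste(utils::head(bad, 5), collapse = ", "))
  if (length(setdiff(decoy_universe, gene_universe)))
    .stopf("decoy_universe must be a subset of gene_universe")
  n <- length(decoy_universe)
  M <- n * (n - 1)
  pair_key <- function(l, r) paste(l, r, sep = "\r")
  true_keys <- pair_key(true_pairs$ligand, true_pairs$receptor)
  if (anyDuplicated(true_keys)) .stopf("duplicate true pairs")
  in_decoy <- true_pairs$ligand %in% decoy_universe &
    true_pairs$receptor %in% decoy_universe
  avail <- M - sum(in_decoy)
  if (n_decoys > avail)
    .stopf("n_decoys (%d) exceeds the %d available distinct non-true pairs",
           n_decoys, avail)
  decoys <- .with_seed(seed, {
    if (n_decoys == 0L) {
      data.frame(ligand = character(0), receptor = character(0),
                 stringsAsFactors = FALSE)
    } else {
      li <- match(true_pairs$ligand[in_decoy], decoy_universe)
      ri <- match(true_pairs$receptor[in_decoy], decoy_universe)
      # index k in 1..n(n-1) encodes ordered non-self pair (i, j)
      rk <- ri - (ri > li)
      true_k <- (li - 1L) * (n - 1L) + rk
      allowed <- setdiff(seq_len(M), true_k)
      ks <- sample(allowed, n_decoys)
      i <- (ks - 1L) %/% (n - 1L) + 1L
      r <- (ks - 1L) %% (n - 1L) + 1L
      j <- r + (r >= i)
      data.frame(ligand = decoy_universe[i], receptor = decoy_universe[j],
                 stringsAsFactors = FALSE)
    }
  })
  out <- rbind(
    data.frame(ligand = as.character(true_pairs$ligand),
               receptor = as.character(true_pairs$receptor),
               true_pair = rep(TRUE, nrow(true_pairs)), stringsAsFactors = FALSE),
    cbind(decoys, true_pair = rep(FALSE, nrow(decoys)))
  )
  rownames(out) <- NULL
  class(out) <- c("lr_database", "data.frame")
  out
}

#' Default desk-scale bulk simulation config
#'
#' A three-arm bulk design mirroring the two-tier TCGA-style contrast at
#' desk scale: 2,000 genes, 20 samples per arm, 100 genes planted up in
#' metastasis, 60 in bone metastasis, 30 in both (the ground-truth
#' panel), log2 fold change 2.
#'
#' @param seed integer seed (default 42).
#' @return a [bulk_sim_config()].
#' @export
default_bulk_config <- function(seed = 42L) {
  bulk_sim_config(n_genes = 2000L, n_samples_per_group = 20L,
                  baseline_mean = 50, dispersion = 0.1,
                  n_meta_up = 100L, n_bom_up = 60L, n_overlap = 30L,
                  log2fc = 2, libsize_sigma = 0.15, seed = seed)
}

#' Default "breast-like" single-cell simulation config
#'
#' Mirrors the topology of a two-condition xenograft/bone-metastasis
#' breast dataset at desk scale: 4 samples (2 PDX = Other, 2 BoM), 8
#' subgroups including one fibroblast-like and two tumor-like
#' populations, 1,500 genes, ~4,000 cells. Five marker genes are planted
#' per subgroup; 150 genes are planted up (log2fc = 3) in BoM-derived
#' fibroblast-like cells; 10 ligand-receptor programs couple the
#' fibroblast-like and first tumor-like subgroup at 4-fold elevation
#' with co-expression rho = 0.5. All planted genes are drawn from the
#' expressed pool (expected detection rate >= 25%) so that planted truth
#' is visible to ratio-filtered screens.
#'
#' @param seed integer seed (default 42).
#' @return a [sc_sim_config()].
#' @export
default_sc_config <- function(seed = 42L) {
  n_genes <- 1500L
  sub_sizes <- c(fibroblast = 100L, tumor_a = 200L, tumor_b = 150L,
                 myeloid = 120L, tcell = 150L, bcell = 80L,
                 endothelial = 100L, stroma = 100L)
  samples <- data.frame(
    sample_id = c("PD01", "PD02", "BM01", "BM02"),
    condition = c("Other", "Other", "BoM", "BoM"),
    sample_type = c("PDX", "PDX", "BoM", "BoM"),
    stringsAsFactors = FALSE
  )
  # draft config: draws gene means so planted genes can target the
  # expressed pool; the final config below reuses the same seed
  draft <- sc_sim_config(
    n_genes = n_genes,
    subgroups = lapply(names(sub_sizes), function(l)
      list(label = l, n_cells_per_sample = sub_sizes[[l]])),
    samples = samples, sparsity = 0.85, seed = seed
  )
  det_rate <- 1 - (1 + draft$gene_means * draft$dispersion)^(-1 / draft$dispersion)
  pool <- draft$genes[det_rate >= 0.25]
  picks <- .with_seed(seed + 1L, sample(pool, 8L * 5L + 150L + 20L))
  marker_sets <- split(picks[1:40], rep(names(sub_sizes), each = 5L))
  cond_genes <- picks[41:190]
  lr_genes <- picks[191:210]
  subgroups <- lapply(names(sub_sizes), function(l)
    list(label = l, n_cells_per_sample = sub_sizes[[l]],
         markers = marker_sets[[l]]))
  condition_effects <- data.frame(
    subgroup = "fibroblast", gene = cond_genes, log2fc = 3,
    stringsAsFactors = FALSE
  )
  lr_programs <- data.frame(
    ligand = lr_genes[1:10], subgroup_a = "fibroblast",
    receptor = lr_genes[11:20], subgroup_b = "tumor_a",
    log2fc = 2, rho = 0.5, stringsAsFactors = FALSE
  )
  sc_sim_config(
    n_genes = n_genes, subgroups = subgroups, samples = samples,
    condition_effects = condition_effects, lr_programs = lr_programs,
    sparsity = 0.85, seed = seed
  )
}

#' Companion ligand-receptor database for the default single-cell config
#'
#' True pairs are the config's planted programs; decoys are sampled from
#' the expressed gene pool (detection rate >= 25%) so that decoy rows are
#' non-trivial negatives for the screen.
#'
#' @param cfg an [sc_sim_config()] with `lr_programs`.
#' @param n_decoys number of decoys (default 40).
#' @param seed integer seed.
#' @return an `lr_database` data.frame.
#' @export
default_lr_db <- function(cfg, n_decoys = 40L, seed = 42L) {
  stopifnot(inherits(cfg, "sc_sim_config"), !is.null(cfg$lr_programs))
  det_rate <- 1 - (1 + cfg$gene_means * cfg$dispersion)^(-1 / cfg$dispersion)
  pool <- cfg$genes[det_rate >= 0.25]
  # decoys must be true negatives: exclude genes the generator itself
  # elevates in BoM cells (condition effects and program genes)
  planted <- unique(c(cfg$lr_programs$ligand, cfg$lr_programs$receptor,
                      cfg$condition_effects$gene))
  pool <- setdiff(pool, planted)
  true_pairs <- cfg$lr_programs[, c("ligand", "receptor")]
  universe <- unique(c(pool, true_pairs$ligand, true_pairs$receptor))
  simulate_lr_db(true_pairs, n_decoys = n_decoys, gene_universe = universe,
                 seed = seed, decoy_universe = pool)
}
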