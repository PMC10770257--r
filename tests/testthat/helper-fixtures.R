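# Shared fixtures, built once per test run (seeded, deterministic).

.fx <- new.env(parent = emptyenv())

fx_bulk <- function() {
  if (is.null(.fx$bulk)) {
    .fx$bulk_cfg <- default_bulk_config(seed = 42L)
    .fx$bulk <- simulate_bulk(.fx$bulk_cfg)
  }
  list(cfg = .fx$bulk_cfg, sim = .fx$bulk)
}

fx_bulk_de <- function() {
  if (is.null(.fx$de_meta)) {
    b <- fx_bulk()$sim
    smp <- b$samples
    .fx$de_meta <- nb_wald_de(b$counts,
                              factor(smp$meta_status, c("nonMeta", "Meta")))
    im <- smp$meta_status == "Meta"
    .fx$de_bom <- nb_wald_de(b$counts[, im],
                             factor(smp$bom_status[im], c("nonBoM", "BoM")))
  }
  list(de_meta = .fx$de_meta, de_bom = .fx$de_bom)
}

fx_sc <- function() {
  if (is.null(.fx$sc)) {
    .fx$sc_cfg <- default_sc_config(seed = 42L)
    .fx$sc <- simulate_sc(.fx$sc_cfg)
    .fx$expr <- lognormalize(.fx$sc$counts)
  }
  list(cfg = .fx$sc_cfg, sim = .fx$sc, expr = .fx$expr)
}

fx_lr_db <- function() {
  if (is.null(.fx$lrdb)) .fx$lrdb <- default_lr_db(fx_sc()$cfg, 40L, 42L)
  .fx$lrdb
}

# tiny two-subgroup single-cell config without planted effects
null_sc_config <- function(n_genes = 400L, seed = 1L, sparsity = 0.75,
                           cells = 80L) {
  sc_sim_config(
    n_genes = n_genes,
    subgroups = list(list(label = "a", n_cells_per_sample = cells),
                     list(label = "b", n_cells_per_sample = cells)),
    samples = data.frame(sample_id = c("A1", "A2", "B1", "B2"),
                         condition = c("Other", "Other", "BoM", "BoM")),
    sparsity = sparsity, seed = seed
  )
}

# Brute-force two-sided rank-sum p by complete enumeration of all
# C(N, m) assignments of the pooled ranks (no ties assumed).
enum_ranksum_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  W <- sum(rank(c(x, y))[seq_len(m)])
  sums <- apply(utils::combn(N, m), 2L, sum)
  p_le <- mean(sums <= W); p_ge <- mean(sums >= W)
  min(1, 2 * min(p_le, p_ge))
}

# Literal BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by direct combinatorial summation.
brute_hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Complete on-disk workspace (bulk + sc + L-R db + GMT + config), built once.
pipeline_workspace <- local({
  ws <- NULL
  function() {
    if (!is.null(ws)) return(ws)
    root <- file.path(tempdir(), "bomscope_ws")
    dir.create(root, showWarnings = FALSE)
    b <- fx_bulk()$sim
    write_sim_bulk(b, file.path(root, "bulk"))
    s <- fx_sc()$sim
    write_sim_sc(s, file.path(root, "sc"))
    write_lr_db(fx_lr_db(), file.path(root, "lr_db.csv"))
    sets <- list(panel_like = b$truth$planted_overlap,
                 random = rownames(b$counts)[1:40])
    attr(sets, "descriptions") <- c(panel_like = "planted overlap",
                                    random = "background")
    write_gmt(sets, file.path(root, "sets.gmt"))
    cfg <- pipeline_config(
      bulk_counts = file.path(root, "bulk", "bulk_counts.tsv"),
      bulk_samples = file.path(root, "bulk", "bulk_samples.tsv"),
      sc_counts = file.path(root, "sc"),
      sc_cells = file.path(root, "sc", "cells.tsv"),
      sc_format = "mtx_triplet",
      lr_db = file.path(root, "lr_db.csv"),
      gmt = file.path(root, "sets.gmt"),
      screen_subgroups = "fibroblast",
      lr_pairs = list(list(from = "fibroblast", to = "tumor_a")),
      correlations = list(list(subgroup = "fibroblast",
                               anchors = fx_sc()$cfg$lr_programs$ligand[1:2],
                               targets = fx_sc()$cfg$lr_programs$receptor[1:2])),
      out_dir = file.path(root, "out"), seed = 42L
    )
    ws <<- list(root = root, cfg = cfg)
    ws
  }
})
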