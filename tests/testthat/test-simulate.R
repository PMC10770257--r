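test_that("bulk simulator: config validation, empty truth, determinism", {
  expect_error(bulk_sim_config(baseline_mean = -1), "baseline_mean")
  expect_error(bulk_sim_config(dispersion = 0), "dispersion")
  expect_error(bulk_sim_config(n_meta_up = 5, n_bom_up = 5, n_overlap = 6),
               "n_overlap")
  expect_error(bulk_sim_config(n_genes = 10, n_meta_up = 8, n_bom_up = 8,
                               n_overlap = 2), "do not fit")

  cfg0 <- bulk_sim_config(n_genes = 200, n_samples_per_group = 3,
                          n_meta_up = 0, n_bom_up = 0, n_overlap = 0, seed = 5)
  s0 <- simulate_bulk(cfg0)
  expect_length(s0$truth$planted_meta_up, 0)
  expect_length(s0$truth$planted_bom_up, 0)
  expect_length(s0$truth$planted_overlap, 0)

  cfg <- bulk_sim_config(n_genes = 300, n_samples_per_group = 4, seed = 9,
                         n_meta_up = 20, n_bom_up = 12, n_overlap = 6)
  a <- simulate_bulk(cfg); b <- simulate_bulk(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("bulk truth is consistent and planted effects hit their contrasts", {
  f <- fx_bulk()
  tr <- f$sim$truth
  genes <- rownames(f$sim$counts)
  expect_true(all(unlist(tr) %in% genes))
  expect_setequal(tr$planted_overlap,
                  intersect(tr$planted_meta_up, tr$planted_bom_up))
  # Monte-Carlo check of the generator's own expectation: normalized
  # BoM/nonBoM mean ratio close to 2^log2fc = 4 for planted BoM genes
  smp <- f$sim$samples
  sf <- size_factors(f$sim$counts)
  y <- sweep(f$sim$counts, 2, sf, "/")
  ib <- !is.na(smp$bom_status) & smp$bom_status == "BoM"
  inb <- !is.na(smp$bom_status) & smp$bom_status == "nonBoM"
  rat <- rowMeans(y[tr$planted_bom_up, ib]) / rowMeans(y[tr$planted_bom_up, inb])
  expect_gte(mean(rat >= 3.0 & rat <= 5.3), 0.95)
})

test_that("sc simulator: determinism, alignment, sparsity, validation", {
  cfg <- null_sc_config(n_genes = 120, seed = 3, cells = 15)
  a <- simulate_sc(cfg); b <- simulate_sc(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(colnames(a$counts), a$cells$cell_id)

  f <- fx_sc()
  zf <- 1 - length(f$sim$counts@x[f$sim$counts@x != 0]) / prod(dim(f$sim$counts))
  expect_lt(abs(zf - 0.85), 0.1)
  tr <- f$sim$truth
  expect_true(all(unlist(tr$planted_markers) %in% rownames(f$sim$counts)))
  expect_true(all(unlist(tr$planted_condition_up) %in% rownames(f$sim$counts)))

  expect_error(sc_sim_config(10, list(), data.frame(sample_id = "a",
                                                    condition = "BoM")),
               "non-empty")
  expect_error(sc_sim_config(
    10, list(list(label = "a", n_cells_per_sample = 5)),
    data.frame(sample_id = c("s1", "s2"), condition = c("BoM", "BoM"))),
    "2 levels")
  expect_error(sc_sim_config(
    10, list(list(label = "a", n_cells_per_sample = 5,
                  markers = "G99999")),
    data.frame(sample_id = c("s1", "s2"), condition = c("BoM", "Other"))),
    "unknown genes")
})

test_that("sc generator is calibrated under its own null", {
  subs <- list(list(label = "s1", n_cells_per_sample = 120))
  smp <- data.frame(sample_id = c("A1", "A2", "B1", "B2"),
                    condition = c("Other", "Other", "BoM", "BoM"))
  cfg <- sc_sim_config(n_genes = 4000, subgroups = subs, samples = smp,
                       sparsity = 0.75, seed = 11)
  sim <- simulate_sc(cfg)
  expr <- lognormalize(sim$counts)
  scr <- screen_condition_genes(expr, sim$counts, sim$cells, "s1")
  expect_gte(nrow(scr), 2000)
  frac <- mean(scr$p_raw < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("a planted condition gene is recovered in nearly all replicates", {
  subs <- list(list(label = "s", n_cells_per_sample = 200))
  smp <- data.frame(sample_id = c("P1", "B1"), condition = c("Other", "BoM"))
  hits <- 0L
  for (s in 1:100) {
    base <- sc_sim_config(n_genes = 60, subgroups = subs, samples = smp,
                          sparsity = 0.7, seed = 300 + s)
    det <- 1 - (1 + base$gene_means * base$dispersion)^(-1 / base$dispersion)
    g <- base$genes[which.min(abs(det - 0.4))]   # a moderately expressed gene
    cfg <- sc_sim_config(n_genes = 60, subgroups = subs, samples = smp,
                         sparsity = 0.7, seed = 300 + s,
                         condition_effects = data.frame(
                           subgroup = "s", gene = g, log2fc = 3))
    sim <- simulate_sc(cfg)
    expr <- lognormalize(sim$counts)
    scr <- screen_condition_genes(expr, sim$counts, sim$cells, "s")
    hits <- hits + (g %in% scr$gene[scr$up_in_bom])
  }
  expect_gte(hits, 99L)
})

test_that("lr database simulator: set algebra, determinism, capacity error", {
  uni <- paste0("g", 1:6)
  tp <- data.frame(ligand = "g1", receptor = "g2")
  d0 <- simulate_lr_db(tp, 0, uni, seed = 1)
  expect_equal(nrow(d0), 1)
  expect_true(all(d0$true_pair))

  d3 <- simulate_lr_db(tp, 3, uni, seed = 1)
  expect_equal(nrow(d3), 4)
  expect_true(any(d3$ligand == "g1" & d3$receptor == "g2" & d3$true_pair))
  dec <- d3[!d3$true_pair, ]
  expect_equal(nrow(dec), 3)
  expect_false(any(dec$ligand == dec$receptor))          # no self-pairs
  expect_false(any(paste(dec$ligand, dec$receptor) %in%
                     paste(tp$ligand, tp$receptor)))
  expect_identical(simulate_lr_db(tp, 3, uni, seed = 7),
                   simulate_lr_db(tp, 3, uni, seed = 7))
  expect_error(simulate_lr_db(tp, 30, uni[1:3], seed = 1), "exceeds")
})
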