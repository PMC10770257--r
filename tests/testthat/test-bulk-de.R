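test_that("size_factors implements median-of-ratios with its conventions", {
  m <- cbind(A = c(2, 4, 8), B = c(1, 2, 4))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m)), c(sqrt(2), 1 / sqrt(2)),
               tolerance = 1e-12)
  same <- matrix(5L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(size_factors(same)), rep(1, 3))
  single <- matrix(c(3L, 9L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(size_factors(single)), 1)
  allz <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(allz), "undefined")
})

test_that("nb_wald_de: exact-equality null, input validation", {
  g1 <- matrix(rpois(60, 20), 10, 6,
               dimnames = list(sprintf("g%02d", 1:10), paste0("a", 1:6)))
  m <- cbind(g1, g1)
  colnames(m) <- c(paste0("a", 1:6), paste0("b", 1:6))
  de <- nb_wald_de(m, rep(c("g1", "g2"), each = 6))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p_raw == 1))
  expect_true(all(de$direction == "ns"))
  expect_error(nb_wald_de(m, rep("x", 12)), "two group")
  expect_error(nb_wald_de(m[, 1:3], c("a", "a", "b")), "at least 2")
  m2 <- m; m2[1, 1] <- 0.5
  expect_error(nb_wald_de(m2, rep(c("g1", "g2"), each = 6)), "integer")
})

test_that("nb_wald_de type-I error is calibrated on the simulator's null", {
  cfg <- bulk_sim_config(n_genes = 2000, n_meta_up = 0, n_bom_up = 0,
                         n_overlap = 0, seed = 7)
  sim <- simulate_bulk(cfg)
  de <- nb_wald_de(sim$counts,
                   factor(sim$samples$meta_status, c("nonMeta", "Meta")))
  frac <- mean(de$p_raw < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("nb_wald_de recovers planted genes with controlled false discoveries", {
  cfg <- bulk_sim_config(n_genes = 2000, n_meta_up = 100, n_bom_up = 0,
                         n_overlap = 0, log2fc = 2, seed = 42)
  sim <- simulate_bulk(cfg)
  de <- nb_wald_de(sim$counts,
                   factor(sim$samples$meta_status, c("nonMeta", "Meta")))
  up <- de$gene[de$direction == "up"]
  expect_gte(sum(sim$truth$planted_meta_up %in% up), 90)
  expect_lte(length(setdiff(up, sim$truth$planted_meta_up)),
             0.10 * length(up))
})

test_that("size factors absorb an integer rescaling of one sample", {
  # Exact invariance of z is unattainable for an NB Wald test: after
  # median-of-ratios normalization a residual global factor c^(1/n)
  # remains, and the Poisson part of the NB variance is genuinely
  # scale-dependent (tripling one sample's reads lowers its shot
  # noise). The attainable contract, asserted here: the scaled sample's
  # size factor absorbs the multiplier up to that residual, and z
  # changes only by the predictable higher-order amount.
  f <- fx_bulk()
  counts <- f$sim$counts[1:400, ]
  n <- ncol(counts)
  grp <- factor(f$sim$samples$meta_status, c("nonMeta", "Meta"))
  de1 <- nb_wald_de(counts, grp)
  counts2 <- counts
  counts2[, 5] <- counts2[, 5] * 3L
  de2 <- nb_wald_de(counts2, grp)
  sf1 <- size_factors(counts); sf2 <- size_factors(counts2)
  expect_equal(unname(sf2[5] / sf1[5]), 3 * 3^(-1 / n), tolerance = 1e-9)
  expect_equal(unname(sf2[-5] / sf1[-5]), rep(3^(-1 / n), n - 1),
               tolerance = 1e-9)
  z1 <- qnorm(de1$p_raw / 2) * sign(de1$log2fc)
  z2 <- qnorm(de2$p_raw / 2) * sign(de2$log2fc)
  ok <- is.finite(z1) & is.finite(z2)
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(z1[ok] - z2[ok])), 0.05)
  expect_lt(stats::median(abs(z1[ok] - z2[ok])), 0.01)
  # significance decisions essentially unchanged (borderline genes only)
  expect_gte(mean(de1$direction == de2$direction), 0.995)
})

test_that("derive_panel is the intersection of up-sets, ordered and monotone", {
  mk <- function(genes, up) {
    data.frame(gene = genes, log2fc = ifelse(genes %in% up, 1, 0),
               p_raw = ifelse(genes %in% up, 1e-6, 0.9),
               p_adj = ifelse(genes %in% up, 1e-5, 0.95),
               stringsAsFactors = FALSE)
  }
  g <- letters[1:6]
  p <- derive_panel(mk(g, c("a", "b", "c")), mk(g, c("b", "c", "d")))
  expect_identical(p$genes, c("b", "c"))
  t1 <- mk(g, c("a", "b", "c"))
  expect_identical(derive_panel(t1, t1)$genes, c("a", "b", "c"))
  # enlarging either up-set never shrinks the panel
  bigger <- derive_panel(mk(g, c("a", "b", "c", "e")), mk(g, c("b", "c", "d")))
  expect_true(all(p$genes %in% bigger$genes))
  expect_warning(derive_panel(mk(letters[1:3], "a"), mk(letters[4:6], "d")),
                 "no genes")
})

test_that("panel recovery on the default bulk fixture is exact", {
  f <- fx_bulk()
  de <- fx_bulk_de()
  panel <- derive_panel(de$de_meta, de$de_bom)
  expect_setequal(panel$genes, f$sim$truth$planted_overlap)
  expect_identical(panel$genes, sort(panel$genes))
})

test_that("classify_bone_site matches case-insensitive substrings", {
  x <- c("Bone, left femur", "LUNG", NA, "bone marrow")
  expect_identical(classify_bone_site(x), c(TRUE, FALSE, NA, TRUE))
})
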