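test_that("read_lr_db validates, deduplicates and upper-cases", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("ligand,receptor", "tgfb1,TGFBR1", "TGFB1,tgfbr1", "BMP2,BMPR1B"),
             tf)
  expect_warning(db <- read_lr_db(tf), "duplicate")
  expect_equal(nrow(db), 2)
  expect_true(all(db$ligand == toupper(db$ligand)))

  tf2 <- tempfile(fileext = ".csv")
  write_lr_db(db, tf2)
  db2 <- read_lr_db(tf2)
  expect_identical(db2[, c("ligand", "receptor")], db[, c("ligand", "receptor")])

  tf3 <- tempfile(fileext = ".csv")
  writeLines("gene_a,gene_b\nX,Y", tf3)
  expect_error(read_lr_db(tf3), "columns")
  tf4 <- tempfile(fileext = ".csv")
  writeLines("ligand,receptor", tf4)
  expect_error(read_lr_db(tf4), "empty")
})

test_that("empty database yields zero candidates with a warning", {
  f <- fx_sc()
  db0 <- data.frame(ligand = character(0), receptor = character(0))
  expect_warning(out <- screen_lr(f$expr, f$sim$counts, f$sim$cells,
                                  "fibroblast", "tumor_a", db0), "empty")
  expect_equal(nrow(out), 0)
})

test_that("crafted 4v4 case: exactly the separating pair is admitted", {
  # subgroup A: L1 separates BoM from Other, L2 exchangeable; subgroup B:
  # R1 separates, R2 exchangeable. Expect candidates == {(L1, R1)}.
  cells <- sprintf("c%02d", 1:16)
  ct <- data.frame(
    cell_id = cells,
    subgroup = rep(c("A", "B"), each = 8),
    condition = rep(rep(c("BoM", "Other"), each = 4), 2)
  )
  counts <- matrix(0L, 4, 16, dimnames = list(c("L1", "L2", "R1", "R2"), cells))
  counts["L1", 1:4] <- c(9L, 8L, 7L, 6L)     # A BoM high
  counts["L1", 5:8] <- c(1L, 2L, 0L, 1L)     # A Other low
  counts["L2", 1:8] <- rep(c(3L, 4L), 4)     # exchangeable in A
  counts["R1", 9:12] <- c(9L, 8L, 7L, 6L)
  counts["R1", 13:16] <- c(1L, 0L, 2L, 1L)
  counts["R2", 9:16] <- rep(c(3L, 4L), 4)
  # keep totals equal so lognorm preserves the ordering
  expr <- log1p(counts)
  attr(expr, "normalization") <- "lognorm"
  db <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  out <- screen_lr(expr, counts, ct, "A", "B", db)
  expect_equal(out$ligand[out$passed], "L1")
  expect_equal(out$receptor[out$passed], "R1")
  expect_equal(sum(out$passed), 1)
})

test_that("planted pairs are recovered with high precision on the fixture", {
  f <- fx_sc()
  db <- fx_lr_db()
  out <- screen_lr(f$expr, f$sim$counts, f$sim$cells, "fibroblast", "tumor_a",
                   db)
  truthp <- paste(f$sim$truth$planted_lr_pairs$ligand,
                  f$sim$truth$planted_lr_pairs$receptor)
  got <- paste(out$ligand[out$passed], out$receptor[out$passed])
  expect_true(all(truthp %in% got))            # recall = 1
  expect_gte(mean(got %in% truthp), 0.9)       # precision
  # output pairs always a subset of the database
  expect_true(all(paste(out$ligand, out$receptor) %in%
                    paste(db$ligand, db$receptor)))
})

test_that("screen is monotone in thresholds and symmetric across directions", {
  f <- fx_sc()
  db <- fx_lr_db()
  loose <- screen_lr(f$expr, f$sim$counts, f$sim$cells, "fibroblast", "tumor_a",
                     db, screen_config(alpha = 0.05, min_ratio = 0.1))
  tight <- screen_lr(f$expr, f$sim$counts, f$sim$cells, "fibroblast", "tumor_a",
                     db, screen_config(alpha = 0.01, min_ratio = 0.2))
  key <- function(d) paste(d$ligand[d$passed], d$receptor[d$passed])
  expect_true(all(key(tight) %in% key(loose)))

  ba1 <- screen_lr(f$expr, f$sim$counts, f$sim$cells, "tumor_a", "fibroblast",
                   db)
  invisible(screen_lr(f$expr, f$sim$counts, f$sim$cells, "fibroblast",
                      "tumor_a", db))
  ba2 <- screen_lr(f$expr, f$sim$counts, f$sim$cells, "tumor_a", "fibroblast",
                   db)
  expect_identical(ba1, ba2)                   # no shared state
})

test_that("lr_summary emits dot-profile statistics consistent with dot_profile", {
  f <- fx_sc()
  db <- fx_lr_db()
  out <- screen_lr(f$expr, f$sim$counts, f$sim$cells, "fibroblast", "tumor_a",
                   db)
  expect_equal(nrow(lr_summary(out[0, ], f$expr, f$sim$counts, f$sim$cells)), 0)

  one <- out[out$passed, ][1, ]
  one$passed <- TRUE
  sm <- lr_summary(one, f$expr, f$sim$counts, f$sim$cells)
  expect_equal(nrow(sm), 4)                    # 2 genes x 2 conditions

  # ratios must match a direct dot_profile recomputation per subgroup
  for (i in seq_len(nrow(sm))) {
    sub <- f$sim$cells[f$sim$cells$subgroup == sm$subgroup[i], ]
    fake <- data.frame(cell_id = sub$cell_id, subgroup = sub$condition)
    dp <- dot_profile(f$expr[, sub$cell_id], f$sim$counts[, sub$cell_id],
                      fake, sm$gene[i])
    expect_equal(sm$pos_ratio[i],
                 dp$pos_ratio[dp$subgroup == sm$condition[i]],
                 tolerance = 1e-12)
  }
})
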