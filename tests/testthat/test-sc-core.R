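test_that("count matrices round-trip through MTX and TSV", {
  f <- fx_sc()
  sub <- f$sim$counts[1:50, 1:40]
  d <- file.path(tempdir(), "mtx_rt")
  write_counts_mtx(sub, d)
  back <- read_counts(d, "mtx_triplet")
  expect_identical(as.matrix(back), as.matrix(sub))

  tf <- tempfile(fileext = ".tsv")
  write_counts_tsv(sub, tf)
  back2 <- read_counts(tf, "tsv")
  expect_equal(unname(back2), unname(as.matrix(sub)), ignore_attr = TRUE)
  expect_identical(dimnames(back2), dimnames(sub))
})

test_that("count reader validates dimensions and degenerate input", {
  f <- fx_sc()
  d <- file.path(tempdir(), "mtx_bad")
  write_counts_mtx(f$sim$counts[1:10, 1:5], d)
  writeLines(sprintf("gene%02d", 1:11), file.path(d, "genes.tsv"))
  expect_error(read_counts(d, "mtx_triplet"), "11 entries")

  tf <- tempfile(fileext = ".tsv")
  writeLines("gene", tf)   # header only, zero observation columns
  expect_error(read_counts(tf, "tsv"), "zero")

  # duplicate gene symbols get suffixed
  m <- matrix(1:4, 2, 2, dimnames = list(c("TP53", "TP53"), c("c1", "c2")))
  tf2 <- tempfile(fileext = ".tsv")
  write_counts_tsv(matrix(1:4, 2, 2,
                          dimnames = list(c("a", "b"), c("c1", "c2"))), tf2)
  dt <- read.delim(tf2)
  dt$gene <- c("TP53", "TP53")
  write.table(dt, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out <- read_counts(tf2, "tsv"), "duplicate")
  expect_identical(rownames(out), c("TP53", "TP53.1"))
})

test_that("lognormalize computes ln(1 + scale*count/total) and drops empty cells", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  e <- lognormalize(m)
  expect_equal(e[, 1], c(g1 = log(10001), g2 = 0), tolerance = 1e-12)

  f <- fx_sc()
  sub <- as.matrix(f$sim$counts[1:30, 1:20])
  e1 <- lognormalize(sub)
  sub2 <- sub; sub2[, 3] <- sub2[, 3] * 2L       # per-cell scale invariance
  e2 <- lognormalize(sub2)
  expect_equal(e1[, 3], e2[, 3], tolerance = 1e-12)
  allzero_gene <- rownames(sub)[rowSums(sub) == 0]
  expect_true(all(e1[allzero_gene, ] == 0))

  sub3 <- sub; sub3[, 5] <- 0L
  expect_message(e3 <- lognormalize(sub3), "zero total")
  expect_equal(ncol(e3), 19)

  # sparse and dense paths agree
  sp <- lognormalize(Matrix::Matrix(sub, sparse = TRUE))
  expect_equal(as.matrix(sp), e1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("dot_profile: hand z-scores, zero-variance rule, pos ratios", {
  # 3 subgroups x 5 cells, constant expression per subgroup
  expr <- rbind(gA = rep(c(1, 2, 3), each = 5),
                gB = rep(2, 15),
                gC = rep(c(0, 1, 0), each = 5))
  colnames(expr) <- sprintf("c%02d", 1:15)
  counts <- matrix(0L, 3, 15, dimnames = dimnames(expr))
  counts[expr > 0] <- 1L
  counts["gA", 1:2] <- 3L; counts["gA", 3:5] <- 0L  # 2/5 positive in sg1
  ct <- data.frame(cell_id = colnames(expr),
                   subgroup = rep(c("s1", "s2", "s3"), each = 5))
  dp <- dot_profile(expr, counts, ct, c("gA", "gB", "gC"))
  zA <- dp$z_expr[dp$gene == "gA"][order(dp$subgroup[dp$gene == "gA"])]
  expect_equal(zA, c(-1, 0, 1), tolerance = 1e-12)
  expect_true(all(dp$z_expr[dp$gene == "gB"] == 0))
  expect_equal(dp$pos_ratio[dp$gene == "gA" & dp$subgroup == "s1"], 0.4)
  expect_warning(dot_profile(expr, counts, ct, c("gA", "nope")), "absent")
})

test_that("dot_profile z rows have mean 0 and sample SD 1 on the fixture", {
  f <- fx_sc()
  genes <- rownames(f$sim$counts)[1:40]
  dp <- dot_profile(f$expr, f$sim$counts, f$sim$cells, genes)
  for (g in genes) {
    z <- dp$z_expr[dp$gene == g]
    if (all(z == 0)) next
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
})

test_that("find_markers: separation, exchangeability, permutation invariance", {
  set.seed(77)
  n1 <- 50; n0 <- 500
  counts <- rbind(
    sep = c(rpois(n1, 8), rep(0L, n0)),                  # only in s
    flat = rpois(n1 + n0, 3),
    house = rpois(n1 + n0, 5) + 1L                       # keeps totals positive
  )
  colnames(counts) <- sprintf("c%03d", seq_len(n1 + n0))
  storage.mode(counts) <- "integer"
  ct <- data.frame(cell_id = colnames(counts),
                   subgroup = rep(c("s", paste0("r", 1:5)), c(n1, rep(100, 5))))
  expr <- lognormalize(counts)
  mk <- find_markers(expr, counts, ct)
  sep_calls <- mk$subgroup[mk$gene == "sep" & mk$is_marker]
  expect_identical(sep_calls, "s")
  expect_false(any(mk$is_marker[mk$gene == "flat"]))

  perm <- sample(ncol(counts))
  mk2 <- find_markers(expr[, perm], counts[, perm], ct)
  expect_equal(mk[order(mk$subgroup, mk$gene), ],
               mk2[order(mk2$subgroup, mk2$gene), ], ignore_attr = TRUE)
})

test_that("planted markers are recovered for their subgroup and no other", {
  f <- fx_sc()
  mk <- find_markers(f$expr, f$sim$counts, f$sim$cells)
  pm <- f$sim$truth$planted_markers
  for (sg in names(pm)) {
    called <- mk$gene[mk$subgroup == sg & mk$is_marker]
    expect_true(all(pm[[sg]] %in% called))
    for (other in setdiff(names(pm), sg))
      expect_length(intersect(pm[[sg]],
                              mk$gene[mk$subgroup == other & mk$is_marker]), 0)
  }
})

test_that("panel_marker_overlap performs per-subgroup set intersection", {
  mk <- data.frame(subgroup = rep(c("s1", "s2"), each = 3),
                   gene = c("a", "b", "c", "c", "d", "e"),
                   is_marker = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  ov <- panel_marker_overlap(c("b", "c", "d", "z"), mk)
  expect_identical(ov$s1, "b")
  expect_identical(ov$s2, c("c", "d"))
  ov0 <- panel_marker_overlap(c("x", "y"), mk)
  expect_true(all(lengths(ov0) == 0))

  # fixture: overlap sets equal panel intersected with called markers
  f <- fx_sc()
  mkx <- find_markers(f$expr, f$sim$counts, f$sim$cells)
  panel <- f$sim$truth$planted_markers$fibroblast
  ovf <- panel_marker_overlap(panel, mkx)
  for (sg in names(ovf))
    expect_setequal(ovf[[sg]],
                    intersect(panel, mkx$gene[mkx$subgroup == sg & mkx$is_marker]))
})
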