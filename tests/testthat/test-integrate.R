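# Integration layer: Venn enumeration, quadrant grid, PCA oracle,
# Pearson closed form, report arithmetic.

test_that("venn3 equals the membership-enumeration oracle", {
  v <- venn3(c("a", "b"), c("b", "c"), c("c", "d"))
  got <- setNames(v$count, v$region)
  expect_equal(got[["ABC"]], 0)
  expect_equal(got[["AB"]], 1)   # b
  expect_equal(got[["BC"]], 1)   # c
  expect_equal(got[["AC"]], 0)
  expect_equal(got[["A_only"]], 1)
  expect_equal(got[["C_only"]], 1)
  expect_equal(attr(v, "union"), 4)
  # identical sets concentrate in the center
  v2 <- venn3(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(setNames(v2$count, v2$region)[["ABC"]], 5)
  expect_equal(sum(v2$count), 5)
  # one empty set zeroes its four regions
  v3 <- venn3(character(0), c("x", "y"), c("y", "z"))
  g3 <- setNames(v3$count, v3$region)
  expect_true(all(g3[c("A_only", "AB", "AC", "ABC")] == 0))
  # randomized property
  set.seed(14)
  for (rep in 1:25) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    c <- sample(letters, sample(0:15, 1))
    v <- venn3(a, b, c)
    expect_equal(setNames(v$count, v$region), oracle_venn3(a, b, c))
    expect_equal(sum(v$count), length(union(union(a, b), c)))
  }
})

test_that("quadrant classification is exhaustive and mutually exclusive", {
  states <- c("up", "ns", "down")
  grid <- expand.grid(ed = states, ex = states, stringsAsFactors = FALSE)
  editing <- data.frame(feature = paste0("g", 1:9),
                        log2FC = ifelse(grid$ed == "up", 2,
                                        ifelse(grid$ed == "down", -2, 0.1)),
                        sig_up = grid$ed == "up",
                        sig_down = grid$ed == "down")
  expression <- data.frame(feature = paste0("g", 1:9),
                           log2FC = ifelse(grid$ex == "up", 2,
                                           ifelse(grid$ex == "down", -2,
                                                  0.1)),
                           sig_up = grid$ex == "up",
                           sig_down = grid$ex == "down")
  q <- quadrant_classify(editing, expression)
  expect_equal(nrow(q), 9)
  expect_equal(length(unique(q$quadrant)), 9)
  both <- q$quadrant[q$color == "both"]
  expect_equal(length(both), 4)
  expect_equal(q$color[q$quadrant == "editing_ns:expression_ns"], "neither")
  expect_equal(q$color[q$quadrant == "editing_up:expression_up"], "both")
  # a gene absent from one table lands in the ns state on that axis
  q2 <- quadrant_classify(editing[1:3, ], expression)
  expect_true(all(q2$editing_state[!q2$gene %in% editing$feature[1:3]] ==
                    "ns"))
})

test_that("editing PCA matches an eigen-decomposition oracle up to sign", {
  set.seed(15)
  freq <- matrix(runif(120), nrow = 20,
                 dimnames = list(paste0("s", 1:20), paste0("smp", 1:6)))
  p <- editing_pca(freq)
  xc <- freq - rowMeans(freq)
  ev <- eigen(crossprod(xc) / 1)   # samples x samples Gram matrix
  want_pct <- 100 * ev$values / sum(ev$values)
  expect_equal(p$var_pct[1:5], want_pct[1:5], tolerance = 1e-8)
  expect_true(all(diff(p$var_pct) <= 1e-12))
  expect_lte(sum(p$var_pct), 100 + 1e-9)
  for (k in 1:3) {
    expect_equal(abs(p$coords[, k]), abs(ev$vectors[, k] *
                                           sqrt(ev$values[k])),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PCA handles structure, missing values and degenerate input", {
  # two duplicated sample groups separate on PC1
  base <- runif(30)
  freq <- cbind(base, base, base + 0.3, base + 0.3)
  rownames(freq) <- paste0("s", 1:30)
  colnames(freq) <- paste0("smp", 1:4)
  p <- editing_pca(freq)
  expect_gt(p$var_pct[1], p$var_pct[2] - 1e-12)
  expect_lt(abs(diff(p$coords[1:2, 1])), 1e-9)
  expect_gt(abs(p$coords[1, 1] - p$coords[3, 1]), 0.1)
  # identical samples: zero variance everywhere
  same <- cbind(base, base, base); colnames(same) <- paste0("x", 1:3)
  rownames(same) <- paste0("s", 1:30)
  p0 <- editing_pca(same)
  expect_true(all(p0$var_pct < 1e-9))
  # all-missing site dropped and reported; mean imputation keeps samples
  fm <- freq
  fm[3, ] <- NA; fm[5, 2] <- NA
  p1 <- editing_pca(fm)
  expect_equal(p1$dropped, "s3")
  expect_equal(nrow(p1$coords), 4)
  # site order must not matter
  p2 <- editing_pca(fm[sample(nrow(fm)), ])
  expect_equal(abs(p2$coords), abs(p1$coords), tolerance = 1e-9)
})

test_that("MAF-expression correlation matches the closed-form oracle", {
  sheet <- data.frame(sample = paste0("s", 1:6), path = "x",
                      condition = rep(c("control", "treated"), each = 3),
                      replicate = rep(1:3, 2))
  set.seed(16)
  maf <- matrix(runif(12, 0.2, 0.8), nrow = 2)
  ann <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "C",
                    alt = "T", gene_id = "gX")
  for (j in 1:6) {
    ann[[paste0("s", j, "_ref")]] <- 10L
    ann[[paste0("s", j, "_alt")]] <- 5L
    ann[[paste0("s", j, "_freq")]] <- maf[, j]
  }
  expr <- matrix(runif(6, 10, 100), nrow = 1,
                 dimnames = list("gEnz", paste0("s", 1:6)))
  got <- maf_expression_correlation("gX", ann, "gEnz", expr, sheet)
  orc <- oracle_pearson(colMeans(maf), expr[1, ])
  expect_equal(got$r, orc$r, tolerance = 1e-12)
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  expect_equal(got$n, 6)
  # colinear vectors give |R| = 1
  ann2 <- ann
  for (j in 1:6) ann2[[paste0("s", j, "_freq")]] <- rep(j / 10, 2)
  expr2 <- matrix(2 * (1:6) / 10 + 1, nrow = 1,
                  dimnames = list("gEnz", paste0("s", 1:6)))
  expect_equal(maf_expression_correlation("gX", ann2, "gEnz", expr2,
                                          sheet)$r, 1, tolerance = 1e-9)
  expr3 <- matrix(-2 * (1:6) / 10 + 1, nrow = 1,
                  dimnames = list("gEnz", paste0("s", 1:6)))
  expect_equal(maf_expression_correlation("gX", ann2, "gEnz", expr3,
                                          sheet)$r, -1, tolerance = 1e-9)
  # degenerate inputs error out
  expect_error(maf_expression_correlation("gX", ann2, "gEnz",
                                          matrix(5, 1, 6,
                                                 dimnames = list(
                                                   "gEnz",
                                                   paste0("s", 1:6))),
                                          sheet), "zero variance")
  expect_error(maf_expression_correlation("gMissing", ann, "gEnz", expr,
                                          sheet), "no retained")
})

test_that("cohort report group totals are sums of per-sample counts", {
  expect_equal(group_total(c(10, 20, 30)), 60)
  ck <- small_called()
  ann <- annotate_sites(ck$called$sites, ck$study$models, ck$genome)
  sc <- editing_counts(ann, ck$sheet)
  dre <- de_call(nb_differential(sc, ck$sheet$condition), 0.05, 0)
  rep <- cohort_report(ann, ck$sheet, dre$table)
  per <- unlist(rep$per_sample_loci)
  ctrl <- ck$sheet$sample[ck$sheet$condition == "control"]
  trt <- ck$sheet$sample[ck$sheet$condition == "treated"]
  expect_equal(rep$group_totals$control, sum(per[ctrl]))
  expect_equal(rep$group_totals$treated, sum(per[trt]))
  ds <- rep$differential_sites
  expect_equal(ds$n_significant, ds$n_up + ds$n_down)
  # both-direction host-gene accounting from set logic
  gm <- setNames(ann$gene_id, site_key(ann))
  gup <- unique(na.omit(gm[dre$up])); gdn <- unique(na.omit(gm[dre$down]))
  expect_equal(ds$genes_both_directions, length(intersect(gup, gdn)))
})
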