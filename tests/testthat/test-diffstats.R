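# NB differential engine: aggregation, normalization identities,
# dispersion limits, Wald vs closed forms and an external GLM, BH, TPM.

test_that("gene aggregation equals a group-by-sum oracle", {
  set.seed(3)
  m <- matrix(rpois(60, 8), nrow = 10,
              dimnames = list(paste0("s", 1:10), paste0("c", 1:6)))
  genes <- c("g1", "g1", NA, "g2", "g2", "g2", "g3", NA, "g1", "g3")
  agg <- aggregate_gene(m, genes)
  manual <- t(sapply(c("g1", "g2", "g3"), function(g)
    colSums(m[which(!is.na(genes) & genes == g), , drop = FALSE])))
  expect_equal(agg, manual, ignore_attr = TRUE)
  expect_equal(rownames(agg), c("g1", "g2", "g3"))
  # single-site gene keeps its row unchanged
  expect_equal(unname(agg["g3", ]), unname(colSums(m[c(7, 10), ])))
})

test_that("size factors satisfy the median-of-ratios definition", {
  # identical columns -> all ones
  m <- matrix(rep(c(5, 9, 13), 4), nrow = 3)
  expect_equal(size_factors(m), rep(1, 4))
  # doubling one column doubles its factor on an all-positive matrix
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  sf <- size_factors(m2)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
  # random all-positive matrix: direct formula oracle
  set.seed(11)
  r <- matrix(rpois(200, 30) + 1, nrow = 40)
  sf <- size_factors(r)
  logg <- rowMeans(log(r))
  oracle <- apply(r, 2, function(col) exp(median(log(col) - logg)))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(sf, oracle, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # all-zero-containing rows only: fallback with warning
  z <- matrix(c(0, 5, 3, 0), nrow = 2)
  expect_warning(size_factors(z), "total-count")
})

test_that("dispersion estimates respect limit cases", {
  cond <- rep(c("control", "treated"), each = 25)
  set.seed(4)
  pois <- matrix(rpois(500 * 50, 40), nrow = 500)
  a_pois <- estimate_dispersion(pois, rep(1, 50), cond)
  expect_lt(median(a_pois), 0.01)
  nb <- matrix(rnbinom(500 * 50, mu = 40, size = 10), nrow = 500)
  a_nb <- estimate_dispersion(nb, rep(1, 50), cond)
  expect_gt(median(a_nb), 0.05)
  expect_lt(median(a_nb), 0.2)
  # constant rows carry zero dispersion
  const <- matrix(7, nrow = 5, ncol = 50)
  expect_true(all(estimate_dispersion(const, rep(1, 50), cond,
                                      shrink = 0) == 0))
})

test_that("Wald z matches the two-sample Poisson log-ratio closed form", {
  set.seed(6)
  y <- matrix(rpois(5 * 6, 200), nrow = 5)
  cond <- rep(c("control", "treated"), each = 3)
  res <- nb_wald_test(y, rep(1, 6), rep(0, 5), cond)
  for (i in 1:5) {
    sc <- sum(y[i, 1:3]); st <- sum(y[i, 4:6])
    z <- log(st / sc) / sqrt(1 / sc + 1 / st)
    expect_equal(res$stat[i], z, tolerance = 1e-6)
    expect_equal(res$log2FC[i], log2(st / sc), tolerance = 1e-9)
  }
})

test_that("NB fit agrees with an external GLM on dispersed counts", {
  skip_if_not_installed("MASS")
  set.seed(7)
  cond <- rep(c("control", "treated"), each = 3)
  sf <- c(0.8, 1.0, 1.2, 0.9, 1.1, 1.05)
  alpha <- 0.1
  y <- rnbinom(6, mu = sf * c(30, 30, 30, 90, 90, 90), size = 1 / alpha)
  y <- matrix(y, nrow = 1)
  res <- nb_wald_test(y, sf, alpha, cond)
  fit <- suppressWarnings(stats::glm(
    y[1, ] ~ factor(cond, levels = c("control", "treated")),
    family = MASS::negative.binomial(theta = 1 / alpha),
    offset = log(sf)))
  co <- summary(fit, dispersion = 1)$coefficients
  expect_equal(res$log2FC[1], co[2, 1] / log(2), tolerance = 1e-4)
  expect_equal(res$se[1], co[2, 2] / log(2), tolerance = 0.02)
})

test_that("all-zero features are excluded from testing and correction", {
  y <- rbind(c(0, 0, 0, 0, 0, 0), c(5, 6, 7, 8, 9, 10))
  cond <- rep(c("control", "treated"), each = 3)
  res <- nb_wald_test(y, rep(1, 6), c(0, 0), cond)
  expect_true(is.na(res$pvalue[1]))
  expect_true(is.na(res$padj[1]))
  expect_false(is.na(res$pvalue[2]))
  expect_equal(res$padj[2], res$pvalue[2])  # m = 1 non-NA test
})

test_that("single-condition designs are refused", {
  y <- matrix(rpois(12, 10), nrow = 2)
  expect_error(nb_wald_test(y, rep(1, 6), c(0, 0), rep("control", 6)),
               "two conditions")
})

test_that("BH adjustment equals the hand-computed step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  p <- c(runif(50), NA, NA, runif(10))
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_true(all(bh_adjust(p) >= p, na.rm = TRUE))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("TPM satisfies its normalization identities", {
  cnt <- matrix(c(10, 10, 40, 20), nrow = 2)
  # equal counts, equal lengths -> half a million each
  expect_equal(tpm(matrix(c(5, 5), ncol = 1), c(100, 100))[, 1],
               c(5e5, 5e5))
  # doubling a length halves its rate share
  t1 <- tpm(cnt, c(100, 200)); t2 <- tpm(cnt, c(200, 200))
  expect_equal(t2[1, 1] / t2[2, 1],
               (t1[1, 1] / t1[2, 1]) / 2, tolerance = 1e-12)
  set.seed(9)
  r <- matrix(rpois(300, 50), nrow = 50)
  tp <- tpm(r, sample(200:2000, 50))
  expect_true(all(abs(colSums(tp) - 1e6) < 1e6 * 1e-6))
  expect_error(tpm(cnt, c(0, 100)), "positive")
})

test_that("de_call applies the fold-change gate only when asked", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    log2FC = c(2, 1.0, -2, 0.5),
                    padj = c(0.01, 0.01, 0.01, 0.2))
  gated <- de_call(res, fdr = 0.05, lfc = 1.2)
  expect_equal(gated$up, "a")
  expect_equal(gated$down, "c")
  ungated <- de_call(res, fdr = 0.05, lfc = 0)
  expect_setequal(c(ungated$up, ungated$down), c("a", "b", "c"))
})

test_that("log2FC is invariant to column scaling (scale invariance)", {
  set.seed(10)
  m <- matrix(rpois(600, 60) + 1, nrow = 100)
  cond <- rep(c("control", "treated"), each = 3)
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  sf1 <- size_factors(m); sf2 <- size_factors(m2)
  # factors keep geometric mean 1, so the scaled column's factor rises by
  # c relative to every other column
  expect_equal(exp(mean(log(sf1))), 1, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf2))), 1, tolerance = 1e-12)
  expect_equal((sf2[3] / sf2[1]) / (sf1[3] / sf1[1]), 4, tolerance = 1e-9)
  # normalized counts, and hence the naive fold change, are exactly
  # invariant; the GLM coefficient reweights the 4x deeper sample and is
  # only approximately so (inherent to NB GLMs with offsets)
  f1 <- nb_differential(m, cond)
  f2 <- nb_differential(m2, cond)
  expect_equal(f2$log2FC_naive, f1$log2FC_naive, tolerance = 1e-9)
  expect_lt(mean(abs(f1$log2FC - f2$log2FC)), 0.05)
  # and neither version manufactures significance on null data
  expect_equal(length(c(de_call(f2, 0.05, 0)$up, de_call(f2, 0.05, 0)$down)),
               length(c(de_call(f1, 0.05, 0)$up, de_call(f1, 0.05, 0)$down)),
               tolerance = 3)
})

test_that("gene with one site tests identically to its site row", {
  ck <- small_called()
  sc <- editing_counts(ck$called$sites, ck$sheet)
  # map every site to its own gene: aggregation must be the identity and
  # the differential results must coincide row for row
  solo_map <- paste0("solo_", seq_len(nrow(sc)))
  gc <- aggregate_gene(sc, solo_map)
  expect_equal(unname(gc[solo_map, ]), unname(sc))
  r_site <- nb_differential(sc, ck$sheet$condition)
  r_gene <- nb_differential(gc[solo_map, ], ck$sheet$condition)
  expect_equal(r_gene$log2FC, r_site$log2FC, tolerance = 1e-12)
  expect_equal(r_gene$pvalue, r_site$pvalue, tolerance = 1e-12)
})

test_that("engine log2FC tracks DESeq2 on a shared matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  mu <- rlnorm(300, log(50), 1)
  fc <- sample(c(1, 1, 1, 3, 1 / 3), 300, replace = TRUE)
  cnt <- t(sapply(seq_len(300), function(i)
    c(rnbinom(3, mu = mu[i], size = 50),
      rnbinom(3, mu = mu[i] * fc[i], size = 50))))
  cond <- rep(c("control", "treated"), each = 3)
  mine <- nb_differential(cnt, cond)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, data.frame(condition = factor(cond,
                                       levels = c("control", "treated"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  ok <- !is.na(mine$log2FC) & !is.na(ref$log2FoldChange) & mu > 20
  expect_gt(cor(mine$log2FC[ok], ref$log2FoldChange[ok]), 0.95)
})
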