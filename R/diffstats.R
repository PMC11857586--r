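# Negative-binomial differential engine, applied three ways: site-level
# editing counts, gene-aggregated editing counts, gene expression.
#
# The model is the classic NB count GLM with log link and per-sample
# offsets: counts_ij ~ NB(mu_ij = s_j * q_{g(i), cond(j)}, alpha_i), with
# median-of-ratios size factors, per-feature method-of-moments dispersion
# shrunk toward a mean-dispersion trend, and a Wald test on the condition
# log-ratio using observed Fisher information. Numerical equivalence with
# any external tool is not a goal; the contract is statistical behaviour
# (null calibration, FDR control, power), which the test suite measures.

#' Site-level editing-read count matrix
#'
#' Entry = alternative-allele read count (editing reads) per site per
#' sample.
#' @param sites site table from [merge_cohort()].
#' @param sample_sheet cohort sample sheet.
#' @return integer matrix (sites x samples) with site keys as rownames.
#' @export
editing_counts <- function(sites, sample_sheet) {
  samples <- sample_sheet$sample
  if (!nrow(sites)) {
    return(matrix(integer(0), nrow = 0, ncol = length(samples),
                  dimnames = list(NULL, samples)))
  }
  m <- as.matrix(sites[, paste0(samples, "_alt"), drop = FALSE])
  colnames(m) <- samples
  rownames(m) <- site_key(sites)
  storage.mode(m) <- "integer"
  m
}

#' Aggregate site counts to the gene level
#'
#' Gene row = column-wise sum of its sites' rows; sites with no host gene
#' (intergenic) are dropped.
#' @param site_counts matrix from [editing_counts()].
#' @param site_gene character vector of host gene ids per row (NA for
#'   intergenic).
#' @return integer matrix (genes x samples).
#' @export
aggregate_gene <- function(site_counts, site_gene) {
  stopifnot(nrow(site_counts) == length(site_gene))
  keep <- !is.na(site_gene) & site_gene != ""
  sc <- site_counts[keep, , drop = FALSE]
  gid <- site_gene[keep]
  if (!nrow(sc)) {
    return(matrix(integer(0), nrow = 0, ncol = ncol(site_counts),
                  dimnames = list(NULL, colnames(site_counts))))
  }
  out <- rowsum(sc, group = gid, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Median-of-ratios size factors
#'
#' factor_j = median over features positive in all samples of
#' count_ij / geometric-mean_i(count), rescaled to geometric mean 1. When
#' no feature is positive in every sample, falls back to total-count
#' ratios with a warning.
#' @param counts features x samples count matrix.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature positive in all samples; using total-count ratios")
    sf <- colSums(counts)
    if (any(sf == 0)) stopf("cannot normalize: a sample has zero counts")
    return(sf / geomean(sf))
  }
  sub <- counts[pos, , drop = FALSE]
  logg <- rowMeans(log(sub))
  sf <- apply(sub, 2, function(col) exp(median(log(col) - logg)))
  sf / geomean(sf)
}

# Constrained, iteratively reweighted fit of the parametric dispersion
# trend alpha(mu) = a0 + a1/mu (a0, a1 >= 0). Weights follow the sampling
# variance of the moment estimates, var(raw_i) ~ (1/mu_i + alpha_i)^2;
# the nonnegativity constraint is enforced jointly (interior solution or
# the better of the two boundary fits), never by clamping coefficients
# independently, which would corrupt the fitted line whenever the
# unconstrained intercept goes negative.
.fit_dispersion_trend <- function(raw, mu) {
  use <- mu > 0
  if (sum(use) < 10) {
    return(c(a0 = max(0, if (any(use)) median(raw[use]) else 0), a1 = 0))
  }
  x <- 1 / mu[use]; y <- raw[use]
  a <- c(max(0, mean(y)), 0)
  for (it in 1:3) {
    w <- 1 / (x + a[1] + a[2] * x + 1e-3)^2
    W <- sum(w); Wx <- sum(w * x); Wxx <- sum(w * x^2)
    Wy <- sum(w * y); Wxy <- sum(w * x * y)
    det <- W * Wxx - Wx^2
    cand <- list()
    if (det > 0)
      cand$interior <- c((Wxx * Wy - Wx * Wxy) / det,
                         (W * Wxy - Wx * Wy) / det)
    cand$flat <- c(max(0, Wy / W), 0)
    cand$prop <- c(0, max(0, Wxy / Wxx))
    sse <- vapply(cand, function(ab) {
      if (any(ab < 0)) return(Inf)
      sum(w * (y - ab[1] - ab[2] * x)^2)
    }, numeric(1))
    a <- cand[[which.min(sse)]]
  }
  c(a0 = a[1], a1 = a[2])
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per feature: normalized counts are pooled within conditions; the raw
#' moment estimate is (s2 - mu) / mu^2 with s2 the pooled
#' within-condition variance (kept untruncated so the fit stays
#' unbiased). A parametric mean-dispersion trend a0 + a1/mu is fitted by
#' constrained, iteratively reweighted least squares, and each feature's
#' dispersion is the raw estimate shrunk toward the trend, truncated to
#' `[0, 20]` at the very end. The default shrinkage weight is
#' prior_df / (prior_df + df) with prior_df = 10 and df the
#' within-condition residual degrees of freedom — the usual
#' empirical-Bayes moderation strength for small designs (weight 0.71
#' for 3 vs 3).
#'
#' @param counts features x samples count matrix.
#' @param sf size factors from [size_factors()].
#' @param condition factor/character of per-sample conditions.
#' @param shrink weight on the trend (0 = raw, 1 = pure trend); NULL
#'   (default) uses the prior-df rule above.
#' @param prior_df prior degrees of freedom behind the default weight.
#' @return numeric vector of per-feature dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, sf, condition, shrink = NULL,
                                prior_df = 10) {
  counts <- as.matrix(counts)
  if (!nrow(counts)) return(numeric(0))
  k <- sweep(counts, 2, sf, "/")
  conds <- unique(condition)
  stopifnot(all(table(condition) >= 2))
  ss <- 0; df <- 0
  for (cc in conds) {
    sub <- k[, condition == cc, drop = FALSE]
    n_c <- ncol(sub)
    mu_c <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu_c)^2)
    df <- df + (n_c - 1)
  }
  s2 <- ss / df
  mu <- rowMeans(k)
  if (is.null(shrink)) shrink <- prior_df / (prior_df + df)
  raw <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
  a <- .fit_dispersion_trend(raw, mu)
  trend <- ifelse(mu > 0, a[["a0"]] + a[["a1"]] / mu, a[["a0"]])
  alpha <- (1 - shrink) * raw + shrink * trend
  pmin(pmax(alpha, 0), 20)
}

# One-group NB mean MLE on the log scale with offsets (Newton); returns
# list(q, info) with info the observed Fisher information for log(q).
.nb_group_fit <- function(y, sf, alpha) {
  tot <- sum(y)
  if (tot == 0) return(list(q = 0, info = 0))
  q <- tot / sum(sf)
  b <- log(q)
  for (it in 1:50) {
    mu <- sf * exp(b)
    w <- 1 + alpha * mu
    score <- sum((y - mu) / w)
    # derivative of score wrt b
    d <- -sum(mu * (1 + alpha * y) / w^2)
    if (abs(d) < 1e-12) break
    step <- score / d
    b <- b - step
    if (abs(step) < 1e-10) break
  }
  mu <- sf * exp(b)
  list(q = exp(b), info = sum(mu / (1 + alpha * mu)))
}

#' Per-feature NB Wald test between two conditions
#'
#' Fits per-condition means by maximum likelihood with fixed dispersion
#' and size-factor offsets; reports the treated/control log2 fold change,
#' its standard error from observed Fisher information, the Wald
#' statistic and a two-sided normal p-value. All-zero features get NA and
#' are excluded from multiplicity correction. When one condition has zero
#' counts everywhere, its mean is replaced by a half-count continuity
#' value for the fold change and test (flagged in `zero_group`).
#'
#' @param counts features x samples count matrix.
#' @param sf size factors.
#' @param dispersions per-feature alpha from [estimate_dispersion()].
#' @param condition per-sample condition labels ("control"/"treated").
#' @return data frame: feature, baseMean, log2FC, se (log2 scale), stat,
#'   pvalue, padj, zero_group.
#' @export
nb_wald_test <- function(counts, sf, dispersions, condition) {
  counts <- as.matrix(counts)
  conds <- unique(condition)
  if (length(conds) != 2)
    stopf("need exactly two conditions, got %d", length(conds))
  if (!all(c("control", "treated") %in% conds))
    stopf("conditions must be 'control' and 'treated'")
  jc <- condition == "control"
  jt <- condition == "treated"
  n <- nrow(counts)
  log2fc <- se <- stat <- pv <- rep(NA_real_, n)
  zero_group <- rep(FALSE, n)
  knorm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(knorm)
  # naive estimate from normalized counts: the plain ratio of group means
  # is exactly invariant to library scaling; the 0.5 pseudocount enters
  # only for zero-mean groups, where the ratio is otherwise undefined
  m_t <- rowMeans(knorm[, jt, drop = FALSE])
  m_c <- rowMeans(knorm[, jc, drop = FALSE])
  naive <- ifelse(m_t > 0 & m_c > 0, log2(m_t / m_c),
                  log2((m_t + 0.5) / (m_c + 0.5)))
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    a <- dispersions[i]
    fc <- .nb_group_fit(y[jc], sf[jc], a)
    ft <- .nb_group_fit(y[jt], sf[jt], a)
    qc <- fc$q; qt <- ft$q
    ic <- fc$info; it <- ft$info
    if (qc == 0) {
      zero_group[i] <- TRUE
      qc <- 0.5 / sum(sf[jc])
      mu <- sf[jc] * qc
      ic <- sum(mu / (1 + a * mu))
    }
    if (qt == 0) {
      zero_group[i] <- TRUE
      qt <- 0.5 / sum(sf[jt])
      mu <- sf[jt] * qt
      it <- sum(mu / (1 + a * mu))
    }
    beta <- log(qt / qc)
    v <- 1 / ic + 1 / it
    log2fc[i] <- beta / log(2)
    se[i] <- sqrt(v) / log(2)
    stat[i] <- beta / sqrt(v)
    pv[i] <- 2 * pnorm(-abs(stat[i]))
  }
  data.frame(feature = rownames(counts) %||% as.character(seq_len(n)),
             baseMean = base_mean, log2FC = log2fc,
             log2FC_naive = naive, se = se, stat = stat,
             pvalue = pv, padj = bh_adjust(pv), zero_group = zero_group,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment, NA-aware
#'
#' Standard step-up with monotonicity; NAs are propagated and not counted
#' in the number of tests.
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Transcripts-per-million from gene counts and lengths
#'
#' rate_i = count_i / length_i; TPM_i = 1e6 * rate_i / sum(rate). Each
#' sample's column sums to 1e6 (when the sample has any reads).
#' @param counts genes x samples count matrix.
#' @param lengths per-gene length in bases (merged exonic length).
#' @return numeric matrix of TPM values.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stopf("gene lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) warning("sample(s) with zero counts produce NaN TPM")
  sweep(rate, 2, denom, "/") * 1e6
}

#' Significance calls from a differential result table
#'
#' Expression convention: up = padj < fdr & log2FC > lfc, down likewise
#' below -lfc. Editing-level analyses use the padj-only rule, exposed as
#' `lfc = 0`.
#' @param res result table from [nb_wald_test()].
#' @param fdr adjusted-p threshold.
#' @param lfc absolute log2-fold-change gate (0 disables the gate).
#' @return list with `up`, `down` (feature id vectors) and logical
#'   columns `sig_up`, `sig_down` bound onto a copy of `res`.
#' @export
de_call <- function(res, fdr = 0.05, lfc = 0) {
  ok <- !is.na(res$padj) & !is.na(res$log2FC)
  up <- ok & res$padj < fdr & res$log2FC > lfc
  down <- ok & res$padj < fdr & res$log2FC < -lfc
  res$sig_up <- up
  res$sig_down <- down
  list(up = res$feature[up], down = res$feature[down], table = res)
}

#' One-call NB differential analysis
#'
#' Convenience wrapper: size factors, dispersion, Wald test.
#' @param counts features x samples count matrix.
#' @param condition per-sample condition labels.
#' @param shrink dispersion shrinkage weight (NULL = prior-df default).
#' @return result table from [nb_wald_test()].
#' @export
nb_differential <- function(counts, condition, shrink = NULL) {
  counts <- as.matrix(counts)
  if (!nrow(counts)) {
    return(data.frame(feature = character(), baseMean = numeric(),
                      log2FC = numeric(), se = numeric(), stat = numeric(),
                      pvalue = numeric(), padj = numeric(),
                      zero_group = logical(), stringsAsFactors = FALSE))
  }
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, condition, shrink = shrink)
  nb_wald_test(counts, sf, disp, condition)
}

#' Merged exonic gene lengths from gene models
#' @param models a `gene_models` object.
#' @return named numeric vector of per-gene merged exon lengths.
#' @export
gene_lengths <- function(models) {
  ex <- merge(models$exons,
              models$transcripts[, c("tx_id", "gene_id")], by = "tx_id")
  out <- vapply(split(ex, ex$gene_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    sum(IRanges::width(ir))
  }, numeric(1))
  out
}

#' Count reads per gene from a BAM file
#'
#' Annotation-based expression quantification: records overlapping each
#' gene span (genes are non-overlapping in this pipeline's studies).
#' @param bam path to a sorted, indexed BAM.
#' @param models a `gene_models` object.
#' @return named integer vector of per-gene read counts.
#' @export
count_reads_per_gene <- function(bam, models) {
  g <- models$genes
  gr <- GenomicRanges::GRanges(g$seqid,
                               IRanges::IRanges(g$start, g$end))
  keep_flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE,
                                      isDuplicate = FALSE)
  cnt <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = keep_flag, which = gr))
  setNames(as.integer(cnt$records), g$gene_id)
}
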