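# Integration of the editing and expression layers: Venn overlap,
# nine-quadrant classification, PCA of editing frequencies, editing
# frequency vs enzyme-expression correlation, and cohort reporting.

#' Three-set Venn region counts
#'
#' @param a,b,c character vectors (gene-id sets).
#' @param names labels for the three sets.
#' @return data frame of the 7 intersection regions plus the union size.
#' @export
venn3 <- function(a, b, c, names = c("A", "B", "C")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  region <- c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC")
  count <- c(
    sum(in_a & !in_b & !in_c), sum(!in_a & in_b & !in_c),
    sum(!in_a & !in_b & in_c), sum(in_a & in_b & !in_c),
    sum(in_a & !in_b & in_c), sum(!in_a & in_b & in_c),
    sum(in_a & in_b & in_c))
  out <- data.frame(region = region, count = count,
                    stringsAsFactors = FALSE)
  attr(out, "sets") <- names
  attr(out, "union") <- length(u)
  out
}

#' Nine-quadrant classification of genes on the editing and expression axes
#'
#' Each gene gets one of the 9 states {editing up/ns/down} x {expression
#' up/ns/down}: "up"/"down" require the significance flag on that axis,
#' everything else is "ns". Genes present in only one table get the ns
#' state on the missing axis. The colour class follows the usual legend:
#' both / editing_only / expression_only / neither, where an axis counts
#' as significant iff its state is not ns.
#'
#' @param editing result table (gene-level editing) with columns feature,
#'   log2FC and logical significance (from [de_call()]'s `table`, i.e.
#'   `sig_up`/`sig_down`).
#' @param expression result table for expression, same shape.
#' @return data frame: gene, editing_log2fc, expression_log2fc,
#'   editing_state, expression_state, quadrant, color.
#' @export
quadrant_classify <- function(editing, expression) {
  state <- function(tab, genes) {
    i <- match(genes, tab$feature)
    lfc <- tab$log2FC[i]
    st <- rep("ns", length(genes))
    st[which(tab$sig_up[i])] <- "up"
    st[which(tab$sig_down[i])] <- "down"
    list(state = st, lfc = ifelse(is.na(lfc), 0, lfc))
  }
  genes <- sort(union(editing$feature, expression$feature))
  ed <- state(editing, genes)
  ex <- state(expression, genes)
  quadrant <- paste0("editing_", ed$state, ":expression_", ex$state)
  color <- ifelse(ed$state != "ns" & ex$state != "ns", "both",
                  ifelse(ed$state != "ns", "editing_only",
                         ifelse(ex$state != "ns", "expression_only",
                                "neither")))
  data.frame(gene = genes,
             editing_log2fc = ed$lfc, expression_log2fc = ex$lfc,
             editing_state = ed$state, expression_state = ex$state,
             quadrant = quadrant, color = color, stringsAsFactors = FALSE)
}

#' PCA of editing frequencies over samples
#'
#' Sites x samples frequency matrix; missing entries are imputed with the
#' per-site mean, all-missing sites are dropped (and reported); sites are
#' centered and samples projected by SVD.
#'
#' @param freq sites x samples matrix from [frequency_matrix()].
#' @return list with `coords` (samples x PCs), `var_pct` (percent
#'   variance per component, non-increasing), `dropped` (site keys with
#'   no data).
#' @export
editing_pca <- function(freq) {
  stopifnot(ncol(freq) >= 2)
  all_na <- rowSums(!is.na(freq)) == 0
  dropped <- rownames(freq)[all_na]
  x <- freq[!all_na, , drop = FALSE]
  site_means <- rowMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- site_means[idx[, 1]]
  xc <- x - rowMeans(x)
  sv <- svd(t(xc))                       # samples x sites
  npc <- min(dim(xc)) - 0L
  lambda <- sv$d^2
  var_pct <- if (sum(lambda) > 0) 100 * lambda / sum(lambda)
  else rep(0, length(lambda))
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(coords) <- colnames(freq)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  list(coords = coords, var_pct = var_pct, dropped = dropped)
}

#' Correlation between a gene's mean editing frequency and an enzyme's
#' expression
#'
#' Per-sample mean MAF (unweighted mean over the target gene's retained
#' sites, missing-aware) against the enzyme gene's per-sample expression;
#' Pearson R with the two-sided t-reference p on n - 2 degrees of
#' freedom.
#'
#' @param target_gene gene whose editing sites are averaged.
#' @param annotated annotated site table (needs `gene_id` and per-sample
#'   `_freq` columns).
#' @param enzyme_gene gene whose expression is correlated.
#' @param expr_matrix genes x samples expression matrix (e.g. TPM).
#' @param sample_sheet cohort sample sheet.
#' @return list with `enzyme_gene`, `target_gene`, `maf`, `expression`,
#'   `r`, `p`, `n`.
#' @export
maf_expression_correlation <- function(target_gene, annotated, enzyme_gene,
                                       expr_matrix, sample_sheet) {
  samples <- sample_sheet$sample
  rows <- which(annotated$gene_id == target_gene)
  if (!length(rows))
    stopf("gene %s has no retained editing sites", target_gene)
  fr <- as.matrix(annotated[rows, paste0(samples, "_freq"), drop = FALSE])
  maf <- colMeans(fr, na.rm = TRUE)
  maf[is.nan(maf)] <- NA_real_
  if (!enzyme_gene %in% rownames(expr_matrix))
    stopf("gene %s absent from the expression matrix", enzyme_gene)
  expr <- expr_matrix[enzyme_gene, samples]
  ok <- !is.na(maf) & !is.na(expr)
  n <- sum(ok)
  if (n < 3) stopf("correlation undefined: only %d complete samples", n)
  if (sd(maf[ok]) == 0 || sd(expr[ok]) == 0)
    stopf("correlation undefined: zero variance in MAF or expression")
  ct <- stats::cor.test(maf[ok], expr[ok], method = "pearson")
  list(enzyme_gene = enzyme_gene, target_gene = target_gene,
       maf = maf, expression = expr,
       r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Group total as the sum of per-sample locus counts
#'
#' The reporting convention for cohort totals: a condition's total editing
#' loci is the SUM of its samples' per-sample counts (so one site detected
#' in three replicates contributes three).
#' @param per_sample_counts numeric vector of per-sample locus counts.
#' @return their sum.
#' @export
group_total <- function(per_sample_counts) sum(per_sample_counts)

#' Cohort summary report
#'
#' Per-sample editing-locus counts with per-condition totals (sum
#' convention), editing-class and region tallies, significant site/gene
#' counts split by direction, and host-gene accounting including genes
#' carrying both up- and downregulated sites.
#'
#' @param annotated annotated site table.
#' @param sample_sheet cohort sample sheet.
#' @param site_res site-level differential table from [de_call()]
#'   (`table` element), or NULL.
#' @param gene_res gene-level editing differential, same shape, or NULL.
#' @param expr_res expression differential, same shape, or NULL.
#' @param filter the calling [filter_config()].
#' @return nested list; serialize with [jsonlite::write_json()].
#' @export
cohort_report <- function(annotated, sample_sheet, site_res = NULL,
                          gene_res = NULL, expr_res = NULL,
                          filter = filter_config()) {
  ann <- summarize_annotations(annotated, sample_sheet, filter)
  per_sample <- ann$detected
  conds <- split(sample_sheet$sample, sample_sheet$condition)
  totals <- lapply(conds, function(ss) group_total(per_sample[ss]))
  rep_out <- list(
    n_sites = nrow(annotated),
    per_sample_loci = as.list(per_sample),
    group_totals = totals,
    class_proportions = ann$class,
    region_proportions = ann$region,
    exonic_func_proportions = ann$exonic_func
  )
  dir_block <- function(res, annotated_gene_map = NULL) {
    up <- res$feature[res$sig_up]
    down <- res$feature[res$sig_down]
    blk <- list(n_up = length(up), n_down = length(down),
                n_significant = length(up) + length(down))
    if (!is.null(annotated_gene_map)) {
      gup <- unique(stats::na.omit(annotated_gene_map[up]))
      gdown <- unique(stats::na.omit(annotated_gene_map[down]))
      blk$genes_up <- length(gup)
      blk$genes_down <- length(gdown)
      blk$genes_both_directions <- length(intersect(gup, gdown))
      blk$genes_total <- length(union(gup, gdown))
    }
    blk
  }
  if (!is.null(site_res)) {
    gene_map <- setNames(annotated$gene_id, site_key(annotated))
    rep_out$differential_sites <- dir_block(site_res, gene_map)
  }
  if (!is.null(gene_res)) rep_out$differential_editing_genes <-
    dir_block(gene_res)
  if (!is.null(expr_res)) rep_out$differential_expression <-
    dir_block(expr_res)
  rep_out
}
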