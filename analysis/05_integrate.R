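#!/usr/bin/env Rscript
# Stage 5 — integrate the editing and expression layers: Venn overlap of
# the three significant gene sets, nine-quadrant classification, PCA of
# editing frequencies, a mean-MAF vs expression correlation, and the
# cohort summary report.

suppressMessages(library(dreseq))

sheet <- read_sample_sheet("results/study/samples.tsv")
ann <- read_site_table("results/run/sites_annotated.tsv")
dre_sites <- read_tsv("results/run/dre_sites.tsv")
dre_genes <- read_tsv("results/run/dre_genes.tsv")
deg <- read_tsv("results/run/deg.tsv")
tpm_tab <- read_tsv("results/run/tpm.tsv")
tpm_mat <- as.matrix(tpm_tab[, -1])
rownames(tpm_mat) <- tpm_tab$gene_id

gm <- setNames(ann$gene_id, site_key(ann))
sig <- function(tab) tab$feature[tab$sig_up | tab$sig_down]
site_host <- unique(na.omit(gm[sig(dre_sites)]))
venn <- venn3(site_host, sig(dre_genes), sig(deg),
              names = c("site_host_genes", "editing_genes",
                        "expression_genes"))
write_tsv(venn, "results/run/venn.tsv")
cat("venn regions (site-host / editing-gene / expression):\n")
print(venn)

quad <- quadrant_classify(dre_genes, deg)
write_tsv(quad, "results/run/quadrants.tsv")
cat("nine-quadrant occupancy:\n")
print(table(quad$quadrant))
cat("colour classes:\n")
print(table(quad$color))

fm <- frequency_matrix(ann, sheet)
pca <- editing_pca(fm$freq)
write_tsv(data.frame(sample = rownames(pca$coords), pca$coords,
                     check.names = FALSE), "results/run/pca.tsv")
cat(sprintf("PCA: PC1 %.2f%%, PC2 %.2f%% of editing-frequency variance\n",
            pca$var_pct[1], pca$var_pct[2]))

# correlation between a heavily edited gene's mean MAF and the expression
# of the strongest expression responder (enzyme stand-in)
target <- names(sort(table(na.omit(ann$gene_id)), decreasing = TRUE))[1]
enzyme <- deg$feature[order(-abs(deg$log2FC * (deg$padj < 0.05)))][1]
corr <- maf_expression_correlation(target, ann, enzyme, tpm_mat, sheet)
write_tsv(data.frame(target = target, enzyme = enzyme, r = corr$r,
                     p = corr$p, n = corr$n),
          "results/run/correlation.tsv")
cat(sprintf("mean MAF of %s vs expression of %s: R = %.3f, p = %.3g\n",
            target, enzyme, corr$r, corr$p))

report <- cohort_report(ann, sheet,
                        de_call(dre_sites, 0.05, 0)$table,
                        de_call(dre_genes, 0.05, 0)$table,
                        de_call(deg, 0.05, 1.2)$table)
jsonlite::write_json(report, "results/run/report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("per-sample loci:", unlist(report$per_sample_loci), "\n")
cat(sprintf("group totals (sum convention): control %d, treated %d\n",
            report$group_totals$control, report$group_totals$treated))
cat("report written to results/run/report.json\n")
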