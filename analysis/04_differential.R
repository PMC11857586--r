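#!/usr/bin/env Rscript
# Stage 4 — differential analysis, three ways with one NB engine:
#   (a) site-level differential editing on alt-read counts (padj < 0.05),
#   (b) gene-level differential editing on counts aggregated per gene,
#   (c) differential expression on gene read counts
#       (FDR < 0.05 and |log2FC| > 1.2), plus TPM quantification.

suppressMessages(library(dreseq))

sheet <- read_sample_sheet("results/study/samples.tsv")
models <- read_gff3("results/study/genes.gff3")
ann <- read_site_table("results/run/sites_annotated.tsv")

sc <- editing_counts(ann, sheet)
dre_sites <- de_call(nb_differential(sc, sheet$condition), 0.05, 0)
write_tsv(dre_sites$table, "results/run/dre_sites.tsv")

gc <- aggregate_gene(sc, ann$gene_id)
dre_genes <- de_call(nb_differential(gc, sheet$condition), 0.05, 0)
write_tsv(dre_genes$table, "results/run/dre_genes.tsv")

expr <- vapply(sheet$path, function(p) {
  bam <- if (grepl("\\.sam$", p)) sam_to_bam(p) else p
  count_reads_per_gene(bam, models)
}, numeric(nrow(models$genes)))
colnames(expr) <- sheet$sample
tpm_mat <- tpm(expr, gene_lengths(models)[rownames(expr)])
write_tsv(data.frame(gene_id = rownames(tpm_mat), tpm_mat,
                     check.names = FALSE), "results/run/tpm.tsv")
deg <- de_call(nb_differential(expr, sheet$condition), 0.05, 1.2)
write_tsv(deg$table, "results/run/deg.tsv")

gm <- setNames(ann$gene_id, site_key(ann))
site_genes <- function(keys) unique(na.omit(gm[keys]))
cat(sprintf("differential editing sites: %d up (%d genes), %d down (%d genes)\n",
            length(dre_sites$up), length(site_genes(dre_sites$up)),
            length(dre_sites$down), length(site_genes(dre_sites$down))))
both <- intersect(site_genes(dre_sites$up), site_genes(dre_sites$down))
cat(sprintf("genes with editing sites in both directions: %d\n",
            length(both)))
cat(sprintf("differential editing genes: %d up, %d down\n",
            length(dre_genes$up), length(dre_genes$down)))
cat(sprintf("differentially expressed genes: %d up, %d down\n",
            length(deg$up), length(deg$down)))
truth_genes <- read_tsv("results/study/truth_genes.tsv")
de_truth <- truth_genes$gene_id[truth_genes$is_de == "TRUE" |
                                  truth_genes$is_de == TRUE]
hits <- c(deg$up, deg$down)
cat(sprintf("DE recovery: %d/%d planted DE genes found, %d false\n",
            sum(de_truth %in% hits), length(de_truth),
            sum(!hits %in% de_truth)))
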