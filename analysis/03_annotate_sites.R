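#!/usr/bin/env Rscript
# Stage 3 — annotate called sites: genomic region (exonic > splicing >
# ncRNA > UTR > intronic > upstream > downstream), substitution class
# (C-to-U = C>T/G>A, A-to-I = A>G/T>C, reference-forward) and, for CDS
# sites, the protein consequence. Writes results/run/sites_annotated.tsv
# and the per-sample tally tables.

suppressMessages(library(dreseq))

sheet <- read_sample_sheet("results/study/samples.tsv")
genome <- read_fasta("results/study/genome.fa")
models <- read_gff3("results/study/genes.gff3")
sites <- read_site_table("results/run/sites.tsv")

ann <- annotate_sites(sites, models, genome)
write_site_table(ann, "results/run/sites_annotated.tsv")

summ <- summarize_annotations(ann, sheet)
write_tsv(summ$region, "results/run/tally_region.tsv")
write_tsv(summ$class, "results/run/tally_class.tsv")
write_tsv(summ$exonic_func, "results/run/tally_exonic_func.tsv")

cat("region distribution (cohort):\n")
print(sort(table(ann$region), decreasing = TRUE))
cat("consequences among exonic sites:\n")
print(table(ann$exonic_func[ann$region == "exonic"]))
mix <- vapply(sheet$sample, function(s) {
  sub <- summ$class[summ$class$sample == s, ]
  sum(sub$prop[sub$level %in% c("C-to-U", "A-to-I")])
}, numeric(1))
cat(sprintf("C-to-U + A-to-I share per sample: %s (mean %.1f%%)\n",
            paste(round(100 * mix, 1), collapse = " "),
            100 * mean(mix)))
cat("per-sample detected loci:\n")
print(summ$detected)
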