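#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Two conditions (control vs MeJA-style treatment) x 3 replicates over a
# 0.7 Mb single-chromosome genome with 200 genes; 2000 editing sites
# planted with an 80% C-to-U + A-to-I class mixture, 20% of them with a
# condition-dependent frequency shift; 15% of genes differentially
# expressed. Writes genome, annotation, per-sample alignments, sample
# sheet and truth tables under results/study/.

suppressMessages(library(dreseq))

cfg <- sim_config(seed = 1)   # defaults ARE the study conditions
st <- simulate_study(cfg, "results/study")

tc <- attr(st$sample_sheet, "true_counts")
cat("genome:", names(st$genome), "-", nchar(st$genome[[1]]), "bp\n")
cat("genes:", nrow(st$models$genes),
    "(", sum(st$models$genes$biotype == "coding"), "coding )\n")
cat("planted sites:", nrow(st$truth$sites),
    "(", sum(st$truth$sites$is_differential), "differential )\n")
cat("class mixture (planted):\n")
print(round(sort(prop.table(table(st$truth$sites$class)),
                 decreasing = TRUE), 3))
cat("region distribution (planted):\n")
print(sort(table(st$truth$sites$region), decreasing = TRUE))
cat("reads per sample:\n")
print(colSums(tc))
cat("DE genes:", sum(st$truth$genes$is_de), "of",
    nrow(st$truth$genes), "\n")
cat("outputs in results/study/\n")
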