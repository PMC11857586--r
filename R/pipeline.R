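# End-to-end orchestration: formats -> calling -> annotate -> diffstats ->
# integrate, with a manifest of record counts per stage. Re-running with
# the same inputs and thresholds reproduces identical tables.

#' Pipeline thresholds
#'
#' @param filter a [filter_config()].
#' @param editing_fdr adjusted-p threshold for differential editing
#'   (site and gene level; no fold-change gate).
#' @param expr_fdr FDR threshold for differential expression.
#' @param expr_lfc absolute log2FC gate for differential expression.
#' @return list of validated thresholds.
#' @export
pipeline_config <- function(filter = filter_config(), editing_fdr = 0.05,
                            expr_fdr = 0.05, expr_lfc = 1.2) {
  assert_that(editing_fdr > 0 && editing_fdr < 1, "editing_fdr in (0,1)")
  assert_that(expr_fdr > 0 && expr_fdr < 1, "expr_fdr in (0,1)")
  assert_that(expr_lfc >= 0, "expr_lfc must be >= 0")
  list(filter = filter, editing_fdr = editing_fdr,
       expr_fdr = expr_fdr, expr_lfc = expr_lfc)
}

#' Run the full editing/expression analysis
#'
#' @param genome_path reference FASTA.
#' @param gff3_path gene annotation GFF3.
#' @param sheet_path sample sheet TSV (sample/path/condition/replicate).
#' @param out_dir output directory for all result tables.
#' @param config a [pipeline_config()].
#' @return invisible list of in-memory results plus `manifest`.
#' @export
run_pipeline <- function(genome_path, gff3_path, sheet_path, out_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_fasta(genome_path)
  models <- read_gff3(gff3_path)
  sheet <- read_sample_sheet(sheet_path)

  called <- call_editing_sites(sheet, genome, config$filter)
  sites <- called$sites
  write_site_table(sites, file.path(out_dir, "sites.tsv"))

  annotated <- annotate_sites(sites, models, genome)
  write_site_table(annotated, file.path(out_dir, "sites_annotated.tsv"))

  # differential editing: site level then gene-aggregated
  sc <- editing_counts(annotated, sheet)
  dre_sites <- nb_differential(sc, sheet$condition)
  dre_sites_call <- de_call(dre_sites, fdr = config$editing_fdr, lfc = 0)
  write_tsv(dre_sites_call$table, file.path(out_dir, "dre_sites.tsv"))

  gene_of_site <- annotated$gene_id
  gc <- aggregate_gene(sc, gene_of_site)
  dre_genes <- nb_differential(gc, sheet$condition)
  dre_genes_call <- de_call(dre_genes, fdr = config$editing_fdr, lfc = 0)
  write_tsv(dre_genes_call$table, file.path(out_dir, "dre_genes.tsv"))

  # expression: annotation-based gene counts, TPM, NB differential
  expr_counts <- vapply(sheet$path, function(p) {
    bam <- if (grepl("\\.sam$", p)) sam_to_bam(p) else p
    count_reads_per_gene(bam, models)
  }, numeric(nrow(models$genes)))
  colnames(expr_counts) <- sheet$sample
  lens <- gene_lengths(models)[rownames(expr_counts)]
  tpm_mat <- tpm(expr_counts, lens)
  write_tsv(data.frame(gene_id = rownames(tpm_mat), tpm_mat,
                       check.names = FALSE),
            file.path(out_dir, "tpm.tsv"))
  deg <- nb_differential(expr_counts, sheet$condition)
  deg_call <- de_call(deg, fdr = config$expr_fdr, lfc = config$expr_lfc)
  write_tsv(deg_call$table, file.path(out_dir, "deg.tsv"))

  # integration
  gene_map <- setNames(annotated$gene_id, site_key(annotated))
  sig_site_genes <- unique(stats::na.omit(
    gene_map[c(dre_sites_call$up, dre_sites_call$down)]))
  sig_edit_genes <- c(dre_genes_call$up, dre_genes_call$down)
  sig_expr_genes <- c(deg_call$up, deg_call$down)
  venn <- venn3(sig_site_genes, sig_edit_genes, sig_expr_genes,
                names = c("site_host_genes", "editing_genes",
                          "expression_genes"))
  write_tsv(venn, file.path(out_dir, "venn.tsv"))

  quad <- quadrant_classify(dre_genes_call$table, deg_call$table)
  write_tsv(quad, file.path(out_dir, "quadrants.tsv"))

  fm <- frequency_matrix(annotated, sheet)
  pca <- if (nrow(fm$freq) >= 2) editing_pca(fm$freq) else NULL
  if (!is.null(pca)) {
    write_tsv(data.frame(sample = rownames(pca$coords), pca$coords,
                         check.names = FALSE),
              file.path(out_dir, "pca.tsv"))
    write_tsv(data.frame(component = paste0("PC",
                                            seq_along(pca$var_pct)),
                         var_pct = pca$var_pct),
              file.path(out_dir, "pca_variance.tsv"))
  }

  report <- cohort_report(annotated, sheet, dre_sites_call$table,
                          dre_genes_call$table, deg_call$table,
                          config$filter)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dreseq")),
    thresholds = list(editing_fdr = config$editing_fdr,
                      expr_fdr = config$expr_fdr,
                      expr_lfc = config$expr_lfc,
                      filter = unclass(config$filter)),
    stage_counts = list(
      samples = nrow(sheet),
      retained_sites = nrow(sites),
      genes_with_sites = length(unique(stats::na.omit(annotated$gene_id))),
      dre_sites_significant = length(c(dre_sites_call$up,
                                       dre_sites_call$down)),
      dre_genes_significant = length(sig_edit_genes),
      deg_significant = length(sig_expr_genes))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sites = annotated, dre_sites = dre_sites_call,
                 dre_genes = dre_genes_call, deg = deg_call,
                 tpm = tpm_mat, expr_counts = expr_counts, venn = venn,
                 quadrants = quad, pca = pca, freq = fm, report = report,
                 manifest = manifest, sheet = sheet))
}

#' Simulate a study and analyse it in one call
#'
#' The bundled demonstration: generates a synthetic study under
#' `dir/study` and runs the full pipeline into `dir/results`.
#' @param config a [sim_config()].
#' @param dir working directory.
#' @param pconfig a [pipeline_config()].
#' @return invisible list with `study` and `results`.
#' @export
run_demo <- function(config = sim_config(), dir = tempfile("dreseq_demo"),
                     pconfig = pipeline_config()) {
  study <- simulate_study(config, file.path(dir, "study"))
  results <- run_pipeline(study$paths$genome, study$paths$gff3,
                          study$paths$sample_sheet,
                          file.path(dir, "results"), pconfig)
  invisible(list(study = study, results = results))
}
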