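# Standard-format IO. Coordinates are 1-based inclusive in every
# serialized artifact; any half-open arithmetic stays internal.

#' Gene-model container
#'
#' Flat, hierarchical gene models: `genes` (gene_id, seqid, start, end,
#' strand, biotype), `transcripts` (tx_id, gene_id, ...), `exons` and
#' `cds` (tx_id, start, end, strand, phase) linked by ids. CDS rows carry
#' the GFF3 phase in transcription order.
#'
#' @param genes,transcripts,exons,cds data frames as above; `cds` may be
#'   NULL when no transcript is coding.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons, cds = NULL) {
  if (is.null(cds))
    cds <- data.frame(tx_id = character(), seqid = character(),
                      start = integer(), end = integer(),
                      strand = character(), phase = integer(),
                      stringsAsFactors = FALSE)
  orphan <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(orphan))
    stopf("transcripts reference unknown gene ids: %s",
          paste(orphan, collapse = ", "))
  orphan <- setdiff(c(exons$tx_id, cds$tx_id), transcripts$tx_id)
  if (length(orphan))
    stopf("exon/CDS rows reference unknown transcript ids: %s",
          paste(unique(orphan), collapse = ", "))
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "gene_models")
}

#' @rdname gene_models
#' @export
empty_gene_models <- function() {
  gene_models(
    genes = data.frame(gene_id = character(), seqid = character(),
                       start = integer(), end = integer(),
                       strand = character(), biotype = character()),
    transcripts = data.frame(tx_id = character(), gene_id = character(),
                             seqid = character(), start = integer(),
                             end = integer(), strand = character()),
    exons = data.frame(tx_id = character(), seqid = character(),
                       start = integer(), end = integer(),
                       strand = character())
  )
}

# ---------------------------------------------------------------------------
# FASTA

#' Read a reference genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector of uppercase sequences with random access via
#' [genome_slice()].
#'
#' @param path FASTA file (gzip transparently supported).
#' @return named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stopf("duplicate sequence names in %s: %s", path,
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  setNames(toupper(as.character(ss)), nm)
}

#' @param genome named character vector from [read_fasta()].
#' @param chrom,start,end 1-based inclusive slice to extract.
#' @rdname read_fasta
#' @export
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stopf("unknown sequence '%s'", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 1 || end > len || start > end)
    stopf("slice %s:%d-%d out of range (length %d)", chrom, start, end, len)
  substr(genome[[chrom]], start, end)
}

#' Write sequences to FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3

#' Write gene models as GFF3
#'
#' gene / mRNA-or-ncRNA / exon / CDS rows with ID/Parent links, 1-based
#' inclusive coordinates and CDS phase.
#' @param models a `gene_models` object.
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  rows <- character(0)
  fmt <- function(seqid, type, start, end, strand, phase, attrs)
    sprintf("%s\tdreseq\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            seqid, type, start, end, strand, phase, attrs)
  g <- models$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    rows <- c(rows, fmt(g$seqid[i], "gene", g$start[i], g$end[i],
                        g$strand[i], ".",
                        sprintf("ID=%s;biotype=%s", gid, g$biotype[i])))
    txs <- models$transcripts[models$transcripts$gene_id == gid, ,
                              drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      tid <- txs$tx_id[j]
      ttype <- if (g$biotype[i] == "coding") "mRNA" else "ncRNA"
      rows <- c(rows, fmt(txs$seqid[j], ttype, txs$start[j], txs$end[j],
                          txs$strand[j], ".",
                          sprintf("ID=%s;Parent=%s", tid, gid)))
      ex <- models$exons[models$exons$tx_id == tid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      for (k in seq_len(nrow(ex)))
        rows <- c(rows, fmt(ex$seqid[k], "exon", ex$start[k], ex$end[k],
                            ex$strand[k], ".", sprintf("Parent=%s", tid)))
      cd <- models$cds[models$cds$tx_id == tid, , drop = FALSE]
      cd <- cd[order(cd$start), , drop = FALSE]
      for (k in seq_len(nrow(cd)))
        rows <- c(rows, fmt(cd$seqid[k], "CDS", cd$start[k], cd$end[k],
                            cd$strand[k], as.character(cd$phase[k]),
                            sprintf("Parent=%s", tid)))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

.parse_gff_attrs <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  lapply(parts, function(p) {
    kv <- strsplit(p, "=", fixed = TRUE)
    setNames(vapply(kv, function(z) z[2] %||% NA_character_, character(1)),
             vapply(kv, `[[`, character(1), 1))
  })
}

#' Read gene models from GFF3
#'
#' Accepts gene / mRNA / ncRNA / transcript / exon / CDS rows linked by
#' ID/Parent. A gene without any CDS row is flagged non-coding. Orphan
#' Parent references are an error listing the offending ids.
#'
#' @param path GFF3 file (gzip transparently supported).
#' @return a `gene_models` object.
#' @export
read_gff3 <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_gene_models())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9)
  if (length(bad))
    stopf("malformed GFF3: line %d has %d fields (9 required)",
          bad[1], length(f[[bad[1]]]))
  m <- do.call(rbind, f)
  df <- data.frame(seqid = m[, 1], type = m[, 3],
                   start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                   strand = m[, 7], phase = m[, 8], attrs = m[, 9],
                   stringsAsFactors = FALSE)
  at <- .parse_gff_attrs(df$attrs)
  df$ID <- vapply(at, function(a) a["ID"] %||% NA_character_, character(1))
  df$Parent <- vapply(at, function(a) a["Parent"] %||% NA_character_,
                      character(1))
  df$biotype <- vapply(at, function(a) a["biotype"] %||% NA_character_,
                       character(1))

  is_gene <- df$type == "gene"
  is_tx <- df$type %in% c("mRNA", "ncRNA", "transcript")
  is_exon <- df$type == "exon"
  is_cds <- df$type == "CDS"
  gene_ids <- df$ID[is_gene]
  tx_ids <- df$ID[is_tx]
  orphan_tx <- df$Parent[is_tx][!df$Parent[is_tx] %in% gene_ids]
  orphan_sub <- df$Parent[is_exon | is_cds][
    !df$Parent[is_exon | is_cds] %in% tx_ids]
  orphans <- unique(c(orphan_tx, orphan_sub))
  orphans <- orphans[!is.na(orphans)]
  if (length(orphans))
    stopf("GFF3 orphan Parent references: %s", paste(orphans, collapse = ", "))

  genes <- data.frame(gene_id = df$ID[is_gene], seqid = df$seqid[is_gene],
                      start = df$start[is_gene], end = df$end[is_gene],
                      strand = df$strand[is_gene],
                      biotype = df$biotype[is_gene],
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(tx_id = df$ID[is_tx], gene_id = df$Parent[is_tx],
                            seqid = df$seqid[is_tx], start = df$start[is_tx],
                            end = df$end[is_tx], strand = df$strand[is_tx],
                            stringsAsFactors = FALSE)
  exons <- data.frame(tx_id = df$Parent[is_exon], seqid = df$seqid[is_exon],
                      start = df$start[is_exon], end = df$end[is_exon],
                      strand = df$strand[is_exon], stringsAsFactors = FALSE)
  cds <- if (any(is_cds))
    data.frame(tx_id = df$Parent[is_cds], seqid = df$seqid[is_cds],
               start = df$start[is_cds], end = df$end[is_cds],
               strand = df$strand[is_cds],
               phase = suppressWarnings(as.integer(df$phase[is_cds])),
               stringsAsFactors = FALSE) else NULL
  # flag biotype from CDS presence when the attribute is absent
  if (any(is.na(genes$biotype))) {
    coding_tx <- unique(cds$tx_id)
    coding_genes <- unique(transcripts$gene_id[transcripts$tx_id %in%
                                                 coding_tx])
    genes$biotype <- ifelse(!is.na(genes$biotype), genes$biotype,
                            ifelse(genes$gene_id %in% coding_genes,
                                   "coding", "ncRNA"))
  }
  ord <- order(genes$seqid, genes$start)
  gene_models(genes[ord, , drop = FALSE], transcripts, exons, cds)
}

#' Assemble a transcript's spliced CDS sequence
#'
#' Concatenates CDS segments in transcription order (reverse-complemented
#' for minus-strand transcripts).
#' @param tx_id transcript id.
#' @param models a `gene_models` object.
#' @param genome named character vector from [read_fasta()].
#' @return character scalar CDS in reading orientation ("" if non-coding).
#' @export
spliced_cds <- function(tx_id, models, genome) {
  cd <- models$cds[models$cds$tx_id == tx_id, , drop = FALSE]
  if (!nrow(cd)) return("")
  cd <- cd[order(cd$start), , drop = FALSE]
  segs <- mapply(function(s, e) genome_slice(genome, cd$seqid[1], s, e),
                 cd$start, cd$end)
  fwd <- paste(segs, collapse = "")
  if (cd$strand[1] == "-") revcomp(fwd) else fwd
}

# ---------------------------------------------------------------------------
# Alignments

#' Convert SAM to sorted, indexed BAM
#' @param sam_path input SAM.
#' @param bam_path output BAM path without extension handling; defaults to
#'   the SAM path with `.bam` substituted.
#' @return path of the sorted BAM.
#' @export
sam_to_bam <- function(sam_path, bam_path = sub("\\.sam$", ".bam", sam_path)) {
  out <- Rsamtools::asBam(sam_path,
                          destination = sub("\\.bam$", "", bam_path),
                          overwrite = TRUE, indexDestination = TRUE)
  out
}

#' Open a coordinate-sorted alignment file
#'
#' Validates that the file is BAM (converting SAM transparently) and
#' coordinate-sorted, and reports how many records are excluded as
#' unmapped, secondary, supplementary or duplicate. Downstream pileups use
#' the same exclusion flags.
#'
#' @param path SAM or BAM file.
#' @return list with `bam` (path to sorted, indexed BAM), `n_used`,
#'   `n_skipped`.
#' @export
open_alignments <- function(path) {
  if (grepl("\\.sam$", path)) {
    # refuse SAM that declares itself unsorted before converting
    first <- readLines(path, n = 1)
    if (grepl("^@HD", first) && grepl("SO:", first) &&
        !grepl("SO:coordinate", first))
      stopf("%s is not coordinate-sorted; sort it (e.g. samtools sort) first",
            path)
  }
  bam <- if (grepl("\\.sam$", path)) sam_to_bam(path) else path
  hd <- Rsamtools::scanBamHeader(bam)[[1]]$text
  so <- hd[["@HD"]]
  if (is.null(so) || !any(grepl("^SO:coordinate$", so)))
    stopf("%s is not coordinate-sorted; sort it (e.g. samtools sort) first",
          path)
  if (!file.exists(paste0(bam, ".bai"))) Rsamtools::indexBam(bam)
  total <- Rsamtools::countBam(bam)$records
  keep_flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE,
                                      isDuplicate = FALSE)
  used <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = keep_flag))$records
  list(bam = bam, n_used = used, n_skipped = total - used)
}

# ---------------------------------------------------------------------------
# TSV tables

#' Write/read plain TSV with fixed conventions
#'
#' All site/truth/result tables round-trip through these two functions:
#' tab-separated, header, no quotes, no row names, gzip by extension.
#' @param x data frame.
#' @param path file path (`.gz` writes gzip).
#' @export
write_tsv <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read and validate a sample sheet
#'
#' Columns `sample`, `path`, `condition` (control/treated), `replicate`.
#' Relative alignment paths are resolved against the sheet's directory.
#' @param path TSV file.
#' @return validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sh <- read_tsv(path)
  need <- c("sample", "path", "condition", "replicate")
  missing <- setdiff(need, names(sh))
  if (length(missing))
    stopf("sample sheet lacks columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(sh$sample))
    stopf("duplicate sample ids in sample sheet")
  if (!all(sh$condition %in% c("control", "treated")))
    stopf("condition must be 'control' or 'treated'")
  tab <- table(sh$condition)
  if (length(tab) < 2 || any(tab < 2))
    stopf("need >= 2 samples in each of two conditions")
  rel <- !file.exists(sh$path) & !grepl("^/", sh$path)
  sh$path[rel] <- file.path(dirname(path), sh$path[rel])
  sh
}

#' Serialize called editing sites
#'
#' One row per site: chrom, pos, ref, alt then per-sample
#' `<sample>_ref`, `<sample>_alt`, `<sample>_freq` columns plus any
#' annotation columns. `read_site_table(write_site_table(x)) == x`.
#' @param sites editing-site data frame from [merge_cohort()].
#' @param path file path.
#' @export
write_site_table <- function(sites, path) write_tsv(sites, path)

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  x <- read_tsv(path)
  x[order(x$chrom, x$pos), , drop = FALSE]
}

#' VCF-style export of called editing sites
#'
#' Convenience writer: one VCF-like row per site with the cohort mean
#' editing frequency and supporting-sample count in an INFO-style
#' column. Tabular TSV remains the primary serialization.
#' @param sites site table from [merge_cohort()].
#' @param sample_sheet cohort sample sheet.
#' @param path output file.
#' @export
write_sites_vcf <- function(sites, sample_sheet, path) {
  samples <- sample_sheet$sample
  fm <- as.matrix(sites[, paste0(samples, "_freq"), drop = FALSE])
  maf <- rowMeans(fm, na.rm = TRUE)
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Mean editing frequency\">",
             "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Supporting samples\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMAF=%.4f;NS=%d",
                     sites$chrom, sites$pos, sites$ref, sites$alt,
                     maf, sites$n_supporting))
  writeLines(lines, path)
  invisible(path)
}
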