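# Site annotation: genomic region, substitution class, protein consequence.
#
# Substitutions are reported reference-forward (the library is treated as
# unstranded), so C-to-U editing on a minus-strand gene appears as G>A and
# A-to-I as T>C. The complement of A>G is taken as T>C, the biologically
# consistent pairing; T>A falls into the residual classes.

REGION_PRECEDENCE <- c("exonic", "splicing", "ncRNA_exonic",
                       "ncRNA_intronic", "UTR", "intronic",
                       "upstream", "downstream", "intergenic")

SPLICE_WINDOW <- 2L
FLANK_WINDOW <- 1000L

#' Classify a substitution into an editing class
#'
#' C>T and G>A map to C-to-U deamination; A>G and T>C map to A-to-I.
#' Everything else is the residual class `other:X>Y` (12 classes total).
#'
#' @param ref,alt reference and alternative bases (vectors recycle).
#' @return character vector of class labels.
#' @export
classify_substitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  if (!all(ref %in% BASES) || !all(alt %in% BASES))
    stopf("ref/alt must be A, C, G or T")
  if (any(ref == alt)) stopf("ref and alt must differ")
  key <- paste0(ref, ">", alt)
  out <- paste0("other:", key)
  out[key %in% c("C>T", "G>A")] <- "C-to-U"
  out[key %in% c("A>G", "T>C")] <- "A-to-I"
  out
}

# Candidate labels of one position against one transcript; returns
# character vector (possibly several, precedence resolved by caller).
.tx_labels <- function(pos, tx, exons, cds_rows) {
  labs <- character(0)
  coding <- nrow(cds_rows) > 0
  inside <- pos >= tx$start && pos <= tx$end
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  in_cds <- coding && any(pos >= cds_rows$start & pos <= cds_rows$end)
  if (in_cds) labs <- c(labs, "exonic")
  if (inside && !in_exon && nrow(exons) > 1) {
    bounds <- sort(c(exons$start, exons$end))
    inner <- bounds[-c(1, length(bounds))]
    if (any(abs(pos - inner) <= SPLICE_WINDOW)) labs <- c(labs, "splicing")
  }
  if (!coding && in_exon) labs <- c(labs, "ncRNA_exonic")
  if (!coding && inside && !in_exon) labs <- c(labs, "ncRNA_intronic")
  if (coding && in_exon && !in_cds) labs <- c(labs, "UTR")
  if (coding && inside && !in_exon) labs <- c(labs, "intronic")
  if (!inside) {
    before <- pos < tx$start && tx$start - pos <= FLANK_WINDOW
    after <- pos > tx$end && pos - tx$end <= FLANK_WINDOW
    if (tx$strand == "+") {
      if (before) labs <- c(labs, "upstream")
      if (after) labs <- c(labs, "downstream")
    } else {
      if (before) labs <- c(labs, "downstream")
      if (after) labs <- c(labs, "upstream")
    }
  }
  labs
}

#' Classify sites by genomic region
#'
#' Assigns each site exactly one region label under the precedence
#' exonic > splicing > ncRNA_exonic > ncRNA_intronic > UTR > intronic >
#' upstream > downstream > intergenic. Splicing means within 2 bases of an
#' exon-intron boundary on the intron side; upstream/downstream are 1 kb
#' windows on the transcript's strand.
#'
#' @param chrom,pos site coordinates (vectors).
#' @param models a `gene_models` object.
#' @return data frame with `region` and `gene_id` (host gene(s) at the
#'   winning precedence, comma-joined; NA for intergenic).
#' @export
classify_region <- function(chrom, pos, models) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  g <- models$genes
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  if (is.null(g) || !nrow(g)) return(data.frame(region = region,
                                                gene_id = gene,
                                                stringsAsFactors = FALSE))
  tx_by_gene <- split(seq_len(nrow(models$transcripts)),
                      models$transcripts$gene_id)
  ex_by_tx <- split(models$exons, models$exons$tx_id)
  cds_by_tx <- split(models$cds, models$cds$tx_id)
  for (i in seq_len(n)) {
    cand <- which(g$seqid == chrom[i] &
                    g$start - FLANK_WINDOW <= pos[i] &
                    g$end + FLANK_WINDOW >= pos[i])
    if (!length(cand)) next
    best_rank <- match("intergenic", REGION_PRECEDENCE)
    best_genes <- character(0)
    for (gi in cand) {
      for (ti in tx_by_gene[[g$gene_id[gi]]]) {
        tx <- models$transcripts[ti, ]
        labs <- .tx_labels(pos[i], tx,
                           ex_by_tx[[tx$tx_id]] %||%
                             models$exons[0, ],
                           cds_by_tx[[tx$tx_id]] %||%
                             models$cds[0, ])
        if (!length(labs)) next
        r <- min(match(labs, REGION_PRECEDENCE))
        if (r < best_rank) {
          best_rank <- r
          best_genes <- g$gene_id[gi]
        } else if (r == best_rank && r < match("intergenic",
                                               REGION_PRECEDENCE)) {
          best_genes <- union(best_genes, g$gene_id[gi])
        }
      }
    }
    if (best_rank < match("intergenic", REGION_PRECEDENCE)) {
      region[i] <- REGION_PRECEDENCE[best_rank]
      gene[i] <- paste(sort(best_genes), collapse = ",")
    }
  }
  data.frame(region = region, gene_id = gene, stringsAsFactors = FALSE)
}

#' Protein-level consequence of a CDS substitution
#'
#' Locates the codon via spliced CDS coordinates (strand- and phase-aware),
#' substitutes the edited base (complemented for minus-strand
#' transcripts), translates with the standard codon table and labels the
#' change: synonymous SNV, nonsynonymous SNV, stopgain or stoploss. When
#' several transcripts' CDS contain the site, the longest CDS is used and
#' the others are reported as `secondary_tx`.
#'
#' @param chrom,pos,ref,alt one site (scalars), reference-forward alleles.
#' @param models a `gene_models` object.
#' @param genome named character vector from [read_fasta()].
#' @return list with `exonic_func`, `codon_change` (e.g. "CTT>CTC"),
#'   `aa_change` (e.g. "L45L"), `tx_id`, `secondary_tx`.
#' @export
exonic_consequence <- function(chrom, pos, ref, alt, models, genome) {
  cd <- models$cds
  hit_tx <- unique(cd$tx_id[cd$seqid == chrom & cd$start <= pos &
                              cd$end >= pos])
  if (!length(hit_tx))
    stopf("site %s:%d is not inside any CDS", chrom, pos)
  cds_len <- vapply(hit_tx, function(t)
    sum(cd$end[cd$tx_id == t] - cd$start[cd$tx_id == t] + 1L), numeric(1))
  tx_id <- hit_tx[order(-cds_len, hit_tx)][1]
  secondary <- setdiff(hit_tx, tx_id)

  rows <- cd[cd$tx_id == tx_id, , drop = FALSE]
  rows <- rows[order(rows$start), , drop = FALSE]
  strand <- rows$strand[1]
  cds_seq <- spliced_cds(tx_id, models, genome)
  # CDS-local (transcription-order) index of pos
  if (strand == "+") {
    before <- 0L
    for (k in seq_len(nrow(rows))) {
      if (pos >= rows$start[k] && pos <= rows$end[k]) {
        idx <- before + (pos - rows$start[k] + 1L)
        break
      }
      before <- before + rows$end[k] - rows$start[k] + 1L
    }
  } else {
    rows_t <- rows[order(-rows$start), , drop = FALSE]
    before <- 0L
    for (k in seq_len(nrow(rows_t))) {
      if (pos >= rows_t$start[k] && pos <= rows_t$end[k]) {
        idx <- before + (rows_t$end[k] - pos + 1L)
        break
      }
      before <- before + rows_t$end[k] - rows_t$start[k] + 1L
    }
  }
  tx_ref <- if (strand == "+") ref else COMPLEMENT[[ref]]
  tx_alt <- if (strand == "+") alt else COMPLEMENT[[alt]]
  if (substr(cds_seq, idx, idx) != tx_ref)
    stopf("reference allele mismatch at %s:%d (CDS has %s, site says %s)",
          chrom, pos, substr(cds_seq, idx, idx), tx_ref)
  codon_i <- (idx - 1L) %/% 3L + 1L
  off <- (idx - 1L) %% 3L + 1L
  codon_ref <- substr(cds_seq, 3L * codon_i - 2L, 3L * codon_i)
  codon_alt <- codon_ref
  substr(codon_alt, off, off) <- tx_alt
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  func <- if (aa_ref == aa_alt) "synonymous SNV"
  else if (aa_ref != "*" && aa_alt == "*") "stopgain"
  else if (aa_ref == "*" && aa_alt != "*") "stoploss"
  else "nonsynonymous SNV"
  list(exonic_func = func,
       codon_change = paste0(codon_ref, ">", codon_alt),
       aa_change = paste0(aa_ref, codon_i, aa_alt),
       tx_id = tx_id, secondary_tx = secondary)
}

#' Translate one codon with the standard genetic code
#' @param codon 3-base string.
#' @return single-letter amino acid, "*" for stop.
#' @export
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Annotate a cohort site table
#'
#' Appends region, host gene, editing class and (for exonic sites on
#' coding transcripts) the consequence columns to a site table.
#'
#' @param sites site table from [merge_cohort()].
#' @param models a `gene_models` object.
#' @param genome named character vector from [read_fasta()].
#' @return the site table with columns region, gene_id, class,
#'   exonic_func, codon_change, aa_change appended.
#' @export
annotate_sites <- function(sites, models, genome) {
  if (!nrow(sites)) {
    sites$region <- character(0); sites$gene_id <- character(0)
    sites$class <- character(0); sites$exonic_func <- character(0)
    sites$codon_change <- character(0); sites$aa_change <- character(0)
    return(sites)
  }
  reg <- classify_region(sites$chrom, sites$pos, models)
  sites$region <- reg$region
  sites$gene_id <- reg$gene_id
  sites$class <- classify_substitution(sites$ref, sites$alt)
  func <- rep("n/a", nrow(sites))
  codon <- rep(NA_character_, nrow(sites))
  aa <- rep(NA_character_, nrow(sites))
  for (i in which(sites$region == "exonic")) {
    cons <- tryCatch(
      exonic_consequence(sites$chrom[i], sites$pos[i], sites$ref[i],
                         sites$alt[i], models, genome),
      error = function(e) NULL)
    if (!is.null(cons)) {
      func[i] <- cons$exonic_func
      codon[i] <- cons$codon_change
      aa[i] <- cons$aa_change
    }
  }
  sites$exonic_func <- func
  sites$codon_change <- codon
  sites$aa_change <- aa
  sites
}

#' Per-sample annotation tallies
#'
#' Counts and proportions of region labels, editing classes and exonic
#' functions per sample, where a site counts for a sample if that sample
#' detects it (frequency >= `min_editing_level` with a passing depth).
#' Proportions sum to 1 per panel per sample.
#'
#' @param annotated annotated site table from [annotate_sites()].
#' @param sample_sheet cohort sample sheet.
#' @param filter the [filter_config()] used for calling.
#' @return list of three data frames (`region`, `class`, `exonic_func`)
#'   with per-sample counts, proportions, and a `detected` per-sample
#'   site-count vector.
#' @export
summarize_annotations <- function(annotated, sample_sheet,
                                  filter = filter_config()) {
  samples <- sample_sheet$sample
  tally <- function(field, universe) {
    out <- list()
    for (s in samples) {
      freq <- annotated[[paste0(s, "_freq")]]
      alt <- annotated[[paste0(s, "_alt")]]
      ref <- annotated[[paste0(s, "_ref")]]
      det <- !is.na(freq) & freq >= filter$min_editing_level &
        (ref + alt) >= filter$min_depth & alt >= filter$min_alt_depth
      vals <- annotated[[field]][det]
      cnt <- table(factor(vals, levels = universe))
      prop <- if (sum(cnt) > 0) as.numeric(cnt) / sum(cnt)
      else rep(0, length(universe))
      out[[s]] <- data.frame(sample = s, level = universe,
                             count = as.integer(cnt), prop = prop,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  detected <- vapply(samples, function(s) {
    freq <- annotated[[paste0(s, "_freq")]]
    alt <- annotated[[paste0(s, "_alt")]]
    ref <- annotated[[paste0(s, "_ref")]]
    sum(!is.na(freq) & freq >= filter$min_editing_level &
          (ref + alt) >= filter$min_depth & alt >= filter$min_alt_depth)
  }, numeric(1))
  class_universe <- c("C-to-U", "A-to-I",
                      paste0("other:", c("A>C", "A>T", "C>A", "C>G",
                                         "G>C", "G>T", "T>A", "T>G")))
  list(region = tally("region", REGION_PRECEDENCE),
       class = tally("class", class_universe),
       exonic_func = tally("exonic_func",
                           c("synonymous SNV", "nonsynonymous SNV",
                             "stopgain", "stoploss", "n/a")),
       detected = detected)
}
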