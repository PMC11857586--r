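# Synthetic-study generator: genome, gene models, planted editing events,
# expression effects, aligned reads and truth tables. The generator is
# first-class, tested code: every acceptance benchmark in the package runs
# against studies it produces.

#' Default substitution-class mixture for planted editing events
#'
#' Twelve substitution classes. The defaults concentrate 80% of the mass on
#' the two deamination-type editing classes as they appear on the reference
#' forward strand: C-to-U editing shows up as C>T (plus-strand genes) or G>A
#' (minus-strand genes), and A-to-I editing as A>G or T>C. The split between
#' the strand-paired classes follows the dominance of C>T and A>G observed
#' in diatom RNA editing surveys.
#'
#' @return named numeric vector over the 12 classes, summing to 1.
#' @export
default_type_mix <- function() {
  mix <- c(
    "C>T" = 0.31, "A>G" = 0.31, "G>A" = 0.09, "T>C" = 0.09,
    "A>C" = 0.025, "A>T" = 0.025, "C>A" = 0.025, "C>G" = 0.025,
    "G>C" = 0.025, "G>T" = 0.025, "T>A" = 0.025, "T>G" = 0.025
  )
  mix / sum(mix)
}

#' Configuration of a synthetic editing study
#'
#' Bundles every tunable of the generator: genome and gene-model sizing,
#' the editing-site plant (count, class mixture, frequency distribution,
#' fraction and margin of differential sites), the read emitter (depth,
#' dispersion, error rate, read length) and the expression layer
#' (fraction of DE genes and their effect size). Two conditions
#' ("control", "treated") with `n_replicates` each.
#'
#' @param genome_length total genome size in bases (single chromosome).
#' @param n_genes number of non-overlapping genes to place.
#' @param n_replicates biological replicates per condition (>= 2).
#' @param n_editing_sites number of editing sites to plant.
#' @param frac_differential_sites proportion of planted sites whose true
#'   frequency differs between conditions.
#' @param freq_shape1,freq_shape2 Beta parameters of the editing-frequency
#'   distribution (rescaled into `freq_band`).
#' @param freq_band closed interval the planted frequencies live in;
#'   default `c(0.10, 1.00)` mirrors the caller's detection band. Set the
#'   lower end below 0.10 (`allow_subthreshold = TRUE` equivalent) to study
#'   filter sensitivity.
#' @param diff_margin minimum separation of per-condition true frequencies
#'   at differential sites.
#' @param diff_up_fraction fraction of differential sites edited more in
#'   the treated condition.
#' @param type_mix probability vector over the 12 substitution classes,
#'   names like `"C>T"`; must sum to 1.
#' @param mean_depth target per-base read coverage over transcribed spans.
#' @param depth_dispersion negative-binomial dispersion of per-gene read
#'   counts (variance = mu + alpha mu^2).
#' @param seq_error_rate per-base sequencing error probability.
#' @param read_length read length in bases (single-end).
#' @param frac_de_genes proportion of genes differentially expressed.
#' @param de_log2fc absolute expression log2 fold change of DE genes
#'   (direction random per gene).
#' @param frac_ncrna proportion of genes modelled as non-coding.
#' @param abundance_sdlog log-scale SD of per-gene expression levels
#'   (0 = every gene at `mean_depth` coverage).
#' @param frac_intron proportion of genes carrying one intron.
#' @param flank read-through flank in bases: reads (and planted sites)
#'   extend this far beyond annotated gene ends, emulating unannotated
#'   UTRs so upstream/downstream editing is observable.
#' @param intergenic_spacer minimum intergenic gap in bases (>= 2 kb keeps
#'   the 1 kb upstream/downstream windows unambiguous).
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 7e5, n_genes = 200,
                       n_replicates = 3, n_editing_sites = 2000,
                       frac_differential_sites = 0.2,
                       freq_shape1 = 2, freq_shape2 = 2,
                       freq_band = c(0.10, 1.00),
                       diff_margin = 0.3, diff_up_fraction = 0.5,
                       type_mix = default_type_mix(),
                       mean_depth = 30, depth_dispersion = 0.01,
                       seq_error_rate = 0.001, read_length = 100,
                       frac_de_genes = 0.15, de_log2fc = 2,
                       frac_ncrna = 0.1, frac_intron = 0.5,
                       abundance_sdlog = 0.5,
                       flank = 300, intergenic_spacer = 2000,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    n_conditions = 2L, n_replicates = as.integer(n_replicates),
    n_editing_sites = as.integer(n_editing_sites),
    frac_differential_sites = frac_differential_sites,
    freq_shape1 = freq_shape1, freq_shape2 = freq_shape2,
    freq_band = freq_band, diff_margin = diff_margin,
    diff_up_fraction = diff_up_fraction, type_mix = type_mix,
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    seq_error_rate = seq_error_rate, read_length = as.integer(read_length),
    frac_de_genes = frac_de_genes, de_log2fc = de_log2fc,
    frac_ncrna = frac_ncrna, frac_intron = frac_intron,
    abundance_sdlog = abundance_sdlog,
    flank = as.integer(flank),
    intergenic_spacer = as.integer(intergenic_spacer),
    seed = as.integer(seed)
  )
  props <- c(cfg$frac_differential_sites, cfg$frac_de_genes, cfg$frac_ncrna,
             cfg$frac_intron, cfg$seq_error_rate, cfg$diff_up_fraction)
  assert_that(all(props >= 0 & props <= 1), "all proportions must lie in [0, 1]")
  assert_that(abs(sum(cfg$type_mix) - 1) < 1e-8, "type_mix must sum to 1")
  assert_that(all(sort(names(cfg$type_mix)) == sort(names(default_type_mix()))),
              "type_mix must name the 12 substitution classes like 'C>T'")
  assert_that(cfg$n_replicates >= 2, "n_replicates must be >= 2")
  assert_that(cfg$freq_band[1] >= 0 && cfg$freq_band[2] <= 1 &&
                cfg$freq_band[1] < cfg$freq_band[2],
              "freq_band must be an interval within [0, 1]")
  assert_that(cfg$diff_margin > 0 &&
                cfg$diff_margin <= diff(cfg$freq_band),
              "diff_margin must be positive and fit inside freq_band")
  structure(cfg, class = "sim_config")
}

# Per-gene structural draw: strand, biotype, element lengths, intron.
.draw_gene_structure <- function(cfg) {
  biotype <- if (runif(1) < cfg$frac_ncrna) "ncRNA" else "coding"
  strand <- sample(c("+", "-"), 1)
  has_intron <- runif(1) < cfg$frac_intron
  intron_len <- if (has_intron) sample(80:250, 1) else 0L
  if (biotype == "coding") {
    utr5 <- sample(40:150, 1)
    ncod <- sample(60:200, 1)           # internal (non-start, non-stop) codons
    cds_len <- 3L * ncod + 6L
    utr3 <- sample(60:200, 1)
    # intron splits the CDS strictly inside, at nucleotide offset k
    k <- if (has_intron) sample(3:(cds_len - 3L), 1) else NA_integer_
    list(biotype = biotype, strand = strand, utr5 = utr5, cds_len = cds_len,
         utr3 = utr3, intron_len = intron_len, k = k,
         length = utr5 + cds_len + intron_len + utr3)
  } else {
    e1 <- sample(200:600, 1)
    e2 <- if (has_intron) sample(100:400, 1) else 0L
    list(biotype = biotype, strand = strand, e1 = e1, e2 = e2,
         intron_len = intron_len,
         length = e1 + e2 + intron_len)
  }
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

.random_cds <- function(cds_len) {
  ncod <- (cds_len - 6L) / 3L
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  sense_codons <- setdiff(all_codons, STOP_CODONS)
  body <- paste(sample(sense_codons, ncod, replace = TRUE), collapse = "")
  paste0("ATG", body, sample(STOP_CODONS, 1))
}

.random_intron <- function(len) {
  if (len < 4) return(random_dna(len))
  paste0("GT", random_dna(len - 4L), "AG")
}

# Build one gene's sense-orientation sequence plus local (sense 1-based)
# feature intervals; mapping to genomic coordinates happens in the caller.
.build_gene <- function(gs) {
  if (gs$biotype == "coding") {
    cds <- .random_cds(gs$cds_len)
    if (!is.na(gs$k)) {
      seq <- paste0(random_dna(gs$utr5), substr(cds, 1, gs$k),
                    .random_intron(gs$intron_len),
                    substr(cds, gs$k + 1, gs$cds_len), random_dna(gs$utr3))
      ex1_end <- gs$utr5 + gs$k
      in_end <- ex1_end + gs$intron_len
      exons <- rbind(c(1L, ex1_end), c(in_end + 1L, gs$length))
      cds_iv <- rbind(c(gs$utr5 + 1L, ex1_end),
                      c(in_end + 1L, in_end + gs$cds_len - gs$k))
      phase <- c(0L, (3L - gs$k %% 3L) %% 3L)
    } else {
      seq <- paste0(random_dna(gs$utr5), cds, random_dna(gs$utr3))
      exons <- rbind(c(1L, gs$length))
      cds_iv <- rbind(c(gs$utr5 + 1L, gs$utr5 + gs$cds_len))
      phase <- 0L
    }
  } else {
    seq <- NULL
    if (gs$intron_len > 0 && gs$e2 > 0) {
      seq <- paste0(random_dna(gs$e1), .random_intron(gs$intron_len),
                    random_dna(gs$e2))
      exons <- rbind(c(1L, gs$e1),
                     c(gs$e1 + gs$intron_len + 1L, gs$length))
    } else {
      seq <- random_dna(gs$length)
      exons <- rbind(c(1L, gs$length))
    }
    cds_iv <- NULL
    phase <- integer(0)
  }
  list(seq = seq, exons = exons, cds = cds_iv, phase = phase)
}

# local sense interval [a, b] on a gene of length L starting at s -> genomic
.local_to_genomic <- function(a, b, s, L, strand) {
  if (strand == "+") c(s + a - 1L, s + b - 1L) else c(s + L - b, s + L - a)
}

#' Simulate a reference genome with non-overlapping gene models
#'
#' Places `n_genes` genes (both strands, ~10% non-coding, ~50% with one
#' intron) on a single random chromosome, separated by intergenic spacers
#' of at least `intergenic_spacer` bases. Every coding transcript's spliced
#' CDS is a multiple of 3, starts with ATG, ends with a stop codon and has
#' no internal stop.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences) and `models` (a `gene_models` object, see [read_gff3()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  chrom <- "chr1"
  if (n == 0) {
    genome <- setNames(random_dna(config$genome_length), chrom)
    return(list(genome = genome, models = empty_gene_models()))
  }
  structures <- replicate(n, .draw_gene_structure(config), simplify = FALSE)
  lens <- vapply(structures, `[[`, numeric(1), "length")
  spacer <- config$intergenic_spacer
  required <- sum(lens) + (n + 1L) * spacer
  if (config$genome_length < required) {
    stopf(paste0("genome_length %d cannot hold %d genes: need >= %d bases ",
                 "(gene footprints %d + %d spacers of %d)"),
          config$genome_length, n, required, sum(lens), n + 1L, spacer)
  }
  extra <- config$genome_length - required
  gaps <- spacer + as.vector(rmultinom(1, extra, rep(1, n + 1L)))
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + as.integer(lens[i])
  }

  base_seq <- sample(BASES, config$genome_length, replace = TRUE)
  genes <- vector("list", n)
  tx <- vector("list", n)
  exons <- vector("list", n)
  cds <- vector("list", n)
  for (i in seq_len(n)) {
    gs <- structures[[i]]
    built <- .build_gene(gs)
    s <- starts[i]; L <- as.integer(gs$length)
    gseq <- if (gs$strand == "+") built$seq else revcomp(built$seq)
    base_seq[s:(s + L - 1L)] <- strsplit(gseq, "", fixed = TRUE)[[1]]
    gid <- sprintf("gene%04d", i)
    tid <- sprintf("tx%04d", i)
    genes[[i]] <- data.frame(gene_id = gid, seqid = chrom, start = s,
                             end = s + L - 1L, strand = gs$strand,
                             biotype = gs$biotype,
                             stringsAsFactors = FALSE)
    tx[[i]] <- data.frame(tx_id = tid, gene_id = gid, seqid = chrom,
                          start = s, end = s + L - 1L, strand = gs$strand,
                          stringsAsFactors = FALSE)
    ex_g <- t(apply(built$exons, 1, function(ab)
      .local_to_genomic(ab[1], ab[2], s, L, gs$strand)))
    exons[[i]] <- data.frame(tx_id = tid, seqid = chrom,
                             start = ex_g[, 1], end = ex_g[, 2],
                             strand = gs$strand, stringsAsFactors = FALSE)
    if (!is.null(built$cds)) {
      cd_g <- t(apply(built$cds, 1, function(ab)
        .local_to_genomic(ab[1], ab[2], s, L, gs$strand)))
      cds[[i]] <- data.frame(tx_id = tid, seqid = chrom,
                             start = cd_g[, 1], end = cd_g[, 2],
                             strand = gs$strand, phase = built$phase,
                             stringsAsFactors = FALSE)
    }
  }
  models <- gene_models(
    genes = do.call(rbind, genes),
    transcripts = do.call(rbind, tx),
    exons = do.call(rbind, exons),
    cds = if (length(Filter(Negate(is.null), cds)))
      do.call(rbind, Filter(Negate(is.null), cds)) else NULL
  )
  genome <- setNames(paste(base_seq, collapse = ""), chrom)
  list(genome = genome, models = models)
}

# ---------------------------------------------------------------------------
# Editing-site plant

# Independent per-transcript interval scan used for TRUTH region labels.
# Deliberately not the annotate module's classifier, so agreement between
# the two is a meaningful cross-check.
.truth_region <- function(pos, models) {
  g <- models$genes
  hit_any <- which(g$start - 1000L <= pos & g$end + 1000L >= pos)
  if (!length(hit_any)) return(c("intergenic", NA_character_))
  best <- "intergenic"; best_gene <- NA_character_
  rank <- function(lbl) match(lbl, REGION_PRECEDENCE)
  for (gi in hit_any) {
    gid <- g$gene_id[gi]
    txs <- models$transcripts[models$transcripts$gene_id == gid, , drop = FALSE]
    for (ti in seq_len(nrow(txs))) {
      t1 <- txs[ti, ]
      ex <- models$exons[models$exons$tx_id == t1$tx_id, , drop = FALSE]
      cd <- models$cds[models$cds$tx_id == t1$tx_id, , drop = FALSE]
      coding <- nrow(cd) > 0
      lbl <- NULL
      inside <- pos >= t1$start && pos <= t1$end
      in_exon <- any(pos >= ex$start & pos <= ex$end)
      in_cds <- coding && any(pos >= cd$start & pos <= cd$end)
      # splice window: within 2 bases of an exon boundary, on the intron side
      splice <- FALSE
      if (inside && !in_exon && nrow(ex) > 1) {
        bounds <- sort(c(ex$start, ex$end))
        inner <- bounds[-c(1, length(bounds))]
        splice <- any(abs(pos - inner) <= 2)
      }
      if (in_cds) lbl <- "exonic"
      else if (splice) lbl <- "splicing"
      else if (!coding && in_exon) lbl <- "ncRNA_exonic"
      else if (!coding && inside && !in_exon) lbl <- "ncRNA_intronic"
      else if (coding && in_exon && !in_cds) lbl <- "UTR"
      else if (coding && inside && !in_exon) lbl <- "intronic"
      else if (!inside) {
        before <- pos < t1$start && t1$start - pos <= 1000L
        after <- pos > t1$end && pos - t1$end <= 1000L
        if (t1$strand == "+") {
          if (before) lbl <- "upstream" else if (after) lbl <- "downstream"
        } else {
          if (before) lbl <- "downstream" else if (after) lbl <- "upstream"
        }
      }
      if (!is.null(lbl) && rank(lbl) < rank(best)) {
        best <- lbl; best_gene <- gid
      }
    }
  }
  c(best, best_gene)
}

#' Plant editing sites and expression effects; build the truth table
#'
#' Draws `n_editing_sites` distinct positions within gene spans (plus the
#' read-through flank), sampling each site's substitution class from
#' `type_mix` and then a position whose reference base matches the class.
#' Non-differential sites get one true frequency (Beta, rescaled into
#' `freq_band`) shared by both conditions; differential sites get
#' per-condition frequencies separated by at least `diff_margin`. The gene
#' layer draws per-gene abundances and flags `frac_de_genes` of genes as
#' differentially expressed at `de_log2fc`.
#'
#' @param config a [sim_config()].
#' @param genome,models output of [simulate_genome()].
#' @return list of class `truth_table` with `sites` and `genes` data frames.
#' @export
plant_editing_sites <- function(config, genome, models) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  chrom <- names(genome)[1]
  g <- models$genes
  if (is.null(g) || nrow(g) == 0)
    stopf("cannot plant editing sites on an empty annotation")
  win_start <- pmax(1L, g$start - config$flank)
  win_end <- pmin(nchar(genome[[1]]), g$end + config$flank)
  cand_pos <- unlist(mapply(seq.int, win_start, win_end, SIMPLIFY = FALSE))
  cand_gene <- rep(g$gene_id, win_end - win_start + 1L)
  dup <- duplicated(cand_pos)
  cand_pos <- cand_pos[!dup]; cand_gene <- cand_gene[!dup]
  if (config$n_editing_sites > length(cand_pos))
    stopf("n_editing_sites (%d) exceeds available positions (%d)",
          config$n_editing_sites, length(cand_pos))
  cand_ref <- strsplit(genome[[1]], "", fixed = TRUE)[[1]][cand_pos]

  mix <- config$type_mix
  counts <- as.vector(rmultinom(1, config$n_editing_sites, mix))
  names(counts) <- names(mix)
  picked <- integer(0); ref_alt <- character(0)
  for (cls in names(counts)) {
    k <- counts[[cls]]
    if (k == 0) next
    ref_b <- substr(cls, 1, 1)
    pool <- setdiff(which(cand_ref == ref_b), picked)
    if (length(pool) < k)
      stopf("not enough positions with reference base %s for class %s",
            ref_b, cls)
    sel <- sample(pool, k)
    picked <- c(picked, sel)
    ref_alt <- c(ref_alt, rep(cls, k))
  }
  ord <- order(cand_pos[picked])
  picked <- picked[ord]; ref_alt <- ref_alt[ord]
  pos <- cand_pos[picked]
  ref <- substr(ref_alt, 1, 1)
  alt <- substr(ref_alt, 3, 3)
  host <- cand_gene[picked]
  n <- length(pos)

  n_diff <- round(config$frac_differential_sites * n)
  is_diff <- logical(n)
  if (n_diff > 0) is_diff[sample.int(n, n_diff)] <- TRUE
  lo <- config$freq_band[1]; hi <- config$freq_band[2]
  f_base <- lo + (hi - lo) * rbeta(n, config$freq_shape1, config$freq_shape2)
  f_control <- f_base; f_treated <- f_base
  if (n_diff > 0) {
    idx <- which(is_diff)
    m <- config$diff_margin
    f1 <- runif(length(idx), lo, hi - m)
    f2 <- f1 + m
    up <- runif(length(idx)) < config$diff_up_fraction
    f_control[idx] <- ifelse(up, f1, f2)
    f_treated[idx] <- ifelse(up, f2, f1)
  }

  reg <- t(vapply(pos, .truth_region, character(2), models = models))
  region <- reg[, 1]; region_gene <- reg[, 2]

  consequence <- rep(NA_character_, n)
  ex_idx <- which(region == "exonic")
  if (length(ex_idx)) {
    for (i in ex_idx) {
      cons <- tryCatch(
        exonic_consequence(chrom, pos[i], ref[i], alt[i],
                           models, genome),
        error = function(e) NULL)
      if (!is.null(cons)) consequence[i] <- cons$exonic_func
    }
  }

  sites <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    class = ref_alt,
    freq_control = f_control, freq_treated = f_treated,
    is_differential = is_diff,
    gene_id = ifelse(is.na(region_gene), host, region_gene),
    region = region, consequence = consequence,
    stringsAsFactors = FALSE
  )

  # expression layer
  sdl <- config$abundance_sdlog
  a <- rlnorm(nrow(g), meanlog = -sdl^2 / 2, sdlog = sdl)  # E[a] = 1
  is_de <- runif(nrow(g)) < config$frac_de_genes
  de_sign <- sample(c(-1, 1), nrow(g), replace = TRUE)
  lfc <- ifelse(is_de, de_sign * config$de_log2fc, 0)
  span <- g$end - g$start + 1L + 2L * config$flank
  base_reads <- config$mean_depth * span / config$read_length * a
  genes <- data.frame(
    gene_id = g$gene_id,
    abundance = a,
    is_de = is_de,
    de_log2fc = lfc,
    mean_reads_control = base_reads,
    mean_reads_treated = base_reads * 2 ^ lfc,
    stringsAsFactors = FALSE
  )
  structure(list(sites = sites, genes = genes), class = "truth_table")
}

# ---------------------------------------------------------------------------
# Read emission

.mutate_base <- function(seqs, offs, newb) {
  # vectorised single-base surgery on equal-length strings
  paste0(substr(seqs, 1, offs - 1L), newb,
         substr(seqs, offs + 1L, nchar(seqs)))
}

#' Emit aligned single-end reads with planted editing and expression effects
#'
#' For each sample, per-gene read counts are negative-binomial around the
#' truth table's condition mean; read starts are uniform over the gene span
#' plus the read-through flank (pre-mRNA-like coverage: introns are
#' covered, splice junctions are not modelled). Each read covering a
#' planted site carries the alternative allele with that condition's true
#' frequency; independent sequencing errors are added at
#' `seq_error_rate`. Base quality is 35 everywhere except simulated error
#' positions, which get quality 15 so the base-quality filter has
#' something to remove. Output is one coordinate-sorted SAM file per
#' sample.
#'
#' @param config a [sim_config()].
#' @param genome,models output of [simulate_genome()].
#' @param truth output of [plant_editing_sites()].
#' @param dir output directory for the SAM files.
#' @return a data frame sample sheet (sample, path, condition, replicate)
#'   with an attribute `true_counts`: the realised per-gene read-count
#'   matrix (genes x samples).
#' @export
emit_reads <- function(config, genome, models, truth, dir) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  set.seed(config$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- names(genome)[1]
  chrom_len <- nchar(genome[[1]])
  chrom_seq <- genome[[1]]
  rl <- config$read_length
  g <- models$genes
  conds <- rep(c("control", "treated"), each = config$n_replicates)
  reps <- rep(seq_len(config$n_replicates), 2)
  samples <- paste0(conds, "_", reps)
  qual_template <- strrep(rawToChar(as.raw(35L + 33L)), rl)   # Q35
  err_q <- rawToChar(as.raw(15L + 33L))                       # Q15

  site_dt <- truth$sites
  true_counts <- matrix(0L, nrow = nrow(g), ncol = length(samples),
                        dimnames = list(g$gene_id, samples))
  paths <- file.path(dir, paste0(samples, ".sam"))

  for (si in seq_along(samples)) {
    cond <- conds[si]
    recs <- vector("list", nrow(g))
    for (gi in seq_len(nrow(g))) {
      mu <- if (cond == "control") truth$genes$mean_reads_control[gi] else
        truth$genes$mean_reads_treated[gi]
      nreads <- rnbinom(1, mu = mu, size = 1 / config$depth_dispersion)
      true_counts[gi, si] <- nreads
      if (nreads == 0) next
      lo <- max(1L, g$start[gi] - config$flank)
      hi <- min(chrom_len - rl + 1L, g$end[gi] + config$flank - rl + 1L)
      if (hi < lo) next
      st <- lo + sample.int(hi - lo + 1L, nreads, replace = TRUE) - 1L
      seqs <- substring(chrom_seq, st, st + rl - 1L)
      quals <- rep(qual_template, nreads)
      # planted editing within this gene's window
      sidx <- which(site_dt$pos >= lo & site_dt$pos <= hi + rl - 1L)
      for (k in sidx) {
        p <- site_dt$pos[k]
        f <- if (cond == "control") site_dt$freq_control[k] else
          site_dt$freq_treated[k]
        cover <- which(st <= p & st + rl - 1L >= p)
        if (!length(cover)) next
        flip <- cover[runif(length(cover)) < f]
        if (length(flip))
          seqs[flip] <- .mutate_base(seqs[flip], p - st[flip] + 1L,
                                     site_dt$alt[k])
      }
      # sequencing errors
      nb <- nreads * rl
      nerr <- rbinom(1, nb, config$seq_error_rate)
      if (nerr > 0) {
        flat <- sample.int(nb, nerr)
        ridx <- (flat - 1L) %/% rl + 1L
        off <- (flat - 1L) %% rl + 1L
        for (e in seq_len(nerr)) {
          cur <- substr(seqs[ridx[e]], off[e], off[e])
          newb <- sample(setdiff(BASES, cur), 1)
          seqs[ridx[e]] <- .mutate_base(seqs[ridx[e]], off[e], newb)
          quals[ridx[e]] <- .mutate_base(quals[ridx[e]], off[e], err_q)
        }
      }
      recs[[gi]] <- data.frame(pos = st, seq = seqs, qual = quals,
                               stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, Filter(Negate(is.null), recs))
    if (is.null(all)) all <- data.frame(pos = integer(), seq = character(),
                                        qual = character())
    all <- all[order(all$pos), , drop = FALSE]
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
    qn <- sprintf("%s_r%07d", samples[si], seq_len(nrow(all)))
    body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                    qn, chrom, all$pos, rl, all$seq, all$qual)
    writeLines(c(header, body), paths[si])
  }

  sheet <- data.frame(sample = samples, path = paths, condition = conds,
                      replicate = reps, stringsAsFactors = FALSE)
  attr(sheet, "true_counts") <- true_counts
  sheet
}

#' Generate a complete synthetic study on disk
#'
#' Runs [simulate_genome()], [plant_editing_sites()] and [emit_reads()]
#' and serializes everything: `genome.fa`, `genes.gff3`, one SAM per
#' sample, `samples.tsv`, `truth_sites.tsv`, `truth_genes.tsv` and
#' `truth_counts.tsv`. With a fixed seed all outputs are byte-identical
#' across runs.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return invisible list with `config`, `genome`, `models`, `truth`,
#'   `sample_sheet` and all file `paths`.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  truth <- plant_editing_sites(config, sim$genome, sim$models)
  sheet <- emit_reads(config, sim$genome, sim$models, truth, dir)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    sample_sheet = file.path(dir, "samples.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_counts = file.path(dir, "truth_counts.tsv")
  )
  write_fasta(sim$genome, paths$genome)
  write_gff3(sim$models, paths$gff3)
  sheet_rel <- sheet
  sheet_rel$path <- basename(sheet_rel$path)   # keep the sheet relocatable
  write_tsv(sheet_rel, paths$sample_sheet)
  write_tsv(truth$sites, paths$truth_sites)
  write_tsv(truth$genes, paths$truth_genes)
  tc <- attr(sheet, "true_counts")
  write_tsv(data.frame(gene_id = rownames(tc), tc, check.names = FALSE),
            paths$truth_counts)
  invisible(list(config = config, genome = sim$genome, models = sim$models,
                 truth = truth, sample_sheet = sheet, paths = paths))
}
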