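# Editing-site calling from per-sample pileups.
#
# Filters: base quality >= 25 applied inside the pileup engine (low-quality
# calls never enter a column); per-sample site emission needs depth >= 5,
# alt depth >= 3 and frequency in [0.10, 1.00]; cohort retention needs a
# passing observation with frequency >= 0.10 in at least two samples.
# Depth here means ref_count + alt_count after quality filtering, so the
# reported frequency is consistent with the counts the filters saw.

#' Filter configuration for editing-site calling
#'
#' @param min_base_quality minimum Phred base quality for a call to enter
#'   a pileup column.
#' @param min_depth minimum per-sample depth (ref + alt after quality
#'   filtering).
#' @param min_alt_depth minimum per-sample alternative-allele depth.
#' @param frequency_band closed per-sample editing-frequency band.
#' @param min_supporting_samples cohort retention: number of samples that
#'   must pass with frequency >= `min_editing_level`.
#' @param min_editing_level cohort retention frequency floor.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_base_quality = 25L, min_depth = 5L,
                          min_alt_depth = 3L,
                          frequency_band = c(0.10, 1.00),
                          min_supporting_samples = 2L,
                          min_editing_level = 0.10) {
  assert_that(min_depth > 0 && min_alt_depth > 0 && min_base_quality >= 0,
              "thresholds must be positive")
  assert_that(frequency_band[1] >= 0 && frequency_band[2] <= 1 &&
                frequency_band[1] <= frequency_band[2],
              "frequency_band must lie within [0, 1]")
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_depth = as.integer(min_depth),
                 min_alt_depth = as.integer(min_alt_depth),
                 frequency_band = frequency_band,
                 min_supporting_samples = as.integer(min_supporting_samples),
                 min_editing_level = min_editing_level),
            class = "filter_config")
}

#' Build a quality-filtered pileup for one sample
#'
#' Runs [Rsamtools::pileup()] excluding unmapped/secondary/supplementary/
#' duplicate reads, N bases and any call below `min_base_quality`, and
#' spreads the result to one row per covered position with A/C/G/T counts.
#'
#' @param path SAM or BAM file (coordinate-sorted).
#' @param filter a [filter_config()].
#' @param max_depth pileup depth cap per position.
#' @return `data.table` with columns chrom, pos, A, C, G, T.
#' @export
build_pileup <- function(path, filter = filter_config(), max_depth = 10000L) {
  al <- open_alignments(path)
  keep_flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE,
                                      isDuplicate = FALSE)
  pp <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth),
    min_base_quality = filter$min_base_quality,
    min_mapq = 0L, min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE, include_insertions = FALSE)
  res <- Rsamtools::pileup(al$bam,
                           scanBamParam = Rsamtools::ScanBamParam(
                             flag = keep_flag),
                           pileupParam = pp)
  dt <- data.table::as.data.table(res)
  if (!nrow(dt)) {
    out <- data.table::data.table(chrom = character(), pos = integer(),
                                  A = integer(), C = integer(),
                                  G = integer(), T = integer())
    data.table::setkey(out, chrom, pos)
    return(out)
  }
  dt <- dt[dt$nucleotide %in% BASES, ]
  dt$nucleotide <- factor(as.character(dt$nucleotide), levels = BASES)
  wide <- data.table::dcast(dt, seqnames + pos ~ nucleotide,
                            value.var = "count", fill = 0L, drop = FALSE)
  data.table::setnames(wide, "seqnames", "chrom")
  wide$chrom <- as.character(wide$chrom)
  for (b in setdiff(BASES, names(wide))) wide[[b]] <- 0L
  data.table::setcolorder(wide, c("chrom", "pos", BASES))
  data.table::setkey(wide, chrom, pos)
  wide[]
}

#' Call a candidate editing observation from one pileup column
#'
#' The alternative allele is the most frequent non-reference base (ties
#' broken in base order A < C < G < T). An observation is emitted iff
#' depth (ref + alt) >= `min_depth`, alt count >= `min_alt_depth` and
#' frequency = alt / (ref + alt) lies in `frequency_band`.
#'
#' @param counts named integer vector of A/C/G/T counts (quality-filtered).
#' @param ref_base reference base at the position.
#' @param filter a [filter_config()].
#' @return one-row data frame (ref_count, alt, alt_count, depth, freq,
#'   pass, second_alt_count) or NULL when no non-reference base is seen.
#' @export
call_candidate <- function(counts, ref_base, filter = filter_config()) {
  counts <- counts[BASES]
  counts[is.na(counts)] <- 0L
  nonref <- counts
  nonref[ref_base] <- -1L
  alt_i <- which.max(nonref)             # first max = base-order tie-break
  if (nonref[alt_i] <= 0) return(NULL)
  alt <- BASES[alt_i]
  ref_count <- as.integer(counts[ref_base])
  alt_count <- as.integer(counts[alt_i])
  depth <- ref_count + alt_count
  freq <- alt_count / depth
  second <- sort(nonref[-alt_i], decreasing = TRUE)[1]
  pass <- depth >= filter$min_depth &&
    alt_count >= filter$min_alt_depth &&
    freq >= filter$frequency_band[1] && freq <= filter$frequency_band[2]
  data.frame(ref = ref_base, ref_count = ref_count, alt = alt,
             alt_count = alt_count, depth = depth, freq = freq,
             pass = pass, second_alt_count = as.integer(max(second, 0L)),
             stringsAsFactors = FALSE)
}

# Vectorised per-sample observation table from a wide pileup.
.sample_observations <- function(wide, genome, filter) {
  if (!nrow(wide)) {
    return(data.table::data.table(
      chrom = character(), pos = integer(), ref = character(),
      ref_count = integer(), alt = character(), alt_count = integer(),
      depth = integer(), freq = numeric(), pass = logical(),
      second_alt_count = integer()))
  }
  unknown <- setdiff(unique(wide$chrom), names(genome))
  if (length(unknown))
    stopf("alignments reference unknown chromosome(s): %s",
          paste(unknown, collapse = ", "))
  m <- as.matrix(wide[, BASES, with = FALSE])
  ref <- character(nrow(wide))
  for (ch in unique(wide$chrom)) {
    i <- which(wide$chrom == ch)
    chars <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    ref[i] <- chars[wide$pos[i]]
  }
  ref_i <- match(ref, BASES)
  keep <- !is.na(ref_i)                   # reference N etc. never called
  nonref <- m
  nonref[cbind(seq_len(nrow(m)), ref_i)] <- -1L
  alt_i <- max.col(nonref, ties.method = "first")
  alt_count <- nonref[cbind(seq_len(nrow(m)), alt_i)]
  ref_count <- m[cbind(seq_len(nrow(m)), ref_i)]
  # second-best non-reference count, for the multi-allelic ambiguity flag
  tmp <- nonref
  tmp[cbind(seq_len(nrow(m)), alt_i)] <- -1L
  second <- tmp[cbind(seq_len(nrow(m)),
                      max.col(tmp, ties.method = "first"))]
  obs <- data.table::data.table(
    chrom = wide$chrom, pos = wide$pos, ref = ref,
    ref_count = as.integer(ref_count), alt = BASES[alt_i],
    alt_count = as.integer(alt_count),
    second_alt_count = as.integer(pmax(second, 0L)))
  obs <- obs[keep & obs$alt_count > 0, ]
  obs$depth <- obs$ref_count + obs$alt_count
  obs$freq <- obs$alt_count / obs$depth
  obs$pass <- obs$depth >= filter$min_depth &
    obs$alt_count >= filter$min_alt_depth &
    obs$freq >= filter$frequency_band[1] &
    obs$freq <= filter$frequency_band[2]
  obs
}

#' Merge per-sample observations into cohort editing sites
#'
#' A site keyed by (chrom, pos, alt) is retained iff at least
#' `min_supporting_samples` samples have a passing observation with
#' frequency >= `min_editing_level`. For retained sites, ref/alt counts
#' are filled for every sample by re-querying the pileups, so zero-alt
#' samples appear with their true depth.
#'
#' @param observations named list of per-sample observation tables.
#' @param pileups named list of per-sample wide pileups (same names).
#' @param genome named character vector from [read_fasta()].
#' @param filter a [filter_config()].
#' @return data frame of retained sites (one row per site, per-sample
#'   `<sample>_ref` / `<sample>_alt` / `<sample>_freq` columns, plus
#'   `n_supporting` and `ambiguous`).
#' @export
merge_cohort <- function(observations, pileups, genome,
                         filter = filter_config()) {
  samples <- names(observations)
  if (length(samples) < 2)
    stopf("cohort calling needs at least 2 samples, got %d", length(samples))
  supp <- data.table::rbindlist(lapply(samples, function(s) {
    o <- observations[[s]]
    o <- o[o$pass & o$freq >= filter$min_editing_level, ]
    if (!nrow(o)) return(NULL)
    data.table::data.table(chrom = o$chrom, pos = o$pos, ref = o$ref,
                           alt = o$alt,
                           ambiguous = o$second_alt_count >=
                             filter$min_alt_depth)
  }))
  if (is.null(supp) || !nrow(supp)) {
    return(.empty_site_table(samples))
  }
  keyed <- supp[, list(n_supporting = .N, ambiguous = any(ambiguous)),
                by = c("chrom", "pos", "ref", "alt")]
  keyed <- keyed[keyed$n_supporting >= filter$min_supporting_samples, ]
  if (!nrow(keyed)) return(.empty_site_table(samples))
  data.table::setorderv(keyed, c("chrom", "pos", "alt"))

  out <- data.frame(chrom = keyed$chrom, pos = keyed$pos, ref = keyed$ref,
                    alt = keyed$alt, n_supporting = keyed$n_supporting,
                    ambiguous = keyed$ambiguous, stringsAsFactors = FALSE)
  for (s in samples) {
    w <- pileups[[s]]
    idx <- w[data.table::data.table(chrom = keyed$chrom, pos = keyed$pos),
             on = c("chrom", "pos")]
    mat <- as.matrix(idx[, BASES, with = FALSE])
    mat[is.na(mat)] <- 0L
    rc <- mat[cbind(seq_len(nrow(mat)), match(keyed$ref, BASES))]
    ac <- mat[cbind(seq_len(nrow(mat)), match(keyed$alt, BASES))]
    depth <- rc + ac
    out[[paste0(s, "_ref")]] <- as.integer(rc)
    out[[paste0(s, "_alt")]] <- as.integer(ac)
    out[[paste0(s, "_freq")]] <- ifelse(depth > 0, ac / depth, NA_real_)
  }
  out
}

.empty_site_table <- function(samples) {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), n_supporting = integer(),
                    ambiguous = logical(), stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0(s, "_ref")]] <- integer()
    out[[paste0(s, "_alt")]] <- integer()
    out[[paste0(s, "_freq")]] <- numeric()
  }
  out
}

#' Call editing sites across a cohort
#'
#' End-to-end caller: per-sample quality-filtered pileups, per-sample
#' candidate observations, cohort retention. Deterministic: the result
#' depends only on the alignment contents, never on read order.
#'
#' @param sample_sheet data frame with sample/path/condition/replicate
#'   (see [read_sample_sheet()]).
#' @param genome named character vector from [read_fasta()].
#' @param filter a [filter_config()].
#' @param keep_pileups return the per-sample pileups too (memory-heavy).
#' @return list with `sites` (retained cohort site table),
#'   `observations`, `filter`, `log` (per-sample candidate and rejection
#'   counts) and optionally `pileups`.
#' @export
call_editing_sites <- function(sample_sheet, genome,
                               filter = filter_config(),
                               keep_pileups = FALSE) {
  samples <- sample_sheet$sample
  pileups <- list(); observations <- list(); log <- list()
  for (i in seq_along(samples)) {
    w <- build_pileup(sample_sheet$path[i], filter)
    o <- .sample_observations(w, genome, filter)
    pileups[[samples[i]]] <- w
    observations[[samples[i]]] <- o
    log[[samples[i]]] <- c(
      candidates = nrow(o),
      fail_depth = sum(o$depth < filter$min_depth),
      fail_alt = sum(o$alt_count < filter$min_alt_depth),
      fail_band = sum(o$freq < filter$frequency_band[1] |
                        o$freq > filter$frequency_band[2]),
      passing = sum(o$pass))
  }
  sites <- merge_cohort(observations, pileups, genome, filter)
  res <- list(sites = sites, observations = observations,
              filter = filter, log = log)
  if (keep_pileups) res$pileups <- pileups
  res
}

#' Editing-frequency matrix and per-condition means
#'
#' @param sites retained site table from [merge_cohort()].
#' @param sample_sheet cohort sample sheet.
#' @return list with `freq` (sites x samples matrix, NA where depth 0),
#'   `mean_control`, `mean_treated` (NA-aware per-site means) and
#'   `all_missing` flags per condition.
#' @export
frequency_matrix <- function(sites, sample_sheet) {
  samples <- sample_sheet$sample
  freq <- as.matrix(sites[, paste0(samples, "_freq"), drop = FALSE])
  colnames(freq) <- samples
  rownames(freq) <- site_key(sites)
  grp <- function(cond) {
    cols <- samples[sample_sheet$condition == cond]
    sub <- freq[, cols, drop = FALSE]
    means <- rowMeans(sub, na.rm = TRUE)
    means[is.nan(means)] <- NA_real_
    means
  }
  mc <- grp("control"); mt <- grp("treated")
  list(freq = freq, mean_control = mc, mean_treated = mt,
       all_missing_control = is.na(mc), all_missing_treated = is.na(mt))
}

#' Stable site identifier "chrom:pos:ref>alt"
#' @param sites site table.
#' @export
site_key <- function(sites) {
  sprintf("%s:%d:%s>%s", sites$chrom, sites$pos, sites$ref, sites$alt)
}
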