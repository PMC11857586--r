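# Independent oracles. Each reimplements the checked quantity by a route
# the package does not use: plain-text SAM recounting, label painting,
# closed forms, exhaustive enumeration.

# --- naive pileup + caller oracle (reads SAM text directly) --------------

oracle_pileup <- function(sam_path, min_bq = 25L) {
  lines <- readLines(sam_path)
  lines <- lines[!grepl("^@", lines)]
  tal <- new.env(parent = emptyenv())
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (bitwAnd(as.integer(f[2]), 4L) != 0) next  # unmapped
    pos <- as.integer(f[4]); seq <- f[10]; qual <- f[11]
    qs <- utf8ToInt(qual) - 33L
    bs <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (i in seq_along(bs)) {
      if (qs[i] < min_bq || bs[i] == "N") next
      key <- as.character(pos + i - 1L)
      cur <- if (exists(key, envir = tal)) get(key, envir = tal) else
        c(A = 0L, C = 0L, G = 0L, T = 0L)
      cur[bs[i]] <- cur[bs[i]] + 1L
      assign(key, cur, envir = tal)
    }
  }
  keys <- as.integer(ls(tal))
  keys <- sort(keys)
  m <- t(vapply(as.character(keys), function(k) get(k, envir = tal),
                integer(4)))
  data.frame(pos = keys, A = m[, "A"], C = m[, "C"], G = m[, "G"],
             T = m[, "T"])
}

# Full cohort caller oracle on SAM text; mirrors the documented filter
# semantics with independent code.
oracle_call <- function(sam_paths, genome_str, chrom = "chr1",
                        min_bq = 25L, min_depth = 5L, min_alt = 3L,
                        band = c(0.10, 1.00), min_samples = 2L,
                        min_level = 0.10) {
  piles <- lapply(sam_paths, oracle_pileup, min_bq = min_bq)
  refchars <- strsplit(genome_str, "", fixed = TRUE)[[1]]
  obs <- list()
  for (s in names(piles)) {
    p <- piles[[s]]
    for (i in seq_len(nrow(p))) {
      ref <- refchars[p$pos[i]]
      if (!ref %in% c("A", "C", "G", "T")) next
      cnt <- c(A = p$A[i], C = p$C[i], G = p$G[i], T = p$T[i])
      nonref <- cnt[setdiff(names(cnt), ref)]
      if (max(nonref) == 0) next
      alt <- names(nonref)[which.max(nonref)]    # first max: A<C<G<T order
      depth <- cnt[[ref]] + nonref[[alt]]
      freq <- nonref[[alt]] / depth
      if (depth >= min_depth && nonref[[alt]] >= min_alt &&
          freq >= band[1] && freq <= band[2] && freq >= min_level) {
        obs[[length(obs) + 1]] <- data.frame(
          sample = s, pos = p$pos[i], ref = ref, alt = alt)
      }
    }
  }
  if (!length(obs)) return(data.frame(pos = integer(), ref = character(),
                                      alt = character()))
  ob <- do.call(rbind, obs)
  keys <- paste(ob$pos, ob$alt)
  keep <- names(which(table(keys) >= min_samples))
  out <- unique(ob[paste(ob$pos, ob$alt) %in% keep,
                   c("pos", "ref", "alt")])
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  # per-sample counts for retained sites
  for (s in names(piles)) {
    p <- piles[[s]]
    idx <- match(out$pos, p$pos)
    cnt <- function(base, j) {
      v <- p[[base]][idx[j]]
      if (is.na(idx[j])) 0L else v
    }
    rc <- ac <- integer(nrow(out))
    for (j in seq_len(nrow(out))) {
      rc[j] <- cnt(out$ref[j], j)
      ac[j] <- cnt(out$alt[j], j)
    }
    out[[paste0(s, "_ref")]] <- rc
    out[[paste0(s, "_alt")]] <- ac
  }
  out
}

# --- region label painting oracle ----------------------------------------

oracle_regions <- function(models, genome_len) {
  lab <- rep("intergenic", genome_len)
  paint <- function(iv, value) {
    for (k in seq_len(nrow(iv))) {
      a <- max(1, iv$start[k]); b <- min(genome_len, iv$end[k])
      if (a <= b) lab[a:b] <<- value
    }
  }
  tx <- models$transcripts
  coding_tx <- unique(models$cds$tx_id)
  # ascending precedence: later paints overwrite earlier ones
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i, ]
    if (t1$strand == "+") {
      paint(data.frame(start = t1$end + 1, end = t1$end + 1000),
            "downstream")
    } else {
      paint(data.frame(start = t1$start - 1000, end = t1$start - 1),
            "downstream")
    }
  }
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i, ]
    if (t1$strand == "+") {
      paint(data.frame(start = t1$start - 1000, end = t1$start - 1),
            "upstream")
    } else {
      paint(data.frame(start = t1$end + 1, end = t1$end + 1000), "upstream")
    }
  }
  introns_of <- function(t1) {
    ex <- models$exons[models$exons$tx_id == t1$tx_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) return(NULL)
    data.frame(start = head(ex$end, -1) + 1, end = tail(ex$start, -1) - 1)
  }
  for (i in seq_len(nrow(tx))) {        # coding introns
    t1 <- tx[i, ]
    if (!t1$tx_id %in% coding_tx) next
    iv <- introns_of(t1)
    if (!is.null(iv)) paint(iv, "intronic")
  }
  for (i in seq_len(nrow(tx))) {        # UTR: exon minus CDS on coding tx
    t1 <- tx[i, ]
    if (!t1$tx_id %in% coding_tx) next
    ex <- models$exons[models$exons$tx_id == t1$tx_id, , drop = FALSE]
    cd <- models$cds[models$cds$tx_id == t1$tx_id, , drop = FALSE]
    in_cds <- rep(FALSE, genome_len)
    for (k in seq_len(nrow(cd))) in_cds[cd$start[k]:cd$end[k]] <- TRUE
    for (k in seq_len(nrow(ex))) {
      span <- ex$start[k]:ex$end[k]
      utr <- span[!in_cds[span]]
      if (length(utr)) lab[utr] <- "UTR"
    }
  }
  for (i in seq_len(nrow(tx))) {        # ncRNA intron then exon
    t1 <- tx[i, ]
    if (t1$tx_id %in% coding_tx) next
    iv <- introns_of(t1)
    if (!is.null(iv)) paint(iv, "ncRNA_intronic")
  }
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i, ]
    if (t1$tx_id %in% coding_tx) next
    ex <- models$exons[models$exons$tx_id == t1$tx_id, , drop = FALSE]
    paint(ex, "ncRNA_exonic")
  }
  for (i in seq_len(nrow(tx))) {        # splicing windows (any transcript)
    t1 <- tx[i, ]
    iv <- introns_of(t1)
    if (is.null(iv)) next
    for (k in seq_len(nrow(iv))) {
      w <- c(iv$start[k]:min(iv$start[k] + 1, iv$end[k]),
             max(iv$end[k] - 1, iv$start[k]):iv$end[k])
      lab[unique(w)] <- "splicing"
    }
  }
  cd <- models$cds
  if (nrow(cd)) paint(cd, "exonic")
  lab
}

# --- closed-form / enumeration oracles ------------------------------------

oracle_bh <- function(p) {
  ok <- which(!is.na(p))
  m <- length(ok)
  out <- rep(NA_real_, length(p))
  if (!m) return(out)
  ord <- order(p[ok])
  sorted <- p[ok][ord]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out[ok][ord] <- adj
  out
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

oracle_venn3 <- function(a, b, c) {
  u <- unique(c(a, b, c))
  pat <- vapply(u, function(e)
    paste0(as.integer(e %in% a), as.integer(e %in% b),
           as.integer(e %in% c)), character(1))
  tab <- table(factor(pat, levels = c("100", "010", "001", "110",
                                      "101", "011", "111")))
  setNames(as.integer(tab),
           c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC"))
}

# translation oracle via seqinr (independent of Biostrings)
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}
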