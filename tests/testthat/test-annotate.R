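# Annotation: substitution classes, region precedence vs painting oracle,
# exhaustive consequence enumeration, strand invariance, tallies.

test_that("substitution classes map deamination pairs and residuals", {
  expect_equal(classify_substitution("C", "T"), "C-to-U")
  expect_equal(classify_substitution("G", "A"), "C-to-U")
  expect_equal(classify_substitution("A", "G"), "A-to-I")
  expect_equal(classify_substitution("T", "C"), "A-to-I")
  expect_equal(classify_substitution("A", "C"), "other:A>C")
  expect_equal(classify_substitution("T", "A"), "other:T>A")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("N", "A"), "must be")
  # all 12 classes exist and are distinct
  pairs <- expand.grid(r = c("A", "C", "G", "T"), a = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  expect_equal(length(unique(classify_substitution(pairs$r, pairs$a))), 10)
  # 12 substitutions collapse into 10 labels (2 pairs + 8 residuals)
})

test_that("region labels equal the painting oracle on random positions", {
  st <- small_study()
  lab_oracle <- oracle_regions(st$models, nchar(st$genome[[1]]))
  set.seed(99)
  pos <- sample.int(nchar(st$genome[[1]]), 400)
  got <- classify_region(rep("chr1", length(pos)), pos, st$models)
  expect_equal(got$region, lab_oracle[pos])
})

test_that("region precedence window rules hold on a hand-built gene", {
  models <- gene_models(
    genes = data.frame(gene_id = "g1", seqid = "chr1", start = 2001L,
                       end = 2900L, strand = "+", biotype = "coding"),
    transcripts = data.frame(tx_id = "t1", gene_id = "g1", seqid = "chr1",
                             start = 2001L, end = 2900L, strand = "+"),
    exons = data.frame(tx_id = "t1", seqid = "chr1",
                       start = c(2001L, 2501L), end = c(2300L, 2900L),
                       strand = "+"),
    cds = data.frame(tx_id = "t1", seqid = "chr1",
                     start = c(2101L, 2501L), end = c(2300L, 2700L),
                     strand = "+", phase = c(0L, 1L))
  )
  cases <- list(
    c(2200, "exonic"), c(2050, "UTR"), c(2800, "UTR"),
    c(2301, "splicing"), c(2302, "splicing"), c(2499, "splicing"),
    c(2400, "intronic"), c(1500, "upstream"), c(3400, "downstream"),
    c(950, "intergenic")
  )
  for (cs in cases) {
    got <- classify_region("chr1", as.integer(cs[1]), models)
    expect_equal(got$region, cs[2], label = paste("pos", cs[1]))
  }
  # same gene on the minus strand flips the flank labels
  models$genes$strand <- models$transcripts$strand <-
    models$exons$strand <- models$cds$strand <- "-"
  expect_equal(classify_region("chr1", 1500L, models)$region, "downstream")
  expect_equal(classify_region("chr1", 3400L, models)$region, "upstream")
})

test_that("all 576 single-base codon substitutions label correctly", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  n <- 0
  for (codon in codons) {
    for (off in 1:3) {
      for (alt in setdiff(bases, substr(codon, off, off))) {
        # one-gene genome: 10 bp pad + ATG + codon + TAA + 10 bp pad
        cds <- paste0("ATG", codon, "TAA")
        geno <- setNames(paste0(strrep("G", 10), cds, strrep("G", 10)),
                         "chr1")
        models <- gene_models(
          genes = data.frame(gene_id = "g", seqid = "chr1", start = 11L,
                             end = 19L, strand = "+", biotype = "coding"),
          transcripts = data.frame(tx_id = "t", gene_id = "g",
                                   seqid = "chr1", start = 11L, end = 19L,
                                   strand = "+"),
          exons = data.frame(tx_id = "t", seqid = "chr1", start = 11L,
                             end = 19L, strand = "+"),
          cds = data.frame(tx_id = "t", seqid = "chr1", start = 11L,
                           end = 19L, strand = "+", phase = 0L)
        )
        pos <- 13L + off
        ref <- substr(codon, off, off)
        got <- exonic_consequence("chr1", pos, ref, alt, models, geno)
        codon_alt <- codon
        substr(codon_alt, off, off) <- alt
        aa_ref <- oracle_translate(codon)
        aa_alt <- oracle_translate(codon_alt)
        want <- if (aa_ref == aa_alt) "synonymous SNV"
        else if (aa_ref != "*" && aa_alt == "*") "stopgain"
        else if (aa_ref == "*" && aa_alt != "*") "stoploss"
        else "nonsynonymous SNV"
        expect_equal(got$exonic_func, want,
                     label = paste(codon, off, alt))
        n <- n + 1
      }
    }
  }
  expect_equal(n, 576)
})

test_that("consequences are invariant under genome reverse-complement", {
  st <- small_study()
  L <- nchar(st$genome[[1]])
  exonic <- st$truth$sites[st$truth$sites$region == "exonic", ]
  exonic <- exonic[seq_len(min(40, nrow(exonic))), ]
  # mirror genome and models
  flip <- function(x) L - x + 1L
  rc_genome <- setNames(revcomp(st$genome[[1]]), "chr1")
  m <- st$models
  sw <- function(df) {
    s <- df$start; df$start <- flip(df$end); df$end <- flip(s)
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  m2 <- gene_models(sw(m$genes), sw(m$transcripts), sw(m$exons), sw(m$cds))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(exonic))) {
    a <- exonic_consequence(exonic$chrom[i], exonic$pos[i], exonic$ref[i],
                            exonic$alt[i], st$models, st$genome)
    b <- exonic_consequence(exonic$chrom[i], flip(exonic$pos[i]),
                            comp[[exonic$ref[i]]], comp[[exonic$alt[i]]],
                            m2, rc_genome)
    expect_equal(b$exonic_func, a$exonic_func)
    expect_equal(b$aa_change, a$aa_change)
  }
})

test_that("annotation tallies give per-sample proportions that sum to 1", {
  ck <- small_called()
  ann <- annotate_sites(ck$called$sites, ck$study$models, ck$genome)
  expect_true(all(ann$exonic_func[ann$region != "exonic"] == "n/a"))
  summ <- summarize_annotations(ann, ck$sheet)
  for (s in ck$sheet$sample) {
    pr <- summ$region$prop[summ$region$sample == s]
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    pc <- summ$class$prop[summ$class$sample == s]
    expect_equal(sum(pc), 1, tolerance = 1e-9)
  }
  # empty site table must not divide by zero
  empty <- ck$called$sites[0, ]
  ann0 <- annotate_sites(empty, ck$study$models, ck$genome)
  s0 <- summarize_annotations(ann0, ck$sheet)
  expect_true(all(s0$region$count == 0))
  expect_true(all(s0$region$prop == 0))
})
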