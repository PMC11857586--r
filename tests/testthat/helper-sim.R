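# Shared fixtures: small synthetic studies, memoized per test run.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(name, config) {
  if (!exists(name, envir = .study_cache)) {
    dir <- file.path(tempdir(), paste0("dreseq_", name))
    assign(name, simulate_study(config, dir), envir = .study_cache)
  }
  get(name, envir = .study_cache)
}

tiny_config <- function(...) {
  args <- list(genome_length = 60000, n_genes = 12, n_editing_sites = 120,
               seed = 5)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# the small cohort most tests share
small_study <- function() cached_study("small", tiny_config())

small_called <- function() {
  if (!exists("small_called", envir = .study_cache)) {
    st <- small_study()
    sheet <- read_sample_sheet(st$paths$sample_sheet)
    genome <- read_fasta(st$paths$genome)
    res <- call_editing_sites(sheet, genome)
    assign("small_called",
           list(study = st, sheet = sheet, genome = genome, called = res),
           envir = .study_cache)
  }
  get("small_called", envir = .study_cache)
}

truth_site_keys <- function(truth_sites) {
  sprintf("%s:%d:%s>%s", truth_sites$chrom, truth_sites$pos,
          truth_sites$ref, truth_sites$alt)
}
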