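# in-code fixtures shared across test files

toy_stockholm <- function(path) {
  writeLines(c(
    "# STOCKHOLM 1.0",
    "#=GF AC PF_TOY",
    "P1/1-4   AC-DE",
    "P2/10-13 A-CDE",
    "P3/5-9   ACCDE",
    "#=GC RF  xx.xx",
    "//"), path)
  path
}

# single-exon plus-strand transcript starting at genomic position offset + 1
make_tx <- function(cds, id = "TX1", gene = "G1", protein = id,
                    chrom = "chr1", strand = "+", offset = 1000L,
                    exons = NULL, flank5 = NULL, flank3 = NULL) {
  if (is.null(exons)) {
    exons <- tibble::tibble(start = offset + 1L,
                            end = offset + nchar(cds))
  }
  tx <- tibble::tibble(transcript_id = id, gene_id = gene, protein_id = protein,
                       chrom = chrom, strand = strand, cds_seq = cds,
                       exons = list(exons))
  if (!is.null(flank5)) tx$flank5 <- flank5
  if (!is.null(flank3)) tx$flank3 <- flank3
  tx
}

# random CDS with clean translation: start codon, no internal stop, final stop
random_cds <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# independent consequence oracle: mutate each base, re-translate the whole
# CDS with Biostrings, and read the classification off the protein diff
oracle_consequences <- function(cds) {
  L <- nchar(cds)
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
  out <- list()
  muts <- list()
  for (i in seq_len(L)) {
    ref <- substr(cds, i, i)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mut <- cds
      substr(mut, i, i) <- alt
      muts[[length(muts) + 1]] <- list(cds_pos = i, alt = alt, seq = mut)
    }
  }
  prots <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(vapply(muts, `[[`, character(1), "seq")),
    no.init.codon = TRUE))
  purrr::map_dfr(seq_along(muts), function(j) {
    m <- muts[[j]]
    codon <- (m$cds_pos + 2L) %/% 3L
    r <- substr(aa_ref, codon, codon)
    a <- substr(prots[[j]], codon, codon)
    cons <- if (r == a) "synonymous"
      else if (codon == 1) "start_lost"
      else if (a == "*") "nonsense"
      else if (r == "*") "stop_lost"
      else "missense"
    tibble::tibble(cds_pos = m$cds_pos, alt_coding = m$alt, consequence = cons)
  })
}

# uniform rate table (all 192 pairs, mu = value)
uniform_rate_table <- function(mu = 1) {
  ctx <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste, collapse = "")
  out <- tidyr::expand_grid(context = ctx, alt = c("A", "C", "G", "T"))
  out <- out[substr(out$context, 2, 2) != out$alt, ]
  out$methyl_level <- 0L
  out$mu <- mu
  out
}

# one shared small simulated universe per test run (built lazily)
.shared <- new.env(parent = emptyenv())

shared_ref <- function() {
  if (is.null(.shared$ref)) {
    .shared$ref <- hmcscore::sim_reference(
      hmcscore::sim_config(seed = 42, cohort_scale = 20))
  }
  .shared$ref
}

shared_null_ref <- function() {
  if (is.null(.shared$null_ref)) {
    .shared$null_ref <- hmcscore::sim_reference(
      hmcscore::sim_config(seed = 43, cohort_scale = 20,
                           selection_profile = "null"))
  }
  .shared$null_ref
}

# deep-cohort regime: large families keep per-variant expectation << 1 while
# per-column expectation sits near 50
shared_e50 <- function() {
  if (is.null(.shared$e50)) {
    ref <- hmcscore::sim_reference(
      hmcscore::sim_config(seed = 31, n_families = 3,
                           copies_per_family = c(50, 60),
                           columns_per_family = c(25, 35), cohort_scale = 50,
                           selection_profile = function(n) rep(0.5, n)))
    .shared$e50 <- list(ref = ref,
                        res = run_shared_pipeline(ref, cohort_seed = 311))
  }
  .shared$e50
}

shared_pipeline <- function() {
  if (is.null(.shared$pipe)) {
    .shared$pipe <- run_shared_pipeline(shared_ref(), cohort_seed = 301)
  }
  .shared$pipe
}

run_shared_pipeline <- function(ref, cohort_seed = NULL) {
  obs <- hmcscore::sim_cohort(ref, seed = cohort_seed)
  hmcscore::hmc_pipeline(ref$transcripts, ref$alignments, obs,
                         ref$rate_table, coverage = ref$coverage,
                         methylation = ref$methylation)
}
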