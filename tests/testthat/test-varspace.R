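test_that("every CDS base yields exactly three possible SNVs", {
  snvs <- enumerate_snvs(make_tx("ATG"))
  expect_equal(nrow(snvs), 9)
  expect_true(all(snvs$ref != snvs$alt))
  expect_equal(as.vector(table(snvs$cds_pos)), rep(3L, 3))
})

test_that("consequences match the exhaustive re-translation oracle", {
  cds <- "ATGGCTTAA"
  got <- enumerate_snvs(make_tx(cds)) |>
    dplyr::select(cds_pos, alt_coding, consequence)
  want <- oracle_consequences(cds)
  expect_equal(dplyr::arrange(got, cds_pos, alt_coding),
               dplyr::arrange(want, cds_pos, alt_coding))

  # partition is exhaustive and disjoint: classes sum to 3L
  set.seed(11)
  for (i in 1:3) {
    cds_i <- random_cds(sample(5:12, 1))
    snvs <- enumerate_snvs(make_tx(cds_i))
    expect_equal(nrow(snvs), 3 * nchar(cds_i))
    expect_true(all(snvs$consequence %in%
      c("missense", "synonymous", "nonsense", "stop_lost", "start_lost")))
    oracle <- oracle_consequences(cds_i)
    expect_equal(
      snvs |> dplyr::select(cds_pos, alt_coding, consequence) |>
        dplyr::arrange(cds_pos, alt_coding),
      dplyr::arrange(oracle, cds_pos, alt_coding))
  }
})

test_that("minus-strand transcripts mirror the plus-strand enumeration", {
  set.seed(21)
  cds <- random_cds(8)
  plus <- enumerate_snvs(make_tx(cds, strand = "+"))
  minus <- enumerate_snvs(make_tx(cds, strand = "-", id = "TXm"))
  # same coding-strand content: identical consequence multisets
  expect_equal(table(plus$consequence), table(minus$consequence))
  expect_equal(plus$context, minus$context)
  # genomic ref is the complement, positions run in reverse
  expect_equal(minus$ref, chartr("ACGT", "TGCA", plus$ref))
  expect_equal(minus$pos, rev(plus$pos))

  # context equals reverse complement of the genomic plus-strand window
  genome_plus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds)))  # single exon: genomic == revcomp(cds)
  L <- nchar(cds)
  interior <- minus |> dplyr::filter(cds_pos > 1, cds_pos < L)
  win <- substr(rep(genome_plus, nrow(interior)),
                interior$pos - 1001L, interior$pos - 999L)
  expect_equal(interior$context,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(win))))
})

test_that("trinucleotide context reads off the coding strand with N edges", {
  tx <- make_tx("ATGGCT")
  expect_equal(trinucleotide_context(tx, 2), "ATG")
  expect_equal(trinucleotide_context(tx, 1), "NAT")
  snvs <- enumerate_snvs(tx)
  expect_false(any(snvs$assessable[snvs$cds_pos %in% c(1, 6)]))

  # provided flanks replace the N and the variant stays assessable
  tx_fl <- make_tx("ATGGCT", flank5 = "CCCCC", flank3 = "GGGGG")
  expect_equal(trinucleotide_context(tx_fl, 1), "CAT")
  expect_equal(trinucleotide_context(tx_fl, 6), "CTG")
  expect_true(all(enumerate_snvs(tx_fl)$assessable))
})

test_that("rarity filter separates absent, rare and common alleles", {
  snvs <- enumerate_snvs(make_tx("ATGGCTTAA"))
  obs <- tibble::tibble(
    chrom = "chr1", pos = c(1004L, 1005L, 1006L), ref = c("G", "C", "T"),
    alt = c("A", "T", "A"), af = c(0, 0.0005, 0.002), passes_filters = TRUE)
  out <- apply_rarity_filter(snvs, obs)
  k <- function(p, a) which(out$pos == p & out$alt == a)
  expect_false(out$observed_rare[k(1004, "A")])   # AF 0: absent
  expect_true(out$assessable[k(1004, "A")])
  expect_true(out$observed_rare[k(1005, "T")])    # AF 0.0005 < 0.1%
  expect_false(out$observed_rare[k(1006, "A")])   # AF 0.002: common
  expect_false(out$assessable[k(1006, "A")])      # excluded from both sides
  expect_true(all(out$assessable[-c(k(1006, "A"))] ==
                    snvs$assessable[-c(k(1006, "A"))]))

  dup <- dplyr::bind_rows(obs, obs[2, ] |> dplyr::mutate(af = 0.0001))
  expect_warning(out2 <- apply_rarity_filter(snvs, dup), "duplicated")
  expect_equal(out2$af[k(1005, "T")], 0.0005)  # max AF kept
})

test_that("meta-position join annotates by codon and skips insert columns", {
  path <- withr::local_tempfile(fileext = ".sto")
  toy_stockholm(path)
  meta <- build_meta_positions(read_alignment(path))
  # P2 covers residues 10-13 mapping to columns 1,4,5 (11 is insert-only)
  cds <- paste0("ATG", strrep("GCT", 12), "TAA")  # protein M + 12 A's
  tx <- make_tx(cds, id = "TX2", protein = "P2")
  snvs <- join_meta_positions(enumerate_snvs(tx), meta)
  by_codon <- snvs |>
    dplyr::distinct(codon_index, family_id, column)
  expect_equal(by_codon$column[by_codon$codon_index == 10], 1L)
  expect_equal(by_codon$column[by_codon$codon_index == 12], 4L)
  expect_true(is.na(by_codon$column[by_codon$codon_index == 11]))
  expect_true(is.na(by_codon$column[by_codon$codon_index == 2]))
  # synonymous variants at an annotated codon are joinable too
  syn10 <- snvs |>
    dplyr::filter(codon_index == 10, consequence == "synonymous")
  expect_true(nrow(syn10) > 0 && all(syn10$family_id == "PF_TOY"))
})

test_that("observed variants read identically from TSV and VCF", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = c(101L, 102L), ref = c("A", "C"),
    alt = c("G", "T"), af = c(0.0004, 0.01)), tsv)
  from_tsv <- read_observed_variants(tsv)
  expect_equal(nrow(from_tsv), 2)
  expect_true(all(from_tsv$passes_filters))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tA\tG\t.\tPASS\tAF=0.0004",
    "chr1\t102\t.\tC\tT\t.\tPASS\tAF=0.01",
    "chr1\t103\t.\tG\tA\t.\tlowqual\tAF=0.2"), vcf)
  from_vcf <- read_observed_variants(vcf)
  expect_equal(from_vcf$af[from_vcf$passes_filters],
               from_tsv$af)
  expect_false(from_vcf$passes_filters[from_vcf$pos == 103])
})
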