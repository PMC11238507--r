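#' Read coding transcript models
#'
#' Builds the transcript table consumed by [enumerate_snvs()] from a CDS FASTA
#' (spliced coding-strand sequence, starting at the start codon and ending at
#' the stop codon) and an exon coordinate table. Exon coordinates are 1-based
#' inclusive genomic intervals; exons are ordered along the transcript
#' (ascending genomic position on `+`, descending on `-`).
#'
#' @param cds_fasta Path to CDS FASTA; sequence names are transcript ids.
#' @param exon_tsv Path to a TSV with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exon_start`, `exon_end` and optionally `protein_id`
#'   (defaults to `transcript_id`).
#' @return A transcript tibble: one row per transcript with `transcript_id`,
#'   `gene_id`, `protein_id`, `chrom`, `strand`, `cds_seq` and a list-column
#'   `exons` of (start, end) tibbles.
#' @export
read_transcripts <- function(cds_fasta, exon_tsv) {
  if (!file.exists(cds_fasta)) abort_data(paste0("no such file: ", cds_fasta))
  if (!file.exists(exon_tsv)) abort_data(paste0("no such file: ", exon_tsv))
  seqs <- Biostrings::readDNAStringSet(cds_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ex <- readr::read_tsv(exon_tsv, show_col_types = FALSE,
                        progress = FALSE)
  required <- c("transcript_id", "gene_id", "chrom", "strand",
                "exon_start", "exon_end")
  missing_cols <- setdiff(required, names(ex))
  if (length(missing_cols) > 0) {
    abort_data(paste0("exon table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (!"protein_id" %in% names(ex)) ex$protein_id <- ex$transcript_id
  tx <- ex |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = first(.data$gene_id),
              protein_id = first(.data$protein_id),
              chrom = first(.data$chrom), strand = first(.data$strand),
              exons = list(tibble(start = as.integer(exon_start),
                                  end = as.integer(exon_end))),
              .groups = "drop")
  absent <- setdiff(tx$transcript_id, names(seqs))
  if (length(absent) > 0) {
    abort_data(paste0("no CDS sequence for transcript(s): ",
                      paste(absent, collapse = ", ")))
  }
  tx$cds_seq <- as.character(seqs[tx$transcript_id])
  tx <- tx[c("transcript_id", "gene_id", "protein_id", "chrom", "strand",
             "cds_seq", "exons")]
  purrr::walk(seq_len(nrow(tx)), function(i) validate_transcript(tx[i, ]))
  tx
}

#' Validate one transcript model
#'
#' Checks CDS length divisibility by 3, agreement between CDS length and the
#' exon map, strand values, and absence of internal stop codons.
#'
#' @param transcript One-row transcript tibble.
#' @return The transcript, invisibly; errors on violation.
#' @export
validate_transcript <- function(transcript) {
  id <- transcript$transcript_id[[1]]
  cds <- transcript$cds_seq[[1]]
  L <- nchar(cds)
  if (L %% 3 != 0) {
    abort_data(sprintf("transcript %s: CDS length %d not divisible by 3",
                       id, L))
  }
  exons <- transcript$exons[[1]]
  if (sum(exons$end - exons$start + 1L) != L) {
    abort_data(sprintf(
      "transcript %s: exon lengths sum to %d but CDS has %d bases",
      id, sum(exons$end - exons$start + 1L), L))
  }
  if (!transcript$strand[[1]] %in% c("+", "-")) {
    abort_data(sprintf("transcript %s: strand must be '+' or '-'", id))
  }
  codons <- substring(toupper(cds), seq(1, L, 3), seq(3, L, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    abort_data(sprintf("transcript %s: non-ACGT base in CDS", id))
  }
  if (any(aa[-length(aa)] == "*")) {
    abort_data(sprintf("transcript %s: internal stop codon", id))
  }
  invisible(transcript)
}

# genomic position of each CDS base, in transcript (5'->3') order
cds_genomic_positions <- function(exons, strand) {
  idx <- if (strand == "+") order(exons$start) else order(-exons$start)
  unlist(lapply(idx, function(i) {
    if (strand == "+") seq.int(exons$start[i], exons$end[i])
    else seq.int(exons$end[i], exons$start[i])
  }), use.names = FALSE)
}
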