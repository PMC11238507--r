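#' Enumerate every possible coding SNV
#'
#' Every CDS base can mutate to three alternative nucleotides, so a transcript
#' of coding length L yields exactly 3L possible SNVs. Each variant carries
#' its genomic coordinates (VCF convention: 1-based, reference and alternate
#' on the plus strand), its coding-strand context and alternate base (what
#' the mutability model consumes), and its protein consequence under the
#' standard nuclear code.
#'
#' Consequence classes: `missense` (amino acid changed), `synonymous`
#' (unchanged, including stop-retained), `nonsense` (gain of stop),
#' `stop_lost`, and `start_lost` (non-synonymous change in codon 1).
#'
#' Trinucleotide contexts at the first and last CDS base use optional
#' `flank5`/`flank3` columns on the transcript table (genomic flanking bases
#' on the coding strand); absent flanks give `'N'` and the variant is marked
#' unassessable for the rate model. Contexts at internal exon junctions use
#' the spliced transcript sequence.
#'
#' @param transcripts Transcript tibble from [read_transcripts()] (or built
#'   in code with the same columns).
#' @return Tibble of possible variants, 3L rows per transcript, with columns
#'   `chrom`, `pos`, `ref`, `alt`, `transcript_id`, `gene_id`, `protein_id`,
#'   `strand`, `cds_pos`, `codon_index`, `aa_ref`, `aa_alt`, `consequence`,
#'   `context`, `ref_coding`, `alt_coding`, `assessable`.
#' @export
enumerate_snvs <- function(transcripts) {
  purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    enumerate_snvs_one(transcripts[i, ])
  })
}

enumerate_snvs_one <- function(tx) {
  validate_transcript(tx)
  cds <- toupper(tx$cds_seq[[1]])
  L <- nchar(cds)
  bases <- chars(cds)
  strand <- tx$strand[[1]]
  gpos <- cds_genomic_positions(tx$exons[[1]], strand)

  flank5 <- if ("flank5" %in% names(tx)) tx$flank5[[1]] else NA_character_
  flank3 <- if ("flank3" %in% names(tx)) tx$flank3[[1]] else NA_character_
  up <- c(if (!is.na(flank5) && nzchar(flank5))
            substr(flank5, nchar(flank5), nchar(flank5)) else "N",
          bases[-L])
  down <- c(bases[-1],
            if (!is.na(flank3) && nzchar(flank3)) substr(flank3, 1, 1) else "N")
  context <- paste0(up, bases, down)

  codon_index <- rep(seq_len(L %/% 3), each = 3)
  codon_str <- substring(cds, seq(1, L, by = 3), seq(3, L, by = 3))
  frame <- rep(1:3, times = L %/% 3)

  cds_pos <- rep(seq_len(L), each = 3)
  ref_coding <- rep(bases, each = 3)
  alt_coding <- unlist(lapply(bases, function(b) setdiff(DNA_BASES, b)),
                       use.names = FALSE)
  idx <- rep(seq_len(L), each = 3)
  codons_ref <- codon_str[codon_index[idx]]
  alt_codon <- codons_ref
  substr(alt_codon, frame[idx], frame[idx]) <- alt_coding

  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codons_ref])
  aa_alt <- unname(code[alt_codon])
  consequence <- classify_consequence(codon_index[idx], aa_ref, aa_alt)

  if (strand == "+") {
    pos <- gpos[idx]; ref <- ref_coding; alt <- alt_coding
  } else {
    pos <- gpos[idx]
    ref <- complement_base(ref_coding); alt <- complement_base(alt_coding)
  }

  ctx <- context[idx]
  tibble(chrom = tx$chrom[[1]], pos = as.integer(pos), ref = ref, alt = alt,
         transcript_id = tx$transcript_id[[1]], gene_id = tx$gene_id[[1]],
         protein_id = tx$protein_id[[1]], strand = strand,
         cds_pos = as.integer(cds_pos),
         codon_index = as.integer(codon_index[idx]),
         aa_ref = aa_ref, aa_alt = aa_alt, consequence = consequence,
         context = ctx, ref_coding = ref_coding,
         alt_coding = alt_coding,
         assessable = !grepl("N", ctx, fixed = TRUE))
}

classify_consequence <- function(codon_index, aa_ref, aa_alt) {
  dplyr::case_when(
    aa_ref == aa_alt ~ "synonymous",
    codon_index == 1 ~ "start_lost",
    aa_ref != "*" & aa_alt == "*" ~ "nonsense",
    aa_ref == "*" & aa_alt != "*" ~ "stop_lost",
    TRUE ~ "missense")
}

#' Trinucleotide context at a CDS position
#'
#' Coding-strand 3-mer centred on the given CDS base; see [enumerate_snvs()]
#' for the flank and junction conventions.
#'
#' @param transcript One-row transcript tibble.
#' @param cds_pos 1-based CDS position(s).
#' @return Character vector of 3-mers (may contain `'N'` at CDS edges).
#' @export
trinucleotide_context <- function(transcript, cds_pos) {
  cds <- toupper(transcript$cds_seq[[1]])
  L <- nchar(cds)
  stopifnot(all(cds_pos >= 1 & cds_pos <= L))
  flank5 <- if ("flank5" %in% names(transcript)) transcript$flank5[[1]] else NA
  flank3 <- if ("flank3" %in% names(transcript)) transcript$flank3[[1]] else NA
  up <- ifelse(cds_pos > 1, substr(cds, cds_pos - 1, cds_pos - 1),
               if (!is.na(flank5) && nzchar(flank5))
                 substr(flank5, nchar(flank5), nchar(flank5)) else "N")
  down <- ifelse(cds_pos < L, substr(cds, cds_pos + 1, cds_pos + 1),
                 if (!is.na(flank3) && nzchar(flank3))
                   substr(flank3, 1, 1) else "N")
  paste0(up, substr(cds, cds_pos, cds_pos), down)
}

#' Read observed population variants
#'
#' TSV input needs columns `chrom`, `pos`, `ref`, `alt`, `af`. VCF input
#' (via the vcfR package) keeps `FILTER == PASS` (or `.`) records and takes
#' the allele frequency from the `AF` INFO field; multiallelic records
#' contribute one row per alternate allele.
#'
#' @param path Input file; format sniffed from the extension unless given.
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `af`, `passes_filters`.
#' @export
read_observed_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_data(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    missing_cols <- setdiff(c("chrom", "pos", "ref", "alt", "af"), names(out))
    if (length(missing_cols) > 0) {
      abort_data(paste0("observed-variant table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
    }
    if (!"passes_filters" %in% names(out)) out$passes_filters <- TRUE
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort_config("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    info <- paste0(";", fix$INFO)
    af <- ifelse(grepl(";AF=", info, fixed = TRUE),
                 sub(".*;AF=([^;]*).*", "\\1", info), NA)
    af <- suppressWarnings(as.numeric(af))
    out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT, af = af,
                  passes_filters = fix$FILTER %in% c("PASS", "."))
    out <- tidyr::separate_rows(out, "alt", sep = ",")
  }
  out <- as_tibble(out)
  bad <- !is.na(out$af) & (out$af < 0 | out$af > 1)
  if (any(bad)) abort_data("allele frequencies outside [0, 1]")
  out |> filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1,
                .data$alt %in% DNA_BASES)  # SNVs only
}

#' Flag rare observed variants on the possible-variant space
#'
#' Matches observed variants to possible SNVs by exact (chrom, pos, ref, alt)
#' allele. A possible variant is *observed-rare* iff a filter-passing match
#' exists with 0 < AF < `maf_threshold`; a match with AF >= `maf_threshold`
#' is *common* and the variant is removed from the assessable-rare set
#' entirely (it contributes to neither observed nor expected counts). AF = 0
#' records count as absent. Duplicate observed records for one allele keep
#' the maximum AF (with a warning).
#'
#' @param possible Possible-variant tibble from [enumerate_snvs()].
#' @param observed Observed-variant tibble from [read_observed_variants()].
#' @param maf_threshold Rarity threshold on allele frequency (default 0.001,
#'   i.e. MAF < 0.1%).
#' @return `possible` with added `af`, `observed_rare`, `is_common` columns
#'   and `assessable` updated to exclude common variants.
#' @export
apply_rarity_filter <- function(possible, observed, maf_threshold = 0.001) {
  stopifnot(maf_threshold > 0, maf_threshold < 1)
  observed <- observed |> filter(.data$passes_filters)
  dup <- observed |>
    count(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf("%d duplicated observed allele(s); keeping max AF",
                 nrow(dup)))
  }
  observed <- observed |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(af = max(.data$af), .groups = "drop")
  out <- possible |>
    left_join(observed, by = c("chrom", "pos", "ref", "alt"))
  out |>
    mutate(
      observed_rare = !is.na(.data$af) & .data$af > 0 &
        .data$af < maf_threshold,
      is_common = !is.na(.data$af) & .data$af >= maf_threshold,
      assessable = .data$assessable & !.data$is_common)
}

#' Join domain meta-positions onto the variant space
#'
#' Annotates each variant whose codon's protein position belongs to a domain
#' meta-position with that position's `family_id`, `column` and `n_copies`.
#' Both missense and synonymous variants are joinable (synonymous ones are
#' needed for calibration); variants in insert columns or outside domains
#' stay unannotated (`NA`). If a residue maps into several families the
#' first family by sorted id keeps it, with a warning, so every variant
#' carries at most one meta-position.
#'
#' @param possible Possible-variant tibble.
#' @param meta_positions Output of [build_meta_positions()].
#' @return `possible` with `family_id`, `column`, `n_copies` columns.
#' @export
join_meta_positions <- function(possible, meta_positions) {
  meta <- meta_positions |>
    select("protein_id", protein_position = "protein_position",
           "family_id", "column", "n_copies") |>
    arrange(.data$family_id)
  multi <- meta |>
    count(.data$protein_id, .data$protein_position) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    warn(sprintf(
      "%d residue(s) map to multiple families; keeping first by family_id",
      nrow(multi)))
    meta <- meta[!duplicated(meta[c("protein_id", "protein_position")]), ]
  }
  possible |>
    left_join(meta, by = c("protein_id", codon_index = "protein_position"))
}
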