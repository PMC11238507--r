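#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: a small
#' universe of domain families whose copies are embedded in single-gene
#' transcripts, a relative trinucleotide rate table, uniform deep coverage,
#' and a population cohort in which rare-variant presence at each possible
#' SNV follows a Poisson-presence model thinned by per-column purifying
#' selection.
#'
#' `cohort_scale` sets the cohort size indirectly as the target mean expected
#' number of rare missense variants per meta-position (the generator derives
#' the true calibration constant `k_true` from it), so conditions like
#' "expected about 20 per column" are stated directly. `selection_profile`
#' gives the per-column depletion `s` in [0, 1] (`"uniform"` draws s ~ U(0,1)
#' per column; `"null"` sets s = 0 everywhere; or supply a function of the
#' column count). The label rule maps `s` to the probability a variant at
#' that column is labeled pathogenic.
#'
#' @param seed Integer seed; the same seed reproduces identical outputs.
#' @param n_families Number of domain families.
#' @param copies_per_family Length-2 range of copies per family.
#' @param columns_per_family Length-2 range of match columns per family.
#' @param n_filler_genes Domain-free genes (never assessable).
#' @param cohort_scale Target mean expected missense count per meta-position.
#' @param selection_profile `"uniform"`, `"null"`, or `function(n) -> s`.
#' @param label_rule `function(s) -> P(pathogenic)`; default a step at
#'   s > 0.8 mixing 90% pathogenic against a 5% background.
#' @param common_variant_fraction Fraction of simulated observed variants
#'   assigned an allele frequency at or above the 0.1% rarity threshold, to
#'   exercise the filter.
#' @param divergence Per-residue probability that a copy differs from the
#'   family consensus amino acid at weakly selected columns.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_families = 6, copies_per_family = c(8, 12),
                       columns_per_family = c(25, 40), n_filler_genes = 2,
                       cohort_scale = 20,
                       selection_profile = "uniform",
                       label_rule = function(s) ifelse(s > 0.8, 0.9, 0.05),
                       common_variant_fraction = 0.05,
                       divergence = 0.15) {
  stopifnot(n_families >= 1, length(copies_per_family) == 2,
            length(columns_per_family) == 2,
            all(copies_per_family >= 1), all(columns_per_family >= 3),
            copies_per_family[1] <= copies_per_family[2],
            columns_per_family[1] <= columns_per_family[2],
            cohort_scale > 0, common_variant_fraction >= 0,
            common_variant_fraction < 1)
  structure(list(seed = as.integer(seed), n_families = n_families,
                 copies_per_family = copies_per_family,
                 columns_per_family = columns_per_family,
                 n_filler_genes = n_filler_genes,
                 cohort_scale = cohort_scale,
                 selection_profile = selection_profile,
                 label_rule = label_rule,
                 common_variant_fraction = common_variant_fraction,
                 divergence = divergence),
            class = "sim_config")
}

AA_ALPHABET20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")

codon_for <- function(aa) {
  # one random codon per amino acid
  vapply(aa, function(a) {
    sample(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a], 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic reference universe
#'
#' Produces, deterministically under the config seed: gapless domain family
#' alignments (`hmc_alignment` objects) whose copies live in single-exon (or
#' occasionally two-exon, minus-strand) transcripts; the transcript table
#' with CDS sequences and genomic flanks; a complete relative rate table
#' (all 192 context/alt pairs at methylation level 0 plus elevated CpG
#' transition rates at levels 1 and 2); uniform deep coverage; a CpG
#' methylation map; and the ground-truth per-column selection profile.
#'
#' @param config A [sim_config()].
#' @return A `sim_reference` list: `transcripts`, `alignments`,
#'   `rate_table`, `coverage`, `methylation`, `truth` (tibble `family_id`,
#'   `column`, `s`), `k_true`, `config`.
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  families <- sprintf("PF%05d", seq_len(config$n_families))
  truth <- list(); alignments <- list(); tx_rows <- list()
  chrom_i <- 0
  for (fi in seq_along(families)) {
    fam <- families[fi]
    L <- sample(seq(config$columns_per_family[1],
                    config$columns_per_family[2]), 1)
    n_cp <- sample(seq(config$copies_per_family[1],
                       config$copies_per_family[2]), 1)
    s <- switch(
      if (is.function(config$selection_profile)) "fn"
      else config$selection_profile,
      uniform = runif(L),
      null = rep(0, L),
      fn = config$selection_profile(L))
    stopifnot(length(s) == L, all(s >= 0 & s <= 1))
    truth[[fam]] <- tibble(family_id = fam, column = seq_len(L), s = s)
    consensus <- sample(AA_ALPHABET20, L, replace = TRUE)
    members <- list()
    for (ci in seq_len(n_cp)) {
      chrom_i <- chrom_i + 1
      aa_dom <- consensus
      div <- runif(L) < config$divergence & s < 0.5
      aa_dom[div] <- sample(AA_ALPHABET20, sum(div), replace = TRUE)
      n_left <- sample(2:5, 1); n_right <- sample(2:5, 1)
      aa_prot <- c("M", sample(AA_ALPHABET20, n_left, replace = TRUE),
                   aa_dom, sample(AA_ALPHABET20, n_right, replace = TRUE))
      cds <- paste(c(codon_for(aa_prot[-1]), "TAA"), collapse = "")
      cds <- paste0("ATG", cds)
      pid <- sprintf("%s_P%02d", fam, ci)
      strand <- if (chrom_i %% 4 == 0) "-" else "+"
      tx_rows[[pid]] <- make_sim_transcript(pid, fam, cds, strand, chrom_i)
      members[[ci]] <- tibble(protein_id = pid,
                              env_start = n_left + 2L,
                              env_end = n_left + 1L + L,
                              aligned_seq = paste(aa_dom, collapse = ""))
    }
    alignments[[fam]] <- domain_alignment(fam, bind_rows(members),
                                          match_columns = seq_len(L))
  }
  for (gi in seq_len(config$n_filler_genes)) {
    chrom_i <- chrom_i + 1
    n_aa <- sample(20:40, 1)
    cds <- paste0("ATG", paste(codon_for(sample(AA_ALPHABET20, n_aa,
                                                replace = TRUE)),
                               collapse = ""), "TAA")
    pid <- sprintf("FILLER_P%02d", gi)
    tx_rows[[pid]] <- make_sim_transcript(pid, "none", cds, "+", chrom_i)
  }
  transcripts <- bind_rows(tx_rows)
  truth <- bind_rows(truth)
  rate_table <- sim_rate_table()
  coverage <- transcripts |>
    mutate(lo = purrr::map_int(.data$exons, ~ min(.x$start)),
           hi = purrr::map_int(.data$exons, ~ max(.x$end))) |>
    mutate(start = .data$lo - 11L, end = .data$hi + 10L,
           median_depth = 50) |>
    select("chrom", "start", "end", "median_depth")
  methylation <- sim_methylation(transcripts)
  ref <- list(transcripts = transcripts, alignments = alignments,
              rate_table = rate_table, coverage = coverage,
              methylation = methylation, truth = truth, config = config)
  ref$annotated <- sim_annotated_space(ref)  # cached for cohort/label draws
  ref$k_true <- derive_k_true(ref, config$cohort_scale)
  class(ref) <- "sim_reference"
  ref
}

make_sim_transcript <- function(pid, fam, cds, strand, chrom_i) {
  L <- nchar(cds)
  chrom <- sprintf("chr%d", chrom_i)
  # coding-strand sequence; genomic = revcomp on '-'
  if (strand == "-") {
    # two exons on minus-strand transcripts to exercise the exon map
    cut <- L %/% 2
    exons <- tibble(start = c(1001L, 1051L + cut),
                    end = c(1000L + cut, 1050L + L))
  } else {
    exons <- tibble(start = 1001L, end = 1000L + L)
  }
  tibble(transcript_id = paste0("TX_", pid), gene_id = paste0("G_", pid),
         protein_id = pid, chrom = chrom, strand = strand, cds_seq = cds,
         exons = list(exons), family_id_hint = fam,
         flank5 = "ACGTA", flank3 = "TACGT")
}

sim_rate_table <- function() {
  pairs <- all_context_alt_pairs()
  base <- exp(stats::rnorm(nrow(pairs), mean = 0, sd = 0.5))
  tab <- tibble(context = pairs$context, alt = pairs$alt,
                methyl_level = 0L, mu = base)
  # methylation accelerates the CpG transition (C>T); other alts unchanged.
  # boosts are kept moderate so per-variant discovery probabilities stay in
  # the linear (unsaturated) regime the expectation model assumes
  cpg <- tab |> filter(substr(.data$context, 2, 3) == "CG")
  bind_rows(
    tab,
    cpg |> mutate(methyl_level = 1L,
                  mu = .data$mu * ifelse(.data$alt == "T", 2, 1)),
    cpg |> mutate(methyl_level = 2L,
                  mu = .data$mu * ifelse(.data$alt == "T", 3.5, 1)))
}

sim_methylation <- function(transcripts) {
  purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    cds <- tx$cds_seq[[1]]
    cpg <- gregexpr("CG", cds, fixed = TRUE)[[1]]
    if (cpg[1] == -1) return(NULL)
    gpos <- cds_genomic_positions(tx$exons[[1]], tx$strand[[1]])
    tibble(chrom = tx$chrom[[1]], pos = gpos[as.integer(cpg)],
           level = sample(0:2, length(cpg), replace = TRUE))
  })
}

# choose k_true so the mean per-meta-position expected missense count equals
# cohort_scale
derive_k_true <- function(ref, cohort_scale) {
  ann <- sim_annotated_space(ref)
  per_col <- ann |>
    filter(!is.na(.data$family_id), .data$consequence == "missense",
           .data$assessable) |>
    group_by(.data$family_id, .data$column) |>
    summarise(smu = sum(.data$mu_adj), .groups = "drop")
  cohort_scale / mean(per_col$smu)
}

sim_annotated_space <- function(ref) {
  if (!is.null(ref$annotated)) return(ref$annotated)
  meta <- build_meta_positions(ref$alignments)
  enumerate_snvs(ref$transcripts) |>
    join_meta_positions(meta) |>
    annotate_mutability(ref$rate_table, coverage = ref$coverage,
                        methylation = ref$methylation)
}

#' Simulate an observed population cohort
#'
#' Each possible SNV is observed as a rare variant with the Poisson-presence
#' probability `1 - exp(-(1 - s) * k_true * mu_adj)`, where the depletion `s`
#' applies only to missense variants inside domain columns (synonymous and
#' non-domain variants are neutral, s = 0). Observed variants get allele
#' frequencies from a rare log-uniform spectrum, except for a configured
#' fraction planted at or above the 0.1% threshold to exercise the rarity
#' filter.
#'
#' @param reference A `sim_reference`.
#' @param seed Seed for the cohort draw (defaults to the config seed + 1).
#' @return Tibble of observed variants (`chrom`, `pos`, `ref`, `alt`, `af`,
#'   `passes_filters`) plus a `truth` attribute with the per-variant
#'   presence probabilities.
#' @export
sim_cohort <- function(reference, seed = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  cfg <- reference$config
  set.seed(seed %||% (cfg$seed + 1L))
  ann <- sim_annotated_space(reference) |>
    left_join(reference$truth, by = c("family_id", "column"))
  s <- ifelse(!is.na(ann$s) & ann$consequence == "missense", ann$s, 0)
  lambda <- (1 - s) * reference$k_true * ifelse(ann$assessable,
                                                ann$mu_adj, 0)
  p_obs <- 1 - exp(-lambda)
  seen <- runif(nrow(ann)) < p_obs
  obs <- ann[seen, c("chrom", "pos", "ref", "alt")]
  n <- nrow(obs)
  af <- 10^runif(n, min = -5, max = log10(0.0009))
  common <- runif(n) < cfg$common_variant_fraction
  af[common] <- 10^runif(sum(common), min = log10(0.001), max = -1)
  out <- obs |> mutate(af = af, passes_filters = TRUE)
  attr(out, "presence_prob") <- p_obs
  out
}

#' Generate labeled evaluation sets with known ground truth
#'
#' Draws (i) a pathogenic/benign set over possible missense variants in
#' domains, where `P(pathogenic) = label_rule(s)` so labels concentrate at
#' strongly depleted columns, and (ii) case/control de novo mutation lists:
#' case DNMs are sampled with weight `1 + 9 s` (enriched at depleted
#' columns), control DNMs uniformly.
#'
#' @param reference A `sim_reference`.
#' @param n_labeled Number of variants in the pathogenic/benign set.
#' @param n_case_dnm,n_control_dnm DNM counts for cases and controls.
#' @param seed Seed (defaults to config seed + 2).
#' @return List of tibbles `clinvar_like` (chrom,pos,ref,alt,label,s) and
#'   `dnm` (chrom,pos,ref,alt,group,s).
#' @export
sim_labels <- function(reference, n_labeled = 400, n_case_dnm = 150,
                       n_control_dnm = 150, seed = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  cfg <- reference$config
  set.seed(seed %||% (cfg$seed + 2L))
  ann <- sim_annotated_space(reference) |>
    left_join(reference$truth, by = c("family_id", "column")) |>
    filter(.data$consequence == "missense", !is.na(.data$s))
  idx <- sample.int(nrow(ann), min(n_labeled, nrow(ann)))
  lab <- ann[idx, ] |>
    mutate(label = as.integer(runif(length(idx)) < cfg$label_rule(.data$s))) |>
    select("chrom", "pos", "ref", "alt", "label", "s")
  case_w <- 1 + 9 * ann$s
  case_idx <- sample.int(nrow(ann), n_case_dnm, replace = TRUE, prob = case_w)
  ctrl_idx <- sample.int(nrow(ann), n_control_dnm, replace = TRUE)
  dnm <- bind_rows(
    ann[case_idx, ] |> mutate(group = "case"),
    ann[ctrl_idx, ] |> mutate(group = "control")) |>
    select("chrom", "pos", "ref", "alt", "group", "s")
  list(clinvar_like = lab, dnm = dnm)
}

#' Write a synthetic universe to pipeline input files
#'
#' Materialises the exact formats the pipeline reads: Stockholm alignments
#' (one file per family), CDS FASTA, exon table TSV, rate table TSV,
#' coverage TSV, methylation TSV, an observed-cohort TSV and label TSVs.
#'
#' @param reference A `sim_reference`.
#' @param dir Output directory (created if needed).
#' @param cohort Optional precomputed [sim_cohort()] table.
#' @param labels Optional precomputed [sim_labels()] list.
#' @return Named list of written paths, invisibly.
#' @export
sim_write <- function(reference, dir, cohort = NULL, labels = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  aln_dir <- file.path(dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (fam in names(reference$alignments)) {
    write_alignment(reference$alignments[[fam]],
                    file.path(aln_dir, paste0(fam, ".sto")))
  }
  paths$alignments <- aln_dir
  tx <- reference$transcripts
  fasta <- sprintf(">%s\n%s", tx$transcript_id, tx$cds_seq)
  paths$cds_fasta <- file.path(dir, "cds.fa")
  writeLines(fasta, paths$cds_fasta)
  exon_tab <- tx |>
    select("transcript_id", "gene_id", "protein_id", "chrom", "strand",
           "exons") |>
    tidyr::unnest("exons") |>
    rename(exon_start = "start", exon_end = "end")
  paths$exons <- file.path(dir, "exons.tsv")
  readr::write_tsv(exon_tab, paths$exons)
  paths$flanks <- file.path(dir, "flanks.tsv")
  readr::write_tsv(tx |> select("transcript_id", "flank5", "flank3"),
                   paths$flanks)
  paths$rate_table <- file.path(dir, "rates.tsv")
  readr::write_tsv(reference$rate_table, paths$rate_table)
  paths$coverage <- file.path(dir, "coverage.tsv")
  readr::write_tsv(reference$coverage, paths$coverage)
  paths$methylation <- file.path(dir, "methylation.tsv")
  readr::write_tsv(reference$methylation, paths$methylation)
  paths$truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(reference$truth, paths$truth)
  if (is.null(cohort)) cohort <- sim_cohort(reference)
  paths$observed <- file.path(dir, "observed.tsv")
  readr::write_tsv(cohort, paths$observed)
  if (is.null(labels)) labels <- sim_labels(reference)
  paths$labels <- file.path(dir, "labels.tsv")
  readr::write_tsv(labels$clinvar_like, paths$labels)
  paths$dnm <- file.path(dir, "dnm.tsv")
  readr::write_tsv(labels$dnm, paths$dnm)
  invisible(paths)
}
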