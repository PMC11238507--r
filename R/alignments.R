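#' Domain family alignments
#'
#' A domain family alignment holds the aligned instances ("copies") of one
#' protein domain family, e.g. one Pfam family. Aggregating rare missense
#' variation down the columns of such an alignment is what turns sparse
#' per-residue counts into an assessable constraint signal: each match column
#' defines a *meta-position*, the set of evolutionarily equivalent residues
#' across all copies.
#'
#' Objects are lightweight lists of class `hmc_alignment` with fields
#' `family_id`, `members` (a tibble with `protein_id`, `env_start`, `env_end`,
#' `aligned_seq`), `n_columns` and `match_columns` (1-based, strictly
#' increasing). Gap characters are `-` and `.`; lowercase letters are
#' insert-state residues (they consume a protein position but are never part
#' of a match column under the Stockholm/Pfam convention).
#'
#' @param family_id Accession-style family identifier (e.g. `"PF00520"`).
#' @param members Tibble/data.frame with columns `protein_id`, `env_start`,
#'   `env_end` (1-based inclusive residue coordinates of the domain instance
#'   in its protein) and `aligned_seq`.
#' @param match_columns Integer vector of 1-based match-column indices, or
#'   `NULL` to apply the gap-fraction rule (a column is a match column iff its
#'   gap fraction is <= `max_gap_frac`).
#' @param max_gap_frac Gap-fraction threshold for the match-column rule.
#' @return An `hmc_alignment` object.
#' @export
domain_alignment <- function(family_id, members, match_columns = NULL,
                             max_gap_frac = 0.5) {
  members <- as_tibble(members)
  required <- c("protein_id", "env_start", "env_end", "aligned_seq")
  missing_cols <- setdiff(required, names(members))
  if (length(missing_cols) > 0) {
    abort_data(paste0("alignment members lack column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (nrow(members) == 0) abort_data("alignment has no members")
  widths <- nchar(members$aligned_seq)
  if (length(unique(widths)) != 1) {
    abort_data(sprintf("ragged alignment in family %s: row widths %s",
                       family_id, paste(unique(widths), collapse = ", ")))
  }
  n_columns <- widths[[1]]
  n_res <- vapply(members$aligned_seq,
                  function(s) sum(!is_gap_char(chars(s))), integer(1),
                  USE.NAMES = FALSE)
  span <- members$env_end - members$env_start + 1L
  bad <- which(n_res != span | members$env_start < 1 |
                 members$env_end < members$env_start)
  if (length(bad) > 0) {
    abort_data(sprintf(
      "member %s (%s): %d aligned residues but envelope %d-%d",
      members$protein_id[bad[1]], family_id, n_res[bad[1]],
      members$env_start[bad[1]], members$env_end[bad[1]]))
  }
  if (is.null(match_columns)) {
    mat <- do.call(rbind, lapply(members$aligned_seq, chars))
    gap_frac <- colMeans(matrix(is_gap_char(mat), nrow = nrow(mat)))
    match_columns <- which(gap_frac <= max_gap_frac)
  }
  match_columns <- as.integer(sort(unique(match_columns)))
  if (any(match_columns < 1 | match_columns > n_columns)) {
    abort_data("match_columns outside [1, n_columns]")
  }
  structure(
    list(family_id = family_id, members = members,
         n_columns = n_columns, match_columns = match_columns),
    class = "hmc_alignment")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

is_gap_char <- function(x) x == "-" | x == "."

#' @export
print.hmc_alignment <- function(x, ...) {
  cat(sprintf("<hmc_alignment> %s: %d members, %d columns (%d match)\n",
              x$family_id, nrow(x$members), x$n_columns,
              length(x$match_columns)))
  invisible(x)
}

#' Read a domain family alignment
#'
#' Reads Stockholm 1.0 (honouring the `#=GC RF` reference annotation when
#' present: RF characters other than `.`, `-`, `~` mark match columns) or
#' aligned FASTA. Member headers must follow the `protein_id/start-end`
#' dialect, giving the 1-based envelope coordinates of the instance in its
#' protein. Without an RF line, match columns follow the gap-fraction rule
#' (see [domain_alignment()]).
#'
#' @param path File path.
#' @param format `"auto"` (by sniffing the first line), `"stockholm"` or
#'   `"fasta"`.
#' @param family_id Family accession; defaults to the Stockholm `#=GF AC`/
#'   `#=GF ID` field when present, else the file base name.
#' @param max_gap_frac Passed to [domain_alignment()] when no RF line exists.
#' @return An `hmc_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "stockholm", "fasta"),
                           family_id = NULL, max_gap_frac = 0.5) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_data(paste0("no such alignment file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    abort_data(paste0("empty alignment file: ", path))
  }
  if (format == "auto") {
    first <- trimws(lines[nzchar(trimws(lines))][1])
    format <- if (startsWith(first, ">")) "fasta" else "stockholm"
  }
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    headers <- names(aa)
    seqs <- as.character(aa)
  } else {
    parsed <- parse_stockholm(lines)
    headers <- names(parsed$seqs)
    seqs <- unname(parsed$seqs)
    if (is.null(family_id)) family_id <- parsed$accession
  }
  if (is.null(family_id)) {
    family_id <- sub("\\.[^.]*$", "", basename(path))
  }
  info <- parse_member_headers(headers)
  members <- tibble(protein_id = info$protein_id,
                    env_start = info$env_start, env_end = info$env_end,
                    aligned_seq = seqs)
  match_columns <- NULL
  if (format == "stockholm" && !is.null(parsed$rf)) {
    rf <- chars(parsed$rf)
    if (length(rf) != nchar(seqs[[1]])) {
      abort_data("#=GC RF length differs from alignment width")
    }
    match_columns <- which(!(rf %in% c(".", "-", "~")))
  }
  domain_alignment(family_id, members, match_columns = match_columns,
                   max_gap_frac = max_gap_frac)
}

parse_stockholm <- function(lines) {
  seqs <- character(0)
  rf <- NULL
  accession <- NULL
  for (ln in lines) {
    ln <- sub("\r$", "", ln)
    if (!nzchar(trimws(ln)) || identical(trimws(ln), "//")) next
    if (startsWith(ln, "#")) {
      if (grepl("^#=GC\\s+RF\\s+", ln)) {
        piece <- sub("^#=GC\\s+RF\\s+", "", ln)
        rf <- paste0(rf %||% "", trimws(piece))
      } else if (grepl("^#=GF\\s+(AC|ID)\\s+", ln) && is.null(accession)) {
        accession <- trimws(sub("^#=GF\\s+(AC|ID)\\s+", "", ln))
      }
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) {
      abort_data(paste0("cannot parse Stockholm sequence line: ", ln))
    }
    nm <- parts[[1]]
    seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[[nm]] else "", parts[[2]])
  }
  if (length(seqs) == 0) abort_data("Stockholm file contains no sequences")
  list(seqs = seqs, rf = rf, accession = accession)
}

parse_member_headers <- function(headers) {
  m <- regmatches(headers, regexec("^(.+)/(\\d+)-(\\d+)\\s*$", headers))
  bad <- which(lengths(m) != 4)
  if (length(bad) > 0) {
    abort_data(sprintf(
      "cannot parse member header '%s' (row %d); expected 'protein_id/start-end'",
      headers[bad[1]], bad[1]))
  }
  list(protein_id = vapply(m, `[[`, character(1), 2),
       env_start = as.integer(vapply(m, `[[`, character(1), 3)),
       env_end = as.integer(vapply(m, `[[`, character(1), 4)))
}

#' Write a domain family alignment
#'
#' Stockholm 1.0 output with a `#=GC RF` line marking the alignment's match
#' columns (`x` for match, `.` for insert), so that reading the file back
#' reproduces the same residue-to-column mapping.
#'
#' @param alignment An `hmc_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "hmc_alignment"))
  m <- alignment$members
  nm <- sprintf("%s/%d-%d", m$protein_id, m$env_start, m$env_end)
  width <- max(nchar(nm), nchar("#=GC RF")) + 2
  rf <- rep(".", alignment$n_columns)
  rf[alignment$match_columns] <- "x"
  lines <- c(
    "# STOCKHOLM 1.0",
    sprintf("#=GF AC %s", alignment$family_id),
    sprintf("%-*s%s", width, nm, m$aligned_seq),
    sprintf("%-*s%s", width, "#=GC RF", paste(rf, collapse = "")),
    "//")
  writeLines(lines, path)
  invisible(path)
}

#' Map member residues to match columns
#'
#' Walks one aligned member string: every non-gap character consumes a protein
#' position (starting at `env_start`); positions falling in match columns are
#' mapped, positions in insert columns are not. The mapping is injective.
#'
#' @param member One row of an alignment's `members` tibble (a list or
#'   one-row data frame with `protein_id`, `env_start`, `aligned_seq`).
#' @param match_columns Integer vector of 1-based match columns.
#' @return Tibble with `protein_id`, `protein_position`, `column`.
#' @export
residue_to_column <- function(member, match_columns) {
  cc <- chars(member$aligned_seq[[1]] %||% member$aligned_seq)
  res <- !is_gap_char(cc)
  protein_position <- member$env_start[[1]] + cumsum(res) - 1L
  keep <- res & seq_along(cc) %in% match_columns
  tibble(protein_id = member$protein_id[[1]],
         protein_position = as.integer(protein_position[keep]),
         column = as.integer(which(keep)))
}

#' Build meta-positions from domain family alignments
#'
#' A meta-position is one (family, match column) pair together with all
#' residues it contains across copies. Returns the long residue-level table
#' the rest of the pipeline joins against; `n_copies` counts distinct
#' contributing residues at the column. Duplicated members (same protein and
#' envelope) are dropped with a warning; when two instances of the same
#' family overlap on one protein, the first by `env_start` keeps the shared
#' residues.
#'
#' @param families A single `hmc_alignment` or a list of them.
#' @return Tibble with `family_id`, `column`, `protein_id`,
#'   `protein_position`, `n_copies`, ordered by (family_id, column).
#' @export
build_meta_positions <- function(families) {
  if (inherits(families, "hmc_alignment")) families <- list(families)
  if (length(families) == 0) {
    return(tibble(family_id = character(0), column = integer(0),
                  protein_id = character(0), protein_position = integer(0),
                  n_copies = integer(0)))
  }
  ids <- vapply(families, function(f) f$family_id, character(1))
  if (anyDuplicated(ids)) abort_data("duplicate family_id across alignments")
  per_family <- lapply(families, function(fam) {
    m <- fam$members
    dup <- duplicated(m[c("protein_id", "env_start", "env_end")])
    if (any(dup)) {
      warn(sprintf("family %s: dropping %d duplicated member(s)",
                   fam$family_id, sum(dup)))
      m <- m[!dup, , drop = FALSE]
    }
    m <- m[order(m$protein_id, m$env_start), , drop = FALSE]
    maps <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
      residue_to_column(m[i, ], fam$match_columns)
    })
    # overlap within the family: first instance by env_start wins
    maps <- maps[!duplicated(maps[c("protein_id", "protein_position")]), ,
                 drop = FALSE]
    maps$family_id <- fam$family_id
    maps
  })
  out <- bind_rows(per_family)
  out |>
    distinct(.data$family_id, .data$column, .data$protein_id,
             .data$protein_position) |>
    group_by(.data$family_id, .data$column) |>
    mutate(n_copies = n()) |>
    ungroup() |>
    arrange(.data$family_id, .data$column, .data$protein_id,
            .data$protein_position)
}

#' Write a meta-position table as TSV
#'
#' @param meta_positions Output of [build_meta_positions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_positions <- function(meta_positions, path) {
  readr::write_tsv(meta_positions, path)
  invisible(path)
}
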