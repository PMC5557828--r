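#' Read tabular alignment hits (12-column BLAST outfmt-6 dialect)
#'
#' The standard tabular alignment format: query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end (1-based inclusive; subject start may exceed subject end on
#' minus-strand hits), e-value, bit score. Comment lines starting with `#`
#' are skipped; rows are preserved in file order.
#'
#' @param path Path to the tab-separated hits file.
#' @return A tibble with columns `query`, `subject`, `pct_identity`,
#'   `aln_len`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bit_score`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query", "subject", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as_tibble(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), cols))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    abort(sprintf("malformed hits line %d in %s: expected 12 tab-separated fields, got %d",
                  which(keep)[which(nf != 12L)[1L]], path, nf[which(nf != 12L)[1L]]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  out <- tibble(
    query = m[, 1L], subject = m[, 2L],
    pct_identity = as.numeric(m[, 3L]), aln_len = as.numeric(m[, 4L]),
    mismatches = as.numeric(m[, 5L]), gap_opens = as.numeric(m[, 6L]),
    q_start = as.numeric(m[, 7L]), q_end = as.numeric(m[, 8L]),
    s_start = as.numeric(m[, 9L]), s_end = as.numeric(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bit_score = as.numeric(m[, 12L])
  )
  if (anyNA(out$evalue) || any(out$evalue < 0)) abort("invalid e-value in hits file")
  out
}

#' Discard candidates with strong homology to the female assembly
#'
#' A stringent Y-candidate fragment that aligns well to the female assembly
#' cannot be male-specific: any hit with `evalue < evalue_max` (strict)
#' causes the fragment to be discarded. The remainder are the marker
#' candidates. A fragment whose best (minimum-e-value) hit is still at or
#' above the threshold is retained. Hits whose query is not among the
#' candidates are ignored with a warning.
#'
#' @param candidates Tibble of stringent candidate fragments (a `name`
#'   column; typically `select_candidates(ratios, 0.15)`).
#' @param hits Alignment hits from [read_blast_tab()], queries named by
#'   fragment.
#' @param evalue_max Discard threshold on the e-value (default 1e-5).
#' @return The retained subset of `candidates`, as a tibble.
#' @export
filter_by_homology <- function(candidates, hits, evalue_max = 1e-5) {
  check_scalar_number(evalue_max, "evalue_max", lower = 0)
  if (!"name" %in% names(candidates)) abort("`candidates` needs a `name` column")
  unknown <- setdiff(unique(hits$query), candidates$name)
  if (length(unknown) > 0L) {
    warn(sprintf("%d hit quer%s not among the candidate fragments; ignored",
                 length(unknown), if (length(unknown) == 1L) "y is" else "ies are"))
  }
  discard <- unique(hits$query[hits$evalue < evalue_max])
  as_tibble(candidates)[!candidates$name %in% discard, ]
}

#' Export marker-candidate fragments as FASTA and TSV
#'
#' Writes the retained marker candidates with their uppercase sequences
#' (for downstream primer design) and a TSV of their statistics, sorted by
#' (scaffold, ordinal).
#'
#' @param retained Retained candidates from [filter_by_homology()]; rows must
#'   carry `name` and the ratio columns `r_norm`, `f_reads`, `m_reads`.
#' @param fragments Fragment table from [split_fragments()] providing the
#'   sequences.
#' @param fasta_path,tsv_path Output paths.
#' @return A tibble of the exported records, invisibly.
#' @export
export_marker_candidates <- function(retained, fragments, fasta_path, tsv_path) {
  if (nrow(retained) > 0L && !all(retained$name %in% fragments$name)) {
    abort(paste0("retained fragments missing from the fragment table: ",
                 paste(utils::head(setdiff(retained$name, fragments$name), 5L),
                       collapse = ", ")))
  }
  if (nrow(retained) == 0L) warn("empty marker-candidate set; writing empty outputs")
  parsed <- if (nrow(retained)) parse_fragment_names(retained$name) else
    tibble(name = character(), scaffold_id = character(), ordinal = integer())
  tab <- retained |>
    dplyr::left_join(dplyr::select(parsed, "name", "scaffold_id", "ordinal"),
                     by = "name") |>
    dplyr::arrange(.data$scaffold_id, .data$ordinal) |>
    dplyr::select("name", "scaffold_id", "r_norm", "f_reads", "m_reads")
  readr::write_tsv(tab, tsv_path)
  frag_sel <- fragments[match(tab$name, fragments$name), , drop = FALSE]
  write_fragments_fasta(frag_sel, fasta_path)
  invisible(tab)
}
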