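#' Read a softmasked FASTA into a scaffold table
#'
#' Lowercase bases mark repeat-masked positions (RepeatMasker softmasking);
#' case is preserved on read. Wrapped and unwrapped FASTA are both accepted.
#'
#' @param path Path to a (multi-record) softmasked FASTA file.
#' @return A tibble with columns `scaffold_id` and `seq`.
#' @export
read_softmasked <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate scaffold ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(scaffold_id = ids, seq = unname(as.character(ss)))
}

validate_scaffolds <- function(scaffolds) {
  if (!is.data.frame(scaffolds) || !all(c("scaffold_id", "seq") %in% names(scaffolds))) {
    abort("`scaffolds` must be a data frame with columns `scaffold_id` and `seq`")
  }
  if (nrow(scaffolds) == 0L) abort("`scaffolds` is empty")
  if (anyDuplicated(scaffolds$scaffold_id)) abort("duplicate `scaffold_id`")
  if (any(!nzchar(scaffolds$seq))) abort("empty scaffold sequence")
  bad <- regexpr("[^ACGTNacgtn]", scaffolds$seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf(
      "invalid character '%s' in scaffold '%s' at offset %d (allowed: ACGTN, acgtn)",
      substr(scaffolds$seq[i], bad[i], bad[i]), scaffolds$scaffold_id[i], bad[i]
    ))
  }
  invisible(scaffolds)
}

#' Split softmasked scaffolds into unmasked fragments
#'
#' Each scaffold is cut at every run of repeat-masked (lowercase) bases and,
#' by default, at every run of `N` gap bases; the maximal uppercase non-`N`
#' runs in between are the fragments. Fragments shorter than `min_len` are
#' discarded, and 1-based ordinals are assigned over the retained fragments in
#' scaffold order. Fragment names follow `"{scaffold}_{ordinal}_{length}"`.
#'
#' @param scaffolds A data frame with columns `scaffold_id` and `seq`
#'   (softmasked nucleotide string), e.g. from [read_softmasked()].
#' @param min_len Minimum fragment length in bp to retain (default 200).
#' @param split_on_n If `TRUE` (default) runs of `N` act as separators like
#'   masked runs, so fragments never contain `N`; if `FALSE`, uppercase `N` is
#'   treated as an ordinary unmasked base and may appear inside fragments.
#' @return A tibble with one row per retained fragment: `scaffold_id`,
#'   `ordinal`, `start`, `end` (0-based half-open), `length`, `name`, `seq`.
#' @examples
#' sca <- tibble::tibble(
#'   scaffold_id = "Sca1",
#'   seq = paste0(strrep("A", 500), strrep("a", 50), strrep("G", 300))
#' )
#' split_fragments(sca)
#' @export
split_fragments <- function(scaffolds, min_len = 200, split_on_n = TRUE) {
  validate_scaffolds(scaffolds)
  check_scalar_number(min_len, "min_len", lower = 1)
  pat <- if (split_on_n) "[ACGT]+" else "[ACGTN]+"
  res <- purrr::map2(scaffolds$scaffold_id, scaffolds$seq, function(id, s) {
    m <- gregexpr(pat, s)[[1L]]
    if (m[1L] == -1L) return(NULL)
    start1 <- as.integer(m)
    len <- attr(m, "match.length")
    keep <- len >= min_len
    if (!any(keep)) return(NULL)
    start1 <- start1[keep]
    len <- len[keep]
    tibble(
      scaffold_id = id,
      ordinal = seq_along(start1),
      start = start1 - 1L,
      end = start1 - 1L + len,
      length = len,
      name = paste(id, seq_along(start1), len, sep = "_"),
      seq = substring(s, start1, start1 + len - 1L)
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(
      scaffold_id = character(), ordinal = integer(), start = integer(),
      end = integer(), length = integer(), name = character(), seq = character()
    )
  }
  out
}

#' Masked-base fraction of a set of scaffolds
#'
#' The repeat content of softmasked sequence: lowercase (masked) bases divided
#' by non-gap bases. Gap bases (`N`/`n`) are excluded from numerator and
#' denominator, so the fraction is reported over resolved sequence, the usual
#' convention for repeat-content percentages.
#'
#' @param scaffolds A data frame with columns `scaffold_id` and `seq`.
#' @param by_scaffold If `TRUE`, return a per-scaffold tibble instead of the
#'   pooled fraction.
#' @return A single numeric fraction in \[0, 1\], or a tibble
#'   (`scaffold_id`, `masked`, `unmasked`, `masked_fraction`) when
#'   `by_scaffold = TRUE`.
#' @examples
#' masked_fraction(tibble::tibble(scaffold_id = "s", seq = "ACGTacgt"))
#' @export
masked_fraction <- function(scaffolds, by_scaffold = FALSE) {
  validate_scaffolds(scaffolds)
  masked <- stringr::str_count(scaffolds$seq, "[acgt]")
  unmasked <- stringr::str_count(scaffolds$seq, "[ACGT]")
  if (by_scaffold) {
    return(tibble(
      scaffold_id = scaffolds$scaffold_id,
      masked = masked,
      unmasked = unmasked,
      masked_fraction = masked / (masked + unmasked)
    ))
  }
  tot <- sum(masked) + sum(unmasked)
  if (tot == 0) abort("no non-N bases in input")
  sum(masked) / tot
}

#' Write fragments to BED4, FASTA or a TSV manifest
#'
#' BED uses 0-based half-open scaffold coordinates with the fragment name in
#' column 4. FASTA records are keyed by fragment name and carry the uppercase
#' fragment subsequence. The TSV manifest holds `scaffold_id`, `ordinal`,
#' `start`, `end`, `length`, `name`.
#'
#' @param fragments A fragment tibble from [split_fragments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fragments_tsv()]
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- dplyr::select(fragments, "scaffold_id", "start", "end", "name")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
write_fragments_fasta <- function(fragments, path) {
  if (nrow(fragments) > 0L && !"seq" %in% names(fragments)) {
    abort("`fragments` has no `seq` column; run split_fragments() on sequence input")
  }
  ss <- Biostrings::DNAStringSet(toupper(fragments$seq %||% character()))
  names(ss) <- fragments$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
write_fragments_tsv <- function(fragments, path) {
  man <- dplyr::select(fragments, "scaffold_id", "ordinal", "start", "end",
                       "length", "name")
  readr::write_tsv(man, path)
  invisible(path)
}

#' Read a fragment manifest TSV written by [write_fragments_tsv()]
#'
#' @param path Path to the manifest.
#' @return A tibble with columns `scaffold_id`, `ordinal`, `start`, `end`,
#'   `length`, `name`.
#' @export
read_fragments_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    scaffold_id = readr::col_character(),
    ordinal = readr::col_integer(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    length = readr::col_integer(),
    name = readr::col_character()
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
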