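#' Read a samtools idxstats table of per-fragment mapped-read counts
#'
#' Expects the four tab-separated idxstats columns: reference name, reference
#' length, mapped read count, unmapped read count. The terminal `*` row for
#' unplaced reads is skipped.
#'
#' @param path Path to the idxstats-style TSV.
#' @return A tibble with columns `name`, `length`, `mapped`, `unmapped`.
#' @export
read_idxstats <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    warn(paste0("empty idxstats file: ", path))
    return(tibble(name = character(), length = integer(),
                  mapped = integer(), unmapped = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    abort(sprintf("malformed idxstats line %d in %s: expected 4 tab-separated fields, got %d",
                  which(nf != 4L)[1L], path, nf[which(nf != 4L)[1L]]))
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  keep <- m[, 1L] != "*"
  m <- m[keep, , drop = FALSE]
  num <- suppressWarnings(cbind(as.numeric(m[, 2L]), as.numeric(m[, 3L]), as.numeric(m[, 4L])))
  if (anyNA(num) || any(num < 0) || any(num != floor(num))) {
    bad <- which(rowSums(is.na(num) | num < 0 | num != floor(num)) > 0)[1L]
    abort(sprintf("malformed idxstats line %d in %s: non-integer count field",
                  which(keep)[bad], path))
  }
  if (anyDuplicated(m[, 1L])) {
    abort(sprintf("duplicate reference name in %s: %s", path,
                  m[duplicated(m[, 1L]), 1L][1L]))
  }
  tibble(name = m[, 1L], length = as.integer(num[, 1L]),
         mapped = as.integer(num[, 2L]), unmapped = as.integer(num[, 3L]))
}

#' Write an idxstats-style TSV
#'
#' Inverse of [read_idxstats()]; used chiefly to materialise simulated pool
#' counts in the format the pipeline ingests. A terminal `*` row with zero
#' counts is appended for format fidelity.
#'
#' @param counts Tibble with columns `name`, `length`, `mapped` and optionally
#'   `unmapped` (defaults to 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idxstats <- function(counts, path) {
  unmapped <- if ("unmapped" %in% names(counts)) counts$unmapped else rep(0L, nrow(counts))
  df <- data.frame(counts$name, counts$length, counts$mapped, unmapped)
  df <- rbind(df, stats::setNames(data.frame("*", 0L, 0L, 0L), names(df)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count mapped reads per reference sequence from a BAM file
#'
#' For pipelines that align pooled reads against the fragment reference, this
#' counts primary, mapped alignments per reference sequence, excluding
#' duplicate-flagged reads by default; with matching conventions it equals
#' `samtools idxstats` on the same BAM. Requires the Rsamtools package and an
#' indexed, coordinate-sorted BAM.
#'
#' @param bam_path Path to a coordinate-sorted BAM with a `.bai` index.
#' @param dedup Exclude duplicate-flagged alignments (default `TRUE`).
#' @return A tibble with columns `name`, `length`, `mapped`.
#' @export
count_bam <- function(bam_path, dedup = TRUE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("count_bam() requires the Rsamtools package")
  }
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    abort(sprintf("BAM index not found for %s; create one with Rsamtools::indexBam() or `samtools index`",
                  bam_path))
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedup) FALSE else NA
  )
  res <- Rsamtools::scanBam(bam_path,
                            param = Rsamtools::ScanBamParam(flag = flag, what = "rname"))
  counts <- table(factor(res[[1L]]$rname, levels = names(hdr)))
  tibble(name = names(hdr), length = as.integer(hdr),
         mapped = as.integer(counts))
}

#' Assemble the female/male pool count table
#'
#' Joins per-fragment mapped-read counts of the two pools into one table and
#' fixes the library totals used by the normalization factor. With
#' `totals_mode = "mapped_reads"` the totals are the column sums of the table
#' itself; with `"total_reads"` they are the externally supplied sequenced
#' library sizes (reads that failed to map still count towards the library).
#' Fragments present in only one pool are zero-filled with a warning: absence
#' from an idxstats table means zero mapped reads, not missing data.
#'
#' @param female,male Tibbles with columns `name`, `length`, `mapped` (e.g.
#'   from [read_idxstats()] or [count_bam()]).
#' @param totals_mode `"mapped_reads"` (default) or `"total_reads"`.
#' @param external_totals Numeric `c(f_total, m_total)`; required when
#'   `totals_mode = "total_reads"`.
#' @param check_names Validate that fragment names parse as
#'   `"{scaffold}_{ordinal}_{length}"` with the stored length (default `TRUE`).
#' @return A tibble with columns `name`, `length`, `f_reads`, `m_reads` and
#'   attributes `f_total`, `m_total`, `totals_mode`.
#' @export
build_count_table <- function(female, male,
                              totals_mode = c("mapped_reads", "total_reads"),
                              external_totals = NULL, check_names = TRUE) {
  totals_mode <- match.arg(totals_mode)
  for (df in list(female, male)) {
    if (!all(c("name", "length", "mapped") %in% names(df))) {
      abort("pool counts need columns `name`, `length`, `mapped`")
    }
    if (any(df$mapped < 0)) abort("negative mapped counts")
  }
  tab <- dplyr::full_join(
    dplyr::select(female, "name", "length", f_reads = "mapped"),
    dplyr::select(male, "name", male_length = "length", m_reads = "mapped"),
    by = "name"
  )
  len_both <- !is.na(tab$length) & !is.na(tab$male_length)
  if (any(tab$length[len_both] != tab$male_length[len_both])) {
    abort("fragment lengths disagree between pools")
  }
  n_fill <- sum(is.na(tab$f_reads)) + sum(is.na(tab$m_reads))
  if (n_fill > 0L) {
    warn(sprintf("%d fragment(s) absent from one pool; zero-filled", n_fill))
  }
  tab <- dplyr::mutate(tab,
    length = dplyr::coalesce(.data$length, .data$male_length),
    f_reads = dplyr::coalesce(.data$f_reads, 0L),
    m_reads = dplyr::coalesce(.data$m_reads, 0L)
  )
  tab <- dplyr::select(tab, "name", "length", "f_reads", "m_reads")
  if (check_names) {
    parsed <- parse_fragment_names(tab$name)
    if (any(parsed$length != tab$length)) {
      abort(paste0("fragment name length differs from stored length: ",
                   tab$name[which(parsed$length != tab$length)[1L]]))
    }
  }
  if (totals_mode == "total_reads") {
    if (is.null(external_totals)) {
      abort("totals_mode = \"total_reads\" requires `external_totals = c(f_total, m_total)`")
    }
    stopifnot(length(external_totals) == 2L, all(external_totals >= 0))
    if (external_totals[1L] < sum(tab$f_reads) || external_totals[2L] < sum(tab$m_reads)) {
      abort("external totals smaller than the mapped-count sums")
    }
    f_total <- external_totals[1L]; m_total <- external_totals[2L]
  } else {
    f_total <- sum(as.numeric(tab$f_reads)); m_total <- sum(as.numeric(tab$m_reads))
  }
  structure(tab, f_total = f_total, m_total = m_total,
            totals_mode = totals_mode,
            class = c("fr_counts", class(tab)))
}

#' Library totals of a count table
#'
#' @param counts A count table from [build_count_table()].
#' @return Named numeric vector `c(f_total, m_total)`.
#' @export
pool_totals <- function(counts) {
  f <- attr(counts, "f_total"); m <- attr(counts, "m_total")
  if (is.null(f) || is.null(m)) {
    f <- sum(as.numeric(counts$f_reads)); m <- sum(as.numeric(counts$m_reads))
  }
  c(f_total = f, m_total = m)
}
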