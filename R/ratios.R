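#' Normalization factor between the two pool libraries
#'
#' The factor `norm = M_total / F_total` corrects the raw per-fragment
#' female:male ratio for unequal library sizes, so that autosomal fragments
#' centre on 1 regardless of how deeply each pool was sequenced. The totals
#' are whatever the count table fixed at build time (mapped-read sums by
#' default, or external sequenced-library sizes).
#'
#' @param counts Count table from [build_count_table()].
#' @return A single positive number.
#' @export
compute_norm <- function(counts) {
  tot <- pool_totals(counts)
  if (tot[["f_total"]] <= 0) abort("female library total is zero; cannot normalize")
  unname(tot[["m_total"]] / tot[["f_total"]])
}

#' Per-fragment normalized female:male ratio statistic
#'
#' For each fragment i with female-pool count F_i and male-pool count M_i,
#' computes the raw ratio `R_i = F_i / M_i` and the normalized ratio
#' `R_i_norm = R_i * norm` with `norm = M_total / F_total`. Under an XX/XY
#' system the expectation of `R_i_norm` is ~0 for Y-linked fragments, ~1 for
#' autosomal fragments and ~2 for X-linked fragments. Fragments with
#' `M_i = 0` have undefined ratios (`NA`) and are banded `low_coverage`, as
#' are all fragments with `M_i < min_male_reads`.
#'
#' @param counts Count table from [build_count_table()].
#' @param norm Normalization factor; defaults to [compute_norm()] of `counts`.
#' @param y_max Upper bound of the Y-candidate band on `R_i_norm`
#'   (default 0.3, strict `<`).
#' @param min_male_reads Minimum male-pool reads for a fragment to be
#'   classifiable (default 15); guards against low-coverage false positives.
#' @param x_min,auto_band Diagnostic band edges for X-like (`>= x_min`) and
#'   autosome-like (within `auto_band`) fragments; only the Y threshold is
#'   used for inference downstream.
#' @return A tibble with columns `name`, `length`, `f_reads`, `m_reads`, `r`,
#'   `r_norm`, `passes_depth`, `band`; attribute `norm`.
#' @export
compute_ratios <- function(counts, norm = NULL, y_max = 0.3,
                           min_male_reads = 15, x_min = 1.5,
                           auto_band = c(0.6, 1.4)) {
  if (is.null(norm)) norm <- compute_norm(counts)
  check_scalar_number(norm, "norm", lower = .Machine$double.xmin)
  out <- tibble(
    name = counts$name,
    length = counts$length,
    f_reads = counts$f_reads,
    m_reads = counts$m_reads,
    r = ifelse(counts$m_reads > 0, counts$f_reads / counts$m_reads, NA_real_),
    passes_depth = counts$m_reads >= min_male_reads
  )
  out$r_norm <- out$r * norm
  out$band <- classify_band(out$r_norm, out$m_reads, y_max = y_max,
                            min_male_reads = min_male_reads, x_min = x_min,
                            auto_band = auto_band)
  structure(out, norm = norm,
            y_max = y_max, min_male_reads = min_male_reads,
            class = c("fr_ratios", class(out)))
}

#' Band classification of normalized ratios
#'
#' Assigns each fragment to `low_coverage` (male-pool depth below
#' `min_male_reads`), `Y_candidate` (`r_norm < y_max`), `X_like`
#' (`r_norm >= x_min`), `autosome_like` (within `auto_band`) or
#' `unclassified` (the gaps between bands). All comparisons on `y_max` are
#' strict.
#'
#' @param r_norm Numeric vector of normalized ratios (`NA` allowed).
#' @param m_reads Integer vector of male-pool counts.
#' @inheritParams compute_ratios
#' @return A factor with levels `Y_candidate`, `autosome_like`, `X_like`,
#'   `low_coverage`, `unclassified`.
#' @export
classify_band <- function(r_norm, m_reads, y_max = 0.3, min_male_reads = 15,
                          x_min = 1.5, auto_band = c(0.6, 1.4)) {
  stopifnot(length(r_norm) == length(m_reads))
  band <- rep("unclassified", length(r_norm))
  band[!is.na(r_norm) & r_norm < y_max] <- "Y_candidate"
  band[!is.na(r_norm) & r_norm >= x_min] <- "X_like"
  band[!is.na(r_norm) & r_norm >= auto_band[1L] & r_norm <= auto_band[2L]] <- "autosome_like"
  band[is.na(r_norm) | m_reads < min_male_reads] <- "low_coverage"
  factor(band, levels = c("Y_candidate", "autosome_like", "X_like",
                          "low_coverage", "unclassified"))
}

#' Select Y-candidate fragments below a ratio threshold
#'
#' Returns the fragments with adequate male-pool depth and
#' `r_norm < y_max` (strict). Candidate sets are nested in the threshold:
#' `select_candidates(x, 0.15)` is always a subset of
#' `select_candidates(x, 0.3)`.
#'
#' @param ratios Ratio table from [compute_ratios()].
#' @param y_max Threshold on `r_norm` (default 0.3; 0.15 is the stringent
#'   marker-selection setting).
#' @return The subset of `ratios` rows that qualify, as a tibble.
#' @export
select_candidates <- function(ratios, y_max = 0.3) {
  check_scalar_number(y_max, "y_max", lower = 0)
  as_tibble(ratios)[which(ratios$passes_depth & !is.na(ratios$r_norm) &
                            ratios$r_norm < y_max), ]
}

#' Write the per-fragment ratio table
#'
#' @param ratios Ratio table from [compute_ratios()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ratios <- function(ratios, path) {
  readr::write_tsv(as_tibble(ratios), path)
  invisible(path)
}
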