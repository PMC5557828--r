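#' Upper-tail hypergeometric probability in log space
#'
#' Computes `P(X >= k)` for `X` hypergeometric with population size `N`, `n`
#' marked elements and sample size `M`: the probability that a scaffold
#' carrying `M` fragments holds `k` or more Y-candidate fragments if
#' candidates were spread over the genome at random. Terms are accumulated as
#' `lchoose` sums combined by log-sum-exp, which keeps full precision at
#' genome scale (N of several hundred thousand, P-values down past 1e-75).
#'
#' All arguments are vectorised and recycled.
#'
#' @param N Population size (total fragments genome-wide).
#' @param n Number of marked elements (candidate fragments genome-wide).
#' @param M Sample size (fragments on the scaffold).
#' @param k Observed marked elements in the sample (candidates on the
#'   scaffold).
#' @param log10 If `TRUE` return `log10(P)` instead of `P`.
#' @return Numeric vector of upper-tail probabilities (or their log10).
#' @examples
#' hypergeom_upper_tail(605448, 923, 7, 6)   # 8.634194e-17
#' hypergeom_upper_tail(20, 5, 4, 2)         # 241/969
#' @export
hypergeom_upper_tail <- function(N, n, M, k, log10 = FALSE) {
  args <- vctrs_recycle(N = N, n = n, M = M, k = k)
  N <- args$N; n <- args$n; M <- args$M; k <- args$k
  if (any(c(N, n, M, k) < 0) || any(c(N, n, M, k) != floor(c(N, n, M, k)))) {
    abort("N, n, M, k must be non-negative integers")
  }
  if (any(n > N) || any(M > N)) abort("n and M cannot exceed N")
  if (any(k > pmin(M, n))) abort("k cannot exceed min(M, n)")
  logp <- purrr::pmap_dbl(list(N, n, M, k), function(N, n, M, k) {
    if (k == 0) return(0)
    i_all <- max(0, M - (N - n)):min(M, n)
    if (k <= i_all[1L]) return(0)
    lt <- lchoose(n, i_all) + lchoose(N - n, M - i_all) - lchoose(N, M)
    tot <- logsumexp(lt)     # ~0; normalizing cancels shared rounding
    up <- logsumexp(lt[i_all >= k]) - tot
    if (up > log(0.5)) {
      # tail close to 1: the complement of the (short) lower tail is far
      # better conditioned than the direct sum
      log1p(-exp(logsumexp(lt[i_all < k]) - tot))
    } else {
      up
    }
  })
  logp <- pmin(logp, 0)
  if (log10) logp / log(10) else exp(logp)
}

# minimal common-length recycling for scalar-or-equal-length args
vctrs_recycle <- function(...) {
  args <- list(...)
  lens <- lengths(args)
  len <- if (any(lens == 0L)) 0L else max(lens)
  if (any(lens != 1L & lens != len)) {
    abort("arguments must have length 1 or a common length")
  }
  lapply(args, rep_len, len)
}

#' Per-scaffold hypergeometric enrichment of Y-candidate fragments
#'
#' Scaffolds descending from the Y chromosome should carry significantly more
#' Y-candidate fragments (low `r_norm`) than expected if candidates were
#' scattered at random over the genome's fragments. For each scaffold with at
#' least one candidate, tests `P(X >= k)` where `M` is the scaffold's fragment
#' count, `k` its candidate count, `N` the genome-wide fragment count and `n`
#' the genome-wide candidate count. The significance call applies a raw
#' threshold `p < alpha` (strict) with no multiple-testing correction by
#' default, matching the method's operating point; Bonferroni/BH-adjusted
#' calls are available via `p_adjust`.
#'
#' @param ratios Ratio table from [compute_ratios()] covering the whole
#'   fragment universe (defines `N`).
#' @param candidates Candidate subset; defaults to
#'   `select_candidates(ratios, y_max)`.
#' @param y_max Candidate threshold used when `candidates` is `NULL`.
#' @param alpha Significance level on the raw P-value (default 1e-5).
#' @param p_adjust Multiple-testing method for the `enriched` flag: `"none"`
#'   (default), `"bonferroni"` or `"BH"`.
#' @param include_zero Also report scaffolds with zero candidates (`p = 1`);
#'   off by default.
#' @return A tibble sorted by (`p_value`, `scaffold_id`) with columns
#'   `scaffold_id`, `M`, `k`, `N`, `n`, `p_value`, `log10_p`, `enriched`;
#'   attributes `alpha`, `N`, `n`.
#' @export
enrich_scaffolds <- function(ratios, candidates = NULL, y_max = 0.3,
                             alpha = 1e-5, p_adjust = c("none", "bonferroni", "BH"),
                             include_zero = FALSE) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(candidates)) candidates <- select_candidates(ratios, y_max)
  if (!all(candidates$name %in% ratios$name)) {
    abort(paste0("candidate fragments missing from `ratios`: ",
                 paste(utils::head(setdiff(candidates$name, ratios$name), 5L),
                       collapse = ", ")))
  }
  frag <- parse_fragment_names(ratios$name)
  N <- nrow(ratios)
  n <- nrow(candidates)
  per <- frag |>
    dplyr::mutate(is_cand = .data$name %in% candidates$name) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::summarise(M = dplyr::n(), k = sum(.data$is_cand), .groups = "drop")
  if (!include_zero) per <- dplyr::filter(per, .data$k > 0L)
  log10_p <- hypergeom_upper_tail(N, n, per$M, per$k, log10 = TRUE)
  padj <- switch(p_adjust,
    none = 10^log10_p,
    stats::p.adjust(10^log10_p, method = p_adjust)
  )
  out <- tibble(
    scaffold_id = per$scaffold_id, M = per$M, k = per$k, N = N, n = n,
    p_value = 10^log10_p, log10_p = log10_p,
    enriched = padj < alpha
  )
  out <- dplyr::arrange(out, .data$p_value, .data$scaffold_id)
  structure(out, alpha = alpha, N = N, n = n,
            class = c("fr_enrichment", class(out)))
}

#' Write the enrichment report as TSV and optionally JSON
#'
#' Rows are ordered by (`p_value`, `scaffold_id`). The JSON mirror carries
#' the same records for programmatic use, with full double precision.
#'
#' @param enrichment Result of [enrich_scaffolds()].
#' @param tsv_path Output TSV path.
#' @param json_path Optional JSON output path.
#' @return `tsv_path`, invisibly.
#' @export
write_enrichment <- function(enrichment, tsv_path, json_path = NULL) {
  tab <- dplyr::arrange(as_tibble(enrichment), .data$p_value, .data$scaffold_id)
  readr::write_tsv(tab, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, digits = NA, auto_unbox = FALSE)
  }
  invisible(tsv_path)
}
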