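#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' @param x An `fr_enrichment` from [enrich_scaffolds()].
#' @param ... Unused.
#' @return A plain tibble of the per-scaffold test results.
#' @method tidy fr_enrichment
#' @export
tidy.fr_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "fr_enrichment")
  out
}

#' One-row summary of an enrichment result
#'
#' @inheritParams tidy.fr_enrichment
#' @return A one-row tibble: `n_scaffolds`, `n_enriched`, `alpha`,
#'   `n_fragments`, `n_candidates`, `min_p`.
#' @method glance fr_enrichment
#' @export
glance.fr_enrichment <- function(x, ...) {
  tibble(
    n_scaffolds = nrow(x),
    n_enriched = sum(x$enriched),
    alpha = attr(x, "alpha"),
    n_fragments = attr(x, "N"),
    n_candidates = attr(x, "n"),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_
  )
}

#' Tidy a pipeline run into the per-fragment ratio table
#'
#' @param x An `fr_run` from [run_fragment_ratio()].
#' @param ... Unused.
#' @return A tibble with the per-fragment statistics plus a `candidate`
#'   flag at the run's `y_max`.
#' @method tidy fr_run
#' @export
tidy.fr_run <- function(x, ...) {
  out <- as_tibble(x$ratios)
  class(out) <- setdiff(class(out), "fr_ratios")
  out$candidate <- out$name %in% x$candidates$name
  out
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.fr_run
#' @return A one-row tibble mirroring [summarize_run()].
#' @method glance fr_run
#' @export
glance.fr_run <- function(x, ...) {
  s <- x$summary
  tibble(
    n_fragments = s$n_fragments,
    n_candidates = s$n_candidates,
    n_candidate_scaffolds = s$n_candidate_scaffolds,
    candidate_bp = s$candidate_bp,
    n_stringent_candidates = s$n_stringent_candidates,
    n_enriched_scaffolds = s$n_enriched_scaffolds,
    n_markers = s$n_markers,
    marker_bp = s$marker_bp,
    norm = s$norm
  )
}
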