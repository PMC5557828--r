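as_scaffold_table <- function(x) {
  if (is.character(x) && length(x) == 1L) read_softmasked(x) else x
}

as_pool_counts <- function(x) {
  if (is.character(x) && length(x) == 1L) read_idxstats(x) else x
}

#' Run the whole fragment-ratio pipeline
#'
#' Chains the stages end to end: split the softmasked reference into
#' fragments, assemble the pooled count table, compute normalized ratios,
#' call Y-candidate fragments below `y_max`, test per-scaffold hypergeometric
#' enrichment at `alpha`, take the stringent candidates
#' (`r_norm < stringent_max`) on the enriched scaffolds, and (when alignment
#' hits against a female assembly are supplied) discard those with strong
#' female homology, leaving the marker candidates.
#'
#' @param reference Softmasked FASTA path, or a scaffold tibble from
#'   [read_softmasked()].
#' @param female,male idxstats TSV paths or count tibbles
#'   (`name`, `length`, `mapped`).
#' @param hits Optional tabular alignment hits (path or tibble from
#'   [read_blast_tab()]) of fragments vs a female assembly; when absent, the
#'   homology stage is skipped and the stringent candidates on enriched
#'   scaffolds stand as markers.
#' @param min_len Minimum fragment length in bp (default 200).
#' @param y_max Y-candidate threshold on `r_norm` (default 0.3).
#' @param stringent_max Stringent marker-selection threshold (default 0.15).
#' @param min_male_reads Minimum male-pool depth (default 15).
#' @param alpha Enrichment significance level (default 1e-5).
#' @param evalue_max Homology discard threshold (default 1e-5).
#' @param totals_mode,external_totals Passed to [build_count_table()].
#' @param out_dir Optional directory; when given, all stage TSV/FASTA/JSON
#'   artifacts and a provenance block are written there.
#' @return An object of class `fr_run`: list with `fragments`, `counts`,
#'   `ratios`, `candidates`, `stringent`, `enrichment`, `markers`, `summary`
#'   and `params`.
#' @export
run_fragment_ratio <- function(reference, female, male, hits = NULL,
                               min_len = 200, y_max = 0.3,
                               stringent_max = 0.15, min_male_reads = 15,
                               alpha = 1e-5, evalue_max = 1e-5,
                               totals_mode = "mapped_reads",
                               external_totals = NULL, out_dir = NULL) {
  if (stringent_max > y_max) abort("`stringent_max` must not exceed `y_max`")
  scaffolds <- as_scaffold_table(reference)
  fragments <- split_fragments(scaffolds, min_len = min_len)
  counts <- build_count_table(as_pool_counts(female), as_pool_counts(male),
                              totals_mode = totals_mode,
                              external_totals = external_totals)
  missing <- setdiff(fragments$name, counts$name)
  if (length(missing) > 0L) {
    warn(sprintf("%d fragment(s) without counts in either pool; treated as zero",
                 length(missing)))
  }
  ratios <- compute_ratios(counts, y_max = y_max,
                           min_male_reads = min_male_reads)
  candidates <- select_candidates(ratios, y_max = y_max)
  stringent <- select_candidates(ratios, y_max = stringent_max)
  enrichment <- enrich_scaffolds(ratios, candidates, alpha = alpha)
  enriched_sc <- enrichment$scaffold_id[enrichment$enriched]
  stringent_on_enriched <- stringent[
    parse_fragment_names(stringent$name)$scaffold_id %in% enriched_sc, ]
  markers <- if (!is.null(hits)) {
    hits_tab <- if (is.character(hits) && length(hits) == 1L)
      read_blast_tab(hits) else hits
    filter_by_homology(stringent_on_enriched, hits_tab,
                       evalue_max = evalue_max)
  } else {
    stringent_on_enriched
  }
  params <- list(min_len = min_len, y_max = y_max,
                 stringent_max = stringent_max,
                 min_male_reads = min_male_reads, alpha = alpha,
                 evalue_max = evalue_max, totals_mode = totals_mode,
                 external_totals = external_totals,
                 norm = attr(ratios, "norm"))
  run <- structure(list(
    fragments = fragments, counts = counts, ratios = ratios,
    candidates = candidates, stringent = stringent,
    enrichment = enrichment, markers = markers, params = params
  ), class = "fr_run")
  run$summary <- summarize_run(run)
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir,
                                             inputs = list(reference = reference,
                                                           female = female,
                                                           male = male,
                                                           hits = hits))
  run
}

candidate_bp <- function(names) {
  if (length(names) == 0L) return(0L)
  sum(parse_fragment_names(names)$length)
}

#' Summarize a pipeline run
#'
#' Mirrors the headline tallies of a fragment-ratio analysis: fragment count,
#' candidate counts at the standard and stringent thresholds with the number
#' of scaffolds involved and candidate bp, the enriched scaffolds with their
#' total bp, and the retained markers with theirs.
#'
#' @param run An `fr_run` from [run_fragment_ratio()].
#' @return A named list (JSON-ready).
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "fr_run"))
  enr <- run$enrichment
  enriched <- enr$scaffold_id[enr$enriched]
  cand_sc <- unique(parse_fragment_names(run$candidates$name)$scaffold_id)
  list(
    n_fragments = nrow(run$ratios),
    n_candidates = nrow(run$candidates),
    n_candidate_scaffolds = length(cand_sc),
    candidate_bp = candidate_bp(run$candidates$name),
    n_stringent_candidates = nrow(run$stringent),
    enriched_scaffolds = enriched,
    n_enriched_scaffolds = length(enriched),
    enriched_scaffold_fragments_bp = candidate_bp(
      run$ratios$name[parse_fragment_names(run$ratios$name)$scaffold_id %in% enriched]),
    marker_fragments = run$markers$name,
    n_markers = nrow(run$markers),
    marker_bp = candidate_bp(run$markers$name),
    norm = run$params$norm
  )
}

write_run_artifacts <- function(run, out_dir, inputs = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_fragments_tsv(run$fragments, p("fragments.tsv"))
  write_fragments_bed(run$fragments, p("fragments.bed"))
  write_ratios(run$ratios, p("ratios.tsv"))
  write_enrichment(run$enrichment, p("enrichment.tsv"), p("enrichment.json"))
  if (nrow(run$markers) > 0L || nrow(run$fragments) > 0L) {
    export_marker_candidates(run$markers, run$fragments,
                             p("markers.fasta"), p("markers.tsv"))
  }
  jsonlite::write_json(run$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  input_paths <- Filter(function(x) is.character(x) && length(x) == 1L &&
                          file.exists(x), inputs)
  prov <- list(
    package = "fragratio",
    version = as.character(utils::packageVersion("fragratio")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    params = run$params,
    input_md5 = if (length(input_paths))
      as.list(stats::setNames(unname(tools::md5sum(unlist(input_paths))),
                              names(input_paths))) else list()
  )
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Rebuild a run summary from stage artifacts on disk
#'
#' Reads the intermediate TSVs written by [run_fragment_ratio()] with an
#' `out_dir` and recomputes the summary, so reporting is idempotent with
#' respect to the pipeline run.
#'
#' @param out_dir Directory holding `fragments.tsv`, `ratios.tsv`,
#'   `enrichment.tsv`, `markers.tsv`.
#' @param y_max,stringent_max Thresholds used in the original run.
#' @return The same summary list shape as [summarize_run()].
#' @export
summarize_from_artifacts <- function(out_dir, y_max = 0.3, stringent_max = 0.15) {
  need <- c("fragments.tsv", "ratios.tsv", "enrichment.tsv")
  miss <- need[!file.exists(file.path(out_dir, need))]
  if (length(miss)) {
    abort(paste0("missing intermediate(s) ", paste(miss, collapse = ", "),
                 "; rerun the corresponding stage"))
  }
  ratios <- readr::read_tsv(file.path(out_dir, "ratios.tsv"),
                            col_types = readr::cols())
  enr <- readr::read_tsv(file.path(out_dir, "enrichment.tsv"),
                         col_types = readr::cols())
  markers <- if (file.exists(file.path(out_dir, "markers.tsv"))) {
    readr::read_tsv(file.path(out_dir, "markers.tsv"),
                    col_types = readr::cols())
  } else tibble(name = character())
  candidates <- ratios[ratios$passes_depth & !is.na(ratios$r_norm) &
                         ratios$r_norm < y_max, ]
  stringent <- ratios[ratios$passes_depth & !is.na(ratios$r_norm) &
                        ratios$r_norm < stringent_max, ]
  enriched <- enr$scaffold_id[enr$enriched]
  cand_sc <- unique(parse_fragment_names(candidates$name)$scaffold_id)
  list(
    n_fragments = nrow(ratios),
    n_candidates = nrow(candidates),
    n_candidate_scaffolds = length(cand_sc),
    candidate_bp = candidate_bp(candidates$name),
    n_stringent_candidates = nrow(stringent),
    enriched_scaffolds = enriched,
    n_enriched_scaffolds = length(enriched),
    enriched_scaffold_fragments_bp = candidate_bp(
      ratios$name[parse_fragment_names(ratios$name)$scaffold_id %in% enriched]),
    marker_fragments = markers$name,
    n_markers = nrow(markers),
    marker_bp = candidate_bp(markers$name),
    norm = NULL
  )
}

#' @export
print.fr_run <- function(x, ...) {
  s <- x$summary
  cat("Fragment-ratio pipeline run\n")
  cat(sprintf("  fragments: %d   norm: %.6f\n", s$n_fragments, s$norm))
  cat(sprintf("  Y candidates (r_norm < %.2f): %d on %d scaffolds (%d bp)\n",
              x$params$y_max, s$n_candidates, s$n_candidate_scaffolds,
              s$candidate_bp))
  cat(sprintf("  stringent candidates (r_norm < %.2f): %d\n",
              x$params$stringent_max, s$n_stringent_candidates))
  cat(sprintf("  enriched scaffolds (p < %g): %d [%s]\n", x$params$alpha,
              s$n_enriched_scaffolds,
              paste(s$enriched_scaffolds, collapse = ", ")))
  cat(sprintf("  marker candidates: %d (%d bp)\n", s$n_markers, s$marker_bp))
  invisible(x)
}
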