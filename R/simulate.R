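#' Configuration for the pooled-count simulator
#'
#' Defines a toy XX/XY genome and sequencing design with known truth. The
#' defaults emulate the study conditions the method was built for: a
#' fragmented softmasked male assembly resequenced as one female and one male
#' pool at ~25x each with 150-bp reads, genome-wide repeat density ~0.17
#' rising to ~0.30 on Y scaffolds.
#'
#' @param seed RNG seed; every random draw in the simulator flows through it.
#' @param n_auto,n_x,n_y Number of autosomal / X / Y scaffolds.
#' @param scaffold_len_range Scaffold length range in bp (uniform draw).
#' @param repeat_density Fraction of masked (lowercase) bases on autosomal
#'   and X scaffolds.
#' @param repeat_density_y Masked fraction on Y scaffolds; higher by default,
#'   reflecting repeat accumulation on non-recombining Y sequence.
#' @param depth_f,depth_m Mean diploid-equivalent coverage of the female and
#'   male pools (an autosomal base receives `depth` regardless of sex).
#' @param leakage Fraction of female-pool depth deposited on Y fragments,
#'   emulating X-homologous Y sequence that attracts female reads;
#'   0 = fully diverged Y.
#' @param read_len Read length in bp; converts base coverage to read counts.
#' @param overdispersion Optional negative-binomial dispersion (variance
#'   `mu + overdispersion * mu^2`); `NULL` (default) draws Poisson counts.
#' @param unmasked_run_mean Mean length in bp of unmasked runs between repeat
#'   blocks; with the class repeat density this sets fragment sizes.
#' @return A list of class `fr_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_auto = 50L, n_x = 5L, n_y = 5L,
                       scaffold_len_range = c(10000L, 40000L),
                       repeat_density = 0.17, repeat_density_y = 0.30,
                       depth_f = 25, depth_m = 25, leakage = 0,
                       read_len = 150L, overdispersion = NULL,
                       unmasked_run_mean = 800) {
  cfg <- list(seed = as.integer(seed), n_auto = as.integer(n_auto),
              n_x = as.integer(n_x), n_y = as.integer(n_y),
              scaffold_len_range = as.integer(scaffold_len_range),
              repeat_density = repeat_density,
              repeat_density_y = repeat_density_y,
              depth_f = depth_f, depth_m = depth_m, leakage = leakage,
              read_len = as.integer(read_len),
              overdispersion = overdispersion,
              unmasked_run_mean = unmasked_run_mean)
  with(cfg, {
    stopifnot(n_auto >= 0L, n_x >= 0L, n_y >= 0L,
              length(scaffold_len_range) == 2L,
              scaffold_len_range[1L] >= 1L,
              scaffold_len_range[1L] <= scaffold_len_range[2L],
              repeat_density >= 0, repeat_density < 1,
              repeat_density_y >= 0, repeat_density_y < 1,
              depth_f >= 0, depth_m >= 0,
              leakage >= 0, leakage <= 1,
              read_len >= 1L, unmasked_run_mean > 0)
  })
  if (!is.null(cfg$overdispersion)) stopifnot(cfg$overdispersion > 0)
  structure(cfg, class = "fr_sim_config")
}

# one softmasked scaffold: alternate unmasked/masked runs at target density
sim_scaffold_seq <- function(len, density, run_mean) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (density > 0) {
    masked_mean <- run_mean * density / (1 - density)
    runs <- integer(0)
    total <- 0L
    unmasked_next <- stats::runif(1) > density
    first_unmasked <- unmasked_next
    while (total < len) {
      mu <- if (unmasked_next) run_mean else masked_mean
      r <- max(1L, as.integer(stats::rexp(1L, rate = 1 / mu)))
      runs <- c(runs, r)
      total <- total + r
      unmasked_next <- !unmasked_next
    }
    mask <- inverse.rle(list(
      lengths = runs,
      values = rep_len(c(!first_unmasked, first_unmasked), length(runs))
    ))[seq_len(len)]
    bases[mask] <- tolower(bases[mask])
  }
  paste(bases, collapse = "")
}

#' Simulate a softmasked toy genome with known chromosome classes
#'
#' Draws `n_auto + n_x + n_y` scaffolds with interleaved uppercase blocks and
#' lowercase repeat runs at the configured density (Y scaffolds at
#' `repeat_density_y`). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `scaffolds` (tibble `scaffold_id`, `seq`) and
#'   `truth` (tibble `scaffold_id`, `class` in `{A, X, Y}`, `length`).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "fr_sim_config"))
  n_total <- config$n_auto + config$n_x + config$n_y
  if (n_total == 0L) abort("config defines zero scaffolds")
  classes <- rep(c("A", "X", "Y"), c(config$n_auto, config$n_x, config$n_y))
  with_seed(config$seed, {
    lens <- sample(config$scaffold_len_range[1L]:config$scaffold_len_range[2L],
                   n_total, replace = TRUE)
    dens <- ifelse(classes == "Y", config$repeat_density_y, config$repeat_density)
    seqs <- purrr::map2_chr(lens, dens, sim_scaffold_seq,
                            run_mean = config$unmasked_run_mean)
  })
  scaffolds <- tibble(scaffold_id = paste0("Sca", seq_len(n_total)), seq = seqs)
  truth <- tibble(scaffold_id = scaffolds$scaffold_id, class = classes,
                  length = lens)
  list(scaffolds = scaffolds, truth = truth)
}

# haploid copies carried by each pool: female is XX, male is XY
copies_female <- c(A = 2, X = 2, Y = 0)
copies_male <- c(A = 2, X = 1, Y = 1)

#' Simulate female/male pooled read counts over fragments
#'
#' Per fragment of length L and chromosome class c, the male-pool count is
#' drawn with mean `depth_m * copies_m(c)/2 * L / read_len` where the male
#' carries (2, 1, 1) copies of (autosome, X, Y); the female-pool count uses
#' copies (2, 2, 0) plus, for Y fragments, an additive leakage term
#' `leakage * depth_f * L / read_len` emulating X-homologous Y sequence.
#' Counts are Poisson, or negative binomial when `config$overdispersion` is
#' set. Deterministic given `config$seed`.
#'
#' @param fragments Fragment table from [split_fragments()] on the simulated
#'   genome.
#' @param truth Truth table from [simulate_genome()].
#' @param config The same [sim_config()] used for the genome.
#' @return A list with `female` and `male` count tibbles (`name`, `length`,
#'   `mapped`, `unmapped`), and `truth_fragments` (per-fragment class and
#'   expected counts `lambda_f`, `lambda_m`).
#' @export
simulate_pool_counts <- function(fragments, truth, config = sim_config()) {
  stopifnot(inherits(config, "fr_sim_config"))
  if (!all(fragments$scaffold_id %in% truth$scaffold_id)) {
    abort("truth table does not cover all fragment scaffolds")
  }
  cls <- truth$class[match(fragments$scaffold_id, truth$scaffold_id)]
  per_read <- fragments$length / config$read_len
  lambda_m <- config$depth_m * copies_male[cls] / 2 * per_read
  lambda_f <- config$depth_f * copies_female[cls] / 2 * per_read +
    ifelse(cls == "Y", config$leakage * config$depth_f * per_read, 0)
  draw <- function(mu) {
    if (is.null(config$overdispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$overdispersion)
    }
  }
  with_seed(config$seed + 1L, {
    f_counts <- draw(lambda_f)
    m_counts <- draw(lambda_m)
  })
  mk <- function(counts) tibble(name = fragments$name,
                                length = fragments$length,
                                mapped = as.integer(counts),
                                unmapped = 0L)
  list(
    female = mk(f_counts),
    male = mk(m_counts),
    truth_fragments = tibble(name = fragments$name,
                             scaffold_id = fragments$scaffold_id,
                             class = unname(cls),
                             lambda_f = unname(lambda_f),
                             lambda_m = unname(lambda_m))
  )
}

#' Run genome simulation, fragmentation and count simulation in one call
#'
#' @param config A [sim_config()].
#' @param min_len Minimum fragment length passed to [split_fragments()].
#' @return A list with `scaffolds`, `truth`, `fragments`, `female`, `male`,
#'   `truth_fragments`.
#' @export
simulate_dataset <- function(config = sim_config(), min_len = 200) {
  gen <- simulate_genome(config)
  fragments <- split_fragments(gen$scaffolds, min_len = min_len)
  counts <- simulate_pool_counts(fragments, gen$truth, config)
  c(gen, list(fragments = fragments), counts)
}

#' Score pipeline recovery against simulation truth
#'
#' Compares the enrichment calls and the fragment-level candidate set with
#' the simulator's ground truth: scaffold-level sensitivity (true Y scaffolds
#' called enriched at `alpha`), scaffold-level false discovery, and the
#' fragment-level confusion matrix of the `r_norm < y_max` rule.
#'
#' @param enrichment Result of [enrich_scaffolds()] on the simulated data.
#' @param candidates Candidate fragments (from [select_candidates()]).
#' @param truth Scaffold truth from [simulate_genome()]; fragment-level truth
#'   is taken from `truth_fragments` when supplied there instead.
#' @param ratios Full ratio table (defines the fragment universe for the
#'   confusion matrix).
#' @param alpha Significance level for the enriched call.
#' @return A list of class `fr_recovery`: `scaffold_sensitivity`,
#'   `scaffold_fdr`, `n_true_y`, `enriched_scaffolds`, `false_enriched`,
#'   and `confusion` (tibble with predicted vs true fragment class).
#' @export
evaluate_recovery <- function(enrichment, candidates, truth, ratios,
                              alpha = 1e-5) {
  frag_truth <- if (all(c("name", "class") %in% names(truth))) truth else NULL
  sc_truth <- if ("scaffold_id" %in% names(truth) && "class" %in% names(truth) &&
                  !"name" %in% names(truth)) truth else {
    dplyr::distinct(dplyr::select(truth, "scaffold_id", "class"))
  }
  if (!all(ratios$name %in% (frag_truth$name %||% ratios$name))) {
    abort("fragment truth does not cover the ratio table")
  }
  enriched <- enrichment$scaffold_id[enrichment$p_value < alpha]
  y_scaffolds <- sc_truth$scaffold_id[sc_truth$class == "Y"]
  sens <- if (length(y_scaffolds)) mean(y_scaffolds %in% enriched) else NA_real_
  false_enr <- setdiff(enriched, y_scaffolds)
  if (is.null(frag_truth)) {
    frag_truth <- tibble(
      name = ratios$name,
      class = sc_truth$class[match(parse_fragment_names(ratios$name)$scaffold_id,
                                   sc_truth$scaffold_id)]
    )
  }
  if (anyNA(frag_truth$class[match(ratios$name, frag_truth$name)])) {
    abort("truth/prediction universe mismatch: unlabelled fragments")
  }
  conf <- tibble(
    name = ratios$name,
    true_y = frag_truth$class[match(ratios$name, frag_truth$name)] == "Y",
    called_y = ratios$name %in% candidates$name
  ) |>
    dplyr::count(.data$true_y, .data$called_y, name = "n_fragments")
  structure(list(
    scaffold_sensitivity = sens,
    scaffold_fdr = if (length(enriched)) length(false_enr) / length(enriched) else 0,
    n_true_y = length(y_scaffolds),
    enriched_scaffolds = enriched,
    false_enriched = false_enr,
    confusion = conf
  ), class = "fr_recovery")
}

#' @export
print.fr_recovery <- function(x, ...) {
  cat("Recovery vs simulation truth\n")
  cat(sprintf("  Y-scaffold sensitivity: %.3f (%d true Y scaffolds)\n",
              x$scaffold_sensitivity, x$n_true_y))
  cat(sprintf("  enriched scaffolds: %d (false: %d; FDR %.3f)\n",
              length(x$enriched_scaffolds), length(x$false_enriched),
              x$scaffold_fdr))
  cat("  fragment confusion (true_y x called_y):\n")
  print(as.data.frame(x$confusion), row.names = FALSE)
  invisible(x)
}

#' Write a minimal SAM file realising simulated per-fragment counts
#'
#' Places the simulated number of single-end reads at the start of each
#' fragment reference so that per-reference counting (idxstats or
#' [count_bam()]) recovers the simulated counts exactly. Intended only to
#' exercise BAM-based counting; no sequencing realism.
#'
#' @param counts Count tibble (`name`, `length`, `mapped`).
#' @param path Output SAM path.
#' @param read_len Read length for the dummy reads.
#' @return `path`, invisibly.
#' @export
write_counts_sam <- function(counts, path, read_len = 50L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", counts$name, counts$length))
  recs <- purrr::pmap(list(counts$name, counts$length, counts$mapped),
                      function(nm, len, n) {
    if (n == 0L) return(character())
    rl <- min(read_len, len)
    sprintf("%s_read%d\t0\t%s\t1\t60\t%dM\t*\t0\t0\t%s\t%s",
            nm, seq_len(n), nm, rl, strrep("A", rl), strrep("I", rl))
  })
  writeLines(c(hdr, unlist(recs)), path)
  invisible(path)
}
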