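test_that("upper-tail probability matches exact small-case arithmetic", {
  # sum_{i=2..4} C(5,i)C(15,4-i)/C(20,4) = (1050+150+5)/4845 = 241/969
  expect_equal(hypergeom_upper_tail(20, 5, 4, 2), 241 / 969, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(20, 5, 4, 0), 1)
  expect_equal(hypergeom_upper_tail(10, 10, 3, 3), 1)  # all marked
  expect_error(hypergeom_upper_tail(10, 5, 4, 5), "k cannot exceed")
  expect_error(hypergeom_upper_tail(10, 11, 4, 2), "exceed N")
  expect_error(hypergeom_upper_tail(-1, 0, 0, 0), "non-negative")
})

test_that("log-space tail equals brute-force enumeration for all N <= 40", {
  # every valid (N, n, M, k) with N <= 40; the full N <= 60 sweep runs in
  # the acceptance suite
  for (N in c(1:15, 20, 30, 40)) {
    for (n in 0:N) {
      for (M in 0:N) {
        k <- 0:min(n, M)
        got <- hypergeom_upper_tail(N, n, M, k, log10 = TRUE)
        want_p <- vapply(k, brute_hyper_upper, 0, N = N, n = n, M = M)
        # near-1 tails are compared on the probability scale, where double
        # arithmetic is well conditioned; the rest on the log scale
        hi <- want_p > 0.5
        expect_equal(10^got[hi], want_p[hi], tolerance = 1e-12)
        lo <- !hi & want_p > 0
        expect_equal(got[lo], log10(want_p[lo]), tolerance = 1e-9)
      }
    }
  }
})

test_that("tail is monotone, symmetric in (n, M), and matches phyper at scale", {
  set.seed(5)
  for (rep in 1:50) {
    N <- sample(100:200000, 1)
    n <- sample(0:N, 1)
    M <- sample(0:min(N, 500), 1)
    k <- sample(0:min(n, M), 1)
    p <- hypergeom_upper_tail(N, n, M, k)
    # independent route: base R distribution function
    expect_equal(log10(p),
                 phyper(k - 1, n, N - n, M, lower.tail = FALSE, log.p = TRUE) / log(10),
                 tolerance = 1e-9)
    # role exchange of sample and success classes
    expect_equal(log10(p), hypergeom_upper_tail(N, M, n, k, log10 = TRUE),
                 tolerance = 1e-9)
    if (k < min(n, M)) {
      expect_lte(hypergeom_upper_tail(N, n, M, k + 1), p)
    }
    # growing the genome with the marked count fixed dilutes the scaffold:
    # the tail can only shrink
    expect_lte(hypergeom_upper_tail(N + 50, n, M, k), p * (1 + 1e-12))
  }
})

test_that("scaffold enrichment counts membership and sorts by p-value", {
  # 3 scaffolds: Sca1 all-candidate, Sca2 mixed, Sca3 none
  f <- c(0, 0, 0, 5, 120, 130, 90, 100)
  m <- c(100, 120, 110, 100, 100, 120, 100, 110)
  n_fr <- length(f)
  names_ <- c(sprintf("Sca1_%d_300", 1:3), sprintf("Sca2_%d_300", 1:3),
              sprintf("Sca3_%d_300", 1:2))
  tab <- build_count_table(
    tibble::tibble(name = names_, length = 300L, mapped = as.integer(f)),
    tibble::tibble(name = names_, length = 300L, mapped = as.integer(m)),
    totals_mode = "total_reads", external_totals = c(1000, 1000)
  )
  rat <- compute_ratios(tab)
  enr <- enrich_scaffolds(rat, alpha = 0.05)
  expect_equal(nrow(enr), 2L)   # Sca3 has no candidates
  s1 <- enr[enr$scaffold_id == "Sca1", ]
  expect_equal(s1$M, 3L); expect_equal(s1$k, 3L)
  expect_equal(s1$N, n_fr); expect_equal(s1$n, 4L)
  expect_equal(s1$p_value, brute_hyper_upper(8, 4, 3, 3), tolerance = 1e-12)
  expect_equal(enr$p_value, sort(enr$p_value))
  expect_equal(enr$enriched, enr$p_value < 0.05)

  full <- enrich_scaffolds(rat, alpha = 0.05, include_zero = TRUE)
  expect_equal(nrow(full), 3L)
  expect_equal(full$p_value[full$scaffold_id == "Sca3"], 1)

  stray <- rat[1, ]; stray$name <- "Sca9_1_300"
  expect_error(enrich_scaffolds(rat, candidates = stray), "missing")
})

test_that("multiple-testing adjustment only tightens the enriched call", {
  set.seed(8)
  f <- rpois(60, 60); m <- rpois(60, 100)
  names_ <- sprintf("Sca%d_%d_300", rep(1:12, each = 5), rep(1:5, 12))
  tab <- build_count_table(
    tibble::tibble(name = names_, length = 300L, mapped = as.integer(f)),
    tibble::tibble(name = names_, length = 300L, mapped = as.integer(m)),
    totals_mode = "total_reads", external_totals = c(1e5, 1e5)
  )
  rat <- compute_ratios(tab)
  raw <- enrich_scaffolds(rat, alpha = 0.1)
  bonf <- enrich_scaffolds(rat, alpha = 0.1, p_adjust = "bonferroni")
  expect_true(all(bonf$scaffold_id[bonf$enriched] %in%
                    raw$scaffold_id[raw$enriched]))
  expect_equal(raw$p_value, bonf$p_value)  # adjustment affects only the flag
})

test_that("enrichment report round-trips through TSV and JSON", {
  f <- c(0, 0, 100); m <- c(100, 100, 100)
  names_ <- c("Sca1_1_300", "Sca1_2_300", "Sca2_1_300")
  tab <- build_count_table(
    tibble::tibble(name = names_, length = 300L, mapped = as.integer(f)),
    tibble::tibble(name = names_, length = 300L, mapped = as.integer(m)),
    totals_mode = "total_reads", external_totals = c(1000, 1000)
  )
  enr <- enrich_scaffolds(compute_ratios(tab), alpha = 0.05)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_enrichment(enr, tsv, json)
  back <- readr::read_tsv(tsv, col_types = readr::cols())
  expect_equal(back$p_value, enr$p_value, tolerance = 1e-12)
  jback <- jsonlite::fromJSON(json)
  expect_equal(jback$p_value, enr$p_value, tolerance = 1e-12)
  expect_equal(jback$scaffold_id, enr$scaffold_id)
})
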