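# Shared fixtures and independent oracles for the test suite.

# random softmasked string over {A,C,G,T,N,a,c,g,t,n}
rand_softmasked <- function(len, p_masked = 0.3, p_n = 0.05) {
  upper <- c("A", "C", "G", "T")
  base <- sample(upper, len, replace = TRUE)
  state <- sample(c("u", "m", "n"), len, replace = TRUE,
                  prob = c(1 - p_masked - p_n, p_masked, p_n))
  base[state == "m"] <- tolower(base[state == "m"])
  base[state == "n"] <- sample(c("N", "n"), sum(state == "n"), replace = TRUE)
  paste(base, collapse = "")
}

# brute-force per-base fragment scan: classify every position, group runs,
# filter on min_len -- independent of the regex-based implementation
brute_split <- function(seq, min_len, split_on_n = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  keepset <- c("A", "C", "G", "T", if (!split_on_n) "N")
  keep <- chars %in% keepset
  frags <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (keep[i]) {
      j <- i
      while (j < length(chars) && keep[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        frags[[length(frags) + 1L]] <- c(start = i - 1L, end = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(frags) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, frags))
}

# brute-force upper-tail hypergeometric: enumerate the tail terms as plain
# products of choose() ratios (no log space); near-1 tails go through the
# complement of the lower sum, which is well conditioned in doubles
brute_hyper_upper <- function(N, n, M, k) {
  if (k == 0) return(1)
  i <- k:min(M, n)
  up <- sum(choose(n, i) * choose(N - n, M - i)) / choose(N, M)
  if (up <= 0.5) return(up)
  i_lo <- 0:(k - 1)
  1 - sum(choose(n, i_lo) * choose(N - n, M - i_lo)) / choose(N, M)
}

# one tiny deterministic pipeline fixture used by several files: 3 scaffolds,
# hand-countable fragments and counts
toy_pipeline_inputs <- function(dir) {
  sca <- tibble::tibble(
    scaffold_id = c("Sca1", "Sca2", "Sca3"),
    seq = c(
      paste0(strrep("A", 300), strrep("a", 20), strrep("C", 250)),   # 2 fragments
      paste0(strrep("G", 400), strrep("n", 10), strrep("T", 150)),   # 1 fragment (150 dropped)
      strrep("T", 500)                                               # 1 fragment
    )
  )
  fr <- fragratio::split_fragments(sca)
  # female counts: Sca1 fragments depleted (Y-like), others balanced
  f_mapped <- c(0L, 2L, 200L, 260L)
  m_mapped <- c(150L, 120L, 210L, 250L)
  female <- tibble::tibble(name = fr$name, length = fr$length,
                           mapped = f_mapped, unmapped = 0L)
  male <- tibble::tibble(name = fr$name, length = fr$length,
                         mapped = m_mapped, unmapped = 0L)
  fasta <- file.path(dir, "ref.fasta")
  ss <- Biostrings::BStringSet(sca$seq)
  names(ss) <- sca$scaffold_id
  Biostrings::writeXStringSet(ss, fasta)
  fem_path <- file.path(dir, "female.tsv")
  male_path <- file.path(dir, "male.tsv")
  fragratio::write_idxstats(female, fem_path)
  fragratio::write_idxstats(male, male_path)
  list(scaffolds = sca, fragments = fr, female = female, male = male,
       fasta = fasta, female_path = fem_path, male_path = male_path)
}
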