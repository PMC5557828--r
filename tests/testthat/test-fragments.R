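test_that("worked splitting examples give the documented fragments", {
  sca <- tibble::tibble(
    scaffold_id = "Sca1",
    seq = paste0(strrep("A", 500), strrep("a", 50), strrep("G", 300))
  )
  fr <- split_fragments(sca, min_len = 200)
  expect_equal(fr$start, c(0L, 550L))
  expect_equal(fr$end, c(500L, 850L))
  expect_equal(fr$ordinal, c(1L, 2L))
  expect_equal(fr$name, c("Sca1_1_500", "Sca1_2_300"))

  # a 150-bp run upstream of the separator is dropped; ordinals re-start at
  # the first retained fragment
  sca2 <- tibble::tibble(
    scaffold_id = "Sca2",
    seq = paste0(strrep("A", 150), strrep("a", 10), strrep("G", 400))
  )
  fr2 <- split_fragments(sca2, min_len = 200)
  expect_equal(nrow(fr2), 1L)
  expect_equal(fr2$start, 160L)
  expect_equal(fr2$end, 560L)
  expect_equal(fr2$ordinal, 1L)

  # all-masked scaffold yields nothing
  fr3 <- split_fragments(tibble::tibble(scaffold_id = "s", seq = strrep("a", 400)))
  expect_equal(nrow(fr3), 0L)

  # naming scheme {scaffold}_{ordinal}_{length}
  sca971 <- tibble::tibble(
    scaffold_id = "Sca971",
    seq = paste0(strrep("A", 300), "a", strrep("C", 250), "a", strrep("G", 662))
  )
  fr971 <- split_fragments(sca971)
  expect_equal(fr971$name[3], "Sca971_3_662")
})

test_that("invalid characters are rejected with scaffold and offset", {
  bad <- tibble::tibble(scaffold_id = "ScaX", seq = "ACGTRACGT")
  expect_error(split_fragments(bad), "ScaX")
  expect_error(split_fragments(bad), "offset 5")
})

test_that("splitting matches a brute-force per-base scan on random strings", {
  set.seed(42)
  for (rep in 1:40) {
    len <- sample(50:2000, 1)
    s <- rand_softmasked(len, p_masked = runif(1, 0.05, 0.6),
                         p_n = runif(1, 0, 0.15))
    min_len <- sample(c(1L, 5L, 50L, 200L), 1)
    for (split_n in c(TRUE, FALSE)) {
      got <- split_fragments(tibble::tibble(scaffold_id = "s", seq = s),
                             min_len = min_len, split_on_n = split_n)
      want <- brute_split(s, min_len, split_on_n = split_n)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      # fragment subsequences are clean and lengths conserve bases
      expect_true(all(got$length == got$end - got$start))
      expect_true(sum(got$length) <= nchar(s))
      if (split_n) expect_false(any(grepl("[a-zN]", got$seq)))
    }
  }
})

test_that("fragment subsequences are exact cut-outs of the scaffold", {
  set.seed(7)
  s <- rand_softmasked(1500, p_masked = 0.3, p_n = 0.05)
  fr <- split_fragments(tibble::tibble(scaffold_id = "s", seq = s), min_len = 10)
  for (i in seq_len(nrow(fr))) {
    expect_identical(fr$seq[i], substr(s, fr$start[i] + 1L, fr$end[i]))
  }
  # an all-uppercase scaffold is one full-length fragment
  full <- split_fragments(tibble::tibble(scaffold_id = "s", seq = strrep("ACGT", 100)))
  expect_equal(nrow(full), 1L)
  expect_equal(full$length, 400L)
  expect_equal(sum(full$length), 400L)
})

test_that("masked_fraction counts lowercase over non-N bases", {
  expect_equal(masked_fraction(tibble::tibble(scaffold_id = "s", seq = "ACGTacgt")), 0.5)
  expect_equal(masked_fraction(tibble::tibble(scaffold_id = "s", seq = "ACGTACGT")), 0)
  # hand count: 2 masked / 4 non-N
  expect_equal(masked_fraction(tibble::tibble(scaffold_id = "s", seq = "ACacNN")), 0.5)
  expect_error(masked_fraction(tibble::tibble(scaffold_id = character(),
                                              seq = character())), "empty")
  per <- masked_fraction(tibble::tibble(scaffold_id = c("a", "b"),
                                        seq = c("ACgt", "acgt")),
                         by_scaffold = TRUE)
  expect_equal(per$masked_fraction, c(0.5, 1))
})

test_that("BED, FASTA and TSV outputs round-trip losslessly", {
  sca <- tibble::tibble(
    scaffold_id = "Sca971",
    seq = paste0(strrep("a", 550), strrep("G", 300))
  )
  fr <- split_fragments(sca)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed(fr, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields, c("Sca971", "550", "850", "Sca971_1_300"))

  set.seed(1)
  sca2 <- tibble::tibble(scaffold_id = "s",
                         seq = rand_softmasked(2000, 0.3, 0.02))
  fr2 <- split_fragments(sca2, min_len = 50)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fragments_fasta(fr2, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(back), fr2$name)
  expect_equal(as.character(back), toupper(fr2$seq), ignore_attr = TRUE)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fragments_tsv(fr2, tsv)
  man <- read_fragments_tsv(tsv)
  expect_equal(as.data.frame(man),
               as.data.frame(dplyr::select(fr2, -"seq")))

  # empty fragment set still writes valid empty files
  empty <- split_fragments(tibble::tibble(scaffold_id = "s", seq = "acgt"))
  for (writer in list(write_fragments_bed, write_fragments_fasta,
                      write_fragments_tsv)) {
    f <- withr::local_tempfile()
    writer(empty, f)
    expect_true(file.exists(f))
  }
})

test_that("softmasked FASTA reader preserves case and rejects duplicates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Sca1 some description", "ACGTac", "gtNN", ">Sca2", "acgt"), fa)
  sca <- read_softmasked(fa)
  expect_equal(sca$scaffold_id, c("Sca1", "Sca2"))
  expect_equal(sca$seq, c("ACGTacgtNN", "acgt"))
  writeLines(c(">a", "ACGT", ">a", "ACGT"), fa)
  expect_error(read_softmasked(fa), "duplicate")
})
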