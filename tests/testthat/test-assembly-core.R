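test_that("FASTA round trip preserves ids and sequences, uppercased", {
  a <- assembly(c("c1", "c2"), c("ACGTACGTAC", "ggttaacc"), name = "toy")
  expect_identical(a$seq[2], "GGTTAACC")

  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a, f)
  b <- read_fasta(f)
  expect_identical(b$id, a$id)
  expect_identical(b$seq, a$seq)
  expect_identical(unname(assembly_lengths(b)), c(10L, 8L))

  # long records wrap at 80 columns but round-trip intact
  long <- assembly("L1", random_dna(500, seed = 5))
  write_fasta(long, f)
  expect_identical(read_fasta(f)$seq, long$seq)
  expect_lte(max(nchar(readLines(f))), 80L)
})

test_that("malformed or empty FASTA input raises a parse error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|malformed")
  expect_error(read_fasta(file.path(tempdir(), "nope_missing.fa")), "no such file")
})

test_that("assembly invariants are enforced", {
  expect_error(assembly(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(assembly("", "ACGT"), "non-empty")
  expect_error(assembly("a", ""), "length")
  expect_error(assembly("a", "ACGTX"), "non-ACGTN")
})

test_that("ng50 matches its worked examples and edge cases", {
  expect_equal(ng50(10, genome_size = 10), 10)
  # 5 < 7.5; 5 + 4 = 9 >= 7.5 -> 4
  expect_equal(ng50(c(5, 4, 3, 2, 1), genome_size = 15), 4)
  # assembly shorter than half the genome
  expect_equal(ng50(c(5, 4, 3, 2, 1), genome_size = 40), 0)
  expect_warning(res <- ng50(numeric(0), genome_size = 10), "empty")
  expect_equal(res, 0)
})

test_that("ng50 equals the brute-force oracle and is permutation-invariant", {
  set.seed(101)
  for (i in 1:200) {
    lens <- sample.int(5000, sample.int(100, 1), replace = TRUE)
    gs <- max(1, round(runif(1, 0.1, 1.5) * sum(lens)))
    expect_equal(ng50(lens, gs), ng50_oracle(lens, gs))
    expect_equal(ng50(sample(lens), gs), ng50(lens, gs))
  }
  # with genome_size = total, NG50 is the classical N50
  lens <- c(80, 70, 50, 40, 30, 20, 10)
  expect_equal(ng50(lens, sum(lens)), 70)
})

test_that("summary statistics reproduce published table arithmetic", {
  # mean sizes recomputed from printed counts/totals
  expect_equal(assembly_mean_bp(17045571778, 829839), 20541)
  expect_equal(assembly_mean_bp(12939100857, 97809), 132289)
  expect_equal(assembly_mean_bp(15344693583, 279439), 54912)

  a <- assembly("one", random_dna(100, seed = 3))
  st <- summary_stats(a, genome_size = 100)
  expect_equal(st$mean_bp, 100)
  expect_equal(st$ng50_bp, 100)
  expect_equal(st$n_records, 1L)
})

test_that("rounded mean stays within the rounding bound of the total", {
  set.seed(77)
  for (i in 1:50) {
    lens <- sample.int(9999, sample.int(40, 1) + 1, replace = TRUE)
    a <- assembly(paste0("r", seq_along(lens)),
                  vapply(lens, function(n) strrep("A", n), character(1)))
    st <- summary_stats(a, genome_size = sum(lens))
    expect_lt(abs(st$mean_bp * st$n_records - st$total_bp), st$n_records / 2 + 1e-9)
  }
})

test_that("coverage fold and compression ratio round half away from zero", {
  expect_equal(coverage_fold(1.0e12, 15.3e9), 65)
  expect_equal(coverage_fold(545e9, 15.3e9), 36)
  expect_equal(coverage_fold(278e9, 15.3e9), 18)
  expect_equal(coverage_fold(15.3e9, 15.3e9), 1)
  expect_equal(compression_ratio(1e12, 31e9), 32)
  expect_equal(compression_ratio(7, 7), 1)
  expect_equal(compression_ratio(100, 3), 33)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(2.5), 3)  # base round() would give 2
})

test_that("scaffolds split into contigs at N runs", {
  a <- assembly("s1", paste0(strrep("A", 30), strrep("N", 12), strrep("C", 20)),
                role = "scaffold")
  s <- split_scaffolds(a, min_n_run = 10)
  expect_identical(s$id, c("s1.1", "s1.2"))
  expect_identical(nchar(s$seq), c(30L, 20L))
  # short N runs are kept
  b <- assembly("s2", paste0(strrep("A", 10), "NNN", strrep("C", 10)))
  expect_identical(split_scaffolds(b, min_n_run = 10)$id, "s2")
})

test_that("stats TSV writer emits one row per assembly", {
  a <- assembly("x", random_dna(50, seed = 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(list(summary_stats(a, 50), summary_stats(a, 100)), f)
  df <- read.delim(f)
  expect_equal(nrow(df), 2L)
  expect_named(df, c("assembly", "number", "total_bp", "average_bp",
                     "ng50_bp", "genome_size_bp"))
})
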