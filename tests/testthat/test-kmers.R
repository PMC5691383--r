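test_that("uniqueness ratio hits its analytic extremes", {
  # random 10 kb at k=21: essentially every position covered by a unique k-mer
  g <- assembly("r", random_dna(10000, seed = 81))
  uc <- uniqueness_curve(g, ks = 21)
  expect_gte(uc$pct_covered, 99.5)

  # homopolymer: one distinct 10-mer occurring 91 times -> nothing unique
  hp <- assembly("h", strrep("A", 100))
  expect_equal(uniqueness_curve(hp, ks = 10)$pct_covered, 0)
})

test_that("uniqueness matches the brute-force oracle on a tandem duplication", {
  set.seed(82)
  unit <- random_dna(500)
  seq2k <- paste0(random_dna(400), unit, unit, random_dna(600))
  g <- assembly("dup", seq2k)
  for (k in c(16, 32)) {
    expect_equal(uniqueness_curve(g, ks = k)$pct_covered,
                 uniqueness_oracle(g$seq, k), tolerance = 1e-9)
  }
  # multi-record genomes count occurrences genome-wide
  g2 <- assembly(c("a", "b"), c(paste0(random_dna(300), unit),
                                paste0(unit, random_dna(300))))
  expect_equal(uniqueness_curve(g2, ks = 24)$pct_covered,
               uniqueness_oracle(g2$seq, 24), tolerance = 1e-9)
})

test_that("uniqueness is non-decreasing in k and strand-symmetric", {
  sim <- simulate_genome(sim_config(seed = 83, subgenome_sizes = c(3e4, 3e4),
                                    subgenome_divergence = c(0.05, 0.01),
                                    target_repeat_fraction = 0.4))
  ks <- c(16, 24, 32, 48, 64)
  uc <- uniqueness_curve(sim$genome, ks = ks)
  expect_true(all(diff(uc$pct_covered) >= -1e-9))
  rcg <- assembly(sim$genome$id, revcomp(sim$genome$seq))
  expect_equal(uniqueness_curve(rcg, ks = ks)$pct_covered, uc$pct_covered)
})

test_that("error-free reads from the assembly itself leave no missing k-mers", {
  g <- assembly("g", random_dna(20000, seed = 84))
  reads <- simulate_reads(g, depth = 20, read_len = 150, seed = 85)
  spec <- kmer_spectrum(reads$reads, k = 31)
  h <- missing_kmer_histogram(spec, g, k = 31)
  expect_equal(h$total_missing, 0L)
})

test_that("one substitution in unique sequence removes exactly k read k-mers", {
  k <- 31
  g_seq <- random_dna(20000, seed = 86)
  asm <- assembly("a", substitute_bases(g_seq, 10000))
  # reads at perfectly uniform depth: every window of the source genome
  depth <- 10
  reads <- unlist(lapply(seq_len(depth), function(i)
    substring(g_seq, seq(1, 20000 - 150 + 1, by = 15), seq(150, 20000, by = 15))))
  spec <- kmer_spectrum(reads, k = k)
  h <- missing_kmer_histogram(spec, asm, k = k)
  expect_equal(h$total_missing, k)
  # missing k-mers concentrate at the uniform window multiplicity
  expect_equal(sum(h$missing_count[h$multiplicity >= depth - 1]), k)
})

test_that("union of two assemblies is bin-wise no worse than either alone", {
  g_seq <- random_dna(30000, seed = 87)
  g <- assembly("g", g_seq)
  left_gap <- assembly("l", paste0(substr(g_seq, 1, 9000),
                                   substr(g_seq, 12001, 30000)))
  right_gap <- assembly("r", paste0(substr(g_seq, 1, 20000),
                                    substr(g_seq, 23001, 30000)))
  reads <- simulate_reads(g, depth = 15, read_len = 120, seed = 88)
  spec <- kmer_spectrum(reads$reads, k = 31)
  h_l <- missing_kmer_histogram(spec, left_gap)
  h_r <- missing_kmer_histogram(spec, right_gap)
  h_u <- missing_kmer_histogram(spec, list(left_gap, right_gap))
  expect_gt(h_l$total_missing, 0L)
  expect_gt(h_r$total_missing, 0L)
  for (h1 in list(h_l, h_r)) {
    common <- intersect(h_u$multiplicity, h1$multiplicity)
    expect_true(all(
      h_u$missing_count[match(common, h_u$multiplicity)] <=
        h1$missing_count[match(common, h1$multiplicity)]))
    expect_true(all(setdiff(h_u$multiplicity, h1$multiplicity) %in% integer(0)))
  }
  expect_lte(h_u$total_missing, min(h_l$total_missing, h_r$total_missing))
})

test_that("duplicated single-copy sequence shows up as excess duplicate k-mers", {
  g_seq <- random_dna(20000, seed = 89)
  g <- assembly("g", g_seq)
  reads <- simulate_reads(g, depth = 25, read_len = 150, seed = 90)
  spec <- kmer_spectrum(reads$reads, k = 31)

  # a faithful assembly has no excess duplicates
  expect_equal(as.integer(excess_duplicate_kmers(spec, g)), 0L)

  # duplicating a 2 kb region creates ~region_length - k + 1 of them
  dup_region <- substr(g_seq, 5001, 7000)
  asm_dup <- assembly("g", paste0(g_seq, dup_region))
  # the single-copy band (spectrum mode +/- width) captures most, not all,
  # of the duplicated region's k-mers
  n <- excess_duplicate_kmers(spec, asm_dup)
  expect_gt(as.integer(n), 0.5 * (2000 - 31 + 1))
  expect_lte(as.integer(n), 2000 + 31)
})

test_that("spectrum and histogram TSV writers emit sorted tables", {
  g <- assembly("g", random_dna(2000, seed = 91))
  spec <- kmer_spectrum(g, k = 31)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(spec, f)
  df <- read.delim(f, colClasses = c("character", "numeric"))
  expect_false(is.unsorted(df$kmer))
  expect_equal(sum(df$count), 2000 - 31 + 1)
})
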