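test_that("consecutive mega-reads yield n-1 innie pairs of 400 bp ends", {
  set.seed(121)
  groups <- list(
    pb1 = c(random_dna(1500), random_dna(2000)),
    pb2 = random_dna(1200),                        # single mega-read: no pair
    pb3 = replicate(5, random_dna(800)))
  pairs <- extract_synthetic_mates(groups, end_length = 400)
  expect_equal(nrow(pairs), 1L + 0L + 4L)
  expect_true(all(nchar(pairs$left_seq) == 400))
  expect_true(all(nchar(pairs$right_seq) == 400))
  # left end comes from the tail of the earlier mega-read, right end is the
  # reverse complement of the head of the later one
  expect_identical(pairs$left_seq[1], substr(groups$pb1[1], 1101, 1500))
  expect_identical(pairs$right_seq[1], revcomp(substr(groups$pb1[2], 1, 400)))
  # total pair count = sum over groups of max(0, n_i - 1)
  expect_equal(nrow(pairs),
               sum(pmax(0, vapply(groups, length, integer(1)) - 1)))
})

test_that("short mega-reads contribute whole-length ends", {
  pairs <- extract_synthetic_mates(list(g = c(random_dna(250, seed = 122),
                                              random_dna(900))),
                                   end_length = 400)
  expect_equal(nchar(pairs$left_seq), 250L)
  expect_equal(nchar(pairs$right_seq), 400L)
})

test_that("pairs simulated from a correct assembly are 100% consistent", {
  set.seed(123)
  g <- assembly(c("c1", "c2"), c(random_dna(40000), random_dna(30000)))
  pairs <- simulate_pairs(g, n_pairs = 60, insert_mean = 5000, insert_sd = 300,
                          end_length = 400, seed = 124)
  pc <- classify_pairs(pairs, g, insert_mean = 5000, insert_sd = 300)
  counts <- pc$summary$counts
  expect_equal(unname(counts[["same_contig_consistent"]]), 60L)
  expect_equal(unname(counts[["same_contig_wrong_orientation"]]), 0L)
  expect_equal(unname(counts[["candidate_misassembly"]]), 0L)
  expect_equal(pc$summary$pct_consistent, 100)
  # class counts always sum to the number of pairs
  expect_equal(sum(counts), nrow(pairs))
})

test_that("published pair-consistency arithmetic reproduces 99%", {
  expect_equal(pair_consistency_pct(2709, 2739), 99)
})

test_that("an engineered translocation yields localized misassembly candidates", {
  set.seed(125)
  chr1 <- random_dna(30000); chr2 <- random_dna(30000)
  truth <- assembly(c("t1", "t2"), c(chr1, chr2))
  # swap the tails of the two chromosomes in the assembly under test
  asm <- assembly(c("m1", "m2"),
                  c(paste0(substr(chr1, 1, 15000), substr(chr2, 15001, 30000)),
                    paste0(substr(chr2, 1, 15000), substr(chr1, 15001, 30000))))
  pairs <- simulate_pairs(truth, n_pairs = 150, insert_mean = 4000,
                          insert_sd = 200, end_length = 350, seed = 126)
  pc <- classify_pairs(pairs, asm, insert_mean = 4000, insert_sd = 200)
  counts <- pc$summary$counts
  expect_gt(unname(counts[["candidate_misassembly"]]), 0L)
  expect_equal(sum(counts), nrow(pairs))
  # candidates involve the two breakpoint-carrying contigs
  cand <- pc$placements[pc$placements$class == "candidate_misassembly", ]
  expect_setequal(unique(c(cand$contig_1, cand$contig_2)), c("m1", "m2"))
  # pairs away from the breakpoint remain consistent
  expect_gt(unname(counts[["same_contig_consistent"]]), 0L)
})

test_that("wrong-orientation and bad-distance pairs are distinguished", {
  g_seq <- random_dna(30000, seed = 127)
  g <- assembly("c", g_seq)
  innie <- function(s, e, len = 300)
    c(substr(g_seq, s, s + len - 1), revcomp(substr(g_seq, e - len + 1, e)))
  p_ok <- innie(1001, 5000)        # distance 4000
  p_far <- innie(9001, 21000)      # distance 12000, far off the 4000 mean
  p_wrong <- c(substr(g_seq, 1001, 1300), substr(g_seq, 4701, 5000))  # same strand
  pairs <- data.frame(pair_id = c("ok", "far", "wrong"),
                      left_seq = c(p_ok[1], p_far[1], p_wrong[1]),
                      right_seq = c(p_ok[2], p_far[2], p_wrong[2]))
  pc <- classify_pairs(pairs, g, insert_mean = 4000, insert_tolerance = 500)
  got <- setNames(pc$placements$class, pc$placements$pair_id)
  expect_equal(unname(got["ok"]), "same_contig_consistent")
  expect_equal(unname(got["far"]), "same_contig_bad_distance")
  expect_equal(unname(got["wrong"]), "same_contig_wrong_orientation")
})

test_that("paired FASTQ round trip preserves pairs", {
  pairs <- extract_synthetic_mates(
    list(g1 = c(random_dna(1000, seed = 128), random_dna(1000)),
         g2 = c(random_dna(900), random_dna(900), random_dna(900))))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_pairs_fastq(pairs, f)
  back <- read_pairs_fastq(f)
  back <- back[match(pairs$pair_id, back$pair_id), ]
  expect_equal(back$left_seq, pairs$left_seq)
  expect_equal(back$right_seq, pairs$right_seq)
})
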