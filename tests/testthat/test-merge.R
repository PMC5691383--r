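# canonical two-contig bridging layout: one 20 kb A contig, two B contigs
# overlapping its ends and extending outward
bridge_fixture <- function(seed = 41, overlap_left = 6000, overlap_right = 6000,
                           ext = 12000) {
  set.seed(seed)
  truth <- random_dna(20000 + 2 * ext)
  a_seq <- substr(truth, ext + 1, ext + 20000)
  b1 <- substr(truth, 1, ext + overlap_left)             # ends 6 kb into A
  b2 <- substr(truth, ext + 20000 - overlap_right + 1, nchar(truth))
  list(truth = truth,
       A = assembly("A1", a_seq),
       B = assembly(c("B1", "B2"), c(b1, b2)))
}

test_that("two terminal overlaps of >= 5 kb produce one gap-filling bridge", {
  fx <- bridge_fixture()
  aln <- align_sets(fx$B, fx$A)
  br <- plan_bridges(aln, fx$B)
  expect_equal(nrow(br), 1L)
  expect_equal(br$a_id, "A1")
  expect_equal(br$left_b_id, "B1")
  expect_equal(br$right_b_id, "B2")
  expect_equal(br$fill_start, 6000L)
  expect_equal(br$fill_end, 14000L)

  merged <- execute_merge(fx$B, fx$A, br)
  expect_equal(length(merged$id), 1L)
  expect_equal(nchar(merged$seq), nchar(fx$truth))
  expect_identical(merged$seq, fx$truth)
})

test_that("a 4999 bp overlap falls below the bridging threshold", {
  fx <- bridge_fixture(seed = 42, overlap_left = 4999)
  br <- plan_bridges(align_sets(fx$B, fx$A), fx$B)
  expect_equal(nrow(br), 0L)
})

test_that("three contigs tiling one bridging contig chain into one output", {
  set.seed(43)
  truth <- random_dna(60000)
  A <- assembly("A1", substr(truth, 10001, 50000))  # 40 kb bridging contig
  B <- assembly(c("B1", "B2", "B3"),
                c(substr(truth, 1, 18000),
                  substr(truth, 24001, 36000),      # fully inside A
                  substr(truth, 42001, 60000)))
  br <- plan_bridges(align_sets(B, A), B)
  expect_equal(nrow(br), 2L)
  merged <- execute_merge(B, A, br)
  expect_equal(length(merged$id), 1L)
  expect_identical(merged$id, "B1+B2+B3")
  expect_identical(merged$seq, truth)  # interval arithmetic recovers truth
})

test_that("no bridges leaves the backbone assembly unchanged", {
  set.seed(44)
  B <- assembly(c("B1", "B2"), c(random_dna(7000), random_dna(7000)))
  A <- assembly("A1", random_dna(7000))
  merged <- execute_merge(B, A, plan_bridges(align_sets(B, A), B))
  expect_identical(merged$id, B$id)
  expect_identical(merged$seq, B$seq)
})

test_that("minus-strand members are reverse-complemented before joining", {
  fx <- bridge_fixture(seed = 45)
  Brc <- assembly(c("B1", "B2"), c(fx$B$seq[1], revcomp(fx$B$seq[2])))
  br <- plan_bridges(align_sets(Brc, fx$A), Brc)
  expect_equal(nrow(br), 1L)
  expect_equal(br$right_strand, "-")
  merged <- execute_merge(Brc, fx$A, br)
  expect_identical(merged$seq, fx$truth)
})

test_that("overlapping (negative-gap) bridges splice at the interval midpoint", {
  set.seed(46)
  truth <- random_dna(40000)
  A <- assembly("A1", substr(truth, 10001, 30000))
  B <- assembly(c("B1", "B2"),
                c(substr(truth, 1, 21000),        # overlap truth[18k..21k)
                  substr(truth, 18001, 40000)))
  br <- plan_bridges(align_sets(B, A), B)
  expect_equal(nrow(br), 1L)
  expect_lt(br$fill_end, br$fill_start)
  merged <- execute_merge(B, A, br)
  expect_equal(length(merged$id), 1L)
  expect_identical(merged$seq, truth)
})

test_that("junction windows realign exactly to the truth sequence", {
  fx <- bridge_fixture(seed = 47)
  br <- plan_bridges(align_sets(fx$B, fx$A), fx$B)
  merged <- execute_merge(fx$B, fx$A, br)
  j <- attr(merged, "junctions")
  expect_gte(nrow(j), 2L)
  for (i in seq_len(nrow(j))) {
    w <- substr(merged$seq[match(j$contig_id[i], merged$id)],
                max(1, j$pos[i] - 20), j$pos[i] + 21)
    expect_true(grepl(w, fx$truth, fixed = TRUE))
  }
})

test_that("merging keeps every backbone contig inside one output contig", {
  set.seed(48)
  sim <- simulate_genome(sim_config(seed = 48, subgenome_sizes = c(8e4, 8e4),
                                    subgenome_divergence = c(0.1, 0.01),
                                    target_repeat_fraction = 0.3))
  A <- fragment_assembly(sim$genome, frag_mean_bp = 2e4, frag_min_bp = 4000,
                         gap_mean_bp = 0, name = "A", seed = 1)
  B <- fragment_assembly(sim$genome, frag_mean_bp = 4e4, frag_min_bp = 8000,
                         gap_mean_bp = 2000, name = "B", seed = 2)
  br <- plan_bridges(align_sets(B$assembly, A$assembly), B$assembly)
  merged <- execute_merge(B$assembly, A$assembly, br)
  for (i in seq_along(B$assembly$id)) {
    hits <- vapply(merged$seq, function(s)
      grepl(B$assembly$seq[i], s, fixed = TRUE), logical(1))
    expect_equal(sum(hits), 1L)
  }
})

test_that("only scaffolds absent from the merged contigs are added", {
  set.seed(49)
  truth <- random_dna(30000)
  merged <- assembly("M1", truth)
  A <- assembly(c("inA", "novel"),
                c(substr(truth, 5001, 15000), random_dna(8000)))
  out <- add_unique_scaffolds(merged, A)
  expect_setequal(out$id, c("M1", "novel"))

  # counting fixture: 5 scaffolds, 2 contained -> 3 added
  set.seed(50)
  A5 <- assembly(paste0("s", 1:5),
                 c(substr(truth, 1, 9000), substr(truth, 12001, 22000),
                   random_dna(6000), random_dna(6000), random_dna(6000)))
  out5 <- add_unique_scaffolds(merged, A5)
  expect_equal(length(out5$id), 1L + 3L)
  expect_setequal(setdiff(out5$id, "M1"), c("s3", "s4", "s5"))
})
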