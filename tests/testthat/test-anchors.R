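test_that("identical records align end to end at identity 100", {
  g <- random_dna(10000, seed = 11)
  aln <- align_sets(assembly("q1", g), assembly("r1", g))
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$q_start, 0L)
  expect_equal(aln$q_end, 10000L)
  expect_equal(aln$r_start, 0L)
  expect_equal(aln$r_end, 10000L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$identity_pct, 100)
})

test_that("reverse-complement queries align on the minus strand", {
  g <- random_dna(8000, seed = 12)
  aln <- align_sets(assembly("q1", revcomp(g)), assembly("r1", g))
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$strand, "-")
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$q_end - aln$q_start, 8000L)
})

test_that("100 substitutions in 10 kb give identity near 99.0", {
  g <- random_dna(10000, seed = 13)
  q <- substitute_bases(g, round(seq(40, 9960, length.out = 100)))
  aln <- align_sets(assembly("q1", q), assembly("r1", g))
  top <- aln[which.max(aln$q_end - aln$q_start), ]
  expect_equal(top$identity_pct, 99.0, tolerance = 0.1 / 99)
})

test_that("self-alignment reports every record fully at identity 100", {
  set.seed(14)
  a <- assembly(paste0("c", 1:4),
                vapply(c(900, 1500, 2200, 3000), function(n)
                  random_dna(n), character(1)))
  aln <- align_sets(a, a)
  for (id in a$id) {
    self <- aln[aln$q_id == id & aln$r_id == id & aln$strand == "+", ]
    expect_true(any(self$q_start == 0 &
                      self$q_end == nchar(a$seq[match(id, a$id)]) &
                      self$identity_pct == 100))
  }
})

test_that("X-vs-Y and Y-vs-X alignments are coordinate mirror images", {
  set.seed(15)
  x <- random_dna(4000)
  y <- paste0(random_dna(1000), substr(x, 1001, 3000), random_dna(500))
  ax <- assembly("x", x); ay <- assembly("y", y)
  f <- align_sets(ax, ay)
  b <- align_sets(ay, ax)
  f <- f[which.max(f$matches), ]
  b <- b[which.max(b$matches), ]
  expect_equal(f$q_start, b$r_start)
  expect_equal(f$q_end, b$r_end)
  expect_equal(f$r_start, b$q_start)
  expect_equal(f$r_end, b$q_end)
  expect_equal(f$identity_pct, b$identity_pct)
})

test_that("reported identity tracks full dynamic programming on <=2 kb pairs", {
  set.seed(16)
  for (i in 1:8) {
    L <- sample(600:2000, 1)
    ref <- random_dna(L)
    qry <- mutate_at_rate(ref, runif(1, 0, 0.05))
    aln <- align_sets(assembly("q", qry), assembly("r", ref))
    expect_gte(nrow(aln), 1L)
    top <- aln[which.max(aln$q_end - aln$q_start), ]
    pa <- Biostrings::pairwiseAlignment(qry, ref, type = "global")
    dp_ident <- 100 * Biostrings::nmatch(pa) /
      nchar(as.character(Biostrings::pattern(pa)))
    expect_lt(abs(top$identity_pct - dp_ident), 0.5)
  }
})

test_that("anchor_k longer than every query record yields empty result", {
  a <- assembly("tiny", "ACGTACGTACGTACG")  # 15 bp < default anchor_k = 21
  r <- assembly("ref", random_dna(1000, seed = 17))
  expect_warning(aln <- align_sets(a, r), "anchor_k")
  expect_equal(nrow(aln), 0L)
})

test_that("best match maximises summed aligned bases with lexicographic ties", {
  aln <- empty_alignments()
  mk <- function(q, r, qs, qe) data.frame(
    q_id = q, r_id = r, q_start = qs, q_end = qe, r_start = qs, r_end = qe,
    strand = "+", matches = qe - qs, columns = qe - qs, identity_pct = 100)
  aln <- rbind(mk("q", "r1", 0, 8000), mk("q", "r2", 0, 2000))
  expect_identical(unname(best_match_per_query(aln)["q"]), "r1")
  tie <- rbind(mk("q", "rB", 0, 5000), mk("q", "rA", 2000, 7000))
  expect_identical(unname(best_match_per_query(tie)["q"]), "rA")
})

test_that("best match agrees with a brute-force summation oracle", {
  set.seed(18)
  for (rep in 1:20) {
    n <- 40
    aln <- data.frame(
      q_id = sample(paste0("q", 1:6), n, TRUE),
      r_id = sample(paste0("r", 1:5), n, TRUE),
      q_start = 0L, strand = "+", identity_pct = 100)
    aln$q_end <- sample.int(5000, n)
    aln$r_start <- 0L; aln$r_end <- aln$q_end
    aln$matches <- aln$q_end; aln$columns <- aln$q_end
    got <- best_match_per_query(aln)
    for (q in unique(aln$q_id)) {
      sums <- tapply(aln$q_end[aln$q_id == q] - aln$q_start[aln$q_id == q],
                     aln$r_id[aln$q_id == q], sum)
      best <- sort(names(sums)[sums == max(sums)])[1]
      expect_identical(unname(got[q]), best)
    }
  }
})

test_that("mutual best matches equal the exhaustive mutual-argmax oracle", {
  # two identical assemblies pair every contig with itself
  set.seed(19)
  a <- assembly(paste0("c", 1:3),
                vapply(c(1500, 2000, 2500), function(n) random_dna(n),
                       character(1)))
  b <- assembly(paste0("d", 1:3), a$seq)
  ab <- align_sets(a, b); ba <- align_sets(b, a)
  mb <- mutual_best(ab, ba)
  expect_equal(nrow(mb), 3L)
  expect_identical(mb$b_id[match(paste0("c", 1:3), mb$a_id)], paste0("d", 1:3))

  # random bipartite weights: asymmetry must exclude pairs
  for (rep in 1:20) {
    W <- matrix(sample.int(100, 12, TRUE), 3, 4,
                dimnames = list(paste0("a", 1:3), paste0("b", 1:4)))
    mkaln <- function(qs, rs, w) data.frame(
      q_id = qs, r_id = rs, q_start = 0L, q_end = w, r_start = 0L, r_end = w,
      strand = "+", matches = w, columns = w, identity_pct = 100)
    ab <- do.call(rbind, lapply(rownames(W), function(i)
      mkaln(i, colnames(W), W[i, ])))
    ba <- do.call(rbind, lapply(colnames(W), function(j)
      mkaln(j, rownames(W), W[, j])))
    got <- mutual_best(ab, ba)
    for (i in rownames(W)) for (j in colnames(W)) {
      besti <- sort(colnames(W)[W[i, ] == max(W[i, ])])[1]
      bestj <- sort(rownames(W)[W[, j] == max(W[, j])])[1]
      expect_equal(i %in% got$a_id && got$b_id[got$a_id == i] == j,
                   besti == j && bestj == i)
    }
  }
})

test_that("alignment TSV dialect round-trips coordinates and strand", {
  g <- random_dna(5000, seed = 20)
  q <- assembly(c("qf", "qr"), c(substr(g, 1001, 3000),
                                 revcomp(substr(g, 2501, 4500))))
  aln <- align_sets(q, assembly("r", g))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignments_tsv(aln, f)
  back <- read_alignments_tsv(f)
  o1 <- order(aln$q_id, aln$q_start)
  o2 <- order(back$q_id, back$q_start)
  for (col in c("q_id", "r_id", "q_start", "q_end", "r_start", "r_end", "strand"))
    expect_equal(back[[col]][o2], aln[[col]][o1])
})
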