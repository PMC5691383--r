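# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute exactly n bases at distinct positions (always to a different base)
substitute_bases <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) ch[p] <- setdiff(BASES, ch[p])[1]
  paste(ch, collapse = "")
}

mutate_at_rate <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(ch)) < rate)
  for (p in idx) ch[p] <- setdiff(BASES, ch[p])[sample.int(3, 1)]
  paste(ch, collapse = "")
}

# independent NG50 oracle: brute force over descending cumulative sums
ng50_oracle <- function(lengths, genome_size) {
  if (length(lengths) == 0) return(0)
  ls <- sort(lengths, decreasing = TRUE)
  run <- 0
  for (l in ls) {
    run <- run + l
    if (run >= genome_size / 2) return(l)
  }
  0
}

# independent canonicaliser for the k-mer oracles (Biostrings-based, not
# the package C++ path)
canon_oracle <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(rc < kmers, rc, kmers)
}

# O(L^2)-style uniqueness oracle: count every window via table(), mark
# covered positions explicitly
uniqueness_oracle <- function(seqs, k) {
  wins <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    canon_oracle(substring(s, 1:(L - k + 1), k:L))
  })
  counts <- table(unlist(wins))
  covered <- 0; denom <- 0
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[[i]])
    if (L < k) next
    denom <- denom + L
    cov <- logical(L)
    uq <- which(counts[wins[[i]]] == 1)
    for (p in uq) cov[p:(p + k - 1)] <- TRUE
    covered <- covered + sum(cov)
  }
  100 * covered / denom
}
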