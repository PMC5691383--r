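#' Alignment parameters
#'
#' Controls for the exact-anchor chaining aligner. Anchors are exact k-mer
#' matches between query and reference; anchors on a shared diagonal are
#' clustered into chains (gap at most `max_gap_bp`), chains are stitched
#' across verified gaps, greedily extended by exact matching at both ends,
#' and the identity of each chain is recomputed from the full spanned
#' region rather than from the anchors alone.
#'
#' @param anchor_k anchor k-mer length, 11..32 (default 21).
#' @param min_cluster_bp minimum chained span to report (default 200).
#' @param max_gap_bp maximum anchor-to-anchor gap within a chain
#'   (default 1000).
#' @param min_identity_pct reporting floor for recomputed identity
#'   (default 90).
#' @param max_kmer_occ reference k-mers occurring more often than this are
#'   masked, mimicking aligner repeat masking (default 100).
#' @param band_bp tolerated diagonal drift when stitching chains across
#'   small indels (default 30).
#' @param stitch_max_gap_bp maximum gap bridged by identity-verified chain
#'   stitching (default 5000).
#' @param end_extend extend chain ends by greedy exact matching
#'   (default TRUE).
#' @return A list of class `align_params`.
#' @export
align_params <- function(anchor_k = 21L, min_cluster_bp = 200L,
                         max_gap_bp = 1000L, min_identity_pct = 90,
                         max_kmer_occ = 100L, band_bp = 30L,
                         stitch_max_gap_bp = 5000L, end_extend = TRUE) {
  stopifnot(anchor_k >= 11L, anchor_k <= 32L, min_cluster_bp > 0,
            max_gap_bp > 0, min_identity_pct > 0, min_identity_pct <= 100,
            max_kmer_occ >= 1L, band_bp >= 0L, stitch_max_gap_bp >= 0L)
  structure(list(anchor_k = as.integer(anchor_k),
                 min_cluster_bp = as.integer(min_cluster_bp),
                 max_gap_bp = as.integer(max_gap_bp),
                 min_identity_pct = min_identity_pct,
                 max_kmer_occ = as.integer(max_kmer_occ),
                 band_bp = as.integer(band_bp),
                 stitch_max_gap_bp = as.integer(stitch_max_gap_bp),
                 end_extend = isTRUE(end_extend)),
            class = "align_params")
}

empty_alignments <- function() {
  structure(data.frame(q_id = character(0), r_id = character(0),
                       q_start = integer(0), q_end = integer(0),
                       r_start = integer(0), r_end = integer(0),
                       strand = character(0), matches = integer(0),
                       columns = integer(0), identity_pct = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("alignments", "data.frame"))
}

# identity of a (possibly unequal-length) pair of substrings; returns
# c(matches, columns). Equal lengths use an exact mismatch count; unequal
# lengths fall back to global dynamic programming on the substrings.
pair_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    mm <- cpp_count_mismatches(a, b)
    c(nchar(a) - mm, nchar(a))
  } else {
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global")
    c(Biostrings::nmatch(pa), nchar(as.character(Biostrings::pattern(pa))))
  }
}

#' Align two assemblies
#'
#' All-vs-all pairwise local alignment of the records of `query` against
#' the records of `reference` by exact-anchor chaining (see
#' [align_params()]). Both strands are searched. Coordinates are 0-based
#' half-open on the forward strand of both sequences; for strand `"-"`
#' the query interval refers to the forward query strand while the aligned
#' sequence is its reverse complement.
#'
#' @param query,reference `assembly` objects.
#' @param params an [align_params()] object.
#' @param skip_same_id ignore alignments of a record to the identically
#'   positioned record (for self-alignment de-duplication); requires
#'   `query` and `reference` to have identical record ids.
#' @return A data frame of class `alignments` with columns `q_id`, `r_id`,
#'   `q_start`, `q_end`, `r_start`, `r_end`, `strand`, `matches`,
#'   `columns`, `identity_pct`.
#' @export
align_sets <- function(query, reference, params = align_params(),
                       skip_same_id = FALSE) {
  stopifnot(inherits(query, "assembly"), inherits(reference, "assembly"))
  if (length(query$id) == 0L || length(reference$id) == 0L)
    stop("assemblies must be non-empty")
  if (skip_same_id && !identical(query$id, reference$id))
    stop("skip_same_id requires identical record sets")
  k <- params$anchor_k
  if (all(nchar(query$seq) < k)) {
    warning("anchor_k exceeds every query record length; no alignments")
    return(empty_alignments())
  }
  hits <- cpp_anchor_hits(query$seq, reference$seq, k, params$max_kmer_occ,
                          skip_same_id)
  if (nrow(hits) == 0L) return(empty_alignments())

  q_pos <- r_pos <- diag <- grp <- chain <- q_idx <- r_idx <- NULL # data.table NSE
  dt <- data.table::as.data.table(hits)
  dt[, diag := r_pos - q_pos]
  data.table::setorder(dt, q_idx, r_idx, strand, diag, q_pos)
  dt[, grp := cumsum(c(1L, as.integer(
    diff(q_idx) != 0L | diff(r_idx) != 0L | diff(strand) != 0L |
      diff(diag) != 0L)))]
  dt[, chain := cumsum(c(1L, as.integer(diff(q_pos) > params$max_gap_bp))),
     by = grp]
  ch <- dt[, list(q_idx = q_idx[1L], r_idx = r_idx[1L], strand = strand[1L],
                  qs = min(q_pos), qe = max(q_pos) + k,
                  rs = min(r_pos), re = max(r_pos) + k),
           by = list(grp, chain)]
  ch <- as.data.frame(ch)

  qlen <- nchar(query$seq)
  # oriented query strings, cached lazily per (record, strand)
  rc_cache <- new.env(parent = emptyenv())
  oriented_q <- function(qi, strand) {
    if (strand > 0L) return(query$seq[qi + 1L])
    key <- as.character(qi)
    if (is.null(rc_cache[[key]]))
      rc_cache[[key]] <- cpp_revcomp(query$seq[qi + 1L])
    rc_cache[[key]]
  }

  # group boundaries over plain vectors (no per-group data frames)
  o <- order(ch$q_idx, ch$r_idx, ch$strand, ch$qs, ch$qe)
  v_qi <- ch$q_idx[o]; v_ri <- ch$r_idx[o]; v_st <- ch$strand[o]
  v_qs <- ch$qs[o]; v_qe <- ch$qe[o]; v_rs <- ch$rs[o]; v_re <- ch$re[o]
  n <- length(v_qi)
  gstart <- which(c(TRUE, diff(v_qi) != 0L | diff(v_ri) != 0L |
                      diff(v_st) != 0L))
  gend <- c(gstart[-1L] - 1L, n)

  acc <- list(q_id = list(), r_id = list(), q_start = list(), q_end = list(),
              r_start = list(), r_end = list(), strand = list(),
              matches = list(), columns = list(), identity_pct = list())
  push <- function(field, value) {
    acc[[field]][[length(acc[[field]]) + 1L]] <<- value
  }
  for (g in seq_along(gstart)) {
    i0 <- gstart[g]; i1 <- gend[g]
    qi <- v_qi[i0]; ri <- v_ri[i0]; strand <- v_st[i0]
    qstr <- oriented_q(qi, strand)
    rstr <- reference$seq[ri + 1L]
    qs <- v_qs[i0:i1]; qe <- v_qe[i0:i1]; rs <- v_rs[i0:i1]; re <- v_re[i0:i1]
    # stitch adjacent chains across identity-verified gaps
    if (length(qs) > 1L) {
      m_qs <- qs[1L]; m_qe <- qe[1L]; m_rs <- rs[1L]; m_re <- re[1L]
      out_i <- 0L
      o_qs <- o_qe <- o_rs <- o_re <- integer(length(qs))
      for (j in 2:length(qs)) {
        gq <- qs[j] - m_qe
        gr <- rs[j] - m_re
        ok <- FALSE
        if (abs(gq - gr) <= params$band_bp &&
            gq <= params$stitch_max_gap_bp && gr <= params$stitch_max_gap_bp) {
          if (gq <= 0L && gr <= 0L) {
            ok <- gq == gr
          } else if (gq > 0L && gr > 0L) {
            mc <- pair_identity(substr(qstr, m_qe + 1L, qs[j]),
                                substr(rstr, m_re + 1L, rs[j]))
            ok <- 100 * mc[1L] / mc[2L] >= params$min_identity_pct
          }
        }
        if (ok) {
          m_qe <- max(m_qe, qe[j]); m_re <- max(m_re, re[j])
        } else {
          out_i <- out_i + 1L
          o_qs[out_i] <- m_qs; o_qe[out_i] <- m_qe
          o_rs[out_i] <- m_rs; o_re[out_i] <- m_re
          m_qs <- qs[j]; m_qe <- qe[j]; m_rs <- rs[j]; m_re <- re[j]
        }
      }
      out_i <- out_i + 1L
      o_qs[out_i] <- m_qs; o_qe[out_i] <- m_qe
      o_rs[out_i] <- m_rs; o_re[out_i] <- m_re
      qs <- o_qs[seq_len(out_i)]; qe <- o_qe[seq_len(out_i)]
      rs <- o_rs[seq_len(out_i)]; re <- o_re[seq_len(out_i)]
    }
    # exact end extension + full-span identity recount, batched in C++
    fin <- cpp_finalize_chains(qstr, rstr, qs, qe, rs, re,
                               params$end_extend, params$min_cluster_bp,
                               params$min_identity_pct)
    m <- length(fin$qs)
    if (m == 0L) next
    matches <- fin$matches; columns <- fin$columns
    for (j in which(fin$needs_dp == 1L)) {  # indel chains: DP recount
      mc <- pair_identity(substr(qstr, fin$qs[j] + 1L, fin$qe[j]),
                          substr(rstr, fin$rs[j] + 1L, fin$re[j]))
      matches[j] <- mc[1L]; columns[j] <- mc[2L]
    }
    idpct <- 100 * matches / columns
    keep <- idpct >= params$min_identity_pct
    if (!any(keep)) next
    L <- qlen[qi + 1L]
    push("q_id", rep(query$id[qi + 1L], sum(keep)))
    push("r_id", rep(reference$id[ri + 1L], sum(keep)))
    push("q_start", if (strand > 0L) fin$qs[keep] else L - fin$qe[keep])
    push("q_end", if (strand > 0L) fin$qe[keep] else L - fin$qs[keep])
    push("r_start", fin$rs[keep])
    push("r_end", fin$re[keep])
    push("strand", rep(if (strand > 0L) "+" else "-", sum(keep)))
    push("matches", matches[keep])
    push("columns", columns[keep])
    push("identity_pct", idpct[keep])
  }
  if (length(acc$q_id) == 0L) return(empty_alignments())
  res <- as.data.frame(lapply(acc, function(x) unlist(x, use.names = FALSE)),
                       stringsAsFactors = FALSE)
  res <- unique(res)
  rownames(res) <- NULL
  class(res) <- c("alignments", "data.frame")
  res
}

#' Best-matching reference per query record
#'
#' For each query record, the reference record maximising the summed
#' aligned query bases across that pair's alignments; ties break to the
#' lexicographically smallest reference id.
#'
#' @param alignments an `alignments` data frame from [align_sets()].
#' @return Named character vector mapping `q_id` to its best `r_id`.
#' @export
best_match_per_query <- function(alignments) {
  if (nrow(alignments) == 0L) return(stats::setNames(character(0), character(0)))
  bases <- stats::aggregate(alignments$q_end - alignments$q_start,
                            by = list(q_id = alignments$q_id,
                                      r_id = alignments$r_id), FUN = sum)
  bases <- bases[order(bases$q_id, -bases$x, bases$r_id), ]
  best <- bases[!duplicated(bases$q_id), ]
  stats::setNames(best$r_id, best$q_id)
}

#' Mutual best matches between two assemblies
#'
#' A pair `(a, b)` is mutual-best when `b` is `a`'s best match in the
#' A-vs-B alignments and `a` is `b`'s best match in the B-vs-A alignments.
#'
#' @param aln_AB alignments with A records as queries, B as references.
#' @param aln_BA alignments with B records as queries, A as references.
#' @return Data frame with columns `a_id`, `b_id`.
#' @export
mutual_best <- function(aln_AB, aln_BA) {
  ab <- best_match_per_query(aln_AB)
  ba <- best_match_per_query(aln_BA)
  keep <- !is.na(ba[ab]) & ba[ab] == names(ab)
  keep[is.na(keep)] <- FALSE
  data.frame(a_id = names(ab)[keep], b_id = unname(ab[keep]),
             stringsAsFactors = FALSE)
}

# keep, per query, only alignments that win their query region: greedy by
# match count, discarding alignments overlapping >= max_frac of their query
# interval with an already-kept alignment (delta-filter -q style).
filter_best_per_region <- function(alignments, max_frac = 0.5) {
  if (nrow(alignments) == 0L) return(alignments)
  pieces <- lapply(split(alignments, alignments$q_id), function(a) {
    a <- a[order(-a$matches, a$r_id, a$r_start), , drop = FALSE]
    kept <- logical(nrow(a))
    for (i in seq_len(nrow(a))) {
      ov <- 0
      if (any(kept)) {
        kk <- which(kept)
        ov <- max(pmin(a$q_end[i], a$q_end[kk]) - pmax(a$q_start[i], a$q_start[kk]), 0)
      }
      kept[i] <- ov < max_frac * (a$q_end[i] - a$q_start[i])
    }
    a[kept, , drop = FALSE]
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  class(res) <- c("alignments", "data.frame")
  res
}

# total bases of the union of [start,end) intervals
interval_union_bp <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
  }
  tot + (ce - cs)
}

#' Write alignments in a show-coords-style TSV dialect
#'
#' Columns are `r_start r_end q_start q_end r_len_aln q_len_aln identity
#' r_id q_id`, 1-based inclusive; minus-strand alignments carry reversed
#' query coordinates (start > end), following the usual coordinate-listing
#' convention of whole-genome aligners.
#'
#' @param alignments an `alignments` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  fw <- alignments$strand == "+"
  df <- data.frame(
    r_start = alignments$r_start + 1L, r_end = alignments$r_end,
    q_start = ifelse(fw, alignments$q_start + 1L, alignments$q_end),
    q_end = ifelse(fw, alignments$q_end, alignments$q_start + 1L),
    r_len_aln = alignments$r_end - alignments$r_start,
    q_len_aln = alignments$q_end - alignments$q_start,
    identity = sprintf("%.2f", alignments$identity_pct),
    r_id = alignments$r_id, q_id = alignments$q_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignments written by [write_alignments_tsv()]
#' @param path TSV path.
#' @return An `alignments` data frame (without match/column counts, which
#'   are not part of the text dialect; `matches` is reconstructed from the
#'   identity and span).
#' @export
read_alignments_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  fw <- df$q_start <= df$q_end
  cols <- pmax(df$r_len_aln, df$q_len_aln)
  res <- data.frame(
    q_id = as.character(df$q_id), r_id = as.character(df$r_id),
    q_start = ifelse(fw, df$q_start, df$q_end) - 1L,
    q_end = ifelse(fw, df$q_end, df$q_start),
    r_start = df$r_start - 1L, r_end = df$r_end,
    strand = ifelse(fw, "+", "-"),
    matches = as.integer(round(df$identity / 100 * cols)),
    columns = cols, identity_pct = df$identity,
    stringsAsFactors = FALSE)
  class(res) <- c("alignments", "data.frame")
  res
}
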