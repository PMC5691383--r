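#' Extract synthetic mate pairs from mega-read groups
#'
#' When one long read is tiled into several accurate mega-reads, each pair
#' of consecutive mega-reads yields one synthetic mate pair linking them:
#' the left mate is taken from the end of the earlier mega-read facing the
#' gap and the right mate from the start of the later one, oriented as an
#' innie pair (mates on opposite strands, facing inward). A group of n
#' mega-reads yields n - 1 pairs; mega-reads shorter than `end_length`
#' contribute their whole sequence.
#'
#' @param mega_read_groups named list; each element is the ordered
#'   character vector of mega-read sequences from one source long read.
#' @param end_length bases taken from each mega-read end (default 400).
#' @return Data frame of class `mate_pairs`: `pair_id`, `left_seq`,
#'   `right_seq`, `source_id`, `left_index`, `right_index`.
#' @export
extract_synthetic_mates <- function(mega_read_groups, end_length = 400L) {
  stopifnot(is.list(mega_read_groups), end_length >= 1)
  if (is.null(names(mega_read_groups)))
    names(mega_read_groups) <- paste0("read", seq_along(mega_read_groups))
  rows <- list()
  for (g in names(mega_read_groups)) {
    seqs <- toupper(mega_read_groups[[g]])
    if (length(seqs) < 2L) next
    for (i in seq_len(length(seqs) - 1L)) {
      a <- seqs[i]; b <- seqs[i + 1L]
      la <- min(end_length, nchar(a)); lb <- min(end_length, nchar(b))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("%s_pair%d", g, i),
        left_seq = substr(a, nchar(a) - la + 1L, nchar(a)),
        right_seq = cpp_revcomp(substr(b, 1L, lb)),
        source_id = g, left_index = i, right_index = i + 1L,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), left_seq = character(0),
               right_seq = character(0), source_id = character(0),
               left_index = integer(0), right_index = integer(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("mate_pairs", "data.frame")
  res
}

#' Pair consistency percentage
#' @param n_consistent pairs aligned in the correct orientation at a
#'   consistent distance.
#' @param n_same_contig all pairs whose two ends aligned to one contig.
#' @return Whole-number percentage (half away from zero).
#' @export
pair_consistency_pct <- function(n_consistent, n_same_contig) {
  stopifnot(n_same_contig > 0, n_consistent >= 0,
            n_consistent <= n_same_contig)
  round_half_away(100 * n_consistent / n_same_contig)
}

# best unambiguous placement of one end; NULL when unaligned or tied
best_placement <- function(aln) {
  if (nrow(aln) == 0L) return(NULL)
  aln <- aln[order(-aln$matches), , drop = FALSE]
  if (nrow(aln) > 1L && aln$matches[2L] == aln$matches[1L] &&
      (aln$r_id[2L] != aln$r_id[1L] || aln$r_start[2L] != aln$r_start[1L]))
    return(NULL)
  aln[1L, , drop = FALSE]
}

#' Classify read/BAC-end pairs against an assembly
#'
#' Each end is placed at its best alignment; pairs are then classified:
#' both ends on one contig in opposite, inward-facing orientation at a
#' distance within tolerance of the insert mean (`same_contig_consistent`),
#' wrong relative orientation (`same_contig_wrong_orientation`), right
#' orientation but inconsistent distance (`same_contig_bad_distance`), ends
#' on two contigs (`split_pair`), upgraded to `candidate_misassembly` when
#' at least one end sits farther than `insert_mean + tolerance` from its
#' contig end on the mate-facing side (the mate should have fit on the same
#' contig), or `unaligned` when an end has no placement or an ambiguous
#' (tied) one. Unaligned pairs are excluded from the consistency
#' denominator.
#'
#' @param pairs a `mate_pairs` data frame (see
#'   [extract_synthetic_mates()]), or any data frame with `pair_id`,
#'   `left_seq`, `right_seq`.
#' @param assembly_x the `assembly` to validate.
#' @param insert_mean expected outer distance between mate ends, bases.
#' @param insert_sd optional insert standard deviation; when supplied the
#'   tolerance defaults to `3 * insert_sd`, otherwise to
#'   `0.25 * insert_mean`.
#' @param insert_tolerance explicit tolerance override, bases.
#' @param align alignment parameters for placing ends.
#' @return A list of class `pair_classification`: `placements` (one row
#'   per pair: class, contig ids, coordinates, distance) and `summary`
#'   (class counts, `n_same_contig`, `pct_consistent`).
#' @export
classify_pairs <- function(pairs, assembly_x, insert_mean, insert_sd = NULL,
                           insert_tolerance = NULL,
                           align = align_params(min_cluster_bp = 100L)) {
  stopifnot(inherits(assembly_x, "assembly"), insert_mean > 0,
            nrow(pairs) >= 1L)
  tol <- if (!is.null(insert_tolerance)) insert_tolerance
  else if (!is.null(insert_sd)) 3 * insert_sd
  else 0.25 * insert_mean
  ends <- assembly(c(paste0(pairs$pair_id, "/1"), paste0(pairs$pair_id, "/2")),
                   c(pairs$left_seq, pairs$right_seq), name = "pair_ends")
  aln <- align_sets(ends, assembly_x, align)
  clen <- stats::setNames(nchar(assembly_x$seq), assembly_x$id)
  by_end <- split(aln, aln$q_id)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$pair_id[i]
    p1 <- best_placement(by_end[[paste0(pid, "/1")]])
    p2 <- best_placement(by_end[[paste0(pid, "/2")]])
    row <- data.frame(pair_id = pid, class = "unaligned",
                      contig_1 = NA_character_, start_1 = NA_integer_,
                      end_1 = NA_integer_, strand_1 = NA_character_,
                      contig_2 = NA_character_, start_2 = NA_integer_,
                      end_2 = NA_integer_, strand_2 = NA_character_,
                      distance = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(p1)) {
      row$contig_1 <- p1$r_id; row$start_1 <- p1$r_start
      row$end_1 <- p1$r_end; row$strand_1 <- p1$strand
    }
    if (!is.null(p2)) {
      row$contig_2 <- p2$r_id; row$start_2 <- p2$r_start
      row$end_2 <- p2$r_end; row$strand_2 <- p2$strand
    }
    if (!is.null(p1) && !is.null(p2)) {
      if (p1$r_id != p2$r_id) {
        row$class <- "split_pair"
        avail <- function(p) if (p$strand == "+") clen[[p$r_id]] - p$r_start
                             else p$r_end
        if (avail(p1) > insert_mean + tol || avail(p2) > insert_mean + tol)
          row$class <- "candidate_misassembly"
      } else if (p1$strand == p2$strand) {
        row$class <- "same_contig_wrong_orientation"
      } else {
        plus <- if (p1$strand == "+") p1 else p2
        minus <- if (p1$strand == "+") p2 else p1
        if (plus$r_start > minus$r_start) {
          row$class <- "same_contig_wrong_orientation"  # outward facing
        } else {
          row$distance <- minus$r_end - plus$r_start
          row$class <- if (abs(row$distance - insert_mean) <= tol)
            "same_contig_consistent" else "same_contig_bad_distance"
        }
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  placements <- do.call(rbind, rows)
  rownames(placements) <- NULL
  classes <- c("same_contig_consistent", "same_contig_wrong_orientation",
               "same_contig_bad_distance", "split_pair",
               "candidate_misassembly", "unaligned")
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(placements$class == cl), integer(1)),
    classes)
  n_same <- sum(counts[1:3])
  summary <- list(counts = counts, n_pairs = nrow(placements),
                  n_same_contig = n_same,
                  pct_consistent = if (n_same > 0)
                    pair_consistency_pct(counts[["same_contig_consistent"]],
                                         n_same) else NA_real_)
  structure(list(placements = placements, summary = summary),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pair classification>: %d pairs, %d on one contig", s$n_pairs,
              s$n_same_contig))
  if (!is.na(s$pct_consistent))
    cat(sprintf(", %d%% consistent", s$pct_consistent))
  cat("\n")
  print(s$counts)
  invisible(x)
}

#' Write mate pairs as interleaved FASTQ
#'
#' Ends are written as `<pair_id>/1` and `<pair_id>/2` with uniform
#' placeholder qualities.
#'
#' @param pairs a `mate_pairs` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_fastq <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(pairs))) {
    for (side in 1:2) {
      s <- if (side == 1L) pairs$left_seq[i] else pairs$right_seq[i]
      writeLines(c(sprintf("@%s/%d", pairs$pair_id[i], side), s, "+",
                   strrep("I", nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read mate pairs from interleaved FASTQ
#' @param path FASTQ path written by [write_pairs_fastq()] (ends named
#'   `<pair_id>/1` and `<pair_id>/2`).
#' @return A `mate_pairs` data frame (`source_id` and indices are NA).
#' @export
read_pairs_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(ss))
  side <- sub("^.*/", "", ids)
  pid <- sub("/[12]$", "", ids)
  left <- side == "1"
  l <- stats::setNames(as.character(ss[left]), pid[left])
  r <- stats::setNames(as.character(ss[!left]), pid[!left])
  common <- intersect(names(l), names(r))
  res <- data.frame(pair_id = common, left_seq = unname(l[common]),
                    right_seq = unname(r[common]),
                    source_id = NA_character_, left_index = NA_integer_,
                    right_index = NA_integer_, stringsAsFactors = FALSE)
  class(res) <- c("mate_pairs", "data.frame")
  res
}
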