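#' Merge parameters
#'
#' Two contigs of assembly B are joined through a single contig of
#' assembly A when each overlaps that contig by at least `min_overlap_bp`
#' at `min_bridge_identity_pct` identity, with the A sequence filling the
#' gap between them.
#'
#' @param min_overlap_bp minimum overlap of each bridged contig with the
#'   bridging contig (default 5000).
#' @param min_bridge_identity_pct identity floor for bridge alignments
#'   (default 96).
#' @param end_tol_bp unaligned overhang tolerated beyond the
#'   junction-facing contig end for an alignment to count as terminal
#'   (default 100).
#' @param align alignment parameters used when the caller lets the merge
#'   functions compute alignments.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_overlap_bp = 5000L, min_bridge_identity_pct = 96,
                         end_tol_bp = 100L, align = align_params()) {
  stopifnot(min_overlap_bp > 0, min_bridge_identity_pct > 0,
            min_bridge_identity_pct <= 100, end_tol_bp >= 0)
  structure(list(min_overlap_bp = as.integer(min_overlap_bp),
                 min_bridge_identity_pct = min_bridge_identity_pct,
                 end_tol_bp = as.integer(end_tol_bp),
                 align = align),
            class = "merge_params")
}

empty_bridges <- function() {
  data.frame(a_id = character(0), left_b_id = character(0),
             right_b_id = character(0), left_strand = character(0),
             right_strand = character(0),
             left_q_start = integer(0), left_q_end = integer(0),
             right_q_start = integer(0), right_q_end = integer(0),
             left_r_start = integer(0), left_r_end = integer(0),
             right_r_start = integer(0), right_r_end = integer(0),
             fill_start = integer(0), fill_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Plan bridges between two assemblies
#'
#' From alignments of assembly-B contigs onto assembly-A contigs, find
#' every A contig that is overlapped terminally by two or more B contigs
#' by at least `min_overlap_bp` each, and emit one bridge per qualifying
#' adjacent pair along the A contig. Alignments are first reduced to
#' per-query-region best matches so that secondary (e.g. homeologous)
#' matches cannot seed bridges. A negative gap (`fill_end < fill_start`)
#' marks overlapping bridge alignments that will be spliced at the
#' midpoint of the shared A interval.
#'
#' @param aln_B_on_A alignments of B (query) on A (reference) from
#'   [align_sets()].
#' @param assembly_b the B `assembly` (for contig lengths and terminal
#'   checks).
#' @param params a [merge_params()] object.
#' @return Data frame of bridges (one row per adjacent pair), with an
#'   attribute `"conflicts"` listing contigs displaced from a contested
#'   interval.
#' @export
plan_bridges <- function(aln_B_on_A, assembly_b, params = merge_params()) {
  stopifnot(inherits(assembly_b, "assembly"))
  aln <- filter_best_per_region(aln_B_on_A)
  aln <- aln[aln$identity_pct >= params$min_bridge_identity_pct &
               (aln$q_end - aln$q_start) >= params$min_overlap_bp, ,
             drop = FALSE]
  if (nrow(aln) == 0L) return(empty_bridges())
  blen <- stats::setNames(nchar(assembly_b$seq), assembly_b$id)
  tol <- params$end_tol_bp
  # junction-facing terminal flags in forward B coordinates
  aln$reach_low <- aln$q_start <= tol                  # forward-left end
  aln$reach_high <- aln$q_end >= blen[aln$q_id] - tol  # forward-right end
  # facing the gap on the high-r side (left member of a bridge)
  aln$term_right <- ifelse(aln$strand == "+", aln$reach_high, aln$reach_low)
  # facing the gap on the low-r side (right member of a bridge)
  aln$term_left <- ifelse(aln$strand == "+", aln$reach_low, aln$reach_high)

  bridges <- list(); conflicts <- character(0)
  for (piece in split(aln, aln$r_id)) {
    if (nrow(piece) < 2L) next
    # one alignment per B contig on this A contig: the largest
    piece <- piece[order(-(piece$q_end - piece$q_start)), , drop = FALSE]
    piece <- piece[!duplicated(piece$q_id), , drop = FALSE]
    piece <- piece[order(piece$r_start, piece$r_end), , drop = FALSE]
    # resolve contigs contesting the same interval: keep the larger overlap
    keep <- rep(TRUE, nrow(piece))
    last <- 1L
    for (i in seq_len(nrow(piece))[-1L]) {
      ov <- min(piece$r_end[last], piece$r_end[i]) -
        max(piece$r_start[last], piece$r_start[i])
      span_i <- piece$r_end[i] - piece$r_start[i]
      span_l <- piece$r_end[last] - piece$r_start[last]
      if (ov > 0.5 * min(span_i, span_l)) {
        if (span_i > span_l) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
        conflicts <- c(conflicts, piece$q_id[if (keep[i]) last else i])
      } else last <- i
    }
    piece <- piece[keep, , drop = FALSE]
    if (nrow(piece) < 2L) next
    for (i in seq_len(nrow(piece) - 1L)) {
      lft <- piece[i, ]; rgt <- piece[i + 1L, ]
      if (!lft$term_right || !rgt$term_left) next
      if (rgt$r_start <= lft$r_start || rgt$r_end <= lft$r_end) next
      bridges[[length(bridges) + 1L]] <- data.frame(
        a_id = lft$r_id, left_b_id = lft$q_id, right_b_id = rgt$q_id,
        left_strand = lft$strand, right_strand = rgt$strand,
        left_q_start = lft$q_start, left_q_end = lft$q_end,
        right_q_start = rgt$q_start, right_q_end = rgt$q_end,
        left_r_start = lft$r_start, left_r_end = lft$r_end,
        right_r_start = rgt$r_start, right_r_end = rgt$r_end,
        fill_start = lft$r_end, fill_end = rgt$r_start,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(bridges)) do.call(rbind, bridges) else empty_bridges()
  rownames(res) <- NULL
  attr(res, "conflicts") <- unique(conflicts)
  res
}

# oriented coordinates of a bridge member: sequence and alignment interval
# in the frame in which the contig enters the merged layout
oriented_member <- function(seqs, lens, id, strand, q_start, q_end) {
  L <- lens[[id]]
  if (strand == "+")
    list(seq = seqs[[id]], s = q_start, e = q_end)
  else
    list(seq = cpp_revcomp(seqs[[id]]), s = L - q_end, e = L - q_start)
}

#' Execute planned bridges
#'
#' Joins each connected chain of B contigs into a single contig: the left
#' contig's sequence up to its alignment end, the A fill interval, then the
#' right contig from its alignment start, recursively along chains.
#' Contigs aligning on the minus strand are reverse-complemented before
#' joining. Overlapping (negative-gap) bridges are spliced at the midpoint
#' of the shared A interval with the left contig supplying the sequence
#' left of the splice. Unbridged B contigs pass through unchanged.
#'
#' @param assembly_b the B `assembly` (contigs being merged).
#' @param assembly_a the A `assembly` (gap-filling contigs).
#' @param bridges output of [plan_bridges()].
#' @return An `assembly` of merged and passthrough contigs. Attribute
#'   `"junctions"` is a data frame of junction coordinates per merged
#'   contig; attribute `"chains"` maps each merged id to its member B ids.
#' @export
execute_merge <- function(assembly_b, assembly_a, bridges) {
  stopifnot(inherits(assembly_b, "assembly"), inherits(assembly_a, "assembly"))
  if (nrow(bridges) == 0L) return(assembly_b)
  # each B contig may head at most one bridge on each side; keep the
  # larger overlap when violated
  ovl <- pmin(bridges$left_q_end - bridges$left_q_start,
              bridges$right_q_end - bridges$right_q_start)
  bridges <- bridges[order(-ovl), , drop = FALSE]
  bridges <- bridges[!duplicated(bridges$left_b_id), , drop = FALSE]
  bridges <- bridges[!duplicated(bridges$right_b_id), , drop = FALSE]
  # drop orientation-inconsistent chains: a contig must use one strand
  str_of <- c(stats::setNames(bridges$left_strand, bridges$left_b_id))
  rstr <- stats::setNames(bridges$right_strand, bridges$right_b_id)
  bad <- intersect(names(str_of), names(rstr))
  bad <- bad[str_of[bad] != rstr[bad]]
  if (length(bad)) {
    warning("dropping orientation-inconsistent bridge member(s): ",
            paste(bad, collapse = ", "))
    bridges <- bridges[!(bridges$left_b_id %in% bad |
                           bridges$right_b_id %in% bad), , drop = FALSE]
  }
  if (nrow(bridges) == 0L) return(assembly_b)

  seqs <- stats::setNames(as.list(assembly_b$seq), assembly_b$id)
  lens <- stats::setNames(nchar(assembly_b$seq), assembly_b$id)
  nxt <- stats::setNames(seq_len(nrow(bridges)), bridges$left_b_id)
  is_right <- unique(bridges$right_b_id)
  starts <- setdiff(bridges$left_b_id, is_right)

  out_ids <- character(0); out_seqs <- character(0)
  junctions <- list(); chains <- list()
  used <- character(0)
  for (s in starts) {
    members <- s; cur <- s
    br_idx <- integer(0)
    while (!is.na(nxt[cur])) {
      i <- nxt[[cur]]
      br_idx <- c(br_idx, i)
      cur <- bridges$right_b_id[i]
      if (cur %in% members) { br_idx <- br_idx[-length(br_idx)]; break } # cycle guard
      members <- c(members, cur)
    }
    if (length(br_idx) == 0L) next
    # left cut of each junction, then compose
    pieces <- character(0); jpos <- integer(0)
    prev_start <- 0L
    for (j in seq_along(br_idx)) {
      b <- bridges[br_idx[j], ]
      lm <- oriented_member(seqs, lens, b$left_b_id, b$left_strand,
                            b$left_q_start, b$left_q_end)
      rm_ <- oriented_member(seqs, lens, b$right_b_id, b$right_strand,
                             b$right_q_start, b$right_q_end)
      gap <- b$fill_end - b$fill_start
      if (gap >= 0L) {
        lcut <- lm$e
        rcut <- rm_$s
        a_seq <- assembly_a$seq[match(b$a_id, assembly_a$id)]
        fill <- if (gap > 0L) substr(a_seq, b$fill_start + 1L, b$fill_end) else ""
      } else {
        mid <- floor((b$fill_start + b$fill_end) / 2)
        lcut <- lm$e - (b$left_r_end - mid)
        rcut <- rm_$s + (mid - b$right_r_start)
        fill <- ""
      }
      left_piece <- substr(lm$seq, prev_start + 1L, lcut)
      pieces <- c(pieces, left_piece, fill)
      base <- sum(nchar(pieces)) - nchar(fill)
      jpos <- c(jpos, base, if (nchar(fill) > 0L) base + nchar(fill))
      prev_start <- rcut
    }
    last_b <- bridges[br_idx[length(br_idx)], ]
    lm <- oriented_member(seqs, lens, last_b$right_b_id, last_b$right_strand,
                          last_b$right_q_start, last_b$right_q_end)
    pieces <- c(pieces, substr(lm$seq, prev_start + 1L, nchar(lm$seq)))
    oid <- paste(members, collapse = "+")
    out_ids <- c(out_ids, oid)
    out_seqs <- c(out_seqs, paste(pieces, collapse = ""))
    junctions[[oid]] <- unique(jpos)
    chains[[oid]] <- members
    used <- c(used, members)
  }
  passthrough <- setdiff(assembly_b$id, used)
  res <- assembly(c(out_ids, passthrough),
                  c(out_seqs, assembly_b$seq[match(passthrough, assembly_b$id)]),
                  name = paste0(assembly_b$name, "_merged"))
  jdf <- if (length(junctions))
    data.frame(contig_id = rep(names(junctions), lengths(junctions)),
               pos = unlist(junctions, use.names = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(contig_id = character(0), pos = integer(0))
  attr(res, "junctions") <- jdf
  attr(res, "chains") <- chains
  res
}

#' Add non-contained scaffolds from assembly A
#'
#' Appends every A record that is not contained (under the containment
#' criterion of [dedup_params()]) in any contig of the merged assembly.
#' Appended records keep their ids, suffixed when an id collides with an
#' existing merged contig id.
#'
#' @param merged the merged `assembly` (output of [execute_merge()]).
#' @param assembly_a the A `assembly` whose scaffolds are candidates.
#' @param params a [dedup_params()] object for the containment test.
#' @return An `assembly` with the unique A scaffolds appended.
#' @export
add_unique_scaffolds <- function(merged, assembly_a, params = dedup_params()) {
  stopifnot(inherits(merged, "assembly"), inherits(assembly_a, "assembly"))
  calls <- containment_calls(assembly_a, merged, params)
  add <- setdiff(assembly_a$id, unique(calls$contained_id))
  if (length(add) == 0L) return(merged)
  ids <- add
  clash <- ids %in% merged$id
  ids[clash] <- paste0(ids[clash], "_A")
  res <- assembly(c(merged$id, ids),
                  c(merged$seq, assembly_a$seq[match(add, assembly_a$id)]),
                  name = merged$name,
                  role = c(merged$role,
                           assembly_a$role[match(add, assembly_a$id)]))
  attr(res, "junctions") <- attr(merged, "junctions")
  attr(res, "chains") <- attr(merged, "chains")
  attr(res, "added") <- ids
  res
}

#' Write planned bridges as TSV
#' @param bridges output of [plan_bridges()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bridges_tsv <- function(bridges, path) {
  utils::write.table(bridges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
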