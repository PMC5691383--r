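#' De-duplication parameters
#'
#' A record is contained when the union of its alignments onto a single
#' longer (or equal-length) record covers at least `min_containment_cov`
#' of its length at a length-weighted identity of at least
#' `min_identity_pct`. Complete containment is operationalised as 99%
#' coverage rather than 100% to tolerate a few bases of unaligned terminal
#' overhang.
#'
#' @param min_identity_pct identity floor, percent (default 96).
#' @param min_containment_cov required covered fraction of the contained
#'   record (default 0.99).
#' @param align alignment parameters ([align_params()]) used for the
#'   self-alignment.
#' @return A list of class `dedup_params`.
#' @export
dedup_params <- function(min_identity_pct = 96, min_containment_cov = 0.99,
                         align = align_params()) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            min_containment_cov > 0, min_containment_cov <= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_containment_cov = min_containment_cov,
                 align = align),
            class = "dedup_params")
}

# containment calls of query records inside reference records; used both
# for self-deduplication and for the "not contained in merged contigs"
# filter of assembly merging. `alignments` may be precomputed.
containment_calls <- function(query, reference, params, alignments = NULL,
                              self = FALSE) {
  ap <- params$align
  ap$min_identity_pct <- min(ap$min_identity_pct, params$min_identity_pct)
  if (is.null(alignments))
    alignments <- align_sets(query, reference, ap, skip_same_id = self)
  if (nrow(alignments) == 0L)
    return(data.frame(contained_id = character(0), container_id = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  qlen <- stats::setNames(nchar(query$seq), query$id)
  rlen <- stats::setNames(nchar(reference$seq), reference$id)
  out <- list()
  for (piece in split(alignments,
                      paste(alignments$q_id, alignments$r_id, sep = "\r"))) {
    q <- piece$q_id[1L]; r <- piece$r_id[1L]
    if (self) {
      if (q == r) next
      # only a record no longer than its container can be contained;
      # equal-length near-identical pairs are broken lexicographically
      if (qlen[q] > rlen[r]) next
      if (qlen[q] == rlen[r] && q < r) next
    }
    cov <- interval_union_bp(piece$q_start, piece$q_end) / qlen[q]
    ident <- 100 * sum(piece$matches) / sum(piece$columns)
    if (cov >= params$min_containment_cov && ident >= params$min_identity_pct)
      out[[length(out) + 1L]] <- data.frame(
        contained_id = q, container_id = r,
        coverage = cov, identity = ident, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(contained_id = character(0), container_id = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find contained records by self-alignment
#'
#' Aligns an assembly against itself and reports every record whose
#' alignments onto some other, no-shorter record satisfy the containment
#' criterion of [dedup_params()]. Self-alignments are ignored.
#'
#' @param x an `assembly` with at least 2 records.
#' @param params a [dedup_params()] object.
#' @param alignments optional precomputed self-alignments (from
#'   `align_sets(x, x, skip_same_id = TRUE)`).
#' @return Data frame with columns `contained_id`, `container_id`,
#'   `coverage`, `identity` (one row per qualifying pair).
#' @export
find_contained <- function(x, params = dedup_params(), alignments = NULL) {
  stopifnot(inherits(x, "assembly"))
  if (length(x$id) < 2L) stop("assembly must have at least 2 records")
  containment_calls(x, x, params, alignments = alignments, self = TRUE)
}

#' Remove contained records from an assembly
#'
#' Containment is computed once against the original assembly, then all
#' contained records are removed. Chains of containment (A contains B
#' contains C) resolve to the maximal container because at the identity
#' levels involved the maximal container absorbs the whole chain directly.
#'
#' @inheritParams find_contained
#' @return The de-duplicated `assembly`, with attribute `"removed"` holding
#'   the containment report of [find_contained()].
#' @export
deduplicate <- function(x, params = dedup_params(), alignments = NULL) {
  stopifnot(inherits(x, "assembly"))
  if (length(x$id) < 2L) return(x)
  calls <- find_contained(x, params, alignments = alignments)
  keep <- setdiff(x$id, unique(calls$contained_id))
  out <- assembly_subset(x, keep)
  out$name <- x$name
  attr(out, "removed") <- calls
  out
}
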