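#' Subgenome partition parameters
#'
#' A contig is assigned to the ancestor-derived subgenome when its
#' best-match alignments to the ancestor assembly reach a length-weighted
#' identity of at least `min_identity_pct` and cover at least
#' `min_assigned_cov` of the contig. The identity floor alone does not
#' discriminate in repeat-rich genomes, where short spurious high-identity
#' repeat hits would otherwise assign homeologous contigs; set
#' `min_assigned_cov = 0` to reproduce the looser identity-only criterion.
#'
#' @param min_identity_pct identity floor, percent (default 97).
#' @param min_assigned_cov required covered fraction of the contig
#'   (default 0.5).
#' @param align alignment parameters ([align_params()]).
#' @return A list of class `partition_params`.
#' @export
partition_params <- function(min_identity_pct = 97, min_assigned_cov = 0.5,
                             align = align_params()) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            min_assigned_cov >= 0, min_assigned_cov <= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_assigned_cov = min_assigned_cov,
                 align = align),
            class = "partition_params")
}

# per-contig best-match statistics (identity weighted by alignment columns,
# coverage from the union of query intervals of the best-match alignments)
best_match_stats <- function(alignments, qlen) {
  best <- best_match_per_query(alignments)
  out <- list()
  for (q in names(best)) {
    piece <- alignments[alignments$q_id == q & alignments$r_id == best[[q]], ,
                        drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      q_id = q, r_id = best[[q]],
      identity = 100 * sum(piece$matches) / sum(piece$columns),
      coverage = interval_union_bp(piece$q_start, piece$q_end) / qlen[[q]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(q_id = character(0), r_id = character(0),
                      identity = numeric(0), coverage = numeric(0)))
  do.call(rbind, out)
}

#' Assign contigs to a subgenome by ancestor alignment
#'
#' Splits an assembly into the contigs attributable to the subgenome
#' descended from a given diploid ancestor (assigned) and the rest
#' (remainder), by aligning the assembly to the ancestor and applying the
#' identity and coverage floors of [partition_params()] to each contig's
#' best-match alignments. Assignment is computed on the
#' assembly-to-ancestor direction by default.
#'
#' @param x the `assembly` to partition.
#' @param ancestor the ancestor `assembly`.
#' @param params a [partition_params()] object.
#' @param direction `"assembly_to_ancestor"` (default) or
#'   `"ancestor_to_assembly"`: which alignment direction defines the best
#'   matches used for assignment.
#' @return A list of class `subgenome_partition` with elements `assigned`
#'   and `remainder` (both `assembly` objects; their union is the input)
#'   and `stats` (per-contig best-match identity and coverage).
#' @export
assign_by_ancestor <- function(x, ancestor, params = partition_params(),
                               direction = c("assembly_to_ancestor",
                                             "ancestor_to_assembly")) {
  stopifnot(inherits(x, "assembly"), inherits(ancestor, "assembly"))
  direction <- match.arg(direction)
  ap <- params$align
  ap$min_identity_pct <- min(ap$min_identity_pct, params$min_identity_pct)
  qlen <- stats::setNames(nchar(x$seq), x$id)
  if (direction == "assembly_to_ancestor") {
    aln <- align_sets(x, ancestor, ap)
    st <- best_match_stats(aln, qlen)
  } else {
    aln <- align_sets(ancestor, x, ap)
    # mirror: credit each assembly contig with the ancestor alignments that
    # chose it as reference, measured on the contig side
    mir <- aln
    names(mir)[match(c("q_id", "r_id", "q_start", "q_end", "r_start", "r_end"),
                     names(mir))] <-
      c("r_id", "q_id", "r_start", "r_end", "q_start", "q_end")
    st <- best_match_stats(mir, qlen)
  }
  ok <- st$identity >= params$min_identity_pct &
    st$coverage >= params$min_assigned_cov
  assigned_ids <- st$q_id[ok]
  rest_ids <- setdiff(x$id, assigned_ids)
  empty_asm <- function(nm)
    structure(list(name = nm, id = character(0), seq = character(0),
                   role = character(0)), class = "assembly")
  sub_asm <- function(ids, nm) {
    if (length(ids) == 0L) return(empty_asm(nm))
    a <- assembly_subset(x, ids); a$name <- nm; a
  }
  res <- list(assigned = sub_asm(assigned_ids, paste0(x$name, "_assigned")),
              remainder = sub_asm(rest_ids, paste0(x$name, "_rest")),
              stats = st)
  class(res) <- "subgenome_partition"
  res
}

#' @export
print.subgenome_partition <- function(x, ...) {
  cat(sprintf("<subgenome partition>: %d assigned, %d remainder\n",
              length(x$assigned$id), length(x$remainder$id)))
  invisible(x)
}

# connected components of a bipartite edge list via union-find
bipartite_components <- function(anc_ids, asm_ids) {
  nodes <- unique(c(paste0("anc:", anc_ids), paste0("asm:", asm_ids)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  for (i in seq_along(anc_ids)) {
    a <- find(paste0("anc:", anc_ids[i])); b <- find(paste0("asm:", asm_ids[i]))
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

#' Reverse-direction coverage of the ancestor by the assigned subgenome
#'
#' Aligns the ancestor assembly to the assigned subgenome and reports how
#' much of the ancestor is covered (union of alignment intervals on the
#' ancestor), plus the multiplicity structure of the best-match mapping
#' between the two record sets (connected components of the bipartite
#' best-match graph).
#'
#' @param ancestor the ancestor `assembly`.
#' @param assigned the assigned subgenome `assembly`.
#' @param params a [partition_params()] object (its identity floor gates
#'   which alignments count as matching).
#' @return A list of class `reverse_coverage` with `total_bp`,
#'   `unaligned_bp`, `aligned_pct` (one decimal) and `multiplicities`
#'   (data frame: `relation`, `anc_members`, `asm_members`).
#' @export
reverse_coverage_stats <- function(ancestor, assigned,
                                   params = partition_params()) {
  stopifnot(inherits(ancestor, "assembly"), inherits(assigned, "assembly"))
  ap <- params$align
  ap$min_identity_pct <- min(ap$min_identity_pct, params$min_identity_pct)
  total <- assembly_total_bp(ancestor)
  if (length(assigned$id) == 0L)
    return(structure(list(total_bp = total, unaligned_bp = total,
                          aligned_pct = 0,
                          multiplicities = data.frame(relation = character(0),
                                                      anc_members = character(0),
                                                      asm_members = character(0))),
                     class = "reverse_coverage"))
  aln <- align_sets(ancestor, assigned, ap)
  aln <- aln[aln$identity_pct >= params$min_identity_pct, , drop = FALSE]
  covered <- 0
  for (piece in split(aln, aln$q_id))
    covered <- covered + interval_union_bp(piece$q_start, piece$q_end)
  unaligned <- total - covered
  # best-match edges in both directions define the multiplicity graph
  aln_back <- align_sets(assigned, ancestor, ap)
  aln_back <- aln_back[aln_back$identity_pct >= params$min_identity_pct, ,
                       drop = FALSE]
  b1 <- best_match_per_query(aln)       # ancestor -> assembly
  b2 <- best_match_per_query(aln_back)  # assembly -> ancestor
  anc_e <- c(names(b1), unname(b2))
  asm_e <- c(unname(b1), names(b2))
  mult <- data.frame(relation = character(0), anc_members = character(0),
                     asm_members = character(0), stringsAsFactors = FALSE)
  if (length(anc_e)) {
    comps <- bipartite_components(anc_e, asm_e)
    rows <- lapply(comps, function(cc) {
      anc <- sort(sub("^anc:", "", cc[startsWith(cc, "anc:")]))
      asm <- sort(sub("^asm:", "", cc[startsWith(cc, "asm:")]))
      # orientation: many assembly contigs on one ancestor contig is
      # many_to_one; one assembly contig absorbing several ancestor contigs
      # is one_to_many
      rel <- if (length(anc) == 1L && length(asm) == 1L) "one_to_one"
      else if (length(anc) == 1L) "many_to_one"
      else if (length(asm) == 1L) "one_to_many"
      else "many_to_many"
      data.frame(relation = rel, anc_members = paste(anc, collapse = ","),
                 asm_members = paste(asm, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    mult <- do.call(rbind, rows)
    rownames(mult) <- NULL
  }
  structure(list(total_bp = total, unaligned_bp = unaligned,
                 aligned_pct = aligned_fraction_pct(total, unaligned),
                 multiplicities = mult),
            class = "reverse_coverage")
}

#' @export
print.reverse_coverage <- function(x, ...) {
  cat(sprintf("%.1f%% of the ancestor aligns (%s of %s bp unaligned)\n",
              x$aligned_pct,
              format(x$unaligned_bp, big.mark = ","),
              format(x$total_bp, big.mark = ",")))
  if (nrow(x$multiplicities))
    print(table(x$multiplicities$relation))
  invisible(x)
}
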