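#' Polishing parameters
#'
#' @param min_span_bp minimum aligned span replaced by donor sequence;
#'   shorter micro-alignments are ignored to avoid churn (default 200).
#' @param align alignment parameters ([align_params()]).
#' @return A list of class `polish_params`.
#' @export
polish_params <- function(min_span_bp = 200L, align = align_params()) {
  stopifnot(min_span_bp >= 1)
  structure(list(min_span_bp = as.integer(min_span_bp), align = align),
            class = "polish_params")
}

#' Re-polish an assembly with donor consensus
#'
#' Replaces the consensus of a primary assembly with sequence from a donor
#' assembly: primary and donor records are paired by mutual best match,
#' and within each pair every aligned span of the primary record is
#' replaced by the corresponding donor span (reverse-complemented for
#' minus-strand alignments). Unaligned primary spans are kept verbatim, so
#' record count and ids never change; total length can shift slightly when
#' the used alignments contain indels. Overlapping replacement spans are
#' resolved left to right, with later spans trimmed.
#'
#' @param primary the `assembly` whose consensus is being replaced.
#' @param donor the `assembly` supplying the consensus.
#' @param params a [polish_params()] object.
#' @return A list of class `repolish_result`: `assembly` (the polished
#'   primary) and `report` (`n_pairs`, `replaced_bp`, `replaced_pct`,
#'   `trimmed_overlaps`).
#' @export
repolish <- function(primary, donor, params = polish_params()) {
  stopifnot(inherits(primary, "assembly"), inherits(donor, "assembly"))
  aln_pd <- align_sets(primary, donor, params$align)
  aln_dp <- align_sets(donor, primary, params$align)
  mb <- mutual_best(aln_pd, aln_dp)
  new_seq <- primary$seq
  replaced_primary <- 0; installed <- 0; trimmed <- 0L
  for (i in seq_len(nrow(mb))) {
    p_id <- mb$a_id[i]; d_id <- mb$b_id[i]
    spans <- aln_pd[aln_pd$q_id == p_id & aln_pd$r_id == d_id &
                      (aln_pd$q_end - aln_pd$q_start) >= params$min_span_bp, ,
                    drop = FALSE]
    if (nrow(spans) == 0L) next
    spans <- spans[order(spans$q_start, spans$q_end), , drop = FALSE]
    pi_ <- match(p_id, primary$id)
    di <- match(d_id, donor$id)
    pseq <- primary$seq[pi_]; dseq <- donor$seq[di]
    pieces <- character(0)
    cursor <- 0L
    for (j in seq_len(nrow(spans))) {
      qs <- spans$q_start[j]; qe <- spans$q_end[j]
      rs <- spans$r_start[j]; re <- spans$r_end[j]
      minus <- spans$strand[j] == "-"
      if (qe <= cursor) { trimmed <- trimmed + 1L; next }
      if (qs < cursor) {  # trim the later span left-to-right
        trimmed <- trimmed + 1L
        shift <- cursor - qs
        qs <- cursor
        if (minus) re <- re - shift else rs <- rs + shift
        if (re <= rs) next
      }
      piece <- substr(dseq, rs + 1L, re)
      if (minus) piece <- cpp_revcomp(piece)
      pieces <- c(pieces, substr(pseq, cursor + 1L, qs), piece)
      replaced_primary <- replaced_primary + (qe - qs)
      installed <- installed + nchar(piece)
      cursor <- qe
    }
    pieces <- c(pieces, substr(pseq, cursor + 1L, nchar(pseq)))
    new_seq[pi_] <- paste(pieces, collapse = "")
  }
  out <- assembly(primary$id, new_seq, name = primary$name,
                  role = primary$role)
  report <- list(n_pairs = nrow(mb), replaced_bp = installed,
                 replaced_pct = 100 * replaced_primary /
                   assembly_total_bp(primary),
                 trimmed_overlaps = trimmed)
  structure(list(assembly = out, report = report), class = "repolish_result")
}

#' @export
print.repolish_result <- function(x, ...) {
  cat(sprintf(
    "<repolish>: %d mutual-best pairs, %s donor bp installed (%.1f%% of consensus replaced)\n",
    x$report$n_pairs, format(x$report$replaced_bp, big.mark = ","),
    x$report$replaced_pct))
  invisible(x)
}

#' Write a polishing report as TSV
#' @param result a `repolish_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polish_tsv <- function(result, path) {
  r <- result$report
  utils::write.table(data.frame(n_pairs = r$n_pairs,
                                replaced_bp = r$replaced_bp,
                                replaced_pct = round_half_away(r$replaced_pct, 1),
                                trimmed_overlaps = r$trimmed_overlaps),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
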