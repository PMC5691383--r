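#' Construct an assembly
#'
#' An assembly is an ordered collection of named nucleotide sequences
#' (contigs and/or scaffolds). Sequences are stored as upper-case character
#' strings over `A,C,G,T,N`; record ids must be unique and non-empty and
#' every sequence must have length >= 1.
#'
#' @param ids character vector of unique record ids.
#' @param seqs character vector of nucleotide sequences (same length as
#'   `ids`). Lower-case input is upper-cased.
#' @param name assembly name (a label carried through reports).
#' @param role per-record role, `"contig"` or `"scaffold"`; recycled.
#' @return An object of class `assembly`: a list with elements `name`,
#'   `id`, `seq` and `role`.
#' @examples
#' a <- assembly(c("c1", "c2"), c("ACGTACGT", "GGGTTTAA"))
#' assembly_lengths(a)
#' @export
assembly <- function(ids, seqs, name = "assembly", role = "contig") {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("record ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) < 1L))
    stop("every record must have length >= 1")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in records: ", paste(ids[bad], collapse = ", "))
  role <- rep_len(as.character(role), length(ids))
  if (!all(role %in% c("contig", "scaffold")))
    stop("role must be 'contig' or 'scaffold'")
  structure(list(name = name, id = ids, seq = unname(seqs), role = role),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s'>: %d records, %s bp\n",
              x$name, length(x$id),
              format(assembly_total_bp(x), big.mark = ",", scientific = FALSE)))
  n <- min(6L, length(x$id))
  for (i in seq_len(n))
    cat(sprintf("  %s  %d bp (%s)\n", x$id[i], nchar(x$seq[i]), x$role[i]))
  if (length(x$id) > n) cat(sprintf("  ... and %d more\n", length(x$id) - n))
  invisible(x)
}

#' @export
length.assembly <- function(x) length(x$id)

#' Record lengths of an assembly
#' @param x an `assembly`.
#' @return Named integer vector of record lengths in bases.
#' @export
assembly_lengths <- function(x) {
  stopifnot(inherits(x, "assembly"))
  stats::setNames(nchar(x$seq), x$id)
}

#' Total assembly span in bases
#' @param x an `assembly`.
#' @return Total length in bp (sum of record lengths, N bases included).
#' @export
assembly_total_bp <- function(x) sum(as.numeric(nchar(x$seq)))

#' Subset an assembly by record id
#' @param x an `assembly`.
#' @param ids record ids to keep, in the given order.
#' @return A new `assembly` with the selected records.
#' @export
assembly_subset <- function(x, ids) {
  stopifnot(inherits(x, "assembly"))
  idx <- match(ids, x$id)
  if (anyNA(idx)) stop("unknown record ids: ", paste(ids[is.na(idx)], collapse = ", "))
  assembly(x$id[idx], x$seq[idx], name = x$name, role = x$role[idx])
}

#' Read a FASTA file into an assembly
#'
#' Sequences are upper-cased on read so that a write/read round trip is the
#' identity on ids and (upper-cased) sequences.
#'
#' @param path path to a (multi-)FASTA file.
#' @param name assembly name; defaults to the file stem.
#' @param role record role assigned to all records.
#' @return An `assembly`.
#' @export
read_fasta <- function(path, name = NULL, role = "contig") {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  assembly(ids, as.character(ss),
           name = if (is.null(name)) tools::file_path_sans_ext(basename(path)) else name,
           role = role)
}

#' Write an assembly to a FASTA file
#'
#' @param x an `assembly`.
#' @param path output path. Records are wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "assembly"))
  ss <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$id))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Split scaffolds into contigs at N runs
#'
#' Helper that breaks each record at runs of `N` of at least `min_n_run`
#' bases; the resulting pieces are returned as contigs named
#' `<id>.1, <id>.2, ...` (records without qualifying N runs keep their id).
#'
#' @param x an `assembly`.
#' @param min_n_run minimum N-run length that constitutes a gap (default 10).
#' @return An `assembly` of contigs.
#' @export
split_scaffolds <- function(x, min_n_run = 10L) {
  stopifnot(inherits(x, "assembly"), min_n_run >= 1L)
  pat <- sprintf("N{%d,}", as.integer(min_n_run))
  ids <- character(0); seqs <- character(0)
  for (i in seq_along(x$id)) {
    pieces <- strsplit(gsub(pat, "\n", x$seq[i]), "\n", fixed = TRUE)[[1]]
    pieces <- pieces[nzchar(pieces)]
    if (length(pieces) <= 1L) {
      ids <- c(ids, x$id[i]); seqs <- c(seqs, x$seq[i])
    } else {
      ids <- c(ids, paste0(x$id[i], ".", seq_along(pieces)))
      seqs <- c(seqs, pieces)
    }
  }
  assembly(ids, seqs, name = x$name, role = "contig")
}

#' Reverse complement sequences
#' @param seqs character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) cpp_revcomp(toupper(seqs))
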