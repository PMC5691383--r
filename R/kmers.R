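#' Canonical k-mer spectrum
#'
#' Counts canonical k-mers (the lexicographic minimum of each k-mer and
#' its reverse complement) over a read set or assembly. K-mers containing
#' `N` are excluded.
#'
#' @param x an `assembly`, or a character vector of read sequences.
#' @param k k-mer length (default 31; minimum 11).
#' @param source label: `"reads"`, `"assembly"` or `"union"`. Guessed from
#'   `x` when missing.
#' @return A list of class `kmer_spectrum` with fields `k`, `kmer`
#'   (character), `count` (numeric) and `source`.
#' @export
kmer_spectrum <- function(x, k = 31L, source = NULL) {
  stopifnot(k >= 11L)
  seqs <- if (inherits(x, "assembly")) x$seq else toupper(as.character(x))
  if (is.null(source))
    source <- if (inherits(x, "assembly")) "assembly" else "reads"
  df <- cpp_kmer_counts(seqs, as.integer(k))
  o <- order(df$kmer)
  structure(list(k = as.integer(k), kmer = df$kmer[o], count = df$count[o],
                 source = source),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum k=%d, %d distinct canonical k-mers, source=%s>\n",
              x$k, length(x$kmer), x$source))
  invisible(x)
}

#' Write a k-mer spectrum as sorted TSV
#' @param spectrum a `kmer_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(data.frame(kmer = spectrum$kmer, count = spectrum$count),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# distinct canonical k-mers present in one assembly or the union of several
assembly_kmer_set <- function(assemblies, k) {
  if (inherits(assemblies, "assembly")) assemblies <- list(assemblies)
  sets <- lapply(assemblies, function(a) cpp_kmer_counts(a$seq, k)$kmer)
  unique(unlist(sets, use.names = FALSE))
}

#' K-mer uniqueness curve of a genome
#'
#' For each k, the percentage of genome positions covered by at least one
#' k-mer window that occurs exactly once genome-wide (canonical counting).
#' This uniqueness ratio quantifies repetitiveness: it approximates the
#' fraction of the genome that reads of length k could place unambiguously,
#' and is non-decreasing in k. The denominator is the number of non-N
#' positions; records shorter than k are skipped with a warning.
#'
#' @param genome an `assembly`.
#' @param ks integer vector of k values (default
#'   `c(16, 24, 32, 48, 64, 96, 128)`).
#' @return A data frame of class `uniqueness_curve` with columns `k` and
#'   `pct_covered`.
#' @export
uniqueness_curve <- function(genome, ks = c(16L, 24L, 32L, 48L, 64L, 96L, 128L)) {
  stopifnot(inherits(genome, "assembly"), all(ks >= 2L))
  pts <- vapply(as.integer(ks), function(k) {
    if (any(nchar(genome$seq) < k))
      warning(sprintf("records shorter than k=%d skipped", k))
    res <- cpp_unique_coverage(genome$seq, k)
    if (res$denom == 0) return(NA_real_)
    100 * res$covered / res$denom
  }, numeric(1))
  structure(data.frame(k = as.integer(ks), pct_covered = pts),
            class = c("uniqueness_curve", "data.frame"))
}

#' Missing k-mer histogram
#'
#' Compares a read k-mer spectrum with the k-mer content of one assembly
#' (or the union of several): for each read multiplicity `m`, the number
#' of distinct canonical read k-mers with count `m` that are absent from
#' the assembly. Peaks near the sequencing depth flag lost single-copy
#' consensus sequence; a perfect assembly of the read source has all bins
#' zero.
#'
#' @param reads_spectrum a `kmer_spectrum` built from reads.
#' @param assemblies an `assembly` or a list of assemblies (their k-mer
#'   sets are unioned, as when evaluating two assemblies as one sequence
#'   set).
#' @param k k-mer length; must equal `reads_spectrum$k` (default 31).
#' @return A list of class `missing_kmer_histogram` with fields `k`,
#'   `multiplicity`, `missing_count` and `total_missing`.
#' @export
missing_kmer_histogram <- function(reads_spectrum, assemblies, k = 31L) {
  stopifnot(inherits(reads_spectrum, "kmer_spectrum"))
  if (reads_spectrum$k != k)
    stop("reads spectrum was counted at k=", reads_spectrum$k)
  present <- assembly_kmer_set(assemblies, as.integer(k))
  miss <- !(reads_spectrum$kmer %in% present)
  tab <- table(reads_spectrum$count[miss])
  structure(list(k = as.integer(k),
                 multiplicity = as.integer(names(tab)),
                 missing_count = as.integer(tab),
                 total_missing = sum(miss)),
            class = "missing_kmer_histogram")
}

#' @export
print.missing_kmer_histogram <- function(x, ...) {
  cat(sprintf("<missing %d-mer histogram>: %d distinct read k-mers missing\n",
              x$k, x$total_missing))
  invisible(x)
}

#' Write a missing-k-mer histogram as TSV
#' @param hist a `missing_kmer_histogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  utils::write.table(data.frame(multiplicity = hist$multiplicity,
                                missing_count = hist$missing_count),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Excess duplicated k-mers in an assembly
#'
#' Counts distinct k-mers whose read multiplicity sits in the single-copy
#' band of the read spectrum (the spectrum mode over multiplicities >= 2,
#' plus/minus a half-width) but which occur two or more times in the
#' assembly. An excess signals over-corrected consensus: near-identical
#' repeat copies homogenised onto one allele duplicate that allele's
#' k-mers while the reads say each should occur once.
#'
#' @param reads_spectrum a `kmer_spectrum` from reads.
#' @param assembly_x an `assembly`.
#' @param k k-mer length, must match the spectrum (default 31).
#' @param band_halfwidth half-width of the single-copy multiplicity band;
#'   default `max(1, round(mode/4))`.
#' @return Integer count, with attributes `mode` and `band`.
#' @export
excess_duplicate_kmers <- function(reads_spectrum, assembly_x, k = 31L,
                                   band_halfwidth = NULL) {
  stopifnot(inherits(reads_spectrum, "kmer_spectrum"),
            inherits(assembly_x, "assembly"))
  if (reads_spectrum$k != k)
    stop("reads spectrum was counted at k=", reads_spectrum$k)
  cnt <- reads_spectrum$count
  tab <- table(cnt[cnt >= 2])
  if (length(tab) == 0L) return(structure(0L, mode = NA, band = c(NA, NA)))
  mode_m <- as.numeric(names(tab))[which.max(tab)]
  if (is.null(band_halfwidth)) band_halfwidth <- max(1, round(mode_m / 4))
  band <- c(mode_m - band_halfwidth, mode_m + band_halfwidth)
  in_band <- cnt >= band[1L] & cnt <= band[2L]
  asm <- cpp_kmer_counts(assembly_x$seq, as.integer(k))
  dup <- asm$kmer[asm$count >= 2]
  n <- sum(reads_spectrum$kmer[in_band] %in% dup)
  structure(as.integer(n), mode = mode_m, band = band)
}
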