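#' Round half away from zero
#'
#' Integer rounding used for all printed assembly statistics (base R's
#' `round()` rounds half to even, which disagrees with the usual convention
#' for reported table values).
#'
#' @param x numeric vector.
#' @param digits decimal digits to keep (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' NG50 of a set of sequence lengths
#'
#' The NG50 is the largest length `L` such that records of length >= `L`
#' jointly cover at least half of a fixed genome-size estimate. Computing
#' N50-style statistics against a common genome size makes them comparable
#' across assemblies of different total span. If the assembly never reaches
#' the genome midpoint the NG50 is 0.
#'
#' @param lengths numeric vector of record lengths in bases.
#' @param genome_size genome-size estimate in bases (> 0). With
#'   `genome_size = sum(lengths)` this is the classical N50.
#' @return The NG50 in bases (a member of `lengths`, or 0).
#' @examples
#' ng50(c(5, 4, 3, 2, 1), genome_size = 15)  # 4
#' @export
ng50 <- function(lengths, genome_size) {
  stopifnot(is.numeric(genome_size), length(genome_size) == 1L, genome_size > 0)
  if (length(lengths) == 0L) {
    warning("ng50 of an empty length list is 0")
    return(0)
  }
  ls <- sort(as.numeric(lengths), decreasing = TRUE)
  idx <- which(cumsum(ls) >= genome_size / 2)
  if (length(idx) == 0L) return(0)
  ls[idx[1L]]
}

#' Mean record size as printed in assembly summary tables
#' @param total_bp total assembly span in bases.
#' @param n_records number of records.
#' @return `total_bp / n_records`, rounded half away from zero.
#' @export
assembly_mean_bp <- function(total_bp, n_records) {
  stopifnot(n_records >= 1)
  round_half_away(total_bp / n_records)
}

#' Summary statistics for an assembly
#'
#' Record count, total and mean size, and the NG50 against a fixed
#' genome-size estimate.
#'
#' @param x an `assembly`.
#' @param genome_size genome-size estimate in bases used as the NG50
#'   denominator.
#' @return An object of class `assembly_stats` with fields `name`,
#'   `n_records`, `total_bp`, `mean_bp`, `ng50_bp`, `genome_size_bp`.
#' @export
summary_stats <- function(x, genome_size) {
  stopifnot(inherits(x, "assembly"))
  if (length(x$id) == 0L) stop("empty assembly")
  ls <- as.numeric(nchar(x$seq))
  structure(list(name = x$name,
                 n_records = length(ls),
                 total_bp = sum(ls),
                 mean_bp = assembly_mean_bp(sum(ls), length(ls)),
                 ng50_bp = ng50(ls, genome_size),
                 genome_size_bp = genome_size),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("Assembly statistics for '%s' (genome size %s bp)\n",
              x$name, format(x$genome_size_bp, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  records: %d   total: %s bp   mean: %s bp   NG50: %s bp\n",
              x$n_records,
              format(x$total_bp, big.mark = ",", scientific = FALSE),
              format(x$mean_bp, big.mark = ",", scientific = FALSE),
              format(x$ng50_bp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Write assembly statistics as TSV
#' @param stats an `assembly_stats` object or a list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  if (inherits(stats, "assembly_stats")) stats <- list(stats)
  df <- do.call(rbind, lapply(stats, function(s)
    data.frame(assembly = s$name, number = s$n_records, total_bp = s$total_bp,
               average_bp = s$mean_bp, ng50_bp = s$ng50_bp,
               genome_size_bp = s$genome_size_bp)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sequencing coverage fold
#' @param total_bases total sequenced bases.
#' @param genome_size genome size in bases.
#' @return `total_bases / genome_size`, rounded half away from zero.
#' @examples
#' coverage_fold(1.0e12, 15.3e9)  # 65
#' @export
coverage_fold <- function(total_bases, genome_size) {
  stopifnot(total_bases > 0, genome_size > 0)
  round_half_away(total_bases / genome_size)
}

#' Data compression ratio
#' @param input_bases bases before compression (e.g. raw short reads).
#' @param output_bases bases after compression (e.g. super-reads).
#' @return `input_bases / output_bases`, rounded half away from zero.
#' @export
compression_ratio <- function(input_bases, output_bases) {
  stopifnot(output_bases > 0)
  round_half_away(input_bases / output_bases)
}

#' Genome completeness percentage
#'
#' Fraction of an (independently estimated) genome size captured by an
#' assembly, as a whole-number percentage.
#'
#' @param assembly_bp assembly span in bases.
#' @param genome_size_estimate independent genome-size estimate in bases.
#' @return Percentage, rounded half away from zero.
#' @export
genome_completeness_pct <- function(assembly_bp, genome_size_estimate) {
  stopifnot(assembly_bp > 0, genome_size_estimate > 0)
  round_half_away(100 * assembly_bp / genome_size_estimate)
}

#' Aligned fraction of a genome, one-decimal percentage
#' @param total_bp total bases of the genome.
#' @param unaligned_bp bases that failed to align.
#' @return `100 * (total_bp - unaligned_bp) / total_bp` rounded to 1 decimal.
#' @export
aligned_fraction_pct <- function(total_bp, unaligned_bp) {
  stopifnot(total_bp > 0, unaligned_bp >= 0, unaligned_bp <= total_bp)
  round_half_away(100 * (total_bp - unaligned_bp) / total_bp, 1L)
}
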