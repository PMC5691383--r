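DNA_BASES <- c("A", "C", "G", "T")

# substitute bases at a fixed per-base rate; ch is a character vector of
# single bases. Substitutions always change the base.
mutate_chars <- function(ch, rate) {
  if (rate <= 0) return(ch)
  idx <- which(stats::runif(length(ch)) < rate)
  if (length(idx)) {
    cur <- match(ch[idx], DNA_BASES)
    ch[idx] <- DNA_BASES[((cur - 1L + sample.int(3L, length(idx),
                                                 replace = TRUE)) %% 4L) + 1L]
  }
  ch
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  paste(mutate_chars(strsplit(seq, "", fixed = TRUE)[[1L]], rate),
        collapse = "")
}

random_chars <- function(n) sample(DNA_BASES, n, replace = TRUE)

#' Simulation configuration
#'
#' Describes a synthetic polyploid, repeat-rich genome: several subgenomes
#' diverged from one common ancestor, with near-identical repeat families
#' stamped into the ancestor before divergence. With three subgenomes the
#' defaults emulate a hexaploid in which one subgenome (D') stays close to
#' the sampled ancestor (1% divergence) while the other two (A', B') are
#' ten times more diverged, and half the genome is repetitive.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param subgenome_sizes subgenome lengths in bases.
#' @param subgenome_divergence per-subgenome substitution rate versus the
#'   common ancestor (same length as `subgenome_sizes`).
#' @param repeat_family_count number of repeat families.
#' @param repeat_unit_bp repeat unit length in bases.
#' @param target_repeat_fraction fraction of the ancestor covered by
#'   repeat copies.
#' @param repeat_copy_divergence per-copy substitution rate, emulating
#'   near-identical transposon copies (default 0.005).
#' @param frag_mean_bp,frag_min_bp default fragmentation controls passed to
#'   [fragment_assembly()].
#' @param error_rate default per-base substitution rate for derived
#'   assemblies and reads.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       subgenome_sizes = c(1e6, 1e6, 1e6),
                       subgenome_divergence = c(0.10, 0.10, 0.01),
                       repeat_family_count = 3L,
                       repeat_unit_bp = 500L,
                       target_repeat_fraction = 0.5,
                       repeat_copy_divergence = 0.005,
                       frag_mean_bp = 5e4, frag_min_bp = 1000L,
                       error_rate = 0) {
  stopifnot(length(subgenome_sizes) == length(subgenome_divergence),
            all(subgenome_sizes > 0),
            all(subgenome_divergence >= 0 & subgenome_divergence <= 1),
            target_repeat_fraction >= 0, target_repeat_fraction <= 1,
            repeat_copy_divergence >= 0, repeat_copy_divergence <= 1,
            error_rate >= 0, error_rate <= 1,
            repeat_family_count >= 1, repeat_unit_bp >= 1)
  nm <- names(subgenome_sizes)
  if (is.null(nm))
    nm <- if (length(subgenome_sizes) == 3L) c("subA", "subB", "subD")
          else paste0("sub", seq_along(subgenome_sizes))
  structure(list(seed = as.integer(seed),
                 subgenome_sizes = stats::setNames(subgenome_sizes, nm),
                 subgenome_divergence = stats::setNames(subgenome_divergence, nm),
                 repeat_family_count = as.integer(repeat_family_count),
                 repeat_unit_bp = as.integer(repeat_unit_bp),
                 target_repeat_fraction = target_repeat_fraction,
                 repeat_copy_divergence = repeat_copy_divergence,
                 frag_mean_bp = frag_mean_bp,
                 frag_min_bp = as.integer(frag_min_bp),
                 error_rate = error_rate),
            class = "sim_config")
}

#' Simulate a polyploid, repeat-rich truth genome
#'
#' Builds a common ancestor sequence, stamps near-identical repeat-family
#' copies into it until the target repeat fraction is reached, then derives
#' each subgenome by substituting bases at its divergence rate. One genome
#' record ("chromosome") is emitted per subgenome. All randomness flows
#' from a single stream seeded once with `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `sim_genome`: `genome` (the truth `assembly`),
#'   and `truth` with `ancestor` (an `assembly`), `labels` (record id ->
#'   subgenome), `repeats` (data frame of planted repeat intervals on the
#'   ancestor) and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- max(config$subgenome_sizes)
  anc <- random_chars(L)
  unit <- config$repeat_unit_bp
  repeats <- data.frame(start = integer(0), end = integer(0),
                        family = integer(0))
  if (config$target_repeat_fraction > 0 && unit <= L) {
    units <- lapply(seq_len(config$repeat_family_count),
                    function(i) random_chars(unit))
    grid <- seq(1L, L - unit + 1L, by = unit)
    n_copies <- min(length(grid),
                    ceiling(config$target_repeat_fraction * L / unit))
    slots <- sort(sample(grid, n_copies))
    fam <- sample.int(config$repeat_family_count, n_copies, replace = TRUE)
    for (i in seq_len(n_copies)) {
      cp <- mutate_chars(units[[fam[i]]], config$repeat_copy_divergence)
      anc[slots[i]:(slots[i] + unit - 1L)] <- cp
    }
    repeats <- data.frame(start = slots - 1L, end = slots + unit - 1L,
                          family = fam)
  }
  nm <- names(config$subgenome_sizes)
  ids <- paste0("chr_", nm)
  seqs <- character(length(nm))
  for (i in seq_along(nm)) {
    sz <- config$subgenome_sizes[[i]]
    seqs[i] <- paste(mutate_chars(anc[seq_len(sz)],
                                  config$subgenome_divergence[[i]]),
                     collapse = "")
  }
  genome <- assembly(ids, seqs, name = "sim_truth")
  ancestor <- assembly("ancestor", paste(anc, collapse = ""),
                       name = "sim_ancestor")
  structure(list(genome = genome,
                 truth = list(ancestor = ancestor,
                              labels = stats::setNames(nm, ids),
                              repeats = repeats,
                              config = config)),
            class = "sim_genome")
}

#' Fragment a genome into a derived assembly
#'
#' Tiles each genome record with fragments whose lengths are drawn around
#' `frag_mean_bp`, separated by gaps around `gap_mean_bp` (negative values
#' produce overlapping fragments), and applies substitution errors at
#' `error_rate`. Every fragment's source coordinates are recorded.
#'
#' @param genome an `assembly` (typically the truth genome of
#'   [simulate_genome()]).
#' @param frag_mean_bp mean fragment length.
#' @param frag_min_bp minimum fragment length; a terminal remnant shorter
#'   than this is absorbed into the previous fragment.
#' @param gap_mean_bp mean inter-fragment gap (0 = seamless tiling;
#'   negative = overlap).
#' @param error_rate per-base substitution rate applied to fragments.
#' @param name assembly name and fragment id prefix.
#' @param seed optional seed; NULL continues the current RNG stream.
#' @param boundaries optional named list (by genome record id) of data
#'   frames with 0-based half-open `start`,`end` columns for fully
#'   deterministic layouts; overrides the random walk.
#' @param labels optional named vector (genome record id -> subgenome
#'   label) propagated into the truth table.
#' @return A list of class `sim_fragments`: `assembly` and `truth_table`
#'   (columns `id`, `src_id`, `src_start`, `src_end`, `strand`, `label`).
#' @export
fragment_assembly <- function(genome, frag_mean_bp = 5e4, frag_min_bp = 1000L,
                              gap_mean_bp = 0, error_rate = 0, name = "frag",
                              seed = NULL, boundaries = NULL, labels = NULL) {
  stopifnot(inherits(genome, "assembly"), frag_min_bp >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- character(0); seqs <- character(0)
  tt <- list()
  for (ri in seq_along(genome$id)) {
    src <- genome$id[ri]
    L <- nchar(genome$seq[ri])
    iv <- if (!is.null(boundaries) && !is.null(boundaries[[src]])) {
      as.data.frame(boundaries[[src]])
    } else {
      starts <- integer(0); ends <- integer(0)
      pos <- 0L
      while (pos < L) {
        len <- max(frag_min_bp,
                   round(stats::rnorm(1L, frag_mean_bp, 0.15 * frag_mean_bp)))
        end <- min(pos + len, L)
        if (L - end < frag_min_bp) end <- L
        starts <- c(starts, pos); ends <- c(ends, end)
        if (end >= L) break
        g <- if (gap_mean_bp == 0) 0
             else round(stats::rnorm(1L, gap_mean_bp, 0.15 * abs(gap_mean_bp)))
        pos <- max(end + g, pos + 1L)
        if (pos >= L) break
      }
      data.frame(start = starts, end = ends)
    }
    for (j in seq_len(nrow(iv))) {
      fid <- sprintf("%s_%s_%04d", name, src, j)
      s <- substr(genome$seq[ri], iv$start[j] + 1L, iv$end[j])
      if (error_rate > 0) s <- mutate_seq(s, error_rate)
      ids <- c(ids, fid); seqs <- c(seqs, s)
      tt[[length(tt) + 1L]] <- data.frame(
        id = fid, src_id = src, src_start = iv$start[j], src_end = iv$end[j],
        strand = "+",
        label = if (is.null(labels)) NA_character_ else unname(labels[src]),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(assembly = assembly(ids, seqs, name = name),
                 truth_table = do.call(rbind, tt)),
            class = "sim_fragments")
}

#' Simulate shotgun reads from a genome
#'
#' Uniformly samples fixed-length reads from both strands at the requested
#' depth, with substitution errors, recording every read's source position.
#'
#' @param genome an `assembly`.
#' @param depth target mean per-base coverage.
#' @param read_len read length in bases.
#' @param error_rate per-base substitution rate.
#' @param seed optional seed; NULL continues the current RNG stream.
#' @return A list of class `sim_reads`: `reads` (named character vector)
#'   and `truth` (data frame `read_id`, `src_id`, `start`, `end`,
#'   `strand`).
#' @export
simulate_reads <- function(genome, depth, read_len, error_rate = 0,
                           seed = NULL) {
  stopifnot(inherits(genome, "assembly"), depth > 0, read_len >= 1)
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(genome$seq)
  ok <- which(lens >= read_len)
  if (length(ok) == 0L) stop("no record is as long as read_len")
  total <- sum(as.numeric(lens[ok]))
  n <- ceiling(depth * total / read_len)
  ri <- ok[sample.int(length(ok), n, replace = TRUE,
                      prob = lens[ok] / total)]
  start <- floor(stats::runif(n) * (lens[ri] - read_len + 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome$seq[ri], start + 1L, start + read_len)
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- cpp_revcomp(seqs[minus])
  if (error_rate > 0)
    seqs <- vapply(seqs, mutate_seq, character(1), rate = error_rate,
                   USE.NAMES = FALSE)
  ids <- sprintf("read_%07d", seq_len(n))
  structure(list(reads = stats::setNames(seqs, ids),
                 truth = data.frame(read_id = ids, src_id = genome$id[ri],
                                    start = start, end = start + read_len,
                                    strand = strand,
                                    stringsAsFactors = FALSE)),
            class = "sim_reads")
}

#' Simulate mate pairs from a genome
#'
#' Samples innie mate pairs with normally distributed insert sizes: the
#' left mate is taken forward from the fragment start, the right mate is
#' the reverse complement of the fragment end.
#'
#' @param genome an `assembly`.
#' @param n_pairs number of pairs.
#' @param insert_mean,insert_sd outer insert size distribution, bases.
#' @param end_length mate length, bases (default 400).
#' @param error_rate per-base substitution rate.
#' @param seed optional seed; NULL continues the current RNG stream.
#' @return A `mate_pairs` data frame with attribute `"truth"` (source
#'   record, fragment start and insert size per pair).
#' @export
simulate_pairs <- function(genome, n_pairs, insert_mean, insert_sd,
                           end_length = 400L, error_rate = 0, seed = NULL) {
  stopifnot(inherits(genome, "assembly"), n_pairs >= 1,
            insert_mean >= 2 * end_length)
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(genome$seq)
  ok <- which(lens >= insert_mean + 4 * insert_sd)
  if (length(ok) == 0L) stop("no record long enough for the insert size")
  total <- sum(as.numeric(lens[ok]))
  ri <- ok[sample.int(length(ok), n_pairs, replace = TRUE,
                      prob = lens[ok] / total)]
  # inserts follow the library spec: normal, truncated at 3 SD so every
  # error-free pair is distance-consistent under the default tolerance
  ins <- round(stats::rnorm(n_pairs, insert_mean, insert_sd))
  ins <- pmin(pmax(ins, insert_mean - 3 * insert_sd),
              insert_mean + 3 * insert_sd)
  ins <- pmin(pmax(ins, 2L * end_length), lens[ri])
  start <- floor(stats::runif(n_pairs) * (lens[ri] - ins + 1))
  left <- substring(genome$seq[ri], start + 1L, start + end_length)
  right <- cpp_revcomp(substring(genome$seq[ri], start + ins - end_length + 1L,
                                 start + ins))
  if (error_rate > 0) {
    left <- vapply(left, mutate_seq, character(1), rate = error_rate,
                   USE.NAMES = FALSE)
    right <- vapply(right, mutate_seq, character(1), rate = error_rate,
                    USE.NAMES = FALSE)
  }
  res <- data.frame(pair_id = sprintf("sim_pair_%06d", seq_len(n_pairs)),
                    left_seq = left, right_seq = right,
                    source_id = genome$id[ri],
                    left_index = NA_integer_, right_index = NA_integer_,
                    stringsAsFactors = FALSE)
  class(res) <- c("mate_pairs", "data.frame")
  attr(res, "truth") <- data.frame(pair_id = res$pair_id,
                                   src_id = genome$id[ri], start = start,
                                   insert = ins, stringsAsFactors = FALSE)
  res
}

#' Write reads as FASTQ
#' @param reads named character vector of read sequences (e.g.
#'   `simulate_reads()$reads`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  n <- length(reads)
  lines <- character(4L * n)
  lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", names(reads))
  lines[seq(2L, 4L * n, by = 4L)] <- unname(reads)
  lines[seq(3L, 4L * n, by = 4L)] <- "+"
  lines[seq(4L, 4L * n, by = 4L)] <- strrep("I", nchar(unname(reads)))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#' @param path input path; format chosen by extension (`.fq`/`.fastq` =>
#'   FASTQ, otherwise FASTA).
#' @return Named character vector of sequences.
#' @export
read_seqs <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}
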