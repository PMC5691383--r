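#' Pipeline configuration
#'
#' Paths and parameters for the full reconciliation pipeline:
#' de-duplication of assembly A, bridge merging of assembly B through A,
#' optional ancestor-guided partitioning, mutual-best-match re-polishing
#' with the de-duplicated A as donor, and k-mer/statistics QC.
#'
#' @param assembly_a path to the A-style assembly FASTA (shorter, complete;
#'   the de-duplication input and gap-fill/polish donor).
#' @param assembly_b path to the B-style assembly FASTA (longer contigs;
#'   the merge backbone).
#' @param ancestor optional path to an ancestor assembly FASTA for
#'   subgenome partitioning.
#' @param reads optional path to reads (FASTA/FASTQ) for missing-k-mer QC.
#' @param out_dir output directory (created if missing).
#' @param genome_size genome-size estimate in bases for NG50 statistics.
#' @param min_overlap_bp minimum bridge overlap (default 5000).
#' @param dedup_identity_pct containment identity floor (default 96).
#' @param partition_identity_pct partition identity floor (default 97).
#' @param end_length synthetic mate end length carried in the manifest
#'   (default 400).
#' @param k k-mer length for QC spectra (default 31).
#' @param seed seed recorded in the manifest.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`. Input existence and
#'   parameter ranges are validated here, before any computation.
#' @export
pipeline_config <- function(assembly_a, assembly_b, ancestor = NULL,
                            reads = NULL, out_dir, genome_size,
                            min_overlap_bp = 5000L, dedup_identity_pct = 96,
                            partition_identity_pct = 97, end_length = 400L,
                            k = 31L, seed = 1L, log_level = "info") {
  for (p in c(assembly_a, assembly_b, ancestor, reads))
    if (!file.exists(p)) stop("input does not exist: ", p)
  if (!(min_overlap_bp > 0)) stop("min_overlap_bp must be positive")
  if (!(dedup_identity_pct > 0 && dedup_identity_pct <= 100))
    stop("dedup_identity_pct out of range")
  if (!(partition_identity_pct > 0 && partition_identity_pct <= 100))
    stop("partition_identity_pct out of range")
  if (!(genome_size > 0)) stop("genome_size must be positive")
  if (!(k >= 11)) stop("k must be >= 11")
  if (!(end_length >= 1)) stop("end_length must be >= 1")
  structure(list(assembly_a = assembly_a, assembly_b = assembly_b,
                 ancestor = ancestor, reads = reads, out_dir = out_dir,
                 genome_size = genome_size,
                 min_overlap_bp = as.integer(min_overlap_bp),
                 dedup_identity_pct = dedup_identity_pct,
                 partition_identity_pct = partition_identity_pct,
                 end_length = as.integer(end_length), k = as.integer(k),
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Run the reconciliation pipeline
#'
#' Executes dedup, merge, optional partition, repolish and QC in order,
#' writing each stage's artifacts and a machine-readable JSON manifest
#' (parameters and per-stage statistics) under `config$out_dir`.
#'
#' @param config a [pipeline_config()] object.
#' @return Invisibly, a list with `status` (0 on success), `manifest` and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!identical(config$log_level, "quiet"))
    message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  set.seed(config$seed)

  asm_a <- read_fasta(config$assembly_a, name = "assembly_A")
  asm_b <- read_fasta(config$assembly_b, name = "assembly_B")
  manifest <- list(parameters = unclass(config), stages = list())

  say("[dedup] self-aligning %d A records", length(asm_a$id))
  dpar <- dedup_params(min_identity_pct = config$dedup_identity_pct)
  a_dedup <- if (length(asm_a$id) >= 2L) deduplicate(asm_a, dpar) else asm_a
  removed <- attr(a_dedup, "removed")
  if (!is.null(removed))
    utils::write.table(removed, out("dedup_removed.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_fasta(a_dedup, out("a_dedup.fasta"))
  manifest$stages$dedup <- list(input_records = length(asm_a$id),
                                removed = length(asm_a$id) - length(a_dedup$id))

  say("[merge] aligning B on de-duplicated A")
  mpar <- merge_params(min_overlap_bp = config$min_overlap_bp,
                       min_bridge_identity_pct = config$dedup_identity_pct)
  aln_ba <- align_sets(asm_b, a_dedup, mpar$align)
  bridges <- plan_bridges(aln_ba, asm_b, mpar)
  write_bridges_tsv(bridges, out("bridges.tsv"))
  merged <- execute_merge(asm_b, a_dedup, bridges)
  merged <- add_unique_scaffolds(merged, a_dedup, dpar)
  write_fasta(merged, out("merged.fasta"))
  manifest$stages$merge <- list(bridges = nrow(bridges),
                                merged_records = length(merged$id),
                                added_scaffolds = length(attr(merged, "added")))

  if (!is.null(config$ancestor)) {
    say("[partition] assigning by ancestor")
    anc <- read_fasta(config$ancestor, name = "ancestor")
    ppar <- partition_params(min_identity_pct = config$partition_identity_pct)
    part <- assign_by_ancestor(merged, anc, ppar)
    write_fasta(part$assigned, out("dgenome.fasta"))
    if (length(part$remainder$id))
      write_fasta(part$remainder, out("rest.fasta"))
    utils::write.table(part$stats, out("partition_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$partition <- list(assigned = length(part$assigned$id),
                                      remainder = length(part$remainder$id))
  }

  say("[repolish] installing donor consensus")
  pol <- repolish(merged, a_dedup)
  write_fasta(pol$assembly, out("polished.fasta"))
  write_polish_tsv(pol, out("polish.tsv"))
  manifest$stages$repolish <- pol$report

  say("[qc] statistics%s", if (is.null(config$reads)) "" else " and k-mer QC")
  stats_list <- list(summary_stats(asm_a, config$genome_size),
                     summary_stats(a_dedup, config$genome_size),
                     summary_stats(asm_b, config$genome_size),
                     summary_stats(merged, config$genome_size),
                     summary_stats(pol$assembly, config$genome_size))
  stats_list[[2]]$name <- "assembly_A_dedup"
  stats_list[[4]]$name <- "merged"
  stats_list[[5]]$name <- "polished"
  write_stats_tsv(stats_list, out("stats.tsv"))
  manifest$stages$qc <- lapply(stats_list, unclass)
  if (!is.null(config$reads)) {
    spec <- kmer_spectrum(read_seqs(config$reads), k = config$k,
                          source = "reads")
    hist <- missing_kmer_histogram(spec, pol$assembly, k = config$k)
    write_histogram_tsv(hist, out("missing_kmers.tsv"))
    manifest$stages$qc$total_missing_kmers <- hist$total_missing
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest,
                 out_dir = config$out_dir))
}

# --- thin command-line front end -------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      a <- sub("^--", "", a)
      if (grepl("=", a, fixed = TRUE)) {
        kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
        flags[[kv[1L]]] <- paste(kv[-1L], collapse = "=")
      } else if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        flags[[a]] <- args[i + 1L]; i <- i + 1L
      } else flags[[a]] <- TRUE
    } else pos <- c(pos, a)
    i <- i + 1L
  }
  list(flags = flags, pos = pos)
}

flag_num <- function(flags, name, default) {
  if (is.null(flags[[name]])) default else as.numeric(flags[[name]])
}

#' Command-line entry point
#'
#' Dispatches the `asmblend` subcommands (`stats`, `align`, `dedup`,
#' `merge`, `partition`, `kmer-uniq`, `kmer-missing`, `repolish`, `mates`,
#' `pair-check`, `simulate`, `pipeline`). A thin Rscript wrapper around
#' this function is installed at `inst/cli/asmblend.R`.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status (0 = success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: asmblend <stats|align|dedup|merge|partition|kmer-uniq|",
        "kmer-missing|repolish|mates|pair-check|simulate|pipeline> ...\n",
        sep = "")
    return(invisible(1L))
  }
  cmd <- args[1L]
  p <- parse_cli_flags(args[-1L])
  fl <- p$flags; pos <- p$pos
  seed <- as.integer(flag_num(fl, "seed", 1))
  status <- 0L
  switch(cmd,
    "stats" = {
      a <- read_fasta(pos[1L])
      st <- summary_stats(a, flag_num(fl, "genome-size", assembly_total_bp(a)))
      print(st)
      if (!is.null(fl$o)) write_stats_tsv(st, fl$o)
    },
    "align" = {
      aln <- align_sets(read_fasta(pos[2L]), read_fasta(pos[1L]))
      write_alignments_tsv(aln, if (is.null(fl$o)) "aln.tsv" else fl$o)
    },
    "dedup" = {
      a <- read_fasta(pos[1L])
      dd <- deduplicate(a, dedup_params(
        min_identity_pct = flag_num(fl, "min-identity", 96)))
      write_fasta(dd, if (is.null(fl$o)) "dedup.fasta" else fl$o)
      if (!is.null(fl$report))
        utils::write.table(attr(dd, "removed"), fl$report, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    },
    "merge" = {
      b <- read_fasta(pos[1L]); a <- read_fasta(pos[2L])
      mpar <- merge_params(min_overlap_bp = flag_num(fl, "min-overlap", 5000))
      br <- plan_bridges(align_sets(b, a, mpar$align), b, mpar)
      if (!is.null(fl$bridges)) write_bridges_tsv(br, fl$bridges)
      m <- add_unique_scaffolds(execute_merge(b, a, br), a)
      write_fasta(m, if (is.null(fl$o)) "merged.fasta" else fl$o)
    },
    "partition" = {
      part <- assign_by_ancestor(read_fasta(pos[1L]), read_fasta(pos[2L]),
        partition_params(min_identity_pct = flag_num(fl, "min-identity", 97)))
      write_fasta(part$assigned, if (is.null(fl$o)) "assigned.fasta" else fl$o)
      if (!is.null(fl$rest) && length(part$remainder$id))
        write_fasta(part$remainder, fl$rest)
      if (!is.null(fl$stats))
        utils::write.table(part$stats, fl$stats, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    },
    "kmer-uniq" = {
      ks <- if (is.null(fl$ks)) c(16, 32, 64)
            else as.integer(strsplit(fl$ks, ",")[[1L]])
      uc <- uniqueness_curve(read_fasta(pos[1L]), ks)
      utils::write.table(uc, if (is.null(fl$o)) "uniqueness.tsv" else fl$o,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    "kmer-missing" = {
      k <- as.integer(flag_num(fl, "k", 31))
      spec <- kmer_spectrum(read_seqs(pos[1L]), k = k, source = "reads")
      hist <- missing_kmer_histogram(spec, read_fasta(pos[2L]), k = k)
      write_histogram_tsv(hist, if (is.null(fl$o)) "missing.tsv" else fl$o)
    },
    "repolish" = {
      pol <- repolish(read_fasta(pos[1L]), read_fasta(pos[2L]))
      write_fasta(pol$assembly, if (is.null(fl$o)) "polished.fasta" else fl$o)
      if (!is.null(fl$report)) write_polish_tsv(pol, fl$report)
    },
    "mates" = {
      mr <- utils::read.table(pos[1L], sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      groups <- split(mr$sequence[order(mr$read_id, mr$index)],
                      mr$read_id[order(mr$read_id, mr$index)])
      pairs <- extract_synthetic_mates(groups,
                                       flag_num(fl, "end-length", 400))
      write_pairs_fastq(pairs, if (is.null(fl$o)) "pairs.fastq" else fl$o)
    },
    "pair-check" = {
      pc <- classify_pairs(read_pairs_fastq(pos[1L]), read_fasta(pos[2L]),
                           insert_mean = flag_num(fl, "insert-mean", 1e5),
                           insert_sd = if (is.null(fl[["insert-sd"]])) NULL
                                       else as.numeric(fl[["insert-sd"]]))
      print(pc)
      if (!is.null(fl$o))
        utils::write.table(pc$placements, fl$o, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    },
    "simulate" = {
      outdir <- if (is.null(fl$o)) "simdir" else fl$o
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      sg <- if (is.null(fl$subgenomes)) c(1e5, 1e5, 1e5)
            else {
              parts <- strsplit(fl$subgenomes, "x", fixed = TRUE)[[1L]]
              rep(as.numeric(parts[2L]), as.integer(parts[1L]))
            }
      sim <- simulate_genome(sim_config(
        seed = seed, subgenome_sizes = sg,
        target_repeat_fraction = flag_num(fl, "repeat-fraction", 0.5)))
      write_fasta(sim$genome, file.path(outdir, "truth.fasta"))
      write_fasta(sim$truth$ancestor, file.path(outdir, "ancestor.fasta"))
      utils::write.table(
        data.frame(id = names(sim$truth$labels),
                   label = unname(sim$truth$labels)),
        file.path(outdir, "truth_labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    },
    "pipeline" = {
      cfg <- pipeline_config(
        assembly_a = fl$a, assembly_b = fl$b, ancestor = fl$ancestor,
        reads = fl$reads, out_dir = if (is.null(fl$o)) "pipeline_out" else fl$o,
        genome_size = flag_num(fl, "genome-size", 15.34e9),
        min_overlap_bp = flag_num(fl, "min-overlap", 5000), seed = seed)
      status <- run_pipeline(cfg)$status
    },
    {
      message("unknown subcommand: ", cmd)
      status <- 1L
    })
  invisible(status)
}
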