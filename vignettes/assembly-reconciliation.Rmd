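---
title: "Reconciling polyploid genome assemblies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling polyploid genome assemblies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Very large polyploid plant genomes are hard to assemble because most of the
sequence is not locally unique: several homeologous subgenomes descend from
closely related diploid ancestors, and long transposon-derived repeats occur
in thousands of near-identical copies. In practice such genomes get
assembled more than once with complementary technologies — call them
assembly **A** (complete coverage, shorter contigs, strong short-read-based
consensus) and assembly **B** (longer contigs from long reads, smaller total
span, weaker consensus). `asmblend` implements the reconciliation
computations that combine the two, plus the k-mer and read-pair diagnostics
used to audit the result. Everything is sized for desk-scale work: whole
workflows run on megabase fixtures in seconds to minutes on one CPU.

# The anchor-chaining aligner

Every stage consumes pairwise local alignments, produced by a compact
aligner in the style of whole-genome alignment tools (cluster exact matches,
then extend):

1. **Anchors.** Exact matches of `anchor_k`-mers (default 21 bp; the
   index packs k-mers into 64-bit words, so `anchor_k` must be 11–32).
   Reference k-mers occurring more than `max_kmer_occ` times (default 100)
   are masked — the same device aligners use to keep repeats from
   generating quadratic work. Both query strands are searched.
2. **Diagonal clustering.** Anchors with a common diagonal
   (`ref_pos − query_pos`) are chained while consecutive anchor starts are
   within `max_gap_bp` (default 1000 bp).
3. **Stitching.** Adjacent chains on nearby diagonals (drift ≤ `band_bp`,
   default 30 bp) separated by at most `stitch_max_gap_bp` (default 5 kb)
   are merged **only if** the skipped gap itself aligns at
   ≥ `min_identity_pct`. This lets one alignment span a masked repeat copy
   (whose anchors were deliberately discarded) without ever bridging a true
   structural break: a wrong stitch fails the gap-identity check.
4. **End extension.** Chain ends are extended by greedy *exact* matching.
   On error-free fixtures this carries alignments to the precise ends of
   the overlap, which the merge stage relies on for clean junctions.
5. **Recount.** Identity is recomputed over the full chained region — an
   exact mismatch count when the two spans are equal length (the common
   case under a substitution-only error model), or a banded global
   dynamic-programming alignment of the spanned substrings when stitching
   crossed an indel. Anchor statistics are never reported as identity.

Reported alignments satisfy `min_cluster_bp` (default 200 bp) and
`min_identity_pct` (default 90). Coordinates are 0-based half-open on the
forward strands internally; the TSV dialect (`write_alignments_tsv`) is
1-based inclusive with reversed query coordinates on the minus strand, the
convention of `show-coords`-style outputs. Degenerate inputs are defined:
`anchor_k` longer than every query record yields an empty result with a
warning; `N` bases never match anything.

Two derived reductions are used downstream: `best_match_per_query`
(reference maximising summed aligned query bases; ties go to the
lexicographically smallest id, so results are deterministic) and
`mutual_best` (pairs that are each other's best match).

# De-duplication

A record is *contained* when the union of its alignments onto one other
record covers ≥ `min_containment_cov` of its length at a length-weighted
identity ≥ `min_identity_pct` (defaults 0.99 and 96). Complete containment
is operationalised as 99% coverage rather than 100% because a single
mismatched terminal base would otherwise defeat the criterion, and no
tolerance is stated by the procedure this implements. Only records no
longer than their container can be contained; equal-length near-identical
pairs remove the lexicographically larger id (determinism). Containment is
assessed against a single container at a time — the conservative reading of
"contained in another scaffold" — rather than a union over several
containers. `deduplicate` computes all calls against the original assembly
in one pass and removes them; chains (A contains B contains C) resolve to
the maximal container because at ≥ 96% identity the maximal container
absorbs the whole chain directly. De-duplication is idempotent and never
increases total length; both properties are tested.

# Bridge merging

The merge joins pairs of B contigs through a single A contig that both
overlap (the gap-filling pattern):

* Alignments of B onto A are first reduced to per-query-region best
  matches (greedy by match count, discarding alignments that overlap a
  kept alignment on more than half their query interval). This is the
  `delta-filter -q` notion of "pairwise best match": a long B contig may
  legitimately keep several A contigs along its length, while homeologous
  secondary matches — which lose the per-region contest to the true locus —
  are removed. Contig-level best match (one A per B) would make bridging
  nearly impossible on realistically tiled inputs.
* A bridge requires, for each of the two B contigs, a qualifying alignment
  of ≥ `min_overlap_bp` (default 5000) at ≥ `min_bridge_identity_pct`
  (default 96) that is *terminal*: it must reach within `end_tol_bp`
  (default 100 bp) of the B-contig end facing the gap. The 100 bp overhang
  allowance absorbs unaligned contig tips caused by terminal errors.
* Minus-strand B contigs are reverse-complemented before joining; each
  contig uses exactly one orientation, and members whose two bridges
  disagree on orientation are dropped with a warning.
* Three or more B contigs contesting one interval: the two with the larger
  overlaps win; displaced contigs are recorded in the `conflicts`
  attribute.
* The output contig is B-left up to its alignment end, then the
  inter-alignment A interval, then B-right from its alignment start,
  recursively along chains. When the two alignments abut or overlap on A
  (a negative gap), the join is spliced at the midpoint of the shared A
  interval with the left contig supplying the sequence left of the splice —
  B sequence is preferred wherever both exist, since B contigs are the
  longer backbone.
* Finally, `add_unique_scaffolds` appends the A records not contained
  (de-duplication criterion) in any merged contig.

Junction positions are recorded per merged contig, so junction fidelity is
directly testable: on error-free fixtures every window across a junction is
an exact substring of the truth genome.

# Subgenome partitioning

A contig is assigned to the ancestor-derived subgenome when its best-match
alignments to the ancestor assembly reach ≥ `min_identity_pct` (default 97)
length-weighted identity **and** cover ≥ `min_assigned_cov` (default 0.5)
of the contig. The coverage floor is deliberate: with half the genome in
near-identical repeats, a short high-identity repeat hit would otherwise
assign contigs from the wrong subgenome; requiring half the contig to
participate makes identity informative again. Setting
`min_assigned_cov = 0` reproduces the looser identity-only criterion.
Assignment uses the assembly→ancestor direction by default; the direction
is genuinely ambiguous in the procedure this follows, so the other
direction is exposed via the `direction` argument.
`reverse_coverage_stats` reports, in the opposite direction, the fraction
of the ancestor covered by the assigned set (union of alignment intervals,
one decimal place) and the multiplicity structure of the best-match
bipartite graph (connected components classified one-to-one, many-to-one —
several assembly contigs on one ancestor record — one-to-many, or
many-to-many).

# Re-polishing

`repolish` pairs primary and donor records by mutual best match and
replaces every aligned span of the primary (minimum `min_span_bp`, default
200 bp, to avoid churn from micro-alignments) with the corresponding donor
span, reverse-complemented for minus-strand alignments. Replacement is at
aligned-span granularity, not whole contigs, because indels shift
coordinates; unaligned primary spans are kept verbatim. Record count and
ids are invariant; total length may drift by at most the indel columns of
the used alignments. Overlapping spans are resolved left-to-right with
later spans trimmed and counted in the report.

# K-mer diagnostics

All k-mer machinery counts **canonical** k-mers (lexicographic minimum of a
k-mer and its reverse complement), the strand-agnostic convention of
standard counters; k-mers containing `N` are excluded from spectra and from
coverage denominators. Counting is exact (hash table) — desk-scale fixtures
fit comfortably in memory, and probabilistic sketches would complicate the
oracle tests for no benefit.

* `uniqueness_curve`: for each k, the percentage of non-N genome positions
  covered by at least one window whose canonical k-mer occurs exactly once
  genome-wide. This implements the fixed-k-window reading of "covered by
  unique sequences of length k"; the alternative reading via maximal
  unique substrings would count a position covered if any unique substring
  of length ≥ k contains it, which for the fixed grid of k values differs
  only at window boundaries. The default grid is
  {16, 24, 32, 48, 64, 96, 128}. The curve is non-decreasing in k and
  strand-symmetric (both tested properties).
* `missing_kmer_histogram`: distinct read k-mers (default k = 31) absent
  from an assembly, binned by read multiplicity. A perfect assembly of the
  read source has all bins zero; one isolated substitution in locally
  unique sequence removes exactly k read k-mers. Passing a list of
  assemblies unions their k-mer sets, which can only shrink the missing
  set (tested bin-wise).
* `excess_duplicate_kmers`: k-mers in the single-copy band of the read
  spectrum (the spectrum mode over multiplicities ≥ 2, ± a half-width
  defaulting to a quarter of the mode) that occur ≥ 2 times in the
  assembly — the signature of over-corrected consensus, where
  near-identical repeat copies were homogenised onto one allele. The mode
  is taken over multiplicities ≥ 2 so the sequencing-error peak at
  multiplicity 1 cannot capture it.

# Pair-based validation

`extract_synthetic_mates` converts each group of consecutive mega-reads
from one long read into n−1 innie pairs: `end_length` bases (default 400)
from the gap-facing end of the earlier mega-read, and the reverse
complement of the leading bases of the later one. Ends shorter than
`end_length` are emitted whole rather than dropped.

`classify_pairs` places each end at its best alignment (ties between
distinct placements are ambiguous and classify the pair `unaligned`,
excluded from the consistency denominator) and classifies same-contig pairs
by orientation first (opposite strands, facing inward), then distance
(|observed − `insert_mean`| ≤ tolerance). The tolerance defaults to
3 standard deviations when an SD is supplied, else a quarter of the mean —
the source procedure states only "consistent with the mean size", so the
band is declared here, not inferred. A split pair becomes a
`candidate_misassembly` when either end sits farther than
`insert_mean + tolerance` from its contig end on the mate-facing side: the
mate *should* have fit on the same contig. The distance in that rule is
likewise declared — the procedure this mirrors gives none.

# The simulator

`simulate_genome` emulates the structure that makes these genomes hard:
one common ancestor sequence, repeat families stamped into it as
near-identical copies (per-copy divergence 0.5% by default) up to a target
repeat fraction, then per-subgenome divergence from the ancestor. The
defaults are a hexaploid reading: three 1 Mb subgenomes at 50% repeat
content, one subgenome (D′) at 1% divergence from the sampled ancestor and
the other two at 10% — the close-ancestor contrast that makes
ancestor-guided partitioning work. `fragment_assembly` derives A-style
(short, seamless tiling) or B-style (long, gappy or overlapping) assemblies
with recorded source coordinates; `simulate_reads` samples uniform
fixed-length reads from both strands; `simulate_pairs` draws innie pairs
with normally distributed inserts truncated at 3 SD, so that error-free
pairs are distance-consistent under the classifier's default tolerance by
construction (the truncation encodes the library specification rather than
loosening the classifier). A single RNG stream is seeded once per
generator call; identical seeds give byte-identical FASTA output.

What the simulator does **not** emulate: indel errors by default (the
substitution-only model keeps alignment oracles exact; an indel mode exists
in the aligner but not the generator), realistic transposon evolution
(nested insertions, truncated copies, families of unequal length),
GC-biased or position-biased read sampling, long-read error profiles, and
chimeric reads. Tests passing on these fixtures therefore demonstrate the
algorithms' correctness on cleanly structured polyploid repeat landscapes,
not robustness to every artefact of real sequencing data.

# Numerical choices and problem sizes

* Printed integer statistics round half away from zero
  (`round_half_away`); base R's banker's rounding disagrees with published
  table conventions at .5 boundaries. Aligned fractions are reported to
  one decimal, consistency percentages as whole numbers.
* NG50 uses the inclusive boundary (cumulative sum ≥ half the genome
  size) and returns the record length at the crossing; an assembly that
  never reaches the midpoint has NG50 0, and an empty length list warns.
* N bases count toward record lengths and totals; gap-free final
  assemblies are a property of the data, not of the metric.
* Tie-breaks are lexicographic everywhere a maximiser could tie, so every
  stage is deterministic.
* Test and acceptance problem sizes, chosen so the full suite runs in a
  couple of minutes on one CPU: unit fixtures 2–60 kb; the end-to-end
  reconciliation fixture 3 × 1 Mb at 50% repeats (dedup + merge in well
  under a minute); partition recovery on ~300 contigs of ~1 kb from a
  3 × 100 kb hexaploid; oracle-equivalence checks on 1000 random NG50
  instances, ≤ 5 kb uniqueness sequences and ≤ 2 kb dynamic-programming
  alignments.

# Known limitations

* The aligner has no affine-gap scoring and no binary delta output; it is
  built for near-identical sequence (≳ 85% identity), which is exactly the
  reconciliation regime, and its identity on heavily indel-ed pairs relies
  on the stitch-time dynamic-programming recount.
* Containment uses one container per call; a record tiled by several
  different containers (without any single one covering 99%) survives
  de-duplication.
* `deduplicate` trusts single-pass transitive resolution; pathological
  chains mixing identities just at the 96% floor could in principle leave
  a removed record whose own container was also removed. Idempotence is
  tested; such a case has not been constructed.
* Partition offers no disambiguation between the two far subgenomes (no
  second ancestor), and no chromosome-level assignment.
* The pipeline runner is sequential and file-based by design; there is no
  workflow-engine integration or cluster scheduling.
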