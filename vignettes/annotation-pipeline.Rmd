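---
title: "Methods: the protannot annotation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the protannot annotation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

De novo assembled transcriptomes arrive as large, heavily redundant sets of
transcripts with no functional labels. The standard way to make them usable
is annotation transfer: translate the transcripts, find homologous proteins
and domain families in well-curated reference databases, and copy the
references' descriptions, GO terms, orthogroups and domain names onto the
queries. protannot implements this as a self-contained pipeline:

1. **Input** — protein FASTA (recommended), nucleotide FASTA or FASTQ reads
   (both routed through six-frame ORF extraction, or an external assembler
   for reads).
2. **Redundancy clustering** (optional) — linear-time greedy clustering
   picks representative sequences so each transcript family is searched
   once.
3. **Search** — every representative is searched against one protein
   *sequence database* and any number of *profile databases* (PSSMs built
   from family alignments). Hits with E-value at or above the threshold
   (default `1e-5`) are discarded.
4. **Retention and transfer** — per query, a sequence database keeps only
   the best hit; a profile database keeps a non-overlapping tiling of hits
   so distinct query regions each receive a domain. Target metadata is
   joined and, if clustering ran, representative records are copied to
   cluster members.
5. **Output** — one merged 13-column TSV, a summary JSON with the
   annotation rate, plus sidecars (cluster table, per-database BLAST-tabular
   dumps, unannotated id list).

A query counts as *annotated* when it has at least one retained record with
at least 50% sequence identity in any database; the summary's
`annotation_rate` is the fraction of queries annotated under that rule. The
rule is applied uniformly: for profile hits "identity" is identity to the
profile consensus (whether the 50% rule should use consensus identity is a
genuinely open design point; uniformity was chosen because it makes the
summary a single, explainable statistic).

# Redundancy clustering

Transcript isoforms make all-vs-all clustering wasteful. The clusterer is
linclust-like: each sequence contributes its `kmers_per_seq` (default 20)
k-mers (default k = 10) with the smallest seeded hash values; sequences are
processed from longest to shortest (ties by id), and each sequence is
aligned only against the representatives that own one of its selected
k-mers. A sequence joins the first representative it *verifies* against —
local alignment identity ≥ `min_seq_id` (matching columns / alignment
columns, gaps included; default 0.9) and coverage ≥ `min_cov` of **both**
sequences (default 0.8) — otherwise it founds its own cluster and claims
its unowned k-mers. The number of verification alignments is bounded by
`n × kmers_per_seq`, and the object carries the counter so the linearity is
testable. Representatives are therefore always a longest member (ties to
the lexicographically smallest id), every membership is verified rather
than assumed, and clustering can be bypassed entirely (`run_clust = FALSE`
/ `--no-run-clust`).

The identity definition and the coverage mode are stated here because the
underlying method descriptions commonly leave both implicit; bidirectional
coverage was chosen so a short fragment can never absorb a full-length
transcript.

# The search engine

## Prefilter

Sequence databases are indexed by exact k-mers (default k = 5). A target
becomes an alignment candidate when it shares at least `min_diag_kmers`
(default 2) k-mers with the query whose diagonals (`target_pos −
query_pos`) fall within a band of half-width 4. Exact k-mer matching (no
reduced alphabet, no similar-k-mer generation) costs sensitivity for remote
homologs; at the identity levels the pipeline targets (≥ 50%) the planted
recovery tests quantify the loss as negligible. Profile databases are
searched without a prefilter — realistic profile collections here are
small, and every (query, profile) pair is scored.

## Alignment

One C++ kernel computes optimal local affine-gap alignments
(Smith–Waterman/Gotoh). A gap of length k costs `gap_open + k ×
gap_extend` (defaults 11/1); substitution scores are BLOSUM62 for
sequence targets, per-column PSSM scores for profiles. The kernel is
checked against two independent oracles in the test suite: a plain-R
wavefront DP (exact integer equality on hundreds of random pairs) and
`Biostrings::pairwiseAlignment`.

Tie handling is fixed so output is deterministic: the best end cell is the
one with maximal score, then smallest query end, then smallest target end,
and traceback prefers diagonal over gap-in-query over gap-in-target.

Repeated domains are found by masked re-alignment: after a profile hit the
aligned query span is overwritten with a hard mask (score −1000 at every
column, so it can never re-align), the query is re-scored, and the loop
stops when the E-value fails the threshold or after `max_domain_hits`
(default 10) rounds. `X` residues score 0 against every profile column and
the BLOSUM62 `X` row against sequences.

## E-values

Sequence hits use Karlin–Altschul statistics with the published gapped
BLOSUM62-11/1 parameters (λ = 0.267, K = 0.041):

    bit = (λ·S − ln K) / ln 2,   E = m · n · 2^(−bit)

with m the query length and n the summed length of that database's targets
— each database is filtered independently, mirroring independent searches
of the three reference databases.

Profile hits need per-profile statistics, so every profile is calibrated at
build time: `n_shuffles` (default 200) random sequences of `shuffle_len`
(default 150) drawn i.i.d. from the background composition are aligned to
the profile, and a Gumbel distribution is fitted to the null scores by the
method of moments (λ = π/(σ√6), μ = mean − γ/λ, with γ the
Euler–Mascheroni constant), giving

    E = K · L_profile · m · exp(−λ·S),  K = exp(λ·μ) / (L_profile · shuffle_len).

Calibration is deterministic given its seed; per-profile seeds are derived
from the database seed and the profile id so a database rebuilds
identically regardless of file order. A moment fit estimates the Gumbel
body, not the extreme tail, so profile E-values near the threshold are
approximate — the decoy tests bound the practical consequence (signal-free
queries essentially never annotate at `1e-5`).

# Profiles

A profile is a PSSM, not a full profile HMM: the hit contract the pipeline
needs (interval, score, E-value, consensus identity) is served at far lower
complexity, and position-specific insert/delete states would be
uncalibratable from the desk-scale alignments the package targets. Match
columns are alignment columns with ≤ 50% gaps. Column frequencies are mixed
with a BLOSUM62-conditional pseudocount,

    f' = (n·f + α·g) / (n + α),   g[a] = Σ_b f[b]·P(a|b),

(α default 1) and scored as half-bit log-odds `2·log2(f'/p)` against the
BLOSUM62 marginal background. The consensus residue of a column is the
residue with the maximal score, which makes "consensus identity" a
well-defined quantity for profile hits.

# Retention policies

*Best hit* (sequence databases): minimal E-value, ties by maximal bit
score, then lexicographically smallest target id — at most one record per
(query, database).

*Non-overlapping tiling* (profile databases): hits are considered by
(E-value ascending, bit score descending, query start, target id) and
accepted when they overlap every accepted hit by at most `max_overlap`
residues (default 0, i.e. strictly non-overlapping on the query). Greedy
selection was chosen over exact weighted-interval scheduling because it is
deterministic, linear, and its two testable guarantees — maximality (no
rejected hit could still be added) and covering at least the single most
significant hit — are what the "full query coverage" motivation actually
needs.

*Propagation*: representative records are copied to cluster members
(`inherited` column names the representative), so enabling clustering does
not change *which* input ids end up annotated, only how much work the
search does. This is controlled by `propagate` (default on) because
member-level completeness is what downstream per-transcript analyses need;
representative-only output remains available.

# Synthetic data

The fixture generators produce the study conditions every test runs under:
random background proteins (BLOSUM62 marginal composition, shared with the
null model), reference databases with synthetic metadata, and query sets
with planted truth. Point mutations are drawn from BLOSUM62-conditional
substitution probabilities excluding the original residue, so a "70%
identity" copy differs at exactly round(0.3·L) positions and stays
detectable the way real homologs are. The default desk-scale fixture is 50
sequence targets (150–400 aa), 8 profiles (MSAs of 10 rows, 60–120
columns, 90% within-MSA identity), 40 queries (70% homolog identity, one
planted domain at 80% identity, 10% decoys) — small enough that the whole
suite runs in about a minute yet large enough that prefilter recall,
calibration and the retention policies are all exercised.

Each generator derives an independent RNG substream from the user seed, so
a database and a query set built with the same seed share no hidden
correlation. What the generator does **not** emulate: sequencing error
profiles, read coverage, splice-isoform structure, indel mutations, biased
composition (low-complexity regions), and real database scale. Passing
tests therefore demonstrate the pipeline's logic and statistics, not
sensitivity at Swiss-Prot/Pfam scale or robustness to assembly artifacts.

# Numerical and interface choices

* Internal coordinates are 0-based half-open; everything written for users
  (annotation TSV, M8 dumps) is 1-based inclusive.
* E-values are written as `%.3g`; the annotation TSV is byte-stable under
  write → read → write.
* Degenerate inputs: empty query sets and empty hit lists flow through as
  empty tables; an all-gap profile column set, ragged MSAs, single-row
  MSAs, malformed GO ids, duplicate ids and alphabet violations are errors
  that name the offending record.
* The command layer returns 0 (success), 2 (user/configuration error,
  e.g. reads under 100 nt on the assembly path, two files for single-end
  input, a database directory with no manifest) or 1 (internal error,
  e.g. a failing external assembler).
* Configuration is CLI flags over built-in defaults; the effective
  configuration is dumped to `outdir/config.json` for provenance. A config
  file layer and a `--threads` flag were considered and dropped: the
  pipeline is deterministic and single-threaded at the scales it targets,
  and thread-count-independent output ordering is exactly what the
  determinism contract requires anyway.
* External assembly is an injected command template (`{in1}`, `{in2}`,
  `{out}`), never reimplemented; without one, reads fall back to direct
  translated search via ORF extraction (maximal stop-free stretches ≥ 30
  aa across all six frames — stop-to-stop, not ATG-initiated, since
  translated search scores any frame segment). The standard genetic code
  is assumed, with initiator-codon rewriting disabled.

# Known limitations

* Profile E-values extrapolate a moment-fitted Gumbel into its tail.
* Exact k-mer prefiltering loses remote (< ~50% identity) sequence homologs
  by design; profile search has no prefilter and scales linearly in the
  number of profiles.
* GO terms are transferred verbatim; there is no propagation up the
  ontology graph and no orthology-aware weighting.
* The 50%-identity annotation rule uses consensus identity for profiles,
  which is stricter than domain-presence definitions used elsewhere.
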