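---
title: "Screening transcriptome assemblies for cross-contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening transcriptome assemblies for cross-contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contamscreen)
```

## The problem

Multi-species transcriptome projects assemble hundreds of libraries, one
per sample, and the samples travel through shared wet-lab and sequencing
infrastructure. RNA carried over between adjacent samples, index
mis-assignment in multiplexed lanes, and commensal organisms living on
the sampled tissue all deposit sequences from one organism into another
organism's library. For whole-transcriptome analyses a handful of
foreign transcripts is noise; for single-gene-family work a contaminant
can silently become "the gene from species X". `contamscreen` detects
such cross-contamination after assembly, assigns each contaminant a
donor library, and validates every sample's organismal identity through
its 18S rRNA.

## The pairwise identity model

Let two libraries $A$ and $B$ be compared all-vs-all at the nucleotide
level, and reduce the hits to the best match per query sequence. If the
libraries are clean, the percent-identity distribution of these matches
is unimodal: its mode sits at the pairwise identity reflecting the
evolutionary distance between the two species, with binomial spread
around it. If sequences leaked from one library into the other, the
leaked copies match their originals at (or very near) 100% identity, so
a second mode appears at the top of the distribution.

The pipeline turns this into a per-pair decision rule:

1. **Histogram** the match identities in bins of width $w$ (default 1
   percentage point, i.e. one bin per percent identity value).
2. **Peak check.** If fewer than `min_peak_support` matches (default 5)
   fall in bins at $\ge 99\%$, there is no contamination peak and the
   pair yields no cutoff (`no_peak`). A contaminated pair should contain
   *many* near-100% matches; the support floor suppresses peaks made of
   one or two spurious hits.
3. **First-minimum scan.** Scanning bins downward from 100%, the cutoff
   $t$ is the lower edge of the first bin whose count is no larger than
   the bin above it and strictly smaller than the bin below it — the
   first local minimum separating the contamination peak from the
   ortholog background. If the counts never rise again before the floor
   of the histogram the distribution is a single near-100% mass
   (typically an unexcluded conspecific pair) and the pair is flagged
   `degenerate` with a warning instead of being given a cutoff.
4. **Candidate calling.** Every match with identity $\ge t$ flags *both*
   member sequences: the foreign copy may sit in either library, so each
   match emits one candidate per library, each naming its partner.
   The comparison is inclusive at the cutoff, which errs toward
   flagging; users who want the strict version can raise the cutoff by
   one bin.

The scan is equated with "the first inflection point" of the count
curve. On unsmoothed integer counts the first local minimum is the
operational reading; a true second-derivative inflection criterion would
differ on smoothed data, which is one reason smoothing is off by
default. An optional centred moving average (`smooth_window`, odd, in
bins) is available for small noisy pairs; window ends fall back to the
raw counts.

### Assumptions

* The two species are diverged enough that the background mode sits
  well below 100%. This is enforced upstream by pair exclusion (below)
  rather than assumed.
* Matches are counted per *sequence* (best hit per query, pooled over
  both search directions), not per alignment, so highly fragmented
  assemblies weigh by fragment count.
* Identity is whatever the upstream aligner reports; the pipeline never
  realigns.

## Taxonomically close pairs

Very close relatives legitimately share near-identical sequences and
would be flagged wholesale. Two screens prevent this:

* **Pair exclusion** (before any comparison). A pair is excluded when
  both samples carry the same family label (case- and
  whitespace-insensitive string equality; the sample table is the
  taxonomic authority, no synonym resolution) or when the two leaves are
  separated by at most `max_branches` edges in the consensus phylogeny.
  "Branches" are edges on the unique leaf-to-leaf path, so sister
  leaves are 2 apart and are excluded at the default `max_branches = 2`
  — the only reading under which the default threshold excludes the
  closest relatives. When a library is missing from the tree, the
  family rule alone decides and a warning is emitted, since a consensus
  tree rarely contains every library.
* **Re-search classification** (after candidate calling). Candidates
  are de-duplicated by sequence id, searched against all non-candidate
  assemblies, and judged on their top `n_top = 3` hits (sorted by bit
  score, then e-value, then identity, then subject id): one same-family
  or closer-than-`close_branches` subject excludes the candidate
  (`excluded_close_taxon`); exclusively distant subjects verify it
  (`verified_contaminant`) with the best hit's library as donor; no
  usable evidence leaves it `unresolved_possible`. Verification
  requires positive distant-hit evidence — absence of evidence is never
  treated as verification, which is why the grey "possible" category
  exists and is typically much larger than the verified one.

The two tree thresholds are deliberately not harmonised: pair screening
excludes at distance $\le$ `max_branches` (default 2) while the
re-search step uses a strict comparison (distance $<$ `close_branches`,
default 2). Both are configurable; the asymmetry is surfaced here and in
the function documentation rather than silently unified, because the
two rules act at different stages and err in different directions.

## Verdicts, summaries and outputs

Every sequence of every library receives exactly one status: `clean`
(never flagged), `verified_contaminant`, `excluded_close_taxon` or
`unresolved_possible`. Only verified contaminants are removed into
`<CODE>.contam.fasta`; everything else stays in `<CODE>.clean.fasta`,
with the possibles counted in the summary so downstream users can apply
their own caution. In the per-library summary the identity
`n_contaminant + n_clean + n_possible = n_total` holds on every run,
with `excluded_close_taxon` counted as clean (such sequences were
affirmatively cleared as close-taxon matches). The contamination matrix
counts verified contaminants by (contaminated, contaminating) library;
its diagonal is structurally absent (stored as `NA`) because a donor is
never its own recipient. The contaminant pair list is written
contaminant-first, partner second.

## SSU validation

Because 18S rRNA is highly expressed and taxonomically informative,
almost every library should contain an assembled 18S scaffold matching
the expected organism. Scaffolds are searched against a
lineage-annotated SSU reference set; alignments under `min_len = 300`
bp or with e-value above `max_evalue = 1e-9` are ignored (inclusive
boundaries: the rule states what is *ignored*, so a 300 bp, 1e-9 hit
survives). Each scaffold is assigned the reference with the lowest
e-value (ties: larger identity × length, then reference id). A sample
is `validated` when some assignment matches its expected family, and
`worrisome` when any assignment is to a *plant* family other than the
expected one — plant membership is read from the reference lineage
against a configurable clade list (default `Viridiplantae`), so
bacterial, fungal or metazoan hits are reported but never set the flag.
A sample can be both validated and worrisome (expected family present
plus a foreign plant family); a sample with no surviving assignment is
neither, which usually means the 18S failed to assemble rather than
that the sample is wrong.

## Completeness

Two completeness proxies are computed from external tool reports: CEG
abundance, $100 \times \text{hits}/248$ over the 248 core eukaryotic
genes, and BUSCO abundance, $100 - \text{missing}\%$. The inclusion
floor used for downstream taxonomic analyses is strict: a sample is
excluded when its BUSCO abundance is strictly below 57.5%, so a sample
exactly at the floor is retained. Percentile tables use linear
interpolation between closest ranks (`stats::quantile` type 7);
published summaries rarely state their convention, so the type is a
parameter and reproduction attempts can switch it. BUSCO recovery is
reported both as complete + fragment and as complete-only.

## The simulator

`simulate_contamination()` generates everything the pipeline consumes.
An ancestral pool of uniform-random transcripts (lengths uniform in
`length_range`, default 300–3000 bp) is diverged independently into
each library by per-site substitution at the rate $q$ solving
$(1-q)^2 + q^2/3 = t$, where $t$ is the configured pairwise identity —
so *every* library pair's background peaks at `divergence_identity`
(default 85%, a typical cross-family distance). One directed spike then
copies `ceiling(contamination_fraction × n)` donor sequences into the
recipient with per-base noise `noise_rate` (defaults 5% and 0.005,
mirroring a single heavily contaminated recipient among otherwise clean
pairs). Divergence is substitution-only — no indels — so percent
identity between any two related sequences is computed exactly by
position-wise comparison and the emitted 12-column hit tables need no
real aligner; their e-values and bit scores are synthetic monotone
functions of identity × length, of which only the ordering is
meaningful. Re-search tables carry each spiked sequence's hits (its
donor plus the background orthologs); original sequences have no
re-search rows, so the spikes' partner sequences land in the grey
`unresolved_possible` category, as in a real screen. SSU fixtures give
every sample a same-family reference hit that survives the filters,
plus optional foreign-family or missing-scaffold samples to express
worrisome and validation-failure truths.

Everything is deterministic given the configuration seed, and truth
labels record each spike's donor and ortholog.

What the simulator does **not** emulate: indels and alignment-length
variation, fragmented or chimeric assembly, expression-driven coverage
differences, multiple simultaneous contamination events per pair,
commensal (third-party) contamination shared by two libraries, or
same-family library pairs with realistically tiny divergence. Passing
the recovery tests therefore shows that the threshold scan, the
classification rule and the bookkeeping are correct under the
generative model — not that the pipeline's sensitivity on real
assemblies matches the simulated one. On real data the aligner, its
scoring and the assembly quality all move the histogram.

Default tree note: with three libraries the ladder topology places the
second and third library 2 branches apart, so that pair is excluded by
the default pair screen while the spiked donor–recipient pair (distance
3) stays eligible; the default scenario thus exercises the exclusion
path on every run.

## Numerical choices and degenerate inputs

* All selection steps (best hit per query, re-search ranking, donor
  choice, scaffold assignment) end with a lexicographic tie-break on the
  subject/reference identifier, so results are invariant under
  permutation of equally scored input rows.
* Histogram bins are half-open `[edge, edge + w)` with identity exactly
  100 assigned to the top bin; `bin_width` must divide 100 evenly.
* Empty inputs are valid where a stage can receive them: an empty hit
  table yields no matches, a pair without a peak yields no candidates,
  a library with no candidates is entirely clean. Malformed inputs
  (wrong column counts, non-numeric fields, duplicate sample codes or
  tree leaves, missing table headers) fail fast with the offending row
  or code named; no data row is ever silently dropped.
* LAST users: convert its tab output to the 12-column dialect (e.g.
  `maf-convert blasttab`) rather than feeding it directly; one internal
  carrier type keeps every downstream contract identical.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on simulated
data: unit tests use 200–300 transcripts per library at 300–800 bp,
the parameter-recovery check runs ten replicates of the default
3 × 2000-transcript scenario, the threshold scanner is cross-checked
against an independent exhaustive oracle on 1000 random histograms, and
the ortholog-divergence model is verified on 1000 replicates of a 10 kb
sequence. These sizes give the binomial identity distributions enough
mass to separate cleanly while keeping a full run on one CPU in tens of
seconds.

## Known limitations

* Donor assignment trusts the single best re-search hit; when the true
  donor is absent from the corpus the most similar present relative is
  named instead.
* A contaminant whose donor pair was excluded (same family / close in
  the tree) is invisible to the pairwise screen by design.
* The first-minimum scan needs a visible valley: contamination between
  species whose divergence identity approaches the noise floor of the
  contaminant copies (e.g. > 97%) merges the two modes and is reported
  `degenerate` rather than guessed at.
* The SSU stage inherits the taxonomic resolution of its reference set;
  families absent from the reference lineage table cannot validate.
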