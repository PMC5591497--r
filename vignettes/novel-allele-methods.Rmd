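---
title: "Predicting and validating novel IGHV germline alleles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and validating novel IGHV germline alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igallele)
```

## The model

An individual's IGHV genotype is a set of germline alleles, 0–4 diploid
copies per gene (segmental duplications and deletions make the locus
copy-number variable).  Expressed IgM heavy chains are drawn from these
copies and carry a small number of somatic hypermutations (SHM); IgM is
naive-enriched, so per-position mutation rates in *unique* IgM sequences
are well below 1%.  A novel allele — a germline variant missing from the
reference database — shows up as the **same** substitution at the **same**
position on a large, genotype-determined fraction of the unique sequences
assigned to its nearest reference allele.  SHM, by contrast, is
quasi-random: it scatters low-frequency substitutions across positions and
alternate bases.

Prediction exploits that separation with two thresholds applied to each
allele's per-position substitution profile:

* **prevalence** (`min_share`, default 0.20): the identical substitution
  (same position *and* alternate base) must be carried by at least 20% of
  the allele's unique sequences.  A heterozygous novel allele on a 4-copy
  gene is used by an expected 25% of sequences, so 20% is the floor that
  still catches the worst genotype the locus commonly offers; more copies
  than 4 would defeat it (a known limitation).
* **discordance** (`max_discordant`, default 0.02): all *other*
  substitutions at that position must together stay below 2%.  Genuine
  germline SNPs are near-clean; SHM hotspots show a mixture of alternate
  bases and are rejected by this ceiling.

An advisory pre-screen computes, per allele, the ratio of perfectly
matched unique sequences to those with exactly k = 1..`max_snps`
mismatches.  Ratios under `ratio_trigger` (default 2:1) are
genotype-like: a heterozygous novel allele roughly balances the classes, a
homozygous one empties the perfect class (ratio 0).  Candidates are then
grouped by **identical co-occurrence**: the unique sequences are keyed by
their substitution pattern restricted to the candidate positions, and each
non-empty pattern reaching `min_share` becomes one novel allele (so three
SNPs riding together yield one triple-substitution allele, while two SNPs
that never co-occur yield two single-SNP alleles).

Validation is genomic: amplicon reads from non-B-cell gDNA carry the
unrecombined germline without SHM.  Reads are filtered to the candidate's
allele group (assignment against the database augmented with the candidate
sequence; indel-containing and distant reads dropped), and reads equal to
the reference or the novel sequence **base-for-base** over the comparison
region are tallied.  The sample is positive when
`novel / (ref + novel) >= novel_read_threshold` (default 0.20 — a
heterozygous single-gene amplicon is expected near 50%, a homozygote near
100%).  Exact matching is deliberately unforgiving: sequencing-error reads
fall into an `other` bin rather than diluting either side.

## Coordinates

Published substitution names index the IMGT unique numbering for V
regions — a fixed codon grid (FR1 1–26, CDR1 27–38, FR2 39–55, CDR2
56–65, FR3 66–104) with gaps where a germline's region is shorter than its
grid (codon 10 for a 25-codon FR1, the middle of the CDR loops, codon 73
for a 38-codon FR3).  We verified on the six bundled alleles that the
printed positions (e.g. 234 for the IGHV1-8\*02 variant) are grid
positions, not indices into the ungapped sequence (where the same base
sits at 210).  The package therefore stores sequences **ungapped** and
keeps a per-allele *position map* used only at naming/reporting time:

* IMGT-gapped FASTA input → map read off the `.` positions (the
  recommended path for real reference directories);
* the bundled example alleles → maps built by `imgt_position_map()` from
  curated region lengths (validated in the test suite against the
  published names);
* bare ungapped input with no annotation → identity map, with positions
  that are then simply sequence indices.

All internal computation (assignment, profiling, simulation) is ungapped;
only names and reports are translated.  A 5'-truncated reference allele
would shift identity-map names — one reason gapped input is preferred.

## Assignment

Queries are anchored on each allele by exact 24-mer seeds (five seed
positions across the 5' half; an allele's k-mers are hashed once), scored
by Hamming distance over the anchored overlap, with free ends: a query may
run past the allele 3' end into the CDR3/junction, and that overhang is
ignored.  The best allele **maximises matched bases** over the aligned
interval.  For equal-length intervals this is exactly the minimum-mismatch
rule; across intervals of different lengths it prefers the longer one,
which resolves truncated-record shadows: a full-length novel sequence that
also matches a both-ends-truncated database record perfectly is still
reported against the full-length allele (with its one mismatch), and the
constructed novel sequence is annotated as *extending* the truncated
record rather than suppressed.  Remaining ties go to the
lexicographically smallest allele name, making assignment invariant to
query and database order.

Queries that no seed can anchor, or whose best anchored distance exceeds
`max(8, 5%)` of the overlap, are re-examined with a gapped overlap
alignment (Biostrings, match +1 / mismatch −1 / gap open 4 / gap extend
1 — substitution-friendly scoring, as the method is defined on SNPs).
Alignments containing indels are flagged and excluded from **both** the
numerator and denominator of all profile fractions: indels are rare in
IgM, corrupt position registration, and the method is a substitution
method.  Queries no allele covers with at least `min_overlap` (default
100 nt) are unassignable — the floor prevents short spurious overlaps
from winning.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_share` | 0.20 | fraction of unique seqs / tallied reads | floor for 1-of-4-copy heterozygotes (25% expected) |
| `max_discordant` | 0.02 | fraction | SHM/hotspot rejection ceiling |
| `ratio_trigger` | 2 | ratio | perfect:k-mismatch screen |
| `max_snps` | 4 | substitutions | largest mismatch class examined; larger patterns reported "out of range" |
| `min_unique` | 50 | sequences | below ~50 the 2% discordance ceiling is meaningless; outcome is `insufficient_depth`, not negative |
| `min_overlap` | 100 | nt | minimum aligned germline interval |
| `min_tallied` | 20 | reads | gDNA depth floor; below it the call is `failed`/N.D., the library-failed-to-amplify state |
| `primer_margin` | 14 | nt | trimmed from each amplicon end; primers sit ≥ 14 nt from predicted SNPs, so trimming provably retains them |
| `cnv_min_alleles` | 3 | alleles | > 2 distinct alleles detected ⇒ CNV flag |

The share denominator is per-position coverage (sequences whose aligned
interval covers the position), so 5'-truncated reads are not penalised;
with full-length reads it coincides with the group size.  The pattern
share in co-occurrence uses all profiled uniques of the allele — the
natural reading of a "% of unique sequences mutated" profile axis; an
alternative (share within the triggered mismatch class only) would be more
permissive and is not implemented.  The gDNA fraction excludes the
`other` bin by default (`denominator = "tallied"`); `"filtered"` is
exposed because the alternative reading (all retained reads) is defensible
— it would make the fraction depth- and error-rate-dependent, which is why
it is not the default.

The ratio screen is **advisory** by default: candidates are evaluated even
when no class is triggered, because the screen and the 20% rule are
redundant in most regimes and a strictly gated flow (available via
`strict = TRUE`) would behave awkwardly exactly in the homozygous case
where the perfect class is empty.  Zygosity hints (heterozygous-like for
novel fractions 0.2–0.8, homozygous-like ≥ 0.9) are descriptive
annotations motivated by the two observed clusters of real
prediction-versus-validation scatters; they never affect status.  SHM
hotspot positions are *not* masked by default — the 20%/2% thresholds are
the method's only stated defence — but `masked_positions` exists.

## What the generator emulates — and what it does not

`simulate_genotype()` builds explicit diploid genotypes (0–4 copies per
gene, any mixture of database alleles, novel substitutions injected on a
chosen number of copies).  `simulate_igm_repertoire()` draws each unique
sequence from a copy (uniform usage by default, so a gene's share is
proportional to its copy number and a 1-of-4 novel copy is carried by 25%
of sequences in expectation), applies independent per-position
substitutions at `shm_rate` (default 0.5% — the naive-IgM regime), with an
optional hotspot multiplier (default 5× at user-chosen positions, off in
acceptance runs), then per-base sequencing error (default 0.1%).
`simulate_gdna_reads()` draws amplicon reads uniformly from the gene's
copies with sequencing error and **no SHM** (gDNA from non-B cells).
Everything is bit-reproducible under a seed.

Not emulated: clonal expansion (inputs model *unique* sequences
post-deduplication; `collapse_unique()` is exercised separately), 5-mer
motif-based SHM targeting (independence suffices to exercise the
thresholds; real hotspots are more clustered), indels, PCR chimeras, and
V(D)J junction diversity (a junction overhang knob exists implicitly via
3'-extended queries).  A green simulation test therefore establishes that
the algorithm implements its stated decision rules under the stated noise
model — not that the thresholds are optimal for any particular real
sequencing protocol.

One subtlety the simulation surfaced: with per-base sequencing error, a
reference gDNA read can in principle acquire an error exactly at a
single-SNP position and tally as one novel-exact read (probability
≈ `error/3` per read, a fraction ~0.3% of tallied reads at depth 500 —
fifty-fold below threshold, so negativity is unaffected).  The stronger
statement "reference-only reads yield novel fraction exactly 0" is a
property of the exact-match semantics, and is asserted at zero sequencing
error where it is deterministic; at the default error rate the suite
asserts status negativity instead.

## Degenerate inputs and numerical choices

Empty FASTA, duplicate allele names, headers without an allele token, and
ambiguity codes (N) in germline sequences are hard errors — every
downstream exact-match tally assumes a concrete base.  Duplicate
*sequences* under different names (duplicated-gene pairs such as
IGHV1-69/1-69D sharing alleles) are allowed; copy-number and deletion
accounting pools these pairs (`default_gene_groups()`, editable) and
counts distinct *sequences*, not names.  Empty read sets and sub-floor
depths validate as `failed`, never negative.  Tallies whose comparison
region cannot contain every predicted SNP position abort with a
primer-design error rather than silently tallying a region that cannot
distinguish the alleles.  All randomness flows through explicit seeds;
file outputs are byte-identical across reruns and each run writes a
manifest (input checksums, parameters, package version) for provenance.

## Known limitations

Only novel alleles *similar to* a database allele are detectable (the
assignment step needs a near neighbour); genes with more than four copies
would dilute a heterozygous novel allele below the 20% floor; light
chains, D/J segments and indel-containing novel alleles are out of scope.
Identity-coordinate naming on unannotated ungapped references will not
match IMGT-numbered publications — supply gapped references when that
matters.
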