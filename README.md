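# igallele

Novel immunoglobulin heavy-chain V-gene (IGHV) germline allele prediction
from bulk IgM repertoire sequencing, with validation against targeted
genomic-DNA amplicon reads.

## The problem

Somatic hypermutation (SHM) calling in antibody repertoire analysis counts
mismatches between each sequence and its best-matched reference germline
allele.  The IGHV locus is polygenic and polyallelic, and reference
databases (IMGT) are not comprehensive: when a subject carries an
undocumented *novel* allele, every sequence using it is charged a phantom
SHM at the polymorphic position — inflating SHM loads, corrupting
replacement/silent ratios, and mis-rooting lineage trees.

`igallele` implements a streamlined two-stage remedy:

1. **Prediction from the expressed repertoire.** Unique IgM sequences
   (naive-enriched, hence low-SHM) are assigned to their best-matched
   germline alleles.  For each allele, the ratios of perfectly matched
   sequences to those with *k* = 1..4 mismatches are screened (ratios below
   2:1 look genotype-like), and a per-position substitution profile is
   built.  A substitution carried **identically by ≥ 20%** of an allele's
   unique sequences, with **< 2%** of sequences carrying *different*
   substitutions at the same position, is a putative germline SNP; identical
   co-occurring patterns are emitted as novel-allele candidates.  The 20%
   floor covers a heterozygous novel allele on a gene with up to 4 diploid
   copies (1 of 4 copies ⇒ an expected 25:75 usage split).
2. **Validation from genomic DNA.** Merged amplicon reads from non-B-cell
   gDNA (no SHM, no V(D)J rearrangement) are filtered to the candidate's
   allele group; reads matching the reference or the novel sequence
   **exactly** are tallied, and the sample is a positive hit when the novel
   sequence accounts for ≥ 20% of the tallied reads.  Per-gene flags mark
   copy-number variants (> 2 distinct alleles detected) and possible gene
   deletions (absent from both repertoire and gDNA).

Novel alleles are named `BASE (REF<pos>ALT[_...])`, e.g.
`IGHV1-8*02 (G234T)`, with positions in IMGT unique-numbering coordinates
(the package keeps a per-allele gapped↔ungapped position map; IMGT-gapped
FASTA input is understood natively).

A synthetic-data generator (diploid genotypes with 0–4 copies per gene,
novel-SNP injection, low-rate SHM with optional hotspots, per-base
sequencing error, gDNA amplicon reads) makes every stage testable with
known truth and no external downloads.

## Worked example

```r
library(igallele)

db <- example_germline_db()          # 6 IGHV genes + synthetic secondary alleles

# a heterozygous subject: one IGHV1-8 copy carries the G234T novel allele
gt   <- simulate_genotype(db, tibble::tibble(
          gene = "IGHV1-8", copies = 2L, novel = "IGHV1-8*02 (G234T)"))
reps <- simulate_igm_repertoire(gt, sim_params(n_unique = 5000), seed = 42)

asn  <- batch_assign(reps, db)       # best-matched allele + mismatch list per sequence
res  <- call_novel_alleles(asn, db)
tidy(res)[, c("novel_name", "n_support", "n_total", "share")]
#> # A tibble: 1 × 4
#>   novel_name         n_support n_total share
#>   <chr>                  <int>   <int> <dbl>
#> 1 IGHV1-8*02 (G234T)      1240    2533 0.490
```

Half of the 2,533 unique sequences assigned to IGHV1-8\*02 carry the
identical G→T mismatch (IMGT position 234; a 50% share is the heterozygous
1-of-2 expectation), far above the 20% threshold, so the novel allele is
called and its full sequence reconstructed.  Validation against simulated
gDNA amplicon reads:

```r
gdna <- simulate_gdna_reads(gt, "IGHV1-8", sim_params(gdna_depth = 500), seed = 7)
validate_candidate(gdna, db, "IGHV1-8*02 (G234T)", subject = "s1")
#>   subject candidate          status   zygosity_hint     n_ref_exact n_novel_exact novel_fraction
#> 1 s1      IGHV1-8*02 (G234T) positive heterozygous-like         193           189          0.495
```

`autoplot()` on a position profile draws the per-position percent-mutated
diagnostic (novel-allele SNPs tower over the sub-threshold SHM noise
floor); `plot_validation()` draws the repertoire-share versus
gDNA-fraction concordance scatter.

A command-line interface wraps the same functions:

```sh
exec/igallele simulate --genotype genotype.tsv --out sim/ --seed 3
exec/igallele predict  --repertoire sim/repertoire.fasta --germline sim/germline.fasta --out pred/
exec/igallele validate --reads sim/gdna_IGHV1-8.fastq --germline sim/germline.fasta \
                       --calls pred/calls.tsv --out val/ --subject s1
exec/igallele report   --predictions preds.tsv --validations val/validation.tsv --out concordance.tsv
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the position of the
single reference/novel mismatch of the bundled IGHV1-8\*02-derived novel
allele (by diffing the reconstructed reference and novel sequences and
reporting the IMGT-coordinate position), and the percentage of unique IgM
sequences carrying a novel pattern when exactly 1 of a gene's 4 carried
copies is novel (simulated at n = 10,000 with zero SHM and zero sequencing
error), writing both as JSON.
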