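---
title: "Methods and design of mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mitocomp implements the standard battery of comparative mitogenomic
statistics — partitioned composition and strand skews, codon usage (RSCU),
Nei–Gojobori ka/ks, perfect-microsatellite scanning, and supermatrix
assembly — over a single annotated-genome container. This vignette explains
each method, the parameters that matter, the numerical conventions, and
what the synthetic-data generator does and does not emulate.

## The genome container

`mito_genome()` holds a nucleotide sequence over {A, C, G, T, N}, a
circular flag, and an ordered feature table (name, kind, 1-based inclusive
start/end, strand). Coordinates are 1-based inclusive throughout, matching
how mitogenome papers print repeat and gene positions (a repeat at
10,168–10,185 spans 18 bp). Other IUPAC ambiguity codes are rejected at
construction: in practice mitogenome submissions are unambiguous, and
silently carrying ambiguity codes would corrupt skew and codon counts. N is
accepted but excluded from every composition denominator and breaks codon
and repeat runs.

Incomplete stop codons, common in mitogenomes where termination is
completed by polyadenylation, make annotated CDS lengths ≡ 1 or 2 (mod 3).
The policy is: composition uses the full annotated span; codon-level
analyses (`cds_sequences(trim = TRUE)`) drop the trailing partial codon,
and `start_stop_summary()` reports it padded with dashes (`TA-`). This
keeps partition totals faithful to the annotation while keeping codon math
well defined. Pseudogenes (e.g. a degraded *nad5* copy) stay in the feature
model — they are genuine annotation — but are excluded from PCG partitions
and codon statistics.

Duplicate tRNAs (Leu, Ser) are kept distinct as `trnL1/trnL2`,
`trnS1/trnS2`; bare `trnL`/`trnS` labels in input are suffixed by order of
appearance, since without an anticodon qualifier the two copies cannot be
told apart.

## Composition and skews

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C) are computed on
integer counts, never on rounded percentages. Skews are measured on the
deposited (sense) strand for the full genome and on reading-direction
sequences for gene partitions; this is the convention under which insect
mitogenomes show a positive AT and negative GC full-genome skew while
*nad*-gene-heavy PCG partitions can flip sign, because most *nad* genes lie
on the minus strand. Reported values round half away from zero
(percentages to 1 decimal, skews to 3), since that is how published
composition tables are printed; full precision is retained internally and
in the JSON output. A partition with A + T = 0 or G + C = 0 has an
undefined skew, reported as `NA` with a warning rather than as 0.

## Codon usage

The genetic code defaults to NCBI translation table 5 (invertebrate
mitochondrial: ATA = Met, TGA = Trp, AGA/AGG = Ser), with tables 1, 2 and 4
selectable; the code table itself comes from Biostrings. RSCU is observed
count × family size / family total within each synonymous family, so a
family used uniformly scores 1 everywhere, and a codon from an unused
family scores 0 (not NaN). Leu and Ser are split into their two codon
families for family math and labels (Leu1/Leu2, Ser1/Ser2), as codon-usage
figures conventionally do; stop codons are excluded from families and from
the amino-acid frequency denominator but tabulated separately. The
preferred-codon summary reports |{c : RSCU(c) > 1}| and the fraction of
those ending in A or T, the usual measure of third-position AT bias.

## Nei–Gojobori ka/ks

`codon_sites()` gives each codon position a synonymous fraction equal to
the proportion of its three single-nucleotide changes that preserve the
amino acid; changes to stop codons count as nonsynonymous (the standard
NG86 convention), so every sense codon contributes exactly 3 sites and
S + N = 3 × codons holds identically. Pairwise, sites are averaged over the
two sequences; differences at codon pairs differing at k ∈ {1,2,3}
positions are averaged over the k! single-step pathways. Pathways passing
through a stop codon are excluded from the average; in the rare case that
every pathway is blocked, the unrestricted average is used with a logged
note — this keeps the estimator total-difference-conserving
(Sd + Nd = number of differing positions) instead of silently dropping
codons. Proportions are Jukes–Cantor corrected, d = −¾ ln(1 − 4p/3);
p ≥ 3/4 yields an undefined distance, reported `NA` with a warning.

Codon pairs containing gaps or N are skipped pairwise. Alignment is an
input: the module does not align, it expects codon-aligned sequences
(equal-length homologs trivially qualify).

Per-gene ω aggregates all unordered taxon pairs. Published per-gene ω
values rarely state their aggregation, and the two obvious choices differ:
the mean of pairwise ratios explodes when any pair has ks ≈ 0, whereas the
ratio of means is robust and corresponds to a single per-gene value. The
headline `omega` is therefore mean ka / mean ks, with
`omega_mean_of_ratios` emitted alongside so either convention can be
compared. ω < 1 is read as purifying selection.

## Microsatellite scanning

`scan_ssrs()` finds all maximal perfect tandem repeats with motif length
1–6 under MISA-style minimum unit counts (defaults 12, 6, 4, 3, 3, 3 for
mono- through hexanucleotides), the settings conventionally used for
mitogenome scans. Conventions, all chosen to match MISA semantics so
results are comparable with the literature:

* forward-strand scanning, motifs reported as they occur (AAAT, TAAA and
  TTAT are distinct motifs, not collapsed to a canonical rotation);
* every repeat reported once, at its primitive (shortest) period —
  ATATATAT is a 4-unit AT run, never a 2-unit ATAT run;
* only complete units count: a trailing partial unit is excluded from both
  `n_units` and `size`, so a 6-unit TAT run is exactly 18 bp;
* `N` breaks runs; scanning is linear, so a repeat spanning the origin of
  the circular molecule is not detected (a documented limitation shared
  with MISA);
* directly adjacent repeats (gap ≤ `max_interruption`, default 0) can be
  merged into compound records by `merge_compound()`, retaining component
  motifs.

The scanner is validated against a brute-force all-substrings enumerator
on hundreds of random sequences in the test suite.

Location classification assigns the name of the gene containing the
repeat's start (CDS, rRNA, tRNA or pseudogene feature), else the control
region, else "Intergenic region". RA = repeats per kb and RD = repeat bp
per kb follow their definitions exactly and are recomputable from the
record list; reports round them to 2 decimals. Note that published RD
values are occasionally inconsistent with the same paper's printed repeat
sizes; mitocomp always reports the definitional value. The cross-species
summary pools motif-class percentages and the AT-only motif fraction and
computes the Pearson correlation (r², two-sided p) between repeat count
and genome size; with fewer than 3 genomes or zero variance the
correlation is reported missing.

## Supermatrix

`build_supermatrix()` concatenates pre-aligned per-gene blocks in a
configured order (the default 13-PCG order used for pentatomid
phylogenies), recording charset coordinates and codon-position labels.
Missing taxa are a hard error by default — a complete dataset should fail
loudly if a gene is dropped — with explicit opt-in gap-filling. Amino-acid
mode translates each aligned block with the selected code (gapped or
ambiguous codons become `-`) before concatenation. Writers cover FASTA,
relaxed PHYLIP and NEXUS (with a `sets` block) plus RAxML-style partition
files; round-trip readers are provided and tested. Alignment, trimming and
tree inference are deliberately out of scope — they belong to dedicated
tools.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth without downloading accessions. `default_layout()` emulates a
pentatomid-like mitogenome: 13 CDS, 22 tRNAs and 2 rRNAs in the ancestral
insect gene order with typical lengths and strands, a control region, 2-bp
spacers and one 500-bp intergenic spacer able to host repeats
(~16.3 kb in total; panel genomes vary 15.9–17.5 kb through the
control-region length). The default composition target,
A 42.5 / T 31.5 / C 15.0 / G 11.0 per cent, reproduces the AT-rich
(74% AT), positively-AT-skewed profile typical of these genomes.

Construction proceeds in four steps: (1) CDS are built as valid reading
frames under code 5 (start ∈ {ATA, ATT, ATG, TTG}, non-stop internal
codons sampled with per-base probabilities, a true stop at the end), with
minus-strand genes built in reading orientation and reverse-complemented
into the genome so strand handling is exercised end to end; non-coding
sequence is sampled per base. (2) Requested repeats are embedded at
recorded coordinates; embeddings into CDS are retried until the reading
frame survives (some motif/strand/frame combinations are genuinely
impossible and error out). (3) Incidental repeats meeting the thresholds
are scrubbed by local resampling — codon-constrained inside CDS, with
embedded positions held fixed — so the embedded repeats are provably the
only ones. (4) A composition trim adjusts non-coding, non-embedded bases
until realized genome-wide counts match the target percentages to within a
base, which pins the full-genome skews to the target values to ~3 decimal
places. The scrub/trim loop is capped (default 1000 iterations) and fails
with a diagnostic rather than returning a genome that violates its own
truth record.

`mutate_cds_pair()` plants exactly the requested numbers of synonymous and
nonsynonymous single-nucleotide changes, at most one per codon (so NG86
pathway averaging is exact and the truth classification unambiguous),
never touching start/stop codons and never creating stops.
`generate_panel()` draws per-species repeat counts from a stated linear
model of genome size (default slope 0.005/bp with Gaussian noise,
sd 1.5, giving 3–20 repeats across the size range — the spread reported
for pentatomid panels), places ~70% of repeats in genes, uses AT-only
motifs with probability 0.988, and draws motif-length classes close to the
published pooled distribution (tri ≈ 40%, tetra ≈ 43%).

What the generator does **not** emulate: phylogenetic structure (taxa are
independent draws, not a tree), indels, heteroplasmy, tRNA secondary
structure, realistic codon autocorrelation, or origin-spanning features.
Passing tests on synthetic data therefore demonstrate the correctness of
the statistics and scanners, not the biological realism of any evolutionary
model.

## Determinism and problem sizes

Every stochastic routine takes an explicit integer seed and is
bit-reproducible under a fixed seed. The test suite validates the scanner
against its brute-force oracle on 200 random 500-bp sequences, the NG86
pathway averaging against exhaustive enumeration on 1000 random codon
pairs and all 62 sense codons, and ω recovery on a 10-taxon, ~1.5-kb gene;
panel summaries use 8–20 genomes. These sizes were chosen to exercise every
code path and keep the default check fast on a laptop; all of them scale
linearly if heavier validation is wanted.

## Known limitations

* GenBank parsing targets the feature subset relevant here (CDS, tRNA,
  rRNA, D-loop/control region, pseudogenes) and common location forms
  (`a..b`, `complement()`, simple `join()`); exotic location operators are
  not supported.
* Repeats spanning the circular origin are invisible to the linear scan.
* ka/ks is the original NG86 estimator: no transition/transversion
  weighting, no ML codon models; saturated pairs (p ≥ 3/4) are undefined
  by construction.
* The pipeline's kaks/supermatrix stages require equal-length homologs
  (i.e. pre-aligned input); genes failing that are skipped with a warning
  rather than aligned in-package.
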