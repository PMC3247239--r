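---
title: "Enriched and conserved motifs in TSS-anchored promoter sets: methods"
author: "promoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enriched and conserved motifs in TSS-anchored promoter sets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large tandemly duplicated gene families — the motivating case is the mouse
olfactory receptor (OR) repertoire — pose an unusual challenge for
regulatory-sequence analysis. Their promoters are extremely AT-rich (around
36% GC against a genomic average of ~42%), they lie far from any CpG
island, the family's recent duplication history means many promoters are
near-identical paralogs rather than independent observations, and
cross-species orthology is frequently disrupted, so binding sites may
survive in an orthologous promoter without sitting at the exactly
orthologous base ("turnover"). `promoscan` packages, as reusable and tested
components, a pipeline that addresses each of these problems in turn:

1. build a non-redundant, TSS-anchored promoter set (TSS inference from
   cDNA/RACE alignments; removal of recent duplicates by single-linkage
   clustering);
2. scan promoters with a library of position weight matrices (PWMs) at two
   stringencies, pruning to the best match per matrix family in any
   overlapping region;
3. test every family for enrichment with three complementary statistics —
   a one-tailed binomial test against the immediately preceding region, an
   empirical null from dinucleotide-preserving shuffles, and a one-tailed
   rank-sum test on per-base conservation scores inside versus outside
   predicted sites;
4. filter predicted sites by cross-species support, allowing positional
   slide and scoring support by the branch length of the supporting
   species' subtree; and
5. mask the dominant motifs identically from promoters *and* every control
   dataset, then repeat the analysis to expose secondary signals.

A synthetic-data module generates inputs with exactly the statistical
structure the analysis assumes, so every stage — and the pipeline end to
end — is testable with no downloads.

## The similarity score

Scanning uses an information-weighted ("MatInspector-style", after Quandt
and colleagues) similarity score. Counts are column-normalized with a
pseudocount of $\varepsilon = 0.01$ per cell into frequencies $f(i, b)$.
Each column carries an information weight

$$C_i = \frac{100}{\ln 4} \sum_b f(i,b)\, \ln\!\big(4 f(i,b)\big),$$

the (scaled) relative entropy of the column against the uniform
background: 0 for an uninformative column, 100 for a deterministic one.
The similarity of a window whose base at column $i$ is $b_i$ is

$$\mathrm{mss} = \frac{\sum_i C_i\, f(i, b_i)}{\sum_i C_i\, \max_b f(i,b)}
\in [0, 1],$$

so a perfect consensus match scores exactly 1. The *core* of a matrix is
its four highest-$C_i$ columns (leftmost on ties); a window is a hit only
when the same score restricted to the core positions reaches 0.75 *and*
the full-matrix score reaches the matrix's threshold. Both strands are
scanned; the minus strand is handled by scoring the reverse-complemented
matrix, which makes strand symmetry exact. Masked bases (lowercase, `N`)
contribute zero frequency wherever they fall in a window.

Two stringencies are used throughout: the per-matrix optimized threshold
("opt"), and the same threshold lowered by 0.1 ("opt-0.1", floored at
0.5), which trades specificity for roughly an order of magnitude more
matches. `calibrate_threshold()` chooses "opt" as the smallest value on a
0.01 grid in $[0.60, 1.00]$ whose background match rate does not exceed
0.3 matches/kb (1.00 if unattainable); matrices with no calibration use a
fixed default of 0.85. The exact core and threshold definitions of the
commercial tool this score emulates are proprietary, so absolute "opt"
values here will not numerically match the vendor's; both the core size
and the gate are configurable.

Within each promoter and family, hits whose intervals overlap
(transitively, either strand) are grouped and only the best-scoring hit
survives (`family_prune()`): ties break toward the longer matrix, then
the leftmost start, then the + strand. The same pruning is applied to
promoter, preceding-region and shuffled datasets alike, since the
original description does not state which convention was used for
controls and an asymmetric choice would bias the counts.

## The three statistical tests

**Binomial versus the preceding region.** With $k$ pruned sites in the
$L$-bp promoters and $m$ in the preceding $L$ bp (TSS-relative
$[-2L, -L)$), the null is that a site is equally likely in either region:
$p = P(X \ge k)$, $X \sim \mathrm{Bin}(k+m, \tfrac12)$. The tail is an
exact sum (R's `pbinom`, accurate in log space far below $10^{-50}$ —
a normal approximation would be useless at the observed extremes).
Families with $k = m = 0$ are skipped. The fold is $k/m$, flagged
infinite when $m = 0$.

**Empirical null from dinucleotide shuffles.** Each promoter is shuffled
by the Altschul–Erickson Eulerian-path algorithm, which preserves the
exact mono- *and* dinucleotide multiset and the terminal bases; runs of
masked bases stay in place and the unmasked segments between them shuffle
independently. A replicate shuffles every promoter once; the pipeline
default is $B = 1000$ replicates (10000 reproduces the original design at
ten times the cost). The empirical p-value is the fraction of replicates
whose pruned family count is **greater than or equal to** the observed
count. The source description is ambiguous between "equal or higher" and
"exceeded"; the $\ge$ convention is the conservative one and is the
default, with `ge = FALSE` available. A count of zero is reported as
"<1/B". The fold is observed/mean(shuffled).

**Conservation rank-sum.** Per-base conservation scores (semantics
$1 - P(\text{neutral})$, higher = more conserved) are pooled across
promoters and split into bases covered by at least one family hit versus
all other promoter bases; a one-tailed Mann–Whitney test asks whether
in-site scores are higher. Two variants run: whole-site, and core-only
(the four core matrix positions of each hit, mirrored for minus-strand
hits). A family passes when *either* variant passes — the core variant
gains signal concentration but loses sample size, and which wins depends
on the family. Out-of-site bases exclude only the *tested* family's
sites; whether other families' sites should also be excluded is not
specified in the source, and excluding them would couple the families'
tests. Missing scores are dropped from both groups, with group sizes
reported. When both groups have at most 10 values the p-value is an exact
enumeration over rank assignments of pooled mid-ranks (valid under ties);
otherwise the normal approximation with tie correction and continuity
correction is used — the continuity-corrected version tracks the exact
enumeration within a few percent at group sizes 8–10, which the test
suite asserts.

All three tests are Bonferroni-controlled at $\alpha/m$ where $m$ is the
number of families actually tested (0.05/177 = 0.000282 in the motivating
study). Report rows carry a three-character code, one character per test:
`X` below $\alpha/m$, `+` below $\alpha$, `.` otherwise. The legend is an
inference — the original table prints codes without one — and is
documented as an assumption, not asserted as the source's intent.

## Cross-species site filtering with turnover

Per-species site predictions (scans of the ungapped alignment rows with
the same thresholds) are mapped into alignment columns. A species
supports a reference site when one of its sites lies within `slide_w`
columns of the reference site's column interval (`slide_w = 0` demands
overlap; the default 50 accommodates turnover). "Within 50 bp" is
interpreted as alignment-column distance between interval boundaries; the
source is ambiguous between column and ungapped distance, and the column
frame is the one in which the sites were compared. The support set's
conservation is scored as the branch length of the minimal spanning
subtree connecting the supporting species (excluding branches above their
MRCA; singletons score 0), and sites are kept when that length reaches
`min_tree_len` (default 0.17 — on the mammalian tree used in the
motivating study, conservation beyond the mouse–rat pair). Support sets
grow monotonically with `slide_w`, and kept-site counts fall
monotonically with `min_tree_len`; both monotonicities are asserted in
the test suite. The species tree is always an input, never hard-coded:
the original tree was manually pruned to placental mammals and its exact
species list is not published.

Orthologous promoter sets lifted from other genomes are deduplicated with
`ortholog_region_merge()`: same-strand overlapping regions merge and each
merged run is replaced by its most upstream window of the original width
(leftmost on +, rightmost on −), i.e. the most upstream of the
alternative promoters is used.

## Masking

`build_mask()` takes the dominant family's **unpruned** lower-stringency
hits over their full extents, plus TATA-box hits at "opt" that touch the
TSS-relative window $[-61, -10]$. Unpruned is deliberate: pruning keeps
one hit per overlap group, and masking only the survivor can leave a
discarded partner's flank unmasked and able to re-fire. With full-extent
masking, a re-scan at the same stringency provably finds zero hits of the
masked family — every former hit window is entirely blanked and every
other window's score can only decrease. Masked bases become `n` in
sequences (scored zero, coordinates preserved — masking never deletes)
and `NA` in score vectors. The identical TSS-relative positions are
masked in the real promoters, the preceding regions (at the equivalent
within-region offsets, i.e. the mask shifted by $-L$), every shuffled
replicate (the shuffle-null engine applies the mask *after* shuffling
each replicate, so shuffled and real datasets lose exactly the same
bases), and the conservation tracks. This keeps the amount of analysed
sequence equal across all dataset kinds.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline targets:
300 promoters of $L = 200$ bp, background GC 36.4%, a dominant long motif
planted at a mean of 1.4 sites per promoter (Poisson counts) with a
TSS-proximal positional law, a conservation boost inside planted sites,
species site sets thinned by branch-length-dependent loss with Gaussian
positional jitter, and duplicate promoters at a configurable substitution
rate.

The background is a first-order Markov chain: stationary base frequencies
$((1-g)/2,\, g/2,\, g/2,\, (1-g)/2)$ with $g$ the GC target, and a
same-base "stickiness" $\kappa = 0.2$ (each base repeats its predecessor
with probability $\kappa$, else draws fresh), so the dinucleotide
composition genuinely differs from the mononucleotide one and the
dinucleotide-preserving shuffle null is exercised non-trivially. The
stationary distribution is unchanged by $\kappa$, so the GC target is hit
exactly in expectation. A first-order chain suffices for testing a
dinucleotide-preserving null; higher-order structure of real promoters is
deliberately not modelled. Conservation backgrounds are i.i.d.
Beta(2, 8) (mean 0.2 — mostly neutral bases with a light right tail);
planted-site bases gain the configured boost, clipped at 1. Planted site
sequences are sampled column-wise from the PWM, so "weak" instances occur
at realistic rates, and densely planted sites may overwrite one another —
parameter-recovery assertions therefore use overlap matching and
tolerate a few percent of unrecoverable truths.

What the generator does *not* emulate: indels and alignment gaps
(turnover alignments are emitted gapless so column equals position — the
coordinate-mapping code is exercised separately on gapped fixtures),
repeat elements, CpG islands, regional GC gradients, and correlated
conservation along the sequence. Passing tests therefore demonstrate the
statistical machinery under the assumed structure, not performance on
real genomes.

All randomness flows from one master seed through derived sub-streams
keyed by module name, so every simulated object is byte-reproducible; the
C++ shuffle engine draws from R's RNG, so `set.seed()` governs it too.

## Numerical and design choices

- **Synonymous divergence.** Recent duplicates are flagged by NG86
  (Nei–Gojobori) pairwise $dS$ with Jukes–Cantor correction, threshold
  $dS < 0.3$, instead of a maximum-likelihood codon model: it is
  dependency-free, desk-scale and transparent; it is documented as an
  approximation to the ML estimate used in the motivating study. Pathway
  averaging over multi-position codon differences excludes paths through
  stop codons unless every path is stopped; saturated pairs ($p_S \ge
  3/4$) are *not* flagged similar, and carry a note.
- **Flank identity.** The second duplicate criterion — a local alignment
  of TSS flanks covering ≥ 200 bp at ≥ 70% identity — uses
  `Biostrings::pairwiseAlignment` (+1/−1 match/mismatch) behind a shared
  12-mer seed prefilter, which keeps the all-pairs cost practical.
- **Representative choice.** Single-linkage components keep one promoter
  each, chosen by a seeded RNG (default 42) — the original choice was
  "arbitrary"; a seed makes it reproducible.
- **Coordinates.** 0-based half-open everywhere, TSS at relative 0,
  upstream negative; position $-1$ is the base adjacent to the TSS. The
  source states no convention; this one round-trips through BED without
  adjustment.
- **Counting scale.** The promoter-count discrepancy in the motivating
  study's own reporting (314 vs 312 after deduplication) is left alone:
  the pipeline reports its own counts and targets neither number.
- **Problem sizes.** The test suite runs the generator at 25–300
  promoters and $B$ = 120–1000 shuffle replicates; the acceptance script
  uses the full study conditions (300 promoters, mean 1.4 sites, boost
  0.4, $B$ = 1000, 50 decoy families). These sizes give the assertions
  comfortable statistical margins while keeping a full run in minutes on
  one core.

## Known limitations

- The similarity score approximates a proprietary scheme; calibrated
  thresholds are internally consistent but not numerically comparable to
  the commercial tool's "opt" values.
- The conservation test consumes per-base scores; the phylogenetic rate
  model that produces them (SCONE in the motivating study) is an
  upstream input, not re-implemented.
- Whole-genome alignment, liftOver and ab initio motif discovery are out
  of scope; their outputs are inputs here.
- GC-matched non-family promoter controls are intentionally absent: the
  motivating study found no satisfiable control set at this GC extreme,
  and the preceding-region + shuffle controls are the designed
  replacement.
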