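---
title: "Methods: lncRNA classification and antisense co-expression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA classification and antisense co-expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnat)
```

# Scope and model

`lncnat` implements a stranded-RNA-seq analysis for discovering long
non-coding RNAs (lncRNAs) and screening natural antisense transcripts
(lncNATs) whose expression tracks their sense partners across a
2-genotype (purple / orange) x 2-tissue (phloem / xylem) x 3-replicate
design.  The pipeline has six analysis stages — classification,
strand-specific counting, normalization, differential expression, NAT
selection and reporting — plus a synthetic-data generator that produces
datasets with fully known ground truth, so every stage can be validated
by closed-loop recovery rather than by reference to any particular
deposited dataset.

## Transcript classification

Novel transcript models are compared against a reference annotation and
given a class code with precedence `equal > sense_overlap > x > i > u`:
identical exon chain; >= 1 bp exonic overlap on the same strand; exonic
overlap on the opposite strand only; full containment in an intron; or
intergenic.  Only `u`, `x` and `i` transcripts represent new loci and
enter the analysis; sense-overlapping models are treated as fragments of
annotated genes.  The long-RNA filter then requires a spliced length
strictly greater than 200 nt.

Each retained transcript is assigned one biotype by ordered rules:

1. **coding** if the longest forward-strand ORF is strictly longer than
   120 aa, or an external coding-potential verdict says coding;
2. **structural** if a structural-RNA homology (tRNA, rRNA, snRNA,
   snoRNA) is recorded;
3. **noncoding** otherwise — on an explicit noncoding verdict, a known
   ncRNA homology, or by default when no evidence exists.

The ordering means a transcript with both a long ORF and an rRNA
homology is called coding; we read the rules as an ordered procedure.
External verdicts enter as plain TSV evidence tables, so the pipeline
never requires the external tools themselves; a transcript with no long
ORF and no evidence rows is noncoding by default, because a tool verdict
cannot be a precondition for classifying one's own assemblies.

Noncoding transcripts get one positional subclass, again by specificity:
**lncNAT** (>= 1 bp exonic overlap antisense to a coding transcript),
else **intronic** (fully inside an intron of a coding gene), else
**lincRNA** (farther than 1 kb from any coding gene), else **proximal**.
The proximal class is our addition: intergenic transcripts within 1 kb
of a coding gene satisfy no standard definition, and folding them
silently into the lincRNAs would blur the distance rule.  Distance is
measured span-to-span and strand-agnostically, with any overlap giving
distance zero; measuring from exons instead would only differ for genes
with long terminal introns, and span-to-span is the conservative choice
for a rule whose intent is "not near a gene".  The boundary itself is
strict: distance 1001 is lincRNA, distance 1000 is proximal.

The ORF finder scans the three forward frames for ATG...stop spans under
the standard codon table, reporting the longest ORF of at least
`orf_search_min_aa` (default 70) amino acids; ties break towards the
smallest start offset; codons containing `N` neither start nor stop an
ORF (a conservative, deterministic rule); an ORF running off the 3' end
still counts, with its length measured to the last complete codon, which
matches the default behaviour of common ORF predictors.  The 70-aa
search floor follows the stated analysis text rather than the `-m 50`
flag of one tool invocation; it is configurable.

## Counting and normalization

Fragments (aligned read pairs reduced to intervals, or BED6 records
carrying the resolved transcript strand) are assigned to a gene when
they overlap at least 1 bp of its exonic sequence *on the same strand*.
Fragments hitting two or more same-strand genes are dropped as
ambiguous, and the per-sample accounting always satisfies assigned +
ambiguous + unassigned = total.  The minimal SAM reader uses read 1 of
each pair and resolves fragment strand by library protocol, defaulting
to `reverse` (dUTP/TruSeq-style stranded chemistry); BED6 input is taken
as already resolved.

Size factors follow the median-of-ratios scheme: genes with strictly
positive counts in every sample define a per-gene geometric-mean
reference, a sample's factor is the median of its count/reference
ratios, and the factors are rescaled to geometric mean 1 so the
normalized scale has a fixed anchor.  At very low counts the
all-positive conditioning biases the shallowest samples slightly upward;
with 2000 genes and a 8x depth range the recovery error of planted
depth multipliers averages about 2 % (recomputed by the acceptance
script), which is the intrinsic accuracy of the estimator at that size,
not an implementation artefact.

## Differential expression

The test is a deliberately transparent substitute for a full NB-GLM
machinery, because the package's claims are exercised by parameter
recovery on synthetic truth rather than by replicating any particular
gene list.  Per gene and contrast side, normalized group means `mu_A`,
`mu_B` give `log2FC = log2(mu_B / mu_A)` (with a 0.5 pseudocount added
to both means only when one of them is zero), and a delta-method
standard error under the NB variance law `var = mu + alpha mu^2`:

```
SE = (1/ln 2) * sqrt( (mu_A + a mu_A^2) / (n_A mu_A^2)
                    + (mu_B + a mu_B^2) / (n_B mu_B^2) )
```

Dispersions come from a method-of-moments fit,
`alpha = max(0, (v - m) / m^2)` per group, combined by a
replicate-weighted mean and floored at `1e-8`.  Making the pseudocount
conditional (rather than unconditional) is what keeps fold changes of
expressed genes exactly invariant to rescaling a sample's depth, a
property the test suite asserts at 1e-6.

**Reference distribution.**  The Wald statistic `log2FC / SE` is
referred to a t distribution with `n_A + n_B - 2` degrees of freedom,
not a standard normal.  With three replicates per condition the
method-of-moments dispersion is extremely noisy, and genes whose
within-group variance fluctuates low get an underestimated SE; under a
normal reference this inflates the far tail badly enough that a
Bonferroni screen at adjusted p < 0.01 over 2000 genes produces false
positives in most null datasets (we measured a family-wise error near
70 % in 200-replicate null simulations).  The t reference absorbs the
SE fluctuation the way a t test absorbs a noisy variance estimate and
brings the measured family-wise error to well below 5 % — the error
control the screen is supposed to provide — while leaving the power
against the very large planted effects of interest untouched.  This is
the one place the implementation departs from the plainest Wald recipe,
and it is deliberate.

Multiplicity is Bonferroni over the testable genes of the contrast
(genes with some expression in at least one side and a defined
dispersion); the significance cut is strict: adjusted p of 0.0099 is
significant, 0.01 is not.  The three standard contrasts are purple vs
orange over all 12 samples and within each tissue (subset re-fits; a
joint multi-factor model is out of scope).

## NAT selection

All (coding, noncoding) transcript pairs on opposite strands with >= 1
bp of exon-vs-exon overlap are enumerated, then filtered by three joint
criteria: both members differentially expressed in the overall genotype
contrast (the per-tissue contrasts are available but the overall one is
the default "both DE" reading); antisense overlap (constitutive of the
pair); and both correlation families passing `|r| >= 0.70` with
`p < 0.01` — Pearson *and* Spearman individually, since the criterion
quotes both.  Correlations are computed on `log2(normalized + 1)`
expression across all 12 samples: the log transform keeps the
genotype-driven bimodality from letting a single high-expression
condition dominate the Pearson moment.  Pearson p values use the exact
t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df; Spearman uses
the same t approximation on rank correlations (with average ranks for
ties), since an exact permutation null at n = 12 is impractical — a
seeded Monte-Carlo permutation p is available for verification.
Zero-variance expression vectors yield an undefined result and the pair
is dropped.  Concordance is the sign of the Pearson coefficient; a
Pearson/Spearman sign conflict cannot pass the joint threshold, so the
case is unreachable at the default cuts.

## PCA, summaries, relative quantification

Sample PCA operates on gene-centred `log2(normalized + 1)` values with
no unit-variance scaling (scaling would let near-silent genes dominate);
scores come from the SVD over samples, each component oriented so its
largest-magnitude sample score is positive, making score signs
reproducible.  Summary tables bin spliced lengths at 200 bp, histogram
exon counts, normalise biotype composition per chromosome, and compare
coding vs noncoding mean log expression by a Welch two-sided t test.
Relative RT-qPCR quantification uses the delta-delta-Ct identity
`RQ = 2^-((Ct_t - Ct_ref)_sample - (Ct_t - Ct_ref)_calibrator)`, so the
calibrator sample has RQ exactly 1 and a one-cycle shift doubles or
halves RQ exactly; undetected targets are flagged rather than imputed.

# The synthetic-data generator

`simulate_genome()` plants, per configuration: reference protein-coding
genes (1–4 exons, embedded ATG...stop ORFs of 130–300 codons, placed
without overlap and separated by 4–8 kb); antisense lncNATs over host
exons (a configurable fraction fully span-contained); lincRNAs more than
1 kb from any coding span; proximal transcripts at 100–900 bp; intronic
transcripts inside introns; and novel coding transcripts with embedded
ORFs.  Noncoding transcripts are single-exon and 400–800 nt, the most
frequent length class of plant lncRNA surveys.  Noncoding sequence is
rejection-sampled until its longest forward ORF is below 70 aa; for
lncNATs, whose sequence is partly pinned by the host, the host's codons
are drawn rich in TTA/CTA/TCA (codons whose reverse complements are
stops) and redrawn on failure, so antisense ORFs die out within the
retry cap.

`simulate_counts()` draws NB counts with dispersion `alpha = 0.05`
(typical for well-behaved bulk RNA-seq replicates) around per-gene means
`2^(base + genotype effect + tissue effect + latent)` times a per-sample
depth multiplier.  Baselines are `2^U[3, 9]` for background genes and 50
for "anthocyanin module" genes, the regime in which fold-change recovery
is meaningfully calibrated; module genotype effects are drawn from
`U[6, 12]` on the log2 scale, the magnitude regime of strongly
genotype-specific pigment-pathway genes, applied to purple.  Members of
a sense/antisense pair share a per-sample latent Gaussian (sd 1.0 log2
units, correlation 0.9 by default, negated for the discordant fraction,
0.25 by default), modelling condition-level co-variation on top of
counting noise.  Tissue effects of `U[1, 3]` hit a random 10 % of genes,
keeping tissue variance well below genotype variance as in the target
design.  `simulate_reads()` realises each count as a fragment placed
uniformly within a single exon on the gene's strand — junction reads add
no power to an exon-overlap counting rule and are omitted.

Identical configurations reproduce byte-identical annotations,
sequences, counts and fragments; every stochastic call derives from the
single configured seed.

**What the generator does not emulate:** sequencing errors and quality
scores, junction-spanning fragments, multi-mapping, transcript-level
ambiguity (one transcript per gene), GC or length biases in coverage,
and real lncRNA sequence composition.  Passing the closed-loop tests
therefore demonstrates the correctness of the decision rules and
estimators under the declared statistical model, not robustness to
alignment artefacts or assembly noise on real data.

# Validation sizes

The test suite exercises: classification closed loops at 90 transcripts
x 20 seeds (exact recovery required); a 200-gene x 12-sample count
round trip (cell-exact); size-factor recovery at 2000 genes x 20 seeds;
effect recovery and a 200-replicate null family-wise-error check at
2000 genes; NAT screening over 12 simulated studies; oracle equivalence
on 1000 random sequences and 1000 interval queries; and 100-seed PCA
structure checks.  These sizes give the binomial margins the asserted
rates need while keeping the full suite in the minutes range on one
core.

# Known limitations

* The moment/Wald test is calibrated for screening very large effects;
  its t reference is an approximation, and subtle effects (log2FC of
  order 1 at n = 3 + 3) are outside its validated regime.
* Bonferroni control is intentionally conservative; no FDR option is
  provided because the downstream NAT screen assumes family-wise logic.
* Class codes cover the novel-gene codes (`u`, `x`, `i`) plus the two
  rejection codes; the finer taxonomy of assembly-vs-reference codes
  (contained, junction-compatible, ...) is out of scope.
* One transcript per gene is assumed throughout quantification;
  isoform-level abundance is a non-goal.
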