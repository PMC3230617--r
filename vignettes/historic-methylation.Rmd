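---
title: "Inferring historic germline methylation from dinucleotide composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring historic germline methylation from dinucleotide composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological signal

5-methylcytosine deaminates to thymine at a much higher rate than unmethylated
cytosine deaminates to uracil (which is repaired). Over evolutionary time,
sequences that are methylated in the germline therefore lose CpG dinucleotides:
each mC→T transition destroys a CpG on one strand and, via the paired
reverse-strand mC, a G→A transition destroys it on the other. The ratio of
observed CpG frequency to the frequency expected from a sequence's C and G
content — CpG O/E — is consequently a fossil record of germline methylation: a
value near 1 means CpG occurs as often as base composition predicts (no
historic methylation pressure), while values well below 1 indicate sustained
CpG erosion. In insect transcriptomes with gene-body methylation, the per-gene
CpG O/E distribution is typically bimodal: a low mode of historically
methylated genes and a high mode near the compositional expectation.

`methtrace` implements this inference chain end to end: the N-corrected O/E
estimator, a mixture-based test of bimodality, classification of genes into
the two populations, EASE-style GO enrichment of each population, an in-silico
methylation-sensitive restriction digest, and a deamination-driven sequence
evolution simulator that provides ground truth for all of it.

## The O/E estimator and its N correction

For a sequence with mononucleotide counts $m_x$ over its $L_\mathrm{eff}$
non-N bases, $d_{xy}$ occurrences of dinucleotide $xy$ among its $W$ N-free
adjacent windows,

$$
\mathrm{O/E}_{xy} \;=\; \frac{d_{xy}/W}{(m_x/L_\mathrm{eff})\,(m_y/L_\mathrm{eff})}.
$$

EST-derived unigenes contain runs of N; a window containing an N is neither a
CpG observation nor a valid trial, so it is excluded from both $d_{xy}$ and
$W$, and N bases are excluded from the mononucleotide frequencies. With no Ns
present the estimator reduces to the textbook formula
$f_{xy}/(f_x f_y)$. Counts are additive across an inserted N block, which the
test suite asserts directly. No small-sample length correction (such as
$L^2/(L-1)$) is applied; the estimator is documented here precisely so results
are reproducible.

The ratio is reported as undefined — with a machine-readable reason code,
never silently dropped — when $W = 0$, when $m_x$ or $m_y$ is zero, or when
$L_\mathrm{eff}$ falls below `min_length`. The default `min_length = 100`
non-N bases reflects EST-scale unigene data, whose shortest members are around
100 bp; shorter fragments give O/E estimates too noisy to interpret. Values
above 3 are retained in all computations and tables; truncation at 3 is a
plotting convention only, and this package does no plotting.

All sixteen dinucleotide profiles can be computed over a single counting pass
(`all_dinucleotide_profiles()`). They are the specificity control: CpG-specific
deamination must depress the CG distribution and leave the other fifteen —
GpC in particular, which shares base composition with CpG — unimodal.

## Mixture model and bimodality test

Per-gene CpG O/E values are modeled as a two-component Gaussian mixture.
`fit_mixture()` maximizes the likelihood by EM with short-EM initialization:
ten starting points (component means at the 25th/75th percentiles, the
remaining nine jittered deterministically from the seed) are each run for at
most 100 iterations, and the two best candidates are polished to a relative
log-likelihood tolerance of 1e-8 with an iteration cap of 1000. Component
variances are floored at 1e-6 so no component can collapse onto a single
observation. The per-iteration log-likelihood trace is returned and asserted
non-decreasing in the tests. All stochastic entry points take an explicit
seed and are bit-reproducible.

Whether the distribution is really bimodal is decided by a parametric
bootstrap likelihood-ratio test (`unimodality_test()`). The observed statistic
is $2(\ell_2 - \ell_1)$; because the single-Gaussian null sits on the boundary
of the mixture parameter space, the usual chi-square reference is invalid, so
the null distribution is built by simulating datasets of the same size from
the fitted single Gaussian, refitting both models, and computing
$p = (1 + \#\{T_b \ge T_\mathrm{obs}\})/(B + 1)$. This is the standard
approach to mixture-order testing and replaces the opaque internal test of
legacy mixture-fitting programs.

That Gaussian null is correct when the values share a common noise scale,
and the test is calibrated there (asserted on standard-normal data in the
suite). Per-gene O/E values do not share one: the sampling standard
deviation of O/E scales inversely with the square root of a gene's window
count, so across genes of 101–4,278 bp it spans roughly a six-fold range. A
single *population* of such genes therefore produces a unimodal but
heavy-tailed (kurtosis 4–6) O/E distribution, and a Gaussian-null LRT
rejects it for the kurtosis alone — a false bimodality call. For O/E
profiles the package therefore provides `oe_unimodality_test()`, which keeps
the identical LRT statistic but builds the null at the level of counts:
under the one-population null with pooled common ratio
$\hat r = \sum_i d_i / \sum_i W_i q_i$ (where $q_i$ is gene $i$'s expected
dinucleotide frequency from its own mononucleotide composition), bootstrap
counts are drawn as $d_i^\ast \sim \mathrm{Binomial}(W_i, \hat r q_i)$,
converted back to O/E, and both models refitted. The null LRT distribution
then contains exactly the length-driven noise heterogeneity of the data.
In the validation suite this restores the nominal rejection rate on
single-population gene sets while a planted two-population set is still
rejected decisively; this count-level null is the package's recommended
bimodality decision for per-gene O/E data, with the value-level test
retained for homoskedastic inputs.

Genes are assigned to populations by the posterior probability of the
lower-mean component; the label is "low" when that posterior is at least 0.5,
with the tie at exactly 0.5 resolved to "low" so classification is
deterministic. `class_boundary()` locates the O/E value where the posterior
crosses 0.5 by bisection to 1e-10; for equal weights and standard deviations
it is the midpoint of the means. How the low/high split is drawn is a genuine
design choice — a fixed O/E cutoff would be an alternative — and the posterior
rule was chosen because it uses the fitted model itself, is exactly
reproducible, and coincides with boundary thresholding when the component
standard deviations are equal.

## GO enrichment: the EASE score

Each gene population is tested for GO biological-process term
over-representation against the background of all annotated genes (genes
without annotation never enter any margin — using the full unigene set as
background would deflate every p-value). For a term annotated to `pop_hits`
of `pop_size` background genes and `list_hits` of the `list_size` class
genes, the plain one-sided Fisher p-value is the hypergeometric tail
$P(X \ge \mathrm{list\_hits})$. The EASE score removes one gene from the
overlap cell first: $P(X \ge \mathrm{list\_hits} - 1)$. This jackknife makes
single-gene categories exactly non-significant and is conservative
(`ease_p >= fisher_p` on every valid table, asserted over random tables in
the tests). Benjamini–Hochberg adjustment is applied to the EASE scores
across all tested terms within a class; terms with fewer than two annotated
background genes are skipped as vacuous. Both classes are tested separately
against the shared background. GO-hierarchy propagation is deliberately not
performed: terms are tested exactly as annotated, and term identifiers are
opaque strings.

## The in-silico digest

HpaII and MspI are isoschizomers cutting C^CGG; HpaII is blocked by
methylation of the internal cytosine on either strand, MspI is not. The
digest model is deliberately minimal: linear molecules; 0-based coordinates
with cuts as inter-base offsets; exact motif matching (an N in a window
prevents a match); HpaII blocked when the internal C is masked on the forward
strand or its reverse-strand partner (the G one base further) is masked; MspI
fully insensitive. MspI's partial sensitivity to outer-C methylation observed
in some vertebrate contexts is documented as out of model. The assay readout
is the high-molecular-weight mass fraction — the proportion of total sequence
length in fragments of at least `hmw_threshold` bases — and the methylation
signal of a molecule is that fraction under HpaII minus under MspI. The
threshold is a resolution parameter with no canonical value (a gel's
resolution is not a number); callers set it relative to their expected
fragment scale, e.g. 500 bp for genomes whose unmethylated fragments are a
few hundred bases. The model guarantees, and the tests assert, that fragment
lengths always sum to the molecule length, that the HpaII cut set is a subset
of the MspI cut set under every mask, and that the signal is monotone
non-decreasing in nested masks.

## What the simulator emulates — and what it does not

The evolution model is a discrete-round approximation of deamination-driven
CpG erosion. Per round, the CpG context is re-evaluated (so newly created
CpGs become hypermutable, as in the biological mechanism); each CpG-context C
deaminates to T — and each CpG-context G, standing in for its reverse-strand
partner C, to A — with probability `min(1, base_rate * cpg_multiplier)`,
while every other site mutates to a uniformly chosen different base with
probability `base_rate`. At `cpg_multiplier = 1` every site carries the same
total mutation probability, so CpG is destroyed no faster than background and
mean CpG O/E is statistically unchanged — the null the tests calibrate
against. Multipliers above 1 emulate increasing germline methylation; mean
CpG O/E is monotone non-increasing in the multiplier.

Unigene sets emulate an EST-derived transcript collection: log-normal lengths
(median ≈ 450 bp, mean ≈ 600 bp, clipped to 101–4,278 bp — the shape of the
law beyond its mean and range is a documented choice), ancestral G+C of 0.42
as typical for insect transcriptomes, and a two-population structure with a
configurable methylated proportion. The default regime — base rate 0.01 per
site per round, 40 rounds, multipliers 4 (methylated) and 1.3 (unmethylated)
— was calibrated once so the class mean CpG O/E values land near 0.4 and 0.9,
the canonical positions of the two modes in a gene-body-methylated insect
transcriptome; these are simulation dials chosen for that phenotype, not
estimates of biological mutation rates. The unmethylated class receives a
mild multiplier above 1 because even the high mode of real data sits below 1.

The simulator does not model indels (O/E statistics are alignment-free),
codon structure or selection, EST positional sampling biases within
transcripts, or real repeat families; genomes for the digest module are
alternating random spacers and copies of a single CCGG-bearing repeat unit.
Passing the planted-truth tests therefore shows the pipeline recovers the
signal its own generative model encodes — it does not validate the biological
realism of that model, which is exactly the epistemic status such synthetic
checks can have.

## Problem sizes and numerical choices

The validation suite runs at deliberately modest scales chosen as realistic
desk-scale workloads: planted-bimodality recovery on 2,000-gene sets with 199
bootstrap replicates; null calibration of the bootstrap LRT on twenty
400-gene single-population sets at 99 replicates (the `+1`-corrected p-value
makes 99 the smallest replicate count with resolution below 0.05, and the
observed rejection rate is required to stay within sampling slack of the
nominal level, at most 0.12); oracle equivalence of the dinucleotide counter
against naive enumeration on a thousand random sequences; and digest
conservation laws on five hundred random genomes. Ties, degenerate inputs and
tolerances are fixed and documented at each function: undefined O/E is a
value with a reason code, not an exception; the posterior tie goes to "low";
bisection runs to 1e-10; EM convergence is relative 1e-8.

## Known limitations

CpG O/E is an indirect, historic signal: it integrates germline methylation
over evolutionary time and says nothing about somatic or current methylation
state, and low-CpG genes can arise from other mutational or compositional
processes. The mixture model assumes Gaussian components on the O/E scale;
heavy tails or skew would distort the boundary. The digest model is
qualitative (no partial digestion kinetics, no fragment-size measurement
error), so it supports reasoning about assay logic, not gel densitometry.
Enrichment treats GO terms as independent flat labels; correlated terms
inflate neither the EASE score nor its FDR adjustment beyond what
Benjamini–Hochberg tolerates, but ancestor terms are not aggregated.
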