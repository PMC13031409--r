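---
title: "Dual SNP panel design and power evaluation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual SNP panel design and power evaluation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtpanel)
```

`gtpanel` evaluates targeted amplicon SNP panels for two jobs that pull in
opposite directions: separating two hybridising species (which wants loci
near fixation for opposite alleles) and assigning parentage within one of
them (which wants loci as heterozygous as possible). This vignette
documents the models behind each stage, the parameters that matter, and
the design decisions taken where more than one defensible choice existed.

## Marker statistics

Between-species divergence is measured per locus by the Weir–Cockerham
estimator θ = a/(a + b + c), computed from the two-population variance
components (among populations, among individuals within populations,
within individuals) using observed allele and heterozygote frequencies.
Negative estimates are kept unclipped so that ranking reproduces the
behaviour of the standard per-site VCF tooling; loci monomorphic across
both samples, or with fewer than two called genotypes in a sample, are
returned as `NA` and flagged rather than silently scored 0. The test
suite checks the closed form against an independent route — the
hierarchical ANOVA mean squares over per-gamete allele indicators — to
1e-12 on random tables.

Within-species diversity uses the unbiased pairwise-difference form
π = (n² − Σᵢnᵢ²)/(n(n−1)) over called alleles, which for a biallelic SNP
is the unbiased expected heterozygosity.

Selection proceeds: one SNP per contig (keeping the criterion maximiser;
position breaks ties), greedy linkage thinning that drops any candidate
within 50 cM of an already-retained locus on the same linkage group
(strict `<`, so a pair at exactly 50 cM survives; unmapped loci pass
through), a 15-bp minimum flank on both sides, then independent top-N
ranking by θ (S panel) and π (P panel). Panels may overlap; the overlap is
reported rather than resolved, since no principled tie-break exists
between the two objectives.

## Primer thermodynamics

Melting temperatures use the unified nearest-neighbour parameter set with
an entropic salt correction of 0.368·(L−1)·ln[Na⁺] and
Tm = 1000ΔH/(ΔS + R ln(C_T/4)) for bimolecular duplexes. Defaults — 50 mM
monovalent salt, 250 nM total oligo — are configurable and logged in every
run manifest, because the published screening contract is the rule
thresholds (58–64 °C primer window, > 15 °C 3′-decamer cross-dimer
rejection, > 50 °C hairpin rejection), not absolute temperatures.

Two interpretations were open:

- The cross-dimer rule is applied as the best gap-free complementary
  duplex between the candidate's 3′-terminal 10 bases and each accepted
  primer, in either orientation; the duplex Tm of the longest
  complementary run is compared against 15 °C.
- Hairpin stability is evaluated unimolecularly (Tm = 1000ΔH/ΔS, no
  concentration term) over all stems of ≥ 3 bp with loops of 3–8 nt, with
  a fixed loop-entropy penalty of −10.5 cal/(mol·K). Without a loop
  penalty every 3-bp stem would nominally melt above 50 °C and no primer
  would survive; the chosen value corresponds to the standard ≈ +3.2
  kcal/mol loop initiation at 37 °C.

Pool assembly is sequential-greedy in the caller's locus priority order —
the first candidate pair passing hairpin and cross-dimer screens against
the accepted pool is taken — and is therefore order-dependent;
`audit_pool()` re-checks the final pool pairwise, which is
order-independent.

## Ratio-based genotype calling

With allele read counts (n₁, n₂) and r = n₁/n₂: depth < 10 is uncalled;
r ≥ 10 and r ≤ 0.1 are the homozygote zones; 0.2 ≤ r ≤ 5 is the
heterozygote zone; the gaps (0.1, 0.2) and (5, 10) are ambiguous and stay
uncalled. These windows reproduce the documented defaults of the reference
amplicon-genotyping pipeline and are fully configurable; all thresholds
are echoed into output metadata. Calling is deliberately scale-aware, not
scale-invariant: (6, 1) fails the depth floor while (60, 10) fails the
ratio windows.

Loci with duplicated (tetrasomic) copies produce intermediate dosage
ratios (e.g. 1:3) that pile up in the ambiguous zones. The published
screen for this is visual; `flag_ratio_anomalies()` formalises it as
"> 10% of depth-passing samples in the ambiguous zones" (with ≥ 20
assessable samples). The 10% default is a package choice, exposed as an
argument.

## QC filters

The concordance score between a reference and a new genotype set takes
values 2 (identical), 1 (reference missing), 0 (new missing), −1 (both
missing), −2 (discordant); loci are retained when discordant cells are
fewer than five per 85-sample comparison (`max_discordant = 4`). The
heterozygote-excess filter is a one-sided exact (Levene) test within the
focal population — excess heterozygosity being the signature of collapsed
duplicated loci — at α = 0.05, with a 20% missingness ceiling; neither
constant is dictated by the workflow being reproduced (which reports only
"significant excess heterozygosity" and "high missing data"), so both are
arguments with those defaults. Imputation replaces missing cells by the
modal genotype of the sample's population at that locus (ties resolve to
the lexicographically smallest allele pair) and is intended only to
complete matrices for simulation, never for empirical inference.

## The six-class hybrid model

Two generations of crossing between two source populations produce six
distinguishable classes; each is summarised by the proportions
φ = (φ_AA, φ_AB, φ_BB) of loci whose two gene copies descend from (A,A),
(A,B) or (B,B): pure A (1,0,0), pure B (0,0,1), F1 (0,1,0), F2
(¼,½,¼), backcross-to-A (½,½,0), backcross-to-B (0,½,½). Genotype
probabilities follow by mixing Hardy–Weinberg products of the parental
frequencies through φ.

The reference workflow classifies with a Gibbs-sampling mixture model that
estimates allele frequencies jointly with class membership. This package
instead fixes parental frequencies from the curated, anchor-designated
baseline and computes the plug-in posterior. The approximation is
justified when the anchored baseline is large (hundreds of individuals per
species, as in the intended use), and it buys determinism given the
baseline plus auditability: the classifier is checked against brute-force
enumeration of the mixture likelihood on small panels. Baseline
frequencies are smoothed with a pseudo-count of 1/(2n+2) per allele so a
genotype carrying an allele unseen in one population never contributes a
−∞ log-likelihood. The class prior is uniform over the six classes.
Markers are treated as unlinked, as the mixture model assumes; no linkage
correction is attempted.

`curate_baseline()` applies the anchored-classification curation step:
frequencies are computed only from designated individuals, every sample is
classified, and samples whose posterior for their designated (or, for
undesignated samples, their population's) pure class falls below the
threshold (default 0.99) are excluded.

## Parentage LOD and Delta

The parent-pair LOD is the log likelihood ratio of "candidate pair are the
parents" to "offspring unrelated", summed over loci typed in all three
individuals. Genotyping error follows the whole-genotype replacement
convention: each observed genotype is, independently with probability e, a
random Hardy–Weinberg draw. Marginalising the three error indicators gives
the per-locus likelihood in closed form; with e = 0 a single Mendelian
incompatibility is a hard exclusion (LOD = −∞), and with e > 0 all scores
are finite. Allele-level error is deliberately not modelled — "mistyped
locus" is the unit of error in the simulation tradition this follows.
Numeric parity with any specific external program is not claimed; the
implementation is validated against exhaustive enumeration over true
genotypes on small cases.

Δ is the LOD gap between the best and second-best pair (a lone candidate
pair takes its own LOD as Δ, so assignment remains defined). The critical
Δ* at confidence c is the smallest threshold such that, among offspring
with Δ ≥ Δ*, the fraction whose best pair is the true pair reaches c;
it is 0 when the unthresholded fraction already does, and it is found by a
scan over distinct Δ values (whole tie groups included), matched in tests
against a brute-force scan.

Simulations draw candidate parents from Hardy–Weinberg frequencies, create
offspring by Mendelian transmission, and apply typing (probability t per
locus) and corruption (probability e) to offspring genotypes; candidate
parents are treated as fully typed, reflecting broodstock-quality
genotyping — offspring typing is the sensitivity axis of interest. With
probability 1 − s both true parents are removed from the candidate pool
(an unsampled pair can never be correctly assigned, which bounds the
assignment rate by s). Offspring typed at fewer than the minimum fraction
of loci are dropped and count as unassigned, so assignment rates are
proportions of all simulated offspring — this is what makes small panels
deteriorate when the minimum-typed threshold rises.

## What the synthetic generators emulate — and what they do not

`simulate_baseline_pair()` uses the Balding–Nichols model: per-locus
ancestral frequencies uniform on [0.05, 0.95], population frequencies Beta
with mean at the ancestral draw and scale (1−F)/F, genotypes in
Hardy–Weinberg proportions. F is the single divergence dial; F = 0.3
produces a θ spectrum whose upper tail resembles strongly diverged species
pairs. `make_species_panel()` skips the spectrum and directly constructs
the two panel signatures: S-like loci with |p_A − p_B| ≥ 0.8 by default
(the near-diagnostic tail that survives ranking; any locus with contrast
≥ 0.5 is species-informative), and P-like loci with expected
heterozygosity ≥ 0.4 in population A. Read counts are negative binomial
(dispersion 5 — amplicon pools are overdispersed; the true depth law of
any given chemistry is instrument-specific) with binomial allele split and
per-read error flips.

Real data differ in ways these generators do not model: physical linkage
between panel loci, locus-specific amplification bias and allele-specific
dropout, index hopping, null alleles, and population structure within each
species. Passing the simulation-based tests therefore demonstrates
correctness of the statistical machinery under the stated models, not
field performance of any particular wet-lab panel.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 155-locus S panels and
112-locus P panels (the dual-panel sizes of the motivating application),
30 individuals per hybrid class, 1,000 simulated offspring against
100 × 100 candidate parents, and 100× mean read depth — sizes at which
every stochastic check is stable across seeds while the whole suite runs
in well under a minute. Posteriors are normalised in log space
(subtract-max), frequency maps must sum to 1 within 1e-9, and all
generators are reproducible from a single integer seed.

## Known limitations

- Biallelic loci only in θ and the parentage machinery (the genotype
  containers and frequency code handle multi-allelic markers, as needed
  for comparison panels read from Genepop files).
- The plug-in classifier understates posterior uncertainty relative to the
  full Bayesian treatment when baselines are small.
- Single-parent (sex-unknown) assignment is not the default analysis;
  parent pairs with known sexes are.
- The primer screen is a rule-based filter, not a thermodynamic partition
  function; it reproduces screening decisions, not free-energy landscapes.
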