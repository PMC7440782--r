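---
title: "Finding fungal signatures of building moisture damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding fungal signatures of building moisture damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycodamp)
```

## The problem

Damp and moldy buildings are associated with asthma and other respiratory
disease, yet no quantitative microbiological measurement reliably
identifies a water-damaged building. Indoor dust contains an enormous,
noisy background of fungi — most of it blown or tracked in from outdoors —
and the signal of indoor growth on damp materials is subtle. `mycodamp`
implements a set of targeted and untargeted analyses for finding that
signal in ITS amplicon count tables, together with a synthetic-study
generator with known ground truth so every stage of the pipeline can be
validated end to end.

The targeted idea is biological: fungi differ enormously in the substrate
moisture they need to grow, quantified by water activity (a_w, the vapor
pressure of water in a material as a fraction of the saturation vapor
pressure; equal to equilibrium relative humidity / 100, see `rh_to_aw()`).
Xerophiles grow on barely damp materials (minimum a_w below 0.80),
mesophiles at intermediate moisture (0.80 to 0.90), and hydrophiles only
on wet materials (0.90 and above). If a building is damp enough to support
indoor growth, the guilds that can exploit that moisture should be
over-represented relative to the total community. A second targeted
aggregate is the ERMI group-1 set — taxa reported at higher levels in
water-damaged homes in national surveys.

## The moisture-guild reference

`read_guild_reference()` loads a curated table of species with
citation-level minimum a_w values. For each species the overall minimum
and the mean of citation minima are derived; classification uses the
**mean** (`classify_guild()`), with both thresholds inclusive at the lower
edge of the wetter group (0.90 is hydrophilic, 0.80 is mesophilic). When
the overall minimum and the mean straddle a threshold, the mean wins; both
are retained in the exported table. A four-group scheme that splits the
xerophiles is available through `guild_scheme(xero_split =)` but is not
the default and not used by the standard analyses.

The reference bundled with the package (`mycodamp_reference()`) is a
**synthetic stand-in** for the published curated lists, built to their
documented structure: 108 a_w species classifying 18/61/29 into
hydrophilic/mesophilic/xerophilic, and an ERMI group 1 of 43 taxa of which
26 appear on the a_w list (4 hydrophilic, 8 mesophilic, 14 xerophilic).
Species names are real indoor-relevant fungi and the a_w minima are
realistic, but individual values are synthetic; analyses of real data
should substitute a genuinely curated file in the same TSV schema. Name
lookups (`normalize_name()`) are case- and whitespace-insensitive and fall
back to registered synonyms, because a large fraction of species curated
from older growth literature have since been renamed; an unknown name is
an explicit no-match, not an error. Synonym ambiguity (one synonym
pointing at two records) is rejected at load time rather than resolved
silently.

## The abundance model

Counts of a taxon group g in sample i are modeled as

  y_i ~ NegBin(mu_i, theta),  log mu_i = beta_0 + sum_k beta_k 1[x_i = k] + log N_i

where x is a categorical building-damage indicator with the no-damage
category as reference and N_i is the sample's **total** read count. The
offset converts count modeling into modeling of relative abundance, so
exp(beta_k) is the multiplicative change in the group's share of the
community at damage level k (`relative_change()`). Microbial counts are
overdispersed (variance well above the mean), which is why the negative
binomial is used rather than the Poisson; `compare_poisson_nb()` makes the
AIC comparison explicit for any particular response. Grouped (guild or
group-1) counts contain few zeros, so no zero adjustment is applied —
per-taxon models would need a zero-adjusted variant, which is out of
scope.

`fit_nb()` estimates theta by the alternating maximum-likelihood algorithm
of `MASS::glm.nb` (IRLS for the coefficients interleaved with a score step
for theta), with convergence tolerance 1e-8 and a 100-iteration cap. When
the dispersion diverges because the data are essentially equidispersed,
the fit is taken at the Poisson limit with a large fixed theta (1e6); a
genuine IRLS failure is an error. AIC counts theta as a parameter.

Inference follows the level count of the indicator: two categories use a
two-sided Wald Z test on the coefficient (`wald_z_p()`); three categories
use a two-degree-of-freedom likelihood-ratio chi-square of the full model
against the intercept-only reduced model (`lrt_2df()`). No
multiple-testing correction is applied across indicators or groups — the
screen reports per-model p-values, and with dozens of models per run some
small p-values are expected by chance; treat the output as hypothesis
generation, not confirmation.

Two abundance scales are supported. Relative abundance (the default) uses
the offset as above. Absolute abundance multiplies the group's share by
the sample's total fungal biomass from qPCR and models the rounded load
without an offset; it is only defined for vacuum and dust-fall samples,
whose standardized collection areas make biomass comparable — requesting
it for door-trim swabs is an error. Loads are rounded to the nearest
integer before fitting; with biomass scales of 1e3 and above the rounding
error is negligible.

## Damage indicators

`derive_home_indicators()` produces the eight standard home-level
indicators from researcher inspection records: visible mold (yes/no),
number of separate mold areas (0/1/2+), total mold area category with the
house cut at 1.9 m2 (the boundary falls in the high category), the same
three for mold-plus-other damage (cracking paint, peeling materials,
water maps), whether any moisture-meter reading exceeds 15 (strictly), and
a composite index in 0–6 summing an area-count score (0/1/2), an area-size
score (0/1/2, reusing the house cuts — the only cuts defined), an
any-elevated-reading score and a condensation-with-growth score. The
composite counts **mold** areas only, since its components are named for
mold; observations with zero recorded area never contribute. Room-level
analysis (`derive_room_indicators()`) uses the four mold/size indicators
with the 0.9 m2 cut.

## Untargeted comparisons

*Indoor-outdoor distance.* Outdoor dust-fall samples are pooled into one
composite profile per location-season pairing by averaging per-taxon
relative abundances and renormalizing (`pool_outdoor()`); each indoor
sample is compared against the composite of its own location and season
(`match_and_measure()`) with the Bray-Curtis dissimilarity
sum|p−q| / sum(p+q). Distances are computed on **relative abundances**, not
raw counts, because indoor sample types differ greatly in depth and most
comparisons cross collection methods; this also makes the distance
invariant to rescaling either sample. Distance distributions across damage
levels are compared with rank tests — Wilcoxon-Mann-Whitney for two
categories, Kruskal-Wallis for three — and the 0.1% rare-taxon filter
(`filter_rare()`) can be applied first.

*Indicator taxa.* `ancom_w()` implements an ANCOM-style compositional
screen: for each taxon, the additive log-ratios log((x_i+1)/(x_j+1))
against every other taxon are compared between groups with two-sided
Mann-Whitney tests, the per-taxon p-values are Benjamini-Hochberg
adjusted, and W is the fraction rejected at alpha = 0.05; detection uses
the loose cutoff W ≥ 0.6. The pseudocount, per-pair test, BH adjustment
and alpha follow the cited method's common usage. Alpha diversity
(observed richness, Shannon in nats, inverse Simpson) is compared between
two damage groups with Welch t tests; Welch was chosen over Student's
because group variances are not assumed equal, and the natural log is used
for Shannon.

*Contaminants.* Negative-control samplers allow prevalence-based
contaminant flagging before any analysis. The score for an ASV is
P_c / (P_c + P_t) with P = (k + 0.5)/(n + 1) the shrunk presence fraction
in controls (c) and true samples (t); an ASV is flagged at score ≥ 0.5.
This is a transparent approximation of the referenced prevalence method,
monotone in control prevalence and anti-monotone in true-sample
prevalence, with 0.5 the indifference point.

## The synthetic-study generator

`generate_study()` emulates the design of a two-borough, two-season home
survey: 60 inspected homes (75% resampled in summer), roughly half with
visible mold damage, per home one vacuum and one dust-fall sample plus two
to four door-trim swabs per season, outdoor dust-fall pools of 10/21/7/3
samples for Brooklyn-winter / Brooklyn-summer / Manhattan-winter /
Manhattan-summer, three unexposed control samplers, and qPCR biomass for
the standardized sample types. Species names are drawn from the bundled
reference so the generated taxonomy resolves against it; a few species are
deliberately represented by two ASVs, and a quarter of ASVs carry no
species-level call, as in real amplicon tables.

Counts are negative binomial (default theta = 2) around per-taxon expected
shares at a uniform random depth of 10k–50k reads. Baseline taxon
abundances are lognormal (sd 1 nat within a guild block) and the guild
blocks are calibrated so the expected undamaged community shares match the
sequence shares reported for guild subsets of a real indoor survey —
about 3% hydrophilic, 20% mesophilic, 6% xerophilic — with the remainder
in unclassified and group-1-only taxa. Damage effects are defined on the
scale the models estimate: in a damaged home, the expected **share** of
each affected set is multiplied by exactly its configured effect
(defaults: hydrophiles x2.5 and mesophiles x0.5 in vacuum dust, ERMI
group 1 x3.2 in door-trim swabs) and the unaffected taxa absorb the
compensation. A naive "multiply and renormalize" construction would
instead realize the effect diluted by the affected set's community share,
leaving the ground truth dependent on the random baseline draw; the
exact-share construction keeps the configured effect equal to the
estimand. Configurations whose effects leave no room for the unaffected
taxa are rejected as infeasible.

Inspections are generated consistently with damage status: damaged homes
draw one to three visible-mold areas with lognormal sizes spanning both
size categories, elevated moisture readings and window condensation with
growth occur only in damaged homes (so an all-undamaged cohort has
composite index 0 everywhere), and "other damage" occurs in damaged and
undamaged homes alike. qPCR biomass is proportional to the sample's
unnormalized community weight with lognormal noise (CV 0.3), so
damage-driven growth raises measured biomass.

What the generator does **not** emulate: taxon-to-taxon correlation
beyond compositional closure, seasonal community turnover, spatial
room-to-room structure, sequence-level artifacts (chimeras, index
hopping), and taxonomy errors. Passing tests therefore demonstrate that
the analysis recovers planted effects under the stated count model — not
that real buildings behave this way.

## Numerical choices and problem sizes

Determinism: every stochastic function takes a seed, and `run_all()`
writes byte-identical outputs for the same configuration and seed, with a
provenance header (package version, seed, config hash) on every TSV.
Model levels with fewer than two samples are dropped before fitting, and
indicators left with a single level are skipped. The validation suite
sizes its simulations for quick, stable runs: 1000 replicates for test
calibration (type-I error of Wald and LRT), 50 replicates for rate-ratio
recovery at n = 200 and for the ANCOM null/spike operating
characteristics, and 1000 random vector pairs for the Bray-Curtis formula
check; `scripts/acceptance.R` recomputes the same quantities from scratch
at any seed.

## A worked run

```{r example, eval = FALSE}
db <- read_guild_reference(mycodamp_reference())
study <- generate_study(scenario_config(), seed = 42)
a1 <- run_approach1(study, db)
subset(a1, sample_type == "vacuum" & indicator == "mold_damage")
```

On this seed the vacuum-dust screen estimates a relative change of about
2.5 for hydrophiles and 0.51 for mesophiles in mold-damaged homes — the
planted ground truth of 2.5 and 0.5 — with Wald p-values far below 0.05,
while xerophiles (planted effect 1) sit near 1. `run_approach2()`,
`run_approach3()` and `run_approach4()` complete the screen, and
`run_all()` writes all result tables.

## Limitations

The bundled reference is synthetic; real-data conclusions require a
genuinely curated a_w/ERMI reference. Relative-abundance effects are
compositional — an increase in one group necessarily depresses the shares
of others, which is visible in the mesophile/hydrophile opposition and is
intrinsic to amplicon data rather than an artifact of this package.
Estimates of large group shares are mildly attenuated because the group
count is part of the random total it is normalized by. Per-taxon
differential abundance near the detection cutoff should be treated as
hypothesis-generating; W values fluctuate at boundary effect sizes.
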