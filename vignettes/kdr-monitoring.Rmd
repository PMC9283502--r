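---
title: "Monitoring kdr and super-kdr pyrethroid resistance in soybean aphid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring kdr and super-kdr pyrethroid resistance in soybean aphid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrmonitor)
```

## The problem

Pyrethroids kill insects by locking the voltage-gated sodium channel (vgsc)
open. Field populations of the soybean aphid *Aphis glycines* have evolved
knockdown resistance through two non-synonymous substitutions in the vgsc-h1
heterodimer, numbered by their *Musca domestica* orthologs: L1014F (*kdr*,
codon CTT→TTT, a C→T transition at transcript position 3070) and M918I
(*super-kdr* when combined with 1014F; ATG→ATA, G→A at position 2784).
Monitoring programs need three things this package provides:

1. **Genotyping** individual aphids at both loci from molecular assays or
   Sanger consensus sequences;
2. **Association statistics** linking genotype to survival of a diagnostic
   insecticide exposure, and allele-frequency trends before and after field
   applications;
3. **Dose-response phenotyping** (LC50, resistance and synergist ratios) from
   dose-mortality bioassays.

A synthetic-data generator produces every input with known ground truth, so
the whole chain is testable end to end.

## Genotype model

Each aphid is diploid at two biallelic amino-acid loci. A call at one locus is
an unordered allele pair rendered wild-type first (`L/F`, never `F/L`); the
two-locus genotype is the nine-class string used as column headers in field
reports (`L/L:M/M` … `F/F:I/I`). Classes are assigned by a fixed rule: any
1014F without 918I is *kdr* (heterozygote or homozygote by 1014 zygosity);
1014F together with any 918I is *super-kdr* (homozygote only when both loci
are homozygous mutant); 918I without 1014F is labelled `918-only` — field
tables report such individuals as a distinct column but the literature does
not name the class, and keeping them out of the kdr/super-kdr classes
preserves the nine-column table layout. The partition is total and disjoint
over the nine concrete strings (asserted by enumeration in the tests).

Heterozygotes are represented the way Sanger sequencing sees them: a single
consensus sequence with IUPAC ambiguity codes at heterozygous positions
(Y = C/T at 3070, R = G/A at 2784 — "co-occurring peaks" in an
electropherogram), not as two separate reads. Assay simulation expands a
consensus into at most `max_het_sites = 2` ambiguous positions' worth of
concrete allele sequences; more ambiguity signals an unusable trace and is an
error rather than a guess.

## The three assay routes

**PCR-RFLP (locus 1014).** A 439 bp amplicon is located by exact,
single-occurrence primer matching (IUPAC codes in the template match a primer
base contained in their expansion; mismatch-tolerant priming is deliberately
out of scope). BstEII recognises the degenerate palindrome GGTNACC and cuts
after the first base (G^GTNACC). The susceptible allele retains the site and
digests into 154 + 285 bp; the resistant C→T allele destroys it, leaving the
undigested 439 bp product, so band patterns {154, 285}, {439} and
{154, 285, 439} call L/L, F/F and L/F respectively. Fragment lengths always
sum to the allele length.

One geometric subtlety: on an intron-less transcript, a BstEII site whose
terminal C is the variant base at position 3070 fixes the cut 154 bp into the
amplicon only if the amplicon starts at 2911. The published primer pair was
designed on genomic DNA (whose amplicon spans introns), so the synthetic
reference adopts the interval 2911–3349: length 439, the diagnostic 154 + 285
digest, and the variant at 3070 are all preserved exactly, which is the
binding contract for the assay.

A second subtlety concerns strand conventions. GGTNACC is its own reverse
complement, so site *detection* is strand-symmetric, but the G^GTNACC cut is
off-centre and leaves a 5-base 5' overhang: single-strand fragment
coordinates from the two strands differ by exactly 5 at every cut. The
published fragment sizes (154 + 285 = 439) follow the top-strand single-cut
convention, which this package uses; the property tests assert the true
duplex geometry (mirror-image cut positions offset by the overhang) rather
than literal fragment equality across strands.

**LCR (locus 918).** Two allele-specific upstream probes end at the variant
base (G for wild type, A for mutant; the mutant probe carries a 24-base 5'
extension) and ligate to a common phosphorylated downstream probe only when
the terminal base matches the template. Amplification with 17 + 18 nt tail
primers yields a 141 bp product for the wild-type allele and 165 bp for the
mutant, so {141} → M/M, {141, 165} → M/I, {165} → I/I. The published probe
sequences are not public, so the product lengths are treated as the binding
contract and the synthetic probe set is constructed to honour them.

**Direct codon calling.** The locus codon is anchored by an exact match of a
20 bp reference flank (downstream flank as fallback), extracted, expanded and
translated. One amino acid is a homozygote, two a heterozygote; more than two
expansions or a stop codon is an error. `genotype_sample()` runs all three
routes and raises a discordance error naming the conflicting calls if any
two disagree — corruption of the restriction site alone, for example, flips
the RFLP call but not the codon call.

## Association and allele-frequency statistics

**RAF.** The resistant allele frequency of a sample of $n$ diploids is
$\mathrm{RAF} = 100\,(2\,\mathrm{hom}_{mut} + \mathrm{het})/(2n)$, computed
identically from nine-class or per-locus three-class counts.

**Exact association test.** Genotype-by-phenotype tables (2 × k, k ≤ 9;
zero-margin columns dropped) are tested with the conventional two-sided exact
test: under fixed margins the table probability is multivariate
hypergeometric, and the p-value sums the probabilities of all tables as or
less probable than the observed one (ties included, with a 1 + 1e-7 relative
tolerance, matching common practice). Enumeration iterates over all first
rows consistent with the margins, leaving the largest column implicit; at the
field sample sizes this is at most a few tens of thousands of candidate rows.
Should a table exceed the enumeration budget, a Monte Carlo estimate over
Patefield-sampled null tables with a fixed, logged seed is returned and
flagged. The implementation is validated exhaustively against an independent
hypergeometric oracle and `stats::fisher.test`.

**Odds ratios and pooling.** Allele counts treat each individual's two
alleles as independent observations (no Hardy–Weinberg adjustment — the
binomial logit model below makes the same assumption). The single-location
odds ratio is the raw cross-ratio with a Wald CI on the log scale; any zero
cell triggers the flagged Haldane–Anscombe 0.5 correction. Across locations,
a binomial GLM with logit link is fitted to
`time * location` — the interaction is required: published per-location odds
ratios equal raw allele-count cross-ratios, which only a saturated model
reproduces. The pooled contrast is the equal-weight average of per-location
(post − pre) logit differences, exponentiated — the geometric mean of the
per-location odds ratios — with its variance taken from the GLM coefficient
covariance. This is exactly the estimated-marginal-means contrast, and the
tests verify it against emmeans to 1e-8. The model-based marginal RAF
reported next to the raw pooled RAF is the inverse-logit of the equal-weight
mean of per-location logit RAFs; its weighting is interpretive (the source
tables do not fully specify it) and it is labelled separately in reports.

Rounding happens only at the report layer: percentages and RAF to one
decimal, odds ratios to two, matching field-report conventions.

## Dose-response model

Mortality at concentration $x$ follows the three-parameter log-logistic law
with lower limit 0:

$$p(x) = \frac{d}{1 + (x/e)^{-b}}$$

with slope $b > 0$ (positive when mortality increases with dose), upper limit
$d \in (0, 1]$ and LC50 $e$ (µg ml⁻¹; $p(e) = d/2$ identically). Counts are
binomial, so the model is fitted by maximum likelihood rather than least
squares — the standard-error magnitudes in published resistance tables are
only consistent with binomial MLE. Replicates are pooled per concentration
(replicate-level structure is not recoverable from printed tables; the
pooling is flagged in the fit object). Dose-0 control rows are excluded from
the likelihood, only validated (a warning at ≥ 10% control mortality); no
Abbott correction is applied.

Numerical choices: optimisation works on (log b, logit d, log e); starting
values come from a coarse grid (b ∈ {0.5, 1, 2, 4}, d ∈ {0.9, 1}, e over five
log-spaced points of the dose range), the three best starts are polished with
BFGS at 1e-10 relative tolerance, and the best converged polish wins. When
the upper limit runs into its boundary (d̂ > 0.995) the model is refitted
with d fixed at 1 and the result flagged (`d_fixed`), with degrees of freedom
adjusted to groups − 2. The LC50 interval is the delta-method Wald interval
ê ± 1.96 SE(ê), truncated at 0; lack of fit is the Pearson statistic over
positive-dose groups on groups − 3 (or − 2) degrees of freedom. Resistance
and synergist ratios are ratios of LC50 point estimates, declared significant
by non-overlap of the two 95% intervals — the decision rule used in the
source analyses, conservative as interval logic but matched deliberately.

Two practical caveats the simulations make visible. First, the Pearson
lack-of-fit statistic is only χ²-calibrated when expected deaths are well
away from 0 and n in every group; dose grids spanning far beyond the response
region (expected counts ≪ 1) deflate it, so the calibration checks run on a
fully informative grid. Second, when a realised assay has partial mortality
at only one concentration the slope is weakly identified (the likelihood is
flat above some b) and its Wald SE explodes while the LC50 remains
reasonably localised; practitioners avoid this by concentrating the dilution
series around the response region, which is what the analysis scripts do.

## What the generator emulates — and what it does not

`make_reference(seed)` builds a deterministic 3,525 bp transcript (30 bp
5' UTR, then CDS) carrying the wild-type codons at positions consistent with
variant sites 3070 and 2784, exactly one BstEII site (any stray chance sites
are scrubbed), unique primer and probe sites, and emits the full assay
bundle. `sample_population()` draws two gametes per individual independently
from the four haplotype frequencies (L·M, L·I, F·M, F·I) — linkage
disequilibrium is controlled entirely by those frequencies, and no inbreeding
parameter is modelled because aphid clonal structure is not identifiable from
count tables. `render_sequences()` writes genotypes into reference copies
with IUPAC codes at heterozygous sites and optional uniform substitution
noise away from assay-critical positions. `apply_selection()` applies
per-class Bernoulli survival; `simulate_bioassay()` draws binomial deaths
from the LL.3 law. All randomness derives from one seed through named
substreams (reference, population, noise, selection, bioassay), so stages
are independently reproducible.

Defaults are fixed study conditions, chosen once: haplotype frequencies
(L·M 0.55, L·I 0.05, F·M 0.30, F·I 0.10) mirror a field spectrum that is
mostly wild-type and kdr-heterozygous with 918I riding almost exclusively on
1014F haplotypes; survival under a field application (wild type and 918-only
0.05, kdr heterozygote 0.50, kdr homozygote 0.60, super-kdr heterozygote
0.90, super-kdr homozygote 0.95) increases monotonically with resistance
class; the bioassay design is 8 concentrations over 0.0008–60 µg ml⁻¹ with
60 aphids (three replicates of 20) per concentration.

The generator does **not** emulate: chromatogram noise or base-quality
structure (consensus sequences are exact outside the injected substitution
noise); PCR or ligation thermodynamics; population dynamics, migration or
multi-generation selection; cryptic vgsc variation beyond the two surveyed
loci. Passing the end-to-end tests therefore shows the pipeline is correct
*given* clean consensus sequences and the published assay geometry — it says
nothing about primer performance on divergent field haplotypes or about
trace-calling quality, which are wet-lab properties.

## Problem sizes used by the checks

The test-suite simulations use cohorts of 2,000 (selection direction, 20
seeds), 10⁵ (selection calibration against the analytic
$f_g s_g / \sum_h f_h s_h$ limit), 200 replicate assays for LC50 interval
coverage at the 8 × 60 design, and 500 replicates for χ² calibration at 240
aphids per dose. The exact-test validation sweeps every 2 × 2 table with
positive margins up to n = 30 against a vectorised hypergeometric oracle,
every 2 × 3 margin class up to n = 15 (spot-checking up to six tables per
class), and 200 random 2 × 3 tables up to n = 30 against
`stats::fisher.test`.

## Known limitations

- The exact test's printed reference values in the source field study could
  not be reproduced from the printed count tables by any conventional
  two-sided exact test (this package and `stats::fisher.test` agree with each
  other throughout); the discrepancy is asserted visibly in the acceptance
  tests rather than papered over.
- Wald intervals (LC50 and log-OR) degrade under weak identification; no
  profile-likelihood intervals are provided.
- The Monte Carlo fallback of the exact test estimates, rather than bounds,
  the p-value; it is flagged and seed-logged whenever used.
- Loci other than 1014/918 (e.g. M918T, L925M reported elsewhere) can be
  declared via `resistance_locus()` and the DCF config, but no resistance
  class semantics are defined for them — classification is specific to the
  two surveyed loci.
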