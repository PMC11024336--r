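---
title: "Eplet mismatch, immunosuppression and allosensitization after kidney graft failure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eplet mismatch and allosensitization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epletrisk)
```

## The problem

When a kidney transplant fails and the patient returns to dialysis, the
failed graft remains an immunological stimulus. Many patients develop
anti-HLA antibodies against it (allosensitization), which shrinks the pool
of compatible donors for a repeat transplant. Two candidate risk factors
dominate the clinical question this package operationalizes: the *eplet
mismatch load* between the failed donor and the recipient — eplets being
small polymorphic surface patches of the HLA molecule treated as the unit
of antibody recognition — and the intensity of *maintenance
immunosuppression* kept after failure.

`epletrisk` implements the full analysis chain as composable, separately
tested stages: HLA data model → eplet mismatch → antibody/DSA calls →
cPRA and meaningful-change outcome → immunosuppression classification →
association statistics, plus a synthetic-cohort generator and a CLI.

## Models and procedures

### Eplet mismatch

For a locus group $G$ (class I, DR, DQ, DP) the recipient repertoire is the
union of eplet sets of all alleles carried at the loci of $G$; the mismatch
set is

$$ M_G = \bigcup_{a \in \text{donor}(G)} E(a) \;\setminus\;
   \bigcup_{b \in \text{recipient}(G)} E(b), $$

with $E(\cdot)$ the registry lookup. Counting is set-based: an eplet shared
by several donor alleles counts once, and homozygosity carries no weight
(copy number never matters for antibody targets). Direction is
donor-minus-recipient because antibody responses target donor eplets the
recipient does not carry. Counts of 0–11 are LOW, 12+ HIGH — the published
threshold for both DR and DQ; class I and DP have no established cut, so
their categories at the shared default should be read as descriptive only.

The eplet registry is a pluggable TSV (`allele`, `eplet`). Lookup tries the
exact canonical allele string, then its two-field truncation; unresolved
alleles are a hard error by default because silently scoring them as
eplet-free would bias counts toward zero. The registry version string is
carried into all mismatch output.

### Antibody calls and de novo DSA

A bead defines an unacceptable antigen when MFI is *strictly* greater than
1000 (a bead at exactly 1000 is negative). Antigen identity is the
*antigen key*: locus plus first allele field (`DQB1*03:01 → DQB1*03`).
True serologic split/broad tables would need external data that is out of
scope here, and allelic-level antibodies are likewise excluded, so the
first-field class is the package's deterministic antigen-level stand-in —
a documented approximation, not a claim about serology.

A de novo DSA event for a donor-mismatched antigen key requires (i) at
least one above-threshold detection after the transplant date and (ii)
negativity on *every* pre-transplant panel ("de novo" means absent before
transplant, not merely before the latest sample). Timing is classified
against a baseline window ending 31 days after graft failure (a baseline
serum drawn up to one month post-failure still describes the failure
time-point): detections only inside the window are PRE_FAILURE, only after
are POST_FAILURE, otherwise BOTH. Beads whose key equals a recipient
self-key are flagged and dropped — at first-field resolution they are
self-reactivity artefacts. A missing pre-transplant baseline panel yields a
warning and a no-preformed-DSA assumption (an error in strict mode).

### cPRA and the meaningful change

cPRA is computed against an explicit reference panel of donor phenotypes:
the percentage of panel donors carrying at least one unacceptable antigen.
Registry calculators use population haplotype frequencies instead; the two
coincide when the panel enumerates the population (a property tested
against a closed-form oracle on a fully enumerated toy population). The
panel file is configuration, so any population can be substituted.

The outcome statistic is the relative reduction of the compatible donor
pool, $\text{pool}(c) = 100 - c$:

$$ R = 100 \times \frac{\text{pool}(c_{\text{base}}) -
  \text{pool}(c_{\text{last}})}{\text{pool}(c_{\text{base}})} , $$

and a *meaningful* cPRA change (mcPRA) is $R \ge 50$, boundary inclusive.
This normalizes the very different clinical impact of the same absolute
rise: 0% → 2% reduces the pool by 2%, while 96% → 98% halves it. The
smallest last cPRA triggering the flag has the closed form
$100 - 0.5\,\text{pool}(c_{\text{base}})$ — 50% from a baseline of 0% and
98% from 96%. A baseline of 100% has an empty pool, so the relative change
is undefined and reported `NA` rather than forced to a value; such patients
are excluded from mcPRA tables and listed. Negative reductions (cPRA fell)
are reported as-is and never flag.

### Immunosuppression classification

Exposure after failure is *reduced* if any of: a complete-withdrawal
interval exists; a CNI-containing interval is followed by CNI-free
intervals (cessation); or the average CNI trough is below 5 ng/mL. The
average is the unweighted mean of all measurements inside CNI intervals —
a single per-patient average without weighting detail is the convention
being mirrored — with a time-weighted variant behind a flag. An average of
exactly 5 ng/mL is maintained (the maintained reference group is defined
by troughs ≥ 5). This three-criterion composite is this package's
operationalization; it is stated as such rather than as an external
standard. Nephrectomy is not modelled (annotation-level in the source
setting, no role in classification).

### Association statistics

The module is self-implemented so the analysis has no hidden dependence on
a particular statistics environment, with mainstream implementations used
as test oracles only:

* **Fisher exact (two-sided)** — point-probability method: with margins
  fixed, sum the hypergeometric probabilities of all tables whose
  probability is ≤ that of the observed table. Probabilities are compared
  with relative tolerance `1e-7` so floating-point ties at symmetric
  tables are included; a zero margin returns p = 1 with a warning.
* **Two-sample t** — Welch by default (the variant used is not always
  reported in small clinical studies; both are exposed), two-sided p from
  the t distribution.
* **Median/IQR** — linear-interpolation quantiles (type 7). The convention
  is documented because the source cohort's IQRs are not reproducible
  anyway (confidential data); what matters is internal consistency.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mfi_threshold` | 1000 (strict >) | MFI | laboratory policy cut for unacceptable antigens; also reused for dnDSA calls (no separate published value) |
| `eplet_threshold` | 12 | eplets | published DR/DQ low (0–11) vs high (12+) cut |
| `hsp_cutoff` | 94.50 (inclusive) | % cPRA | highly-sensitized registry definition |
| `trough_cutoff` | 5 (at-cut = maintained) | ng/mL | trough below which dnDSA risk rises |
| `mcpra_cutoff` | 50 (inclusive) | % pool reduction | definition of a meaningful cPRA change |
| `baseline_window_days` | 31 | days | baseline serum accepted up to 1 month post-failure |

All six live in one `pipeline_config()` object, giving sensitivity
analyses for free.

## The synthetic cohort: what it emulates and what it does not

The study data this pipeline is designed for are confidential, so the
generator produces a *stated world* with the same structure: n = 21 pairs
by default, transplant-to-failure intervals of 50–123 months, post-failure
antibody follow-up uniform on 12–42 months (median 27), and a 500-donor
reference panel. Genotypes are two independent draws per locus from
compact common-allele frequency tables (random mating, no linkage
disequilibrium); DRB3/4/5 include a null pseudo-allele. The synthetic
registry gives every allele of a first-field class the same eplet count
(drawn once per class from 5–10) with half shared across the class — the
5–10 load keeps DR/DQ group mismatches on both sides of the threshold of
12, mirroring the near-even low/high split of the motivating cohort.

Seroconversion is a per-patient, per-group latent Bernoulli event with

$$ P(\text{dnDSA}) = \operatorname{logit}^{-1}(\alpha + \beta_{mm}
   \cdot \text{mismatch count} + \gamma_{IS} \cdot \text{reduced}), $$

defaults $\alpha = -3.5$, $\beta_{mm} = 0.1$, $\gamma_{IS} = 1.5$, chosen
once to give a DQ dnDSA frequency near the observed ~38% at realistic
mismatch loads. Pairs with zero group mismatch or no antigen-level target
are gated to probability zero — there is nothing to respond to — so the
logistic form holds exactly *conditional on eligibility*, which is how the
parameter-recovery test fits it. Events arise pre-failure with probability
0.35 (mirroring the observed mix of pre- and post-failure dnDSA), and
pre-failure antibodies wane after the baseline draw with probability 0.5,
which is what makes the pre-failure-only timing class reachable; cPRA is
cumulative, so waning never lowers it. On an event, all beads sharing an
eplet with a donor target turn positive (epitope spreading), with MFI
uniform on [3000, 15000] versus [0, 500] for negatives — deliberately far
from the 1000 cut so calls are deterministic given the latent state.

Known departures from real data, hence what a green test does *not*
establish: no linkage disequilibrium or haplotype structure, no ethnic
stratification, no transfusion-induced third-party sensitization, no MFI
saturation/prozone behaviour, and an overall meaningful-change rate that
runs above the motivating cohort's 8/21 because all four locus groups can
seroconvert and spread. The tests establish that the pipeline measures the
generative structure faithfully (parameter recovery within 2 SE at
n = 2000; the high-DQ-mismatch + reduced-IS arm carrying the highest
meaningful-change rate), not that the generator is a demographic model of
any real population.

## Numerical conventions and degenerate inputs

* cPRA is reported at 2 decimals (the convention of national calculators,
  whose exact internal rounding is unpublished); all other arithmetic is
  full precision.
* Fisher probability ties: relative tolerance `1e-7`.
* Homozygosity is encoded as a single allele at a locus; duplicate
  genotype rows collapse; three distinct alleles at a locus is an error
  naming subject and locus.
* Empty bead panels yield an empty unacceptable set (not an error); an
  empty donor panel or empty IS timeline is an error.
* A CNI interval without trough measurements warns and drops out of the
  average; if none remain the average is `NA` and criterion (3) cannot
  fire.
* Sub-seeds for the generator stages are derived from the user seed with a
  fixed linear map mod $2^{31}-1$, so stage draws are independent yet
  fully reproducible; pipeline outputs are byte-identical across reruns.

## Design choices made where the design was open

* Antigen resolution = first allele field (see above); flagged, not
  hidden, in the DSA/cPRA docs.
* The dnDSA MFI threshold reuses the unacceptable-antigen cut of 1000
  since no separate value is published; it is configuration.
* The low/high threshold is applied to class I/DP only descriptively.
* Welch is the t-test default; pooled is one flag away.
* All-registry eplets are counted (no antibody-verified subset), with the
  registry version recorded so a verified-only registry can be swapped in.

## Limitations

The package analyzes one failed-graft episode per patient; regression
modelling, survival outcomes, multiple-testing control and
PIRCHE/EMMA-style alternative mismatch scores are out of scope. The
first-field antigen key is a stand-in for serologic equivalence tables.
Conclusions from the synthetic world transfer to real cohorts only to the
extent the generative assumptions above hold.
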