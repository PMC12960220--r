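---
title: "Inferring embryo aneuploidy and crossovers from parental haplotype transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring embryo aneuploidy and crossovers from parental haplotype transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiotrace)
```

## The inference problem

Preimplantation genetic testing (PGT) genotypes a few trophectoderm cells
of a day-5 blastocyst on a SNP array, alongside DNA from both parents. At
each biallelic SNP the embryo contributes a B-allele frequency (BAF), the
fraction of array signal attributable to the alternate allele. Its
expectation is the alternate-allele dosage among the chromosome copies the
embryo actually inherited, divided by the copy number. Whole-chromosome
gains and losses therefore reshape the BAF distribution (a trisomy places
heterozygous-site signal at 1/3 and 2/3, a monosomy at 0 and 1), and a
switch in which parental haplotype is being transmitted marks a meiotic
crossover.

`meiotrace` models both phenomena jointly with a hidden Markov model over
the *transmitted parental haplotypes*. Given phased parental genotypes
(four haplotypes m1, m2, p1, p2), the hidden state at a SNP is the multiset
of haplotypes present in the embryo. Six per-chromosome copy-number
hypotheses are scored:

| hypothesis   | copies | states | composition                     |
|--------------|--------|--------|---------------------------------|
| nullisomy    | 0      | 1      | none                            |
| monosomy_m   | 1      | 2      | one paternal (maternal lost)    |
| monosomy_p   | 1      | 2      | one maternal (paternal lost)    |
| disomy       | 2      | 4      | one maternal + one paternal     |
| trisomy_m    | 3      | 6      | two maternal + one paternal     |
| trisomy_p    | 3      | 6      | one maternal + two paternal     |

Same-parent copy pairs are unordered multisets ({m1,m1}, {m1,m2},
{m2,m2}), which is what makes trisomies identifiable by *parental
homologue content*: both homologues present near the centromere (BPH) is
the signature of a meiosis-I-type error, a single homologue at the
centromere with BPH confined to distal recombinant segments indicates a
meiosis-II-type error, and a single homologue everywhere (SPH) a mitotic
duplication.

## Emission and transition models

**Emissions.** Observed BAF at a site with state dosage $\mu$ is modelled
as a two-component mixture

$$ b \sim \pi_0\,\mathrm{U}(0,1) + (1-\pi_0)\,\mathrm{TN}(\mu,\sigma;[0,1]), $$

a truncated normal around the dosage plus a uniform "outlier" component
absorbing array artifacts and contamination. Missing BAF contributes a
constant likelihood, as does the nullisomy hypothesis (no dosage signal).
The uniform floor deliberately caps the likelihood ratio any single site
can contribute (at most roughly $(1-\pi_0)/( \pi_0) \cdot \phi(0)/\sigma$),
which keeps one aberrant probe from moving a crossover breakpoint — this
cap is exploited again when resolution intervals are reported (below).
$(\sigma, \pi_0)$ are estimated per embryo by grid search
($\sigma \in \{0.05,\dots,0.30\}$ step $0.025$;
$\pi_0 \in \{0.01, 0.05, 0.1, 0.2, 0.35, 0.5\}$) maximizing the summed
disomy forward log-likelihood; the grid matches the coarse identifiability
of these nuisance parameters and avoids optimizer fragility.

**Transitions.** Between adjacent SNPs separated by $d$ cM (linear
interpolation on a genetic map, terminal clamping), each transmitted copy
switches its source haplotype independently with the Haldane recombination
fraction $r = (1 - e^{-2d/100})/2$. Interference is negligible at
inter-probe scales, so a memoryless map function suffices. Multi-copy
transitions are polynomials in $r$: the probability of moving between
state multisets is $\sum_h N_{ij}(h)\, r^h (1-r)^{k-h}$, where $N_{ij}(h)$
counts ordered per-copy switch assignments — computed once per hypothesis
and evaluated per gap inside the compiled forward/backward/Viterbi
recursions. The initial distribution is uniform (haplotypes are
exchangeable a priori).

## Calling

Per chromosome, hypothesis posteriors are proportional to
$e^{\log L_h}\,\mathrm{prior}(h)$ with a uniform default prior; the argmax
is called when its posterior reaches $\tau = 0.9$ (configurable),
otherwise "nocall" — a conservative default in the absence of an
established convention. Trisomy calls are classified from the per-site BPH
posterior: mean BPH $\ge 0.5$ within $\pm 5$ Mb of the centromere gives
MI-like; otherwise any 5-Mb bin elsewhere with mean BPH $\ge 0.5$ gives
MII-like; otherwise putative mitotic. Monosomies carry no transmission
signal about their meiotic stage; they are counted as maternal meiotic
events under a configurable flag (default on), consistent with
maternal-loss accounting in clinical cohorts. Embryos with more than five
aneuploid chromosomes are flagged complex; embryos where $\ge 80\%$ of
called chromosomes are same-parent trisomies (or monosomies) are flagged
as genome-wide ploidy abnormalities (triploid/haploid patterns). Both are
excluded from cohort summaries.

## Phasing parents from sibling embryos

Clinical parental genotypes are unphased. With at least three sibling
embryos, phase is recovered from transmission: at each parent-heterozygous
site, hard-thresholded BAF (< 0.25, 0.25–0.75, > 0.75 mapping to 0/1/2 alt
alleles) yields a transmitted-allele indicator per embryo (at double-
heterozygous sites only embryo homozygotes are informative). A greedy
left-to-right chain chooses each site's phase orientation by weighted
majority vote against exponentially smoothed per-embryo haplotype scores
(memory $\lambda = 0.3$), so an isolated mis-thresholded site cannot flip
the chain. The chain is run in both directions; a chain error persists to
the end of its pass, so forward/backward disagreement localizes mis-phased
segments, which are assigned zero phase confidence. Sites phased with a
vote margin below 0.75 or on fewer than three voting embryos are treated
as unreliably phased: their BAF is masked for the HMM fits and they are
dropped from the informative set for crossover calling (resolution
intervals simply span them). The voter minimum matters at
double-heterozygous sites, where only embryo homozygotes are informative
and one or two noisy voters can otherwise fix a confidently wrong
orientation. The global orientation
per chromosome and parent remains arbitrary and is recorded; all
downstream quantities (copy number, crossover counts, BPH profiles) are
invariant to it. `analyze_family()` optionally re-phases each chromosome
using only embryos called disomic there and refits (default on), removing
contamination of the vote by aneuploid siblings.

## Crossover events and artifact filters

On chromosomes called disomic, the per-parent haplotype marginal is
hard-called at informative sites; a crossover is detected between
consecutive sites whose maximum marginal reaches $\gamma = 0.9$ where the
argmax flips. The reported interval extends each flank outward to the
nearest informative site decoded at $\ge 0.999$: because the uniform
emission component caps per-site evidence, a single aberrant site cannot
clear this stronger bar for the wrong haplotype, so the widened interval
retains the true breakpoint while staying at the scale of one informative
SNP spacing on clean data.

Two cohort filters follow. First, overlapping event clusters shared by
more than half of at least three siblings are removed: true crossovers are
meiosis-specific, whereas a parental phase error produces the same
apparent switch in every sibling (overlap rather than exact interval
identity is used because noisy flanks shift the reported SNPs slightly).
Second, embryos whose per-parent total autosomal crossover count deviates
more than 3 s.d. from the cohort parent-specific mean are excluded from
phenotype tables.

## Cohort statistics

*Aneuploidy summaries* tabulate aneuploid calls by chromosome, type and
parental origin after the embryo-level exclusions, with exact binomial
tests of the trisomy:monosomy and maternal:paternal ratios against 0.5.

*Overdispersion.* Per-patient counts of affected embryos are fitted with a
binomial GLM (logit link, maternal age + age²). The Pearson dispersion
$\varphi = \sum r_i^2/(n-p)$ is compared with a parametric bootstrap under
the fitted binomial means ($B = 999$ by default; add-one p-value
$(1+\#\{\varphi_b \ge \varphi\})/(B+1)$). Pearson rather than deviance
residuals are used because the dispersion of interest is variance
inflation on the count scale; the bootstrap makes the reference
distribution exact for the actual trial-size pattern.

*Cross-chromosome ICC.* Crossover counts are z-standardized within
chromosome (chromosome length otherwise confounds raw counts), then a
one-way random-effects ICC(1) with embryo as the grouping factor is
computed from ANOVA mean squares, with a percentile bootstrap over embryos
for the CI. On exchangeable-correlation data the estimator recovers the
generating $\rho$.

*Sequence context.* Hotspot occupancy counts events whose resolution
interval overlaps a merged hotspot interval by $\ge 1$ bp (a midpoint rule
is available); replication timing reads the covering bedGraph value at the
interval midpoint; GC content is computed over midpoint $\pm 500$ bp.

## The meiosis simulator

Because raw clinical SNP-array data cannot be redistributed, the package
ships a generative model of the statistical structure the HMM assumes,
with full ground truth. Parents are four haplotypes with per-site
alternate-allele frequencies uniform on [0.1, 0.5]; sites are a sorted
uniform draw along each chromosome. Per meiosis, crossover counts are
Poisson with mean equal to the sex-specific map length in Morgans
(default maternal 120 cM, paternal 80 cM per 100-Mb chromosome,
reflecting the roughly 1.5:1 female:male map-length ratio) and positions
uniform on the cM scale; no crossover interference and no obligate
crossover are imposed (chromosomes without crossovers are an observed
feature of real cohorts). Mis-segregation modes (MI-type with BPH at the
centromere, MII-type with centromeric SPH and recombinant distal
segments, mitotic duplication, monosomy, nullisomy, digynic triploidy)
are drawn per embryo from a configurable spectrum, default 25% of embryos
with a maternally dominated composition. BAF is synthesized from the
transmitted dosage through the same truncated-normal + uniform mixture
the HMM assumes, with defaults $\sigma = 0.1$, $\pi_0 = 0.05$
(bulk-biopsy-scale noise); this is a declared stand-in for any particular
array's noise process.

Two optional couplings create biology-like cohort structure: a shared
per-meiosis log-normal crossover propensity (inducing positive
cross-chromosome covariance within meioses) and a logit-scale coupling of
that propensity to mis-segregation risk, so low-crossover meioses are
error-prone. Both default to off; switching them on reproduces, as an
emergent property of the pipeline, the deficit of crossovers on disomic
chromosomes of aneuploid embryos.

What the simulator does **not** emulate: linkage disequilibrium and
realistic allele-frequency spectra, probe-specific bias and missingness
patterns, segmental aneuploidy, within-biopsy mosaicism, and sex
chromosomes. Pipeline accuracy on simulated cohorts therefore bounds what
the model can do when its assumptions hold, not array-platform
performance in the wild.

## The selection-proxy model

Aneuploidy risk is modelled on the logit scale as
$p_g(a) = \mathrm{logistic}(\beta_0 + \beta_1 a + \beta_2 a^2 + \beta_g g)$
for maternal age $a$ and risk-allele count $g$ (additive). The lifetime
production of chromosomally normal embryos is the weighted window average

$$ W(g) = \int_{a_0}^{a_1} f(a)\,(1 - p_g(a))\,da \Big/ \int_{a_0}^{a_1} f(a)\,da, $$

with a uniform default weight $f$ over a historical reproductive window
(default 18–35 years; tabulated fertility weights can be supplied),
evaluated by composite Simpson quadrature at a 0.05-year step (error
below $10^{-8}$ for logistic risk curves). The selection-coefficient
proxy is $s_\mathrm{proxy} = 1 - W(1)/W(0)$, and with a scaling factor
$\alpha$ relating the proxy to realized fitness, the allele is
effectively neutral when $\alpha\, s_\mathrm{proxy} < 1/(2N_e)$; the
threshold $\alpha^* = 1/(2 N_e s_\mathrm{proxy})$ is reported
($N_e = 10^4$ by default). With constant risks $p_0 = 0.30$,
$p_1 = 0.35$ the proxy is exactly $1 - 0.65/0.70 = 1/14$, which the test
suite uses as a closed-form oracle; with an age-increasing risk curve
$s_\mathrm{proxy}$ grows with the window's upper bound.

## Numerical choices and problem sizes

The forward/backward/Viterbi recursions run in compiled code with
per-site rescaling, stable on chromosomes of 50,000+ sites; Viterbi ties
break toward the lowest state index. Exhaustive path enumeration on
chromosomes of up to six sites serves as an independent oracle for the
forward likelihood across all six hypotheses. The packaged simulation
studies use cohorts of 100 families x 8 embryos with 2 chromosomes x
5,000 sites each — large enough that copy-number and origin accuracy, the
fraction of exactly recovered crossover counts, and breakpoint-interval
containment are measured on hundreds of chromosomes, while a full run
stays within a coffee break on a single core. Crossovers falling outside
the span of a parent's informative sites, or in pairs within a single
informative gap, are undetectable in principle and bound the count-exact
fraction below 100%.

## Known limitations

Trisomy states assume the two same-parent copies switch haplotypes
independently, the simplest model consistent with treating transitions as
crossovers; real MI/MII products are correlated through the tetrad.
Crossovers on trisomic chromosomes are not called (reciprocal products of
one exchange can both be transmitted, hiding the event). Monosomy meiotic
stage is not identifiable from transmission. Mosaicism is not modelled:
intermediate BAF shifts from mixed biopsies will be absorbed by the noise
model or produce nocalls. The phasing chain requires three or more
disomic siblings per chromosome and leaves a global haplotype-label flip
per chromosome and parent unresolved.
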