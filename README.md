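# meiotrace

Joint inference of whole-chromosome aneuploidy and meiotic crossovers in
IVF embryos from SNP-array B-allele frequencies (BAF) of trophectoderm
biopsies, given the parents' genotypes.

Preimplantation genetic testing data have an unusual structure: each
family contributes both parents and several sibling embryos, genotyped on
the same SNP panel. Tracing which parental haplotypes each embryo
inherited reveals, at once, chromosome gains and losses (with their
parental origin and meiotic mechanism) and the crossover recombination
events of the underlying meioses. `meiotrace` is aimed at researchers
analysing such cohorts — and at methodologists who want a fully
synthetic, ground-truthed test bed for this class of inference.

## The model

At SNP *i* the embryo's BAF is modelled as

> b_i ~ pi0 * U(0,1) + (1 - pi0) * TN(mu_i, sigma; [0,1])

where mu_i = (alternate alleles among transmitted copies) / k for copy
number k. The hidden state is the multiset of transmitted parental
haplotypes from {m1, m2, p1, p2}; six per-chromosome copy-number
hypotheses are scored (nullisomy, maternal/paternal monosomy, disomy,
maternal/paternal trisomy; 1–6 states each). Between adjacent SNPs each
transmitted copy switches its source haplotype independently with the
Haldane recombination fraction r = (1 − exp(−2d/100))/2 for a gap of d cM.
Copy-number calls maximize the hypothesis posterior; crossovers are
posterior haplotype switches on disomic chromosomes; trisomies are
classified MI-like / MII-like / mitotic from the pericentromeric
both-parental-homologues (BPH) posterior. Parents are phased from three
or more sibling embryos by transmission. Downstream, the package derives
cohort phenotypes (crossover counts, hotspot occupancy, replication
timing and GC context), a parametric-bootstrap overdispersion test of
per-patient aneuploidy incidence, the cross-chromosome intraclass
correlation of crossover counts, and a selection-coefficient proxy based
on lifetime euploid-embryo production
(s_proxy = 1 − W(carrier)/W(non-carrier), neutral when
alpha * s_proxy < 1/(2 Ne)).

## Worked example

Simulate a family of eight sibling embryos (two chromosomes, 5,000 SNPs
each; under this seed the simulator gives embryo 2 a maternal monosomy of
chr2), then run the full pipeline:

```r
library(meiotrace)

cfg <- sim_config(n_embryos = 8, seed = 11)
fam <- simulate_family(cfg)

fit <- karyohmm(fam$bafs[["embryo02"]], fam$panel, fam$map,
                centromeres = fam$centromeres)
summary(fit)
#>      embryo_id chrom       call   origin k meiotic_class posterior   loglik
#> chr1  embryo02  chr1     disomy     <NA> 2          <NA>         1 4880.194
#> chr2  embryo02  chr2 monosomy_m maternal 1          <NA>         1 5955.820

cs <- analyze_family(fam$panel, fam$bafs, fam$map,
                     centromeres = fam$centromeres)
cs
#> <callset> 8 embryos, 16 chromosome calls, 26 crossover events
```

The fit reports, per chromosome, the copy-number call with its posterior
probability (here: the maternal homologue of chr2 is missing, posterior
rounding to 1), the parental origin and meiotic class of any trisomy,
and posterior haplotype marginals from which crossover intervals are
read. `analyze_family()` phases the parents from the siblings first, and
`filter_artifacts()` then removes shared phase-error events and flags
outlier embryos before phenotype tables are built. The numbers above are
what the code prints for this seed.

A thin CLI over the same functions is installed at
`inst/cli/meiotrace` with subcommands `simulate`, `call`, `phenotypes`
and `selection`.

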