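# crisprRepair

Repair-pathway classification of CRISPR/Cas9 editing outcomes in embryo
cohorts.

## The problem

When Cas9 cuts a zygote's genome, the double-strand break is resolved by
competing repair pathways, and the allele spectrum read out of each embryo
(typically the allele table produced by Sanger-trace decomposition, one row
per allele with a percent frequency) mixes their products:

- **NHEJ** (non-homologous end joining): insertions, single-base deletions,
  and deletions without repeated sequence at the junction;
- **MMEJ** (microhomology-mediated end joining): deletions that anneal a
  short repeated sequence (here 2–25 nt) flanking the break, removing one
  repeat copy and everything between;
- **HDR** (homology-directed repair): exact reproduction of a programmed
  donor edit;
- unedited alleles.

`crisprRepair` turns per-allele indel descriptions into these categories and
aggregates them into the statistics used to characterize repair bias across
a guide panel. The key primitive is **junction microhomology = deletion
placement ambiguity**: a deletion flanked by an *m*-nt repeat can be placed
at exactly *m* + 1 coordinates that give the same edited sequence, so after
left-normalizing a reported deletion, the number of alternative placements
*is* the microhomology length

    mh(deletion) = #{equivalent placements} − 1,

and a pure deletion of ≥ 2 nt is MMEJ iff `mh_min ≤ mh ≤ mh_max`
(defaults 2 and 25). Per guide g with embryo-mean category frequencies
f̄\_NHEJ, f̄\_MMEJ, the repair-bias ratio is

    R(g) = f̄_NHEJ / f̄_MMEJ,

with R < 0.5 called MMEJ-biased, 0.5 ≤ R ≤ 2 balanced, R > 2 NHEJ-biased.

The package also ships a seeded cohort simulator with ground-truth labels
(planted repeat cassettes whose junction ambiguity is verified by exhaustive
enumeration at build time) and three off-target bookkeeping rules:
three-caller variant consensus, chimeric-read breakpoint thresholding
(support ≥ 10 / ≥ 20), and cut-site coverage loss.

## Worked example

```r
library(crisprRepair)

loc <- locus("toy", "GGGCATCATGGG")
normalize_deletion(loc, 6, 9)
#> $start [1] 3   $end [1] 6   $ambiguity_span [1] 3
detect_microhomology(loc, 3, 6)
#> $mh_length [1] 3   $mh_sequence [1] "CAT"   $mh_capped [1] FALSE
```

The reported deletion `[6,9)` left-normalizes to `[3,6)` with three
equivalent placements beyond the canonical one: the junction carries a 3-nt
`CAT` microhomology, so this deletion is called MMEJ. End to end on a
simulated cohort:

```r
sim   <- simulate_cohort(simulation_config(seed = 1, n_guides = 2, n_embryos = 3))
calls <- classify_alleles(sim$alleles, sim$loci, sim$guides)
summarize_guides(embryo_profiles(calls))
#>   guide_id n_embryos mean_f_nhej mean_f_mmej mean_f_hdr mean_f_unedited
#> 1   sg_001         3    6.268394    42.30807          0        51.42353
#> 2   sg_002         3   29.873562    44.62900          0        25.49744
#>   mean_efficiency     ratio  bias_class
#> 1        48.57647 0.1481607 MMEJ-biased
#> 2        74.50256 0.6693756    balanced
```

`mean_efficiency` is the embryo-mean edited fraction (percent of allele
mass carrying any attributable edit), `ratio` is R(g) above, and
`bias_class` applies the 0.5/2 boundaries. Guide `sg_001` is MMEJ-biased:
most of its edited mass comes from microhomology deletions.

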