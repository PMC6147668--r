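# kbcascade

Classify NF-kB/RELA target genes by integrating kinetic expression,
transcription-factor binding, perturbation responses, Pol II chromatin
looping and kB-motif conservation - with a synthetic-data generator that
plants a known ground truth so every stage is testable end to end.

## The problem

Inducible transcription factors like NF-kB bind thousands of genomic
sites, yet most bound genes never respond, and most responding genes are
driven indirectly.  Calling a gene a *functional target* requires three
coupled observations: its expression changes after stimulation, the
factor binds nearby, and blocking the factor abolishes the change.  This
package implements that integration for a B-cell activation time course
(0/1/4 h), a dominant-negative IkBa (dnIkBa) perturbation expressed in
two independent Tet-inducible clones, replicate RELA and Pol II ChIP peak
sets, Pol II ChIA-PET loops, and promoter-motif conservation across six
mammals.  It is aimed at computational biologists who want the
classification logic as reusable, tested functions rather than a one-off
analysis.

## The classification at its core

Let `S_c(t)` be the event "expression significantly lower at +Tet than
-Tet (FDR <= 0.05) in clone `c` at time `t`", and `R` the set of genes
with an assigned reproducible inducible RELA peak (replicate-common peaks
with score >= 100, assigned to the gene whose body/promoter contains the
peak midpoint or whose TSS is nearest within 50 kb).  Then

    dn-reduced   = { g : exists t in {1h, 4h} with S_1(t) and S_2(t) }
    Ad = dn-reduced intersect R        (direct activated targets)
    Ai = dn-reduced minus R            (indirect targets)

and symmetrically `Rd`/`Ri` for genes up-regulated by dnIkBa.  RELA-bound
genes with no response anywhere are *nonfunctional bound*; unbound,
unchanged genes are *unaffected*.  By construction
`|Ad| + |Ai| = |dn-reduced|` and `|Rd| + |Ri| = |dn-increased|`.
Kinetic patterns come from k-means with correlation distance
`d(x, y) = 1 - cor(x, y)` (k = 6, 5 restarts) with a permutation-null
silhouette; loop categories I-IV combine promoter Pol II status with
single- vs multi-gene PET clusters (>= 2 tags, FDR <= 0.05); site
conservation requires >= 40% identity in a 51-bp alignment window plus an
ortholog motif hit at >= 80% relative PWM score.

## Worked example

```r
library(kbcascade)

cfg <- sim_config(n_genes = 300, seed = 7)   # study-like synthetic design
pl  <- run_kb_pipeline(cfg, conservation = FALSE)
pl
#> kb_pipeline over 300 genes
#> class
#>                  Ad                  Ai nonfunctional_bound               other
#>                  20                  25                  34                  30
#>                  Rd                  Ri          unaffected
#>                   5                  17                 169
#> loop categories:
#>   I  II III  IV
#> 118  92  58  32

summary(pl$taxonomy)
#> ...
#> Partition identity: |Ad|+|Ai| = 45 dn-reduced genes; |Rd|+|Ri| = 22 dn-increased genes

truth_agreement(pl$taxonomy, pl$sim$truth)
#> [1] 0.89
```

Twenty of 300 genes are called direct activated targets (`Ad`): reduced
by dnIkBa in both clones *and* RELA-bound.  The partition identity line
is the structural check that direct + indirect counts add up to the
dn-responsive set.  Under negative-binomial noise with two replicates the
taxonomy matches the planted truth for ~90% of genes; with
`sim_config(noise = "deterministic", decoys = FALSE)` the match is exact
(that is the configuration the acceptance checks assert).  Individual
stages are available as plain functions: `filter_reproducible()`,
`assign_to_genes()`, `test_differential()`, `kmeans_patterns()`,
`classify_targets()`, `categorize_loops()`, `scan_motif()`,
`conserved_site_fraction()`, and the generator `simulate_dataset()` /
`write_sim_dataset()`.

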