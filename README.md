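# mtphylo

Phylogeographic analysis of human mitochondrial DNA at complete-genome
resolution: variant parsing and hotspot masking, haplogroup
classification, exact maximum-parsimony genealogies verified by
median-joining networks, rho-statistic founder dating under a
purifying-selection-corrected molecular clock, and kriged haplogroup
frequency surfaces. Written for population geneticists who work with
rCRS-relative haplotype tables (the branch-label notation of published
mtDNA cladograms) and want the whole chain — classification →
reconstruction → dating → mapping — reproducible from code instead of
hand-curated.

## The statistics at the core

For a clade of *n* sampled haplotypes, the founder age is estimated from
the **rho statistic** — the mean number of mutations separating each
sample from the reference node — with the Saillard standard error computed
from the genealogy's edge structure:

    rho   = (1/n) * sum_i d_i
    sigma = sqrt( sum_e (n_e/n)^2 * l_e )

where edge *e* carries `l_e` mutations and subtends `n_e` samples. Two
nodes are dated per clade: the MRCA (**coalescence age**) and its parent
in the haplogroup motif tree (**splitting age**), related exactly by the
stem branch of *s* mutations: `rho_split = rho_coal + s`,
`sigma_split^2 = sigma_coal^2 + s`.

Mutation counts convert to years with a complete-genome clock correcting
for purifying selection (young lineages still carry transient deleterious
variants, so their apparent rate is faster than the long-term one):

    t(rho) = 3624 * rho - B * (1 - exp(-rho / C)),   B = 24376.79, C = 23.0702

with 95% CIs from `rho ± 1.96 sigma` mapped through the clock. See the
methods vignette (`vignettes/mtphylo-methods.Rmd`) for the calibration and
every design decision.

## Worked example

Classify the bundled synthetic clade mitogenomes, reconstruct the U5b1f
genealogy, and date its founder both ways:

```r
library(mtphylo)

motif <- load_motif_tree(system.file("extdata", "motif_tree_synthetic.txt",
                                     package = "mtphylo"))
haps <- read_haplotype_table(system.file(
  "extdata", "clades_synthetic_mitogenomes.tsv", package = "mtphylo"))
masked <- lapply(haps, apply_mask)          # drop 16519, poly-C tract, ...

u5 <- masked[grep("U5b1f", sapply(masked, `[[`, "sample_id"))]
tree <- build_mp_tree(u5, root_motif = full_motif(motif, "U5b1f"))
tree <- with_stem(tree, motif$defining[["U5b1f"]],
                  parent_name = "U5b1", clade_name = "U5b1f")

date_clade(tree, "U5b1f", "coalescence")
#>   haplogroup        mode  n rho     sigma age_years ci_low_years ci_high_years
#> 1      U5b1f coalescence 12 1.5 0.4082483      3901         1808          6023
date_clade(tree, "U5b1f", "splitting")
#>   haplogroup      mode  n rho    sigma age_years ci_low_years ci_high_years
#> 1      U5b1f splitting 12 4.5 1.779513     11988         2622         21814
```

Reading: the twelve U5b1f mitogenomes carry 18 mutations to their MRCA
(rho = 1.50 ± 0.41), a coalescence around 3.9 kyr BP; the three-mutation
stem pushes the split from its sister lineage back to ~12 kyr BP — a
pre-Neolithic founder with a Bronze-Age-era diversification. The
median-joining network (`build_mj_network(u5)`) reproduces the parsimony
tree exactly on these data (`network_matches_tree()`).

The numbered scripts under `analysis/` run the full workflow — simulation
validation, classification, phylogeny, dating, frequency map — and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # estimator validation on synthetic clades
Rscript analysis/02_classify.R
Rscript analysis/03_phylogeny.R
Rscript analysis/04_dating.R        # the six-row dating table
Rscript analysis/05_frequency_map.R # kriged U5b1f surface
```

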