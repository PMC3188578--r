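# mtlineage

Detecting and dating maternal lineage expansions from complete human
mitochondrial genomes.

When a population grows rapidly, the genealogy of an mtDNA lineage founded
just before the growth looks like a star: many branches radiating from a
single founder haplotype. `mtlineage` implements the full analysis chain
that turns raw per-site read pileups into dated expansion events:

1. **Haploid consensus calling** (`parse_pileup()`,
   `assemble_consensus()`): at every rCRS-numbered site the called allele
   must be covered by at least 2 reads making up at least 3/4 of the site
   depth; sites below 2x coverage are missing and sites with no
   3/4-majority allele look heteroplasmic — both become `N`. Differences
   from the reference are emitted as HVS-style variants (`8701G`,
   `309.1C`, `249d`).
2. **Haplogroup assignment** (`load_haplotree()`,
   `assign_haplogroups()`): each sample is scored against a
   Phylotree-style definition tree as (matched − missing) cumulative
   defining mutations, with back-mutations honoured, `N` sites neutral,
   and the highly recurrent positions 309.1C, 16182C, 16183C, 16193.1C /
   16194C and 16519 excluded. `frequency_table()` and `macro_fraction()`
   tabulate per-population haplogroup frequencies and the M/N
   macrohaplogroup split.
3. **Median-joining network** (`build_matrix()`, `median_joining()`):
   coding-region (577–16023) haplotypes are linked by the minimum
   spanning network and augmented with quasi-median (per-site majority)
   vectors until convergence, after which median vectors not on any
   shortest connection between observed haplotypes are pruned.
   `detect_star_clusters()` reports every node with ≥ 5 radiating
   branches as a distinct expansion, with its member samples.
4. **Rho dating** (`cluster_genealogy()`, `rho()`, `saillard_sigma()`,
   `rho_to_time()`): with branch *b* carrying *m_b* mutations and
   subtending *n_b* of *n* sampled lineages,

       rho        = (1/n) * sum_b n_b * m_b        (mean founder-to-tip distance)
       sigma_rho  = sqrt( sum_b (n_b/n)^2 * m_b )  (Saillard standard error)

   and a molecular clock converts both to years. Two clocks ship by
   default: a purifying-selection-corrected complete-genome clock with
   expected substitutions `s(t) = mu_n*t + mu_d*tau*(1 - exp(-t/tau))`
   (long-run pace one substitution per 3,624 years), inverted
   numerically with delta-method errors, and a linear synonymous clock
   (one synonymous substitution per 7,884 years). Clock constants are
   configuration, not code.

A seeded synthetic-data generator (`simulate_genealogy()`,
`drop_mutations()`, `haplotypes_from_tree()`, `simulate_pileup()`,
`simulate_study()`) produces genealogies with known TMRCA, haplotypes
from a bundled toy haplogroup tree, and read pileups with known truth, so
every stage is testable without any external download. The package is
aimed at population geneticists who want a scripted, reproducible
equivalent of the usual pileup → Phylotree → Network → rho workflow.

## Worked example

Simulate a 40-lineage star expansion of haplogroup D4 with a true founder
age of 20,000 years, then recover and date it:

```r
library(mtlineage)
set.seed(7)
ref  <- simulate_reference()
tree <- load_haplotree(system.file("extdata", "haplotree_synthetic.tsv",
                                   package = "mtlineage"), ref = ref)
phy  <- simulate_genealogy(40, "star", tmrca = 20000)
sim  <- drop_mutations(phy, clock = default_clocks()$complete, ref = ref,
                       founder = expected_variants(tree, "D4"))

hm  <- build_matrix(sim$vsets)          # coding-region haplotype matrix
net <- median_joining(hm)
clusters <- detect_star_clusters(net)
calls    <- assign_haplogroups(sim$vsets, tree)
clusters <- label_clusters(clusters, calls)
ages <- estimate_ages(clusters, net, sim$vsets, ref = ref)
```

The run prints:

```
Haplotype matrix: 40 haplotypes ( 40 samples ) x 255 polymorphic sites
Median-joining network: 48 nodes ( 40 observed, 8 median ), 50 edges
Star cluster at mv1: 39 branches, 40 samples [D4]
  haplogroup  n rho sigma_rho t_years sigma_t_years      clock
1         D4 40 6.9    0.4183   22731          1490   complete
2         D4 40 1.3    0.1837   10249          1448 synonymous
```

All 40 samples radiate from one reconstructed founder node (`mv1`) and
are classified as D4. The mean founder-to-tip distance rho = 6.9
substitutions inverts, under the corrected complete-genome clock, to
22.7 ± 1.5 kya — within two standard errors of the generating 20 kya.
(The synonymous-clock row is computed from the synthetic genome's
synonymous sites, whose density differs from real mtDNA; see the
vignette.)

The same chain runs from files via `run_pipeline()` (YAML config) or the
command-line wrapper `inst/cli/mtlineage.R` with subcommands `assemble`,
`classify`, `network`, `date`, `simulate` and `run`.

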