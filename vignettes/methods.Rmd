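---
title: "Models and methods behind mtlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtlineage` turns mitochondrial read pileups into dated maternal lineage
expansions. This vignette explains the models at each stage, the
parameters that matter, the numerical and design choices that were
genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## Haploid consensus calling

mtDNA is effectively haploid, so a site is either the reference allele,
a substitution, an indel, or unresolvable. The calling rule has two
thresholds, `min_depth = 2` reads and `min_frac = 3/4` of the site depth,
applied to whichever allele (reference included, and indel alleles) is
in the majority:

* depth below `min_depth`: a *missing* site, reported `N`;
* no allele at ≥ `min_frac` of depth: a *heterozygous-looking* site
  (contamination, heteroplasmy, mapping artefact), reported `N`.

Two alleles can never both reach a fraction above 1/2, so the rule needs
no tie-break; the implementation asserts that impossibility rather than
silently picking. Base qualities are deliberately not consulted — the
rule is a pure coverage/fraction filter — though the thresholds are
arguments and can be tightened. The genome is treated linearly over
positions 1–16,569; the circular origin junction is never re-joined,
which is harmless because the network stage only uses positions
577–16,023. Insertions are named with the decimal-suffix convention
(`309.1C`), deletions per deleted position (`249d`). `N` positions emit
no variant but are carried alongside the variant set, so applying the
variants to the reference reproduces the consensus exactly (a tested
round-trip) and downstream stages can treat `N` as neither evidence for
nor against a mutation.

## Haplogroup assignment

The definition tree is a small configuration table: one node per row
with parent, defining mutations and macrohaplogroup label. Defining
mutations may name the derived allele (`8701G`), be bare positions
(resolved as the transition partner of the reference base), or carry a
trailing `!` for a back-mutation, which requires the *ancestral* state.
Five highly recurrent control-region descriptors (`309.1C`, `16182C`,
`16183C`, `16193.1C`, `16519`) are excluded from assignment. Two
published exclusion lists name the same poly-C artefact differently
(`16193.1C` vs `16194C`); both descriptors are excluded in both the
assignment and dating contexts by default, a deliberate merging of the
two lists.

Assignment scores every node as (matched − missing) cumulative defining
mutations along the root-to-node path. `N`-masked positions count as
neither. Ties break towards the deeper node, then lexicographically, so
assignment is deterministic and invariant to variant order. This
nearest-defined-node rule is a design choice: no published algorithm
accompanies the classification tools it emulates, and the rule recovers
the generating node with probability 1 on noise-free tree-generated
haplotypes (a tested invariant). The bundled tree fixture is *synthetic*:
it reuses the field's haplogroup names and realistic topology but
invents defining positions, because real reference trees cannot be
bundled. Any tree in the same format, including ones with explicit real
alleles, loads the same way.

Frequency tables round half-up to one decimal, the convention of
published haplogroup tables; the bundled per-population haplogroup
counts reproduce their published percentages exactly under this
rounding, which is how the table was validated.

## Median-joining networks

The network stage follows the classic median-joining construction. The
haplotype matrix keeps coding-region substitutions only (indels can be
included as binary characters via a flag, but are off by default,
matching common practice). Identical haplotypes collapse with
multiplicity. Missing data are handled by pairwise deletion: distances
are computed over mutually non-missing sites and rescaled to the full
site count. With an average of only a few ambiguous sites per sample
this wastes far less information than complete deletion, which remains
available as `scale = "complete"`.

The iteration alternates three steps until stable:

1. link the current node set by its **minimum spanning network** — the
   union of all minimum spanning trees, with an `epsilon` weight
   tolerance (`epsilon = 0` by default, the common default of network
   software);
2. delete **obsolete median vectors** — unsampled nodes with at most two
   links, whose connection a direct edge serves equally well; a deleted
   vector is never re-proposed, which guarantees termination;
3. add **quasi-medians** (per-site majority vectors) of linked node
   triplets, restricted to triplets whose connection cost is minimal
   within `epsilon`. Sites where all three states differ expand the
   quasi-median set combinatorially; the expansion is capped at
   `max_tie_sites = 2` such sites per triplet, after which the triplet
   is skipped (with four-state characters this is already a rare corner).

After convergence, median vectors that do not lie on any shortest
connection between observed haplotypes are pruned. The resulting graph
always contains a minimum spanning tree of its final node set and keeps
all observed haplotypes connected (tested against an independent Kruskal
oracle). On tree-like data — the regime mtDNA genealogies occupy — every
minimum-spanning link between observed haplotypes is realised as an
equal-length path through the network; on deliberately reticulate random
data that stronger guarantee cannot hold for any network of this family,
which is why the test suite asserts it only for tree-generated data.

**Star clusters.** A node (observed or median — published networks allow
either as a founder) with at least `min_branches = 5` incident branches
is reported as a distinct expansion. Membership walks each branch
outward, traversing median vectors freely (they carry no samples),
collecting observed haplotypes of degree ≤ 2, and stopping — without
collecting — at another cluster center, at an observed node with more
than two links (the start of a different radiation), or at any node
bordering a foreign center. The last rule exists because recurrent
mutations create median vectors that thread *around* a center node;
without it, one radiation's periphery leaks into another's membership.
With it, the synthetic study recovers every expansion's membership
exactly.

## Rho dating and clocks

For a cluster genealogy with branches *b* carrying *m_b* mutations and
subtending *n_b* of *n* tips,

$$\rho = \frac{1}{n}\sum_b n_b m_b, \qquad
  \sigma_\rho = \sqrt{\sum_b \left(\frac{n_b}{n}\right)^2 m_b},$$

the mean founder-to-tip mutation count and its standard error from the
branch decomposition. For a perfect star, $\sigma_\rho^2 = \rho/n$
exactly. Both identities, the equality of the branch-sum and direct-mean
forms of $\rho$, and the agreement of $\sigma_\rho$ with the Monte-Carlo
spread of $\rho$ (within 5% at 10^4 replicates) are tested.

The founder of a detected cluster is its center node's haplotype:
coding-region state from the network, extended to the full genome by the
members' majority state at positions the network matrix does not carry
(non-coding sites and sites monomorphic within the data set, notably the
cluster's shared defining mutations). Mutation counts use complete
genomes — substitutions only, never indels — minus the dating exclusion
list (`16519`, `16182C`, `16183C`, `16194C`, and `16193.1C` by the
merging described above). Cluster membership comes from the
coding-region network while counting uses complete genomes; this mixed
convention is deliberate and configurable.

Clocks are configuration data. Two defaults ship:

* **corrected complete-genome clock** — expected observable
  substitutions after $t$ years
  $s(t) = \mu_n t + \mu_d \tau (1 - e^{-t/\tau})$: a neutral component
  accumulating linearly plus a transient excess of effectively
  deleterious changes that purifying selection removes on timescale
  $\tau$. Defaults: $\mu_n = 1/3624\ \mathrm{yr^{-1}}$ (the published
  corrected complete-genome pace), $\mu_d = 1/12000\ \mathrm{yr^{-1}}$
  and $\tau = 8000$ years, chosen once as a plausible selection
  timescale; the exact published correction curve lives in its original
  reference and any monotone recalibration can be supplied instead. Ages
  invert $s$ with `uniroot` (tolerance $10^{-6}$ years) and
  $\sigma_T = \sigma_\rho / s'(T)$ by the delta method, matching the
  ± presentation of published age tables.
* **synonymous clock** — linear at one synonymous substitution per
  7,884 years, counting only substitutions that preserve the encoded
  amino acid given the reference codon background (vertebrate
  mitochondrial code, 13-gene annotation bundled). At sites covered by
  overlapping genes a change must be synonymous in every frame; variants
  in incomplete terminal codons count as non-synonymous.

Degenerate inputs are explicit errors: negative $\rho$, non-positive
clock constants, clusters whose members lack full-genome variants.
$\rho = 0$ dates to $T = 0$ under every clock.

## What the synthetic data emulate — and what they do not

The generator produces star and coalescent genealogies (standard
exponential waiting times, optional exponential growth) with branch
lengths in years, drops Poisson mutations per branch (rate × years, or a
clock's expected-substitution increment), assigns uniform random sites
with uniform alternative alleles, and logs recurrent-site collisions
rather than forbidding them (infinite-alleles-approximate). Pileups draw
Poisson depths and uniform errors. Everything is byte-reproducible under
a fixed seed.

The packaged synthetic study emulates the conditions of the motivating
East Asian data set: 367 samples in four population samples of
121/73/55/118, fifteen star expansions whose sizes (70, 42, 28, …) and
founder ages (26.66 kya, 36.24 kya, …) follow the published age table,
and 86 background samples in 22 small non-expanding haplogroup groups.
Passing tests therefore show that the pipeline recovers known expansions
of realistic size, age and multiplicity from realistic-scale data. They
do not show performance under features the generator omits: nested
expansions (the real D4 contains D4a, D4b2b and D4j; the synthetic
clusters are siblings, so membership truth is unambiguous), site-rate
heterogeneity (a gamma-rates flag exists for stress tests but is off by
default, as rate heterogeneity belongs to the likelihood analyses this
package does not attempt), real mutational spectra, mapping artefacts,
or heteroplasmy. Synonymous-clock ages on synthetic data reflect the
synthetic genome's synonymous-site density, not real mtDNA's, and are
reported as computed rather than adjusted.

Problem sizes in the test-suite and acceptance script — 367 samples,
10^4-replicate Monte-Carlo checks, 500-replicate recovery runs — were
chosen as the smallest sizes at which the statistical assertions have
comfortable margins.

## Known limitations

* The haplogroup tree fixture is synthetic; real classifications need a
  real tree file (the loader accepts Phylotree-style content).
* BAM handling, duplicate marking and realignment are upstream of the
  pileup entry point and out of scope, as are Bayesian (MCMC) dating and
  skyline analyses.
* The corrected-clock defaults approximate, not reproduce, the published
  correction curve; supply measured constants for publication-grade ages.
* Membership of nested expansions is resolved in favour of the inner
  cluster's own radiation; fully hierarchical membership reporting would
  require a different cluster model.
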