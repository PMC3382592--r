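---
title: "Mapping heterotic trait loci in a diallel: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping heterotic trait loci in a diallel: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htlmap)
```

## The problem

Heterosis — the superiority of an F1 hybrid over its inbred parents — is
usually mapped through biparental designs that average over allelic
diversity. A diallel of homozygous founder lines offers a different route:
because every founder is fully inbred, the genotype of each hybrid at every
marker is known without genotyping the hybrids (it is the unordered pair of
the parental alleles), and a multi-allelic marker panel sorts the hybrids
at each locus into several *hetero-genotypic groups* (one per allele pair)
plus a pooled *homo-genotypic* reference group. A **heterotic trait locus
(HTL)** is a locus at which at least one specific allele pair shows
significantly advantageous overdominant heterosis relative to the pooled
homozygotes, reproducibly across years.

`htlmap` implements the whole chain: heterosis statistics, genotype
projection and grouping, a two-step permutation-thresholded genome scan
with Kolmogorov–Smirnov contrasts, population-structure adjustment,
epistasis quantification among detected loci, and a single-locus F2
validation — together with a synthetic-data generator that emulates the
field design so every stage can be exercised and power-tested without
field data.

## Overdominant heterosis (ODH)

For a cross with low and high parental means $P1 \le P2$ (computed from
the parents' replicates in the same year), each hybrid replicate $F1_r$
contributes

$$
ODH_r =
\begin{cases}
 (F1_r - P2)/P2 & F1_r \ge P2 \\
 (F1_r - P1)/P1 & F1_r \le P1 \\
 0 & \text{otherwise,}
\end{cases}
$$

and the cross-level value is the mean over its $R$ replicates. Unlike
mid-parent heterosis ($MPH = (\bar{F1} - MP)/MP$) or best-parent heterosis
($BPH = (\bar{F1} - P2)/P2$), ODH is zero for any replicate inside the
parental range, so it isolates the over/under-dominant component of
inheritance. Both classical estimators are computed alongside
(`odh_table()`). Traits must be positive-valued; crosses with a
non-positive or missing parental mean are flagged and excluded rather than
silently propagated.

Reciprocal crosses are pooled before ODH computation. When both directions
have at least three replicates they are first compared with a Welch
two-sample t-test at $P \le 0.01$ (`reciprocal_test()`); the source method
does not name the test used for this check, so the t-test is a documented,
swappable choice. Crosses whose reciprocals differ are flagged and dropped
from the scan — a conservative generalization, since maternal effects on
heterosis are expected to be negligible in this design.

## The two-step scan

Years are analyzed separately throughout; an HTL must be supported in all
scanned years by the same allele pair (strict mode, the default — a
lenient mode unions years).

**Step 1.** At each marker the cross-level mean ODH values are modeled as
$Y_{ij} = \mu + \alpha_i + e_{ij}$, where $\alpha_i$ is the genotypic-group
effect and $e_{ij}$ the between-cross variation within groups; the group
effect is tested by a fixed-effects one-way ANOVA. The analysis unit is
the cross-level mean, not the plant-level replicate: the model's error
term is the cross-to-cross variation. The genome-wide significance
threshold is non-parametric: ODH values are permuted against cross
identities `n_perm` times (default 1000), the minimum nominal p-value
across markers is recorded per permutation, and the threshold is the
empirical $\alpha$-quantile (default $\alpha = 0.05$) of that minimum-p
distribution. A marker passes when its observed p-value does not exceed
the threshold. The permuted statistic is the minimum p rather than the
maximum F because group counts (hence df) differ across markers.

**Step 2.** Only at passing markers, each hetero-genotypic group is
contrasted with the pooled homozygous group by a two-sample
Kolmogorov–Smirnov test. The directed statistic is
$D = \sup_x [F_{homo}(x) - F_{hetero}(x)]$, large when the hetero group is
stochastically larger; the default is one-sided, because the question is
*advantageous* heterosis (a two-sided option exists; published examples of
the procedure do not disambiguate the sidedness). The p-value uses the
asymptotic two-sample law ($e^{-2 m D^2}$ one-sided, with
$m = n n'/(n + n')$); the critical-value form of the rejection rule is
equivalent and the p-value is authoritative in code. ECDFs are
right-continuous; ties are allowed and never jittered. Step-2 p-values
are not multiplicity-corrected across the hetero groups of a locus
(matching how such raw contrasts are conventionally reported); a
per-locus Bonferroni switch is available.

Groups smaller than `min_group` crosses are excluded. The default
`min_group = 3` generalizes the rare-allele rule — an allele carried by
fewer than three founders cannot form a comparable group — to the
genotypic-group level; the source method states a minimal genotypic
frequency without a number. Homozygous hybrids are pooled into a single
reference group on the hypothesis that homo-allelic combinations do not
produce synergistic interactions; `split_homo = TRUE` keeps per-allele
homozygous groups for the extension. Rare-allele homozygotes stay in the
pooled group (the pooling is unconditional).

### Population structure

Founder panels are usually structured. When cluster labels are supplied
(e.g. from an external model-based clustering at $K = 4$), each hybrid is
assigned the unordered pair of its parents' cluster labels, and this
combination enters the analysis twice: in step 1 as an additive cofactor
($Y_{ij} = \mu + \alpha_i + \beta_k + e_{ij}$, the genotype effect tested
sequentially after the cofactor), and in step 2 by adjusting each ODH
value by its combination's deviation from the size-weighted grand mean
(`adjust_for_structure()`). The adjustment preserves the grand mean and
removes all between-combination variance. Genotypic groups nested within
cofactor levels are flagged as untestable rather than silently dropped.

### Seeds and determinism

A single top-level seed drives the scan; per-year permutation streams are
derived deterministically from it, and all permutation index matrices are
drawn up front, so marker order cannot change results. Identical seeds
and inputs give byte-identical outputs.

## Epistasis among detected loci

Because the population is multi-parental and the markers multi-allelic, a
direct allele-by-allele interaction analysis is not estimable. Each
detected HTL is therefore binarized (`pn_recode()`): `P` for hybrids
carrying the advantaged pair, `N` for every other combination. The
two-locus model is $Y = \mu + A + B + A{:}B + year + e$ and the
three-locus model adds the third main effect while keeping only the
interaction between the first two loci. Year enters first as a random
blocking term whose variance is absorbed before the fixed tests, and
fixed effects are tested against the residual — the expected-mean-squares
convention for a random block without block-by-factor interactions (the
original analyses were run in closed-source software whose exact EMS
denominators are not published; this reproducible convention is the
package's own). Unbalanced data use sequential (Type I) sums of squares
so the decomposition always sums to the total; main effects enter in
descending single-factor $R^2$ order by default (configurable), and
`variance_explained()` reports the non-decreasing accumulated $R^2$.

## F2 validation

A called HTL can be confounded by loci in linkage disequilibrium that
sort the founders identically. The single-locus check is an F2 from one
hybrid carrying the advantaged pair: genotypes segregate 1:2:1, linkage
is tested by one-way ANOVA (`f2_group_stats()`), and the heterozygote is
compared with the best other group by Hsu's
multiple-comparisons-with-the-best (`hsu_mcb()`). With two groups the MCB
verdict reduces exactly to a one-sided pooled t-test (handled
analytically); for three or more groups the critical constants are
computed by seeded Monte-Carlo from the fitted null (equal means, pooled
variance, 20 000 draws by default) so the implementation needs no
external tables; the Monte-Carlo error at the default draw count is below
0.002 on the p scale. The percent overdominance effect is
$100\,(\bar{y}_{het} - b)/b$ with baseline $b$ the unweighted mean of the
two homozygote means — the symmetric convention, chosen because a single
effect against both homozygotes is reported in this field; `baseline =
"best"` uses the better homozygote instead.

## The synthetic study

`sim_config()` defaults encode the emulated field design: 19 homozygous
founders, 85 SSR markers on 10 chromosomes with 5–8 alleles each (every
locus keeps at least two alleles carried by three or more founders — the
condition that makes the groups comparable), four founder clusters with
cluster-correlated allele frequencies, a near-complete half-diallel with
about 10% of crosses missing and about 15% grown also as reciprocals, two
years with 7/4 hybrid and 14/10 parent replicates, and a positive
grain-yield-like trait (baseline 60 g).

The phenotype model is additive on the trait scale: founder replicates
are $baseline + 2\,GCA_f + year + \varepsilon$; hybrid replicates are
$baseline + GCA_x + GCA_y + cluster\text{-}pair + year + SCA_{xy}(year) +
shifts + \varepsilon$. The defaults (GCA sd 2 g, cluster-pair sd 1 g,
year sd 2 g, residual sd 6 g) were chosen once as realistic magnitudes
for a yield trait with moderate combining-ability variance. The
cross-by-year specific deviation $SCA_{xy}$ (sd 6 g) is the non-additive
background — specific combining ability and genotype-by-year interaction
— that every hybrid carries; it is what makes weak locus effects
year-inconsistent in real trials, and without it the cross-level ODH
distribution would be unrealistically tight.

A planted HTL multiplies the trait of every hybrid carrying its allele
pair by $(1 + d)$ (implemented as an additive $d \cdot baseline$ term),
so the carriers' mean ODH exceeds the homozygotes' by about $d$; the
multiplicative form keeps traits positive and makes $d$ interpretable on
the ODH scale. When the planted pair is left unspecified, the founder
simulator lays out a balanced configuration at the planted locus: two
alleles carried by three founders each (a hetero group of about nine
crosses), with carrier founder sets disjoint across planted loci as
far as 19 founders allow. This emulates a founder panel deliberately
selected to balance allele frequencies at the mapped loci, and it keeps
each planted group specific to its locus — with unbalanced SSR allele
frequencies, a planted pair defined by the two most common alleles would
span a third of the diallel and its carriers would leak into the
genotypic groups of unrelated markers, which both dilutes the step-1 F
(the leaked carriers inflate the within-group error) and creates
spurious co-segregating "echo" groups that replicate across years.

What the generator does **not** emulate: linkage between markers (loci
are drawn independently, so LD-driven confounding — the very thing the F2
validation exists for — must be constructed deliberately, e.g. by
duplicating a marker column), trait–trait correlation networks, spatial
field effects, and selection or non-random mating. Passing tests on this
generator therefore demonstrate the statistical machinery under the
stated inheritance model, not robustness to those field realities.

## Numerical and testing choices

* KS p-values use the asymptotic series (100 terms, clamped to $[0,1]$);
  exact small-sample p-values are not attempted because group sizes in
  practice are near or above the asymptotic regime and the permutation
  step, not the KS p, carries the genome-wide error control.
* The permutation engine recomputes the marker F from precomputed QR
  projections; unit tests assert exact agreement with the `lm()`/
  `anova()` route on the same data.
* The permutation threshold is the $\lfloor \alpha \cdot n\_perm
  \rfloor$-th smallest minimum p (with 100 permutations and $\alpha =
  0.05$: the 5th smallest).
* Degenerate cases are explicit: zero total variance gives $F = 0, p = 1$;
  perfect group separation gives $F = \infty, p = 0$ flagged; zero
  residual variance in the F2 yields the exact group ordering.
* Test problem sizes: the end-to-end recovery test runs the full
  19-founder, 85-marker, two-year design with 1000 permutations and a
  planted shift of `d = 1.2` — carriers roughly double the parental
  baseline, the upper range of reported sorghum yield heterosis, chosen
  so that recovery of the planted loci tests the procedure's selectivity
  rather than its marginal power; the
  type-I calibration runs 200 null datasets at 200 permutations and pools
  the two years of each (400 per-year events); the epistasis recovery
  uses 50 seeds at 280 cross-year observations. These sizes give
  Monte-Carlo standard errors comfortably inside the asserted bands while
  keeping the default test run short.

## Known limitations

* Single-point analysis only: no interval mapping between markers and no
  joint multi-locus scan; epistasis is quantified only among detected
  loci.
* The permutation threshold treats cross-level ODH values as
  exchangeable; strong planted signals make the permuted distribution
  heavy-tailed and the threshold correspondingly stricter, which is the
  standard behavior of this family of thresholds, not an error.
* Two features of the design break exchangeability even without any
  locus effect, and make the scan mildly anti-conservative at field
  replication levels (we measure an any-marker pass rate of ~0.08 at a
  nominal 0.05 on the default generator with no planted loci): founder
  general effects and cluster-pair effects shift ODH along the founder
  structure that also determines the genotypic groups, and — more
  subtly — the estimation error of a parent's mean is shared by all of
  that founder's crosses, so their ODH values are positively correlated
  through the parental bounds. The first is what the structure cofactor
  absorbs; the second shrinks with parental replication (at 10–14
  parent replicates it contributes a cross-level ODH correlation of the
  order of the parent-mean CV). The two-year same-pair intersection is
  what keeps false HTL calls near zero regardless.
* The structure adjustment is a mean shift per cluster-pair combination;
  it does not model admixture proportions.
* Hsu-MCB constants are Monte-Carlo estimates; verdicts within ~0.002 of
  the level boundary can flip between draw counts (the seed is fixed by
  default).
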