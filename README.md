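# htlmap — heterotic trait locus mapping in diallel populations

`htlmap` finds **heterotic trait loci (HTLs)**: markers at which a
*specific* heterozygous allele combination confers overdominant hybrid
vigor. It is built for diallel populations of homozygous founder lines —
the setting in which every hybrid's genotype is known from its parents'
genotypes — phenotyped with replication over multiple years, and
genotyped with multi-allelic markers (e.g. SSRs).

## The method

**Overdominant heterosis (ODH).** For a cross with low/high parental
means `P1 ≤ P2`, each hybrid replicate `F1_r` scores

```
ODH_r = (F1_r − P2)/P2   if F1_r ≥ P2     (above the high parent)
        (F1_r − P1)/P1   if F1_r ≤ P1     (below the low parent)
        0                otherwise        (inside the parental range)
```

and the cross-level ODH is the mean over replicates. Mid-parent and
best-parent heterosis (MPH, BPH) are computed alongside.

**Two-step scan, per year.** Step 1 tests each marker's genotypic-group
model `Y_ij = µ + α_i + e_ij` (hetero-genotypic groups keyed by unordered
allele pair; all homozygotes pooled) against an experiment-wise threshold
obtained from the permutation distribution of the genome-wide minimum
p-value (1000 permutations, α = 0.05). Step 2 contrasts each hetero
group with the pooled homozygotes by a one-sided two-sample
Kolmogorov–Smirnov test, `D = sup_x [F_homo(x) − F_het(x)]`. A locus is
called an HTL when the same allele pair is significantly advantaged in
every scanned year. Founder population structure can be absorbed as a
cluster-pair cofactor (step 1) and a mean adjustment (step 2).

Detected loci are quantified by P/N recoding (carriers of the advantaged
pair vs all others) in sequential ANOVAs with year as a random block, and
validated in an F2 by one-way ANOVA plus Hsu's
multiple-comparisons-with-the-best.

A synthetic-data generator (`sim_config()`, `simulate_diallel()`,
`simulate_f2()`, `simulate_epistasis()`) emulates the study design — 19
founders, 85 multi-allelic markers, four founder clusters, a
near-complete two-year half-diallel with reciprocals and missing crosses
— with planted overdominant allele pairs as ground truth.

## Worked example

Simulate a two-year diallel with one strongly overdominant allele pair
planted at marker `M002`, then scan:

```r
library(htlmap)

cfg <- sim_config(n_founders = 14, n_markers = 20,
                  planted_htls = data.frame(marker = 2, d = 1.2),
                  seed = 42)
sim <- simulate_diallel(cfg)
scan <- htl_scan(sim$geno, sim$design, trait = "DPW",
                 config = scan_config(n_perm = 1000, seed = 7),
                 pheno = sim$pheno)
scan
```

```
HTL scan of trait DPW over year(s): 1, 2 
  year 1: 20/20 markers testable, threshold p <= 0.0009189, 1 passed step 1
  year 2: 20/20 markers testable, threshold p <= 0.0007555, 1 passed step 1
HTL calls:
     name marker chromosome position    pair
1 hDPW2.1   M002          2    1e+06 190/192
```

One locus passes the permutation threshold in both years, its `190/192`
hetero-genotypic group beats the pooled homozygotes in the KS step in
both years, and the call is named `hDPW2.1` (trait, chromosome, ordinal).
It is exactly the planted locus:

```r
sim$truth$planted
#   marker   d allele1 allele2    pair
# 1   M002 1.2     190     192 190/192
```

The per-year step statistics live in `scan$per_year`, and
`write_reports(scan, "out/")` writes `scan.tsv`, `ks.tsv` and a
schema-versioned `htl_calls.json`.

The F2 confirmation of a called pair:

```r
f2 <- simulate_f2(190, 192, shift = 0.21, n_plants = 100, seed = 1)
st <- f2_group_stats(f2$genotype, f2$value)
hsu_mcb(st)
#     group  n     mean diff_best p in_best_set letter
# 1 190/190 27 60.75069 -11.41610 0       FALSE      b
# 2 190/192 52 72.16679  11.41610 1        TRUE      a
# 3 192/192 21 59.60527 -12.56152 0       FALSE      b
overdominance_effect(st)
# [1] 19.92226
```

The heterozygote is the sole member of the best set (letter `a`; both
homozygotes are significantly worse at the 0.05 level), and its measured
overdominant effect is 19.9% over the mean of the homozygote groups —
close to the planted 21% shift at this sample size.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "htlmap.R", package = "htlmap")` with subcommands
`simulate`, `odh`, `scan` and `f2`.

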