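# m6Asig

Signature-based analysis of N6-methyladenosine (m6A) regulation in tumor
cohorts. m6A — the most abundant internal mRNA modification — is deposited
by *writer* methyltransferases (METTL3, METTL14), transduced by *reader*
proteins (YTHDF1, YTHDF2, YTHDF3) and removed by *eraser* demethylases
(ALKBH5, FTO). Since bulk cohorts carry no direct per-patient m6A
measurement, the expression of this machinery serves as a surrogate:
`m6Asig` builds per-patient writer/reader/eraser signatures, stratifies
patients into m6A-indication classes, and quantifies how those classes
relate to overall survival, driver-gene mutations, clinical indexes and
pathway activity. It is aimed at computational oncologists analyzing
gastric-cancer-style expression + clinical + mutation cohorts (proteomic
or transcriptomic), and ships a fully seeded synthetic-cohort generator
so the entire pipeline is testable without any external download.

## The model

Per sample $s$, each signature is the geometric mean of its regulator
group (computed in log space; $\varepsilon$ is 0 for strictly positive
matrices, half the smallest positive value otherwise):

$$W_s = \sqrt{x_{METTL3,s}\,x_{METTL14,s}},\quad
R_s = (x_{YTHDF1,s}\,x_{YTHDF2,s}\,x_{YTHDF3,s})^{1/3},\quad
E_s = \sqrt{x_{ALKBH5,s}\,x_{FTO,s}}.$$

Each signature is split at the per-cohort median (`high` iff strictly
above; ties low). Seven stratification schemes follow — single W/R/E,
double WE/RE/WR (e.g. `WL_EH` = writer-low-eraser-high) and triple WRE
(`WRdL_EH` … `WRdH_EL`, by the number of high writers/readers crossed
with the eraser level). Because writers/readers add and erasers remove
m6A, exactly seven strata are **low m6A-indications** (W^L, R^L, E^H,
W^L E^H, R^L E^H, W^L R^L, WR^dL E^H) and their seven mirrors **high**.
Downstream analyses compare these classes with:

* Kaplan–Meier / log-rank survival comparison (omnibus or extreme-pair),
  plus an optional minimum-log-rank-P cutoff scan;
* Haldane–Anscombe-smoothed mutation-frequency fold changes, intersected
  across two cohorts into UP/DN consensus calls;
* two-sided Fisher exact (sum-of-small-P convention) / chi-square /
  Monte-Carlo exact contingency tests of clinical indexes;
* per-gene Welch differential expression with Venn overlap counts, and a
  phenotype-permutation GSEA engine (weighted-KS enrichment score,
  NES, nominal P and pooled-NES FDR).

## Worked example

```r
library(m6Asig)

co  <- generate_cohort(simulation_params(seed = 7))   # n = 600 synthetic GC cohort
sig <- compute_wre(co$expression)
signature_correlations(sig, "pearson")
#>   pair  method coefficient      p_value   n degenerate
#> 1  W~R pearson   0.6748989 5.615827e-81 600      FALSE
#> 2  W~E pearson  -0.4215231 3.035574e-27 600      FALSE
#> 3  R~E pearson  -0.4373643 1.995285e-29 600      FALSE
```

Writers and readers rise together while erasers move oppositely — the
correlation structure the signature construction assumes. Stratifying
and comparing the two extreme WRE corners:

```r
strata <- stratify_all(sig)
cmp <- compare_strata_survival(co$clinical, strata$WRE,
                               pair = c("WRdL_EH", "WRdH_EL"))
cmp$logrank
#> Log-rank test: 2 groups, chi-square = 17.65 on 1 df, P = 2.655e-05
#>     group   n observed  expected
#> 1 WRdH_EL 161      111 142.24383
#> 2 WRdL_EH 158      128  96.75617
sapply(cmp$curves, km_median)
#> WRdH_EL WRdL_EH
#>   19.68   10.92
```

The low-m6A corner (`WRdL_EH`) dies faster than expected (128 observed
vs 97 expected events) and its median survival is roughly half that of
the high-m6A corner. Driver mutations concentrate in the low-indication
groups (fold change > 1 in every scheme, strongest in the WRE triple):

```r
round(foldchange_low_vs_high(co$mutations, strata,
                             genes = attr(co$truth, "spiked_drivers"))[, c("W", "E", "WRE")], 2)
#>           W    E  WRE
#> CDH1   1.56 1.49 2.44
#> TP53   1.37 1.23 1.56
#> ...
```

On real data, replace the generator by `read_expression()`,
`read_clinical()`, `read_mutations()` and `read_gmt()` (TSV / MAF-lite /
GMT), or drive everything from one config with `run_pipeline()`.
Published contingency tables bundled as worked examples reproduce their
printed P values exactly, e.g.
`fisher_exact_2x2(gc_reference_tables()$ms_gender)$p_value` → 0.6785.

## Documentation

The methods vignette (`vignettes/m6asig-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the package's numerical conventions.
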