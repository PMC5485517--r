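---
title: "Two-stage detection of high-order SNP interactions"
author: "episcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage detection of high-order SNP interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The problem

Genome-wide association studies routinely test one SNP at a time, which
misses risk configurations that only become visible when several loci are
considered jointly. Exhaustively testing all $\binom{M}{K}$ K-locus
combinations is computationally and statistically hopeless at genome scale:
for $M \approx 4 \times 10^5$ SNPs there are $\sim 10^{16}$ triples, each
tested against a Bonferroni level of order $10^{-18}$.

episcreen implements a two-stage strategy. Stage 1 reduces the search space
to SNP *pairs* that show at least intermediate association with the
phenotype, discarding pairs whose association is explained by single-locus
(marginal) effects. Stage 2 then looks for K-locus interactions
($K \ge 3$) only among combinations assembled from those candidate pairs —
exhaustively when the candidate set is small, or with ant colony
optimization (ACO) when it is large. The key premise is that a K-locus
interaction usually leaves at least a weak footprint on some of its
$\binom{K}{2}$ pairs, even when no pair is significant on its own, so a
deliberately permissive pair filter retains the building blocks of
higher-order signals.

## Stage 1: the pair screen

For SNPs coded 0/1/2 (minor-allele count), every pair defines a
$9 \times 2$ genotype-combination by case/control contingency table, scored
with the chi-squared statistic of independence

$$\chi^2 = \sum_{u} \sum_{v}
  \frac{(n_{uv} - n_{u+} n_{+v} / N)^2}{n_{u+} n_{+v} / N},$$

referred to $\chi^2_{df}$ with $df = 3^2 - 1 = 8$. Rows with zero margin
are skipped in the summation, but the degrees of freedom stay at $3^k - 1$
so that critical values remain comparable across combinations of the same
order. Two thresholds partition the pairs:

* $\alpha = \alpha_0 / \binom{M}{2}$ — the Bonferroni level; pairs with
  $\chi^2 > \chi^2(\alpha)$ are *significant*;
* $\alpha' = \omega \alpha$ (capped at 1) — a relaxed level; pairs with
  $\chi^2(\alpha') < \chi^2 \le \chi^2(\alpha)$ have *intermediate*
  association and are retained as well.

The scale factor $\omega$ (default $10^4$) trades detection against
runtime: a larger $\omega$ keeps more weakly-associated pairs, which can
carry purely epistatic signals, at the cost of a larger stage-2 search.
Pairs below $\chi^2(\alpha')$ are never materialized: the scan streams over
all $\binom{M}{2}$ pairs and keeps only the retained band.

Strong single-locus effects inflate pair statistics without any
interaction. Each SNP is therefore tested on its own $3 \times 2$ table
(df 2) against the Bonferroni level $\alpha_0 / M$; for retained pairs
containing at least one flagged SNP, a likelihood-ratio test compares

* a *full* logistic model — intercept, two genotype indicators per SNP
  (levels 1 and 2 against baseline 0) and the four pairwise products
  (9 parameters), against
* a *reduced* model holding only the indicators of the flagged SNP(s)
  (5 parameters when both are flagged, 3 when one is).

The deviance $D = 2(\ln \hat L_F - \ln \hat L_M)$ is referred to
$\chi^2_{df}$ with $df = 4$ or $6$. A pair whose deviance p-value exceeds
$\alpha'$ owes its signal to main effects and is discarded. Genotypes are
treated as categorical because only that coding yields the stated degrees
of freedom; indicator columns for genotype levels absent from the data are
pruned from both models and the df reduced accordingly. When no SNP is
flagged at all, the likelihood-ratio stage is skipped.

Both models are maximized by Newton–Raphson on the binomial log-likelihood
(convergence when the log-likelihood moves by less than $10^{-8}$, at most
50 iterations). Complete separation is detected by a diverging coefficient
norm and resolved by a $10^{-6}$ ridge on the Hessian, flagged in the
result. These numerical choices are the package's own; they are tested
against an independent IRLS fit.

## Stage 2: the interaction search

Let $W$ be the number of candidate pairs. For small $W$ (below 2000), all
SNPs appearing in candidates are merged into a set $S$ and every K-subset
of $S$ is tested on its $3^K \times 2$ table ($df = 3^K - 1$, i.e. 26 for
triples, 80 for quadruples); subsets with p-value below
$\alpha_0 / \binom{M}{K}$ are reported.

For large $W$ the package runs ACO over the candidate *pairs*. Each pair
$C_i$ carries a pheromone $\tau_i$, initialized at $\tau_0 = 100$. In every
iteration, each of $n$ ants selects $d$ distinct pairs by roulette-wheel
selection with probability

$$p(i) = \frac{\tau_i^{\delta} \eta_i^{\beta}}
              {\sum_j \tau_j^{\delta} \eta_j^{\beta}},$$

with uniform prior $\eta \equiv 1$ and $\delta = \beta = 1$ by default. The
union of the selected pairs is scored by its chi-squared statistic,
multiplied by a scale factor $f_s = 2$ when the union has exactly three
SNPs — a three-SNP critical value is roughly half a four-SNP one, and
without the scale three-SNP merges would be systematically out-competed.
The best `top_t` (default 100) merged combinations by fitness are kept in a
global list. After each iteration all pheromones evaporate,
$\tau_i \leftarrow (1 - \rho)\tau_i$, and every selected pair receives a
deposit of $0.01 \times$ its ant's fitness; deposits from multiple ants
accumulate. Evaporation is applied to *all* candidates, not only the
selected ones — evaporating only selected pairs would freeze the pheromone
of never-selected candidates and defeat exploration decay. Finally, every
K-subset of every stored combination is tested and the Bonferroni-filtered
results reported, deduplicated and sorted by p-value.

Defaults follow the recommended scaling: $n$ and the iteration budget are
both $0.1\,W$ ($n$ clamped to $[500, 5000]$), $\rho = 0.05$ for simulated
data sizes, $d = 2$ for three-locus detection. With a fixed `seed` the
search is exactly reproducible. Two structural properties hold by
construction and are tested: the ACO report is always a subset of the
exhaustive report on the same candidates, and every reported set passes the
Bonferroni filter.

## Bitwise counting

All contingency tables are built from a bitset encoding: per SNP, one
bit-array per genotype code per phenotype class (six per SNP). A k-locus
cell count is the popcount of the AND of k bit-arrays; samples missing at
any of the k SNPs drop out of that table automatically because a missing
genotype sets no bit in any of its three arrays. The C++ kernel operates on
64-bit words. The R-level naive tally is kept in the test suite as the
oracle; the two agree exactly on randomized data for $k \le 4$.

## Quality control

Filters run in a fixed order, each on the data surviving the previous
step: samples with call rate below 0.98; SNPs with call rate below 0.95;
SNPs with a Hardy–Weinberg (1-df goodness-of-fit) p-value below $10^{-4}$
in controls; SNPs with minor allele frequency below 0.1. The HWE test is
the chi-squared goodness of fit rather than an exact test, consistent with
the package's chi-squared toolkit; monomorphic SNPs return p = 1 by
convention and are left to the MAF filter. Each removal is recorded with
the triggering rule and value. The procedure is idempotent.

## The simulator

The simulator generates case-control data under explicit penetrance models
$f(g_1, \dots, g_k) = P(\text{disease} \mid g)$, with disease-locus
genotypes in Hardy–Weinberg proportions and background SNPs at MAFs drawn
uniformly from $[0.05, 0.5]$ (the default range; the baseline prevalence
for calibrated families defaults to 0.01). Case status is assigned with
probability $f(g)$ and sampling continues until the case/control quota is
met exactly.

Three parameterized families cover the usual simulation designs:

* **multiplicative3** — odds multiplicative in the genotype product:
  $f/(1-f) = a(1+\theta)^{g_1 g_2 g_3}$;
* **threshold3** — odds raised once all loci carry a minor allele:
  $f/(1-f) = a(1+\theta)$ iff $\min(g_i) \ge 1$;
* **pure3** — pure epistasis at MAF 0.5: $f = p_\text{hi}$ when
  $g_1 + g_2 + g_3$ is odd, $p_\text{lo}$ otherwise.

The first two families are calibrated by root-finding so that the
per-locus marginal effect size
$\lambda = \frac{P_{Aa}/(1 - P_{Aa})}{P_{AA}/(1 - P_{AA})} - 1$
hits its target (0.2 and 0.3 by default) with the baseline $a$ solved at
each $\theta$ so the prevalence matches. The odds-scale parameterization is
deliberate: a penetrance-scale multiplicative form saturates at the
$(2,2,2)$ cell and cannot reach $\lambda = 0.2$ at MAF 0.2 and prevalence
0.01, whereas the odds form is feasible for any target.

The parity construction of **pure3** makes every marginal penetrance equal
to the prevalence for *any* $(p_\text{hi}, p_\text{lo})$ — the
heterozygote/homozygote distinction is invisible marginally, so all
$\lambda = 0$ exactly; the two penetrance values are then solved for the
target heritability
$h^2 = \mathrm{Var}(f(G)) / (P(D)(1 - P(D)))$
(the standard dichotomous-scale definition, recoverable from the table).
With equal-weight high/low classes the construction obeys
$h^2 \le P(D)/(1 - P(D))$, so large heritabilities require non-rare
prevalence: by default $p_\text{lo} = 0$, giving $P(D) = h^2/(1 + h^2)$
(e.g. 0.29 at $h^2 = 0.4$); a user-supplied prevalence is honored whenever
feasible and rejected with the feasible range otherwise. Arbitrary models
(including published three- and six-locus tables) can be supplied as
`custom_table`. All stored annotations — prevalence, marginal penetrances,
$\lambda$, $h^2$ — are recomputed from the table and verified in the tests.

Linkage disequilibrium between an ungenotyped disease locus and its
genotyped marker is simulated by equal-frequency haplotype coupling: each
marker haplotype copies the disease allele with probability
$1 - \epsilon$ and redraws it independently otherwise, with
$\epsilon = 1 - \sqrt{r^2}$, which yields haplotype correlation $\sqrt{r^2}$
and hence LD $r^2$ in closed form; $r^2 = 1$ genotypes the locus directly.

Power is the fraction of replicates in which the reported significant sets
contain the *exact* planted tuple (marker tuple when $r^2 < 1$); partial
recovery earns no credit. Replicate seeds derive deterministically from the
configuration seed.

### What the simulator does and does not emulate

Simulated data are idealized: independent SNPs (no background LD),
Hardy–Weinberg genotypes, no genotyping error, no population structure and
no missingness unless injected. Passing the recovery and calibration tests
therefore demonstrates correctness of the statistics and search under the
stated models, not robustness to the confounders of real cohorts
(stratification, batch effects, haplotype structure), which remain the
analyst's responsibility.

## Worked example

```{r example}
model <- penetrance_model("pure3", h2 = 0.4)
model
sim <- sample_case_control(
  model, sim_config(M = 100, n_case = 200, n_control = 200, seed = 42))
res <- episcreen(sim$dataset, seed = 1)
res
sort(sim$truth$disease_cols)
```

The planted triple is recovered whenever its table statistic clears the
three-locus Bonferroni bar; at $h^2 = 0.4$ and $N = 400$ this happens in
essentially every replicate.

## Design choices and limitations

* **Problem sizes in the test-suite simulations** (e.g. $M = 100$ SNPs,
  $N = 400$–$2000$, 20–200 replicates; padded candidate sets of
  $5 \times 10^3$ pairs for the ACO study) are chosen so the full suite
  exercises every code path on commodity hardware while keeping each
  estimate's Monte-Carlo error well inside the asserted bounds.
* **Pairs with no flagged SNP bypass the likelihood-ratio filter** — the
  filter exists to remove main-effect artifacts, and without a flagged SNP
  there is no artifact to remove.
* **Discard boundary**: a pair is discarded iff its deviance p-value is
  strictly greater than $\alpha'$.
* **Candidate ordering** (descending $\chi^2$, ties by index) is a
  package convention for reproducibility; no ordering is intrinsic.
* **The deposit uses the fs-scaled fitness**, consistent with the scaled
  statistic driving the stored-combination list.
* **Per-ant selection is without replacement** ($d$ distinct pairs);
  selecting the same pair twice would waste an ant on a 2-SNP union that
  cannot enter $K \ge 3$ reporting.
* **Minor alleles are defined over all samples** (not controls only),
  making the 0/1/2 coding dataset-intrinsic and deterministic.
* **Missing genotypes** are excluded per table (listwise within each
  k-SNP set), preserving margins without imputation.
* At the reference genome-wide SNP count $M = 423{,}234$ the corrected
  levels are $\alpha_0/\binom{M}{1} = 1.181 \times 10^{-7}$ and
  $\alpha_0/\binom{M}{2} = 5.583 \times 10^{-13}$; the analogous
  three-locus computation gives $3.957 \times 10^{-18}$ (mantissa as
  commonly quoted, exponent following directly from
  $\binom{M}{3} = 1.263 \times 10^{16}$).
* The CLI front end (`inst/cli/episcreen.R`) resolves options as flags
  over defaults; a configuration-file layer is deliberately omitted.
* Orders $K > 6$, covariate adjustment, PLINK binary/VCF input and
  X-chromosome handling are out of scope.
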