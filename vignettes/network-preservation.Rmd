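---
title: "Methods: differential coexpression network preservation with CoexPreserve"
author: "CoexPreserve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential coexpression network preservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoexPreserve)
```

# The question the package answers

A gene set can keep its average expression between two conditions and still
lose its internal organisation: genes that rise and fall together in one
condition may decouple in the other. CoexPreserve quantifies this for bulk
RNA-seq designs with two groups of samples — the motivating setting is a
sheep feeding study in which lambs from dams on a gossypol-rich cottonseed
diet were compared with lambs from control-fed dams, using a set of 145
spermatogenesis-related genes and 9 samples per diet.

# Model and procedure

## Per-condition binary coexpression network

For each condition separately, let $x_{is}$ be the normalized expression of
gene $i$ in sample $s$ (log2-CPM by default). The package computes the
Pearson correlation matrix $R = (r_{ij})$ across that condition's samples
and converts it to a binary adjacency matrix $A = (a_{ij})$ by a hard
double threshold:

$$a_{ij} = 1 \iff |r_{ij}| \ge 0.5 \text{ and } p_{ij} \le 0.05,
\qquad a_{ii} = 0,$$

with both inequalities inclusive. The p-value for $H_0: \rho_{ij} = 0$ uses
the exact t transform $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of
freedom; no other test form is offered because it is the standard null
distribution of a sample Pearson correlation under bivariate normality.

A useful arithmetic fact, asserted programmatically in the test suite: with
$n = 9$ samples, $p \le 0.05$ already implies $|r| \ge 0.666$, so at the
default settings the significance criterion is the binding one and the
$|r| \ge 0.5$ criterion never removes a significant edge. Users lowering
`pMax` or working with more samples will see both criteria matter.

## Node statistics

The network topology is summarised per gene by

* **connectivity** $k_i = \sum_{j \ne i} a_{ij}$, the number of partners, and
* **clustering coefficient**
  $c_i = \dfrac{\sum_{j\ne i}\sum_{k\ne i} a_{ij}a_{jk}a_{ki}}
  {\left(\sum_{j\ne i} a_{ij}\right)^2 - \sum_{j\ne i} a_{ij}^2}$,
  the local edge density among a gene's neighbours.

For a binary adjacency matrix the denominator reduces algebraically to
$k_i(k_i - 1)$ (because $a^2 = a$ entrywise), which makes $c_i$ twice the
number of triangles through $i$ divided by the number of ordered neighbour
pairs. The implementation computes the numerator as
$\mathrm{diag}(A^3)$ via one matrix product and keeps the denominator in
the printed form; the identity is asserted on random graphs rather than
assumed.

**Degenerate nodes.** $c_i$ is undefined when $k_i \le 1$ (denominator
zero). Such genes are reported as missing and excluded from clustering
means; substituting 0 would drag condition means down in sparse networks
and manufacture spurious "disruption". Isolated genes do contribute
$k_i = 0$ to connectivity means, since losing all partners is precisely the
effect being measured.

## Preservation comparison and permutation test

The per-gene statistics of the two condition networks are aligned into one
table with differences $\Delta k_i = k_i^{(B)} - k_i^{(A)}$ and
$\Delta c_i$, plus condition means (connectivity over all genes; clustering
over defined genes). Because the two networks are estimated from disjoint
sample sets, a formal test is possible: under the null hypothesis of no
condition effect, all samples are exchangeable, so the package pools the
$n_A + n_B$ samples, reassigns them at random to groups of the original
sizes, rebuilds both networks per permutation, and uses

$$T = \overline{k}^{(B)} - \overline{k}^{(A)}$$

(and likewise for $\overline{c}$) with the two-sided add-one estimator
$p = (1 + \#\{|T_\pi| \ge |T_{obs}|\})/(B + 1)$. The add-one form keeps
$p > 0$ and is the standard conservative choice for Monte-Carlo tests. The
pooled matrix is put in a canonical column order before permuting, so the
p-value is invariant to swapping the two condition labels (exact when group
sizes are equal). Permutations in which a statistic is undefined (no gene
with two neighbours) are dropped from that statistic's count; this is rare
outside near-empty networks.

The difference-in-means statistic was chosen over, say, a correlation of
per-gene $k$ between conditions because the scientific claim being tested
is a *shift* of the connectivity and clustering distributions between
diets, which the mean captures directly.

## Normalization and filtering

The expression scale fed to the correlation step is the package's choice:
log2-CPM with a prior count of 0.5,
$\log_2\!\big((x + 0.5)/(L + 1) \cdot 10^6\big)$ with $L$ the library
size. The log transform tames the mean-variance relation of counts before
Pearson correlation, and the prior keeps zeros finite; plain CPM
(`cpmValues()`, each sample summing to exactly $10^6$) is available where
exactness matters. Genes are pre-filtered to CPM $> 1$ in at least half
the samples by default — a conventional bulk RNA-seq expression filter;
both knobs are exposed. Genes with zero variance within a condition have
no defined correlation and are excluded with a warning (or an error in
strict mode). Missing expression values are rejected outright; imputation
is upstream's job.

Whether the focal gene set should be taken from raw or normalized
expression is genuinely ambiguous in this kind of design; the pipeline
subsets *after* normalization, so filtering and library-size correction
see the full transcriptome, which is the defensible order (set membership
does not change normalization).

# Differential-expression selection and overrepresentation

The pipeline consumes a per-gene p-value table from an upstream DE tool and
implements only the selection arithmetic: Benjamini–Hochberg step-up at
level $q$ (reject the largest rank $k$ with $p_{(k)} \le (k/m)q$ and all
smaller), with q-values delegated to `stats::p.adjust` and the implied
p-value cutoff $(k/m)q$ reported. With $m = 18{,}326$ tests, $84$
rejections and $q = 0.01$ this cutoff is $4.6\times 10^{-5}$ to two
significant figures — the arithmetic consistency check used in the
acceptance suite. Note that BH is *not* idempotent: re-adjusting q-values
inflates them (e.g. $p = (0.01, 0.5) \mapsto (0.02, 0.5) \mapsto
(0.04, 0.5)$), so q-values are computed once from raw p-values.

Gene-set overrepresentation uses the one-sided Fisher test: with $N$
background genes, $K$ set members in the background, $n$ selected DE genes
and overlap $x$, $p = P(X \ge x)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$, computed with `stats::phyper` and
cross-checked in the tests against full enumeration of all tables with the
given margins and against `fisher.test`. The background is all genes in
the DE table (restricted to annotated genes when the table flags
annotation), set members are intersected with the background before
counting, and no correction across sets is applied by default — the raw
Fisher p is the primary output, with a BH option for users who test many
sets. Ancestor propagation of ontology terms is out of scope; sets are
taken literally from the GMT.

# qPCR validation statistics

Relative expression follows the standard doubling model: per sample,
$\Delta Ct = Ct_{target} - Ct_{reference}$ (reference gene measured in the
same well/sample, e.g. a housekeeping control);
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}$; fold change
$2^{-\Delta\Delta Ct}$. Amplification efficiency is fixed at 2 per cycle —
the method's defining assumption; efficiency-corrected variants are out of
scope. By construction the control group's geometric-mean fold change is
exactly 1. Technical replicates should be averaged per sample upstream.

The group effect on $\Delta Ct$ is tested with a likelihood ratio under a
two-group Gaussian linear model: $LRT = n\,\ln(RSS_0/RSS_1)$ comparing the
common-mean and group-means fits, referred to $\chi^2_1$. This is the
minimal model consistent with a likelihood-ratio framework for a two-level
treatment factor. The $\chi^2$ reference is asymptotic; at the design size
($n = 18$) the simulated type-I error sits near but not exactly at the
nominal 5% (the tolerance used in the tests is $\pm 0.03$). Degenerate
inputs with zero residual variance under the full model raise an error
rather than reporting $p = 0$.

# The synthetic-data generator

No public generative model exists for the motivating dataset, so the
package ships a generator whose parameters *are* the study design, used by
every downstream test:

* **Design**: two conditions $\times$ 9 samples; 18,000 genes; a focal
  "spermatogenesis-like" set of 145 genes emitted as a GMT record.
* **Coexpression**: planted one-factor modules inside the focal set. For
  module $m$ with target correlation $\rho$, each sample gets a factor
  $f \sim N(0,1)$ and gene $g$ a latent
  $z = \sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$, giving exactly
  pairwise latent correlation $\rho$. Defaults: modules of 40, 30 and 25
  genes at $\rho = 0.80, 0.75, 0.70$ — strong but not deterministic
  coregulation, the regime where a 9-sample network is informative.
* **Disruption**: condition B attenuates every module to
  $\rho(1-\delta)$, default $\delta = 0.85$; a single multiplicative knob
  matching the direction of the motivating finding (loss of connectivity
  and clustering under treatment). Baseline means are shared between
  conditions, so disruption is purely a second-moment effect.
* **Observation model**: counts $\sim$ NB with mean
  $s_j \exp(\mu_g + \sigma z)$ and variance $\mu + \phi\mu^2$;
  $\mu_g \sim U(2, 6)$ on the natural-log scale (mean counts roughly
  7–400), biological signal $\sigma = 1$, dispersion $\phi = 0.1$
  (typical bulk RNA-seq), and mild log-normal(0, 0.1) library-size factors
  so CPM normalization is non-trivial.
* **Companion tables**: a DE p-value table (first $n_{true}$ genes
  $\sim \mathrm{Beta}(a, 1)$, rest uniform; the true signals sit inside
  the focal set by construction) and a qPCR Ct table (reference
  $Ct \sim N(20, \sigma_{noise})$, target offset by a baseline plus a
  group shift).

Everything is deterministic given the seed. What the generator does *not*
emulate — and what passing tests therefore do not establish about real
data: read-level artefacts, batch effects, GC/length bias, outlier
samples, heavy-tailed expression, non-Gaussian dependence, and overlap
between gene sets. The generator validates that the *statistics* behave as
designed, not that any particular biological dataset will reproduce.

# Numerical choices and problem sizes

* Correlations are clamped to $[-1, 1]$ and symmetrised before
  thresholding; thresholds are inclusive exactly as stated above.
* Inside the permutation loop the p-criterion is applied as the equivalent
  $|r| \ge t_{crit}/\sqrt{n - 2 + t_{crit}^2}$ bound — the same inclusive
  rule without recomputing p matrices.
* Monte-Carlo suites run at deliberately scaled-down sizes chosen to make
  their conclusions stable: oracle equivalence on 200 random graphs of up
  to 25 nodes; hypergeometric enumeration on 500 random margins with
  $N \le 60$; the disruption-recovery study on a 145-gene focal set at the
  full design (100 replicates, 199 permutations); type-I calibration on a
  60-gene set (400 replicates). The acceptance script runs the full
  pipeline once at the complete design scale (18,000 genes).

# Known limitations

* Two conditions only; multi-group designs need repeated pairwise runs.
* The permutation test assumes exchangeable samples under the null — it
  does not accommodate batch structure or paired designs.
* Hard thresholding discards edge-weight information by design (the point
  is the binary-network statistics); weighted alternatives are a
  different method family.
* With 9 samples per group, individual correlations are noisy; results
  should be read at the distribution level (means over a gene set), which
  is what the report and test provide.
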