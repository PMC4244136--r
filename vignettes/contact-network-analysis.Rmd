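---
title: "Contact-network analysis of webRDS surveys: models and methods"
author: "rdsmix"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsmix)
```

# The design being analysed

Online respondent-driven sampling (webRDS) starts from investigator-chosen
*seeds* (wave 0) who each invite up to four contact persons; each recruitee
who completes the questionnaire may invite up to four more, and so on. The
recruiter-recruitee links are tracked, so the sample is not a set of
independent egos but a *forest* of recruitment trees. Two quantities drive
everything downstream:

* a participant's **degree** — the total number of contact persons reported
  for one recording day, defined as the sum of contacts *at different
  locations* plus contacts *while travelling*. Contacts while eating and
  household members are recorded separately and deliberately excluded from
  the degree;
* the **link distance** between two participants — the length of the unique
  path joining them in their recruitment tree.

`rds_forest()` is the central container: a participant table plus an edge
table, validated against the design invariants (single recruiter, no
cycles, fan-out at most four, non-negative counts) with waves and tree
membership always re-derived by breadth-first search, never trusted from
the input file.

# Statistical components

## Degree distributions

Degrees are overdispersed counts, modelled as negative binomial in the
ecology parameterisation $N(\mu, k)$ with variance $\mu + \mu^2/k$; small
$k$ means strong overdispersion. `fit_negbin()` exploits the structure of
the NB likelihood: for any $k$ the ML estimate of $\mu$ is the sample mean,
so the likelihood is profiled and only $k$ is searched, on
$k \in [10^{-3}, 10^3]$ (log scale, tolerance $10^{-8}$). Confidence
intervals are percentile intervals over parametric-bootstrap refits
(default $B = 1000$); coverage is insensitive to $B$ well below that, which
is why the heavier simulation tests use $B = 200$.

Sample comparisons use the Anderson-Darling $k$-sample test in the
Scholz-Stephens midrank form — count data are tie-heavy, so the
discrete-data version of the statistic is the only defensible one. The
p-value is either the standard-normal approximation of the standardized
statistic or a permutation p-value; the default switches to permutation
when the smallest sample has fewer than 200 observations because the
normal approximation is visibly anti-conservative at the 5% level there.
The two-sample Kolmogorov-Smirnov test (asymptotic p) and matched empirical
quantiles (`qq_pairs()`) complete the comparison toolkit.

## Mixing by link distance

Assortative mixing is measured as a correlation over all pairs of
participants at link distance $d \in \{1, 2, 3, \text{4+}\}$ within a tree
(distances of four and more are lumped; beyond that pair counts collapse).
`pairs_at_distance()` enumerates the pairs per tree from shortest paths;
the default includes non-lineal pairs (siblings, cousins) because any two
persons in the same chain stand in a contact-relevant relation, while
`mode = "lineal-only"` restricts to ancestor-descendant pairs for analyses
phrased in terms of consecutive waves. Where the two modes disagree
materially, both should be reported.

For unordered pairs the estimate is computed on the symmetrized pair list
(each pair entered in both orientations), the standard way to make a
network assortativity coefficient orientation-free; inference, however,
uses the number of *distinct* pairs (Fisher-$z$ for Pearson and Spearman,
the 1-df $\chi^2$ of $n\varphi^2$ for the phi coefficient). These
asymptotics treat pairs as independent although pairs sharing a tree are
not; a cluster bootstrap over whole trees ($B = 1000$) is available as the
honest alternative. Transforms mirror standard practice for skewed counts:
`log` uses $\log(x+1)$ since zero degrees occur, and `categorize` uses
quintiles of the pooled distribution (the bin definition is a package
choice; no canonical one exists).

## First-order Markov check

If recruitment is first-order Markov — a recruitee's attributes depend only
on the direct recruiter — then for a (linear, stationary) numeric attribute
the seed-to-wave-3 correlation should equal the product
$r_{01} r_{12} r_{23}$ of the stepwise correlations, and for a binary
attribute the phi coefficient implied by $\mathrm{diag}(\pi) P^3$, where
$P$ is the one-step transition matrix and $\pi$ the wave-0 marginal (the
marginal is taken from the seeds because the construct starts there). The
stepwise and direct correlations use *ordered* (earlier-wave, later-wave)
pairs without symmetrization: for a nonstationary chain the telescoping
identity $r_{03} = r_{01} r_{12} r_{23}$ holds for the ordered Pearson
coefficient but not for its symmetrized variant, and the direct estimate is
restricted to lineal pairs since the comparison concerns chains. The module
reports both numbers and never issues a verdict: with at most a handful of
deep trees the exact order of the process is not identifiable, only the
direction of the discrepancy.

For the symmetric two-state chain with stay probability $q$ and uniform
marginal the implied three-step phi is exactly $(2q-1)^3$, which the test
suite verifies both algebraically and through the matrix route.

## Effective contact rate

Under proportionate mixing the basic reproduction number is proportional to
the effective contact rate
$$C = m + \frac{v}{m},$$
with $m$ and $v$ the mean and variance of individual contact rates. The
sample variance uses the $n-1$ denominator (at the survey's $n \approx 350$
the choice does not move $C$ at one decimal). `category_summaries()`
computes $C$ for total degree, locations-only, travel-only, eating contacts
and household size; `effective_contact_from_moments()` is the
printed-inputs path that reproduces a published table from its means and
variances alone. Reported rates are rounded half-up to one decimal, the
convention of the published tables. Note that recomputing $C$ from
*rounded* printed means does not always reproduce a printed $C$ at one
decimal — the degree and household rows do, which is exactly what the
acceptance script checks.

For NB$(\mu, k)$ degrees, $C \to \mu + 1 + \mu/k$ as $n \to \infty$, a
closed form the tests use as an oracle.

## Drivers of online recruitment

The intention to recruit (did the participant request invitations on the
last survey page?) is modelled by logistic regression on degree, age, sex
(indicator for female), education as ordered codes 1-3, and household size
— the smallest model consistent with the adjustment set; degree enters
untransformed by default with a log variant behind a flag. Fitting is IRLS
(tolerance $10^{-8}$, 100 iterations) with standard errors from the inverse
observed information; constant covariates are dropped rather than silently
aliased, and separation surfaces as an explicit error naming the suspect
covariate. The fit is run with and without the seeds, since seeds did not
enter through peer invitation. `probability_vs_degree()` produces the
predicted probability along a degree grid at a fixed covariate profile,
with the 95% band formed on the link scale ($\pm 1.96 \cdot$ SE of the
linear predictor) and then inverse-logit transformed, so it respects
$[0,1]$ by construction.

# The synthetic generator

Real webRDS data cannot ship with the package, so `generate_forest()`
produces datasets with the statistical structure the analyses assume. The
built-in profiles pin every parameter that the published per-country tables
print:

* degree NB$(\mu, k)$: NL-like $(25.65, 1.00)$, TH-like $(58.51, 0.83)$;
* the expected locations/travel split of the degree, and the
  eating-contact NB parameters, derived from the printed per-category means
  and variances via $k = \mu^2/(v-\mu)$;
* seed demographics (age ranges, sex split, education shares),
  recruitment-method shares and completion rates.

Where nothing is printed, values were chosen once at levels realistic for
student-seeded online surveys and documented here: within-setting
sub-shares of contacts; a homophily kernel of recruitee age = reference age
$+\ \mathcal{N}(0, 8)$ years truncated to ages 14-80; sex retained with
probability $q = 0.65$; an education transition that keeps the seed
education distribution stationary (stay probability 0.5, otherwise redraw
from the marginal); and an invitation model
$\mathrm{logit}\,P(\text{invite}) = 0 + 0.01\,\text{degree} +
0.5\,\mathbb{1}[\text{female}]$ with success probability 0.3 per invitation
and at most four invitations — subcritical branching, as in the real
surveys, which died out within 5-6 waves. With `markov_order = 2` each
recruitee from wave 2 on draws its attribute kernel centred on the
recruiter or the grand-recruiter with probability 1/2 each — the minimal
deviation from first-order structure that the Markov check should detect.

Degrees are decomposed into per-setting counts by sequential-binomial
multinomial draws, so location + travel counts reconstruct the degree
*exactly*; the age-direction tallies make the share of younger contacts
grow with the participant's own age.

What the generator deliberately does **not** emulate: any dependence of
degree on demographics (the joint distribution is unobserved, so degrees
are independent of age/sex/education — flagged because real data almost
certainly violate it); clustering and repeated contacts across
participants; geography; epidemic processes on the network. Consequently,
passing tests demonstrate that the estimators recover the structure they
target under the stated model, not that the model captures every feature
of real survey data. Two further honest gaps: the random-walk age kernel
produces somewhat stronger distance-1 age assortativity than the published
correlations, and household sizes are capped at six, which understates the
published household-size variance.

# Numerical and design choices

* **Outlier filter**: degrees above 2200 are implausible under the contact
  definition and are removed by default; children of a removed participant
  are promoted to seeds so link distances inside surviving subtrees remain
  exact (dropping whole subtrees is available behind a flag). The filter is
  idempotent.
* **Completeness**: incomplete responses stay in the forest for structure
  but are excluded from attribute correlations and, by default, from the
  distribution fits and contact-rate summaries; the survey tables report
  both totals, and the package keeps the same distinction.
* **Rounding**: reported percentages and contact rates round half-up to one
  decimal, matching the published tables (base R's `round()` rounds half to
  even, hence `round_half_up()`).
* **File dialect**: UTF-8 CSV with a header, one row per participant,
  semicolon-joined symptom tokens, `loc_*`/`tra_*` prefixes for per-setting
  counts — chosen to round-trip exactly through `write_survey()` /
  `load_survey()`.
* **Reproducibility**: all generator randomness flows from a single
  `rng_seed`; identical seeds give bit-identical datasets and pipeline
  reruns give identical CSVs.
* **Degenerate inputs**: constant counts make $k$ unidentifiable
  (explicit error); all-zero contact rates leave $C$ undefined (error);
  a transition-matrix state never seen as recruiter keeps a uniform row
  with a warning; an empty wave stratum reports `NA` rather than failing.

# Problem sizes in the test suite

The simulation-based checks run at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: $n = 10^5$ draws for the NB
closed-form limit of $C$; 100 random forests (up to 200 nodes) against a
hand-written BFS oracle; 100 recovery runs at $n = 5000$ (NB, bootstrap
$B = 200$) and $n \approx 2000$ (logistic); 3000 chains for the first-order
Markov agreement and 50 replicates of 300 chains for the second-order sign
test; 100 power runs at $n = 300$ per sample and 1000 size runs at
$n = 100$ per sample (199 permutations each) for the Anderson-Darling
test.

# Limitations

The inferential machinery treats pairs as independent even though trees
induce dependence (the cluster bootstrap is the package's mitigation, not a
cure); the mixing analyses cannot see clustering or the unobserved full
contact network; the Markov check can flag higher-order structure but not
estimate its order; and RDS population-proportion estimation with degree
weighting is intentionally out of scope — the package analyses the sampled
forest itself.
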