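---
title: "Identity-by-state hierarchies in structured populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identity-by-state hierarchies in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgst)
```

## The hierarchy of non-identity probabilities

`popgst` works with probabilities of identity by state (IBS): the chance
that two genes sampled under a given scheme belong to the same allelic
class, regardless of genealogy.  A structured population defines an
ordered hierarchy of sampling levels — the pair of gametes that united
to form an individual, two genes from one deme, two genes from the
metapopulation — and each level $i$ is summarised by its non-IBS
probability $h_i$.  The association at level $i$ *relative to the level
below* is

$$G_i^\ast = \frac{h_i - h_{i-1}}{h_i}, \qquad
  1 - G_{IT}^\ast = \prod_{i=1}^{L} (1 - G_i^\ast) = \frac{h_0}{h_L}.$$

This is the diversity-based analog of the classical F-statistic
partition $1 - F_{IT} = (1 - F_{IS})(1 - F_{ST})$; `g_statistics()`
supports arbitrary depth $L$, and negative values are returned as-is —
a negative $G_i^\ast$ means pairs at level $i$ are *more* similar than
pairs at the level below, which is meaningful (and attainable; see the
two-deme model) rather than an estimation artefact.

For the island hierarchy (`island_levels()`) the three levels are
assembled from the IBS triple $(f, g_w, g_b)$ — uniting gametes,
distinct individuals within a deme, distinct demes — at finite deme
size $N$ and deme count $d$:

$$h_0 = 1 - f, \qquad
  h_1 = \frac{(1-f)/2}{N} + (1 - g_w)\Big(1 - \frac{1}{N}\Big), \qquad
  h_2 = \frac{h_1}{d} + (1 - g_b)\Big(1 - \frac{1}{d}\Big).$$

The $1/N$ term in $h_1$ deserves a note, because it is easy to get
wrong.  Sampling two genes from a deme without regard to zygote
structure picks both from one individual with probability $1/N$; that
pair is the *same physical gene* with probability $1/2$ (certainly IBS)
and the individual's two distinct genes otherwise (non-IBS with
probability $1 - f$), so the within-individual contribution to $h_1$ is
$(1-f)/2$, i.e. one minus the familiar identity term $(1+f)/2$.
Writing the term as $(1+f)/(2N)$ — omitting the complement — produces a
"non-identity" of $1/N$ in a completely monomorphic population.  The
form used here gives exactly $h = (0,0,0)$ at complete identity, sends
monomorphic data to the documented error path in
`estimate_hierarchy()`, and leaves all $O(1/N)$ asymptotics unchanged.
No truncation is applied: the $1/N$ and $1/d$ factors are kept exactly.

## The island model with partial selfing

The island model has $d$ demes of $N$ diploid reproductives.  Each
offspring chooses the deme its parents lived in by backward migration
(stay with probability $1-m$, each other deme with probability
$m/(d-1)$), a mother uniform in that deme, and a father who is the
mother with probability $s$ (selfing) and otherwise uniform in the deme
— so the outcross partner is again the mother with probability $1/N$,
giving a uniparental probability $\sigma = s + (1-s)/N$
(`uniparental_prob()`).  Each transmitted gene mutates independently
with probability $u$; a mutation moves the gene to any of the other
$K - 1$ allelic classes uniformly, and `K = Inf` is handled as the exact
infinite-alleles model (every mutation creates a novel allele), not a
large-$K$ approximation.

### The one-generation recursion and its event order

The recursion advanced by `island_step()` is *exact* for the
reproduction scheme above, which is also precisely the scheme the
forward simulator `sim_island()` executes.  With
$\psi = (1-m)^2 + m^2/(d-1)$ and
$\chi = 2m(1-m)/(d-1) + m^2(d-2)/(d-1)^2$ the probabilities that two
independently migrating genes end up in the same deme, and
$w = \tfrac{1}{N}\tfrac{1+f}{2} + (1 - \tfrac{1}{N}) g_w$ the identity
of two genes drawn from the same deme allowing for parent sharing:

$$f' = a\!\left(\sigma \tfrac{1+f}{2} + (1 - \sigma)\, g_w\right),\quad
  g_w' = a(\psi w + (1 - \psi) g_b),\quad
  g_b' = a(\chi w + (1 - \chi) g_b),$$

where $a(g) = A g + B(1-g)$ is the two-lineage K-allele mutation
operator (`mutation_step()`).  The model itself does not dictate a
unique bookkeeping of the migration step for the uniting-gamete
identity $f'$; alternatives that pass both parents' genes through the
migration mixing differ at $O(u + m)$.  We chose the form above because
it makes the recursion agree with the forward simulator *exactly* —
there is then no $O(m)$ bias hiding inside the Monte Carlo
cross-checks, and the oracle tests can run at tight standard errors.
At $u = 0$ the stationary condition reproduces the quasi-equilibrium
resolution $1 - f = (1 - g_w)(1-\sigma)/(1-\sigma/2)$ exactly, and the
property suite verifies the two scaled asymptotics

$$G_{IS}^\ast = \frac{s/2}{1 - s/2}, \qquad
  G_{ST}^\ast = \frac{\Delta}{\Delta + \frac{d}{d-1}
    \left[M \frac{d}{d-1} + \theta \frac{K}{K-1}\right]},$$

with error at most $c/N$ ($c \le 10$; measured $c \approx 0.3$ for
$G_{ST}^\ast$), halving as $N$ doubles over $N = 10^3, 2\cdot10^3,
4\cdot10^3$.  Here $M = 4Nm$, $\theta = 4Nu$ and
$\Delta = N/N_e = 1/(1 - s/2)$: partial selfing enters the
between-deme index only through the accelerated coalescence rate
(`effective_size()`), and a finite allele count inflates the effective
mutation pressure by $K/(K-1)$ — a factor $4/3$ for $K = 4$.

### Steady state

Because the recursion is affine, `island_steady_state()` obtains the
stationary triple by one exact $3\times 3$ linear solve rather than
fixed-point iteration; for $u \in (0,1)$ the map is a strict contraction
and the system is never singular.  At $u = 0$ the absorbing state
$(1,1,1)$ is returned directly.  Structural limits are preserved
exactly: with $m = 0$ the demes decouple and $g_b = 1/K$; with $d = 1$,
$s = 0$ the within-deme identity converges to the Malécot/Ewens value
$1/(1+\theta)$ as $N$ grows.

## The asymmetric two-deme model

The two-deme module works directly in coalescent scaling: deme 0 holds
a proportion $r$ of the reproductives, time is measured in units of
$2N$ generations with $N = (N_0 + N_1)/2$ the average deme size, a pair
of lineages in deme $i$ coalesces at rate $1/(2r)$ or $1/(2(1-r))$,
each lineage in deme $i$ migrates at $M_i/2$ ($M_i = 4Nm_i$), and
mutation strikes the pair at total rate $\theta = 4Nu$.  This is the
unique scaling in which the raw-parameter limits $M_i = 4Nm_i$ make all
three processes compete on one timescale; `two_deme_params()` warns
when migration rates are large relative to $1/N$, where the scaled
steady-state formulas stop being trustworthy.

Identity is modelled as the probability that the pair coalesces before
either lineage mutates — the infinite-alleles reading, under which the
negativity threshold below carries $\theta$ without any $K/(K-1)$
factor.  `two_deme_identities()` solves the three-state first-step
system (states: both lineages in deme 0, both in deme 1, one in each)
exactly.  Degenerate corners are handled explicitly: $\theta = 0$
returns all identities 1 (coalescence is certain); $M_0 = M_1 = 0$ with
$\theta > 0$ returns $g_b = 0$ with a warning (disconnected demes never
share ancestry — an answer, not an error).

The deme-specific indices
$\beta_{WT0} = (g_{w,0} - g_b)/(1 - g_b)$ and
$G_{ST,0}^\ast = (1-r)(g_{w,0} - g_b) /
[r(1 - g_{w,0}) + (1-r)(1 - g_b)]$ share their sign and satisfy
$|\beta_{WT0}| \ge |G_{ST,0}^\ast|$ everywhere.  Both go negative only
when between-deme identity exceeds within-deme identity, which at
steady state requires the focal deme's share to exceed

$$r_{\min} = \frac{1 + M_0 + 2(M_1 + \theta)}{2(M_0 + M_1 + \theta)} > \tfrac12,$$

so negativity needs $M_0 > 1$ *and* a majority deme; under hard
(conservative) migration $r M_0 = (1-r) M_1$ the condition is never
met.  The test suite confirms the closed form against a bisection on
the solver itself to $10^{-8}$ over a 50+ point grid, and the package
exposes the soft-migration monotonicity (`plot_r_min()`).

For Slatkin's coalescence-time index, `coalescence_times()` solves the
mutation-free first-step system for $E(T)$ by starting configuration.
The sampling weights for $E(T_s)$ and $E(T)$ are not dictated by the
model; the default draws two individuals uniformly from the
metapopulation, so within-deme pairs carry weights $r^2$ and $(1-r)^2$
(conditioned on cohabitation for $E(T_s)$, unconditional for $E(T)$).
An equal-deme weighting is available as an option.  A finite-difference
check in the suite confirms that the diversity-based index converges to
$F_{ST}^\ast = (E(T) - E(T_s))/E(T)$ as $\theta \to 0$.

## Stochastic oracles and what they do (not) emulate

Three simulators provide verification paths that share no algebra with
the analytic solvers:

* `sim_island()` — forward Wright–Fisher with the exact reproduction
  scheme above.  Migration is implemented as a per-offspring choice of
  parental deme (deme sizes therefore never fluctuate), selfing leaves
  an individual's contribution to the gamete pool unchanged, and every
  locus draws its own pedigree so loci are genuinely independent
  replicates; standard errors are computed across loci.  Defaults
  follow the stationary-regime conditions: burn-in $20 \cdot 2Nd$
  generations, samples every $2N$ generations, and a first-half versus
  second-half drift check on the sampling window (warning at $2$ SE,
  applied when the window holds at least 10 samples).
* `sim_pair_island()` — the same process run backward for a single pair
  of lineages, tracking allele labels along both branches (any mutation
  under `K = Inf` settles the outcome immediately).  Replicates that
  fail to coalesce within the generation cap — possible only when
  migration disconnects demes — are scored non-identical with a
  warning.
* `sim_two_deme_identity()` / `sim_two_deme_times()` — continuous-time
  event races in the two-deme scaling.

What the generators deliberately do **not** emulate: linkage (loci are
unlinked by construction, so tests say nothing about LD), selection,
fluctuating deme sizes, extinction–recolonisation, sequence-level
mutation models beyond K-allele/infinite-alleles, or genotyping error.
Agreement of the estimators with the analytic values on simulated data
therefore validates the estimation arithmetic under the model's own
assumptions, not robustness to real-data complications.

The oracle-equivalence tests run at deliberately modest problem sizes
chosen to keep the whole suite desk-scale while leaving Monte Carlo
standard errors well below the effects being checked: the forward
cross-validation grid uses $N = 50$, $d = 5$ with 40 loci and 50
sampled generations per configuration (about $2\times10^3$ per-locus
samples, hundreds of thousands of gene pairs), backward samplers use
$2$–$4 \times 10^4$ replicates, and the estimator-consistency check
uses 200 and 800 loci.  All comparisons are made at 3 standard errors.

## Estimators

`estimate_identities()` uses plug-in estimators matching the parameter
definitions: per locus, $\hat f$ is the proportion of homozygous
individuals; $\hat g_w$ averages over all unordered pairs of distinct
individuals within a deme the mean of the four cross-individual gene
comparisons; $\hat g_b$ does the same across deme pairs.  No
small-sample bias correction is applied — the targets are the model's
parameters, not any particular unbiased estimator, and corrections
would break the exact finite-$N$ identities used in the tests.  Demes
receive equal weight by default (the island model's demes are
exchangeable); a size-weighted option exists for strongly unequal
samples.  Missing genotypes are excluded pairwise, demes with fewer
than two callable individuals contribute nothing at that locus, and a
statistic with no usable data is reported as `NA`, never coerced to
zero.

`estimate_hierarchy()` combines loci by averaging the $h$ levels before
forming ratios (a ratio of averages, the standard construction for
multilocus diversity indices, which is far more stable than averaging
per-locus ratios whose denominators can be tiny); per-locus values are
emitted alongside so users can form either.  The census sizes $N$ and
$d$ entering the $1/N$ and $1/d$ terms default to the sample counts —
the right choice when the sample *is* the deme, and an explicit
escape hatch (`N =`, `d =` arguments) otherwise, since the model does
not tell us how to shrink the within-individual term when the sample is
a small fraction of the deme.

VCF input parses diploid `GT` fields with allele indices as labels;
phased and unphased calls are the same unordered pair, multiallelic
sites are kept, and sites are treated as independent loci — no LD
pruning is attempted, which is the user's responsibility.

## Numerical choices and edge cases

* All steady states are exact linear solves; no iteration, no
  convergence tolerance.
* Probability-level identities (partition closure, the difference
  formula for $\beta_{WT0} - G_{ST,0}^\ast$) are asserted at absolute
  tolerance $10^{-12}$ — all quantities are $O(1)$ probabilities.
* The complement-sharing probability in the selfing resolution
  ($c = 1/2$) is a named constant, not a magic number.
* Zero denominators raise errors that name the offending level or
  quantity (`h_i = 0`: fixation at level $i$; $g_b = 1$ or $g_w = 1$:
  no diversity at that level; $G_w = 1$ in the F-partition).
* Negative index values are never clamped anywhere.
* `d = 1` forces `m = 0` at parameter construction; single-deme data
  yield `G_1*` only, with `G_2*` reported missing rather than zero.

## Limitations

The package covers pair identities only — no three- or four-gene
coefficients, no sample-frequency spectra, and the two-deme solver is
exactly that (the pair-state machinery would generalise to $n$ demes,
but no such surface is exposed).  Variance estimation for the genotype
estimators (jackknife/bootstrap over loci) is a natural extension that
is not included; the per-locus output makes it straightforward
downstream.  The asymptotic formulas assume $s, 1-s \gg u, m, 1/N$;
the solvers themselves are exact for any parameter values, but
comparisons against the scaled formulas (and `r_min`) degrade outside
that regime, which is why the raw-parameter constructors warn there.
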