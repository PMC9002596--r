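---
title: "Statistical methods behind thermoherb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind thermoherb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoherb)
```

## The problem

Traditional pharmacopoeias annotate each herb with a temperament — a hot or
cold physiological effect — on a nine-level ordinal scale. Two public
databases provide such annotations along with each herb's chemical
ingredients and the ingredients' protein target genes, but the two do not
always agree, ingredient records are riddled with synonyms, and claims about
"hot-specific" chemistry require a statistical definition rather than
anecdote. `thermoherb` formalizes the whole chain: harmonize the two
annotations, test features for category enrichment, map the resulting
target genes onto pathways, and contrast expression signatures of hot- and
cold-associated components.

## Ordinal harmonization

Labels are normalized (case folding, whitespace squeezing, and one
separator family: `/`, `,`, and `-` are interchangeable) and matched against
a synonym table covering the nine classes; unknown labels are an error that
lists the accepted classes — they are never guessed, because a silently
mis-parsed label would propagate into every downstream count. The table is
user-extensible for database dialects.

For a herb present in both databases with levels $a$ and $b$:

* $a = b$: **exact** match, resolved level $a$;
* $\operatorname{sign}(a) = \operatorname{sign}(b) \neq 0$, $a \neq b$:
  **similar** — the two databases agree on the side but not the strength,
  and the herb is resolved to the level of smaller magnitude. Taking the
  milder annotation is deliberately conservative: it only ever moves a herb
  *out* of the extreme groups, so a "hot" call never rests on the more
  enthusiastic of two disagreeing sources.
* anything else: **discordant**, excluded from analysis.

Herbs found in one database only are reported and excluded by default
(`include_single_db = TRUE` keeps them at their single annotation).

Group membership is driven by a configurable `group_scheme`. The databases'
level semantics pin the endpoints but not the cutoffs, so the default is the
natural reading of the scale: HG = {+3, +4}, CG = {−4, −3}, EG = {0},
HGE = {+1..+4}, CGE = {−4..−1}, with NHG/NCG the complements among analyzed
herbs. The scheme validator enforces the containments (HG ⊆ HGE, CG ⊆ CGE,
HGE ∩ CGE = ∅, EG disjoint from both); under any valid scheme covering the
observed levels the five display bins CG, CGE∖CG, EG, HGE∖HG, HG partition
the analyzed herbs — a property the test suite checks on every synthetic
catalog.

## Ingredient identity

Ingredient records are merged by transitive closure over shared keys (alias,
PubChem ID, CAS ID) with a union–find; the canonical ID is the
lexicographically smallest alias of the component, which makes the partition
and its names independent of row order. An ingredient with zero target rows
is an explicit empty set ("target information unavailable"), distinct from
an ingredient that is absent — the distinction matters for the intersection
rule below.

## Enrichment statistics

Incidence is binary per herb: multiplicity of an ingredient within a herb,
or of a target gene across a herb's ingredients, carries no information
about category membership and is discarded. For focal category $A$ and
disjoint reference $B$ (complement categories already exclude the focal
side), a feature carried by $k$ of the $n = |A|$ focal herbs and $K$ herbs
of the $N = |A| + |B|$ combined herbs is scored by the one-sided upper tail

$$p = \sum_{x=k}^{\min(K,n)} \frac{\binom{K}{x}\binom{N-K}{n-x}}{\binom{N}{n}},$$

computed through the hypergeometric survival function. Only the top-$k$
features by focal occurrence (default 30 for ingredients, 50 for target
genes; ties broken lexicographically) are tested, and the BH correction is
applied within that tested family — the family is the set of hypotheses
actually examined, not the full feature universe. A feature is
**property-specific** when $p_{\mathrm{adj}} < \alpha$ (default 0.01) in
*both* of two comparisons; requiring both references simultaneously is the
stricter of the two readings the dual-comparison rule admits, and the
reference pair is an argument, so the (CG, NHG) and (CG, CGE) variants are
both available.

The common target of the specific ingredients is the intersection of their
target sets over *informative* ingredients only: an ingredient with no
target information cannot witness against a gene, so it is excluded from the
intersection and reported. If no ingredient is informative the result is an
empty set with an explicit flag.

Per-bin occurrence ratios $k_b/n_b$ over the five ordered bins are
standardized with the sample standard deviation; a flat profile maps to the
zero vector rather than 0/0.

## Pathway map

ORA of a gene list against a GMT collection uses the same hypergeometric
tail with the universe defaulting to the union of collection genes
(overridable — the right universe is the assay's, when known). Enriched sets
with $q \le 0.05$ become nodes; edges carry the combined similarity
$\tfrac12 J + \tfrac12 O$ (Jaccard and overlap coefficient; pure variants
available) and survive at $\ge 0.375$, the conventional enrichment-map
default.
Clusters are connected components, labeled by the largest member set —
cluster structure in such maps is read off connectivity, so no extra
clustering step is imposed. Raising the edge cutoff is a pure filter and can
only remove edges (property-tested).

## Component selection and preranked GSEA

An assayed component's z-profile over the five bins classifies it hot (HC)
or cold (CC) when the profile attains its maximum at the HG or CG bin with
$z \ge 1$. "Skewed towards" a group needs an operational threshold; one
sample standard deviation above the mean is the smallest round value that
rejects flat profiles, and it is exposed as `z_threshold`. Exclusion lists
are applied *after* classification with the original class logged, so an
audit trail survives.

Gene ranking between HC and CC samples uses a pooled-variance t with a
relative variance floor, $s^2 \leftarrow \max(s^2,
\epsilon\,\mathrm{median}(s^2))$, $\epsilon = 0.01$. The floor plays the
stabilizing role of an empirical-Bayes moderated variance in a deterministic,
dependency-free form; at the scale this package targets the induced rankings
agree at the top of the list. A zero-variance, zero-difference gene scores
0. The plain mean difference (`statistic = "lfc"`) is also available: with
few samples per side the t statistic rewards luckily small within-group
variances, so a strongly shifted gene set is recovered *exactly* at the top
of the list more reliably by the mean difference, while the t is the better
calibrated choice for inference — the tests exercise both.

The enrichment score of a set with $m$ of $N$ ranked genes is the signed
extremum of the running sum that rises by $|s_j|^w / \sum_{hits} |s|^w$ at
members and falls by $1/(N-m)$ otherwise ($w = 1$ by default; 0 and 1.5
supported; an all-zero hit profile falls back to equal weights). When the
maximal rise and fall tie exactly, the positive extremum is taken. The null
is gene-label permutation: random same-size sets from the same ranking,
which is the appropriate regime for a preranked list where no sample-level
exchangeability is available. With observed score $ES$ and null scores
$\{ES^*_i\}$,

$$p = \frac{1 + \#\{|ES^*| \ge |ES|,\ \text{same sign}\}}
          {1 + \#\{\text{same-sign } ES^*\}},\qquad
  NES = \frac{ES}{\operatorname{mean}|ES^*_{\text{same sign}}|},$$

with BH across the collection. If no null score shares the observed sign the
p-value floors at $1/(1+n_{perm})$ and the result is flagged degenerate
rather than silently normalized. Permutation scores are computed from hit
positions alone in $O(m \log m)$, which the suite verifies against the full
running-sum scan; the running-sum implementation itself is cross-checked
against an independent preranked implementation (`fgsea::calcGseaStat`).
The ranking is defined by the statistic with lexicographic tie-break, never
by storage order, so shuffling input rows cannot change any score.

## What the synthetic generator emulates — and what it does not

`synth_config()` fixes the study conditions: 300 herbs with a symmetric
nine-level distribution putting roughly 75 herbs on each of the hot and cold
sides (so both compared sides comfortably exceed 40 herbs);
exact/similar/discordant concordance at 0.83/0.11/0.06, the proportions
observed when two real property databases are intersected; 400 ingredients
of which five are planted hot-specific at occurrence 0.5 in hot-level herbs
versus 0.05 elsewhere against a 0.08 background rate; a planted target gene
shared by every informative planted ingredient, with one planted ingredient
deliberately emitted without target information; and a 2,000-gene expression
matrix, five samples per side, with a 50-gene set shifted by δ = 1.0 against
unit noise. The "similar" perturbation moves the second database's level one
step toward zero where a milder same-sign level exists (one step away for
the ±1 levels), so the resolved "milder" level is always well defined; an
even herb drawn similar is recorded as exact, since zero-level pairs cannot
differ. Per-table RNG streams are derived from the one seed, so generating
the expression matrix never perturbs the catalog draws.

The generator reproduces the *statistical* structure the pipeline consumes —
it makes no attempt at chemical realism, real databases' heavy-tailed
ingredients-per-herb distributions, correlated gene expression, or
annotation biases. Passing recovery tests therefore demonstrates that the
statistics find what they are defined to find under controlled signal, not
that any particular real herb or gene will reproduce.

## Numerical and design notes

* Hypergeometric tails come from the survival function, never summed naive
  mass; BH is the standard step-up. Both are verified against brute-force
  oracles (full enumeration for all populations up to 12; sort/cummin
  reconstruction on random p-vectors) to 1e−12.
* Readers reject malformed input with row/line numbers; nothing is coerced
  silently. Gene symbols are upper-cased; no alias or orthology mapping is
  attempted.
* Problem sizes in the test suite are the package's own choices: recovery
  and calibration claims use 100–200 seeds at the generator defaults, the
  GSEA power check uses 1,000 permutations and the null-calibration check
  499 (granularity 1/500 is ample at the 0.05 level).
* Known limitations: the dual-comparison rule is sensitive to small focal
  groups (the hypergeometric tail is discrete); the variance-floor t is not
  a calibrated test statistic and is used only for ranking; network
  clusters being connected components means one spurious high-similarity
  edge can merge two themes — inspect the exported edge table when a
  cluster looks too broad.
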