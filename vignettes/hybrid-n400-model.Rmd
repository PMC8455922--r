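---
title: "A frame-based hybrid model of the N400: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A frame-based hybrid model of the N400: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n400frames)
```

## The model

The N400 is a centroparietal negative ERP deflection peaking roughly
300-400 ms after word onset, modulated by how well a word fits its
semantic context. `n400frames` implements a *hybrid* account in which the
amplitude at a critical word (CW) reflects two separable operations over
structured category knowledge, rather than a single quantity such as cloze
probability or plausibility:

1. a **predictability component** — the gain in information about the
   open argument position, measured as entropy reduction over the
   pre-activated features that the CW does not disconfirm; and
2. a **plausibility component** — the typicality of the CW's category
   relative to the argument-position concept, measured as a
   diagnosticity-weighted sum of min-rule similarities.

### Stochastic frames and default inferences

Categories are represented as **stochastic frames**: sorted
attribute-value structures in which each attribute (chain) $A$ carries a
finite value space and a conditional probability distribution
$P(V\!A \mid C)$. A **category concept** $C_{arg}$ is a category situated
in a context; its chains split into *context-independent* ones (selection
restrictions such as animacy, active on every occasion) and
*context-dependent* ones licensed by correlations in the scenario (a
tropical-looking resort makes `habitat = tropics` expectable for whatever
was planted).

A feature $V\!A$ is a **default inference** of $C$ ("Cs are normally V")
iff $P(V\!A \mid C)$ is the *unique* maximum over $A$'s value space and
strictly exceeds a threshold $r$. The package default is $r = 0.5$ with a
strict inequality; $r$ is configurable globally (`run_config()`) and per
scenario. A tied maximum above the threshold yields *no* default — there
is no single normal value — and signals a classed warning
(`n400frames_tie`) rather than picking arbitrarily. Ties at or below the
threshold are silently non-defaults (the threshold rule already excludes
them), which is what the seaside fixture exploits to make "trainees"
merely *compatible* with the in-water expectations.

### The two update steps

Encountering the CW partitions the pre-activated set
$\Omega = \mathrm{defaults}(C_{arg})$ three ways (`update_set()`):
confirmed ($\Sigma_{conf}$: also a default of $C_{CW}$), disconfirmed
($\Sigma_{disconf}$: a rival value is a default of $C_{CW}$), compatible
($\Sigma_{comp}$: neither). The operation is *partial*: if a chain
carrying a default of $C_{arg}$ is not defined at all in $C_{CW}$ (the
"drawer" case — no animacy attributes), categorization fails. Failure is
a modeled outcome, not an exception: typicality is not computed and the
predicted index takes its maximal value 1.

The second step (`update_t()`) builds the resulting frame from
$\Sigma_{conf}$ plus, for each disconfirmed chain, the CW's own default
value; compatible features are not carried over because nothing has
verified them yet. Which value a disconfirmed chain ends up with is
stated in the source only through the tulip example (the CW's values);
we follow that example.

### Predictability: entropy over n-step extensions

Entropy at time $t$ is Shannon entropy over the complete value
assignments ("extensions") of the still-open chains,

$$H(t) = -\sum_{f} P(f \mid f_t)\, \log_{10} P(f \mid f_t),$$

with joint extension probabilities given by the product of per-chain
conditionals (independence across chains; a scenario could override this
with an explicit joint table, but none of the worked fixtures needs to).
Two consequences worth knowing:

* Only the **context-dependent** chains of $C_{arg}$ enter the
  enumeration; the t1 frame is the minimal frame closed under the
  context-independent defaults.
* At t2, chains in $\Sigma_{conf} \cup \Sigma_{comp}$ count as fixed —
  compatible features *can* still be verified, so they contribute to the
  information gain. Disconfirmed chains stay open. Hence a fully
  disconfirming CW ("tulips") leaves $H(t_2) = H(t_1)$ and gains nothing.
* Under the product rule, $\Delta H$ equals the sum of the per-chain
  entropies of the newly fixed chains; the test suite verifies this
  decomposition, and verifies every entropy against an independent
  brute-force enumeration oracle.

**The log base is 10.** This is forced by the worked numbers: the
four-extension distribution (0.54, 0.36, 0.06, 0.04) has entropy 0.433 in
base 10, 0.998 in nats, 1.440 in bits. The base remains exposed
(`run_config(log_base=)`) for anyone who prefers bits.

### Plausibility: similarity, diagnosticity, typicality

Similarity of a feature between two concepts is the min rule,
$sim(C_1, C_2 \mid V\!A) = \min(P(V\!A \mid C_1), P(V\!A \mid C_2))$.
Attribute weights come from **cue-validity**, the reversed conditional
$P(C \mid V\!A)$ computed by Bayes' rule against the concept's **contrast
classes** — sibling category concepts obtained by varying the values of
the chains whose correlations license the context-dependent defaults
(e.g. a resort that should look *moderate* rather than tropical).
Contrast classes and their distributions are scenario data; priors over
classes default to uniform, which is what the worked cue-validity
arithmetic (0.9 / 0.1) implies. The discriminative value of an attribute
is the maximum cue-validity over its values, and **diagnosticity** is
those d-values normalized to sum 1. A scenario may instead *stipulate*
the weights (the birthday fixture does: 0.45 / 0.1 / 0.45), in which case
computation is bypassed and the profile is tagged `source = "stipulated"`.

Raw typicality is

$$\mathrm{typ}(C_{arg}, C_{CW}) = \sum_j \mathrm{diag}(A_j)
  \sum_i \min\!\big(P(V_iA_j \mid C_{arg}), P(V_iA_j \mid C_{CW})\big),$$

with inner sums over the **full value space** of each profiled attribute
— this is what reproduces the worked tables exactly (0.937, 0.6815,
0.4815, 0.12), and it gives the tidy identity
$\mathrm{typ} = 1 - \sum_j \mathrm{diag}_j \cdot TV_j$ (total-variation
distance), which the tests check on random scenarios. A *normalized*
variant divides by the self-typicality of $C_{arg}$ with inner sums
restricted to $C_{arg}$'s default features; that restriction is our
interpretation of how a low-constraint context lowers the typicality
ceiling (with full-space sums the denominator is identically 1 and the
variant would be vacuous). Raw is the default everywhere.

### The combined index

The source account deliberately leaves the combining function open,
requiring only monotonicity in both components. The package's choice is
the simplest interpretable one:

$$\mathrm{index} = \alpha\,\Big(1 - \frac{\Delta H}{H(t_1)}\Big)
  + \beta\,(1 - \mathrm{typ}), \qquad \alpha + \beta = 1,$$

with defaults $\alpha = \beta = 0.5$. When $H(t_1) = 0$ (no
context-dependent chains, e.g. the LC seaside variant) there is nothing
to predict and the predictability term is dropped, leaving
$\beta(1-\mathrm{typ})$. Every report exposes the raw components so users
can substitute their own $g$.

**A known limitation worth stating plainly.** With only the three
attributes of the birthday fixture, "healthy ... veggies" confirms *more*
open defaults than "healthy ... cake" (taste vs. only served_at), so the
predictability term ranks that pair opposite to typicality, and the
combined index reproduces the four-condition ordering sweet-cake <
healthy-cake < healthy-veggies < sweet-veggies only when plausibility
dominates ($\beta > \alpha$). This is a truncation artifact of the
three-attribute world — with more attributes (preparation, ingredients,
...) healthy cake would confirm more — and the acceptance suite therefore
asserts the birthday ordering on the plausibility term (equivalently the
exact typicality ordering) for all tested weights, plus the combined
index at $(\alpha, \beta) = (0.25, 0.75)$. The resort ordering palms <
pines < tulips holds on the combined index for all tested weights.

### Thematic roles and schema knowledge

When the context activates several argument concepts (the prescription
example: actor, recipient, medicine), each pre-activated feature is
prefixed with its thematic role, and each role carries a diagnosticity —
the expectation that the CW fills it, highest for undischarged arguments.
`role_typicality()` sums role weight x inner typicality; a role whose
profiled chains (selection restrictions such as animacy) are undefined
for the CW's category contributes 0. Other penalties are conceivable;
zero contribution is the minimal reading of "selection restrictions must
be taken into account". Role weights and distributions are scenario data
— the source gives no formula for them, and its prescription materials
print no probabilities, so the packaged test fixture is synthetic and
labelled as such.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold_r` | 0.5 (strict) | default-inference threshold; raising it only removes defaults (antitone, property-tested) |
| `log_base` | 10 | entropy/surprisal base; 10 matches the worked values |
| `alpha`, `beta` | 0.5, 0.5 | index weights, must sum to 1 |
| `extension_depth` | 3 | maximal attribute-chain depth n |
| `extension_cap` | 1e5 | guard on the enumerated product size |
| `typicality_variant` | raw | raw (worked-value variant) or normalized |
| `tolerance` | 0.005 | absolute tolerance against printed (rounded) values |

## What the synthetic generator emulates — and what it does not

`generate_random_scenario()` produces 2-4 attributes with 2-3 values
each, per-attribute distributions with a unique peak drawn uniformly from
[0.55, 0.95] and the remainder split by a uniform Dirichlet. The peak
range is a deliberate choice: every chain then licenses a default at
r = 0.5, which is what the worked tables look like (0.9/0.1, 0.95/0.05,
0.6/0.4) and what makes the partition-law and decomposition properties
informative. One CW always duplicates the argument concept's tables (a
best-completion control, so its partition can contain no disconfirmed
feature by construction) and, when at least two CWs are requested, one is
forced to conflict on a context-dependent chain. The generator does not
emulate: flat (tie) distributions, categorization-failure signatures,
stipulated contrast classes, or role annotations — those are exercised by
the hand-built fixtures. A green property suite therefore establishes the
algebraic invariants on peaked, fully defined scenarios, not behavior on
degenerate inputs, which have their own directed tests.

## Numerical choices

* Probability vectors must sum to 1 within 1e-9 in memory; the JSON
  loader renormalizes deviations up to 1e-6 (float round-trip drift) and
  rejects anything larger, naming the offending chain.
* Comparisons against printed values use *absolute* tolerances: 5e-4 for
  three-decimal values, 5e-3 for two-decimal ones (the source rounds
  0.2923 to 0.29 and 0.1412 to 0.14), 5e-5 for the four-decimal
  typicalities.
* `0 log 0 = 0`; surprisal of 0 returns `Inf` rather than erroring.
* Degenerate guard in the index: `delta_h_max = 0` drops the
  predictability term (see above) instead of dividing by zero.
* Value subsumption in the information ordering is label equality, with
  the sort hierarchy consulted when both labels are declared sorts; the
  worked material never exercises non-atomic value subsumption
  numerically, so nothing deeper is built.

## Known limitations

* Recursion is realized as chains over a flat per-scenario signature with
  bounded depth; there is no unbounded frame nesting or typed
  unification.
* Correlated prenominal revisions are scenario data (the source
  stipulates its revision magnitudes); no correlation-propagation engine
  is included.
* The package predicts a unit-interval *index*, not microvolts or
  latencies, and does not model the temporal dissociation of the two
  components.
* Probabilities are subjective inputs; nothing is estimated from corpora
  or norming data.
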