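---
title: "Scanning, calibrating and perturbing Boolean signalling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning, calibrating and perturbing Boolean signalling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolcal)
```

## The modelling problem

Large molecular interaction maps of cell signalling can be converted into
executable Boolean models: each biomolecule is a node holding 0 or 1, and a
logical rule over its regulators (AND/OR/NOT) updates it. Under the
*synchronous* scheme every node applies its rule simultaneously at each
discrete step, so the dynamics is a deterministic map $F$ on the state
space $\{0,1\}^n$. Long-run behaviour is captured by attractors: *steady
states* $s$ with $F(s) = s$, and *cycles* of length $\ge 2$. Attractors are
the modelling analogue of stable cell phenotypes, which is why this
package's whole pipeline is organised around finding them, filtering them,
and matching them to expression data.

Environmental context enters through *input nodes* — nodes without
regulators, clamped externally. A model with $n$ free inputs has $2^n$
environmental conditions, each with its own attractor structure, so the
central computation is a scan: for every combination of free-input values,
decide whether the model stabilises and to which state.

`boolcal` implements that pipeline end to end:

1. **model_core** — read models from SBML-qual or a BMA-style JSON dialect,
   classify nodes (inputs / internals / suffix-named phenotypes), and
   restrict a model to the ancestors of its phenotype nodes.
2. **dynamics** — synchronous stepping, trajectory simulation, and a
   two-phase stability proof per input combination.
3. **attractor_scan** — deterministic enumeration of input combinations,
   parallel collection of per-combination verdicts, checkpoint/resume.
4. **calibration** — discretize differential-expression evidence, filter
   steady states by phenotype constraints, score them with the simple
   matching coefficient, and average the top scorers into a calibrated
   state.
5. **perturbation** — single and double knockout screens from the
   calibrated state, with synergy detection.
6. **synthetic_fixtures** — seeded model generators and a brute-force
   attractor oracle that every stage is validated against.

Only granularity-1 (strictly Boolean) models are supported; parsers reject
wider ranges up front rather than approximating multi-valued semantics.

## The two-phase stability proof

Explicitly enumerating $2^n$ states per input combination is hopeless at
realistic model sizes, so `prove_stability()` follows a two-phase scheme.

**Phase 1 — range reduction.** Every ruled node starts with the value set
$\{0,1\}$; inputs start at their clamped singleton. Each node's set is
repeatedly replaced by the image of its rule over the product of its
regulators' current sets until nothing changes. Starting from the top
element and applying a monotone operator, the iteration converges to the
greatest fixpoint, which contains every attractor state: if all sets
collapse to singletons, the model provably has a unique steady state and no
cycle under these inputs, and the proof is done without touching the state
space. For feedback-free (acyclic) regulation this always succeeds, which
is why DAG fixtures have a closed-form oracle (topological evaluation).

**Phase 2 — residual search.** Nodes whose sets stay at $\{0,1\}$ span a
residual space that is forward-closed under $F$. When its size is within
`search_budget` (default $2^{16}$), the package enumerates it, builds the
successor map in vectorized form, and extracts all fixed points and cycles
of the functional graph exactly: the verdict is *stable* iff there is
exactly one fixed point and no cycle, otherwise *not stable* with a witness
(a cycle, or multiple fixed points — both reported distinctly, since a
scan consumer may treat multistability differently from oscillation).
Published tools prove the same property with satisfiability queries; the
guarantee — find any cycle or extra fixed point — is what matters here, not
the mechanism, and exhaustive search over the reduced space keeps the
implementation dependency-free and exactly checkable against the oracle.

When the residual space exceeds the budget, seeded simulations from a
deterministic pseudo-random stream (a documented LCG constant; R's global
RNG is never touched) can still *refute* stability by finding a cycle or a
second fixed point, but can never prove it — such runs return
`"inconclusive"` as a first-class status rather than a silent guess.

Every steady state returned anywhere is re-checked against
`sync_step()` before it is reported (a cheap soundness guard).

## Scan determinism and the combination index

The scan orders free inputs lexicographically and encodes combination $i$
little-endian: bit $j$ of $i$ is the value of the $j$-th free input. The
encoding is a stable contract so published scans can be referenced by
index. Records are keyed by index, which makes the aggregate independent of
worker count and scheduling; checkpoint blocks are written (and re-read)
as TSV so resumed and uninterrupted scans serialize identically.
Free-input counts above $2^{24}$ combinations require an explicit
`allow_large` override: full-scale scans (e.g. $2^{21}$ combinations)
belong on clusters, and the guard prevents accidental week-long desk runs.

## Calibration against expression evidence

Differential-expression calls are discretized: significant up-regulation
(adjusted $p <$ 0.05 by default) maps to 1, significant down-regulation to
0, everything else is excluded — Boolean states carry no information about
unchanged molecules. The threshold comparison is strict by default (the
common convention; inclusivity is configurable), and literature-derived
values are merged with expression-derived ones, failing loudly on
disagreement unless a resolution policy is chosen.

Candidate steady states are first filtered by phenotype constraints (the
biologically required values of the cell-specific phenotype nodes), then
scored against the observation vector with the simple matching coefficient

$$S = \frac{N_{00} + N_{11}}{N_{00} + N_{11} + N_{10} + N_{01}},$$

counting agreement and disagreement over the observed nodes only. Observed
names that resolve to no model node are quarantined and excluded from the
counts (an optional name map translates gene symbols to node names), since
observation tables routinely mix mRNA- and protein-level identifiers.

All states tied at the maximal score are kept — no secondary ordering is
imposed — and averaged per node. Nodes with mean exactly 0 or 1 are
*fixed*; fractional nodes are *unfixed* (the evidence does not pin them
down). `match_report()` classifies each observed node as match, mismatch or
unfixed-overlap; the headline percentage counts only fixed matches and is
rounded half-up to one decimal, with unfixed overlaps reported separately
rather than silently counted either way.

A planted-observation argument underpins the recovery tests: if the
observation is a steady state with $k$ positions flipped, and $k$ is below
half the Hamming distance to every other steady state, that state is the
unique argmax of $S$. The suite verifies this by brute force on seeded
models.

## Knockout screens

A knockout clamps nodes at 0, mimicking pharmacological inhibition (the
screens target inhibitor-druggable components; clamping at 1 is exposed for
over-expression studies but unused by default). Simulation starts from the
*resolved* calibrated state: fixed nodes take their calibrated value, and
unfixed nodes take a policy value — zeros by default, with the policy
recorded in every result. The choice is deliberately explicit because the
averaged state does not dictate it; a sensitivity check re-running a screen
under the `ones` policy shows when labels depend on it (the toy fixture's
JAK-pair effect is such a case, because an unfixed receptor branch can
substitute for the knocked-out kinases).

Each phenotype is classified against its baseline: *induced* (0
$\rightarrow$ 1), *suppressed* (1 $\rightarrow$ 0) or *unchanged*; cyclic
attractors mark the run *oscillatory* and report the per-phenotype value
sets over the cycle. The double screen tests all unordered pairs and flags
a pair *synergistic* when it produces a phenotype change neither single
knockout produces alone — the signature of redundant pathway branches that
must be cut together.

## What the synthetic fixtures do and do not emulate

`random_boolean_model()` draws signed regulator sets from a seeded stream
and builds rules by the topology-derived default
`(OR of activators) AND NOT (OR of inhibitors)`; the acyclic flag restricts
regulators to smaller topological indices, forcing a DAG. This emulates the
structural features the pipeline depends on — input nodes, signed
regulation, feedback (or its absence) — but not the degree distribution,
motif structure or rule heterogeneity of curated disease maps, nor
realistic transcriptome statistics (DEG fixtures are minimal typed rows).
Because the real map-conversion tooling does not document a unique rule
form for heterogeneous co-regulation, the default-rule builder is for
fixture generation only and is not claimed to reproduce any converter's
output. Passing tests therefore demonstrate correctness of the algorithms
on the contract (Boolean rules, granularity 1, suffix-named phenotypes),
not biological fidelity of any particular generated network.

`brute_force_attractors()` is the independent oracle: it enumerates the
full functional graph (all $2^n$ non-input assignments), so cycles of any
length are found exactly; a 20-node guard keeps it near $10^6$ states. The
oracle deliberately shares no code with `prove_stability()`'s reduced-space
path.

The toy macrophage fixture is a 17-node acyclic model with the naming
conventions of disease-map derived models (`_M1_macrophage` and `_signal`
phenotype suffixes), wired so that one input condition satisfies the
inflammatory constraint, the NFkB hub knockout flips both cell-specific
phenotypes, an ERK knockout suppresses proliferation only, and the
JAK1/JAK2 pair is the unique synergy. Its golden outputs under
`inst/extdata/toy/` were computed with the brute-force oracle, so the
end-to-end test compares the pipeline against an independent route.

## Numerical and design choices

- **Evaluation.** Rules compile to vectorized R expressions (`pmin` for
  AND, `pmax` for OR, `1 - x` for NOT) over a 0/1 state matrix, so the
  oracle and the residual search evaluate whole state spaces per call; all
  arithmetic is exact on integers and no tolerances are involved anywhere.
- **Degenerate inputs.** Models with zero inputs scan as a single
  combination ($2^0$); empty constraints filter vacuously; a constant rule
  is a valid expression, and a knocked-out input becomes a constant-0
  non-input so enumeration and dynamics stay consistent.
- **Ties.** Top-score ties are all kept (the calibrated state is defined
  over them); `as_is_threshold` initial-state resolution refuses a mean of
  exactly 0.5 instead of breaking the tie arbitrarily.
- **Grammar subsets.** The BMA-dialect parser accepts variable references,
  `min`, `max`, integer constants and the complement form `1 - expr`
  (rejecting `avg`/`ceil`/`floor` with a clear error): every accepted
  formula is exactly Boolean. The SBML-qual reader accepts the
  AND/OR/NOT/eq MathML fragment and names the offending node in errors.
  Node identity across formats is the whitespace-trimmed display name,
  because observation tables are keyed by biological names; the format ids
  are preserved in annotations.
- **Upstream restriction.** Inputs feeding only removed nodes are removed
  with them and listed in the removal report (they cannot influence the
  retained dynamics; the report preserves traceability for pipelines that
  fixed them at a default constant instead).
- **Simulation caps.** Knockout simulations default to
  `2 * n_nodes + 10` steps, matching the fast convergence of granularity-1
  models while staying bounded; the scan path uses the stability proof,
  not simulation.
- **Problem sizes.** The test suite and the acceptance script validate the
  proof against the oracle on 100 seeded models of 3–10 ruled nodes and
  1–3 inputs across every input combination, recovery on 8-node DAG
  batteries, and determinism on 4-free-input scans — sizes chosen so the
  whole validation runs in seconds on a laptop while still covering
  feedback, multistability and oscillation.

## Known limitations

- Only the synchronous scheme is implemented; asynchronous updates can
  exhibit attractors the synchronous scan never visits.
- Filtering to steady states discards oscillatory behaviour by design;
  cyclic witnesses are counted and reported but not analysed further.
- `"inconclusive"` is possible when a residual space exceeds the search
  budget and no witness is found by seeded simulation; the verdict is
  honest but not a proof either way.
- The calibrated state averages over tied steady states; it is generally
  not itself a steady state of the unperturbed model, and screen baselines
  therefore depend (visibly, via the recorded policy) on how unfixed nodes
  are resolved.
- Observation evidence is assumed cell- and condition-specific but not
  phenotype-specific; mismatches concentrated in redundant or
  phenotype-divergent pathways are expected and are surfaced per node by
  `match_report()` rather than hidden in the percentage.
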