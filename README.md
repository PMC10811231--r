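# boolcal

Steady-state scanning, calibration and in-silico knockout screening of
large Boolean models of cell signalling.

## What problem this solves

Curated molecular interaction maps (hundreds of biomolecules) can be
converted into executable Boolean models: every node holds 0/1 and is
updated by a logical rule (AND/OR/NOT) over its regulators. Under the
synchronous update scheme the dynamics is a deterministic map `F` on
`{0,1}^n`, and the biology lives in its attractors — steady states
`F(s) = s` correspond to differentiated cell states, cycles to oscillatory
programs. The difficulty is scale: environmental context enters through
*input* nodes (no regulators, clamped externally), and a model with `n`
free inputs has `2^n` conditions to examine, each over an exponentially
large state space.

`boolcal` is for modellers who have such a model (from SBML-qual or a
BMA-style JSON dialect) plus binary expression evidence, and want to:

1. **Scan** every free-input combination for its attractor, using a
   two-phase stability proof — iterative *range reduction* of each node's
   reachable value set (all singletons = proof of a unique steady state),
   then exact fixed-point/cycle search over the residual space — instead of
   brute-force state enumeration. Scans are parallel, checkpointed, and
   deterministic for any worker count.
2. **Calibrate** the model: filter the steady states by required phenotype
   values, score each against discretized differential-expression
   observations with the simple matching coefficient

   `S = (N00 + N11) / (N00 + N11 + N10 + N01)`,

   keep all top scorers, and average them into the calibrated state, whose
   per-node means classify nodes as fixed (0/1) or unfixed.
3. **Screen knockouts**: clamp candidate drug targets at 0, simulate from
   the calibrated state, classify every phenotype node as induced,
   suppressed or unchanged, and flag target *pairs* whose combined knockout
   produces a phenotype change neither single knockout achieves (synergy).

Everything is validated against an independent brute-force oracle that
enumerates the full synchronous transition graph on seeded random models.

## Worked example

The package ships a 17-node toy macrophage model (4 inputs, an NFkB hub,
redundant JAK kinases, suffix-named phenotype nodes) with an observation
vector and phenotype constraint, mirroring the structure of disease-map
derived models at a desk-testable size:

```r
library(boolcal)

fx <- toy_macrophage_fixture()
fx$model
#> <boolean_model> toy_m1_macrophage: 17 nodes (4 inputs, 3 phenotypes), granularity 1

result <- scan(fx$model)
result
#> <scan_result> toy_m1_macrophage: 16 combinations (16 stable, 0 cyclic, 0 multistable, 0 inconclusive)
```

All 16 input combinations stabilise (the model is acyclic). Calibration
filters the steady states by the inflammatory constraint (Apoptosis OFF,
Proliferation ON), scores the survivors against the 8-node observation
vector, and averages the top scorers:

```r
steady <- filter_steady(result)$states
cal <- calibrate(steady, fx$observation, fx$constraint)
cal$calibrated
#> <calibrated_state> mean over 2 states: 15 fixed, 2 unfixed nodes
cal$report$percentage
#> [1] 100
```

Two tied steady states (differing only in the LPS/TLR4 branch) match the
observation perfectly, so 15 nodes are fixed, 2 remain unfixed, and the
calibrated state reproduces 100% of the observed values. Knockout screens
then run from this state:

```r
screen <- single_ko_screen(fx$model, cal$calibrated, fx$targets)
screen$table
#>   target status Proliferation_M1_macrophage Apoptosis_M1_macrophage Inflammation_signal
#> 1   NFkB steady                  suppressed                 induced          suppressed
#> 2    ERK steady                  suppressed               unchanged           unchanged
#> 3   JAK1 steady                   unchanged               unchanged           unchanged
#> 4   JAK2 steady                   unchanged               unchanged           unchanged
#> 5  STAT3 steady                   unchanged               unchanged           unchanged

pairs <- double_ko_screen(fx$model, cal$calibrated, fx$targets, single = screen)
pairs$synergy_pairs
#> [1] "JAK1+JAK2"
```

Knocking out the NFkB hub induces apoptosis and suppresses proliferation
of the modelled inflammatory cell; ERK knockout suppresses proliferation
only; and JAK1/JAK2 is flagged as the one synergistic pair — each kinase
alone is redundant, but cutting both silences the STAT branch and flips
both cell phenotypes.

Command-line wrappers for the scan and the screens are in `inst/cli/`
(`scan.R`, `ko.R`), thin Rscripts over the same functions.

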