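---
title: "Archiving, validating and reusing QSAR models with qdbtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archiving, validating and reusing QSAR models with qdbtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdbtools)
```

## The problem

A published QSAR model is only as useful as it is reproducible. An
archive that merely states coefficients is not enough: to audit or reuse
a model one needs the compounds, the measured endpoint values, the exact
descriptor values the authors used, the mathematical form of the model,
and the predictions the authors obtained — all cross-linked so that a
machine can re-derive the predictions and compare. qdbtools implements
such an archive format (the QSAR DataBank container layout) and the
computations a model repository runs on top of it: structural
validation, reproducibility checking, prediction statistics,
applicability-domain (AD) analysis and a prediction engine.

## The archive model

An archive holds five ordered registries of *containers* — compounds,
properties, descriptors, models, predictions — each an identified record
with optional name/description/labels and named *cargo* payloads.
Conventions:

* Container ids follow `^[a-z0-9][a-z0-9-]*$` so that they can name
  directories inside the ZIP container and appear in URLs.
* `values` cargos are two-column TSV (`compound-id<TAB>value`) with
  `N/A` for missing values. Values are kept as **decimal text**,
  verbatim: the package never re-formats a stored number, so archives
  round-trip byte-exactly and the printed precision of a value remains
  observable (it defines the reproducibility tolerance below).
* References come in two strengths. *Strong* references
  (model→property, model→descriptors, prediction→model) must resolve;
  a dangling one is a structural error. *Weak* references — the
  compound-id keys inside a values cargo — are data whose resolution
  status the validator reports.
* A model's mathematical form lives in its `equation` cargo, in a small
  dialect fixed by this package (the format itself does not prescribe
  one): a header line `type=regression` or
  `type=classification; cuts=...; labels=...`, then one expression over
  descriptor ids with `+ - * / ^`, parentheses and
  `ln, log10, exp, sqrt, abs`. Classification is a thresholded
  regression score: score ≤ cutᵢ selects the i-th label, anything above
  the last cut the last label. One deliberate restriction: although
  container ids may contain `-`, identifiers inside an equation may not
  (it would be ambiguous with subtraction), so descriptors referenced by
  equations should use ids like `d1`, `logp`.

The writer is deterministic — entries in a fixed order (archive
metadata, bibliography, registries, cargos sorted by path), ZIP entries
stored uncompressed with a fixed epoch timestamp — so equal archives
yield equal bytes. This is what makes hash-based provenance and the
byte-determinism tests possible. Reading accepts ZIP containers or
unpacked directories and is deliberately lenient: a declared cargo whose
payload is missing loads as `NULL` and is *reported by the validator*
rather than aborting the read, mirroring the upload-first,
validate-second workflow of a repository.

`normalize_internal()` reproduces the repository practice of keeping the
deposited archive verbatim while deriving an optimized working copy: it
canonicalizes values-cargo row order (compound-registry order, value
text untouched) and attaches each model's precomputed AD parameters as a
`derived` JSON cargo. It is idempotent and never fails — models whose AD
cannot be estimated are skipped with a warning.

## Validation: three levels

`qdb_validate()` runs the requested level plus all lower ones; findings
carry a severity (ERROR/WARNING), level, check id and container path,
and the outcome derives mechanically from the findings (`failed` iff any
ERROR, `warnings` iff only warnings, else `clean`).

* **Basic** ("sanity testing") checks structure and well-formedness:
  required attributes, declared cargos present, system cargos
  parseable, CAS Registry Numbers (shape *and* check digit — the
  weighted digit sum modulo 10), InChI syntax, equation presence and
  parseability on models, strong and weak reference resolution.
  Missing *optional* attributes (name, description, labels) are
  warnings, never errors.
* **Intermediate** ("reusability testing") ensures unique
  identification: InChI on every compound, both endpoint attributes and
  a unit (`ucum`) cargo on every property, an application attribute on
  every descriptor. Two compounds sharing an InChI are flagged as a
  warning — the format does not forbid it, but identity is then
  ambiguous.
* **Advanced** ("reproducibility testing") re-evaluates every model on
  the stored descriptor data and compares each recomputed prediction
  with the stored one.

The advanced comparison needs a tolerance: stored values are printed
with finite precision, so exact float equality is meaningless. The
package uses **half a unit in the last decimal place of the stored
text** (e.g. ±0.0005 for `2.301`), with an absolute floor of 1e-8. This
makes the check as strict as the archive's own precision and no
stricter; a value stored at 10 significant digits is reproduced to 10
significant digits or flagged. An explicit absolute tolerance can be
supplied instead.

The InChI check is syntactic only (layered grammar:
`InChI=1`/`InChI=1S`, a non-empty formula layer, then letter-prefixed
layers). Semantic verification would require a chemistry engine, which
is exactly the kind of dependency basic validation must not have;
structure-aware descriptor calculators remain available as plugins in
the prediction engine.

## Prediction statistics

Per prediction subset (training/validation/testing are kept separate,
as a repository presents them): `r² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²`,
`rmse = √(Σ(y−ŷ)²/n)`, `mae = Σ|y−ŷ|/n` over the key intersection after
dropping missing values. r² on external subsets may legitimately be
negative and is reported as computed, never clamped; constant
experimental values make r² undefined and raise a classed
`zero_variance` condition rather than reporting a misleading 0.
Classification models get actual-by-predicted confusion matrices
(labels: sorted union of observed labels) and accuracy.

## Applicability domain

All AD reference quantities are estimated from the **training
compounds only** (those keyed in the model's training prediction cargo,
with complete descriptor rows); validation, testing and external points
are scored against them. This matches the purpose of the plots —
flagging extrapolation relative to the data the model was built on.

* Leverage uses the intercept-augmented design:
  `h = [1,x](XᵀX)⁻¹[1,x]ᵀ`, with the customary Williams-plot warning
  threshold `h* = 3(d+1)/n`.
* Mahalanobis distance is taken from the training centroid under the
  training sample covariance (divisor n−1).
* Standardized residuals divide by the training RMSE — the usual
  Williams-plot convention.
* Singular designs (duplicate rows, collinear descriptors) switch to
  the Moore–Penrose pseudo-inverse and set a `singular` flag instead of
  failing; the hat-trace identity Σh = rank is preserved.

`williams_data()` emits one profile per predicted compound in registry
order; compounds lacking an experimental value still carry distance and
prediction — the points of a Gramatica/Insubria graph.
`similar_compounds()` ranks dataset compounds by raw Euclidean distance
over the model's descriptors (an optional flag z-scores the space
first; raw is the default because descriptor values are what the
archive stores), with ties broken by registry order.

## The prediction engine

Structure input follows the three-step pipeline — prepare the structure
text, compute descriptors, evaluate the equation. Descriptor
calculators are plugins identified by an application text; the package
ships a table-driven `mock_calculator()` and an `archive_calculator()`
that recognizes structures already present in the archive. A calculator
*declines* ids it cannot compute by omitting them (never a silent
zero), which surfaces as a `descriptor_not_computable` condition and is
the caller's cue to fall back to manual entry. The domain flag uses the
leverage criterion only (`h ≤ h*`); Mahalanobis distance is reported
but not thresholded — one documented cutoff is better than two
undocumented ones. The default neighbour count is 5 and configurable.
Batch mode maps the same single-prediction routes over records,
isolates per-record failures and preserves order.

## The synthetic-archive generator

`generate_fixture()` emulates a deposited archive with known ground
truth. Defaults, chosen once as a plausible small QSAR study: 30
compounds; two descriptors drawn N(2, 1) and N(0, 0.5); property
`y = 1.2 + 0.55·d1 − 0.75·d2 + ε` with ε ~ N(0, 0.2); a 70/15/15
training/validation/testing split by seeded shuffle. Compounds get
checksum-valid CAS numbers and pairwise-distinct, grammar-valid
InChIs from the alkane formula series (`InChI=1S/CnH2n+2`) — distinct
by construction so that a defect-free fixture is clean at every level,
including the duplicate-InChI warning check. Randomness comes from R's
own seeded generator, which is stable across platforms for a given R
version; the same spec therefore always writes a byte-identical
archive.

Two details make self-consistency exact rather than approximate. The
stored descriptor *text* (10 significant digits) is the single source
of truth: predictions are computed by parsing the equation cargo and
evaluating it on the re-parsed descriptor text, exactly the path
advanced validation takes. And each defect token edits the finished
archive minimally, so it breaks exactly one level: `bad-cas`,
`orphan-cargo` and `dangling-weak-ref` break basic; `drop-inchi` breaks
intermediate while leaving basic clean; `tamper-prediction` adds +1.0
to one stored prediction and breaks only advanced, producing exactly
one mismatch finding.

What the generator does **not** emulate: correlated descriptors,
non-normal descriptor distributions, nonlinear true models, activity
cliffs, measurement error in descriptors, or realistic chemical
diversity (the InChIs are syntactically real but chemically trivial).
Passing tests therefore demonstrate the correctness of the archive
machinery, the validator, the evaluator and the AD algebra — not that
any particular modelling methodology works on real chemistry.

## Numerical choices and problem sizes

* Values are stored and compared as decimal text; computed values are
  rendered with `%.10g`.
* Pseudo-inverse fallbacks use `MASS::ginv`; rank decisions use QR.
* Equation evaluation reports domain violations (log of a non-positive
  number, division by zero, non-finite results) as classed conditions.
* The test suite exercises randomized archives of 10–40 compounds with
  1–4 descriptors (50 archives for round-trip checks, 100 random
  designs for the AD oracles, 1000 random CAS candidates and 400
  InChI candidates for the identifier fuzz checks), sizes at which
  every property holds exactly and the whole suite runs in well under a
  minute.

## Known limitations

* The equation dialect covers linear and elementary nonlinear forms;
  tree ensembles, SVMs and other opaque model families are out of
  scope, as are multi-property models.
* Unit (`ucum`) cargos are checked for presence, not grammar.
* InChI/CAS validation is syntactic; chemical identity resolution needs
  an external engine plugged in as a descriptor calculator.
* The archive reader targets desk-scale archives (it materializes
  entries in memory); streaming multi-gigabyte containers is a
  non-goal.
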