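---
title: "RDML format handling, migration and efficiency estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RDML format handling, migration and efficiency estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmlkit)
```

## The problem

Quantitative real-time PCR instruments collect fluorescence per cycle for
every reaction, plus the metadata (samples, targets, dyes, cycling
conditions) that later analysis depends on. RDML — the Real-time PCR Data
Markup Language — is the instrument-independent interchange format for this
collection: a zip archive containing one XML document with top-level
element lists for experimenters, documentations, dyes, samples, targets,
thermal cycling conditions and experiments; each experiment holds runs,
each run the set of reactions with raw fluorescence series, baseline,
quantification threshold and the observed Cq.

Three format versions coexist in the wild. 1.0 described plates by
predefined plate-type tokens and identified wells by letter+number labels;
1.1 replaced both with an explicit rows × columns format and numeric
reaction positions, and made dye registration mandatory; 1.2 added sample
annotations (free property/value pairs that also subsume the earlier
DNA/RNA quality elements), unified the DNA and RNA quantity elements into
one quantity element, and added `amplificationEfficiencySE` for
MIQE-compatible uncertainty reporting. `rdmlkit` reads, writes, validates
and migrates all three dialects, reconstructs plate tables and curves, and
estimates amplification efficiency with uncertainty.

## The document model

Documents are plain R lists with S3 class tags, mirroring the XML tree.
Optional fields are `NULL`; every node carries an `extra` slot where
unrecognised child elements (vendor extensions) are stored as serialized
XML and re-emitted on write. Two deliberate interpretation choices:

* **Efficiency scale.** `amplificationEfficiency` is stored as fold-change
  of product per cycle (perfect doubling = 2.0), the `E = 10^(-1/slope)`
  convention of standard-curve analysis; values are never rescaled on
  read, because files from other tools may encode percentages and silent
  rescaling would corrupt them.
* **Dye attachment.** The dye reference lives on the target only; reaction
  data reference the dye through their target. This is the simplest
  reading consistent with mandatory top-level dye registration.

The sample-type vocabulary is `unknown`, `standard`,
`no-template-control`, `no-amplification-control`, `positive-control`,
serialized as the short tokens `unkn/std/ntc/nac/pos`; unknown tokens read
from third-party files are kept verbatim and flagged as warnings, so
round-tripping a foreign file never destroys information.

`rdml_equal()` is the round-trip oracle: content equality that ignores
order within unordered lists and compares numbers to a relative tolerance
(default `1e-9`). File output is deterministic — fixed element order,
15-significant-digit numeric formatting, fixed zip metadata — so writing
the same document twice yields byte-identical archives, which makes files
diffable and regressions detectable at the byte level.

## Validation

Validation is rule-based over the in-memory model: the differences between
the three dialects are a handful of explicit gates, and encoding them
directly keeps one rule table authoritative for reading, writing and
migration alike (an XSD can additionally be supplied for cross-checking).
Referential or structural breaches (dangling references, duplicate
identifiers, out-of-bounds or duplicated plate positions, non-monotone
cycle or temperature series, 1.2-only elements in older documents,
unregistered dyes from 1.1 on) are errors; vocabulary deviations and
missing recommended metadata are warnings, reflecting that such files are
valid but difficult to use. A clean report renders exactly as
`"validation successful"`. Writing refuses documents with errors unless
forced, so invalid files are never produced silently.

## Migration

`migrate_rdml()` moves documents between versions through adjacent steps
(1.0 ↔ 1.1 ↔ 1.2), recording every change as a `transformed`,
`synthesized` or `dropped` action so information loss is explicit rather
than silent. Upgrading 1.0 resolves the plate-type token to its geometry
and renumbers wells; targets without dye information receive a
deterministic synthesized dye (`dye_<targetid>`, deduplicated with numeric
suffixes) because 1.1 makes dyes mandatory. Upgrading to 1.2 unifies the
quantity housing and converts legacy quality records to annotations with
the reserved properties `"dna quality"`/`"rna quality"`. Downgrades
reverse each rule where possible: reserved-property annotations fold back
into quality records, all other annotations and the efficiency SE are
dropped (one action each), and the unified quantity is emitted in the DNA
slot with a `transformed` action noting the ambiguity when the source
material is unknown.

Well numbering is row-major and 1-based (`A1 = 1`, `B1 = columns + 1`),
the conventional reading order of a microtiter plate; the conversion is
centralised so a column-major dialect could be added behind a flag if
rotor-style files that number down columns ever require it. The shipped
plate-type map covers 96-well (8×12), 384-well (16×24), 48-well (6×8) and
the 72- and 100-position rotors (n×1); any other token raises an error
that carries the token, and callers can pass a custom map — guessing a
geometry would silently corrupt every position on the plate.

## Efficiency estimation

For each target, a dilution series of standards gives Cq versus
log10(input). Ordinary least squares yields slope $b$ and intercept, and
the amplification efficiency

$$E = 10^{-1/b},$$

so a perfect doubling assay has $b = -3.3219$ cycles per 10-fold dilution
and $E = 2$. The base-10 logarithm is fixed and documented since the slope
interpretation depends on it. Replicate standards enter as independent
observations — pre-averaging would discard degrees of freedom from the
uncertainty estimate. The standard error of $E$ uses first-order
(delta-method) propagation of the slope's standard error:

$$\mathrm{SE}(E) = E \cdot \ln(10) \cdot \mathrm{SE}(b) / b^2 .$$

The test suite cross-checks this against an independent parametric
bootstrap (10,000 closed-form OLS refits of the fitted model, no shared
code with the implementation) and requires agreement within 20%. When
per-curve efficiency values from amplification-curve analysis software are
available instead, `efficiency_from_per_curve()` summarises them as mean
and SEM. `annotate_target_efficiency()` writes estimates back into the
document; the SE is version-gated to 1.2.

Degenerate inputs are refused (fewer than 3 points or fewer than 2
distinct concentrations); a non-negative slope warns — the estimate is
outside the meaningful range but returned so batch pipelines can log it.

## The synthetic generator

`generate_rdml_document()` produces complete, valid documents of any
version from a `synthetic_run_spec()`. The amplification model is a
logistic sigmoid, $F(c) = 0.05 + 1/(1 + e^{-(c - c_{mid})/1.2})$, with
$c_{mid}$ placed so the crossing of the quantification threshold
(0.1 fluorescence units) falls exactly at the reaction's true Cq. True Cq
values follow the dilution model
$\mathrm{Cq} = \mathrm{Cq}_{unit} - \log_{10}(\mathrm{input})/\log_{10}(E^*)$
for a known true efficiency $E^*$. Melt curves are decreasing sigmoids of
width 1.5 °C centred at the product Tm; no-template controls carry flat
noise-only curves and no Cq, exercising optional-field handling
downstream.

Two noise dials are separated on purpose: `cqNoiseSd` perturbs the true Cq
before the curve is placed, and the recorded Cq is the analytic threshold
crossing of that continuous curve — not a linear interpolation of the
sampled points, whose systematic O(0.01 cycle) error would contaminate
efficiency recovery. `noiseSd` adds Gaussian noise to the stored
fluorescence points only. Noise-free series therefore recover $E^*$ to
machine precision, and Cq-noise experiments have exactly the noise level
they request.

Defaults describe a routine single-target SYBR assay: a five-step 10-fold
dilution series from $10^5$ copies in duplicate, one unknown, one
no-template control, 40 cycles, on a 96-well plate. Generation consumes a
single seeded random stream in fixed order, so fixtures are reproducible
byte-for-byte through the writer.

What the generator does not emulate: amplification plateaus that drift,
inhibition-induced efficiency changes along the dilution, multiplex dye
crosstalk, or instrument-specific baseline artefacts. Tests passing on
synthetic data therefore demonstrate format fidelity and estimator
correctness under the stated model, not robustness to pathological real
curves.

## Problem sizes and numerical choices

File-level test fixtures use compact runs (3-step series, 16 cycles,
5 reactions) so suites covering 100+ round-trip documents finish in tens
of seconds; estimator tests use the full default layout. Numbers are
serialized with 15 significant digits, far inside the `1e-9` semantic
tolerance. CSV export follows RFC 4180 with `.` decimal separator and
empty fields (never `NA`/`NaN` text) for missing values. SVG charts map
data linearly into a fixed viewBox with 5% margins and inline styling
only, so output is deterministic and renders standalone.

## Known limitations

* The official XSD schemas are not bundled; rule-based validation covers
  the documented version deltas, and everything undocumented is at most a
  warning. An external schema can be passed for cross-checking.
* The exact token list of 1.0 plate types is instrument-dependent; the
  shipped map covers the common geometries and unknown tokens raise.
* Per-curve efficiency analysis (window-of-linearity fitting of single
  amplification curves) is out of scope; its results are consumed via
  `efficiency_from_per_curve()`, not computed.

## A worked session

```{r example}
spec <- synthetic_run_spec(version = "1.0", seed = 42,
                           cqNoiseSd = 0.1, noiseSd = 0.005)
doc <- generate_rdml_document(spec)
path <- tempfile(fileext = ".rdml")
write_rdml(doc, path)
detect_rdml_version(path)

up <- migrate_rdml(read_rdml(path), "1.2")
up$report

fit <- fit_standard_curve(standard_points_from_document(up$document, "tgt1"))
fit

annotated <- annotate_target_efficiency(up$document, "tgt1", fit)
validate_rdml(annotated)
```
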