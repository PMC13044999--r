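---
title: "Methods: governed ETL for intensive-care PDMS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: governed ETL for intensive-care PDMS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmsetl)
```

## The problem

Patient data management systems (PDMS) on intensive-care and perioperative
units continuously document vital signs, medication administrations,
laboratory results and device therapies. Their relational back-ends are
optimized for bedside documentation and transactional integrity, not for
analysis: tables are denormalized and fragmented, coding is vendor-specific,
therapy intervals routinely lack end timestamps, and re-confirming an
ongoing therapy ("reverification") creates additional rows for one
continuous intervention. At the same time, secondary use of these data is
governed by strict data-protection law, so who extracted what, for which
purpose, and how identifiers were protected must be demonstrable.

`pdmsetl` implements that combination as a pipeline: read-only source
access with bounded identifier batching, domain-specific transformation
(episode reconstruction, medication rate standardization), schema-contract
validation, salted irreversible pseudonymization, JSON-lines audit logging,
and analysis-ready CSV/Parquet export. Because operational PDMS content
cannot be shared, the package ships a seeded synthetic PDMS generator with
retained ground truth; every stage is exercised and scored against that
fixture.

## Therapy-episode reconstruction

Device support (ECMO, dialysis, microaxial pumps, IABP) is documented as
interval records with two pathologies: missing end timestamps and
overlapping reverification duplicates. Reconstruction proceeds per
(case, device) group:

1. **Merge.** Records sorted by start are joined into one episode when they
   overlap, abut, or are separated by at most a *gap tolerance* (default 60
   minutes, configurable per device type — the merging rule is a heuristic,
   so its threshold lives in configuration, never in code). An open-ended
   record extends coverage indefinitely and therefore absorbs every later
   record of its group: a reverification after an unterminated record
   re-documents the same intervention. The merged episode's end is the
   latest documented end, unless an open record starts at or after that
   end, in which case the end remains unresolved.
2. **Infer.** An unresolved end is closed against bed occupancy: a therapy
   cannot outlive the occupancy interval containing its start. If that
   interval has ended, the episode end is set to the occupancy end and
   flagged `end_inferred`; if the bed is still occupied the episode is
   flagged `ongoing` with a null end. Documented ends are authoritative and
   are never shortened or overridden. An episode starting outside every
   occupancy interval is retained and flagged as an orphan with a warning.

All intervals use half-open `[start, end)` semantics, which makes "abutting
is not overlapping" unambiguous for both episode disjointness and
admission-window overlap checks.

The merge is verified against an independent brute-force oracle (transitive
closure of the pairwise join relation on up to 12 records, with the end
rule re-derived from its definition) on 1000 random instances, plus
idempotence, coverage and disjointness properties.

## Medication standardization

Medication rows document administrations as a **volume** (mL), a **dose**
(e.g. µg, mg, U), or a pump **rate** (mL/h) — without explicit
concentrations. Concentrations are reconstructed from mixture definitions
in the internal drug catalog as `ingredient amount / diluent volume`
(mg/mL or U/mL). Standardization then yields ingredient-keyed events:

* rate-documented → infusion with `rate = mL/h × concentration`;
* volume-documented → infusion assumed evenly administered over its
  documented interval, `rate = mL × concentration / duration`; the source
  does not state the temporal semantics of volume entries, so uniform
  infusion is this package's explicit modelling choice;
* dose-documented → bolus, converted to the drug's standard base unit via
  a flat curated unit registry (µg/mg/g, mL/L, U≡IU, s/min/h). Mass and
  activity are never mixed within an ingredient.

Unresolvable rows (unknown drug, volume or rate without a usable interval,
cross-dimension dose units) are routed to an explicit failure table, never
silently dropped. Catalog resolution is deliberately transparent — a
deterministic `drug_id` lookup — because product-classification logic is
site-specific; anything unresolved is surfaced as such. Window aggregation
(used for the perioperative "drug windows" table) adds bolus amounts whose
instant falls in the half-open window and pro-rates infusions by overlap
duration; it is additive over window partitions, which the tests check on
random partitions.

## Schema contracts and plausibility

Every exported domain has a JSON schema contract (packaged under
`inst/extdata/contracts/`) declaring fields with semantic types, closed
plausibility intervals or enumerations, and cross-field predicates
(`start ≤ end`, value within catalog bounds). Validation is first-violation
per record, in declared rule order (required → type → plausibility →
cross-field): that yields a stable, cheap failure accounting with
`n_valid + n_failed = n_input` and `failure_rate = n_failed / max(n_input, 1)`
on every batch. Failed records are excluded from export but fully listed in
the report.

Default bounds are conventional clinical plausibility ranges — heart rate
0–300 /min, mean arterial pressure 0–250 mmHg, SpO₂ 0–100 %, temperature
20–45 °C, medication value 0–10000, age 0–120 years. They are editable
configuration, not code: per-variable vitals bounds travel with the
variable catalog (`lower`/`upper` columns enforced by a generic `between`
rule), fixed-field bounds live in the contract files.

## Governance

Identifiers are pseudonymized with keyed hashing (HMAC-SHA-256, the salt as
key) rather than plain salt‖id concatenation — a standard primitive with
the stronger irreversibility guarantee for the same stated property.
Pseudonyms are deterministic per (identifier, salt), so one case keeps one
pseudonym across all domains of a run and cross-domain linkage happens
entirely in pseudonymized space; per-project salts make pseudonyms
unlinkable across projects. The salt comes from configuration or the
`PDMSETL_SALT` environment variable, is at least 16 bytes, and is never
written to any export, log or audit record — a property the tests enforce
by scanning every produced artifact for raw identifiers and the salt.

Every resource execution appends one JSON object to an append-only
JSON-lines audit log: actor, purpose, resource, redacted parameters (id
lists hashed element-wise), requested case count, exported row count,
start/finish timestamps, runtime, a hashed identifier sample, and the
outcome. The sink is opened before any export, so a run that cannot be
audited cannot export; audit conservation (one entry per artifact, counts
equal) is asserted end-to-end. A static actor→template role map provides
the enforcement hook for institutional access control; full user management
belongs to a front end and is out of scope.

## Pipeline and export

Extractors are registered in a resource registry; predefined templates
bundle them: `demographics`, the multi-domain `periop_study`
(demographics, standardized drugs, operating-room timestamps, and
per-ingredient drug totals within each case's operating-room window — the
"aggregated drug windows" table is defined here as exactly that), and
`icu_course`. Each resource follows fetch (identifier chunks of at most
`chunk_size`, default 500, deduplicated set-semantics) → transform →
pseudonymize → validate → export → audit. Rows are sorted by a total order
(pseudonym, domain timestamp, then all remaining columns), which makes CSV
artifacts byte-identical across chunk sizes and repeated runs. Timestamps
are normalized one-way from stored UTC to Europe/Berlin (CET/CEST) with an
explicit offset, so ambiguous local times cannot arise and the instant is
always recoverable.

## The synthetic PDMS generator

The generator emulates, per seeded configuration: patients and cases with
non-overlapping admission windows (built sequentially with positive gaps,
so overlap is impossible by construction), about 8 % repeat admissions and
5 % still-admitted cases; 1–2 abutting bed-occupancy intervals per case;
vitals and point-of-care analytes with specimen context (≈40 + 12 rows per
case) drawn inside the catalog bounds; medication records at a default
density of 266 records/case — the observed drugs-per-case density of a
transformation-heavy ICU extraction — documented uniformly as
volume/dose/rate with concentrations present only in the catalog; and
device therapies for ≈40 % of cases (one episode per case and device).
Identifier inconsistencies are injected deterministically:
`round(n_cases × p)` cases (default `p = 1/1838`, the empirically observed
rate) additionally appear under a ghost patient identifier.

Documentation pathologies default to `p_missing_end = 0.3` and
`p_reverify = 0.5`. A nulled end is interpreted, in the emulated world, as
a therapy still running when the bed was vacated — the clinical situation
in which termination is typically never charted — so the true episode end
is the enclosing occupancy end (or remains open when the bed is still
occupied). That makes "recoverable in principle" well defined: every
missing end with a closed occupancy is recovered exactly, and open
occupancies map to truly ongoing episodes. Reverification appends one or
two overlapping duplicate records inside the episode's coverage. The true
distribution of reverification counts and documentation gaps is not
empirically characterized anywhere; these are stated assumptions of the
generator, and real data may fragment episodes in ways the recovery tests
do not cover (e.g. gaps exceeding any fixed tolerance, or transfers across
case numbers, which are out of scope).

The hidden truth — episodes, infusion rates and bolus amounts, the
case→patient identity map, conflicted cases — is returned and serialized
as JSON next to the fixture, so recovery is scored without ever consulting
the pipeline's own outputs.

## Numerical and design notes

* Timestamps are whole seconds, stored as UTC ISO-8601 strings; arithmetic
  happens on epoch seconds, so no floating-point time drift arises.
* Rate recovery is exact to ≈1e-15 relative error (two float operations);
  the tests assert 1e-9.
* Unit conversion factors satisfy `f(a→b)·f(b→a) = 1` within 1e-12 and
  chain within 1e-9; `U` and `IU` are treated as synonyms because the
  distinction is not consistently charted.
* Degenerate inputs: empty id lists, empty batches and empty windows yield
  empty, well-typed results; a zero-amount mixture is a legal placebo with
  concentration 0; a dose with a volume unit is a routed failure.
* Problem sizes used by the shipped tests and acceptance script — cohorts
  of 100–1000 cases, 150-case pathology grids, 1000 random oracle
  instances of ≤12 records — were chosen as desk-scale renditions of the
  workloads the pipeline targets.

## Limitations

The fixture is a simplified, documented stand-in for proprietary vendor
schemas; porting to a real PDMS means rewriting the source adapter and
catalogs while keeping contracts, governance and orchestration unchanged.
No physiological realism is attempted in the simulated values beyond
plausibility ranges, so passing tests demonstrate structural correctness
of the transformations, not clinical validity of any derived dataset.
Weight-indexed dose rates, ATC coding, cross-case episode stitching and
common-data-model mapping are explicitly out of scope.
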