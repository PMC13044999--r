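# pdmsetl

Governed extraction, transformation and export of intensive-care
patient-data-management-system (PDMS) records.

ICU and perioperative documentation systems hold high-frequency clinical
data in denormalized, transaction-oriented relational schemas that are
hostile to research use: therapy intervals lack end timestamps,
reverification duplicates fragment one continuous intervention into many
rows, medications are charted as volumes, doses or pump rates without
explicit concentrations, and data-protection law requires demonstrable
control of who extracted what, for which purpose, and how identifiers were
protected. `pdmsetl` is an ETL toolkit for exactly this setting, aimed at
clinical data engineers and study teams who need reproducible,
pseudonymized, auditable exports from such a source.

Core methods:

* **Therapy-episode reconstruction.** Per (case, device), interval records
  are merged when they overlap, abut, or fall within a gap tolerance *g*
  (default 60 min); an open-ended record absorbs all later records of its
  group. Unresolved ends are inferred from bed occupancy: for an episode
  starting inside occupancy interval `[s, e)`, a missing end becomes `e`
  (flagged `end_inferred`), or the episode is flagged `ongoing` when the
  bed is still occupied.
* **Medication standardization.** Concentration `c = amount / volume`
  (mg/mL or U/mL) is reconstructed from the drug catalog; rate records give
  infusions `r = (mL/h)·c`, volume records `r = mL·c / duration`, dose
  records boluses in mg or U. Window aggregation sums boluses and
  pro-rates infusions: `∑ amountᵢ + ∑ rateⱼ·|windowⱼ ∩ window|`.
* **Schema contracts.** Per-domain field types, plausibility bounds and
  cross-field rules with first-violation failure accounting
  (`n_valid + n_failed = n_input`).
* **Governance.** HMAC-SHA-256 pseudonyms `p = HMAC(salt, id)`, append-only
  JSON-lines audit records (actor, purpose, parameters, row counts,
  runtime), and actor→template authorization.
* **Synthetic PDMS.** A seeded SQLite fixture with injected documentation
  pathologies and retained ground truth (true episodes, rates, identity
  map), so everything above is testable without clinical data.

## Worked example

Extract pseudonymized demographics for two cases from a synthetic
100-case cohort:

```r
library(pdmsetl)

fx  <- generate_fixture(synthetic_config(n_cases = 100, seed = 2024),
                        "pdms.sqlite")
ids <- fx$ground_truth$identity_map$case_id[1:2]
cfg <- pdms_config(salt = "example-salt-0123456789abcdef", out_dir = "out")
res <- run_template("demographics", fx$handle, ids,
                    actor = "perioperative_researcher",
                    purpose = "feasibility count for trial X", cfg = cfg)
```

`out/demographics.csv`:

```
"case_pseudonym","admission_ts","discharge_ts","age_at_admission","sex","ward"
"39cd88437847f0661865b247adcaf3034755560b1845f23a957d3047dc7ccdee","2024-01-02T20:00:13+01:00","2024-01-07T05:55:19+01:00",77,"m","ICU-1"
"ae51b80602eaf8445f4a7482cf9afc34aa6a36cfb87d116f6410cc0eb82c529b","2024-01-01T10:09:03+01:00","2024-01-01T22:09:03+01:00",51,"m","ICU-2"
```

Each row is one case: the 64-hex-character pseudonym replaces the case
number (the same case gets the same pseudonym in every domain of the run,
so pseudonymized tables remain joinable), timestamps are local CET/CEST
with explicit offsets, and `age_at_admission` is derived from the date of
birth, which itself never leaves the extraction layer. `out/audit.jsonl`
gains one corresponding entry:

```json
{"event_id":"04ded7ae65c4cb0e88ab65c69c0e6260741dc46b","actor":"perioperative_researcher",
 "purpose":"feasibility count for trial X","resource":"demographics",
 "parameters":{"template":"demographics","resource":"demographics",
   "case_ids":["ae51b806…","39cd8843…"],"chunk_size":500,"format":"csv",
   "n_validation_failed":0},
 "n_cases_requested":2,"n_rows_exported":2,
 "started_at":"2026-09-22T19:23:48+02:00","finished_at":"2026-09-22T19:23:48+02:00",
 "runtime_s":0.032,"id_sample":["ae51b806…","39cd8843…"],"outcome":"success"}
```

Requested case ids are hashed even inside the audit parameters; the salt
appears nowhere. The multi-domain template
`run_template("periop_study", …)` additionally exports standardized drug
events, operating-room timestamps and per-ingredient drug totals within
each case's operating-room window, with one audit entry per artifact.

A thin CLI wraps the same functions
(`inst/cli/pdms-etl synth|run|audit-show`); the salt is taken from the
`PDMSETL_SALT` environment variable, never from a flag.

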