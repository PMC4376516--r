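---
title: "The extract-server model: separation, governance and extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extract-server model: separation, governance and extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caresr)
```

## The model

A data linkage unit sits between administrative data collections and
researchers. It creates person-level links from demographic fields, but —
under the separation principle — must never hold identities and service
content together. Historically each research extract therefore fanned out
to every participating collection, which extracted its own records,
in its own software, its own file type and its own date conventions, on
its own schedule. `caresr` implements the centralised alternative: a hub
holding **partial, de-identified copies** of each collection, governed by
the collections' custodians, from which one operator can serve a whole
multi-collection request.

Three structural invariants define the model, and the test suite enforces
each of them mechanically:

1. **De-identification at rest.** A hub table holds only the custodian's
   approved field subset, keyed by a one-way encrypted record token
   (a "CARES ID"). Source UIDs and all demographics (name, birth date,
   address) exist only in the synthetic-data module; a repository-wide
   scan of every extract, QA report, layout and log finds none of them.
2. **Unlinked at rest.** Without imported project keys the hub is
   isolated, unlinked information: no hub operation joins records at the
   person level, and tokens for the same person in different collections
   are unrelated keyed hashes.
3. **Governed access.** Every retrieval requires all three access tiers
   (below) and every decision, load, transfer read, bridge decryption and
   extraction run is written to an append-only audit log with gap-free
   sequence numbers.

## One-way record identifiers

`encrypt_id()` realises the requirement that loading software can encrypt
record IDs but users can never decrypt them. The transformation is a
keyed pseudorandom function (HMAC-SHA256 of `collection_id` and
`source_uid` under the collection's secret), truncated to 32 hex
characters. At desk scale the collision probability over $10^4$ records
is negligible ($\approx 10^{-31}$), and a fixed width simplifies file
formats.

Linkage officers *can* decrypt, via `bridge_decrypt()`. Since a truncated
keyed hash is not invertible, the loader escrows the forward mapping
(CARES ID → source UID); the bridge requires **both** the escrow store
and the linkage-officer role, fails without either, and audits every
call with the caller's identity and ID count. Whether a production
system would use reversible encryption instead is unobservable from the
stated behaviour; the escrow reproduces exactly the observable contract
(ordinary users cannot backtrack, authorised officers can), which is why
it was chosen.

## Governance

`check_access()` allows a retrieval if and only if:

1. the user signed the standard confidentiality agreement on or before
   the evaluation date;
2. an unexpired custodian grant for (user, collection) covers the date —
   grants are valid **through the expiry date inclusive**, matching
   form-based administrative practice (the convention is otherwise
   arbitrary and is fixed here so the boundary is testable); and
3. a custodian approval exists for (task, collection); approval evidence
   may be informal (an email reference) and is stored with the task.

Tiers are evaluated in that fixed order so the deny reason is always the
first failing tier — a determinism choice made purely for testability.
Custodianship is per collection and shareable (several custodians may
serve one collection); the alternative, exclusive custodianship, is not
implied by anything in the governance description and would forbid
realistic delegation.

## The extraction module

`run_module()` executes, per collection of a task: key-file import,
governed retrieval, appending of the project person key, the optional
transform steps, and emission of the standardised file with its layout
file and QA summary. Two design decisions deserve explanation:

- **The CARES ID is dropped from researcher-facing output** (reversible
  with `keep_record_token = TRUE` for QA workflows). The researcher needs
  person-level links and content; a durable record-level token would
  weaken the unlinked posture of everything downstream. Records in the
  output are therefore ordered by `(person_key, content tiebreak)`, where
  the tiebreak is the concatenation of all rendered field values — a
  stable, content-derived order that makes diffs reproducible without a
  record key.
- **Transforms are a closed set**, not a scripting hook: field
  maps/recodes, filter and exclusion predicates over the comparators
  `=, !=, <, <=, >, >=, in, date-range`, and derived fields restricted to
  `+ - * / ( )` arithmetic, date differences in days or whole years
  (`floor(days / 365.25)`), and categorical recodes. Ad-hoc steps exist
  in operational practice but are not specifiable in a testable way; the
  closed set is fully checkable against the brute-force oracle, including
  its order sensitivity. Predicates evaluate to false on missing values,
  so a filter never *keeps* a row it cannot evaluate, and an exclusion
  never removes one.

Governance is **fail-closed at task granularity**: if any collection of a
task fails any tier, the whole task is refused before any data is
touched, because a partial extraction would silently change the approved
scope.

`run_classical()` runs the identical record path but renders each
collection's file the way that collection would have delivered it — dates
in the collection's own input dialect, a collection-specific field order
and delimiter, and a simulated completion delay — providing the
heterogeneous baseline against which standardisation and the turnaround
metrics are demonstrated.

## Standardisation and QA

The canonical output convention is RFC-4180 CSV, UTF-8, LF endings,
header row, dates `YYYYMMDD`, missing values as empty fields.
`standardise()` is idempotent, and because hub-mode extracts are emitted
in canonical form directly, re-standardising them is a no-op — the
mechanism by which centralised extraction eliminates post-extraction
standardisation work. For character date columns the dialect is detected
per column (canonical `YYYYMMDD` tried first), requiring every non-empty
value to parse under one dialect; a value parseable under no dialect is a
standardisation error naming the row and field.

"Correctness of content" in the QA summary is operationalised as
recomputed structural checksums (row/field/cell counts and per-field
non-null counts) plus type conformity, since no stronger definition is
available without clinical semantics. A **missing record** is a key row
whose CARES ID matches nothing on the hub — the only interpretation
checkable at extraction time. The QA conservation identities
(`matched key rows + unmatched = rows in`;
`Σ category level counts + missing = rows out`, per field) are recomputed
from the emitted files, never copied from engine state.

## Parallel-run validation

`compare_extracts()` replicates go-live testing. Because researcher
extracts carry no record token, the default matching key is
`person_key` plus all date fields; rows whose keys collide are
deduplicated upstream or the comparison refuses (duplicate keys cannot
identify records). All value comparison is exact string equality after
standardisation — extracts are administrative fields, not measurements,
so no numeric tolerance is appropriate. `classify_discrepancies()`
assigns each finding to exactly one of the operationally observed cause
buckets: whole-record absences outside the task window → *cut-off dates*;
other absences → *exclusion criteria*; one-sided empty values →
*missing data*; remaining single-field deltas → *script bugs*.

## Turnaround metrics

Turnaround is elapsed **calendar** days (no business-day adjustment)
from formal request to file return (extraction level) or final dispatch
(project level). Summaries report the arithmetic mean, quartiles and the
sample (n−1) standard deviation; singleton groups report an undefined
sd. Quartiles use linear interpolation between order statistics
(type 7). The operational data behind any published quartiles is not
available and its quantile convention is unstated, so matching printed
values is explicitly **not** an objective; the tests instead require
agreement with an independent naive sort-and-interpolate implementation
on 1000 random inputs.

## What the synthetic generator emulates — and what it does not

The generator is the package's stand-in for the source collections:

- **Populations** are placeholder tokens: opaque root IDs, token names
  and addresses, uniform birth dates. They exercise the separation scans
  but carry no demographic realism, and no linkage errors — link creation
  is upstream of the extract server, so cohort keys are error-free by
  construction.
- **Record multiplicity** per covered person is zero-truncated Poisson
  with rate `mean_records_per_person` (default 1.6, realised mean
  $m/(1-e^{-m})$), capped at 1 for registry-style collections (births,
  deaths) — repeating service contacts versus one-per-person
  registrations. A degenerate constant-count model supports boundary
  tests. Coverage (the fraction of the population with any record,
  default drawn 0.4–0.9 per collection) and these multiplicities are
  free parameters: no operational record-multiplicity distribution is
  published, so the defaults are fixed once at values a linkage analyst
  would call unremarkable and are not tuned further.
- **Project fixtures** carry ground truth computed by a literal
  row-by-row filter/join/transform in the synthetic module itself, never
  by the engine — the two paths share only the output ordering contract,
  so fixture equality is an informative oracle.
- **Delay models**: classical completion delays are lognormal
  (`meanlog = log(18)`, `sdlog = 1`), hub delays lognormal
  (`meanlog = log(2)`, `sdlog = 0.7`). The lognormal shape reflects
  queues with competing priorities and unpredictable long tails; the
  medians (18 vs 2 days) are calibrated once to the magnitude of
  operational turnaround figures for classical and hub extraction. Only
  the *qualitative* pattern — lower mean and lower spread under the hub —
  is asserted, over 100 replicates of 200 simulated extractions.

Passing tests therefore demonstrate the mechanics — separation,
governance, exactness of extraction, recovery of injected discrepancies —
on data with realistic shape but synthetic content. They do not
demonstrate robustness to real-world linkage error, clinically
implausible values, or schema drift across decades of collection history.

## Numerical and degenerate-input choices

- Dates parse strictly: a value must round-trip through its declared
  dialect, so `31/02/2010` is rejected at load with a per-row reason
  rather than being silently coerced.
- Loading rejects row-by-row and reports every rejection; `strict = TRUE`
  converts the first rejection into a whole-load abort. Append mode
  upserts on the record token with the new value winning; deletions at
  source propagate only via full reload.
- All comparisons in validation are exact; the only tolerance anywhere is
  `all.equal`'s default in the metrics-vs-oracle tests, where both sides
  are floating-point summaries of identical inputs.
- Empty cohorts, empty key files, zero-coverage collections and
  zero-variance count models are all legal inputs with defined outputs,
  and are exercised in the suite.

## Problem sizes

The test suite and the acceptance script run, among other checks:
50 randomised project fixtures (cohorts 0–500, 1–6 collections, 0–4
transform steps) for engine-vs-oracle equivalence; $10^4$ UIDs per
collection for collision scans; 30 perturbed fixtures (1–10 dropped,
1–10 altered rows each) for validation recall; 1000 random groups for
the metrics oracle; and 100 replicates of 200 simulated extractions for
the turnaround pattern. These sizes were chosen so each property is
exercised well past its boundary cases while the whole suite remains
convenient to run routinely.

## Known limitations

- The transfer partition and workspaces model access contracts in
  memory; real filesystem ACLs, authentication backends and hardware
  security are out of scope.
- Update schedules are metadata; there is no scheduling daemon.
- Only the closed transform-step set is supported; no free-form
  scripting.
- The escrow realisation of the decrypt-and-forward bridge reproduces
  observable behaviour; it is not a claim about the production cipher.
- Cross-collection clinical consistency checks (e.g. service contacts
  after a death date) belong to the collections' own QA and are not
  performed.
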