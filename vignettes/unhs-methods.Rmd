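---
title: "Methods: code algebra, harmonization metrics and synthetic fixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: code algebra, harmonization metrics and synthetic fixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unhs)
```

This vignette documents the package's methods in full: the identifier
encoding and checksum, the registry invariants, the exact definitions (and
denominators) of the assessment statistics, how the synthetic-fixture
generator plants its rates, and the design decisions taken where more than
one reasonable convention existed.

## 1. The code algebra

### Bijective base-35 numeration

The code alphabet has 35 symbols — A–Z valued 1–26 followed by 1–9 valued
27–35 — and deliberately no zero. With digit values 1..35 the numeration is
*bijective*: every positive integer has exactly one representation, and 0
has none, which is why identifiers start at 1. Encoding peels digits with
`d = ((n − 1) mod 35) + 1`, `n ← (n − d)/35`; decoding is the positional
sum of symbol values.

```{r}
base35_digits(22718)
encode_identifier(22718)
```

Two consequences that the test suite turns into properties: encoding is
injective, and code length is non-decreasing in the identifier, stepping up
exactly at 36, 1 261 (= 35² + 35 + 1) and 44 136 (= 35³ + 35² + 35 + 1).

This is the only scheme consistent with a worked decomposition such as
22718 = 18·35² + 19·35¹ + 3·35⁰ with all digits in 1..35: standard base-35
(digits 0..34) would require a zero symbol the alphabet does not have.

### The check letter

The checksum value is `26 − (n mod 26)`, always in 1..26, mapped to the
letter of that value; an identifier divisible by 26 therefore gets Z. It is
computed from the *numeric identifier*, before any suffix is attached, so
the extension suffix and the check letter itself are outside its scope. The
check letter detects any single corrupted check letter and most core
corruptions; it is a detection code only, with no correction capability.

```{r}
check_value(22718); check_digit(22718)
make_code(22718)
validate_code("RSCF.3")$valid  # suffix excluded from the checksum
```

A consistency audit of a published sample of codes with this rule is part
of the test suite: all five-character sample codes (AYAXU, AINXD, AOSUV,
ASSZE, ATSSI, AROEM) and the operational examples (BCK9K, BCLAJ, BCK7M,
BCK8L, BCKLH) verify, while the four-character rows AX8D and A6IG do not
(the recomputed check letters for their cores are G and L). The package
follows the algorithm as stated and *flags* such rows as
checksum-inconsistent rather than inferring an undocumented alternative
rule; `validate_code()` reports the expected letter so the discrepancy is
visible, not hidden.

### Parsing conventions

Input is uppercased before parsing (codes are identifiers, not free text);
canonical output is always uppercase. The extension suffix is one dot
followed by a base-10 integer ≥ 1 with no leading zeros; nested suffixes
(`X.1.2`) are rejected because the hierarchy is single-level by design.
Digits 1–9 are legal both as core symbols and in suffixes — the dot removes
any ambiguity, so no escaping is needed. Construction functions
(`make_code`, `register_concept`, …) are strict and reject bad input;
`validate_code()` is total and reports every failure in-band, because batch
audits must collect all problems in one pass rather than stop at the first.

## 2. The registry

A registry binds concepts (identifier, code, source reference, one of
twelve domain acronyms, labels in fr/en/es/pt, operational flag) to a table
of source classifications with unique one-letter prefixes: ICD-10-PCS → I
(domains MENT, PHY, PROC, IMG, RXT), CPT → C (EVAL), HCPCS → H (CONS,
PROT, TRANS), LOINC → L (LAB), RxNorm → R (MED), UB04 → U (LOG). `TRAN`
appears in the wild as a variant of the transport acronym and is accepted
on input, canonicalized to `TRANS`.

Design decisions worth recording:

* **Extension identifiers.** Extension concepts carry their own sequential
  registry identifier (bookkeeping; one identifier per billable service)
  but their *code* is parent-derived (`parent.k`), so the identifier is not
  encoded in it. One shared counter allocates identifiers for plain,
  operational and extension concepts alike, gap-free across the sequence.
* **Suffix density.** Suffixes under one parent are dense from 1; the audit
  rejects `X.2` without `X.1`.
* **Source references** are `<prefix>-<source code>` and split on the
  *first* hyphen only, because some laboratory codes contain internal
  hyphens (`L-15074-8`).
* **Labels.** Four languages are supported but only one non-empty label is
  required — a toolkit must accept partial drafts; export writes empty
  cells for the missing ones.
* **Operational codes** never carry a source reference (they exist
  precisely because no international equivalent does).

`registry_audit()` re-checks every invariant — uniqueness of identifiers
and codes, per-row checksums, the identifier↔code relation, parent
existence and suffix density, the operational/source-reference exclusion,
prefix/domain consistency and label presence — and is run by
`read_registry()` before a file is accepted, with violations reported by
name and line.

Persistence is plain delimited text (TSV default, CSV selectable, UTF-8,
header required) with a mirrored JSON export; `write_registry()` followed
by `read_registry()` is the identity on canonical registries.

## 3. Assessment metrics and their denominators

Billing catalogs are tables of (facility, local code, label, optional
price). Items are aligned across facilities by **normalized label** —
uppercase, accents transliterated away, punctuation collapsed to single
spaces — unless an explicit concept key is supplied, in which case the key
always wins. This default is deterministic and reproducible; the key
override exists because label equality is only a proxy for "same service"
and an expert review can correct it.

Published versions of these statistics rarely state their denominators, so
the package fixes them explicitly and prints them next to each percentage:

| metric | numerator | denominator |
|---|---|---|
| consistent nomenclature | clusters whose raw labels agree verbatim everywhere | clusters present in *all* facilities |
| duplicate codes within facility | items sharing a local code with another item of the same facility | all items |
| multiple codes across facilities | clusters with ≥ 2 distinct (code, label) realizations | clusters present in ≥ 2 facilities |
| same code for different services | items whose code also names a different cluster in the same facility | all items |

Two structural facts follow from these definitions and are enforced as
feasibility constraints by the fixture generator: a cluster whose labels
diverge is necessarily multi-coded (so the multi-coded rate is at least one
minus the consistent rate), and every code-reuse item is by definition also
a duplicate-within item (so the duplicate rate is at least the reuse rate).
Note the *consistent* and *multi-coded* sets overlap: a service can keep
one verbatim label everywhere yet carry different codes, which is exactly
the configuration that lets a catalog be 33% consistent and 100%
multi-coded at the same time.

Both item-denominated metrics are deliberately percentages **of items**,
not of distinct codes: a code-denominated reuse rate cannot coexist with a
lower item-denominated duplicate rate (each reused code forces at least two
duplicate items), whereas the item-denominated pair is coherent.

### Coverage

`match_catalog_to_registry()` gives every item exactly one status:
`direct` (exact match via hint or normalized-label equality),
`extension_required` (matches a parent but needs a new suffix),
`header_mapped` (absorbed by a more generic code), `operational_only`
(no international equivalent) or `unmatched`. Expert mapping hints carry a
relation and a target code; hint codes are checksum-validated and must
exist in the registry. Fuzzy label matching (edit distance,
`utils::adist`) exists but is **off by default** and flagged per item when
on — the conservative default mirrors a manual-review workflow, and the
default threshold of 2 edits is a label-typo scale, not a synonym scale.

`coverage_report()` rolls statuses up per domain plus an Overall row. The
roll-up convention is:

* international coverage = direct share;
* national extension = extension + header + operational share (everything
  needing any national addition);
* operational-only reported separately;
* **overall coverage = direct + extension + header** — operational-only
  items are excluded from this numerator, since they are covered only by
  codes with no international anchor. All five raw counts are reported, so
  any alternative roll-up can be recomputed from the same output.

Percentages are rounded half-up to one decimal (banker's rounding would
turn a planted 2.25 into 2.2); unrounded arithmetic is used internally and
the per-status counts are exact.

## 4. What the fixture generator emulates — and what it does not

`generate_mock_registry()` builds per-domain mock concepts whose source
codes imitate each classification's surface shape (7-character
alphanumerics for the procedure-coding mock, 5-digit numerics for the
evaluation mock, digit–hyphen–digit for the laboratory mock, …) without
containing any real licensed code, plus extension families and operational
codes, and guarantees the result passes the full audit.

`generate_catalogs()` emulates a multi-facility rate-list review. Each of
`n_services` services appears once per facility; the configured rates are
planted by exact counts:

* label-consistent services keep one verbatim label in every facility;
  divergent services receive one deterministic corruption (lowercasing,
  punctuation injection, synonym swap, word-order shuffle or abbreviation)
  in one seeded facility;
* multi-coded services get facility-specific codes, others share one code;
* code reuse is planted by giving two multi-coded services the same code
  within one facility (2 reuse items per planted pair);
* duplicate listings are planted as verbatim repeated rows (2 duplicate
  items per copy, same service, hence no spurious reuse);
* every item receives an intended coverage status by largest-remainder
  apportionment of `coverage_split` over the final item count, together
  with the mapping hints that realize it.

The achieved rates (returned in `$planted`) equal the requested ones
whenever the counts divide evenly and are within one planting unit (one
cluster, or one two-item pair) otherwise; the closed-loop tests assert
exactly that. With a single facility no label divergence is possible, so
such configurations are used for coverage arithmetic only.

The generator emulates the *structure* of disharmonized billing data, not
its content: labels are synthetic, price distributions are uniform noise,
corruption styles are drawn from a short fixed list, and item volumes are
balanced across facilities. Passing closed-loop tests therefore shows that
the metrics recover planted structure correctly — it does not show that
normalized-label clustering would align real, messy hospital rate lists,
which is precisely why the concept-key override and mapping hints are
first-class inputs.

### Problem sizes in the shipped tests

The property suites sweep identifiers 1..100 000 (round-trip, injectivity,
length thresholds), all 44 135 cores of length ≤ 3 against an independent
Horner oracle, 25 000 perturbed check letters, and a full-scale sweep of
82 433 codes — the size of a complete national release — for uniqueness and
self-consistency. The closed-loop assessments use 1 000-item (5 × 200) and
4 667-item fixtures, sizes chosen to make the planted splits land on whole
items.

## 5. Determinism and numerical notes

All generators run under an explicit seed with RNG state saved and
restored, so the same configuration is byte-identical across runs and
leaves the caller's RNG untouched. The CLI exposes the same seed: every
command is deterministic given identical inputs, configuration and seed.
Identifiers are handled as R doubles and bounded by 2^53, far beyond any
realistic registry; no maximum code length is imposed.

## 6. Known limitations

* Real classification content is out of scope (licensing); only prefixes,
  domain assignments and code *shapes* are modeled.
* Label normalization is ASCII-oriented transliteration; scripts without
  an ASCII transliteration pass through unchanged (uppercased).
* The consistency metrics treat each catalog row as one item; if a
  facility's export already aggregates duplicates, the duplicate and reuse
  rates will understate the underlying problem.
* Traditional-medicine code systems and terminology-server protocols are
  not modeled.
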