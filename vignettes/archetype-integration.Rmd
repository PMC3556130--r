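---
title: "Archetype-to-form integration: models, mapping rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetype-to-form integration: models, mapping rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archeform)
```

## The dual-model setting

An archetype is a constraint model over a fixed Reference Model (RM): a
tree of nodes, each constraining an RM class (`OBSERVATION`, `HISTORY`,
`EVENT`, `CLUSTER`, `ELEMENT`) or a data type (`DV_QUANTITY`,
`DV_DATE_TIME`, ...), whose leaves constrain one of the eight primitive
types of the Archetype Model: Boolean, String, Integer, Real, Date, Time,
Date_Time and Duration. Only the leaves describe data to be collected;
all other nodes provide structural and semantic context. `archeform`
turns such an archetype into a generic legacy-EHR entry form plus a
mapping table, records documents against the form, and exports them as
archetype-compliant XML extracts assembled from the mapping table alone.

## The ADL 1.4 subset

`parse_adl()` accepts a defined subset of ADL 1.4: the
`archetype`/`concept`/`definition`/`ontology` sections, complex nodes
with `occurrences`, attribute constraints with `existence` and
`cardinality`, the primitive constraint forms (string value lists,
regular expressions, numeric value lists and intervals, Boolean lists,
date/time/date-time format masks, duration pattern masks, `[local::...]`
code lists, assumed values after `;`), slots
(`allow_archetype ... include archetype_id/value matches {/.../}` and the
`{*}` wildcard), internal references (`use_node`), `C_DV_*` domain-type
shorthand blocks, and `term_definitions`/`term_bindings`. Anything else —
including any `adl_version` other than 1.4 — raises an explicit
"unsupported ADL construct" error rather than a silent partial parse.
`language` and `description` sections are skipped unmodelled. Comments
are supported between tokens of the structural grammar but not inside
primitive constraint blocks, whose raw text is interpreted as a whole.

Two defaulting rules matter downstream:

* **Occurrences.** A node without explicit `occurrences` inherits the
  enclosing attribute's `cardinality` when one is present, else `1..1`.
  A node is *repeating* when its upper occurrence bound exceeds 1.
* **Anonymous nodes.** `node_id` may be empty (typical for data-type
  nodes such as an `ITEM_TREE` or `C_DV_QUANTITY`); their path predicates
  then carry only `@xsi:type`.

`serialize_adl()` writes exactly this subset back out, and
parse–serialize–parse is a fixed point — the property the test suite
asserts over the synthetic corpus. Internal references are expanded by
`resolve_internal_refs()` (deep copy with the reference's own
occurrences; cycles and dangling targets are errors); expansion must
precede augmentation.

## Comprehensive archetypes

Archetypes state only the constraints they tighten, so mandatory RM
attributes they do not mention are implicit. `augment()` makes them
explicit from a declarative RM schema (`inst/extdata/rm_schema.yaml`,
loadable via `rm_schema()`), so that, for instance, a history node gains
its mandatory `origin` timestamp and an event node its `time`. Choices
made here, each genuinely open:

* **Only mandatory unconstrained attributes are added.** Optional RM
  attributes were presumed not needed for data collection; a
  `include_optional_rm_attributes` switch exists in
  `generation_config()` but defaults off, and the shipped schema does not
  act on it beyond augmentation.
* **Recursive augmentation.** Implicit subtrees are typed by the RM and
  expanded recursively until they end in primitive leaves
  (`origin → DV_DATE_TIME → value: Date_Time`). Data types terminate in
  primitives, so the recursion is bounded by the schema.
* **`auto_fill` context attributes.** Mandatory structural attributes
  with no clinical entry semantics (`language`, `encoding`, `subject` of
  entry classes; `territory`, `category`, `composer` of compositions)
  are flagged `auto_fill` in the schema with a documented default and are
  excluded from forms by default, so generated forms are not flooded
  with non-clinical fields.
* **Abstract RM types are not synthesized.** If a mandatory attribute's
  type is abstract (`ITEM_STRUCTURE`, `ITEM`), no concrete structure can
  be invented for it; such attributes are skipped and must be constrained
  by the archetype itself to appear. The per-node count property in the
  tests accounts for both exclusions.
* **Deprecated attributes** (`DV_QUANTITY.property` in the shipped
  schema) are table-driven and never added or rendered.

Augmentation is idempotent and embeds the explicit tree order-preserving;
both are asserted structurally.

## Structural mapping rules

`generate_form()` walks the comprehensive, slot-expanded tree depth-first
in pre-order (the traversal order is fixed and documented here because it
determines component ids and sibling order):

* The **root** becomes the form. Archetype roots usually sit below
  `COMPOSITION` (an `OBSERVATION`, `CLUSTER` or `ELEMENT`); the form is
  then an artificial container named after the root's local term.
* **`SECTION` nodes → pages**; label context restarts inside a page.
* **Named intermediate nodes → text objects** carrying the local term;
  implicit nodes are labelled with their RM attribute name (`origin`).
  Anonymous explicit intermediates produce no component of their own.
* **Leaves → entry fields.** Labels concatenate, with a configurable
  separator (default `.`), the local terms of named ancestors plus the
  attribute names below the last named ancestor. Multi-word terms drop
  internal whitespace with each word capitalized (`Body Mass Index` →
  `BodyMassIndex`); single-word segments, including attribute names such
  as `value`, stay verbatim. Duplicate labels get a parenthesized
  disambiguator. Page titles and table names keep the verbatim term.
* **Repeating nodes → tables**, named after the repeating node's local
  term, whose columns are all eligible leaves below it with `multi =
  TRUE`; column labels start at the repeating node itself. A repeating
  node inside another repeating node cannot be represented by a flat
  table — `check_supported()` classifies this as the failure mode
  `nested_repeats`, and `generate_form()` refuses such archetypes. The
  classifier is equivalent to a brute-force ancestor/descendant
  occurrence scan, which the acceptance suite checks on 200 random
  archetypes.
* **Slots are expanded in place**: the included archetype is resolved,
  reference-expanded, augmented and spliced in with the slot's
  occurrences; path predicates inside the expansion carry the included
  archetype's id at its root. Wildcard slots (and slots allowing several
  archetypes) must be narrowed to exactly one via
  `generation_config(slot_choices = ...)`; inclusion cycles and
  class-incompatible choices are errors.

Every component stores the full path of its source node in an XPath
dialect: a root predicate
`[@archetype_node_id = '<archetype-id>' and @xsi:type = '<class>']`
followed by `/<attribute>[...]` steps, anonymous nodes contributing only
`@xsi:type`, primitive leaves the upper-cased primitive kind
(`DATE_TIME`). Paths use ASCII quotes and a fixed attribute order, so
generation is a pure function of (archetype text, RM schema, config) —
regenerated output is byte-identical, which the tests assert on
serialized JSON.

## Data values and terminology

The eight AM primitive types map onto five legacy types (Text, Number,
Date, Time, Timestamp). Boolean collapses to Text stored as `Y`/`N` and
rendered as a checkbox — the underlying legacy store has no Boolean — and
is converted to `true`/`false` only at extract time. Date/time format
masks become entry format strings; regular expressions, duration patterns
and similar non-representable constraints ride along as non-enforced
annotations and surface as warnings in `check_supported()`, never as
failures. Value lists become choice lists in archetype order; local code
lists become (code, display-text) choices with the code as stored value.
Term bindings to external terminologies cannot be rendered in the form
model and are preserved in the parsed ontology only; the local-term
labelling is treated as sufficient form semantics.

## Documents and extracts

Documents validate at entry (`set_value()`) and again as a whole
(`validate_document()`): typed literals normalized to ISO 8601, choice
lists enforced, table rows dense in the sense that every *required*
column (implicit-mandatory leaves, or chains of mandatory occurrences)
must be present in every row — sparse optional cells are allowed, a
choice made where the form model leaves row density open.

`generate_extract()` assembles the XML from the form, mapping table and
values only — deliberately never touching the archetype, which is the
point of storing complete paths. Parsed path steps are merged on longest
common prefix (on steps, not strings); the multi-row instantiation point
is the deepest step carrying the repeating node's id, i.e. the table's
own path; rows appear as sibling elements in row order even when the
first-ordered column is empty in a row; components without values are
omitted. The envelope is the minimal generic-extract wrapper this package
defines — one `extract`, optional `subject`/`time`, one `chapter` per
document — because no richer envelope inventory is pinned down by the
form layer; it is validated against the synthetic envelope XSD shipped in
`inst/extdata/extract_envelope_synthetic.xsd` (the mapped content is
wildcard-skipped there; official RM schemas can be supplied to
`validate_extract()` instead when available). The structure-independence
property — assembly from (form, mapping, document) equals an oracle that
walks the archetype — is asserted on the synthetic corpus.

## The synthetic generator

`gen_archetype()` builds seeded cluster/element trees with controlled
depth, leaf count, primitive mix, repeating and nested-repeating
clusters, slots, internal references and choice-list sizes; local terms
are pronounceable synthetic words so failures read well. Defaults (depth
3, a handful of leaves, one repeating node, two-to-three-item choice
lists) mirror the shallow-to-moderate nesting typical of published
clinical archetypes, where repeating event or specimen structures are
common and two-level repeats are the documented integration killer. What
the generator does *not* emulate: archetype specialization,
multi-language ontologies, the `property`-style deprecated attributes
beyond what fixtures encode explicitly, terminology bindings at scale,
and the "maximal data set" breadth of real library archetypes (hundreds
of optional nodes). Passing tests therefore demonstrate correctness of
the mapping machinery on controlled structures, not coverage of every
construct in the public archetype library; the benchmark runner
(`table3_benchmark()`) exists for exactly that external validation and
reports per-archetype drift against its reference verdicts.

Problem sizes used by the automated checks — a corpus of a dozen mixed
fixtures for the structural properties, 200 random archetypes for the
failure-mode classifier, 100 archetype/document pairs for the extract
round trip — keep the full suite in the tens of seconds while giving the
brute-force oracles enough variety to be meaningful.

## Degenerate inputs and tie-breaks

Empty documents refuse to export ("nothing to export"); two fields
mapping to one leaf element is a path-collision error; a childless
cluster is unrepresentable in ADL and the generator inserts a filler
element instead; duplicate labels are disambiguated by suffix; duplicate
sibling node ids are rejected at parse time (and the generator avoids
creating them through reference expansion). Intervals are validated
(`lower ≤ upper`, integer bounds); numbers print without locale
separators or scientific notation.

## Known limitations

* The ADL subset excludes specialization semantics, `.oet` templates,
  ordinal syntax (`0|[local::...]`), date/time *value* intervals and
  ADL 1.5/2 features; these raise errors by design.
* The RM schema is a deliberately small subset of one RM release
  (`version_tag` records it); swapping in a fuller schema is a data-file
  change, but untyped corners (e.g. `ITEM_SINGLE`) are untested.
* Extract validation against the official RM/extract schemas requires
  the user to supply those XSDs; the shipped synthetic envelope schema
  pins only this package's wrapper.
* No extract import (XML back to documents) and no ISO 13606 data-type
  mapping; the 13606 route would need its own data-type table and
  extract model.
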