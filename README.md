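# archeform

Plug-and-play integration of openEHR archetypes into legacy EHR form
systems, in R.

## The problem

In the dual-model EHR architecture, a fixed **Reference Model** (RM —
classes such as `OBSERVATION`, `HISTORY`, `EVENT`, `ELEMENT`, and data
types such as `DV_QUANTITY`) is constrained by **archetypes**: shareable
models of single clinical content types (a body-mass-index observation, a
blood-pressure measurement), serialized as ADL 1.4 text. Legacy EHR
systems, however, store data in proprietary form models. For the
dual-model approach to be practical there, an archetype must be turned
into a data-entry form *automatically*, and data recorded through that
form must be exportable as a standardized, archetype-compliant XML EHR
extract — without reprogramming the EHR system per archetype.

`archeform` implements that pipeline for anyone studying or building
archetype integration: clinical-informatics researchers, EHR vendors
evaluating what their form model can and cannot represent, and students of
the dual-model architecture.

## What the package does

1. **Parse** a defined ADL 1.4 subset into a constraint tree
   (`parse_adl()`, `read_adl()`), with local terms, term bindings, slots
   and internal references (`resolve_internal_refs()`).
2. **Augment** the archetype with the RM's implicit constraints
   (`augment()`): mandatory RM attributes the archetype leaves
   unconstrained — `HISTORY.origin`, `EVENT.time` — are added from a
   declarative, editable RM schema (`rm_schema()`), producing a
   *comprehensive archetype*.
3. **Generate a form and mapping table** (`generate_form()`): leaf
   constraints become labelled entry fields; named intermediate nodes
   become text objects; `SECTION` nodes become pages; a *repeating node*
   (occurrence upper bound > 1) becomes a table with extendable rows whose
   columns are the leaves below it, labelled
   `RepeatingNode.Intermediate...leaf` (e.g.
   `Single.BodyMassIndex.value.units`); the eight AM primitive types map
   onto five legacy data types (Boolean → Text rendered as a Y/N
   checkbox). Every component records the path of its source archetype
   node in an XPath dialect. `check_supported()` reports structures the
   form model cannot represent — above all **nested repeating nodes**,
   which would need recursive tables and make integration fail.
4. **Record documents** against the form (`new_document()`,
   `set_value()`, `add_table_row()`), with validation (types, choice
   lists, checkbox Y/N, ISO 8601 normalization).
5. **Export extracts** (`generate_extract()`): using only the form, the
   mapping table and the stored values — never the archetype — the stored
   paths are merged into an archetype- and RM-compliant XML tree inside a
   generic extract envelope; `Y`/`N` become `true`/`false`;
   `validate_extract()` checks it against an XSD.
6. **Generate synthetic archetypes** (`gen_archetype()`,
   `fixture_spec()`, `write_fixtures()`) with controlled depth, leaf
   count, primitive mix, repeats, nested repeats, slots and internal
   references, so every stage is testable without downloading library
   archetypes. `paper_fixtures()` ships excerpt reconstructions of the
   body-mass-index observation and a two-level repeating cluster.

A thin CLI wraps these steps: `inst/cli/archeform.R
{check|generate|extract|fixtures|benchmark}`.

## Worked example

```r
library(archeform)
s   <- rm_schema()                                  # shipped RM subset
a   <- parse_adl(paper_fixtures()$bmi_excerpt)      # BMI observation
ca  <- augment(a, s)                                # + origin, time
gen <- generate_form(ca, s)
gen$form
#> <ehr_form> 'Body mass index' from openEHR-EHR-OBSERVATION.body_mass_index.v1
#>   entry_field 5, page 1, table 1, text_object 2
```

The form holds one table (named `Single`, after the repeating event node)
with columns `Single.BodyMassIndex.value.units` (choice list `kg/m2`,
`lb/in2`), `...magnitude`, `...precision` and `Single.time.value`, plus a
single field for the implicit `HISTORY.origin`. The deprecated
`DV_QUANTITY.property` attribute is skipped. The mapping table stores, for
example, for the origin value field:

```
[@archetype_node_id = 'openEHR-EHR-OBSERVATION.body_mass_index.v1' and @xsi:type = 'OBSERVATION']/data[@archetype_node_id = 'at0001' and @xsi:type = 'HISTORY']/origin[@xsi:type = 'DV_DATE_TIME']/value[@xsi:type = 'DATE_TIME']
```

Record a document and export it:

```r
d <- new_document(gen$form)
d <- set_value(d, gen$form, "field-5", "2012-03-01T10:00:00")   # origin
d <- add_table_row(d, gen$form, "table-1")
d <- set_value(d, gen$form, "field-1", "kg/m2", row_index = 0)
d <- set_value(d, gen$form, "field-2", "23.5",  row_index = 0)
d <- set_value(d, gen$form, "field-4", "2012-03-01T10:05:00", row_index = 0)
x <- generate_extract(d, gen$form, gen$mapping)
validate_extract(x)
#> character(0)        # schema-valid
```

```xml
<extract xmlns="http://schemas.openehr.org/v1" ...>
  <chapter document_id="doc-1">
    <content archetype_node_id="openEHR-EHR-OBSERVATION.body_mass_index.v1" xsi:type="OBSERVATION">
      <data archetype_node_id="at0001" xsi:type="HISTORY">
        <events archetype_node_id="at0002" xsi:type="EVENT">
          <data xsi:type="ITEM_TREE">
            <items archetype_node_id="at0003" xsi:type="ELEMENT">
              <value xsi:type="DV_QUANTITY">
                <units xsi:type="STRING">kg/m2</units>
                <magnitude xsi:type="REAL">23.5</magnitude>
              </value>
            </items>
          </data>
          <time xsi:type="DV_DATE_TIME">
            <value xsi:type="DATE_TIME">2012-03-01T10:05:00</value>
          </time>
        </events>
        <origin xsi:type="DV_DATE_TIME">
          <value xsi:type="DATE_TIME">2012-03-01T10:00:00</value>
        </origin>
      </data>
    </content>
  </chapter>
</extract>
```

Each stored mapping path selects exactly one element per recorded row in
this tree (`extract_query()`), which is the round-trip property the test
suite checks at scale.

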