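# Structural, data-value and terminology mapping of comprehensive
# archetypes to forms.

test_that("the eight AM primitive types map onto the five legacy types", {
  expect_equal(map_primitive("Boolean"), "Text")
  expect_equal(map_primitive("String"), "Text")
  expect_equal(map_primitive("Integer"), "Number")
  expect_equal(map_primitive("Real"), "Number")
  expect_equal(map_primitive("Date"), "Date")
  expect_equal(map_primitive("Time"), "Time")
  expect_equal(map_primitive("Date_Time"), "Timestamp")
  expect_equal(map_primitive("Duration"), "Text")
  # total over the eight kinds, and over nothing else
  expect_setequal(vapply(archeform:::AM_PRIMITIVE_KINDS, map_primitive, ""),
                  c("Text", "Number", "Date", "Time", "Timestamp"))
  expect_error(map_primitive("Complex"), "unknown AM primitive")
})

test_that("labels concatenate normalized ancestor names", {
  expect_equal(build_label(c("Single", "Body Mass Index", "value"), "units"),
               "Single.BodyMassIndex.value.units")
  expect_equal(build_label("A", "b"), "A.b")
  expect_equal(build_label(c("x y z"), "w", separator = "-"), "XYZ-w")
  expect_error(build_label(character(), "x"), "non-empty")
})

test_that("archetype paths reproduce the stored XPath dialect", {
  a <- bmi()
  root <- a$definition
  root$path_id <- a$archetype_id
  hist <- root$attributes[[1]]$children[[1]]
  p_root <- archetype_path(list(root))
  expect_identical(
    p_root,
    "[@archetype_node_id = 'openEHR-EHR-OBSERVATION.body_mass_index.v1' and @xsi:type = 'OBSERVATION']")
  p_hist <- archetype_path(list(root, list(attr = "data", node = hist)))
  expect_identical(
    p_hist,
    paste0(p_root, "/data[@archetype_node_id = 'at0001' and @xsi:type = 'HISTORY']"))
  dvdt <- archeform:::new_complex_node("DV_DATE_TIME")
  p_origin <- archetype_path(list(root, list(attr = "data", node = hist),
                                  list(attr = "origin", node = dvdt)))
  expect_identical(p_origin,
                   paste0(p_hist, "/origin[@xsi:type = 'DV_DATE_TIME']"))
  leaf <- archeform:::new_primitive("Date_Time")
  p_value <- archetype_path(list(root, list(attr = "data", node = hist),
                                 list(attr = "origin", node = dvdt),
                                 list(attr = "value", node = leaf)))
  expect_identical(p_value,
                   paste0(p_origin, "/value[@xsi:type = 'DATE_TIME']"))
})

test_that("the BMI excerpt generates the printed form structure", {
  gen <- generate_form(augment(bmi(), RM), RM)
  comp <- archeform:::form_components(gen$form)
  kinds <- vapply(comp, `[[`, "", "kind")

  # a table named after the repeating node's local term
  tab <- comp[[which(kinds == "table")]]
  expect_equal(tab$name, "Single")
  labels <- vapply(tab$columns, `[[`, "", "label")
  expect_true("Single.BodyMassIndex.value.units" %in% labels)
  expect_true("Single.BodyMassIndex.value.magnitude" %in% labels)
  # deprecated DV_QUANTITY.property is ignored
  expect_false(any(grepl("property", labels)))
  # all columns duplicable
  expect_true(all(vapply(tab$columns, `[[`, TRUE, "multi")))
  # the units column is textual with the archetype's choice list, in order
  units <- tab$columns[[which(labels == "Single.BodyMassIndex.value.units")]]
  expect_equal(units$variable$data_type, "Text")
  expect_equal(vapply(units$variable$choice_list, `[[`, "", "value"),
               c("kg/m2", "lb/in2"))

  # implicit attributes origin and time appear as fields
  all_labels <- vapply(comp[kinds == "entry_field"], `[[`, "", "label")
  expect_true("Single.time.value" %in% all_labels)      # EVENT.time column
  expect_true("history.origin.value" %in% all_labels)   # HISTORY.origin field
  # text objects for the named intermediate and the implicit origin
  texts <- vapply(comp[kinds == "text_object"], `[[`, "", "text")
  expect_setequal(texts, c("history", "origin"))

  # every component has exactly one mapping entry
  ids <- vapply(comp, `[[`, "", "id")
  expect_setequal(names(gen$mapping$entries), ids)
})

test_that("the smallest generatable archetype yields one page, one field and a mapping", {
  gen <- generate_form(augment(parse_adl(minimal_adl()), RM), RM)
  comp <- archeform:::form_components(gen$form)
  kinds <- vapply(comp, `[[`, "", "kind")
  expect_equal(sum(kinds == "page"), 1L)
  expect_equal(sum(kinds == "entry_field"), 1L)
  expect_gte(length(gen$mapping$entries), 2L)
})

test_that("nested repeating nodes block generation; detection matches brute force", {
  nr <- augment(parse_adl(paper_fixtures()$nested_repeat_cluster), RM)
  v <- check_supported(nr, generation_config(), RM)
  expect_true("nested_repeats" %in% v$kind)
  expect_true(all(v$severity[v$kind == "nested_repeats"] == "failure"))
  expect_error(generate_form(nr, RM), "nested_repeats")

  # equivalence with the independent ancestor/descendant scan
  for (i in 1:60) {
    txt <- gen_archetype(fixture_spec(
      depth = 3L + (i %% 3L), leaf_count = 3L + (i %% 5L),
      nested_repeat = (i %% 2L == 0L),
      repeat_nodes = if (i %% 2L == 0L) 0L else (i %% 3L),
      seed = 500L + i))
    ca <- augment(parse_adl(txt), RM)
    flagged <- "nested_repeats" %in% check_supported(ca, generation_config(), RM)$kind
    expect_equal(flagged, oracle_nested_repeats(ca$definition),
                 info = paste("fixture seed", 500L + i))
  }
})

test_that("archetypes without repeats or unsupported constructs check clean", {
  txt <- gen_archetype(fixture_spec(depth = 3L, leaf_count = 4L,
                                    repeat_nodes = 0L, seed = 77L))
  ca <- augment(parse_adl(txt), RM)
  v <- check_supported(ca, generation_config(), RM)
  expect_equal(nrow(v), 0L)
})

test_that("non-enforceable constraints surface as warnings, not failures", {
  txt <- sub('value matches \\{"x"\\}', "value matches {/^[A-Z]+$/}",
             minimal_adl())
  ca <- augment(parse_adl(txt), RM)
  v <- check_supported(ca, generation_config(), RM)
  expect_true("unsupported_constraint" %in% v$kind)
  expect_true(all(v$severity == "warning"))
  # generation still succeeds; the constraint rides along as an annotation
  gen <- generate_form(ca, RM)
  fld <- Filter(function(c) c$kind == "entry_field",
                archeform:::form_components(gen$form))[[1]]
  expect_match(fld$variable$annotations$not_enforced, "pattern")
})

test_that("generation is deterministic: byte-identical serialized output", {
  for (txt in fixture_corpus(4L)) {
    a <- parse_adl(txt)
    ca <- augment(resolve_internal_refs(a), RM)
    if ("nested_repeats" %in%
          check_supported(ca, generation_config(), RM)$kind) next
    p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
    write_form(generate_form(ca, RM), p1)
    write_form(generate_form(augment(resolve_internal_refs(parse_adl(txt)),
                                     RM), RM), p2)
    expect_identical(readLines(p1), readLines(p2))
    unlink(c(p1, p2))
  }
})

test_that("every eligible leaf maps to exactly one field: counts agree with brute force", {
  for (txt in fixture_corpus(8L)) {
    ca <- augment(resolve_internal_refs(parse_adl(txt)), RM)
    if ("nested_repeats" %in%
          check_supported(ca, generation_config(), RM)$kind) next
    gen <- generate_form(ca, RM)
    expect_equal(count_form_fields(gen$form),
                 oracle_leaf_count(ca$definition, RM))
  }
})

test_that("duplicate labels are disambiguated", {
  # two anonymous sibling elements would collide on the same label
  txt <- paste0(
    "archetype (adl_version=1.4)\n    openEHR-EHR-CLUSTER.twins.v1\n\n",
    "concept\n    [at0000]\n\n",
    "definition\n",
    "    CLUSTER[at0000] matches {\n",
    "        items matches {\n",
    "            ELEMENT[at0001] matches {\n",
    "                value matches { DV_TEXT matches { value matches {\"a\"} } }\n",
    "            }\n",
    "            ELEMENT[at0002] matches {\n",
    "                value matches { DV_TEXT matches { value matches {\"b\"} } }\n",
    "            }\n",
    "        }\n    }\n\n",
    "ontology\n    term_definitions = <\n        [\"en\"] = <\n",
    "            items = <\n",
    "                [\"at0000\"] = <\n                    text = <\"t\">\n",
    "                    description = <\"d\">\n                >\n",
    "                [\"at0001\"] = <\n                    text = <\"same name\">\n",
    "                    description = <\"d\">\n                >\n",
    "                [\"at0002\"] = <\n                    text = <\"same name\">\n",
    "                    description = <\"d\">\n                >\n",
    "            >\n        >\n    >\n")
  gen <- generate_form(augment(parse_adl(txt), RM), RM)
  labels <- vapply(Filter(function(c) c$kind == "entry_field",
                          archeform:::form_components(gen$form)),
                   `[[`, "", "label")
  expect_equal(anyDuplicated(labels), 0L)
})

test_that("slots expand in place; wildcards require an explicit choice", {
  fx <- slot_fixture()
  a <- parse_adl(fx$main)
  ca <- augment(a, RM)
  res <- archetype_resolver(list(fx$included))

  # unresolved wildcard: flagged and generation fails
  v <- check_supported(ca, generation_config(), RM)
  expect_true("unresolved_wildcard_slot" %in% v$kind)
  expect_error(generate_form(ca, RM, generation_config(), res),
               "narrowed down to a single archetype")

  cfg <- generation_config(
    slot_choices = list("/items[at0003]" = fx$included$archetype_id))
  expect_false("unresolved_wildcard_slot" %in%
                 check_supported(ca, cfg, RM, res)$kind)
  gen <- generate_form(ca, RM, cfg, res)
  # both slots expanded: fields from the included archetype appear twice
  # (once per slot) plus the includer's own element
  inc_ca <- augment(resolve_internal_refs(fx$included), RM)
  n_inc <- oracle_leaf_count(inc_ca$definition, RM)
  expect_equal(count_form_fields(gen$form), 1L + 2L * n_inc)
  # expansion paths carry the included archetype's id in their predicates
  expect_true(any(grepl(fx$included$archetype_id,
                        unlist(gen$mapping$entries), fixed = TRUE)))
})

test_that("slot expansion rejects incompatible classes, disallowed ids and cycles", {
  fx <- slot_fixture()
  a <- parse_adl(fx$main)
  ca <- augment(a, RM)
  # incompatible class: offer an OBSERVATION for a CLUSTER slot
  obs <- bmi()
  cfg <- generation_config(
    slot_choices = list("/items[at0003]" = obs$archetype_id))
  expect_error(generate_form(ca, RM, cfg,
                             archetype_resolver(list(obs, fx$included))),
               "not compatible")
  # id not allowed by the slot's patterns
  slot <- archeform:::new_slot("CLUSTER", "at0002",
                               "openEHR-EHR-CLUSTER\\.something_else\\.v1")
  expect_error(expand_slot(slot, fx$included, RM), "not allowed")
  # self-inclusion cycle
  self_id <- a$archetype_id
  cfg <- generation_config(slot_choices = list("/items[at0003]" = self_id))
  expect_error(generate_form(ca, RM, cfg,
                             archetype_resolver(list(a, fx$included))),
               "cycle|includes itself")
})

test_that("term bindings are parsed and preserved without being rendered", {
  txt <- sub(
    "ontology\n    term_definitions",
    paste0("ontology\n    term_bindings = <\n",
           "        [\"SNOMED-CT\"] = <\n            items = <\n",
           "                [\"at0000\"] = <[SNOMED-CT::60621009]>\n",
           "            >\n        >\n    >\n    term_definitions"),
    minimal_adl())
  a <- parse_adl(txt)
  expect_equal(a$ontology$bindings[["SNOMED-CT"]][["at0000"]],
               "SNOMED-CT::60621009")
  gen <- generate_form(augment(a, RM), RM)
  # nothing in the rendered form carries the external code
  comp_text <- paste(unlist(archeform:::strip_classes(gen$form)),
                     collapse = " ")
  expect_false(grepl("60621009", comp_text))
})
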