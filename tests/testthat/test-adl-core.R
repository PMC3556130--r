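# ADL parsing, navigation, serialization and internal-reference expansion.

test_that("a minimal element archetype parses to one complex chain with a string leaf", {
  a <- parse_adl(minimal_adl())
  expect_s3_class(a, "archetype")
  expect_equal(a$archetype_id, "openEHR-EHR-ELEMENT.minimal.v1")
  expect_equal(a$concept_code, "at0000")
  expect_equal(a$definition$rm_class, "ELEMENT")
  leaf <- a$definition$attributes[[1]]$children[[1]]$attributes[[1]]$children[[1]]
  expect_s3_class(leaf, "adl_primitive")
  expect_equal(leaf$kind, "String")
  expect_equal(leaf$allowed_values, "x")
})

test_that("the body-mass-index excerpt parses with the printed structure", {
  a <- bmi()
  expect_equal(a$definition$node_id, "at0000")
  expect_equal(a$definition$rm_class, "OBSERVATION")
  hist <- a$definition$attributes[[1]]$children[[1]]
  expect_equal(hist$rm_class, "HISTORY")
  expect_equal(hist$node_id, "at0001")
  ev <- hist$attributes[[1]]$children[[1]]
  expect_equal(ev$node_id, "at0002")
  # repeating: upper occurrence limit unbounded
  expect_true(is.infinite(ev$occurrences$upper))
  expect_equal(ev$occurrences$lower, 0L)
  # the units leaf carries a two-item value list
  tree <- ev$attributes[[1]]$children[[1]]
  el <- tree$attributes[[1]]$children[[1]]
  expect_equal(el$node_id, "at0003")
  qty <- el$attributes[[1]]$children[[1]]
  expect_equal(qty$rm_class, "DV_QUANTITY")
  units <- NULL
  for (attr in qty$attributes) if (attr$name == "units") units <- attr
  expect_equal(units$children[[1]]$allowed_values, c("kg/m2", "lb/in2"))
  # anonymous item tree: no node id
  expect_equal(tree$node_id, "")
})

test_that("missing sections and malformed input raise targeted errors", {
  txt <- paper_fixtures()$bmi_excerpt
  no_def <- sub("definition.*ontology", "ontology", txt)
  expect_error(parse_adl(no_def), "missing section 'definition'")
  no_ont <- sub("\nontology.*$", "", txt)
  expect_error(parse_adl(no_ont), "missing section 'ontology'")
  expect_error(parse_adl(sub("concept\n    \\[at0000\\]\n", "", txt)),
               "concept")
  # node id without a term definition
  broken <- sub('\\["at0001"\\]', '["at0099"]', txt)
  expect_error(parse_adl(broken), "no term definition")
  # syntax errors carry line/column
  expect_error(parse_adl(sub("matches \\{", "matches {{", txt)), "line [0-9]+")
})

test_that("ADL versions other than 1.4 are rejected", {
  txt <- sub("adl_version=1.4", "adl_version=2.0", minimal_adl())
  expect_error(parse_adl(txt), "only ADL 1.4")
})

test_that("duplicate node ids among siblings are rejected", {
  txt <- paste0(
    "archetype (adl_version=1.4)\n    openEHR-EHR-CLUSTER.dup.v1\n\n",
    "concept\n    [at0000]\n\n",
    "definition\n",
    "    CLUSTER[at0000] matches {\n",
    "        items matches {\n",
    "            ELEMENT[at0001] matches {\n",
    "                value matches { DV_TEXT matches { value matches {\"a\"} } }\n",
    "            }\n",
    "            ELEMENT[at0001] matches {\n",
    "                value matches { DV_TEXT matches { value matches {\"b\"} } }\n",
    "            }\n",
    "        }\n    }\n\n",
    "ontology\n    term_definitions = <\n        [\"en\"] = <\n",
    "            items = <\n",
    "                [\"at0000\"] = <\n                    text = <\"t\">\n",
    "                    description = <\"d\">\n                >\n",
    "                [\"at0001\"] = <\n                    text = <\"u\">\n",
    "                    description = <\"d\">\n                >\n",
    "            >\n        >\n    >\n")
  expect_error(parse_adl(txt), "duplicate node id")
})

test_that("primitive constraint forms are inferred from their literals", {
  mk <- function(constraint) {
    txt <- sub('value matches \\{"x"\\}',
               paste0("value matches {", constraint, "}"), minimal_adl())
    a <- parse_adl(txt)
    a$definition$attributes[[1]]$children[[1]]$attributes[[1]]$children[[1]]
  }
  expect_equal(mk('"a", "b"')$allowed_values, c("a", "b"))
  p <- mk("|0..10|"); expect_equal(p$kind, "Integer")
  expect_equal(p$range, list(lower = 0, upper = 10))
  p <- mk("|0.5..2.5|"); expect_equal(p$kind, "Real")
  p <- mk("1, 2, 3"); expect_equal(p$kind, "Integer")
  expect_equal(p$allowed_values, c(1, 2, 3))
  p <- mk("True, False"); expect_equal(p$kind, "Boolean")
  p <- mk("yyyy-mm-dd"); expect_equal(p$kind, "Date")
  expect_true(p$enforceable); expect_equal(p$pattern, "yyyy-mm-dd")
  p <- mk("hh:mm:ss"); expect_equal(p$kind, "Time")
  p <- mk("yyyy-mm-ddThh:mm:ss"); expect_equal(p$kind, "Date_Time")
  p <- mk("PYMWD"); expect_equal(p$kind, "Duration")
  expect_false(p$enforceable)
  p <- mk("/ab?c+/"); expect_equal(p$kind, "String")
  expect_false(p$enforceable); expect_equal(p$pattern, "ab?c+")
  p <- mk('"a", "b"; "a"'); expect_equal(p$assumed_value, "a")
  p <- mk("[local::at0000, at0000]")
  expect_true(p$local_coded)
  expect_error(mk("@@nonsense@@"), "unsupported ADL construct")
})

test_that("local_term returns display texts and rejects unknown codes", {
  a <- bmi()
  expect_equal(local_term(a, "at0000")$text, "Body mass index")
  expect_equal(local_term(a, "at0001")$text, "history")
  expect_error(local_term(a, "at9999"), "unknown local code")
})

test_that("parse-serialize-parse is a fixed point over the fixture corpus", {
  for (txt in fixture_corpus(8L)) {
    a <- parse_adl(txt)
    b <- parse_adl(serialize_adl(a))
    expect_true(archetypes_equal(a, b))
    # and serialization itself is stable
    expect_identical(serialize_adl(a), serialize_adl(b))
  }
})

test_that("every branch of a parsed definition terminates in a primitive, slot or reference", {
  for (txt in fixture_corpus(6L)) {
    a <- parse_adl(txt)
    walk <- archeform:::walk_definition
    walk(a$definition, function(node, chain) {
      if (inherits(node, "adl_node"))
        expect_gt(length(node$attributes), 0)
      else
        expect_true(inherits(node, "adl_primitive") ||
                      inherits(node, "adl_slot") ||
                      inherits(node, "adl_ref"))
    })
  }
})

test_that("internal references expand to structurally equal subtrees and are idempotent", {
  # no references: identity
  a <- bmi()
  expect_true(archetypes_equal(a, resolve_internal_refs(a)))

  txt <- gen_archetype(fixture_spec(depth = 3L, leaf_count = 3L,
                                    internal_ref_count = 1L,
                                    repeat_nodes = 0L, seed = 11L))
  a <- parse_adl(txt)
  refs <- Filter(function(n) inherits(n, "adl_ref"),
                 archeform:::archetype_nodes(a))
  expect_equal(length(refs), 1L)
  r <- resolve_internal_refs(a)
  expect_equal(length(Filter(function(n) inherits(n, "adl_ref"),
                             archeform:::archetype_nodes(r))), 0L)
  # the expansion equals its target (independent comparator), except for
  # the reference's own occurrences
  target <- archeform:::resolve_path_node(a$definition, refs[[1]]$target_path)
  expanded <- archeform:::resolve_path_node(r$definition, refs[[1]]$target_path)
  expect_true(archeform:::trees_equal(target, expanded))
  # idempotent
  expect_true(archetypes_equal(r, resolve_internal_refs(r)))
})

test_that("a self-referencing use_node is reported as a cycle", {
  txt <- paste0(
    "archetype (adl_version=1.4)\n    openEHR-EHR-CLUSTER.cycle.v1\n\n",
    "concept\n    [at0000]\n\n",
    "definition\n",
    "    CLUSTER[at0000] matches {\n",
    "        items matches {\n",
    "            CLUSTER[at0001] matches {\n",
    "                items matches {\n",
    "                    use_node CLUSTER /items[at0001]\n",
    "                }\n            }\n",
    "        }\n    }\n\n",
    "ontology\n    term_definitions = <\n        [\"en\"] = <\n",
    "            items = <\n",
    "                [\"at0000\"] = <\n                    text = <\"t\">\n",
    "                    description = <\"d\">\n                >\n",
    "                [\"at0001\"] = <\n                    text = <\"u\">\n",
    "                    description = <\"d\">\n                >\n",
    "            >\n        >\n    >\n")
  a <- parse_adl(txt)
  expect_error(resolve_internal_refs(a), "cycle")
})

test_that("dangling reference targets are reported", {
  txt <- gen_archetype(fixture_spec(depth = 3L, leaf_count = 3L,
                                    internal_ref_count = 1L,
                                    repeat_nodes = 0L, seed = 12L))
  a <- parse_adl(txt)
  # retarget the reference to a non-existing path
  retarget <- function(node) {
    if (inherits(node, "adl_ref")) { node$target_path <- "/items[at9999]"; return(node) }
    if (inherits(node, "adl_node"))
      node$attributes <- lapply(node$attributes, function(at) {
        at$children <- lapply(at$children, retarget); at
      })
    node
  }
  a$definition <- retarget(a$definition)
  expect_error(resolve_internal_refs(a), "dangling")
})

test_that("reading and writing .adl files round-trips", {
  path <- tempfile(fileext = ".adl")
  a <- bmi()
  write_adl(a, path)
  expect_true(archetypes_equal(a, read_adl(path)))
  unlink(path)
})
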