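# Extract generation: path-driven XML assembly, value conversion,
# round-trip queries, schema validation, structure independence.

bmi_pipeline <- function() {
  gen <- generate_form(augment(bmi(), RM), RM)
  list(ca = augment(bmi(), RM), form = gen$form, mapping = gen$mapping)
}

test_that("a recorded origin timestamp lands on the Table-2 path", {
  p <- bmi_pipeline()
  d <- new_document(p$form)
  d <- set_value(d, p$form, "field-5", "2012-03-01T10:00:00")
  x <- generate_extract(d, p$form, p$mapping)
  hits <- extract_query(x, p$mapping$entries[["field-5"]])
  expect_length(hits, 1L)
  expect_equal(xml2::xml_text(hits), "2012-03-01T10:00:00")
  # the enclosing elements carry the printed identifiers
  hist <- xml2::xml_find_all(
    x, "//d1:data[@archetype_node_id = 'at0001']",
    ns = c(d1 = "http://schemas.openehr.org/v1"))
  expect_length(hist, 1L)
})

test_that("two table rows become two sibling events elements in row order", {
  p <- bmi_pipeline()
  d <- new_document(p$form)
  d <- add_table_row(d, p$form, "table-1")
  d <- add_table_row(d, p$form, "table-1")
  d <- set_value(d, p$form, "field-1", "kg/m2", 0)
  d <- set_value(d, p$form, "field-4", "2012-03-01T10:05:00", 0)
  d <- set_value(d, p$form, "field-1", "lb/in2", 1)
  d <- set_value(d, p$form, "field-4", "2012-03-01T10:06:00", 1)
  x <- generate_extract(d, p$form, p$mapping)
  ev <- xml2::xml_find_all(x, "//d1:events",
                           ns = c(d1 = "http://schemas.openehr.org/v1"))
  expect_length(ev, 2L)
  units <- extract_query(x, p$mapping$entries[["field-1"]])
  expect_equal(xml2::xml_text(units), c("kg/m2", "lb/in2"))
})

test_that("an empty document cannot be exported", {
  p <- bmi_pipeline()
  expect_error(generate_extract(new_document(p$form), p$form, p$mapping),
               "nothing to export")
})

test_that("legacy literals convert to RM value representations", {
  expect_equal(convert_value("Y", "Text", "BOOLEAN"), "true")
  expect_equal(convert_value("N", "Text", "BOOLEAN"), "false")
  expect_error(convert_value("yes", "Text", "BOOLEAN"), "'Y' or 'N'")
  expect_equal(convert_value("12.5", "Number", "REAL"), "12.5")
  expect_equal(convert_value("0012.50", "Number", "REAL"), "12.5")
  expect_error(convert_value("many", "Number", "REAL"), "unrepresentable")
  expect_equal(convert_value("free text", "Text", "STRING"), "free text")
  expect_equal(convert_value("2012-03-01", "Date", "DATE"), "2012-03-01")
})

test_that("round trip: every valued field's path selects its converted value", {
  set.seed(321)
  n_checked <- 0L
  for (txt in fixture_corpus(8L)) {
    ca <- augment(resolve_internal_refs(parse_adl(txt)), RM)
    if ("nested_repeats" %in%
          check_supported(ca, generation_config(), RM)$kind) next
    gen <- generate_form(ca, RM)
    d <- random_document(gen$form, n_rows = 2L)
    x <- generate_extract(d, gen$form, gen$mapping)
    expect_length(validate_extract(x), 0L)
    by_field <- split(d$values, vapply(d$values, `[[`, "", "field_id"))
    for (fid in names(by_field)) {
      vs <- by_field[[fid]]
      vs <- vs[order(vapply(vs, function(v) v$row_index, 0L))]
      field <- archeform:::form_component(gen$form, fid)
      path <- gen$mapping$entries[[fid]]
      hits <- extract_query(x, path)
      expect_length(hits, length(vs))
      target <- archeform:::parse_mapping_path(path)
      target_type <- target[[length(target)]]$type
      expect_equal(xml2::xml_text(hits),
                   unname(vapply(vs, function(v) {
                     convert_value(v$literal, field$variable$data_type,
                                   target_type)
                   }, "")))
      n_checked <- n_checked + length(vs)
    }
  }
  expect_gt(n_checked, 30L)
})

test_that("extract assembly from (form, mapping, document) equals the archetype-walking oracle", {
  set.seed(99)
  for (txt in fixture_corpus(6L)) {
    a <- resolve_internal_refs(parse_adl(txt))
    ca <- augment(a, RM)
    if ("nested_repeats" %in%
          check_supported(ca, generation_config(), RM)$kind) next
    gen <- generate_form(ca, RM)
    d <- random_document(gen$form, n_rows = 2L)
    x <- generate_extract(d, gen$form, gen$mapping)
    got <- extract_content_string(x)
    want <- oracle_extract_content(ca, RM, gen$form, gen$mapping, d)
    expect_identical(got, want)
  }
})

test_that("adding a value never removes elements from the extract", {
  p <- bmi_pipeline()
  d <- new_document(p$form)
  d <- set_value(d, p$form, "field-5", "2012-03-01T10:00:00")
  x1 <- generate_extract(d, p$form, p$mapping)
  d <- add_table_row(d, p$form, "table-1")
  d <- set_value(d, p$form, "field-4", "2012-03-01T10:05:00", 0)
  x2 <- generate_extract(d, p$form, p$mapping)
  # signature of every element: name chain from the root plus node id
  elem_sigs <- function(x) {
    vapply(xml2::xml_find_all(x, "//*"), function(n) {
      chain <- c(rev(xml2::xml_name(xml2::xml_parents(n))), xml2::xml_name(n))
      paste(paste(chain, collapse = "/"),
            xml2::xml_attr(n, "archetype_node_id"), sep = "|")
    }, "")
  }
  s1 <- table(elem_sigs(x1)); s2 <- table(elem_sigs(x2))
  expect_true(all(names(s1) %in% names(s2)))
  expect_true(all(s1 <= s2[names(s1)]))
  expect_gt(sum(s2), sum(s1))
})

test_that("extracts validate against the envelope schema; broken trees do not", {
  p <- bmi_pipeline()
  d <- set_value(new_document(p$form), p$form, "field-5",
                 "2012-03-01T10:00:00")
  x <- generate_extract(d, p$form, p$mapping)
  expect_length(validate_extract(x), 0L)
  empty <- xml2::read_xml('<extract xmlns="http://schemas.openehr.org/v1"><chapter/></extract>')
  expect_gt(length(validate_extract(empty)), 0L)
  wrong_root <- xml2::read_xml('<not_an_extract xmlns="http://schemas.openehr.org/v1"/>')
  expect_gt(length(validate_extract(wrong_root)), 0L)
  expect_error(validate_extract(x, "/no/such/schema.xsd"), "unreadable")
})

test_that("path collisions and unmapped fields are reported", {
  p <- bmi_pipeline()
  d <- set_value(new_document(p$form), p$form, "field-5",
                 "2012-03-01T10:00:00")
  m2 <- p$mapping
  m2$entries[["field-5"]] <- NULL
  expect_error(generate_extract(d, p$form, m2), "no mapping path")
  m3 <- p$mapping
  m3$entries[["field-5"]] <- "not a path"
  expect_error(generate_extract(d, p$form, m3), "unparseable")
})

test_that("extract files are written as formatted UTF-8 XML", {
  p <- bmi_pipeline()
  d <- set_value(new_document(p$form), p$form, "field-5",
                 "2012-03-01T10:00:00")
  x <- generate_extract(d, p$form, p$mapping)
  path <- tempfile(fileext = ".xml")
  write_extract(x, path)
  re <- xml2::read_xml(path)
  expect_length(validate_extract(re), 0L)
  unlink(path)
})
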