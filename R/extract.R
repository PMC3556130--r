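# Archetype-compliant XML extract generation.
#
# The extract is assembled from the document, the form and the mapping
# table alone: the stored archetype paths are parsed into element chains,
# merged on shared prefixes, and wrapped in a generic extract envelope.
# The source archetype is never consulted — that is the point of storing
# complete paths per form component.

OPENEHR_NS <- "http://schemas.openehr.org/v1"
XSI_NS <- "http://www.w3.org/2001/XMLSchema-instance"

# Parse a stored mapping path into steps: list(name, node_id, type).
# The first step has name NA (it is the content root of the document).
parse_mapping_path <- function(path) {
  root_re <- "^\\[@archetype_node_id = '([^']*)' and @xsi:type = '([^']*)'\\]"
  m <- regmatches(path, regexec(root_re, path))[[1]]
  if (length(m) != 3L)
    stop("unparseable mapping path (root predicate): ", path, call. = FALSE)
  steps <- list(list(name = NA_character_, node_id = m[2], type = m[3]))
  rest <- substr(path, nchar(m[1]) + 1L, nchar(path))
  step_re <- "^/([A-Za-z_][A-Za-z0-9_]*)\\[(@archetype_node_id = '([^']*)' and )?@xsi:type = '([^']*)'\\]"
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(step_re, rest))[[1]]
    if (length(m) == 0L)
      stop("unparseable mapping path near '", substr(rest, 1, 40), "'",
           call. = FALSE)
    steps[[length(steps) + 1L]] <-
      list(name = m[2],
           node_id = if (nzchar(m[4])) m[4] else NA_character_,
           type = m[5])
    rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
  }
  steps
}

#' Convert a stored legacy literal to its RM representation
#'
#' Checkbox-backed Booleans stored as "Y"/"N" become "true"/"false";
#' numbers are rendered without locale separators; dates and times stay in
#' ISO 8601; text passes through.
#'
#' @param literal the stored text literal.
#' @param legacy_type the variable's legacy data type.
#' @param target_type the RM leaf type from the mapping path (e.g.
#'   `"BOOLEAN"`, `"REAL"`, `"DATE_TIME"`).
#' @return the text content for the extract leaf element.
#' @export
convert_value <- function(literal, legacy_type, target_type) {
  if (identical(target_type, "BOOLEAN")) {
    if (identical(literal, "Y")) return("true")
    if (identical(literal, "N")) return("false")
    stop("Boolean-backed value must be 'Y' or 'N', got '", literal, "'",
         call. = FALSE)
  }
  if (identical(legacy_type, "Number") ||
      target_type %in% c("REAL", "INTEGER")) {
    x <- suppressWarnings(as.numeric(literal))
    if (is.na(x))
      stop("unrepresentable number: '", literal, "'", call. = FALSE)
    return(format(x, scientific = FALSE, trim = TRUE))
  }
  literal
}

#' Generate an XML EHR extract from a recorded document
#'
#' Uses only the form, the mapping table and the stored values. Paths of
#' valued components are parsed into element chains and merged into one
#' tree (longest-common-prefix on parsed steps); table rows instantiate the
#' subtree below the repeating node's path once per row, in row order;
#' components without values are omitted. The content is wrapped in a
#' minimal generic extract envelope.
#'
#' @param d an `ehr_document` (must validate against the form).
#' @param f the `ehr_form`.
#' @param m the `mapping_table` generated with the form.
#' @param subject optional subject identifier recorded in the envelope.
#' @param time optional extraction time recorded in the envelope (kept out
#'   of the default output so generation is deterministic).
#' @return an `xml_document` (see [xml2::xml_root()]).
#' @export
generate_extract <- function(d, f, m, subject = NULL, time = NULL) {
  stopifnot(inherits(d, "ehr_document"), inherits(f, "ehr_form"))
  problems <- validate_document(d, f)
  if (length(problems) > 0L)
    stop("document does not validate against its form: ",
         paste(problems, collapse = "; "), call. = FALSE)
  if (length(d$values) == 0L)
    stop("nothing to export: document holds no values", call. = FALSE)

  # order values deterministically: component order in the form, then row
  comp_order <- vapply(form_components(f), `[[`, "", "id")
  vals <- d$values[order(match(vapply(d$values, `[[`, "", "field_id"),
                               comp_order),
                         vapply(d$values, function(v) v$row_index, 0L))]

  tree <- list(children = list(), order = character())
  # when a table is first touched, register all its valued rows at once so
  # repeated subtrees appear as siblings in row order even if the earliest
  # column is unfilled in some row
  rows_registered <- character()
  register_rows <- function(tree, tab) {
    col_ids <- vapply(tab$columns, `[[`, "", "id")
    steps <- parse_mapping_path(m$entries[[tab$id]])
    for (r in seq_len(d$rows[[tab$id]] %||% 0L) - 1L) {
      has_value <- any(vapply(d$values, function(v) {
        v$row_index == r && v$field_id %in% col_ids
      }, TRUE))
      if (has_value)
        tree <- insert_chain(tree, steps, r, length(steps), NULL,
                             m$entries[[tab$id]])
    }
    tree
  }
  for (v in vals) {
    field <- form_component(f, v$field_id)
    path <- m$entries[[v$field_id]]
    if (is.null(path))
      stop("no mapping path for valued field '", v$field_id, "'",
           call. = FALSE)
    steps <- parse_mapping_path(path)
    tab <- field_table(f, v$field_id)
    tab_depth <- NA_integer_
    if (!is.null(tab)) {
      tab_depth <- length(parse_mapping_path(m$entries[[tab$id]]))
      if (!(tab$id %in% rows_registered)) {
        tree <- register_rows(tree, tab)
        rows_registered <- c(rows_registered, tab$id)
      }
    }
    text <- convert_value(v$literal, field$variable$data_type,
                          steps[[length(steps)]]$type)
    tree <- insert_chain(tree, steps, v$row_index, tab_depth, text, path)
  }

  doc <- xml2::read_xml(paste0(
    '<extract xmlns="', OPENEHR_NS, '" xmlns:xsi="', XSI_NS,
    '" schema_version="archeform-extract-1"/>'))
  root <- xml2::xml_root(doc)
  if (!is.null(subject)) {
    s_el <- xml2::xml_add_child(root, "subject")
    xml2::xml_set_text(s_el, as.character(subject))
  }
  if (!is.null(time)) {
    t_el <- xml2::xml_add_child(root, "time")
    xml2::xml_set_text(t_el, as.character(time))
  }
  chapter <- xml2::xml_add_child(root, "chapter")
  xml2::xml_set_attr(chapter, "document_id", d$id)
  emit_tree(chapter, tree, top = TRUE)
  # reparse so every element is properly placed in the default namespace
  xml2::read_xml(as.character(doc))
}

# Insert one parsed path into the merge tree. Children are keyed by
# (element name, node id, type, row discriminator at the repeating step);
# insertion order is preserved so table rows appear as siblings in row
# order.
insert_chain <- function(tree, steps, row_index, tab_depth, text, path) {
  rec <- function(node, i) {
    if (i > length(steps)) {
      if (!is.null(node$text))
        stop("path collision: two fields map to the same leaf element at ",
             path, call. = FALSE)
      node$text <- text
      return(node)
    }
    st <- steps[[i]]
    key <- paste(st$name, st$node_id, st$type, sep = "\r")
    if (!is.na(tab_depth) && i == tab_depth)
      key <- paste0(key, "\r#", row_index)
    child <- node$children[[key]]
    if (is.null(child)) {
      child <- list(step = st, children = list(), text = NULL,
                    order = character())
      node$order <- c(node$order, key)
    }
    node$children[[key]] <- rec(child, i + 1L)
    node
  }
  rec(tree, 1L)
}

emit_tree <- function(xml_parent, tree, top = FALSE) {
  for (key in tree$order) {
    child <- tree$children[[key]]
    st <- child$step
    name <- if (is.na(st$name)) "content" else st$name
    el <- xml2::xml_add_child(xml_parent, name)
    if (!is.na(st$node_id))
      xml2::xml_set_attr(el, "archetype_node_id", st$node_id)
    xml2::xml_set_attr(el, "xsi:type", st$type)
    if (!is.null(child$text)) xml2::xml_set_text(el, child$text)
    emit_tree(el, child)
  }
  invisible()
}

#' Evaluate a stored mapping path against a generated extract
#'
#' Rewrites the stored path (which is relative to the document content
#' root) into a namespace-qualified XPath query and runs it against the
#' extract, returning the matching elements. Used for round-trip checks:
#' every valued field's path must select exactly one element per recorded
#' row.
#'
#' @param x an extract (`xml_document`).
#' @param path a stored mapping path.
#' @return an `xml_nodeset`.
#' @export
extract_query <- function(x, path) {
  steps <- parse_mapping_path(path)
  pred <- function(st) {
    if (is.na(st$node_id))
      paste0("[@xsi:type = '", st$type, "']")
    else
      paste0("[@archetype_node_id = '", st$node_id,
             "' and @xsi:type = '", st$type, "']")
  }
  q <- paste0("//d1:content", pred(steps[[1]]))
  for (st in steps[-1]) q <- paste0(q, "/d1:", st$name, pred(st))
  xml2::xml_find_all(x, q, ns = c(d1 = OPENEHR_NS, xsi = XSI_NS))
}

#' Validate an extract against a schema set
#'
#' @param x an extract (`xml_document`).
#' @param schema_path an XSD file; defaults to the synthetic envelope
#'   schema shipped with the package (official RM/extract schemas may be
#'   supplied instead when available).
#' @return a character vector of violations; empty when the document
#'   validates.
#' @export
validate_extract <- function(x, schema_path = NULL) {
  if (is.null(schema_path))
    schema_path <- system.file("extdata", "extract_envelope_synthetic.xsd",
                               package = "archeform", mustWork = TRUE)
  if (!file.exists(schema_path))
    stop("schema set unreadable: ", schema_path, call. = FALSE)
  schema <- xml2::read_xml(schema_path)
  ok <- xml2::xml_validate(x, schema)
  if (isTRUE(ok)) character() else attr(ok, "errors")
}

#' Write an extract to a file
#' @param x an extract (`xml_document`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extract <- function(x, path) {
  xml2::write_xml(x, path, options = "format")
  invisible(path)
}
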