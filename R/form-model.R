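# Generic legacy-EHR form model.
#
# Mirrors the typical proprietary form package of a legacy EHR system: a
# FORM consists of PAGEs; pages contain pages, TEXT_OBJECTs and
# ENTRY_FIELDs; entry fields reference VARIABLEs typed with one of five
# primitive legacy data types; fields that must be duplicable during
# documentation are embedded in TABLEs (which never nest). Documents record
# VALUEs against a form. Everything serializes to JSON so the command-line
# steps can be piped.

LEGACY_DATA_TYPES <- c("Text", "Number", "Date", "Time", "Timestamp")

new_variable <- function(id, name, data_type, choice_list = NULL,
                         render_hint = "default", format = NULL,
                         annotations = NULL) {
  data_type <- match.arg(data_type, LEGACY_DATA_TYPES)
  render_hint <- match.arg(render_hint, c("default", "checkbox"))
  if (render_hint == "checkbox") {
    if (data_type != "Text")
      stop("checkbox variables must have data_type Text", call. = FALSE)
    choice_list <- list(list(value = "Y", display = "Yes"),
                        list(value = "N", display = "No"))
  }
  structure(list(id = id, name = name, data_type = data_type,
                 choice_list = choice_list, render_hint = render_hint,
                 format = format, annotations = annotations),
            class = "form_variable")
}

new_entry_field <- function(id, label, variable, name = label, multi = FALSE,
                            required = FALSE) {
  stopifnot(nzchar(label))
  structure(list(kind = "entry_field", id = id, label = label, name = name,
                 variable = variable, multi = isTRUE(multi),
                 required = isTRUE(required)),
            class = "form_component")
}

new_table <- function(id, name, columns) {
  stopifnot(all(vapply(columns, function(c) isTRUE(c$multi), TRUE)))
  structure(list(kind = "table", id = id, name = name, columns = columns),
            class = "form_component")
}

new_text_object <- function(id, text) {
  structure(list(kind = "text_object", id = id, text = text),
            class = "form_component")
}

new_page <- function(id, title, children = list()) {
  structure(list(kind = "page", id = id, title = title, children = children),
            class = "form_component")
}

new_form <- function(id, name, source_archetype_id, pages) {
  stopifnot(length(pages) >= 1)
  structure(list(id = id, name = name,
                 source_archetype_id = source_archetype_id, pages = pages),
            class = "ehr_form")
}

#' @export
print.ehr_form <- function(x, ...) {
  comp <- form_components(x)
  kinds <- table(vapply(comp, `[[`, "", "kind"))
  cat("<ehr_form> '", x$name, "' from ", x$source_archetype_id, "\n", sep = "")
  cat(" ", paste(names(kinds), as.integer(kinds), collapse = ", "), "\n")
  invisible(x)
}

# Flat list of all components (pages, text objects, tables, entry fields
# including table columns), pre-order.
form_components <- function(form) {
  out <- list()
  visit <- function(c) {
    out[[length(out) + 1L]] <<- c
    if (c$kind == "page") for (ch in c$children) visit(ch)
    if (c$kind == "table") for (col in c$columns) visit(col)
  }
  for (p in form$pages) visit(p)
  out
}

form_component <- function(form, id) {
  for (c in form_components(form)) if (identical(c$id, id)) return(c)
  NULL
}

# The table (if any) owning an entry field.
field_table <- function(form, field_id) {
  for (c in form_components(form)) {
    if (c$kind == "table") {
      for (col in c$columns) if (identical(col$id, field_id)) return(c)
    }
  }
  NULL
}

# Structural lint: ids unique form-wide, tables never nest, columns multi.
form_lint <- function(form) {
  comp <- form_components(form)
  ids <- vapply(comp, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate component id: ", ids[duplicated(ids)][1], call. = FALSE)
  for (c in comp) {
    if (c$kind == "table") {
      for (col in c$columns) {
        if (col$kind != "entry_field")
          stop("table '", c$id, "' may only contain entry fields",
               call. = FALSE)
        if (!col$multi)
          stop("table column '", col$id, "' must be multi", call. = FALSE)
      }
    }
  }
  invisible(form)
}

# ---- prerequisites --------------------------------------------------------

#' Check a form model against the integration prerequisites
#'
#' Four capabilities are required of a legacy form model before archetypes
#' can be integrated: an entry-form component, labelled entry fields,
#' dynamic duplication of fields during documentation (tables with
#' extendable rows), and coverage of textual/numeric/date/time data types.
#'
#' @param model a declarative description of the target form model:
#'   a list with flags `has_forms`, `has_labelled_fields`,
#'   `has_dynamic_duplication` and a character vector `data_types`. The
#'   default describes the form model shipped in this package, which
#'   satisfies all four prerequisites.
#' @return a data frame with one row per prerequisite: `prerequisite`,
#'   `satisfied`, `detail`.
#' @export
capability_report <- function(model = shipped_form_model()) {
  required_types <- c("Text", "Number", "Date", "Time")
  missing_types <- setdiff(required_types, model$data_types)
  data.frame(
    prerequisite = c("entry forms", "labelled entry fields",
                     "dynamic duplication of entry fields",
                     "textual, numeric, date and time data types"),
    satisfied = c(isTRUE(model$has_forms),
                  isTRUE(model$has_labelled_fields),
                  isTRUE(model$has_dynamic_duplication),
                  length(missing_types) == 0L),
    detail = c("", "", "",
               if (length(missing_types) == 0L) "" else
                 paste("missing:", paste(missing_types, collapse = ", "))),
    stringsAsFactors = FALSE)
}

#' Declarative description of the shipped form model
#' @return a list consumable by [capability_report()].
#' @export
shipped_form_model <- function() {
  list(has_forms = TRUE, has_labelled_fields = TRUE,
       has_dynamic_duplication = TRUE, data_types = LEGACY_DATA_TYPES)
}

# ---- documents ------------------------------------------------------------

#' Create an empty document for a form
#' @param form an `ehr_form`.
#' @param id document identifier.
#' @return an `ehr_document`.
#' @export
new_document <- function(form, id = "doc-1") {
  structure(list(id = id, form_id = form$id, values = list(), rows = list()),
            class = "ehr_document")
}

#' Append an empty row to a table of a document
#' @param d an `ehr_document`.
#' @param form the owning `ehr_form`.
#' @param table_id id of a table component of `form`.
#' @return the document with the new row registered (`row_index` is the
#'   previous maximum plus one, starting at 0).
#' @export
add_table_row <- function(d, form, table_id) {
  tab <- form_component(form, table_id)
  if (is.null(tab) || tab$kind != "table")
    stop("table '", table_id, "' is not part of form '", form$id, "'",
         call. = FALSE)
  n <- d$rows[[table_id]] %||% 0L
  d$rows[[table_id]] <- n + 1L
  d
}

# Normalize + validate one literal against a variable; returns the stored
# text representation.
validate_literal <- function(variable, literal) {
  lit <- as.character(literal)
  if (length(lit) != 1L || is.na(lit))
    stop("a value must be a single non-missing literal", call. = FALSE)
  if (variable$render_hint == "checkbox" && !(lit %in% c("Y", "N")))
    stop("checkbox field accepts only 'Y' or 'N', got '", lit, "'",
         call. = FALSE)
  if (!is.null(variable$choice_list)) {
    allowed <- vapply(variable$choice_list, `[[`, "", "value")
    if (!(lit %in% allowed))
      stop("value '", lit, "' not in choice list {",
           paste(allowed, collapse = ", "), "}", call. = FALSE)
    return(lit)
  }
  switch(variable$data_type,
    Text = lit,
    Number = {
      x <- suppressWarnings(as.numeric(lit))
      if (is.na(x)) stop("'", lit, "' is not a number", call. = FALSE)
      if (!is.null(variable$annotations$range)) {
        r <- variable$annotations$range
        if (x < r$lower || x > r$upper)
          stop("value ", lit, " outside range ", r$lower, "..", r$upper,
               call. = FALSE)
      }
      format(x, scientific = FALSE, trim = TRUE)
    },
    Date = {
      if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", lit))
        stop("'", lit, "' is not an ISO 8601 date (YYYY-MM-DD)", call. = FALSE)
      lit
    },
    Time = {
      if (!grepl("^[0-9]{2}:[0-9]{2}(:[0-9]{2})?$", lit))
        stop("'", lit, "' is not an ISO 8601 time (hh:mm[:ss])", call. = FALSE)
      if (!grepl(":[0-9]{2}:[0-9]{2}", lit)) paste0(lit, ":00") else lit
    },
    Timestamp = {
      if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}(:[0-9]{2})?$",
                 lit))
        stop("'", lit, "' is not an ISO 8601 timestamp", call. = FALSE)
      if (!grepl("T[0-9]{2}:[0-9]{2}:[0-9]{2}$", lit)) paste0(lit, ":00")
      else lit
    })
}

#' Record a value in a document
#'
#' The literal is validated against the field's variable (legacy data type,
#' choice list, checkbox Y/N, ISO 8601 normalization for dates and times)
#' before being stored.
#'
#' @param d an `ehr_document`.
#' @param form the owning `ehr_form`.
#' @param field_id id of an entry field (possibly a table column).
#' @param literal the value to store.
#' @param row_index 0-based row for table columns; must have been created
#'   with [add_table_row()].
#' @return the updated document.
#' @export
set_value <- function(d, form, field_id, literal, row_index = 0L) {
  field <- form_component(form, field_id)
  if (is.null(field) || field$kind != "entry_field")
    stop("no entry field '", field_id, "' in form '", form$id, "'",
         call. = FALSE)
  tab <- field_table(form, field_id)
  if (!is.null(tab)) {
    nrows <- d$rows[[tab$id]] %||% 0L
    if (row_index < 0L || row_index >= nrows)
      stop("row ", row_index, " out of range for table '", tab$id,
           "' (", nrows, " rows)", call. = FALSE)
  } else if (row_index != 0L) {
    stop("field '", field_id, "' is not a table column; row_index must be 0",
         call. = FALSE)
  }
  stored <- validate_literal(field$variable, literal)
  key <- paste0(field_id, "@", row_index)
  d$values[[key]] <- list(field_id = field_id, row_index = as.integer(row_index),
                          literal = stored)
  d
}

#' Re-validate every stored value of a document
#'
#' Checks the same predicate [set_value()] enforces, plus row density:
#' every required column must be present in every row of its table.
#'
#' @param d an `ehr_document`.
#' @param form the owning `ehr_form`.
#' @return a character vector of violations (empty when valid).
#' @export
validate_document <- function(d, form) {
  problems <- character()
  for (v in d$values) {
    field <- form_component(form, v$field_id)
    if (is.null(field)) {
      problems <- c(problems, paste0("value for unknown field ", v$field_id))
      next
    }
    ok <- tryCatch({ validate_literal(field$variable, v$literal); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) problems <- c(problems, paste0(v$field_id, ": ", ok))
  }
  for (tab_id in names(d$rows)) {
    tab <- form_component(form, tab_id)
    if (is.null(tab) || tab$kind != "table") next
    for (r in seq_len(d$rows[[tab_id]]) - 1L) {
      for (col in tab$columns) {
        if (col$required &&
            is.null(d$values[[paste0(col$id, "@", r)]]))
          problems <- c(problems, paste0("row ", r, " of table '", tab_id,
                                         "' misses required column ",
                                         col$id))
      }
    }
  }
  problems
}
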