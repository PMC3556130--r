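# Structured-text serialization of forms, mapping tables and documents
# (JSON with stable key order), so the command-line steps can be piped.

#' Write / read a generated form
#' @param gen a list with `form` and `mapping` as returned by
#'   [generate_form()], or an `ehr_form` (then `mapping` must be given).
#' @param path output file.
#' @param mapping a `mapping_table` when `gen` is a bare form.
#' @return `path`, invisibly.
#' @export
write_form <- function(gen, path, mapping = NULL) {
  if (inherits(gen, "ehr_form")) gen <- list(form = gen, mapping = mapping)
  payload <- list(form = strip_classes(gen$form),
                  mapping = gen$mapping$entries)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_form
#' @export
read_form <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  form <- restore_form(payload$form)
  mapping <- structure(list(entries = lapply(payload$mapping, as.character)),
                       class = "mapping_table")
  list(form = form, mapping = mapping)
}

#' Write / read a document
#' @param d an `ehr_document`.
#' @param path file path.
#' @return `path` (write) or an `ehr_document` (read).
#' @export
write_document <- function(d, path) {
  jsonlite::write_json(unclass(d), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_document
#' @export
read_document <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  payload$values <- lapply(payload$values, function(v) {
    v$row_index <- as.integer(v$row_index)
    v
  })
  payload$rows <- lapply(payload$rows, as.integer)
  structure(payload, class = "ehr_document")
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

restore_form <- function(p) {
  restore_comp <- function(c) {
    switch(c$kind,
      page = new_page(c$id, c$title, lapply(c$children, restore_comp)),
      text_object = new_text_object(c$id, c$text),
      table = new_table(c$id, c$name, lapply(c$columns, restore_comp)),
      entry_field = new_entry_field(c$id, c$label, restore_variable(c$variable),
                                    name = c$name, multi = isTRUE(c$multi),
                                    required = isTRUE(c$required)),
      stop("unknown component kind: ", c$kind, call. = FALSE))
  }
  new_form(p$id, p$name, p$source_archetype_id,
           lapply(p$pages, restore_comp))
}

restore_variable <- function(v) {
  out <- new_variable(v$id, v$name, v$data_type,
                      choice_list = v$choice_list,
                      render_hint = v$render_hint %||% "default",
                      format = v$format,
                      annotations = v$annotations)
  out
}
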