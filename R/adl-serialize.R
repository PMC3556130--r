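# Canonical ADL 1.4 serialization of the archetype model.
#
# The writer emits exactly the grammar subset the parser accepts, so
# parse -> serialize -> parse is a fixed point. It is used by the synthetic
# archetype generator and as a debugging dump of parsed archetypes.

quote_adl <- function(s) paste0('"', gsub('(["\\\\])', "\\\\\\1", s), '"')

serialize_interval <- function(iv) {
  up <- if (is.infinite(iv$upper)) "*" else iv$upper
  paste0(iv$lower, "..", up)
}

serialize_primitive <- function(p) {
  body <- if (!is.null(p$pattern)) {
    if (p$kind == "String") paste0("/", p$pattern, "/") else p$pattern
  } else if (isTRUE(p$local_coded)) {
    paste0("[local::", paste(p$allowed_values, collapse = ", "), "]")
  } else if (!is.null(p$allowed_values)) {
    if (p$kind == "String") {
      paste(vapply(p$allowed_values, quote_adl, ""), collapse = ", ")
    } else if (p$kind == "Boolean") {
      paste(ifelse(p$allowed_values, "True", "False"), collapse = ", ")
    } else {
      paste(format_adl_number(p$allowed_values, p$kind), collapse = ", ")
    }
  } else if (!is.null(p$range)) {
    paste0("|", format_adl_number(p$range$lower, p$kind), "..",
           format_adl_number(p$range$upper, p$kind), "|")
  } else {
    stop("primitive constraint with no serializable constraint", call. = FALSE)
  }
  if (!is.null(p$assumed_value)) {
    av <- p$assumed_value
    av <- if (is.character(av)) quote_adl(av)
          else if (is.logical(av)) (if (av) "True" else "False")
          else format_adl_number(av, p$kind)
    body <- paste0(body, "; ", av)
  }
  body
}

# Integers print bare; reals always carry a decimal point so the parser
# re-infers the same kind.
format_adl_number <- function(x, kind) {
  if (kind == "Integer") return(format(as.integer(x), scientific = FALSE))
  vapply(x, function(v) {
    s <- format(v, scientific = FALSE, trim = TRUE)
    if (!grepl("\\.", s)) s <- paste0(s, ".0")
    s
  }, "")
}

serialize_node <- function(node, indent, terms) {
  pad <- strrep("    ", indent)
  if (inherits(node, "adl_primitive")) {
    stop("primitive constraints are serialized inline", call. = FALSE)
  }
  occ <- ""
  if (node$occurrences$lower != 1L || node$occurrences$upper != 1L)
    occ <- paste0(" occurrences matches {",
                  serialize_interval(node$occurrences), "}")
  if (inherits(node, "adl_slot")) {
    idpart <- if (nzchar(node$node_id)) paste0("[", node$node_id, "]") else ""
    body <- if (length(node$allowed_ids) == 1L && node$allowed_ids == ".*") {
      "*"
    } else {
      paste0("include archetype_id/value matches {/",
             paste(node$allowed_ids, collapse = "|"), "/}")
    }
    return(paste0(pad, "allow_archetype ", node$rm_class, idpart, occ,
                  " matches {", body, "}"))
  }
  if (inherits(node, "adl_ref")) {
    return(paste0(pad, "use_node ", node$rm_class, occ, " ", node$target_path))
  }
  idpart <- if (nzchar(node$node_id)) paste0("[", node$node_id, "]") else ""
  comment <- if (nzchar(node$node_id) && !is.null(terms[[node$node_id]]))
    paste0("    -- ", terms[[node$node_id]]$text) else ""
  lines <- paste0(pad, node$rm_class, idpart, occ, " matches {", comment)
  for (attr in node$attributes) {
    lines <- c(lines, serialize_attribute(attr, indent + 1L, terms))
  }
  c(lines, paste0(pad, "}"))
}

serialize_attribute <- function(attr, indent, terms) {
  pad <- strrep("    ", indent)
  head <- attr$name
  if (!is.null(attr$existence))
    head <- paste0(head, " existence matches {",
                   serialize_interval(attr$existence), "}")
  if (!is.null(attr$cardinality))
    head <- paste0(head, " cardinality matches {",
                   serialize_interval(attr$cardinality), "; unordered}")
  only <- attr$children[[1]]
  if (length(attr$children) == 1L && inherits(only, "adl_primitive")) {
    return(paste0(pad, head, " matches {", serialize_primitive(only), "}"))
  }
  lines <- paste0(pad, head, " matches {")
  for (ch in attr$children) {
    lines <- c(lines, serialize_node(ch, indent + 1L, terms))
  }
  c(lines, paste0(pad, "}"))
}

#' Serialize an archetype back to canonical ADL 1.4 text
#'
#' @param a an `archetype`.
#' @return a single string of ADL source that reparses to a structurally
#'   equal archetype.
#' @export
serialize_adl <- function(a) {
  stopifnot(inherits(a, "archetype"))
  terms <- a$ontology$terms
  lines <- c(
    "archetype (adl_version=1.4)",
    paste0("    ", a$archetype_id),
    "",
    "concept",
    paste0("    [", a$concept_code, "]"),
    "",
    "definition")
  lines <- c(lines, serialize_node(a$definition, 1L, terms), "", "ontology")
  lines <- c(lines, "    term_definitions = <")
  lines <- c(lines, '        ["en"] = <')
  lines <- c(lines, "            items = <")
  for (code in names(terms)) {
    entry <- terms[[code]]
    lines <- c(lines,
               paste0('                ["', code, '"] = <'),
               paste0("                    text = <",
                      quote_adl(entry$text), ">"),
               paste0("                    description = <",
                      quote_adl(entry$description %||% ""), ">"),
               "                >")
  }
  lines <- c(lines, "            >", "        >", "    >")
  if (length(a$ontology$bindings) > 0L) {
    lines <- c(lines, "    term_bindings = <")
    for (terminology in names(a$ontology$bindings)) {
      lines <- c(lines, paste0('        ["', terminology, '"] = <'),
                 "            items = <")
      codes <- a$ontology$bindings[[terminology]]
      for (code in names(codes)) {
        lines <- c(lines,
                   paste0('                ["', code, '"] = <[',
                          codes[[code]], "]>"))
      }
      lines <- c(lines, "            >", "        >")
    }
    lines <- c(lines, "    >")
  }
  paste(c(lines, ""), collapse = "\n")
}

#' Write an archetype to an .adl file
#' @param a an `archetype`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_adl <- function(a, path) {
  writeLines(serialize_adl(a), path, useBytes = TRUE)
  invisible(path)
}
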