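# In-memory constraint model for parsed archetypes.
#
# The definition section of an archetype is a tree of constraint nodes. Four
# node flavours exist: complex nodes (constraining an RM class or data type),
# primitive leaves (constraining one of the eight AM primitive types), slots
# (inclusion points for other archetypes) and internal references (use_node).
# Children are reachable only through attribute constraints.

AM_PRIMITIVE_KINDS <- c("Boolean", "String", "Integer", "Real",
                        "Date", "Time", "Date_Time", "Duration")

#' Interval for occurrences / cardinality / existence
#'
#' @param lower non-negative integer lower bound.
#' @param upper integer upper bound or `Inf` for unbounded.
#' @return a list with class `adl_interval`.
#' @keywords internal
adl_interval <- function(lower = 1L, upper = 1L) {
  stopifnot(lower >= 0, is.infinite(upper) || upper >= lower)
  structure(list(lower = as.integer(lower),
                 upper = if (is.infinite(upper)) Inf else as.integer(upper)),
            class = "adl_interval")
}

format.adl_interval <- function(x, ...) {
  up <- if (is.infinite(x$upper)) "*" else x$upper
  paste0(x$lower, "..", up)
}

#' Primitive constraint leaf
#'
#' One of the eight AM primitive types, optionally constrained by a value
#' list, a numeric/temporal range, or a pattern. Regular expressions,
#' duration patterns and assertion-like constraints are parsed but carried
#' with `enforceable = FALSE`: the form layer cannot enforce them and only
#' surfaces them as warnings.
#'
#' @keywords internal
new_primitive <- function(kind, allowed_values = NULL, range = NULL,
                          pattern = NULL, enforceable = TRUE,
                          assumed_value = NULL, local_coded = FALSE) {
  kind <- match.arg(kind, AM_PRIMITIVE_KINDS)
  if (!is.null(allowed_values) && !is.null(range))
    stop("a primitive constraint may carry a value list or a range, not both",
         call. = FALSE)
  structure(list(node = "primitive", kind = kind,
                 allowed_values = allowed_values, range = range,
                 pattern = pattern, enforceable = isTRUE(enforceable),
                 assumed_value = assumed_value,
                 local_coded = isTRUE(local_coded)),
            class = "adl_primitive")
}

#' Complex node constraining an RM class
#' @keywords internal
new_complex_node <- function(rm_class, node_id = "", occurrences = adl_interval(),
                             attributes = list(), provenance = "explicit",
                             rm_attribute = NULL) {
  stopifnot(nzchar(rm_class))
  structure(list(node = "complex", rm_class = rm_class, node_id = node_id,
                 occurrences = occurrences, attributes = attributes,
                 provenance = provenance, rm_attribute = rm_attribute),
            class = "adl_node")
}

#' Attribute constraint: the only edge type between complex nodes
#' @keywords internal
new_attribute <- function(name, children, existence = NULL, cardinality = NULL) {
  stopifnot(nzchar(name), length(children) >= 1)
  list(name = name, children = children,
       existence = existence, cardinality = cardinality)
}

#' Archetype slot (inclusion point for other archetypes)
#' @keywords internal
new_slot <- function(rm_class, node_id = "", allowed_ids = ".*",
                     occurrences = adl_interval()) {
  stopifnot(length(allowed_ids) >= 1)
  structure(list(node = "slot", rm_class = rm_class, node_id = node_id,
                 allowed_ids = allowed_ids, occurrences = occurrences),
            class = "adl_slot")
}

#' Internal reference (use_node)
#' @keywords internal
new_internal_ref <- function(rm_class, target_path, occurrences = adl_interval()) {
  stopifnot(nzchar(target_path))
  structure(list(node = "ref", rm_class = rm_class, target_path = target_path,
                 occurrences = occurrences),
            class = "adl_ref")
}

new_ontology <- function(terms = list(), bindings = list()) {
  structure(list(terms = terms, bindings = bindings), class = "adl_ontology")
}

new_archetype <- function(archetype_id, concept_code, definition, ontology,
                          adl_version = "1.4") {
  structure(list(archetype_id = archetype_id, concept_code = concept_code,
                 adl_version = adl_version, definition = definition,
                 ontology = ontology),
            class = "archetype")
}

# A node is repeating when its upper occurrence limit exceeds 1 (including
# the unbounded case); such nodes map to tables with extendable rows.
is_repeating <- function(node) {
  (inherits(node, "adl_node") || inherits(node, "adl_slot")) &&
    node$occurrences$upper > 1
}

#' @export
print.archetype <- function(x, ...) {
  cat("<archetype> ", x$archetype_id, "\n", sep = "")
  cat("  concept: ", x$concept_code, "  (", local_term(x, x$concept_code)$text,
      ")\n", sep = "")
  cat("  nodes: ", length(archetype_nodes(x)), ", local terms: ",
      length(x$ontology$terms), "\n", sep = "")
  invisible(x)
}

# ---- tree walking ---------------------------------------------------------

#' Walk the definition tree depth-first, pre-order
#'
#' Calls `fn(node, chain)` for every node (complex, primitive, slot, ref).
#' `chain` is the list of steps leading to the node: element 1 is the root
#' node; every later step is `list(attr = <name>, node = <child>)`.
#'
#' @keywords internal
walk_definition <- function(node, fn, chain = NULL) {
  if (is.null(chain)) chain <- list(node)
  fn(node, chain)
  if (inherits(node, "adl_node")) {
    for (attr in node$attributes) {
      for (child in attr$children) {
        walk_definition(child, fn,
                        c(chain, list(list(attr = attr$name, node = child))))
      }
    }
  }
  invisible(NULL)
}

#' All nodes of an archetype definition as a flat list
#' @keywords internal
archetype_nodes <- function(a) {
  def <- if (inherits(a, "archetype")) a$definition else a
  out <- list()
  walk_definition(def, function(node, chain) out[[length(out) + 1L]] <<- node)
  out
}

#' Structural equality of two definition subtrees
#'
#' Field-by-field recursive comparison, ignoring provenance marks so that an
#' augmented-then-reaugmented tree compares equal to its first augmentation.
#'
#' @keywords internal
trees_equal <- function(a, b, ignore_provenance = TRUE) {
  if (!identical(class(a), class(b))) return(FALSE)
  drop <- if (ignore_provenance) c("provenance", "rm_attribute") else character()
  if (inherits(a, "adl_primitive")) {
    return(identical(a[setdiff(names(a), drop)],
                     b[setdiff(names(b), drop)]))
  }
  if (inherits(a, "adl_slot") || inherits(a, "adl_ref")) {
    return(identical(unclass(a), unclass(b)))
  }
  if (inherits(a, "adl_node")) {
    fa <- a[setdiff(names(a), c(drop, "attributes"))]
    fb <- b[setdiff(names(b), c(drop, "attributes"))]
    if (!identical(fa, fb)) return(FALSE)
    if (length(a$attributes) != length(b$attributes)) return(FALSE)
    for (i in seq_along(a$attributes)) {
      aa <- a$attributes[[i]]; ab <- b$attributes[[i]]
      if (!identical(aa$name, ab$name)) return(FALSE)
      if (!identical(aa$existence, ab$existence)) return(FALSE)
      if (!identical(aa$cardinality, ab$cardinality)) return(FALSE)
      if (length(aa$children) != length(ab$children)) return(FALSE)
      for (j in seq_along(aa$children)) {
        if (!trees_equal(aa$children[[j]], ab$children[[j]], ignore_provenance))
          return(FALSE)
      }
    }
    return(TRUE)
  }
  identical(a, b)
}

#' Structural equality of two archetypes
#' @param a,b archetype objects.
#' @return `TRUE` if identifier, concept, definition tree and ontology agree.
#' @export
archetypes_equal <- function(a, b) {
  identical(a$archetype_id, b$archetype_id) &&
    identical(a$concept_code, b$concept_code) &&
    trees_equal(a$definition, b$definition) &&
    identical(a$ontology$terms, b$ontology$terms) &&
    identical(a$ontology$bindings, b$ontology$bindings)
}

# ---- ontology lookup ------------------------------------------------------

#' Look up the local term of an archetype node code
#'
#' Local terms are the display texts defined in the archetype's ontology
#' section; they are the source of labels in generated forms.
#'
#' @param a an `archetype`.
#' @param code a local code such as `"at0000"`.
#' @return a list with elements `text` and `description`.
#' @export
local_term <- function(a, code) {
  stopifnot(inherits(a, "archetype"))
  entry <- a$ontology$terms[[code]]
  if (is.null(entry))
    stop("unknown local code '", code, "' in archetype ", a$archetype_id,
         call. = FALSE)
  entry
}

# ---- internal reference resolution ---------------------------------------

# Parse an archetype-internal path such as "/data[at0001]/items[at0002]"
# into steps of (attribute, optional node code).
parse_internal_path <- function(path) {
  if (!grepl("^/", path)) stop("internal path must start with '/': ", path,
                               call. = FALSE)
  segs <- regmatches(path,
                     gregexpr("/([A-Za-z_][A-Za-z0-9_]*)(\\[(at[0-9.]+)\\])?",
                              path))[[1]]
  if (sum(nchar(segs)) != nchar(path))
    stop("malformed internal path: ", path, call. = FALSE)
  lapply(segs, function(s) {
    attr_name <- sub("^/([A-Za-z_][A-Za-z0-9_]*).*$", "\\1", s)
    code <- if (grepl("\\[", s)) sub("^.*\\[(at[0-9.]+)\\]$", "\\1", s) else ""
    list(attr = attr_name, code = code)
  })
}

# Follow an internal path from the definition root; NULL if unresolvable or
# ambiguous (must select exactly one complex node).
resolve_path_node <- function(def, path) {
  steps <- parse_internal_path(path)
  node <- def
  for (step in steps) {
    if (!inherits(node, "adl_node")) return(NULL)
    attr <- NULL
    for (cand in node$attributes) if (cand$name == step$attr) attr <- cand
    if (is.null(attr)) return(NULL)
    hits <- Filter(function(ch) {
      inherits(ch, "adl_node") &&
        (step$code == "" || identical(ch$node_id, step$code))
    }, attr$children)
    if (step$code == "" && length(hits) > 1) return(NULL)
    if (length(hits) != 1) return(NULL)
    node <- hits[[1]]
  }
  node
}

#' Expand internal references (use_node) in place
#'
#' Every internal reference is replaced by a deep copy of its target subtree,
#' carrying the reference's own occurrences. The operation is idempotent: an
#' archetype without references is returned unchanged.
#'
#' @param a an `archetype`.
#' @return an `archetype` whose definition contains no internal references.
#' @export
resolve_internal_refs <- function(a) {
  stopifnot(inherits(a, "archetype"))
  expand <- function(node, active) {
    if (inherits(node, "adl_ref")) {
      if (node$target_path %in% active)
        stop("internal reference cycle via path ", node$target_path,
             call. = FALSE)
      target <- resolve_path_node(a$definition, node$target_path)
      if (is.null(target))
        stop("dangling internal reference: ", node$target_path, call. = FALSE)
      copy <- target
      copy$occurrences <- node$occurrences
      return(expand(copy, c(active, node$target_path)))
    }
    if (inherits(node, "adl_node")) {
      node$attributes <- lapply(node$attributes, function(attr) {
        attr$children <- lapply(attr$children, expand, active = active)
        attr
      })
    }
    node
  }
  a$definition <- expand(a$definition, character())
  a
}
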