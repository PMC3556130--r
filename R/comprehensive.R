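# Comprehensive archetypes.
#
# Archetypes only state the constraints they tighten with respect to the RM.
# Mandatory RM attributes left unconstrained are implicit constraints that
# still have to appear in a generated form (e.g. origin of HISTORY, time of
# EVENT). Augmentation makes them explicit: each gains an attribute edge
# whose child is an anonymous node typed by the RM attribute, recursively
# expanded down to primitive leaves. All downstream stages work on the
# comprehensive archetype exclusively.

#' Augment an archetype with implicit RM constraints
#'
#' For every complex node, every mandatory effective attribute of its RM
#' class that the archetype does not constrain is added as an implicit
#' attribute edge. Implicit subtrees are typed by the RM and recursively
#' augmented until they terminate in primitive leaves. Never added:
#' deprecated attributes, optional attributes, `auto_fill` context
#' attributes (unless requested), and attributes of an abstract RM type
#' (there is no concrete structure to synthesize; the archetype must
#' constrain those itself).
#'
#' The operation is idempotent and never removes or reorders explicit nodes.
#'
#' @param a an `archetype` (internal references should be resolved first,
#'   see [resolve_internal_refs()]).
#' @param s an `rm_schema`.
#' @param include_auto_fill also add mandatory context attributes flagged
#'   `auto_fill` in the schema (off by default so forms are not flooded
#'   with non-clinical fields).
#' @return a `comprehensive_archetype`: the input archetype with provenance
#'   marks (`explicit`/`implicit`) on every node and implicit subtrees
#'   added.
#' @examples
#' ca <- augment(parse_adl(paper_fixtures()$bmi_excerpt), rm_schema())
#' @export
augment <- function(a, s, include_auto_fill = FALSE) {
  stopifnot(inherits(a, "archetype"), inherits(s, "rm_schema"))
  aug_node <- function(node) {
    if (inherits(node, "adl_primitive")) {
      if (is.null(node$provenance)) node$provenance <- "explicit"
      return(node)
    }
    if (inherits(node, "adl_slot") || inherits(node, "adl_ref")) return(node)
    check_rm_class(s, node$rm_class)
    if (is.null(node$provenance)) node$provenance <- "explicit"
    node$attributes <- lapply(node$attributes, function(attr) {
      attr$children <- lapply(attr$children, aug_node)
      attr
    })
    constrained <- vapply(node$attributes, `[[`, "", "name")
    for (a_rm in mandatory_unconstrained(s, node$rm_class, constrained)) {
      if (a_rm$deprecated) next
      if (a_rm$auto_fill && !include_auto_fill) next
      child <- implicit_child(s, a_rm)
      if (is.null(child)) next               # abstract type: not synthesizable
      node$attributes[[length(node$attributes) + 1L]] <-
        new_attribute(a_rm$name, list(child))
    }
    node
  }
  a$definition <- aug_node(a$definition)
  class(a) <- unique(c("comprehensive_archetype", class(a)))
  a
}

# Build the implicit subtree for one mandatory unconstrained RM attribute.
implicit_child <- function(s, a_rm) {
  if (rm_is_primitive(a_rm$type_name)) {
    p <- new_primitive(a_rm$type_name)
    p$provenance <- "implicit"
    p$rm_attribute <- a_rm$name
    return(p)
  }
  if (rm_is_abstract(s, a_rm$type_name)) return(NULL)
  node <- new_complex_node(a_rm$type_name, node_id = "",
                           occurrences = adl_interval(1L, 1L),
                           attributes = list(),
                           provenance = "implicit",
                           rm_attribute = a_rm$name)
  for (sub in mandatory_unconstrained(s, a_rm$type_name)) {
    if (sub$deprecated || sub$auto_fill) next
    child <- implicit_child(s, sub)
    if (is.null(child)) next
    node$attributes[[length(node$attributes) + 1L]] <-
      new_attribute(sub$name, list(child))
  }
  if (length(node$attributes) == 0L) return(NULL)
  node
}

#' Is a node implicit (added by augmentation)?
#' @keywords internal
is_implicit <- function(node) identical(node$provenance, "implicit")
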