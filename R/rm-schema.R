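# Declarative Reference Model subset.
#
# The dual-model architecture keeps the RM fixed ("hardcoded") while
# archetypes constrain it. Augmentation and extract typing only need a small
# slice of RM knowledge: the class hierarchy, attribute names and types,
# mandatory flags and multiplicities. That slice is shipped as an editable
# YAML file rather than compiled in, so a different RM release (or an
# ISO 13606-style RM) can be substituted without touching code.

#' Load a Reference Model schema
#'
#' @param path path to an RM schema YAML file; the default is the subset of
#'   the openEHR RM shipped with the package (entry classes, history/event,
#'   item structures, and the data value types down to the eight primitive
#'   kinds).
#' @return an object of class `rm_schema`.
#' @examples
#' s <- rm_schema()
#' effective_attributes(s, "HISTORY")
#' @export
rm_schema <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rm_schema.yaml", package = "archeform",
                        mustWork = TRUE)
  spec <- yaml::read_yaml(path)
  classes <- lapply(spec$classes, function(cls) {
    attrs <- lapply(cls$attributes %||% list(), function(a) {
      list(name = a$name,
           type_name = a$type,
           mandatory = isTRUE(a$mandatory),
           multiple = isTRUE(a$multiple),
           deprecated = isTRUE(a$deprecated),
           auto_fill = isTRUE(a$auto_fill),
           default = a$default %||% NULL)
    })
    names(attrs) <- vapply(attrs, `[[`, "", "name")
    list(parent = cls$parent %||% NULL,
         is_abstract = isTRUE(cls$abstract),
         attributes = attrs)
  })
  s <- structure(list(classes = classes,
                      version_tag = spec$version %||% "unversioned"),
                 class = "rm_schema")
  rm_schema_lint(s)
  s
}

#' @export
print.rm_schema <- function(x, ...) {
  cat("<rm_schema> ", x$version_tag, ": ", length(x$classes), " classes\n",
      sep = "")
  invisible(x)
}

rm_class_exists <- function(s, class_name) class_name %in% names(s$classes)

rm_is_abstract <- function(s, class_name)
  rm_class_exists(s, class_name) && isTRUE(s$classes[[class_name]]$is_abstract)

rm_is_primitive <- function(type_name) type_name %in% AM_PRIMITIVE_KINDS

check_rm_class <- function(s, class_name) {
  if (!rm_class_exists(s, class_name))
    stop("unknown RM class '", class_name, "' (schema ", s$version_tag, ")",
         call. = FALSE)
  invisible()
}

#' Effective attributes of an RM class
#'
#' Own attributes plus inherited ones; an attribute redefined in a child
#' class overrides the parent's definition. Parents' attributes come first,
#' in schema order.
#'
#' @param s an `rm_schema`.
#' @param class_name RM class name.
#' @return a list of attribute records (`name`, `type_name`, `mandatory`,
#'   `multiple`, `deprecated`, `auto_fill`, `default`).
#' @export
effective_attributes <- function(s, class_name) {
  check_rm_class(s, class_name)
  lineage <- character()
  cls <- class_name
  while (!is.null(cls)) {
    if (cls %in% lineage)
      stop("RM inheritance cycle at class '", cls, "'", call. = FALSE)
    lineage <- c(cls, lineage)
    cls <- s$classes[[cls]]$parent
    if (!is.null(cls)) check_rm_class(s, cls)
  }
  out <- list()
  for (cls in lineage) {
    for (a in s$classes[[cls]]$attributes) out[[a$name]] <- a
  }
  unname(out)
}

#' Mandatory attributes not constrained by the archetype
#'
#' The implicit constraints of the dual-model architecture: mandatory RM
#' attributes absent from an archetype node's explicit constraints still
#' have to appear in the generated form (for example `origin` of HISTORY).
#'
#' @param s an `rm_schema`.
#' @param class_name RM class name.
#' @param constrained character vector of attribute names the archetype
#'   already constrains at this node.
#' @return the mandatory effective attributes not in `constrained`, in
#'   schema order.
#' @export
mandatory_unconstrained <- function(s, class_name, constrained = character()) {
  eff <- effective_attributes(s, class_name)
  Filter(function(a) a$mandatory && !(a$name %in% constrained), eff)
}

#' Is an RM attribute deprecated?
#'
#' Table-driven: the shipped schema marks `property` of DV_QUANTITY, which
#' is no longer supported in the current RM release and is skipped during
#' form generation.
#'
#' @param s an `rm_schema`.
#' @param class_name RM class name.
#' @param attr attribute name.
#' @return `TRUE` if the attribute is flagged deprecated in the schema.
#' @export
is_deprecated_attribute <- function(s, class_name, attr) {
  if (!rm_class_exists(s, class_name)) return(FALSE)
  eff <- effective_attributes(s, class_name)
  for (a in eff) if (a$name == attr) return(isTRUE(a$deprecated))
  FALSE
}

# Schema sanity: referenced types exist, no attribute is both mandatory and
# deprecated, abstract classes have a concrete descendant.
rm_schema_lint <- function(s) {
  for (cls in names(s$classes)) {
    for (a in s$classes[[cls]]$attributes) {
      if (!rm_is_primitive(a$type_name) && !rm_class_exists(s, a$type_name))
        stop("schema lint: attribute ", cls, ".", a$name,
             " references unknown type '", a$type_name, "'", call. = FALSE)
      if (a$mandatory && a$deprecated)
        stop("schema lint: attribute ", cls, ".", a$name,
             " is both mandatory and deprecated", call. = FALSE)
    }
  }
  concrete <- names(Filter(function(c) !isTRUE(c$is_abstract), s$classes))
  ancestors_of <- function(cls) {
    out <- character()
    while (!is.null(cls)) { out <- c(out, cls); cls <- s$classes[[cls]]$parent }
    out
  }
  reachable <- unique(unlist(lapply(concrete, ancestors_of)))
  for (cls in names(s$classes)) {
    if (isTRUE(s$classes[[cls]]$is_abstract) && !(cls %in% reachable))
      stop("schema lint: abstract class '", cls,
           "' has no concrete descendant", call. = FALSE)
  }
  invisible(s)
}
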