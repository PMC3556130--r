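# Three-layer mapping of a comprehensive archetype to a legacy form:
# structural constraints (tree -> form/page/text-object/table/field),
# data value constraints (eight AM primitive types -> five legacy types),
# and terminology (local terms as labels and choice lists; term bindings
# carried as metadata only).
#
# Traversal is depth-first pre-order; generation is a pure function of
# (archetype, RM schema, configuration), so serialized output is
# byte-identical across runs.

#' Configuration for form generation
#'
#' @param slot_choices named list mapping a slot position (its
#'   archetype-internal path, e.g. `"/items[at0005]"`) to the archetype id
#'   chosen for it. Required for every wildcard slot: a wildcard allows any
#'   archetype and must be narrowed to exactly one before a form can exist.
#' @param label_separator separator between concatenated label segments.
#' @param include_optional_rm_attributes also add unconstrained optional RM
#'   attributes during augmentation (off by default; optional attributes
#'   were presumed not needed for data collection).
#' @return a `generation_config` list.
#' @export
generation_config <- function(slot_choices = list(), label_separator = ".",
                              include_optional_rm_attributes = FALSE) {
  structure(list(slot_choices = slot_choices,
                 label_separator = label_separator,
                 include_optional_rm_attributes =
                   isTRUE(include_optional_rm_attributes)),
            class = "generation_config")
}

#' Map an AM primitive type to a legacy form data type
#'
#' Total mapping of the eight archetype primitive types onto the five
#' legacy types. Boolean and Duration collapse onto Text (Booleans are
#' stored as "Y"/"N" and rendered as checkboxes); Integer and Real collapse
#' onto Number; Date_Time becomes Timestamp.
#'
#' @param kind one of `Boolean`, `String`, `Integer`, `Real`, `Date`,
#'   `Time`, `Date_Time`, `Duration`.
#' @return one of `Text`, `Number`, `Date`, `Time`, `Timestamp`.
#' @export
map_primitive <- function(kind) {
  if (!kind %in% AM_PRIMITIVE_KINDS)
    stop("unknown AM primitive type '", kind, "'", call. = FALSE)
  switch(kind,
         Boolean = "Text", String = "Text", Integer = "Number",
         Real = "Number", Date = "Date", Time = "Time",
         Date_Time = "Timestamp", Duration = "Text")
}

# Label segment normalization: multi-word local terms drop their internal
# whitespace with each word's initial capitalized ("Body mass index" ->
# "BodyMassIndex"); single-word segments (including attribute names such as
# "value") are kept verbatim.
normalize_label_segment <- function(s) {
  words <- strsplit(trimws(s), "\\s+")[[1]]
  if (length(words) <= 1L) return(trimws(s))
  paste(vapply(words, function(w) {
    paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
  }, ""), collapse = "")
}

#' Build a concatenated component label
#'
#' Ancestor names down to the leaf are joined by the separator after
#' whitespace normalization of multi-word terms.
#'
#' @param ancestors ordered character vector of ancestor names (non-empty).
#' @param leaf the leaf name.
#' @param separator separator string.
#' @return the label string, e.g. `"Single.BodyMassIndex.value.units"`.
#' @export
build_label <- function(ancestors, leaf, separator = ".") {
  if (length(ancestors) == 0L)
    stop("ancestors must be a non-empty list of names", call. = FALSE)
  paste(vapply(c(ancestors, leaf), normalize_label_segment, ""),
        collapse = separator)
}

#' Archetype path of a node chain in the stored XPath dialect
#'
#' The root contributes a bare predicate carrying the archetype id; every
#' later step contributes `/<attribute>` plus a predicate: identified nodes
#' carry `@archetype_node_id` and `@xsi:type`, anonymous nodes only
#' `@xsi:type`, primitive leaves the upper-cased primitive kind.
#'
#' @param chain a list: first element the root node; each later element a
#'   list with `attr` (attribute name) and `node`.
#' @return the path string (ASCII quotes).
#' @export
archetype_path <- function(chain) {
  stopifnot(length(chain) >= 1)
  root <- chain[[1]]
  root_id <- root$path_id %||% root$node_id
  out <- paste0("[@archetype_node_id = '", root_id,
                "' and @xsi:type = '", root$rm_class, "']")
  for (step in chain[-1]) {
    node <- step$node
    pred <- if (inherits(node, "adl_primitive")) {
      paste0("[@xsi:type = '", toupper(node$kind), "']")
    } else {
      nid <- node$path_id %||% node$node_id
      if (nzchar(nid))
        paste0("[@archetype_node_id = '", nid,
               "' and @xsi:type = '", node$rm_class, "']")
      else
        paste0("[@xsi:type = '", node$rm_class, "']")
    }
    out <- paste0(out, "/", step$attr, pred)
  }
  out
}

# Archetype-internal path (short dialect) of a chain, used for violation
# reports and slot_choices keys.
internal_path <- function(chain) {
  if (length(chain) <= 1L) return("/")
  paste(vapply(chain[-1], function(step) {
    nid <- step$node$node_id %||% ""
    paste0("/", step$attr, if (nzchar(nid)) paste0("[", nid, "]") else "")
  }, ""), collapse = "")
}

# ---- slot expansion -------------------------------------------------------

#' Turn a set of archetypes into a slot resolver
#'
#' @param x a named list of `archetype` objects or ADL texts (names are
#'   ignored; ids come from the archetypes), a character vector of .adl file
#'   paths, or a directory containing .adl files.
#' @return a function mapping an archetype id to an `archetype` (or `NULL`).
#' @export
archetype_resolver <- function(x) {
  if (is.character(x) && length(x) == 1L && dir.exists(x))
    x <- list.files(x, pattern = "\\.adl$", full.names = TRUE)
  if (is.character(x)) {
    x <- lapply(x, function(p) if (file.exists(p)) read_adl(p) else parse_adl(p))
  }
  x <- lapply(x, function(a) if (inherits(a, "archetype")) a else parse_adl(a))
  ids <- vapply(x, `[[`, "", "archetype_id")
  function(archetype_id) {
    hit <- which(ids == archetype_id)
    if (length(hit) == 0L) return(NULL)
    x[[hit[1]]]
  }
}

# Attach resolved term texts to named nodes and display texts to local
# code lists, so expanded subtrees stay self-describing without their
# source ontology.
annotate_terms <- function(node, ontology) {
  if (inherits(node, "adl_primitive")) {
    if (isTRUE(node$local_coded) && is.null(node$choice_display)) {
      node$choice_display <- vapply(node$allowed_values, function(code) {
        t <- ontology$terms[[code]]
        if (is.null(t)) code else t$text
      }, "")
    }
    return(node)
  }
  if (inherits(node, "adl_node") || inherits(node, "adl_slot")) {
    if (is.null(node$term) && nzchar(node$node_id %||% "")) {
      t <- ontology$terms[[node$node_id]]
      if (!is.null(t)) node$term <- t
    }
  }
  if (inherits(node, "adl_node")) {
    node$attributes <- lapply(node$attributes, function(attr) {
      attr$children <- lapply(attr$children, annotate_terms, ontology = ontology)
      attr
    })
  }
  node
}

#' Expand one slot with a chosen archetype
#'
#' The chosen archetype is reference-resolved, augmented and spliced in at
#' the slot position with the slot's occurrences; its root carries the
#' included archetype's id in path predicates.
#'
#' @param slot an `adl_slot`.
#' @param chosen the included `archetype`.
#' @param s an `rm_schema`.
#' @return the expanded subtree (an `adl_node`).
#' @export
expand_slot <- function(slot, chosen, s) {
  stopifnot(inherits(slot, "adl_slot"), inherits(chosen, "archetype"))
  root_class <- chosen$definition$rm_class
  if (!class_compatible(s, root_class, slot$rm_class))
    stop("archetype ", chosen$archetype_id, " of class ", root_class,
         " is not compatible with a slot of class ", slot$rm_class,
         call. = FALSE)
  ok <- any(vapply(slot$allowed_ids, function(p) {
    grepl(paste0("^(", p, ")$"), chosen$archetype_id)
  }, TRUE))
  if (!ok)
    stop("archetype id ", chosen$archetype_id,
         " is not allowed by the slot's id patterns", call. = FALSE)
  chosen <- resolve_internal_refs(chosen)
  ca <- augment(chosen, s)
  sub <- annotate_terms(ca$definition, ca$ontology)
  sub$occurrences <- slot$occurrences
  sub$path_id <- chosen$archetype_id
  sub$included_from <- chosen$archetype_id
  sub
}

class_compatible <- function(s, cls, wanted) {
  while (!is.null(cls)) {
    if (identical(cls, wanted)) return(TRUE)
    if (!rm_class_exists(s, cls)) return(FALSE)
    cls <- s$classes[[cls]]$parent
  }
  FALSE
}

# Replace every slot in the tree by its chosen archetype's subtree.
# `active` carries the archetype ids on the inclusion stack for cycle
# detection.
expand_all_slots <- function(node, chain, s, cfg, resolver, active) {
  if (inherits(node, "adl_slot")) {
    path <- internal_path(chain)
    wildcard <- length(node$allowed_ids) == 1L && node$allowed_ids == ".*"
    choice <- cfg$slot_choices[[path]] %||%
      (if (nzchar(node$node_id)) cfg$slot_choices[[node$node_id]] else NULL)
    chosen_id <- if (!is.null(choice)) choice
      else if (!wildcard && length(node$allowed_ids) == 1L)
        gsub("\\\\", "", node$allowed_ids)
      else NULL
    if (is.null(chosen_id))
      stop("wildcard slot at ", path,
           " has no slot_choices entry; the allowed archetypes must be ",
           "narrowed down to a single archetype", call. = FALSE)
    if (chosen_id %in% active)
      stop("slot expansion cycle: archetype ", chosen_id,
           " transitively includes itself", call. = FALSE)
    chosen <- if (is.null(resolver)) NULL else resolver(chosen_id)
    if (is.null(chosen))
      stop("no archetype available for slot choice '", chosen_id, "'",
           call. = FALSE)
    sub <- expand_slot(node, chosen, s)
    return(expand_all_slots(sub, chain, s, cfg, resolver,
                            c(active, chosen$archetype_id)))
  }
  if (inherits(node, "adl_node")) {
    node$attributes <- lapply(node$attributes, function(attr) {
      attr$children <- lapply(attr$children, function(ch) {
        expand_all_slots(ch, c(chain, list(list(attr = attr$name, node = ch))),
                         s, cfg, resolver, active)
      })
      attr
    })
  }
  node
}

# ---- support check --------------------------------------------------------

#' Check whether a comprehensive archetype can be mapped to a form
#'
#' Reports violations instead of failing. `nested_repeats` (a repeating
#' node holding a repeating subnode — the structure a flat table cannot
#' represent), `unresolved_wildcard_slot` and `unknown_rm_class` are
#' failures; unsupported value constraints (regular expressions, duration
#' patterns) are warnings: the field is still generated, the constraint is
#' carried as a non-enforced annotation.
#'
#' @param ca a `comprehensive_archetype` (or plain archetype).
#' @param cfg a [generation_config()].
#' @param s an `rm_schema`, used to flag unknown classes (optional).
#' @param resolver slot resolver (see [archetype_resolver()]); when
#'   supplied, slots are expanded before scanning, mirroring what
#'   [generate_form()] will do.
#' @return a data frame with columns `kind`, `path`, `message`, `severity`.
#'   [generate_form()] succeeds iff no row has `severity == "failure"`.
#' @export
check_supported <- function(ca, cfg = generation_config(), s = NULL,
                            resolver = NULL) {
  def <- ca$definition
  violations <- list()
  add <- function(kind, path, message, severity) {
    violations[[length(violations) + 1L]] <<-
      data.frame(kind = kind, path = path, message = message,
                 severity = severity, stringsAsFactors = FALSE)
  }
  if (!is.null(resolver) && !is.null(s)) {
    def <- tryCatch(
      expand_all_slots(def, list(def), s, cfg, resolver, character()),
      error = function(e) {
        add("unresolved_wildcard_slot", "/", conditionMessage(e), "failure")
        NULL
      })
    if (is.null(def)) return(do.call(rbind, violations))
  }
  walk_definition(def, function(node, chain) {
    path <- internal_path(chain)
    if (inherits(node, "adl_slot")) {
      wildcard <- length(node$allowed_ids) == 1L && node$allowed_ids == ".*"
      choice <- cfg$slot_choices[[path]] %||%
        (if (nzchar(node$node_id)) cfg$slot_choices[[node$node_id]] else NULL)
      if ((wildcard || length(node$allowed_ids) > 1L) && is.null(choice))
        add("unresolved_wildcard_slot", path,
            "slot must be narrowed to a single archetype", "failure")
      return(invisible())
    }
    if (inherits(node, "adl_primitive")) {
      if (!node$enforceable)
        add("unsupported_constraint", path,
            paste0(node$kind, " constraint cannot be enforced by the form ",
                   "model; carried as annotation"), "warning")
      return(invisible())
    }
    if (inherits(node, "adl_node")) {
      if (!is.null(s) && !rm_class_exists(s, node$rm_class) &&
          !rm_is_primitive(node$rm_class))
        add("unknown_rm_class", path,
            paste0("RM class '", node$rm_class, "' unknown to schema"),
            "failure")
      if (is_repeating(node) && length(chain) > 1L) {
        ancestors <- chain[-length(chain)]
        above <- c(list(ancestors[[1]]),
                   lapply(ancestors[-1], `[[`, "node"))
        if (any(vapply(above, is_repeating, TRUE)))
          add("nested_repeats", path,
              "repeating node inside another repeating node cannot be mapped to a flat table",
              "failure")
      }
    }
    invisible()
  })
  if (length(violations) == 0L)
    return(data.frame(kind = character(), path = character(),
                      message = character(), severity = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, violations)
}

# ---- form generation ------------------------------------------------------

#' Generate a legacy form and mapping table from a comprehensive archetype
#'
#' Structural mapping: the root node becomes the form (an artificial
#' container when the root sits below COMPOSITION); SECTION nodes become
#' pages; named intermediate nodes become text objects carrying their local
#' term; leaf nodes become entry fields labelled with the concatenated
#' names of their context; repeating nodes become tables whose columns are
#' the leaf fields below them, dynamically duplicable during documentation.
#' Slots are expanded in place; deprecated RM attributes are skipped. Every
#' generated component records the path of its source archetype node in the
#' mapping table, which later drives extract generation without access to
#' the archetype.
#'
#' @param ca a `comprehensive_archetype` (see [augment()]); internal
#'   references must already be resolved.
#' @param s the `rm_schema` used for augmentation.
#' @param cfg a [generation_config()].
#' @param resolver slot resolver (see [archetype_resolver()]); required
#'   when the archetype contains slots.
#' @return a list with elements `form` (an `ehr_form`) and `mapping` (a
#'   `mapping_table`).
#' @examples
#' s <- rm_schema()
#' ca <- augment(parse_adl(paper_fixtures()$bmi_excerpt), s)
#' gen <- generate_form(ca, s)
#' gen$form
#' @export
generate_form <- function(ca, s, cfg = generation_config(), resolver = NULL) {
  stopifnot(inherits(ca, "archetype"), inherits(s, "rm_schema"))
  def <- annotate_terms(ca$definition, ca$ontology)
  def <- expand_all_slots(def, list(def), s, cfg, resolver, ca$archetype_id)
  def$path_id <- ca$archetype_id

  viol <- check_supported(list(definition = def), cfg, s)
  viol <- viol[viol$severity == "failure", , drop = FALSE]
  if (nrow(viol) > 0L)
    stop("archetype cannot be mapped: ", viol$kind[1], " at ", viol$path[1],
         ": ", viol$message[1], call. = FALSE)

  st <- new.env(parent = emptyenv())
  st$mapping <- list()
  st$counters <- list()
  st$used_labels <- character()
  st$sep <- cfg$label_separator

  next_id <- function(prefix) {
    n <- (st$counters[[prefix]] %||% 0L) + 1L
    st$counters[[prefix]] <- n
    paste0(prefix, "-", n)
  }
  map_put <- function(id, chain) st$mapping[[id]] <- archetype_path(chain)
  uniquify <- function(label, node_id) {
    if (label %in% st$used_labels) {
      suffix <- if (nzchar(node_id %||% "")) node_id else
        as.character(sum(st$used_labels == label) + 1L)
      label <- paste0(label, " (", suffix, ")")
    }
    st$used_labels <- c(st$used_labels, label)
    label
  }

  node_label_text <- function(node) {
    if (!is.null(node$term)) return(node$term$text)
    if (is_implicit(node) && !is.null(node$rm_attribute))
      return(node$rm_attribute)
    NULL
  }

  make_variable <- function(p, leaf_attr) {
    dtype <- map_primitive(p$kind)
    choice <- NULL; hint <- "default"; fmt <- NULL; ann <- NULL
    if (p$kind == "Boolean") {
      hint <- "checkbox"
    } else if (!is.null(p$allowed_values)) {
      display <- if (!is.null(p$choice_display)) p$choice_display
                 else as.character(p$allowed_values)
      stored <- if (is.numeric(p$allowed_values))
        format(p$allowed_values, scientific = FALSE, trim = TRUE)
      else as.character(p$allowed_values)
      choice <- Map(function(v, d) list(value = v, display = d),
                    stored, display)
      names(choice) <- NULL
    }
    if (!is.null(p$range)) ann$range <- p$range
    if (!is.null(p$pattern)) {
      if (p$enforceable) fmt <- p$pattern
      else ann$not_enforced <- paste0(p$kind, " pattern: ", p$pattern)
    }
    new_variable(next_id("var"), leaf_attr, dtype, choice_list = choice,
                 render_hint = hint, format = fmt, annotations = ann)
  }

  leaf_required <- function(boundary_chain) {
    # required when nothing on the chain below the container boundary is
    # optional: node occurrence lower bounds and attribute existence
    for (step in boundary_chain) {
      node <- step$node
      if (inherits(node, "adl_node") && node$occurrences$lower < 1L &&
          !is_implicit(node))
        return(FALSE)
      if (!is.null(step$existence) && step$existence$lower < 1L)
        return(FALSE)
    }
    TRUE
  }

  make_field <- function(p, leaf_attr, segs, chain, multi, boundary_chain) {
    label <- uniquify(build_label(segs, leaf_attr, st$sep), NULL)
    fld <- new_entry_field(next_id("field"), label,
                           make_variable(p, leaf_attr),
                           name = leaf_attr, multi = multi,
                           required = is_implicit(p) ||
                             leaf_required(boundary_chain))
    map_put(fld$id, chain)
    fld
  }

  # Collect table columns below a repeating node (pre-order). `segs` starts
  # with the repeating node's own name; intermediates contribute to labels
  # only.
  collect_columns <- function(node, chain, segs, boundary_chain) {
    cols <- list()
    for (attr in node$attributes) {
      if (is_deprecated_attribute(s, node$rm_class, attr$name)) next
      for (child in attr$children) {
        chain2 <- c(chain, list(list(attr = attr$name, node = child,
                                     existence = attr$existence)))
        bchain2 <- c(boundary_chain,
                     list(list(attr = attr$name, node = child,
                               existence = attr$existence)))
        if (inherits(child, "adl_primitive")) {
          cols[[length(cols) + 1L]] <-
            make_field(child, attr$name, segs$named_tail(attr$name), chain2,
                       multi = TRUE, boundary_chain = bchain2)
        } else if (inherits(child, "adl_node")) {
          lab <- node_label_text(child)
          segs2 <- if (!is.null(lab)) segs$push_named(lab)
                   else segs$push_attr(attr$name)
          cols <- c(cols, collect_columns(child, chain2, segs2, bchain2))
        }
      }
    }
    cols
  }

  # Label context: named-node segments plus attribute names accumulated
  # since the last named node.
  label_ctx <- function(named = character(), tail = character()) {
    ctx <- list(named = named, tail = tail)
    ctx$push_named <- function(text)
      label_ctx(c(ctx$named, text), character())
    ctx$push_attr <- function(a) label_ctx(ctx$named, c(ctx$tail, a))
    ctx$named_tail <- function(leaf_prefixes = character())
      c(ctx$named, ctx$tail)
    ctx
  }

  # Build the components for one node's children; returns a flat list of
  # components for the enclosing page.
  build_children <- function(node, chain, segs) {
    comps <- list()
    for (attr in node$attributes) {
      if (is_deprecated_attribute(s, node$rm_class, attr$name)) next
      for (child in attr$children) {
        chain2 <- c(chain, list(list(attr = attr$name, node = child,
                                     existence = attr$existence)))
        if (inherits(child, "adl_primitive")) {
          comps[[length(comps) + 1L]] <-
            make_field(child, attr$name, segs$named_tail(), chain2,
                       multi = FALSE,
                       boundary_chain = list(list(attr = attr$name,
                                                  node = child,
                                                  existence = attr$existence)))
        } else if (inherits(child, "adl_node")) {
          lab <- node_label_text(child)
          if (is_repeating(child)) {
            tab_name <- lab %||% child$rm_class
            tab_segs <- label_ctx()$push_named(tab_name)
            cols <- collect_columns(child, chain2, tab_segs,
                                    list(list(attr = attr$name, node = child,
                                              existence = attr$existence)))
            tab <- new_table(next_id("table"), tab_name, cols)
            map_put(tab$id, chain2)
            comps[[length(comps) + 1L]] <- tab
          } else if (identical(child$rm_class, "SECTION")) {
            pg <- new_page(next_id("page"), lab %||% "Section",
                           build_children(child, chain2, label_ctx()))
            map_put(pg$id, chain2)
            comps[[length(comps) + 1L]] <- pg
          } else if (!is.null(lab)) {
            tobj <- new_text_object(next_id("text"), lab)
            map_put(tobj$id, chain2)
            comps[[length(comps) + 1L]] <- tobj
            comps <- c(comps, build_children(child, chain2,
                                             segs$push_named(lab)))
          } else {
            comps <- c(comps, build_children(child, chain2,
                                             segs$push_attr(attr$name)))
          }
        }
      }
    }
    comps
  }

  root_title <- node_label_text(def) %||% def$rm_class
  root_chain <- list(def)
  root_page <- new_page(next_id("page"), root_title,
                        build_children(def, root_chain, label_ctx()))
  map_put(root_page$id, root_chain)

  form <- new_form("form-1", root_title, ca$archetype_id, list(root_page))
  form_lint(form)
  mapping <- structure(list(entries = st$mapping), class = "mapping_table")
  list(form = form, mapping = mapping)
}

#' @export
print.mapping_table <- function(x, ...) {
  cat("<mapping_table> ", length(x$entries), " entries\n", sep = "")
  invisible(x)
}
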