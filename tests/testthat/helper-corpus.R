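# Shared fixtures and independent oracles for the test suite.
# The oracles re-derive structural properties by direct tree walks that
# share no logic with the generator or the implementation under test.

RM <- rm_schema()

bmi <- function() parse_adl(paper_fixtures()$bmi_excerpt)

minimal_adl <- function() {
  paste0(
    "archetype (adl_version=1.4)\n",
    "    openEHR-EHR-ELEMENT.minimal.v1\n\n",
    "concept\n    [at0000]\n\n",
    "definition\n",
    "    ELEMENT[at0000] matches {    -- Minimal\n",
    "        value matches {\n",
    "            DV_TEXT matches { value matches {\"x\"} }\n",
    "        }\n",
    "    }\n\n",
    "ontology\n",
    "    term_definitions = <\n",
    "        [\"en\"] = <\n",
    "            items = <\n",
    "                [\"at0000\"] = <\n",
    "                    text = <\"Minimal\">\n",
    "                    description = <\"smallest case\">\n",
    "                >\n",
    "            >\n        >\n    >\n")
}


# A mixed corpus of synthetic archetypes plus the hand-written fixtures.
fixture_corpus <- function(n = 12L, seed = 100L) {
  out <- lapply(seq_len(n), function(i) {
    gen_archetype(fixture_spec(
      depth = 3L + (i %% 2L), leaf_count = 3L + (i %% 4L),
      primitive_mix = c("String", "Integer", "Real", "Boolean",
                        "Date", "Time", "Date_Time", "Duration"),
      nested_repeat = (i %% 3L == 0L),
      repeat_nodes = if (i %% 3L == 0L) 0L else 1L,
      internal_ref_count = (i %% 4L == 0L) * 1L,
      seed = seed + i))
  })
  c(out, unname(paper_fixtures()))
}

# Builder for a slot-including archetype: returns the includer text, the
# included archetype and a wildcard-slot variant.
slot_fixture <- function(seed = 42L) {
  inc <- parse_adl(gen_archetype(fixture_spec(depth = 2L, leaf_count = 2L,
                                              repeat_nodes = 0L, seed = seed)))
  esc_id <- gsub(".", "\\.", inc$archetype_id, fixed = TRUE)
  main <- paste0(
    "archetype (adl_version=1.4)\n",
    "    openEHR-EHR-CLUSTER.includer.v1\n\n",
    "concept\n    [at0000]\n\n",
    "definition\n",
    "    CLUSTER[at0000] matches {    -- Main cluster\n",
    "        items matches {\n",
    "            ELEMENT[at0001] matches {\n",
    "                value matches {\n",
    "                    DV_TEXT matches { value matches {\"a\", \"b\"} }\n",
    "                }\n",
    "            }\n",
    "            allow_archetype CLUSTER[at0002] occurrences matches {0..1}",
    " matches {include archetype_id/value matches {/", esc_id, "/}}\n",
    "            allow_archetype CLUSTER[at0003] matches {*}\n",
    "        }\n",
    "    }\n\n",
    "ontology\n",
    "    term_definitions = <\n",
    "        [\"en\"] = <\n",
    "            items = <\n",
    "                [\"at0000\"] = <\n",
    "                    text = <\"Main cluster\">\n",
    "                    description = <\"d\">\n                >\n",
    "                [\"at0001\"] = <\n",
    "                    text = <\"Elem one\">\n",
    "                    description = <\"d\">\n                >\n",
    "                [\"at0002\"] = <\n",
    "                    text = <\"Slot one\">\n",
    "                    description = <\"d\">\n                >\n",
    "                [\"at0003\"] = <\n",
    "                    text = <\"Slot wild\">\n",
    "                    description = <\"d\">\n                >\n",
    "            >\n        >\n    >\n")
  list(main = main, included = inc)
}

# ---- independent oracles --------------------------------------------------

# Flat (node, ancestor-nodes) enumeration; nested repeats iff some pair
# (ancestor, descendant) both have occurrence upper bounds > 1.
oracle_nested_repeats <- function(def) {
  found <- FALSE
  rec <- function(node, ancestors) {
    if (!is.null(node$occurrences) && node$occurrences$upper > 1) {
      for (anc in ancestors) {
        if (!is.null(anc$occurrences) && anc$occurrences$upper > 1)
          found <<- TRUE
      }
    }
    if (!is.null(node$attributes)) {
      for (attr in node$attributes) {
        for (ch in attr$children) rec(ch, c(ancestors, list(node)))
      }
    }
  }
  rec(def, list())
  found
}

# Count primitive leaves of a (comprehensive, expanded) definition that are
# not under a deprecated attribute: each must map to exactly one entry
# field or table column.
oracle_leaf_count <- function(def, s) {
  n <- 0L
  rec <- function(node) {
    if (inherits(node, "adl_primitive")) { n <<- n + 1L; return(invisible()) }
    if (is.null(node$attributes)) return(invisible())
    for (attr in node$attributes) {
      if (is_deprecated_attribute(s, node$rm_class, attr$name)) next
      for (ch in attr$children) rec(ch)
    }
  }
  rec(def)
  n
}

# Maximum CLUSTER nesting level (for generator property checks).
oracle_cluster_depth <- function(def) {
  best <- 0L
  rec <- function(node, lvl) {
    if (identical(node$rm_class, "CLUSTER")) {
      lvl <- lvl + 1L
      best <<- max(best, lvl)
    }
    if (!is.null(node$attributes)) {
      for (attr in node$attributes) for (ch in attr$children) rec(ch, lvl)
    }
  }
  rec(def, 0L)
  best
}

oracle_element_count <- function(def) {
  n <- 0L
  rec <- function(node) {
    if (identical(node$rm_class %||% "", "ELEMENT")) n <<- n + 1L
    if (!is.null(node$attributes)) {
      for (attr in node$attributes) for (ch in attr$children) rec(ch)
    }
  }
  rec(def)
  n
}

count_form_fields <- function(form) {
  sum(vapply(archeform:::form_components(form),
             function(c) c$kind == "entry_field", TRUE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- archetype-walking extract oracle ------------------------------------

# Builds the extract content element by walking the comprehensive
# (slot-expanded) archetype tree directly, looking up values through the
# mapping paths. Independent of the path-merging implementation in
# generate_extract.
oracle_extract_content <- function(ca, s, form, mapping, doc) {
  def <- archeform:::annotate_terms(ca$definition, ca$ontology)
  def$path_id <- ca$archetype_id
  path_to_field <- list()
  for (id in names(mapping$entries)) {
    comp <- archeform:::form_component(form, id)
    if (!is.null(comp) && comp$kind == "entry_field")
      path_to_field[[mapping$entries[[id]]]] <- comp
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  open_tag <- function(name, node) {
    nid <- node$path_id %||% node$node_id
    id_attr <- if (nzchar(nid %||% ""))
      paste0(' archetype_node_id="', nid, '"') else ""
    type <- if (inherits(node, "adl_primitive")) toupper(node$kind)
            else node$rm_class
    paste0("<", name, id_attr, ' xsi:type="', type, '">')
  }
  walk <- function(node, chain, row) {
    parts <- character()
    for (attr in node$attributes) {
      if (is_deprecated_attribute(s, node$rm_class, attr$name)) next
      for (ch in attr$children) {
        chain2 <- c(chain, list(list(attr = attr$name, node = ch)))
        if (inherits(ch, "adl_primitive")) {
          fld <- path_to_field[[archetype_path(chain2)]]
          if (is.null(fld)) next
          rows <- if (is.na(row)) 0L else row
          v <- doc$values[[paste0(fld$id, "@", rows)]]
          if (is.null(v)) next
          txt <- convert_value(v$literal, fld$variable$data_type,
                               toupper(ch$kind))
          parts <- c(parts, paste0(open_tag(attr$name, ch), esc(txt),
                                   "</", attr$name, ">"))
        } else if (inherits(ch, "adl_node")) {
          if (archeform:::is_repeating(ch) && is.na(row)) {
            tab_path <- archetype_path(chain2)
            tab_id <- NULL
            for (id in names(mapping$entries)) {
              if (identical(mapping$entries[[id]], tab_path)) tab_id <- id
            }
            nrows <- if (is.null(tab_id)) 0L else (doc$rows[[tab_id]] %||% 0L)
            for (r in seq_len(nrows) - 1L) {
              inner <- walk(ch, chain2, r)
              if (nzchar(inner))
                parts <- c(parts, paste0(open_tag(attr$name, ch), inner,
                                         "</", attr$name, ">"))
            }
          } else {
            inner <- walk(ch, chain2, row)
            if (nzchar(inner))
              parts <- c(parts, paste0(open_tag(attr$name, ch), inner,
                                       "</", attr$name, ">"))
          }
        }
      }
    }
    paste0(parts, collapse = "")
  }
  inner <- walk(def, list(def), NA_integer_)
  paste0('<content archetype_node_id="', ca$archetype_id, '" xsi:type="',
         def$rm_class, '">', inner, "</content>")
}

# Canonical string of the content element of a generated extract, for
# comparison against the oracle.
extract_content_string <- function(x) {
  node <- xml2::xml_find_first(
    x, "//d1:chapter/*", ns = c(d1 = "http://schemas.openehr.org/v1"))
  s <- gsub(">\\s+<", "><", as.character(node))
  gsub(' xmlns(:[a-z]+)?="[^"]*"', "", s)
}
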