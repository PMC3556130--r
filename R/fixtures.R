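# Synthetic archetype fixtures.
#
# Every pipeline stage must be testable without downloading archetypes from
# an external library. gen_archetype() builds seeded random archetypes with
# controlled structural properties (depth, leaf count, primitive mix,
# repeating nodes, nested repeats, slots, internal references); the
# properties are meant to be re-derived from the parsed tree by independent
# scans that share no logic with the generator. paper_fixtures() ships
# hand-written excerpt reconstructions of the printed examples: the body
# mass index observation and a two-level repeating cluster.

#' Specification for a synthetic archetype
#'
#' @param depth number of nested CLUSTER levels including the root
#'   (&ge; 1).
#' @param leaf_count number of ELEMENT leaves (&ge; 1).
#' @param primitive_mix character vector of AM primitive kinds assigned to
#'   the leaves cyclically.
#' @param repeat_nodes either an integer count of repeating (non-root)
#'   clusters, or a list of `list(position=, upper=)` entries where
#'   `position` indexes non-root clusters in pre-order and `upper` is the
#'   occurrence upper bound (`Inf` for unbounded).
#' @param nested_repeat force one repeating cluster strictly inside
#'   another (requires `depth >= 3`); the structure a flat-table form
#'   model cannot represent.
#' @param slot_count number of slot nodes.
#' @param internal_ref_count number of use_node references to an existing
#'   element.
#' @param choice_list_sizes sizes of the string choice lists, cycled.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(depth = 3L, leaf_count = 6L,
                         primitive_mix = c("String", "Integer", "Real"),
                         repeat_nodes = 1L, nested_repeat = FALSE,
                         slot_count = 0L, internal_ref_count = 0L,
                         choice_list_sizes = c(2L, 3L), seed = 1L) {
  stopifnot(depth >= 1, leaf_count >= 1,
            all(primitive_mix %in% AM_PRIMITIVE_KINDS),
            length(choice_list_sizes) >= 1)
  if (isTRUE(nested_repeat) && depth < 3L)
    stop("inconsistent spec: nested_repeat requires depth >= 3", call. = FALSE)
  structure(list(depth = as.integer(depth), leaf_count = as.integer(leaf_count),
                 primitive_mix = primitive_mix, repeat_nodes = repeat_nodes,
                 nested_repeat = isTRUE(nested_repeat),
                 slot_count = as.integer(slot_count),
                 internal_ref_count = as.integer(internal_ref_count),
                 choice_list_sizes = as.integer(choice_list_sizes),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Pronounceable synthetic words so failure output stays readable.
gen_word <- function() {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  n <- sample(2:3, 1)
  paste0(paste0(sample(cons, n, TRUE), sample(vow, n, TRUE)), collapse = "")
}

#' Generate a synthetic archetype as ADL text
#'
#' Deterministic given the spec's seed; the output parses under
#' [parse_adl()] and its structural properties match the spec.
#'
#' @param spec a [fixture_spec()].
#' @return a single string of ADL 1.4 source.
#' @export
gen_archetype <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, build_fixture(spec))
}

build_fixture <- function(spec) {
  code_n <- 0L
  next_code <- function() {
    code_n <<- code_n + 1L
    sprintf("at%04d", code_n - 1L)
  }
  terms <- list()
  used_words <- character()
  fresh_term <- function(two_words = FALSE) {
    repeat {
      w <- if (two_words) paste(gen_word(), gen_word()) else gen_word()
      if (!(w %in% used_words)) break
    }
    used_words <<- c(used_words, w)
    w
  }
  add_term <- function(code, text) {
    terms[[code]] <<- list(text = text, description = paste("synthetic node", text))
  }

  # cluster skeleton: a chain guarantees the requested depth; extra
  # clusters attach to levels < depth
  n_extra <- max(0L, ceiling(spec$leaf_count / 3) - spec$depth)
  n_clusters <- spec$depth + n_extra
  parent <- integer(n_clusters); level <- integer(n_clusters)
  parent[1] <- 0L; level[1] <- 1L
  for (i in seq_len(n_clusters)[-1]) {
    if (i <= spec$depth) {
      parent[i] <- i - 1L
    } else {
      cand <- which(level < spec$depth)
      parent[i] <- cand[sample.int(length(cand), 1L)]
    }
    level[i] <- level[parent[i]] + 1L
  }

  # occurrence upper bounds for repeating clusters (non-root)
  upper <- rep(1, n_clusters)
  is_ancestor <- function(a, d) {
    while (d != 0L) { d <- parent[d]; if (d == a) return(TRUE) }
    FALSE
  }
  if (spec$nested_repeat) {
    # chain positions 2 and 3 are in ancestor relation by construction
    upper[2L] <- Inf; upper[3L] <- sample(2:5, 1L)
  }
  want <- spec$repeat_nodes
  if (is.list(want)) {
    for (r in want) {
      idx <- r$position + 1L          # positions index non-root clusters
      if (idx < 2L || idx > n_clusters)
        stop("inconsistent spec: repeat position ", r$position,
             " out of range", call. = FALSE)
      upper[idx] <- r$upper
    }
  } else if (want > 0L) {
    todo <- as.integer(want)
    cand <- setdiff(seq_len(n_clusters), 1L)
    cand <- cand[sample.int(length(cand))]
    for (i in cand) {
      if (todo == 0L) break
      if (upper[i] > 1) next
      clash <- any(vapply(which(upper > 1), function(j) {
        is_ancestor(j, i) || is_ancestor(i, j)
      }, TRUE))
      if (!spec$nested_repeat && clash) next
      upper[i] <- if (runif(1) < 0.5) Inf else sample(2:6, 1L)
      todo <- todo - 1L
    }
  }
  if (!spec$nested_repeat) {
    reps <- which(upper > 1)
    for (a in reps) for (d in reps) {
      if (a != d && is_ancestor(a, d))
        stop("inconsistent spec: requested repeats are nested", call. = FALSE)
    }
  }

  # build cluster nodes bottom-up
  cluster_code <- character(n_clusters)
  cluster_children <- vector("list", n_clusters)   # lists of adl nodes
  for (i in seq_len(n_clusters)) {
    cluster_code[i] <- next_code()
    add_term(cluster_code[i],
             if (i == 1L) fresh_term(TRUE) else fresh_term(runif(1) < 0.3))
    cluster_children[[i]] <- list()
  }

  kinds <- rep_len(spec$primitive_mix, spec$leaf_count)
  sizes <- rep_len(spec$choice_list_sizes, spec$leaf_count)
  first_element <- NULL                 # (cluster index, code) for use_node
  for (k in seq_len(spec$leaf_count)) {
    host <- sample.int(n_clusters, 1L)
    code <- next_code()
    add_term(code, fresh_term(runif(1) < 0.4))
    el <- new_complex_node(
      "ELEMENT", code,
      if (runif(1) < 0.5) adl_interval(0L, 1L) else adl_interval(1L, 1L),
      list(new_attribute("value", list(leaf_value_node(kinds[k], sizes[k])))))
    cluster_children[[host]] <- c(cluster_children[[host]], list(el))
    if (is.null(first_element)) first_element <- list(host = host, code = code)
  }

  for (sl in seq_len(spec$slot_count)) {
    host <- sample.int(n_clusters, 1L)
    code <- next_code()
    add_term(code, fresh_term())
    slot <- new_slot("CLUSTER", code,
                     paste0("openEHR-EHR-CLUSTER\\.", gen_word(), "\\.v1"),
                     adl_interval(0L, 1L))
    cluster_children[[host]] <- c(cluster_children[[host]], list(slot))
  }

  ref_path <- NULL
  if (spec$internal_ref_count > 0L) {
    # archetype-internal path from the root to the first element
    segs <- character(); i <- first_element$host
    while (i != 0L) {
      if (i != 1L) segs <- c(paste0("/items[", cluster_code[i], "]"), segs)
      i <- parent[i]
    }
    ref_path <- paste0(paste(segs, collapse = ""),
                       "/items[", first_element$code, "]")
    # hosts must differ from the target's own cluster: expansion would
    # otherwise duplicate a node id among siblings, making paths ambiguous
    hosts <- setdiff(seq_len(n_clusters), first_element$host)
    for (rf in seq_len(spec$internal_ref_count)) {
      if (length(hosts) == 0L) break
      host <- hosts[sample.int(length(hosts), 1L)]
      ref <- new_internal_ref("ELEMENT", ref_path, adl_interval(0L, 1L))
      cluster_children[[host]] <- c(cluster_children[[host]], list(ref))
    }
  }

  # assemble clusters from deepest to shallowest
  nodes <- vector("list", n_clusters)
  for (i in rev(seq_len(n_clusters))) {
    kids <- cluster_children[[i]]
    for (j in which(parent == i)) kids <- c(kids, list(nodes[[j]]))
    if (length(kids) == 0L) {
      # a childless cluster is not expressible; give it a filler element
      code <- next_code()
      add_term(code, fresh_term())
      kids <- list(new_complex_node(
        "ELEMENT", code, adl_interval(0L, 1L),
        list(new_attribute("value", list(leaf_value_node("String", 2L))))))
    }
    occ <- if (is.infinite(upper[i])) adl_interval(0L, Inf)
           else if (upper[i] > 1) adl_interval(0L, as.integer(upper[i]))
           else adl_interval(1L, 1L)
    nodes[[i]] <- new_complex_node("CLUSTER", cluster_code[i], occ,
                                   list(new_attribute("items", kids)))
  }

  id <- paste0("openEHR-EHR-CLUSTER.synthetic_", gen_word(), code_n, ".v1")
  a <- new_archetype(id, cluster_code[1], nodes[[1]],
                     new_ontology(terms))
  serialize_adl(a)
}

# Typed data-value wrapper for a leaf of the given primitive kind.
leaf_value_node <- function(kind, choice_size) {
  wrap <- function(cls, attr, prim)
    new_complex_node(cls, "", adl_interval(1L, 1L),
                     list(new_attribute(attr, list(prim))))
  switch(kind,
    String = wrap("DV_TEXT", "value",
                  new_primitive("String",
                                allowed_values = replicate(max(1L, choice_size),
                                                           gen_word()))),
    Integer = wrap("DV_COUNT", "magnitude",
                   new_primitive("Integer",
                                 range = list(lower = 0, upper = 100))),
    Real = new_complex_node(
      "DV_QUANTITY", "", adl_interval(1L, 1L),
      list(new_attribute("magnitude",
                         list(new_primitive("Real",
                                            range = list(lower = 0,
                                                         upper = 250)))),
           new_attribute("units",
                         list(new_primitive("String",
                                            allowed_values = gen_word()))))),
    Boolean = wrap("DV_BOOLEAN", "value",
                   new_primitive("Boolean", allowed_values = c(TRUE, FALSE))),
    Date = wrap("DV_DATE", "value",
                new_primitive("Date", pattern = "yyyy-mm-dd")),
    Time = wrap("DV_TIME", "value",
                new_primitive("Time", pattern = "hh:mm:ss")),
    Date_Time = wrap("DV_DATE_TIME", "value",
                     new_primitive("Date_Time",
                                   pattern = "yyyy-mm-ddThh:mm:ss")),
    Duration = wrap("DV_DURATION", "value",
                    new_primitive("Duration", pattern = "PYMWD",
                                  enforceable = FALSE)))
}

#' Hand-written fixtures transcribing the printed examples
#'
#' `bmi_excerpt` is an excerpt reconstruction of the body-mass-index
#' observation: OBSERVATION at0000 "Body mass index" -> data HISTORY at0001
#' "history" -> events EVENT at0002 "Single" (0..*) -> data ITEM_TREE ->
#' items ELEMENT at0003 "Body Mass Index" -> value C_DV_QUANTITY with units
#' in {kg/m2, lb/in2}, magnitude, precision and the deprecated property
#' attribute. It encodes only the printed structure, not the full library
#' archetype. `nested_repeat_cluster` mirrors the two-level repeating
#' cluster structure (a microscopy-style finding repeated per specimen)
#' that form generation must reject.
#'
#' @return a named list of ADL texts.
#' @export
paper_fixtures <- function() {
  list(bmi_excerpt = bmi_excerpt_adl(), nested_repeat_cluster = nested_repeat_adl())
}

bmi_excerpt_adl <- function() {
'archetype (adl_version=1.4)
    openEHR-EHR-OBSERVATION.body_mass_index.v1

concept
    [at0000]

definition
    OBSERVATION[at0000] matches {    -- Body mass index
        data matches {
            HISTORY[at0001] matches {    -- history
                events cardinality matches {0..*; unordered} matches {
                    EVENT[at0002] occurrences matches {0..*} matches {    -- Single
                        data matches {
                            ITEM_TREE matches {
                                items cardinality matches {0..1; ordered} matches {
                                    ELEMENT[at0003] occurrences matches {0..1} matches {    -- Body Mass Index
                                        value matches {
                                            C_DV_QUANTITY <
                                                property = <"mass per area">
                                                units = <"kg/m2", "lb/in2">
                                                magnitude = <|0.0..1000.0|>
                                                precision = <|0..1|>
                                            >
                                        }
                                    }
                                }
                            }
                        }
                    }
                }
            }
        }
    }

ontology
    term_definitions = <
        ["en"] = <
            items = <
                ["at0000"] = <
                    text = <"Body mass index">
                    description = <"Index describing ratio of weight to height">
                >
                ["at0001"] = <
                    text = <"history">
                    description = <"history structural node">
                >
                ["at0002"] = <
                    text = <"Single">
                    description = <"a single, unrepeated measurement event">
                >
                ["at0003"] = <
                    text = <"Body Mass Index">
                    description = <"the measured index value">
                >
            >
        >
    >
'
}

nested_repeat_adl <- function() {
'archetype (adl_version=1.4)
    openEHR-EHR-CLUSTER.microscopy_specimen_synthetic.v1

concept
    [at0000]

definition
    CLUSTER[at0000] matches {    -- Microscopic findings
        items matches {
            CLUSTER[at0001] occurrences matches {0..*} matches {    -- Specimen
                items matches {
                    ELEMENT[at0002] occurrences matches {0..1} matches {    -- Specimen id
                        value matches {
                            DV_TEXT matches {
                                value matches {"left", "right"}
                            }
                        }
                    }
                    CLUSTER[at0003] occurrences matches {0..*} matches {    -- Focal finding
                        items matches {
                            ELEMENT[at0004] occurrences matches {0..1} matches {    -- Finding
                                value matches {
                                    DV_TEXT matches {
                                        value matches {"benign", "atypical", "malignant"}
                                    }
                                }
                            }
                        }
                    }
                }
            }
        }
    }

ontology
    term_definitions = <
        ["en"] = <
            items = <
                ["at0000"] = <
                    text = <"Microscopic findings">
                    description = <"container for findings per specimen">
                >
                ["at0001"] = <
                    text = <"Specimen">
                    description = <"repeats per examined specimen">
                >
                ["at0002"] = <
                    text = <"Specimen id">
                    description = <"laterality of the specimen">
                >
                ["at0003"] = <
                    text = <"Focal finding">
                    description = <"repeats per focal site within a specimen">
                >
                ["at0004"] = <
                    text = <"Finding">
                    description = <"categorical assessment">
                >
            >
        >
    >
'
}

#' Write a corpus of synthetic fixtures plus a property manifest
#'
#' @param dir output directory (created if missing).
#' @param n number of archetypes.
#' @param seed corpus seed; fixture i uses `seed + i`.
#' @param nested_frac fraction of fixtures carrying a nested repeat.
#' @return the manifest data frame, invisibly; files `fix_###.adl` and
#'   `manifest.csv` are written under `dir`.
#' @export
write_fixtures <- function(dir, n = 20L, seed = 7L, nested_frac = 0.4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    nested <- ((i - 1) / n) < nested_frac
    spec <- fixture_spec(depth = 3L + (i %% 2L), leaf_count = 4L + (i %% 4L),
                         nested_repeat = nested,
                         repeat_nodes = if (nested) 0L else 1L,
                         seed = seed + i)
    adl <- gen_archetype(spec)
    file <- sprintf("fix_%03d.adl", i)
    writeLines(adl, file.path(dir, file))
    data.frame(file = file, seed = spec$seed, depth = spec$depth,
               leaf_count = spec$leaf_count, nested_repeat = nested,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Fill a generated form with random values
#'
#' Creates a document with every single entry field valued, and `n_rows`
#' rows per table with required columns always present and optional ones
#' included at random. Draws from choice lists when present, otherwise
#' from type-appropriate random literals. Uses the current RNG state.
#'
#' @param form an `ehr_form`.
#' @param n_rows number of rows per table.
#' @return an `ehr_document`.
#' @export
random_document <- function(form, n_rows = 2L) {
  d <- new_document(form, id = "doc-1")
  rand_literal <- function(variable) {
    if (!is.null(variable$choice_list)) {
      opts <- vapply(variable$choice_list, `[[`, "", "value")
      return(opts[sample.int(length(opts), 1L)])
    }
    switch(variable$data_type,
      Text = paste0("txt_", paste0(sample(letters, 5, TRUE), collapse = "")),
      Number = {
        r <- variable$annotations$range %||% list(lower = 0, upper = 100)
        format(round(stats::runif(1, r$lower, r$upper), 1),
               scientific = FALSE)
      },
      Date = sprintf("20%02d-%02d-%02d", sample(0:25, 1), sample(1:12, 1),
                     sample(1:28, 1)),
      Time = sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1),
                     sample(0:59, 1)),
      Timestamp = sprintf("20%02d-%02d-%02dT%02d:%02d:%02d", sample(0:25, 1),
                          sample(1:12, 1), sample(1:28, 1), sample(0:23, 1),
                          sample(0:59, 1), sample(0:59, 1)))
  }
  fill <- function(comp) {
    if (comp$kind == "page") {
      for (ch in comp$children) fill(ch)
    } else if (comp$kind == "table") {
      for (r in seq_len(n_rows) - 1L) {
        d <<- add_table_row(d, form, comp$id)
        for (col in comp$columns) {
          if (col$required || stats::runif(1) < 0.7)
            d <<- set_value(d, form, col$id, rand_literal(col$variable), r)
        }
      }
    } else if (comp$kind == "entry_field") {
      d <<- set_value(d, form, comp$id, rand_literal(comp$variable))
    }
  }
  for (p in form$pages) fill(p)
  d
}
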