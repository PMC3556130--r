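# Recursive-descent parser for the supported ADL 1.4 subset.
#
# Covered: the archetype/concept/definition/ontology sections, cADL complex
# nodes with occurrences, attribute constraints with existence/cardinality,
# primitive constraints (string value lists, regular expressions, numeric
# value lists and intervals, Boolean lists, date/time/date-time format
# masks, duration pattern masks, local code lists, assumed values), slot
# nodes (allow_archetype ... include), internal references (use_node),
# C_DV_* domain-type shorthand blocks, and ontology term_definitions /
# term_bindings. Everything else raises an "unsupported ADL construct"
# error; ADL versions other than 1.4 are rejected up front.

SECTION_KEYWORDS <- c("concept", "language", "description", "definition",
                      "ontology")

is_class_ident <- function(v) grepl("^C?_?[A-Z][A-Z0-9_]*$", v) &&
  grepl("^[A-Z]", v)

is_at_code <- function(v) grepl("^at[0-9]+(\\.[0-9]+)*$", v)

#' Parse ADL 1.4 text into an archetype object
#'
#' @param text a single string of ADL source (or a connection/file path via
#'   [read_adl()]).
#' @return an object of class `archetype`: the constraint tree
#'   (`$definition`), the concept code and the ontology (local terms and
#'   term bindings).
#' @examples
#' a <- parse_adl(paper_fixtures()$bmi_excerpt)
#' a$archetype_id
#' local_term(a, "at0000")$text
#' @export
parse_adl <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  cur <- new_cursor(adl_lex(text))

  expect_tok(cur, "ident", "archetype")
  adl_version <- "1.4"
  if (at_tok(cur, "punct", "(")) {
    advance(cur)
    expect_tok(cur, "ident", "adl_version")
    expect_tok(cur, "punct", "=")
    adl_version <- expect_tok(cur, "number")
    expect_tok(cur, "punct", ")")
  }
  if (adl_version != "1.4")
    stop("unsupported ADL version '", adl_version,
         "': only ADL 1.4 is supported", call. = FALSE)
  if (cur_type(cur) != "ident")
    cur_error(cur, "expected archetype identifier")
  archetype_id <- advance(cur)
  if (!grepl("^[A-Za-z][A-Za-z0-9]*-[A-Za-z0-9]+-[A-Z][A-Z0-9_]*\\.[A-Za-z0-9_-]+(\\.[A-Za-z0-9_-]+)*\\.v[0-9]+$",
              archetype_id))
    stop("malformed archetype identifier: ", archetype_id, call. = FALSE)

  concept_code <- NULL; definition <- NULL; ontology <- NULL
  while (cur_type(cur) != "eof") {
    if (cur_type(cur) != "ident" || !(cur_value(cur) %in% SECTION_KEYWORDS))
      cur_error(cur, "expected a section keyword")
    section <- advance(cur)
    if (section == "concept") {
      expect_tok(cur, "punct", "[")
      concept_code <- expect_tok(cur, "ident")
      if (!is_at_code(concept_code))
        cur_error(cur, "concept code must be a local 'atNNNN' code")
      expect_tok(cur, "punct", "]")
    } else if (section %in% c("language", "description")) {
      skip_section(cur)
    } else if (section == "definition") {
      definition <- parse_complex_node(cur)
      definition$occ_explicit <- NULL
    } else if (section == "ontology") {
      ontology <- parse_ontology(cur)
    }
  }
  if (is.null(concept_code)) stop("missing section 'concept'", call. = FALSE)
  if (is.null(definition))   stop("missing section 'definition'", call. = FALSE)
  if (is.null(ontology))     stop("missing section 'ontology'", call. = FALSE)
  if (!identical(definition$node_id, concept_code))
    stop("definition root node id '", definition$node_id,
         "' does not match concept code '", concept_code, "'", call. = FALSE)

  a <- new_archetype(archetype_id, concept_code, definition, ontology,
                     adl_version)
  check_parsed_archetype(a)
  a
}

#' Read and parse an .adl file
#' @param path path to an ADL 1.4 text file.
#' @return an `archetype` object.
#' @export
read_adl <- function(path) {
  parse_adl(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n"))
}

# Skip an unmodelled section (language, description) up to the next
# top-level section keyword.
skip_section <- function(cur) {
  depth <- 0L
  while (cur_type(cur) != "eof") {
    v <- cur_value(cur); ty <- cur_type(cur)
    if (depth == 0L && ty == "ident" && v %in% SECTION_KEYWORDS) return(invisible())
    if (ty == "punct") {
      if (v %in% c("{", "<", "(")) depth <- depth + 1L
      if (v %in% c("}", ">", ")")) depth <- depth - 1L
    }
    advance(cur)
  }
  invisible()
}

# ---- cADL -----------------------------------------------------------------

parse_interval <- function(cur) {
  if (at_tok(cur, "punct", "*")) { advance(cur); return(adl_interval(0L, Inf)) }
  lo <- expect_tok(cur, "number")
  if (grepl("\\.", lo)) cur_error(cur, "interval bounds must be integers")
  lo <- as.integer(lo)
  if (!at_tok(cur, "dotdot")) return(adl_interval(lo, lo))
  advance(cur)
  if (at_tok(cur, "punct", "*")) { advance(cur); return(adl_interval(lo, Inf)) }
  up <- expect_tok(cur, "number")
  adl_interval(lo, as.integer(up))
}

parse_occurrences <- function(cur) {
  advance(cur)                       # 'occurrences'
  expect_tok(cur, "ident", "matches")
  expect_tok(cur, "punct", "{")
  iv <- parse_interval(cur)
  expect_tok(cur, "punct", "}")
  iv
}

parse_complex_node <- function(cur) {
  if (cur_type(cur) != "ident" || !is_class_ident(cur_value(cur)))
    cur_error(cur, "expected an RM class name")
  cls <- advance(cur)
  domain_shorthand <- grepl("^C_DV_", cls)
  rm_class <- if (domain_shorthand) sub("^C_", "", cls) else cls

  node_id <- ""
  if (at_tok(cur, "punct", "[")) {
    advance(cur)
    node_id <- expect_tok(cur, "ident")
    if (!is_at_code(node_id)) cur_error(cur, "expected a local 'atNNNN' code")
    expect_tok(cur, "punct", "]")
  }
  occurrences <- NULL
  if (at_tok(cur, "ident", "occurrences")) occurrences <- parse_occurrences(cur)

  if (at_tok(cur, "ident", "matches")) advance(cur)
  if (at_tok(cur, "punct", "<")) {
    attributes <- parse_domain_shorthand(cur)
  } else {
    expect_tok(cur, "punct", "{")
    attributes <- list()
    while (!at_tok(cur, "punct", "}")) {
      attributes[[length(attributes) + 1L]] <- parse_attribute(cur)
    }
    expect_tok(cur, "punct", "}")
    if (length(attributes) == 0L)
      cur_error(cur, "complex node without attribute constraints")
  }
  node <- new_complex_node(rm_class, node_id,
                           occurrences %||% adl_interval(), attributes)
  node$occ_explicit <- !is.null(occurrences)
  node
}

# Occurrences default when absent: the enclosing attribute's cardinality if
# present, else 1..1. Applied once the attribute context is known.
apply_occurrence_default <- function(child, cardinality) {
  if (is.null(cardinality) || isTRUE(child$occ_explicit) ||
      inherits(child, "adl_primitive")) {
    child$occ_explicit <- NULL
    return(child)
  }
  child$occurrences <- cardinality
  child$occ_explicit <- NULL
  child
}

parse_attribute <- function(cur) {
  if (cur_type(cur) != "ident" || is_class_ident(cur_value(cur)))
    cur_error(cur, "expected an RM attribute name")
  name <- advance(cur)
  existence <- NULL; cardinality <- NULL
  if (at_tok(cur, "ident", "existence")) {
    advance(cur); expect_tok(cur, "ident", "matches"); expect_tok(cur, "punct", "{")
    existence <- parse_interval(cur)
    expect_tok(cur, "punct", "}")
  }
  if (at_tok(cur, "ident", "cardinality")) {
    advance(cur); expect_tok(cur, "ident", "matches"); expect_tok(cur, "punct", "{")
    cardinality <- parse_interval(cur)
    while (at_tok(cur, "punct", ";")) {
      advance(cur)
      ord <- expect_tok(cur, "ident")
      if (!ord %in% c("ordered", "unordered", "unique"))
        cur_error(cur, "expected 'ordered', 'unordered' or 'unique'")
    }
    expect_tok(cur, "punct", "}")
  }
  expect_tok(cur, "ident", "matches")
  open_idx <- cur$i
  expect_tok(cur, "punct", "{")

  children <- list()
  first <- cur_value(cur)
  # an all-caps ident could also be a pattern mask (e.g. a duration mask):
  # it starts a node only when followed by node syntax
  node_start <- cur_type(cur) == "ident" &&
    (first %in% c("allow_archetype", "use_node") ||
       (is_class_ident(first) &&
          (cur_value(cur, 1L) %in% c("matches", "occurrences") ||
             (cur_type(cur, 1L) == "punct" &&
                cur_value(cur, 1L) %in% c("[", "<")))))
  if (node_start) {
    while (!at_tok(cur, "punct", "}")) {
      children[[length(children) + 1L]] <- parse_node_child(cur)
    }
    expect_tok(cur, "punct", "}")
  } else {
    close_idx <- matching_brace(cur, open_idx)
    raw <- raw_span(cur, cur$i, close_idx - 1L)
    children <- list(parse_primitive_raw(raw, cur))
    cur$i <- close_idx + 1L
  }
  if (length(children) == 0L)
    cur_error(cur, "attribute constraint without children")
  children <- lapply(children, apply_occurrence_default,
                     cardinality = cardinality)
  new_attribute(name, children, existence, cardinality)
}

parse_node_child <- function(cur) {
  v <- cur_value(cur)
  if (v == "allow_archetype") return(parse_slot(cur))
  if (v == "use_node") return(parse_use_node(cur))
  parse_complex_node(cur)
}

parse_slot <- function(cur) {
  advance(cur)                       # 'allow_archetype'
  if (cur_type(cur) != "ident" || !is_class_ident(cur_value(cur)))
    cur_error(cur, "expected an RM class name after allow_archetype")
  cls <- advance(cur)
  node_id <- ""
  if (at_tok(cur, "punct", "[")) {
    advance(cur); node_id <- expect_tok(cur, "ident"); expect_tok(cur, "punct", "]")
  }
  occurrences <- NULL
  if (at_tok(cur, "ident", "occurrences")) occurrences <- parse_occurrences(cur)
  expect_tok(cur, "ident", "matches")
  open_idx <- cur$i
  expect_tok(cur, "punct", "{")
  close_idx <- matching_brace(cur, open_idx)
  raw <- trimws(raw_span(cur, cur$i, close_idx - 1L))
  cur$i <- close_idx + 1L

  allowed <- ".*"
  if (raw != "" && raw != "*") {
    m <- regmatches(raw,
                    regexec("^include\\s+archetype_id/value\\s+matches\\s*\\{\\s*/(.*)/\\s*\\}$",
                            raw, perl = TRUE))[[1]]
    if (length(m) != 2L)
      cur_error(cur, "unsupported ADL construct in slot body")
    allowed <- strsplit(m[2], "|", fixed = TRUE)[[1]]
    allowed <- trimws(allowed)
    if (length(allowed) == 0L) allowed <- ".*"
  }
  slot <- new_slot(cls, node_id, allowed, occurrences %||% adl_interval())
  slot$occ_explicit <- !is.null(occurrences)
  slot
}

parse_use_node <- function(cur) {
  advance(cur)                       # 'use_node'
  if (cur_type(cur) != "ident" || !is_class_ident(cur_value(cur)))
    cur_error(cur, "expected an RM class name after use_node")
  cls <- advance(cur)
  occurrences <- NULL
  if (at_tok(cur, "ident", "occurrences")) occurrences <- parse_occurrences(cur)
  if (!at_tok(cur, "punct", "/"))
    cur_error(cur, "expected an archetype-internal path after use_node")
  path <- ""
  while (at_tok(cur, "punct", "/")) {
    advance(cur)
    seg <- expect_tok(cur, "ident")
    path <- paste0(path, "/", seg)
    if (at_tok(cur, "punct", "[")) {
      advance(cur)
      code <- expect_tok(cur, "ident")
      expect_tok(cur, "punct", "]")
      path <- paste0(path, "[", code, "]")
    }
  }
  ref <- new_internal_ref(cls, path, occurrences %||% adl_interval())
  ref$occ_explicit <- !is.null(occurrences)
  ref
}

# ---- C_DV_* domain shorthand ---------------------------------------------

matching_angle <- function(cur, open) {
  depth <- 0L
  for (i in open:cur$toks$n) {
    if (cur$toks$types[i] == "punct") {
      v <- cur$toks$values[i]
      if (v == "<") depth <- depth + 1L
      if (v == ">") {
        depth <- depth - 1L
        if (depth == 0L) return(i)
      }
    }
  }
  cur$i <- open
  cur_error(cur, "unbalanced '<'")
}

parse_domain_shorthand <- function(cur) {
  expect_tok(cur, "punct", "<")
  attributes <- list()
  while (!at_tok(cur, "punct", ">")) {
    if (cur_type(cur) != "ident" || is_class_ident(cur_value(cur)))
      cur_error(cur, "expected an attribute name in domain-type block")
    name <- advance(cur)
    expect_tok(cur, "punct", "=")
    open_idx <- cur$i
    expect_tok(cur, "punct", "<")
    close_idx <- matching_angle(cur, open_idx)
    raw <- raw_span(cur, cur$i, close_idx - 1L)
    cur$i <- close_idx + 1L
    attributes[[length(attributes) + 1L]] <-
      new_attribute(name, list(parse_primitive_raw(raw, cur)))
  }
  expect_tok(cur, "punct", ">")
  if (length(attributes) == 0L)
    cur_error(cur, "empty domain-type block")
  attributes
}

# ---- primitive constraints -----------------------------------------------

# Split a raw primitive block on the last top-level ';' (assumed value),
# ignoring ';' inside string literals.
split_assumed <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  in_str <- FALSE; esc <- FALSE; last_semi <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (esc) { esc <- FALSE; next }
    if (ch == "\\") { esc <- TRUE; next }
    if (ch == '"') in_str <- !in_str
    if (ch == ";" && !in_str) last_semi <- i
  }
  if (is.na(last_semi)) return(list(constraint = raw, assumed = NULL))
  list(constraint = substr(raw, 1L, last_semi - 1L),
       assumed = trimws(substr(raw, last_semi + 1L, nchar(raw))))
}

is_date_mask <- function(s)
  grepl("^[yY]{4}(-([mM]{2}|\\?\\?|XX))(-([dD]{2}|\\?\\?|XX))?$", s)
is_time_mask <- function(s)
  grepl("^[hH]{2}(:([mM]{2}|\\?\\?|XX))(:([sS]{2}|\\?\\?|XX))?$", s)
is_datetime_mask <- function(s) {
  if (!grepl("T", s, fixed = TRUE)) return(FALSE)
  parts <- strsplit(s, "T", fixed = TRUE)[[1]]
  length(parts) == 2L && is_date_mask(parts[1]) && is_time_mask(parts[2])
}

parse_primitive_raw <- function(raw, cur = NULL) {
  fail <- function(msg) {
    msg <- paste0("unsupported ADL construct in primitive constraint: ", msg)
    if (!is.null(cur)) cur_error(cur, msg) else stop(msg, call. = FALSE)
  }
  parts <- split_assumed(trimws(raw))
  s <- trimws(parts$constraint)
  assumed <- parts$assumed
  if (!is.null(assumed) && grepl('^"', assumed)) assumed <- unquote_adl(assumed)
  if (s == "") fail("empty constraint block")

  # regular expression: parsed, retained, not enforceable
  if (grepl("^/", s)) {
    if (!grepl("/$", s) || nchar(s) < 2L) fail(s)
    return(new_primitive("String", pattern = substr(s, 2L, nchar(s) - 1L),
                         enforceable = FALSE, assumed_value = assumed))
  }
  # local term code list -> coded-text choice represented as String codes
  if (grepl("^\\[\\s*local\\s*::", s)) {
    codes <- regmatches(s, gregexpr("at[0-9]+(\\.[0-9]+)*", s))[[1]]
    if (length(codes) == 0L) fail(s)
    return(new_primitive("String", allowed_values = codes,
                         local_coded = TRUE, assumed_value = assumed))
  }
  # numeric interval |a..b|
  if (grepl("^\\|", s)) {
    m <- regmatches(s, regexec(
      "^\\|\\s*(-?[0-9]+(\\.[0-9]+)?)\\s*\\.\\.\\s*(-?[0-9]+(\\.[0-9]+)?)\\s*\\|$",
      s))[[1]]
    if (length(m) == 0L) fail(s)
    real <- grepl("\\.", m[2]) || grepl("\\.", m[4])
    lo <- as.numeric(m[2]); up <- as.numeric(m[4])
    if (up < lo) fail("interval upper bound below lower bound")
    return(new_primitive(if (real) "Real" else "Integer",
                         range = list(lower = lo, upper = up),
                         assumed_value = if (is.null(assumed)) NULL
                                         else as.numeric(assumed)))
  }
  # string value list
  if (grepl('^"', s)) {
    vals <- regmatches(s, gregexpr('"(\\\\.|[^"\\\\])*"', s))[[1]]
    leftover <- gsub('"(\\\\.|[^"\\\\])*"', "", s)
    if (!grepl("^[\\s,]*$", leftover, perl = TRUE)) fail(s)
    return(new_primitive("String",
                         allowed_values = unname(vapply(vals, unquote_adl, "")),
                         assumed_value = assumed))
  }
  # Boolean list
  if (grepl("^(True|False)(\\s*,\\s*(True|False))*$", s)) {
    vals <- unique(trimws(strsplit(s, ",", fixed = TRUE)[[1]])) == "True"
    return(new_primitive("Boolean", allowed_values = vals,
                         assumed_value = if (is.null(assumed)) NULL
                                         else identical(assumed, "True")))
  }
  # numeric value list
  if (grepl("^-?[0-9]", s)) {
    toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    if (!all(grepl("^-?[0-9]+(\\.[0-9]+)?$", toks))) fail(s)
    real <- any(grepl("\\.", toks))
    return(new_primitive(if (real) "Real" else "Integer",
                         allowed_values = as.numeric(toks),
                         assumed_value = if (is.null(assumed)) NULL
                                         else as.numeric(assumed)))
  }
  # date / time / date-time format masks; duration pattern masks
  if (is_datetime_mask(s))
    return(new_primitive("Date_Time", pattern = s, assumed_value = assumed))
  if (is_date_mask(s))
    return(new_primitive("Date", pattern = s, assumed_value = assumed))
  if (is_time_mask(s))
    return(new_primitive("Time", pattern = s, assumed_value = assumed))
  if (grepl("^P[yYmMwWdDtThHsS]*$", s))
    return(new_primitive("Duration", pattern = s, enforceable = FALSE,
                         assumed_value = assumed))
  fail(s)
}

# ---- post-parse validation -----------------------------------------------

check_parsed_archetype <- function(a) {
  terms <- names(a$ontology$terms)
  check_node <- function(node) {
    if (!inherits(node, "adl_node")) return(invisible())
    if (nzchar(node$node_id) && !(node$node_id %in% terms))
      stop("node id '", node$node_id,
           "' has no term definition in the ontology", call. = FALSE)
    for (attr in node$attributes) {
      ids <- vapply(attr$children, function(ch) {
        if (!is.null(ch$node_id)) ch$node_id else ""
      }, "")
      ids <- ids[nzchar(ids)]
      if (anyDuplicated(ids))
        stop("duplicate node id '", ids[duplicated(ids)][1],
             "' among siblings under attribute '", attr$name, "'",
             call. = FALSE)
      for (ch in attr$children) {
        if (inherits(ch, "adl_slot") && nzchar(ch$node_id) &&
            !(ch$node_id %in% terms))
          stop("node id '", ch$node_id,
               "' has no term definition in the ontology", call. = FALSE)
        check_node(ch)
      }
    }
    invisible()
  }
  check_node(a$definition)
  invisible(a)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
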