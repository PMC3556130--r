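# dADL block parsing for the ontology section (term_definitions and
# term_bindings) and assembly into the ontology model.

parse_dadl <- function(cur) {
  open_idx <- cur$i
  expect_tok(cur, "punct", "<")
  # decide: map of entries vs literal content
  is_map <- FALSE
  if (cur_type(cur) == "ident" && at_tok_at(cur, 1L, "punct", "=")) {
    is_map <- TRUE
  } else if (at_tok(cur, "punct", "[")) {
    # find the matching ']' and check for '='
    j <- cur$i
    depth <- 0L
    while (j <= cur$toks$n) {
      v <- cur$toks$values[j]
      if (cur$toks$types[j] == "punct") {
        if (v == "[") depth <- depth + 1L
        if (v == "]") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
      }
      j <- j + 1L
    }
    if (j < cur$toks$n && cur$toks$types[j + 1L] == "punct" &&
        cur$toks$values[j + 1L] == "=")
      is_map <- TRUE
  }
  if (!is_map) {
    close_idx <- matching_angle(cur, open_idx)
    raw <- trimws(raw_span(cur, cur$i, close_idx - 1L))
    cur$i <- close_idx + 1L
    return(list(kind = "literal", raw = raw))
  }
  entries <- list()
  while (!at_tok(cur, "punct", ">")) {
    key <- parse_dadl_key(cur)
    expect_tok(cur, "punct", "=")
    entries[[key]] <- parse_dadl(cur)
  }
  expect_tok(cur, "punct", ">")
  list(kind = "map", entries = entries)
}

at_tok_at <- function(cur, k, type, value) {
  cur_type(cur, k) == type && cur_value(cur, k) == value
}

parse_dadl_key <- function(cur) {
  if (cur_type(cur) == "ident") return(advance(cur))
  expect_tok(cur, "punct", "[")
  key <- if (cur_type(cur) == "string") unquote_adl(advance(cur)) else advance(cur)
  expect_tok(cur, "punct", "]")
  key
}

dadl_text <- function(node, default = "") {
  if (is.null(node)) return(default)
  if (identical(node$kind, "literal")) {
    raw <- node$raw
    if (grepl('^"', raw)) return(unquote_adl(raw))
    return(raw)
  }
  default
}

parse_ontology <- function(cur) {
  terms <- list(); bindings <- list()
  while (cur_type(cur) != "eof") {
    if (cur_type(cur) != "ident" ||
        !(cur_value(cur) %in% c("term_definitions", "term_bindings")))
      cur_error(cur, "expected 'term_definitions' or 'term_bindings'")
    what <- advance(cur)
    expect_tok(cur, "punct", "=")
    block <- parse_dadl(cur)
    if (!identical(block$kind, "map"))
      cur_error(cur, paste0("malformed ", what, " block"))
    if (what == "term_definitions") {
      # language -> (items ->) code -> {text, description}
      for (lang in names(block$entries)) {
        lang_block <- block$entries[[lang]]
        items <- lang_block$entries$items %||% lang_block
        if (!identical(items$kind, "map")) next
        for (code in names(items$entries)) {
          e <- items$entries[[code]]$entries
          if (is.null(terms[[code]]))
            terms[[code]] <- list(text = dadl_text(e$text),
                                  description = dadl_text(e$description))
        }
      }
    } else {
      for (terminology in names(block$entries)) {
        t_block <- block$entries[[terminology]]
        items <- t_block$entries$items %||% t_block
        if (!identical(items$kind, "map")) next
        codes <- list()
        for (code in names(items$entries)) {
          raw <- dadl_text(items$entries[[code]])
          codes[[code]] <- gsub("^\\[|\\]$", "", raw)
        }
        bindings[[terminology]] <- codes
      }
    }
  }
  new_ontology(terms, bindings)
}
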