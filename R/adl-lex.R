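# Tokenizer for the supported ADL 1.4 subset.
#
# Comments ("--" to end of line) and whitespace are skipped; every token
# records its line/column so parse errors can point at the source.

adl_lex <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  rules <- list(
    list(type = "ws",      re = "^[ \t\r\n]+"),
    list(type = "comment", re = "^--[^\n]*"),
    list(type = "string",  re = "^\"(\\\\.|[^\"\\\\])*\""),
    list(type = "dotdot",  re = "^\\.\\."),
    list(type = "number",  re = "^-?[0-9]+(\\.[0-9]+)?"),
    list(type = "ident",   re = "^[A-Za-z][A-Za-z0-9_]*([.-][A-Za-z0-9_]+)*"),
    list(type = "coloncolon", re = "^::"),
    list(type = "punct",   re = "^[{}<>\\[\\]()=,;*|/:]"),
    # characters only legal inside raw blocks (regex bodies, masks); the
    # parser rejects them anywhere else
    list(type = "other",   re = "^[^ \t\r\n]")
  )
  n <- nchar(text)
  pos <- 1L; line <- 1L; col <- 1L
  types <- character(); values <- character()
  lines <- integer(); cols <- integer(); starts <- integer(); ends <- integer()
  while (pos <= n) {
    rest <- substr(text, pos, n)
    hit <- NULL
    for (rule in rules) {
      m <- regexpr(rule$re, rest, perl = TRUE)
      if (m == 1L) {
        hit <- list(type = rule$type,
                    value = substr(rest, 1L, attr(m, "match.length")))
        break
      }
    }
    if (is.null(hit))
      stop(sprintf("ADL syntax error at line %d, column %d: unexpected '%s'",
                   line, col, substr(rest, 1, 1)), call. = FALSE)
    len <- nchar(hit$value)
    if (!hit$type %in% c("ws", "comment")) {
      k <- length(types) + 1L
      types[k] <- hit$type; values[k] <- hit$value
      lines[k] <- line; cols[k] <- col
      starts[k] <- pos; ends[k] <- pos + len - 1L
    }
    nl <- gregexpr("\n", hit$value, fixed = TRUE)[[1]]
    if (nl[1] != -1L) {
      line <- line + length(nl)
      col <- len - max(nl) + 1L
    } else {
      col <- col + len
    }
    pos <- pos + len
  }
  list(types = types, values = values, lines = lines, cols = cols,
       starts = starts, ends = ends, src = text, n = length(types))
}

# Parser cursor over a token stream.
new_cursor <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env
}

cur_type  <- function(cur, k = 0L) {
  i <- cur$i + k
  if (i > cur$toks$n) "eof" else cur$toks$types[i]
}
cur_value <- function(cur, k = 0L) {
  i <- cur$i + k
  if (i > cur$toks$n) "" else cur$toks$values[i]
}

cur_error <- function(cur, msg) {
  if (cur$i > cur$toks$n)
    stop("ADL syntax error at end of input: ", msg, call. = FALSE)
  stop(sprintf("ADL syntax error at line %d, column %d (near '%s'): %s",
               cur$toks$lines[cur$i], cur$toks$cols[cur$i],
               cur$toks$values[cur$i], msg), call. = FALSE)
}

advance <- function(cur) {
  v <- cur_value(cur)
  cur$i <- cur$i + 1L
  v
}

expect_tok <- function(cur, type, value = NULL) {
  if (cur_type(cur) != type ||
      (!is.null(value) && cur_value(cur) != value))
    cur_error(cur, paste0("expected ",
                          if (is.null(value)) type else paste0("'", value, "'")))
  advance(cur)
}

at_tok <- function(cur, type, value = NULL) {
  cur_type(cur) == type && (is.null(value) || cur_value(cur) == value)
}

# Raw source text spanned by tokens [from, to] (token indices, inclusive).
raw_span <- function(cur, from, to) {
  if (to < from) return("")
  substr(cur$toks$src, cur$toks$starts[from], cur$toks$ends[to])
}

# Index of the '}' matching an opening '{' at token index `open`.
matching_brace <- function(cur, open) {
  depth <- 0L
  for (i in open:cur$toks$n) {
    v <- cur$toks$values[i]
    if (cur$toks$types[i] == "punct") {
      if (v == "{") depth <- depth + 1L
      if (v == "}") {
        depth <- depth - 1L
        if (depth == 0L) return(i)
      }
    }
  }
  cur$i <- open
  cur_error(cur, "unbalanced '{'")
}

unquote_adl <- function(s) {
  s <- sub('^"', "", sub('"$', "", s))
  gsub('\\\\(["\\\\])', "\\1", s)
}
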