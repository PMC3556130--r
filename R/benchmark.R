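# External benchmark runner: integration verdicts for a user-supplied
# directory of library archetypes.
#
# The shipped reference table records, per archetype id, whether
# integration into the flat-table form model succeeded in the original
# evaluation of the 27-archetype test set. Library archetypes drift across
# revisions, so the runner reports per-archetype agreement rather than
# silently absorbing differences; it never downloads anything.

#' Reference verdicts for the 27-archetype evaluation set
#' @return data frame with columns `archetype_id` and `expected` ("Yes" if
#'   integration succeeded, "No" if it failed on nested repeating nodes).
#' @export
benchmark_reference <- function() {
  path <- system.file("extdata", "benchmark_verdicts.csv",
                      package = "archeform", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify one archetype: can it be integrated?
#'
#' Parses, resolves references, augments and checks support. Slots are
#' resolved against the other archetypes in the supplied set.
#'
#' @param a an `archetype` or ADL text.
#' @param s an `rm_schema`.
#' @param resolver slot resolver over the candidate set.
#' @return a list: `verdict` ("Yes"/"No"/"Error"), `reasons` (violation
#'   kinds for "No", condition message for "Error").
#' @export
integration_verdict <- function(a, s = rm_schema(), resolver = NULL) {
  tryCatch({
    if (!inherits(a, "archetype")) a <- parse_adl(a)
    ca <- augment(resolve_internal_refs(a), s)
    viol <- check_supported(ca, generation_config(), s, resolver)
    fails <- viol[viol$severity == "failure", , drop = FALSE]
    if (nrow(fails) == 0L) list(verdict = "Yes", reasons = character())
    else list(verdict = "No", reasons = unique(fails$kind))
  }, error = function(e) list(verdict = "Error",
                              reasons = conditionMessage(e)))
}

#' Run the integration benchmark over a directory of .adl files
#'
#' @param dir directory containing the downloaded library archetypes.
#' @param s an `rm_schema`.
#' @return a data frame with one row per reference archetype:
#'   `archetype_id`, `expected`, `found` (file present), `verdict`,
#'   `reasons`, `agrees`. Archetype revisions that drifted from the
#'   originally evaluated files are visible as per-row disagreements.
#' @export
table3_benchmark <- function(dir, s = rm_schema()) {
  ref <- benchmark_reference()
  files <- list.files(dir, pattern = "\\.adl$", full.names = TRUE)
  parsed <- list()
  for (f in files) {
    a <- tryCatch(read_adl(f), error = function(e) e)
    if (inherits(a, "archetype")) parsed[[a$archetype_id]] <- a
  }
  resolver <- function(id) parsed[[id]]
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    id <- ref$archetype_id[i]
    a <- parsed[[id]]
    if (is.null(a)) {
      return(data.frame(archetype_id = id, expected = ref$expected[i],
                        found = FALSE, verdict = NA_character_,
                        reasons = "file not supplied or unparseable",
                        agrees = NA, stringsAsFactors = FALSE))
    }
    v <- integration_verdict(a, s, resolver)
    data.frame(archetype_id = id, expected = ref$expected[i], found = TRUE,
               verdict = v$verdict,
               reasons = paste(v$reasons, collapse = ";"),
               agrees = identical(v$verdict, ref$expected[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
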