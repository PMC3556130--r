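#!/usr/bin/env Rscript
# Integration benchmark over a user-supplied directory of openEHR library
# archetypes (.adl, ADL 1.4):
#   Rscript scripts/table3_benchmark.R <dir> [--out report.csv]
# Classifies each archetype of the 27-archetype reference set found in
# <dir> (integration possible: Yes/No) and reports agreement with the
# shipped reference verdicts per archetype. Library revisions drift, so
# disagreements are expected to be inspected, not absorbed.

suppressPackageStartupMessages(library(archeform))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: Rscript scripts/table3_benchmark.R <dir> [--out report.csv]")
dir <- args[1]
out <- if (length(args) >= 3L && args[2] == "--out") args[3] else NULL

res <- table3_benchmark(dir)
print(res, right = FALSE)
cat(sprintf("\nfound: %d/%d, agreement among found: %d/%d\n",
            sum(res$found), nrow(res),
            sum(res$agrees, na.rm = TRUE), sum(res$found)))
if (!is.null(out)) {
  utils::write.csv(res, out, row.names = FALSE)
  cat("wrote", out, "\n")
}
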