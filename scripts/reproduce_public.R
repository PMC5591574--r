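#!/usr/bin/env Rscript

# Out-of-CI reproduction on recorded data.
#
# The healthy-participant recordings used to validate this kind of system
# are published in a public repository (EyeWriting/EyewritingNumber on
# GitHub). Their on-disk layout is not documented alongside the recordings,
# so this script does not guess it: point it at a local clone plus a
# manifest you prepare (participant,trial,digit,path) and a channel-column
# layout, and it runs the full pipeline and leave-one-subject-out
# evaluation. Expect accuracies in the low-to-mid 90s (percent) for
# DPW+SVM if the layout and units are mapped correctly.
#
# Usage:
#   Rscript scripts/reproduce_public.R --root <dir> --manifest <csv> \
#     [--layout left,right,above,below] [--theta 120] [--out report.json]

suppressPackageStartupMessages(library(eyescript))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(
  root = NULL, manifest = NULL, layout = "left,right,above,below",
  theta = 120, out = "public_report.json"
)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
if (is.null(opt$root) || is.null(opt$manifest)) {
  stop("both --root and --manifest are required; see the header of this script")
}
cols <- strsplit(opt$layout, ",")[[1]]
if (length(cols) != 4L) stop("--layout must name four columns")
layout <- c(left = cols[1], right = cols[2], above = cols[3], below = cols[4])

ds <- load_dataset(opt$root, opt$manifest, layout = layout)
cfg <- reconstruct_config(theta = as.numeric(opt$theta))
traces <- lapply(ds$recordings, function(r) {
  tryCatch(reconstruct(r, cfg), error = function(e) NULL)
})
cat(sprintf(
  "%d recordings, %d failed reconstructions\n",
  length(traces), sum(vapply(traces, is.null, logical(1)))
))
for (m in c("dtw", "dpw")) {
  for (s in c(FALSE, TRUE)) {
    rep <- loso_evaluate(
      traces, ds$index$digit, ds$index$participant,
      measure = m, svm = s
    )
    cat(sprintf(
      "%s%s: %.2f%%\n", toupper(m), if (s) "+SVM" else "",
      100 * rep$overall_acc
    ))
    if (m == "dpw" && s) write_report(rep, opt$out)
  }
}
cat(sprintf("wrote %s\n", opt$out))
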