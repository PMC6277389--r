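# Shared header for the analysis drivers: fixes the run seed, creates the
# results directory, and caches the synthetic library so that later drivers
# reuse the exact objects computed by earlier ones.

library(bamscope)

SEED <- 1L
RESULTS <- file.path("results")
CACHE <- file.path(RESULTS, "cache")
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

# load a cached stage output, computing and caching it on first use
cached <- function(name, expr) {
  path <- file.path(CACHE, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- expr
  saveRDS(value, path)
  value
}
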