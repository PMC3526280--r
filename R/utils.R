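# internal utilities

# Atomic file write: `writer(tmp)` produces the file at a temp path in the
# same directory, which is then renamed over `path`.  Keeps partial pipeline
# runs inspectable: an artifact either exists complete or not at all.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path), ".tmp"))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path, call. = FALSE)
  invisible(path)
}

# Deterministic child seeds so that each randomised stage of a run has an
# independent stream derived from the one user-facing seed.  Kept below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  x <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    x <- (x * 31 + ch) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
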