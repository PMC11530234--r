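# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# 12 significant digits for all floating-point TSV output; lossless round-trip
fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

# write a data.frame as TSV atomically (tempfile in target dir, then rename)
write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  out <- df
  dbl <- vapply(out, is.double, logical(1))
  out[dbl] <- lapply(out[dbl], fmt_num)
  utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_tsv_plain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# run expr with a private RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library calls do not perturb user simulations
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
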