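# internal validation and RNG helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assert_number <- function(x, name, min = -Inf, max = Inf,
                           strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x), call. = FALSE)
  as.numeric(x)
}

.assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One root seed deterministically spawns child seeds (kept below 2^31) so
# stages / resamples can be re-run in isolation with identical results.
.spawn_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# 12 significant digits: enough that digests are stable across platforms,
# short enough to keep TSV outputs readable.
.fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  is_num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[is_num] <- lapply(df[is_num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
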