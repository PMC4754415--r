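# Internal helpers shared across modules.

# Deterministic 32-bit substream seed derived from a master seed and a string
# key. Used to give each fish / dyad / reaction its own reproducible RNG
# stream, so that subsetting a design does not shift other units' draws.
substream_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master))
  chars <- utf8ToInt(paste0(key, "#", format(master, scientific = FALSE)))
  h <- 0
  for (ch in chars) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under a temporary seed, restoring global RNG state
# afterwards (lean equivalent of withr::with_seed; called very often in the
# simulator, so kept allocation-free).
with_substream <- function(master, key, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(),
                          inherits = FALSE)
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(substream_seed(master, key))
  expr
}

# All permutations of 1..n as an (n! x n) integer matrix, lexicographic in
# construction order. Only used for small n (QAP exhaustive mode, n <= 8).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(p) + seq_len(nrow(p))
    out[rows, ] <- cbind(i, p + (p >= i))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable CSV writer used by every stage (fixed settings => byte-stable reruns)
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
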