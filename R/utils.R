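# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded operations do not perturb the
# global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# All permutations of 1..n as an n! x n integer matrix (used by the exact
# Spearman permutation null; n is capped by the caller).
all_permutations <- function(n) {
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      out[[i]] <- cbind(v[i], perm_rec(v[-i]), deparse.level = 0)
    }
    do.call(rbind, out)
  }
  perm_rec(seq_len(n))
}
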