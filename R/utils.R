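# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded components stay independently reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed derived from a master seed; keeps values inside
# the 32-bit integer range expected by set.seed().
child_seed <- function(seed, stream) {
  x <- (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483563
  as.integer(x) + 1L
}

# Overflow-safe log(2 cosh(h)).
log2cosh <- function(h) {
  a <- abs(h)
  a + log1p(exp(-2 * a))
}

# Canonical key for a disease subset: "" for the all-healthy hypothesis,
# otherwise sorted 1-based disease indices joined by commas.
hypothesis_key <- function(hypothesis) {
  idx <- which(hypothesis == 1L)
  if (length(idx) == 0L) "" else paste(sort(idx), collapse = ",")
}

# Inverse of hypothesis_key().
key_to_hypothesis <- function(key, n_diseases) {
  d <- integer(n_diseases)
  if (nzchar(key)) {
    idx <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    d[idx] <- 1L
  }
  d
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

assert_sign_config <- function(values, n_signs = NULL, what = "sign configuration") {
  if (!is.numeric(values) || anyNA(values) || !all(values %in% c(-1, 1))) {
    stopf("%s must contain only values -1 and +1", what)
  }
  if (!is.null(n_signs) && length(values) != n_signs) {
    stopf("%s has length %d, expected %d", what, length(values), n_signs)
  }
  invisible(as.integer(values))
}

assert_disease_config <- function(values, n_diseases = NULL) {
  if (!is.numeric(values) || anyNA(values) || !all(values %in% c(0, 1))) {
    stopf("disease configuration must contain only values 0 and 1")
  }
  if (!is.null(n_diseases) && length(values) != n_diseases) {
    stopf("disease configuration has length %d, expected %d",
          length(values), n_diseases)
  }
  invisible(as.integer(values))
}

# All 2^n binary configurations as an (2^n x n) 0/1 integer matrix, row
# order fixed (row r encodes r-1 in binary, least significant bit first).
enumerate_binary <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# All 2^n sign configurations (+/-1), same ordering convention.
enumerate_signs <- function(n) {
  m <- enumerate_binary(n)
  m * 2L - 1L
}
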