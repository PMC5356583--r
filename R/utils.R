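## internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
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
  force(code)
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_scalar(x, name)
  if (x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must be a matrix with gene rownames and sample colnames", name),
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

# z-score the rows of a matrix; zero-variance rows become all-zero
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0] <- 1
  (x - mu) / s
}
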