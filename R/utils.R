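# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# any pre-existing global state afterwards. All package randomness funnels
# through this so that no user-visible RNG state is disturbed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("suaseg_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(name, " must be a numeric matrix")
  }
  invisible(x)
}

assert_probabilities <- function(x, name = deparse(substitute(x))) {
  assert_matrix(x, name)
  if (anyNA(x) || any(!is.finite(x))) {
    stop_invalid(name, " contains non-finite values")
  }
  if (any(x < 0) || any(x > 1)) {
    stop_invalid(name, " has values outside [0, 1]")
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop_invalid(what, " must share one shape; got ",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x"))
  }
  invisible(NULL)
}

# Binary (Shannon) entropy in nats with the 0 log 0 = 0 convention.
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -(q * log(q) + (1 - q) * log(1 - q))
  dim(h) <- dim(p)
  h
}

# Inverse of binary_entropy on the upper branch p in [0.5, 1]:
# the probability >= 0.5 whose entropy equals e.
entropy_inverse <- function(e) {
  stopifnot(all(e >= 0), all(e <= log(2) + 1e-12))
  vapply(e, function(ei) {
    if (ei >= log(2)) return(0.5)
    if (ei <= 0) return(1)
    stats::uniroot(
      function(p) -(p * log(p) + (1 - p) * log(1 - p)) - ei,
      lower = 0.5, upper = 1 - 1e-12, tol = 1e-12
    )$root
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
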