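#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  expr
}

abort_validation <- function(msg, class = "mtoscca_validation_error") {
  stop(structure(
    class = c(class, "mtoscca_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_numerical <- function(msg) {
  abort_validation(msg, class = "mtoscca_numerical_error")
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= lower) {
    abort_validation(sprintf("`%s` must be > %s (got %s)", name, lower, x))
  }
  if (!strict && x < lower) {
    abort_validation(sprintf("`%s` must be >= %s (got %s)", name, lower, x))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_validation(sprintf("`%s` must be an integer (got %s)", name, x))
  }
  invisible(x)
}

check_binary_labels <- function(labels, n = NULL) {
  if (!is.numeric(labels) && !is.logical(labels)) {
    abort_validation("labels must be a numeric or logical 0/1 vector")
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    abort_validation("labels must contain only 0 and 1 with no missing values")
  }
  if (!is.null(n) && length(labels) != n) {
    abort_validation(sprintf(
      "labels have length %d but %d samples are present", length(labels), n
    ))
  }
  labels
}
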