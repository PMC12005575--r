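#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All seeded operations in the package
# go through this so that a fixed seed gives bit-identical output regardless
# of surrounding RNG use.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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

# Derive a deterministic child seed from a base seed and a purpose label,
# kept below 2^31 so it is a valid R integer. Adding a purpose never
# perturbs another purpose's stream.
derive_seed <- function(seed, purpose) {
  stopifnot(is.character(purpose), length(purpose) == 1L)
  h <- utils::head(utf8ToInt(purpose), 16L)
  x <- (as.double(seed) %% 2147483647) + 1
  for (ch in h) {
    x <- (x * 69069 + ch) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_config("%s must be finite and nonnegative", what)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_config("%s must sum to 1 (got %.12f)", what, sum(p))
  }
  invisible(p)
}

check_sex <- function(sex) {
  if (!(is.character(sex) && length(sex) == 1L && sex %in% c("male", "female"))) {
    stop_config("sex must be \"male\" or \"female\"")
  }
  sex
}

# Draw from a Gaussian truncated to [lower, upper] by inverse-CDF, which is
# vectorised and keeps draw counts (hence reproducibility) independent of
# the truncation bounds.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
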