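#' @keywords internal
"_PACKAGE"

# Stable 31-adic string hash, folded into [0, 2^31 - 2]. Used to derive
# independent child seeds from one root seed so that adding a generator
# never perturbs the random stream of another.
hash_string <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a child seed from a root seed and a stream name
#'
#' Every stochastic generator in the package draws from its own stream,
#' seeded by `child_seed(root, name)`. Streams are independent of the order
#' in which generators are called.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  as.integer((as.numeric(seed) + hash_string(name)) %% 2147483647)
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Round half-up to a fixed number of decimals
#'
#' Unlike [round()] (banker's rounding), ties go away from zero, matching the
#' print style of clinical frequency tables (e.g. 59.185 -> 59.19).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated-normal draw by rejection: resample until >= lower. Doses are
# positive with a hard per-herb floor, so the truncation mass is small.
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}
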