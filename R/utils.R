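# internal helpers: seed management, matrix square roots, logit utilities

#' Derive a child seed from a master seed and an index
#'
#' The engine gives every scenario (and every iteration within a scenario) its
#' own random stream derived deterministically from one master seed, so that
#' scenarios are independent work units: results are identical whether they
#' run serially or concurrently.
#'
#' @param seed master seed (integer-valued).
#' @param index non-negative integer index of the child stream.
#' @param salt optional second index (e.g. iteration within scenario).
#' @return an integer seed in `[1, 2^31 - 20]`.
#' @export
derive_seed <- function(seed, index, salt = 0L) {
  # affine congruential mix; all arithmetic exact in doubles (< 2^53)
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  v <- (s * 48271 + as.double(index) * 69621 + as.double(salt) * 40692) %%
    2147483629
  as.integer(v + 1)
}

# Evaluate code under a given seed, restoring the caller's RNG state after.
# seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Right factor M with t(M) %*% M = omega, tolerant of PSD (singular) omega.
psd_sqrt <- function(omega, tol = 1e-8) {
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(omega, symmetric = TRUE)
  if (min(e$values) < -tol) {
    stop("covariance matrix is not positive semi-definite within tolerance")
  }
  diag(sqrt(pmax(e$values, 0)), nrow = length(e$values)) %*% t(e$vectors)
}

# Intercept b0 such that mean(plogis(b0 + eta)) == prev.
tune_intercept <- function(eta, prev) {
  uniroot(function(b) mean(plogis(b + eta)) - prev,
          lower = -40, upper = 40, tol = 1e-10)$root
}

# Population (outcome-marginalised) concordance of a risk score eta with true
# event probabilities p: P(eta_case > eta_control) computed by a single sort,
# with ties contributing zero mass (eta is continuous in all uses).
population_cstat <- function(eta, p) {
  o <- order(eta)
  p <- p[o]
  n <- length(p)
  cs <- cumsum(1 - p)
  num <- sum(p * c(0, cs[-n]))
  den <- sum(p) * sum(1 - p) - sum(p * (1 - p))
  num / den
}

clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
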