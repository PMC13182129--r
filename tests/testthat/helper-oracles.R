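# Independent oracles used to cross-check the package's compiled routines.
# These deliberately take different computational routes (general-purpose
# optimisation, exhaustive enumeration, direct arithmetic).

# logistic MLE by direct likelihood maximisation with a generic optimiser
oracle_logistic <- function(x, y, start = NULL) {
  x <- cbind(1, as.matrix(x))
  softplus <- function(e) ifelse(e > 30, e, log1p(exp(pmax(e, -30))))
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(y * eta - softplus(eta))
  }
  gr <- function(b) {
    p <- plogis(drop(x %*% b))
    -drop(crossprod(x, y - p))
  }
  start <- start %||% rep(0, ncol(x))
  o <- stats::optim(start, nll, gr, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 500))
  # polish with a few Newton steps for near-machine accuracy
  b <- o$par
  for (i in 1:25) {
    p <- plogis(drop(x %*% b))
    g <- drop(crossprod(x, y - p))
    h <- crossprod(x * (p * (1 - p)), x)
    b <- b + solve(h, g)
    if (max(abs(g)) < 1e-12) break
  }
  eta <- drop(x %*% b)
  list(coef = b, loglik = sum(y * eta - softplus(eta)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# concordance by exhaustive pair counting
oracle_cstat <- function(p_hat, y) {
  ev <- p_hat[y == 1]; ne <- p_hat[y == 0]
  tot <- 0; conc <- 0
  for (a in ev) for (b in ne) {
    tot <- tot + 1
    conc <- conc + (a > b) + 0.5 * (a == b)
  }
  conc / tot
}

# quantiles by manual sort-and-interpolate (type-7 definition, written out)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# fully independent bootstrap-shrinkage loop: same index-generation scheme
# (floor of uniform draws) so a shared seed yields the same resamples, but
# refits and slopes go through stats::glm
oracle_s_boot <- function(x, y, b) {
  n <- length(y)
  slopes <- rep(NA_real_, b)
  for (i in seq_len(b)) {
    idx <- floor(runif(n) * n) + 1
    idx[idx > n] <- n
    yb <- y[idx]
    if (all(yb == 0) || all(yb == 1)) next
    fit <- suppressWarnings(
      glm.fit(cbind(1, x[idx, , drop = FALSE]), yb, family = binomial(),
              control = list(epsilon = 1e-14, maxit = 200)))
    lp <- drop(cbind(1, x) %*% fit$coefficients)
    cal <- suppressWarnings(
      glm.fit(cbind(1, lp), y, family = binomial(),
              control = list(epsilon = 1e-14, maxit = 200)))
    slopes[i] <- cal$coefficients[2]
  }
  mean(slopes, na.rm = TRUE)
}

# evaluate `code` under a seed, restoring the ambient RNG state, so oracles
# can share a resampling stream with the routine they check
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# a small, well-behaved scenario used across engine tests
toy_scenario <- function(q_meas = 2L, n_dev = 5000L, prop = 0.3,
                         beta = c(0.5, -0.4)) {
  structure(list(q_meas = q_meas, q_unmeas = 0L, beta = beta,
                 beta0 = qlogis(prop), omega = diag(q_meas), prop = prop,
                 n_dev = as.integer(n_dev), covariance_mode = "identity",
                 dgm = "default", target_c = NA_real_, seed = NA_integer_),
            class = "shrink_scenario")
}
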