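## R-side driver for the package's No-U-Turn HMC engine: multi-chain runs,
## jittered initial values, and split-Rhat convergence diagnostics.

#' Sampler settings for the Bayesian models
#'
#' Defaults follow the package-wide convention of four independent chains,
#' each with 1000 warmup iterations and 1000 retained draws.
#'
#' @param chains number of chains.
#' @param warmup warmup iterations per chain.
#' @param draws retained draws per chain.
#' @param max_treedepth NUTS maximum tree depth.
#' @param adapt_delta target acceptance statistic.
#' @param seed integer seed.
#' @export
sampler_settings <- function(chains = 4L, warmup = 1000L, draws = 1000L,
                             max_treedepth = 10L, adapt_delta = 0.8,
                             seed = 1L) {
  as.list(environment())
}

## run one model over several chains; returns stacked draws plus diagnostics
run_nuts <- function(model_id, data, init_fun, settings = sampler_settings(),
                     par_names = NULL) {
  chains <- lapply(seq_len(settings$chains), function(ch) {
    with_seed(settings$seed * 1000L + ch, {
      init <- init_fun()
      .nuts_chain(model_id, data, init,
                  as.integer(settings$warmup), as.integer(settings$draws),
                  as.integer(settings$max_treedepth), settings$adapt_delta)
    })
  })
  draws_by_chain <- lapply(chains, `[[`, "draws")
  draws <- do.call(rbind, draws_by_chain)
  if (!is.null(par_names)) colnames(draws) <- par_names
  rhat <- split_rhat(draws_by_chain)
  if (!is.null(par_names)) names(rhat) <- par_names
  divergences <- sum(vapply(chains, `[[`, numeric(1), "divergences"))
  converged <- all(rhat < 1.01, na.rm = TRUE) && divergences == 0
  warnings_out <- character(0)
  if (any(rhat > 1.01, na.rm = TRUE))
    warnings_out <- c(warnings_out, sprintf(
      "NON-CONVERGENCE: %d parameter(s) with split-Rhat > 1.01 (max %.3f)",
      sum(rhat > 1.01, na.rm = TRUE), max(rhat, na.rm = TRUE)))
  if (divergences > 0)
    warnings_out <- c(warnings_out, sprintf(
      "NON-CONVERGENCE: %d divergent transition(s) after warmup", divergences))
  for (w in warnings_out) warning(w, call. = FALSE)
  list(draws = draws, lp = unlist(lapply(chains, `[[`, "lp")),
       rhat = rhat, divergences = divergences, converged = converged,
       warnings = warnings_out,
       n_chains = settings$chains, n_draws_per_chain = settings$draws,
       stepsize = vapply(chains, `[[`, numeric(1), "stepsize"),
       accept_stat = vapply(chains, `[[`, numeric(1), "accept_stat"))
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, per parameter.
#'
#' @param draws_by_chain list of iterations x parameters matrices, one per
#'   chain.
#' @return numeric vector of Rhat values, one per parameter.
#' @export
split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (d in draws_by_chain) {
    n <- nrow(d)
    h <- floor(n / 2)
    halves <- c(halves, list(d[seq_len(h), , drop = FALSE],
                             d[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(x) apply(x, 2, var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1)
                             vars <- matrix(vars, nrow = 1) }
  B <- n * apply(means, 1, var)
  W <- rowMeans(vars)
  vhat <- (n - 1) / n * W + B / n
  out <- sqrt(vhat / W)
  out[W == 0] <- NA_real_
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Cholesky factor of a (numerically) positive semidefinite matrix
#'
#' Attempts a direct Cholesky after adding a 1e-8 diagonal jitter; on
#' failure, clips negative eigenvalues at zero (symmetric eigenvalue repair)
#' and retries.
#'
#' @param S symmetric matrix.
#' @return lower-triangular factor `L` with `L %*% t(L) ~ S`.
#' @export
chol_psd <- function(S, jitter = 1e-8) {
  S <- (S + t(S)) / 2
  out <- tryCatch(t(chol(S + diag(jitter, nrow(S)))), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(S, symmetric = TRUE)
    v <- pmax(e$values, 0)
    S2 <- e$vectors %*% (v * t(e$vectors))
    out <- t(chol((S2 + t(S2)) / 2 + diag(jitter, nrow(S))))
  }
  out
}
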