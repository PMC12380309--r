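#' Fit the covariate-modulated movement HMM
#'
#' Maximum a posteriori estimation of all free parameters of the `K`-state
#' movement HMM from one or more movement series, under weakly informative
#' priors scale-matched to a 30 cm arena. The cliff influence pair is held
#' fixed at 6 cm / -1; the state-ordering constraint
#' `m_1 < ... < m_K` is enforced through the parameterization. Optimisation
#' uses multi-start L-BFGS-B on the unconstrained scale (a short exploratory
#' stage for every start, then a full polish of the best start), with the
#' exact forward log-likelihood in compiled code. Uncertainty comes from a
#' Laplace approximation at the mode (89% intervals, the reporting
#' convention used throughout), optionally refined by adaptive random-walk
#' Metropolis sampling.
#'
#' Priors: `log m_k ~ N(log 1, 1.5)`; `log a_k ~ N(0, 1)`;
#' `atanh(rho) ~ N(0, 1)`; transition intercepts and slopes `~ N(0, 2.5)`;
#' `x_edge, x_center ~ N(5, 10)` truncated positive; `beta_edge, beta_center
#' ~ N(-1, 1)` truncated negative.
#'
#' @param series A `movement_series` or a list of them (sessions are
#'   independent chains sharing parameters).
#' @param K Number of states (default 3).
#' @param starts Number of random starts (default 5).
#' @param seed Integer seed controlling the random starts (and the Laplace
#'   draws); refitting with the same seed and data reproduces the estimates.
#' @param init Optional [cliff_hmm_params()] used as the first start.
#' @param se Compute the Laplace covariance, 89% intervals and posterior
#'   draws (default `TRUE`).
#' @param n_draws Number of Laplace (or Metropolis) draws kept (default 1000).
#' @param mcmc Refine uncertainty by adaptive random-walk Metropolis?
#'   (default `FALSE`).
#' @param mcmc_iter Metropolis iterations (post warm-up draws are thinned to
#'   `n_draws`).
#' @param control List: `maxit_stage1` (default 30), `maxit` (default 500),
#'   `factr` passed to [optim()].
#' @param verbose Print per-start progress.
#' @return An object of class `cliff_hmm` with components `par`
#'   ([cliff_hmm_params()] point estimates), `theta` (unconstrained mode),
#'   `loglik`, `logpost`, `vcov` (unconstrained Laplace covariance), `ci`
#'   (89% intervals on the natural scale), `draws` (natural-scale draws),
#'   `convergence`, `opt_trace` (best objective per start), `seed`, and the
#'   data used.
#' @seealso [decode()], [state_profile()], [cliff_effect()],
#'   [posterior_predictive()], [simulate_session()]
#' @export
cliff_hmm <- function(series, K = 3, starts = 5, seed = 1, init = NULL,
                      se = TRUE, n_draws = 1000, mcmc = FALSE, mcmc_iter = 4000,
                      control = list(), verbose = FALSE) {
  sl <- as_series_list(series)
  dat <- flatten_series(sl)
  n_steps <- sum(dat$sess_len)
  if (n_steps < 1) stop("no steps to fit")
  ctl <- modifyList(list(maxit_stage1 = 30, maxit = 500, factr = 1e8), control)
  infl_cliff <- c(x = 6, beta = -1)

  nll <- function(theta) {
    p <- try(unpack_params(theta, K, infl_cliff), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ll <- cpp_forward_loglik(dat$l, dat$logl, dat$cosphi, dat$w_step, dat$w_angle,
                             dat$d_edge, dat$d_center, dat$I_cliff,
                             dat$sess_start, dat$sess_len,
                             p$step_mean, p$step_shape, p$rho, p$tpm_alpha,
                             matrix(p$tpm_beta[, , "cliff"], K, K),
                             matrix(p$tpm_beta[, , "edge"], K, K),
                             matrix(p$tpm_beta[, , "center"], K, K),
                             p$infl$edge[["x"]], p$infl$edge[["beta"]],
                             p$infl$center[["x"]], p$infl$center[["beta"]])
    out <- -(ll + log_prior(p))
    if (!is.finite(out)) 1e10 else out
  }
  grad <- function(theta) {
    f0 <- nll(theta)
    vapply(seq_along(theta), function(i) {
      h <- 1e-6 * max(1, abs(theta[i]))
      th <- theta; th[i] <- th[i] + h
      (nll(th) - f0) / h
    }, 0)
  }

  set.seed(seed)
  inits <- lapply(seq_len(starts), function(s)
    pack_params(init_params(dat, K, jitter = (s > 1) || !is.null(init),
                            base = if (s == 1) init else NULL)))
  stage1 <- lapply(seq_along(inits), function(s) {
    o <- optim(inits[[s]], nll, gr = grad, method = "L-BFGS-B",
               control = list(maxit = ctl$maxit_stage1, factr = ctl$factr))
    if (verbose) message(sprintf("start %d: objective %.3f", s, o$value))
    o
  })
  vals <- vapply(stage1, `[[`, 0, "value")
  best <- stage1[[which.min(vals)]]
  opt <- optim(best$par, nll, gr = grad, method = "L-BFGS-B",
               control = list(maxit = ctl$maxit, factr = ctl$factr))
  if (opt$value > best$value + 1e-6) opt <- best  # never accept a worse polish
  if (min(vals, opt$value) >= 1e10)
    stop("optimisation failed from every start; inspect the data or initial values")

  par <- unpack_params(opt$par, K, infl_cliff)
  loglik <- forward_loglik(sl, par)
  fit <- structure(list(
    par = par, theta = opt$par, K = K,
    loglik = loglik, logpost = -opt$value, prior = -opt$value - loglik,
    convergence = opt$convergence, opt_trace = sort(c(vals, opt$value)),
    n_steps = n_steps, n_sessions = length(sl),
    series = sl, seed = seed, infl_cliff = infl_cliff,
    call = match.call()
  ), class = "cliff_hmm")

  if (se) {
    H <- optimHess(opt$par, nll)
    # eigen-clipped inverse: numerical Hessians at near-flat directions can
    # be indefinite, and the Laplace covariance must be positive definite
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-6 * max(abs(ev$values), 1))
    V <- ev$vectors %*% diag(1 / lam) %*% t(ev$vectors)
    V <- (V + t(V)) / 2
    fit$vcov <- V
    set.seed(seed + 1L)
    th_draws <- MASS::mvrnorm(n_draws, mu = opt$par, Sigma = V)
    if (mcmc) {
      mc <- rwm_sample(nll, opt$par, V, iter = mcmc_iter, seed = seed + 2L)
      keep <- seq(floor(nrow(mc) / 2) + 1L, nrow(mc),
                  length.out = min(n_draws, floor(nrow(mc) / 2)))
      th_draws <- mc[round(keep), , drop = FALSE]
      fit$mcmc <- TRUE
    }
    fit$theta_draws <- th_draws
    nat <- t(apply(th_draws, 1, function(t2)
      natural_params(unpack_params(t2, K, infl_cliff))))
    fit$draws <- nat
    est <- natural_params(par)
    qs <- apply(nat, 2, quantile, c(0.055, 0.945))
    fit$ci <- data.frame(parameter = names(est), estimate = est,
                         lower = pmin(qs[1, ], est), upper = pmax(qs[2, ], est),
                         row.names = NULL)
  }
  fit
}

log_prior <- function(p) {
  tr <- allowed_transitions(p$K)
  sum(dnorm(log(p$step_mean), log(1), 1.5, log = TRUE)) +
    sum(dnorm(log(p$step_shape), 0, 1, log = TRUE)) +
    sum(dnorm(atanh(p$rho), 0, 1, log = TRUE)) +
    sum(dnorm(p$tpm_alpha[tr], 0, 2.5, log = TRUE)) +
    sum(dnorm(apply(p$tpm_beta, 3, function(m) m[tr]), 0, 2.5, log = TRUE)) +
    dnorm(p$infl$edge[["x"]], 5, 10, log = TRUE) +
    dnorm(p$infl$center[["x"]], 5, 10, log = TRUE) +
    dnorm(p$infl$edge[["beta"]], -1, 1, log = TRUE) +
    dnorm(p$infl$center[["beta"]], -1, 1, log = TRUE)
}

# data-driven starting values: quantile-split gamma moments for the state
# means, moderate concentrations, small random transition scores
init_params <- function(dat, K, jitter = TRUE, base = NULL) {
  if (!is.null(base)) {
    p <- base
  } else {
    l <- dat$l[dat$l > 0 & dat$w_step > 0]
    qs <- quantile(l, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    m <- sort(pmax(qs, 1e-3))
    if (any(diff(m) <= 0)) m <- m[1] * (1.5 ^ (seq_len(K) - 1))
    rho0 <- seq(0.2, 0.7, length.out = K)
    alpha <- matrix(0, K, K)
    tr <- allowed_transitions(K)
    alpha[tr] <- -1.5
    p <- cliff_hmm_params(step_mean = m, step_shape = rep(2, K),
                          rho = cbind(rho0, rho0, rho0, rho0),
                          tpm_alpha = alpha,
                          infl = influence_params(x_edge = 3, beta_edge = -1.5,
                                                  x_center = 8, beta_center = -1.5))
  }
  theta <- pack_params(p)
  if (jitter) theta <- theta + rnorm(length(theta), 0, 0.25)
  unpack_params(theta, K)
}

# natural-scale named parameter vector (for intervals, draws, reporting)
natural_params <- function(p) {
  K <- p$K
  tr <- allowed_transitions(K)
  trn <- paste0(tr[, 1], tr[, 2])
  out <- c(setNames(p$step_mean, paste0("m", seq_len(K))),
           setNames(p$step_shape, paste0("a", seq_len(K))),
           setNames(as.numeric(p$rho),
                    paste0("rho_", rep(colnames(p$rho), each = K), rep(seq_len(K), 4))),
           setNames(p$tpm_alpha[tr], paste0("alpha", trn)),
           setNames(as.numeric(apply(p$tpm_beta, 3, function(m) m[tr])),
                    paste0("beta", trn, "_", rep(dimnames(p$tpm_beta)[[3]], each = nrow(tr)))),
           x_edge = p$infl$edge[["x"]], x_center = p$infl$center[["x"]],
           beta_edge = p$infl$edge[["beta"]], beta_center = p$infl$center[["beta"]])
  out
}

# adaptive random-walk Metropolis on the unconstrained scale
rwm_sample <- function(nll, theta0, V, iter = 4000, seed = 1, target = 0.25) {
  set.seed(seed)
  d <- length(theta0)
  L <- t(chol((V + t(V)) / 2 + diag(1e-10, d)))
  sc <- 2.38 / sqrt(d)
  th <- theta0
  f <- -nll(th)
  out <- matrix(NA_real_, iter, d)
  acc <- 0L
  for (i in seq_len(iter)) {
    prop <- th + sc * as.numeric(L %*% rnorm(d))
    fp <- -nll(prop)
    if (is.finite(fp) && log(runif(1)) < fp - f) { th <- prop; f <- fp; acc <- acc + 1L }
    out[i, ] <- th
    if (i %% 100 == 0 && i <= iter / 2) {   # adapt during warm-up only
      rate <- acc / i
      sc <- sc * exp(0.5 * (rate - target))
    }
  }
  attr(out, "accept_rate") <- acc / iter
  out
}

#' Posterior parameter draws from a fitted model
#'
#' @param fit A `cliff_hmm` fit (with `se = TRUE`).
#' @param n Number of draws (default: all stored).
#' @return A list of [cliff_hmm_params()] objects.
#' @export
parameter_draws <- function(fit, n = NULL) {
  if (is.null(fit$theta_draws)) stop("fit has no stored draws (refit with se = TRUE)")
  td <- fit$theta_draws
  if (!is.null(n)) td <- td[seq_len(min(n, nrow(td))), , drop = FALSE]
  lapply(seq_len(nrow(td)), function(i)
    unpack_params(td[i, ], fit$K, fit$infl_cliff))
}

## ---- S3 methods ----

#' @export
print.cliff_hmm <- function(x, ...) {
  cat(sprintf("Covariate-modulated movement HMM (K = %d), MAP fit\n", x$K))
  cat(sprintf("  %d session(s), %d steps; log-likelihood %.2f, log-posterior %.2f\n",
              x$n_sessions, x$n_steps, x$loglik, x$logpost))
  print(x$par)
  invisible(x)
}

#' @export
summary.cliff_hmm <- function(object, ...) {
  out <- list(K = object$K, n_steps = object$n_steps,
              n_sessions = object$n_sessions, loglik = object$loglik,
              logpost = object$logpost, convergence = object$convergence,
              ci = object$ci, mcmc = isTRUE(object$mcmc))
  class(out) <- "summary.cliff_hmm"
  out
}

#' @export
print.summary.cliff_hmm <- function(x, ...) {
  cat(sprintf("Movement HMM fit: K = %d, %d steps over %d session(s)\n",
              x$K, x$n_steps, x$n_sessions))
  cat(sprintf("log-likelihood %.2f, log-posterior %.2f (convergence code %d)\n",
              x$loglik, x$logpost, x$convergence))
  if (!is.null(x$ci)) {
    cat(sprintf("89%% intervals (%s):\n",
                if (x$mcmc) "Metropolis draws" else "Laplace approximation"))
    ci <- x$ci
    ci[, -1] <- round(ci[, -1], 4)
    print(ci, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cliff_hmm <- function(object, ...) natural_params(object$par)

#' @export
logLik.cliff_hmm <- function(object, ...) {
  structure(object$loglik, df = n_pack(object$K), nobs = object$n_steps,
            class = "logLik")
}

#' @export
nobs.cliff_hmm <- function(object, ...) object$n_steps

#' Decode states with a fitted model
#'
#' @param object A `cliff_hmm` fit.
#' @param newdata A `movement_series` (or list); defaults to the training
#'   series.
#' @param mode `"local"` (posterior argmax) or `"global"` (most probable
#'   path).
#' @param ... Unused.
#' @return A `state_sequence` data frame, see [decode()].
#' @export
predict.cliff_hmm <- function(object, newdata = NULL, mode = "local", ...) {
  decode(newdata %||% object$series, object$par, mode = mode)
}

#' Simulate sessions from a fitted model
#'
#' @param object A `cliff_hmm` fit.
#' @param nsim Number of sessions.
#' @param seed Seed.
#' @param n_steps Steps per session.
#' @param ... Passed to [simulate_session()].
#' @return A list of [simulate_session()] results.
#' @export
simulate.cliff_hmm <- function(object, nsim = 1, seed = 1, n_steps = 3000, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_session(object$par, n_steps = n_steps, seed = seed + i - 1L, ...))
}

#' One-step-ahead pseudo-residuals
#'
#' Forward (filtering) pseudo-residuals: each observation is transformed by
#' its one-step-ahead predictive CDF under the fitted model and mapped
#' through the normal quantile function, so a well-specified model yields
#' standard-normal residuals. Available for step lengths and turning
#' increments; steps with zero likelihood weight give `NA`.
#'
#' @param object A `cliff_hmm` fit.
#' @param type `"step"` or `"angle"`.
#' @param ... Unused.
#' @return Numeric vector (concatenated over sessions).
#' @export
residuals.cliff_hmm <- function(object, type = c("step", "angle"), ...) {
  type <- match.arg(type)
  p <- object$par
  unlist(lapply(object$series, function(s) {
    s <- refresh_influences(s, p)
    fw <- forward_r(s, p, return_filter = TRUE)
    Tn <- nrow(s); K <- p$K
    u <- rep(NA_real_, Tn)
    pred <- matrix(0, Tn, K)
    pred[1, ] <- stationary(fw$tpm[, , 1])
    if (Tn > 1) for (t in 2:Tn)
      pred[t, ] <- (fw$alpha[t - 1, ] %*% fw$tpm[, , t])[1, ]
    for (t in seq_len(Tn)) {
      if (type == "step") {
        if (s$w_step[t] > 0 && s$l[t] > 0)
          u[t] <- sum(pred[t, ] * pgamma(s$l[t], shape = p$step_shape,
                                         rate = p$step_shape / p$step_mean))
      } else if (s$w_angle[t] > 0) {
        rho <- effective_rho(seq_len(K), s$I_cliff[t], s$I_edge[t],
                             s$I_center[t], p)
        u[t] <- sum(pred[t, ] * pwrapped_cauchy(s$phi[t], rho))
      }
    }
    qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  }), use.names = FALSE)
}

# wrapped-Cauchy CDF on (-pi, pi]
pwrapped_cauchy <- function(phi, rho) {
  cc <- (1 + rho) / (1 - rho)
  0.5 + atan(cc * tan(phi / 2)) / pi
}

#' Plot a fitted movement HMM
#'
#' Three panels: per-state step-length densities, per-state basal angular
#' densities, and the fitted edge/centre influence functions.
#'
#' @param x A `cliff_hmm` fit.
#' @param ... Unused.
#' @export
plot.cliff_hmm <- function(x, ...) {
  p <- x$par
  K <- p$K
  cols <- c("firebrick", "steelblue", "forestgreen", "orange", "purple")[seq_len(K)]
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  lmax <- max(qgamma(0.995, p$step_shape, p$step_shape / p$step_mean))
  lgrid <- seq(1e-3, lmax, length.out = 300)
  dens <- sapply(seq_len(K), function(k) exp(step_logpdf(lgrid, k, p)))
  matplot(lgrid, dens, type = "l", lty = 1, col = cols,
          xlab = "step length (cm)", ylab = "density", main = "step emissions")
  legend("topright", state_labels(K), col = cols, lty = 1, bty = "n")
  agrid <- seq(-pi, pi, length.out = 361)
  adens <- sapply(seq_len(K), function(k) dwrapped_cauchy(agrid, p$rho[k, "basal"]))
  matplot(agrid, adens, type = "l", lty = 1, col = cols,
          xlab = "turning increment (rad)", ylab = "density",
          main = "angular emissions (basal)")
  abline(h = 1 / (2 * pi), lty = 3)
  dgrid <- seq(0, 30, length.out = 300)
  plot(dgrid, influence(dgrid, p$infl$edge[["x"]], p$infl$edge[["beta"]]),
       type = "l", col = "black", ylim = c(0, 1),
       xlab = "distance (cm)", ylab = "influence", main = "influence functions")
  lines(dgrid, influence(dgrid, p$infl$center[["x"]], p$infl$center[["beta"]]),
        col = "grey50")
  lines(dgrid, influence(dgrid, p$infl$cliff[["x"]], p$infl$cliff[["beta"]]),
        col = "grey75", lty = 2)
  legend("topright", c("edge", "center", "cliff (fixed)"),
         col = c("black", "grey50", "grey75"), lty = c(1, 1, 2), bty = "n")
  invisible(x)
}
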