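#' Partially pooled fits across animals
#'
#' Two-stage partial pooling: each animal is fitted by MAP ([cliff_hmm()]),
#' then, parameter by parameter on the unconstrained scale, the per-animal
#' estimates and their Laplace standard errors enter a normal-normal
#' random-effects model (REML, via \pkg{metafor}). Animal-level estimates are
#' shrunk toward the group mean by the usual precision weighting, and the
#' group level reports the pooled mean, its standard error, and the
#' between-animal spread. With a single animal the function falls back to the
#' unpooled fit with a warning.
#'
#' @param animals A list of per-animal inputs: each element a
#'   `movement_series` or list of them.
#' @param K Number of states.
#' @param seed Seed (animal `i` uses `seed + i`).
#' @param ... Passed to [cliff_hmm()].
#' @return A `cliff_hmm_pooled` list: `fits` (per-animal `cliff_hmm`),
#'   `group` (data frame: parameter, mean, se, tau — between-animal s.d., all
#'   on the unconstrained scale), `group_params` ([cliff_hmm_params()] at the
#'   pooled means), `shrunk` (per-animal [cliff_hmm_params()] after
#'   shrinkage).
#' @export
fit_hierarchical <- function(animals, K = 3, seed = 1, ...) {
  n <- length(animals)
  fits <- lapply(seq_len(n), function(i)
    cliff_hmm(animals[[i]], K = K, seed = seed + i, ...))
  if (n < 2L) {
    warning("only one animal: returning the unpooled fit")
    return(structure(list(fits = fits, group = NULL,
                          group_params = fits[[1]]$par, shrunk = list(fits[[1]]$par)),
                     class = "cliff_hmm_pooled"))
  }
  th <- t(vapply(fits, `[[`, fits[[1]]$theta, "theta"))
  se <- t(vapply(fits, function(f) sqrt(pmax(diag(f$vcov), 1e-12)),
                 numeric(length(fits[[1]]$theta))))
  P <- ncol(th)
  mu <- tau <- mu_se <- numeric(P)
  shrunk <- th
  for (j in seq_len(P)) {
    re <- tryCatch(
      metafor::rma.uni(yi = th[, j], sei = se[, j], method = "REML"),
      error = function(e) metafor::rma.uni(yi = th[, j], sei = se[, j], method = "DL"))
    mu[j] <- as.numeric(re$beta)
    tau[j] <- sqrt(re$tau2)
    mu_se[j] <- re$se
    w <- re$tau2 / (re$tau2 + se[, j]^2)       # BLUP shrinkage weight
    shrunk[, j] <- mu[j] + w * (th[, j] - mu[j])
  }
  nat_names <- names(natural_params(fits[[1]]$par))
  group <- data.frame(parameter = nat_names, mean = mu, se = mu_se, tau = tau)
  structure(list(
    fits = fits, group = group,
    group_params = unpack_params(mu, K, fits[[1]]$infl_cliff),
    shrunk = lapply(seq_len(n), function(i)
      unpack_params(shrunk[i, ], K, fits[[1]]$infl_cliff))
  ), class = "cliff_hmm_pooled")
}

#' @export
print.cliff_hmm_pooled <- function(x, ...) {
  cat(sprintf("Partially pooled movement-HMM fit: %d animal(s)\n", length(x$fits)))
  if (!is.null(x$group)) {
    cat("Group-level parameters (natural scale):\n")
    print(x$group_params)
  }
  invisible(x)
}

#' Mixture-model screen for emission families and state counts
#'
#' Fits independent (non-HMM) finite mixtures to the pooled step lengths
#' (gamma or lognormal components) or turning increments (wrapped Cauchy or
#' von Mises components centred at zero) by expectation-maximisation, for
#' 1 to `max_components` components, and ranks them by the small-sample
#' corrected Akaike criterion. The preferred component count per family
#' guides the choice of the HMM's state count and emission families.
#'
#' @param x Numeric data: positive step lengths, or angles in `(-pi, pi]`.
#' @param families Character vector: subsets of `c("gamma", "lognormal")`
#'   (steps) or `c("wrapped_cauchy", "von_mises")` (angles).
#' @param max_components Maximum number of components (default 3).
#' @param n_restarts EM restarts per candidate (default 3).
#' @param seed Seed for the restarts.
#' @return A `mixture_screen` data frame: `family`, `components`,
#'   `loglik`, `aicc`, `recommended`, with fitted parameter lists in
#'   attribute `fits`.
#' @export
mixture_screen <- function(x, families = c("gamma", "lognormal"),
                           max_components = 3, n_restarts = 3, seed = 1) {
  stopifnot(length(x) >= 500)
  families <- match.arg(families, c("gamma", "lognormal", "wrapped_cauchy",
                                    "von_mises"), several.ok = TRUE)
  set.seed(seed)
  rows <- list(); fits <- list()
  for (fam in families) {
    for (cc in seq_len(max_components)) {
      best <- NULL
      for (rs in seq_len(n_restarts)) {
        f <- tryCatch(em_mixture(x, fam, cc), error = function(e) NULL)
        if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
      }
      if (is.null(best)) stop(sprintf("EM failed for %s with %d component(s)", fam, cc))
      p <- best$n_par
      n <- length(x)
      aicc <- -2 * best$loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
      rows[[length(rows) + 1L]] <- data.frame(family = fam, components = cc,
                                              loglik = best$loglik, aicc = aicc)
      fits[[paste(fam, cc, sep = "_")]] <- best
    }
  }
  out <- do.call(rbind, rows)
  out$recommended <- FALSE
  for (fam in unique(out$family)) {
    i <- which(out$family == fam)
    out$recommended[i[which.min(out$aicc[i])]] <- TRUE
  }
  structure(out, fits = fits, class = c("mixture_screen", "data.frame"))
}

# EM for the four supported mixture families; angular families are centred
# at zero and differ only in concentration
em_mixture <- function(x, family, C, max_iter = 500, tol = 1e-7) {
  n <- length(x)
  angular <- family %in% c("wrapped_cauchy", "von_mises")
  if (angular) stopifnot(all(x > -pi - 1e-9), all(x <= pi + 1e-9))
  else { x <- x[x > 0]; n <- length(x) }
  # initial split by quantiles / concentration ladder
  if (angular) {
    par <- list(w = rep(1 / C, C), rho = seq(0.1, 0.85, length.out = C))
  } else {
    qs <- quantile(x, (seq_len(C) - 0.5) / C, names = FALSE)
    par <- list(w = rep(1 / C, C), mean = as.numeric(qs) * runif(C, 0.9, 1.1),
                shape = rep(2, C))
  }
  comp_logdens <- function(par) {
    sapply(seq_len(C), function(c) {
      if (family == "gamma")
        dgamma(x, shape = par$shape[c], rate = par$shape[c] / par$mean[c], log = TRUE)
      else if (family == "lognormal")
        dnorm(log(x), par$mean[c], par$shape[c], log = TRUE) - log(x)
      else if (family == "wrapped_cauchy")
        dwrapped_cauchy(x, par$rho[c], log = TRUE)
      else dvon_mises(x, par$rho[c], log = TRUE)
    })
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- sweep(comp_logdens(par), 2, log(par$w), `+`)
    mx <- apply(ld, 1, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    ll <- sum(lse)
    resp <- exp(ld - lse)
    par$w <- colMeans(resp)
    for (c in seq_len(C)) {
      w <- resp[, c]
      sw <- sum(w)
      if (family == "gamma") {
        mb <- sum(w * x) / sw
        mlx <- sum(w * log(x)) / sw
        par$mean[c] <- mb
        par$shape[c] <- gamma_shape_mle(log(mb) - mlx)
      } else if (family == "lognormal") {
        par$mean[c] <- sum(w * log(x)) / sw
        par$shape[c] <- sqrt(max(sum(w * (log(x) - par$mean[c])^2) / sw, 1e-8))
      } else if (family == "wrapped_cauchy") {
        par$rho[c] <- optimize(function(r) sum(w * dwrapped_cauchy(x, r, log = TRUE)),
                               c(0, 0.999), maximum = TRUE)$maximum
      } else {
        rbar <- sum(w * cos(x)) / sw
        par$rho[c] <- a1inv(max(min(rbar, 0.999), 0))
      }
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  n_par <- (C - 1L) + C * if (angular) 1L else 2L
  list(family = family, components = C, par = par, loglik = ll, n_par = n_par,
       iterations = it)
}

# weighted gamma shape MLE from s = log(mean) - mean(log): generalized
# Newton iteration (converges in a handful of steps)
gamma_shape_mle <- function(s, max_iter = 50) {
  s <- max(s, 1e-9)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(max_iter)) {
    num <- log(a) - digamma(a) - s
    a_new <- a - num / (1 / a - trigamma(a))
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  max(a, 1e-3)
}

# von Mises density centred at 0 (kappa via concentration parameter)
dvon_mises <- function(x, kappa, log = FALSE) {
  ld <- kappa * cos(x) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
  if (log) ld else exp(ld)
}

# inverse of A1(kappa) = I1/I0 (standard piecewise approximation)
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' @importFrom stats digamma trigamma optimize cor
NULL

#' Posterior predictive replication of step and angle data
#'
#' Simulates `n_draws` replicated datasets conditional on the observed
#' covariate path: parameters are drawn from the fit's stored posterior
#' draws (or fixed at the MAP estimate if none), a state chain is sampled
#' along the observed influences, and step lengths / turning increments are
#' emitted. Histograms of the replicates against the observed data are the
#' standard goodness-of-fit overlay.
#'
#' @param fit A `cliff_hmm` fit.
#' @param series A `movement_series` or list; defaults to the training data.
#' @param n_draws Number of replicated datasets (default 10).
#' @param seed Seed.
#' @param breaks_l,breaks_phi Histogram break counts.
#' @return A `cliff_ppc` list: `replicates` (list of data frames `l`, `phi`),
#'   `observed`, histogram summaries `hist_l`, `hist_phi` (observed counts,
#'   replicate envelope), and the quantile table `quantiles`.
#' @export
posterior_predictive <- function(fit, series = NULL, n_draws = 10, seed = 1,
                                 breaks_l = 30, breaks_phi = 30) {
  sl <- as_series_list(series %||% fit$series)
  obs_l <- unlist(lapply(sl, function(s) s$l[s$w_step > 0 & s$l > 0]))
  obs_phi <- unlist(lapply(sl, function(s) s$phi[s$w_angle > 0]))
  if (n_draws == 0)
    return(structure(list(replicates = list(), observed = list(l = obs_l, phi = obs_phi)),
                     class = "cliff_ppc"))
  draws <- if (!is.null(fit$theta_draws)) parameter_draws(fit, n_draws)
           else rep(list(fit$par), n_draws)
  set.seed(seed)
  reps <- lapply(seq_len(n_draws), function(i)
    replicate_series(sl, draws[[min(i, length(draws))]]))
  br_l <- seq(0, max(obs_l, vapply(reps, function(r) max(r$l), 0)) * 1.001,
              length.out = breaks_l + 1L)
  br_p <- seq(-pi, pi, length.out = breaks_phi + 1L)
  hcount <- function(v, br) hist(pmin(pmax(v, br[1]), br[length(br)]),
                                 breaks = br, plot = FALSE)$counts
  Hl <- sapply(reps, function(r) hcount(r$l, br_l))
  Hp <- sapply(reps, function(r) hcount(r$phi, br_p))
  qs <- c(0.055, 0.25, 0.5, 0.75, 0.945)
  structure(list(
    replicates = reps,
    observed = list(l = obs_l, phi = obs_phi),
    hist_l = list(breaks = br_l, observed = hcount(obs_l, br_l),
                  lower = apply(Hl, 1, min), upper = apply(Hl, 1, max)),
    hist_phi = list(breaks = br_p, observed = hcount(obs_phi, br_p),
                    lower = apply(Hp, 1, min), upper = apply(Hp, 1, max)),
    quantiles = data.frame(
      q = qs,
      l_obs = quantile(obs_l, qs, names = FALSE),
      l_rep = quantile(unlist(lapply(reps, `[[`, "l")), qs, names = FALSE),
      phi_obs = quantile(obs_phi, qs, names = FALSE),
      phi_rep = quantile(unlist(lapply(reps, `[[`, "phi")), qs, names = FALSE))
  ), class = "cliff_ppc")
}

# sample states along the observed covariate path and emit observations
replicate_series <- function(series_list, params) {
  out_l <- list(); out_phi <- list()
  for (s in series_list) {
    s <- refresh_influences(s, params)
    Tn <- nrow(s)
    G <- tpm_series(s, params)
    st <- integer(Tn)
    st[1] <- sample.int(params$K, 1, prob = stationary(G[, , 1]))
    if (Tn > 1) for (t in 2:Tn) st[t] <- sample.int(params$K, 1, prob = G[st[t - 1], , t])
    l <- rgamma(Tn, shape = params$step_shape[st],
                rate = params$step_shape[st] / params$step_mean[st])
    rho <- effective_rho(st, s$I_cliff, s$I_edge, s$I_center, params)
    u <- runif(Tn, -pi, pi)
    phi <- ifelse(rho > 0,
                  .wrap_angle(rcauchy(Tn, 0, -log(pmax(rho, 1e-12)))), u)
    out_l[[length(out_l) + 1L]] <- l[s$w_step > 0]
    out_phi[[length(out_phi) + 1L]] <- phi[s$w_angle > 0]
  }
  list(l = unlist(out_l), phi = unlist(out_phi))
}

#' Sample autocorrelation function
#'
#' Standard sample ACF (lag 0 equals 1 by definition); errors on constant
#' series, for which the autocorrelation is undefined.
#'
#' @param x Numeric series.
#' @param max_lag Maximum lag (must be smaller than `length(x)`).
#' @return Data frame `lag`, `acf`.
#' @export
acf_series <- function(x, max_lag = 40) {
  stopifnot(length(x) > max_lag)
  if (sd(x) == 0) stop("constant series: autocorrelation undefined")
  a <- acf(x, lag.max = max_lag, plot = FALSE)
  data.frame(lag = as.numeric(a$lag), acf = as.numeric(a$acf))
}
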