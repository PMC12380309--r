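#' Wrapped-Cauchy density and sampler
#'
#' Circular density on `(-pi, pi]` centred at `mu` with concentration
#' `rho` in `[0, 1)`:
#' `f(phi) = (1 - rho^2) / (2 * pi * (1 + rho^2 - 2 * rho * cos(phi - mu)))`.
#' `rho = 0` is the circular uniform (density `1 / (2 * pi)` = 0.159...).
#'
#' @param phi Angle(s), radians.
#' @param rho Concentration in `[0, 1)`.
#' @param mu Centre (default 0: directional persistence model on turning
#'   increments).
#' @param log Return the log density?
#' @return Density (or log density) values.
#' @export
dwrapped_cauchy <- function(phi, rho, mu = 0, log = FALSE) {
  stopifnot(all(rho >= 0), all(rho < 1))
  ld <- log1p(-rho^2) - log(2 * pi) -
    log1p(rho^2 - 2 * rho * cos(phi - mu))
  if (log) ld else exp(ld)
}

#' @rdname dwrapped_cauchy
#' @param n Number of draws.
#' @export
rwrapped_cauchy <- function(n, rho, mu = 0) {
  stopifnot(rho >= 0, rho < 1)
  if (rho == 0) return(runif(n, -pi, pi))
  # wrapping a Cauchy with scale -log(rho) yields concentration rho
  .wrap_angle(mu + rcauchy(n, 0, -log(rho)))
}

#' Step-length log density for one state
#'
#' Gamma log density with the state's shape `a_k` and rate `a_k / m_k`, so
#' the mean is `m_k`. Non-positive lengths carry no step-length information
#' (they are weighted out of the likelihood) and return `NA`.
#'
#' @param l Step length(s), cm.
#' @param k State index.
#' @param params [cliff_hmm_params()].
#' @return Log density values (`NA` where `l <= 0`).
#' @export
step_logpdf <- function(l, k, params) {
  out <- rep(NA_real_, length(l))
  pos <- l > 0
  out[pos] <- dgamma(l[pos], shape = params$step_shape[k],
                     rate = params$step_shape[k] / params$step_mean[k], log = TRUE)
  out
}

#' Effective angular concentration under blended influences
#'
#' Blends the per-state concentrations on the `atanh` scale with hierarchical
#' precedence edge > cliff > centre: `w_edge = I_edge`,
#' `w_cliff = I_cliff (1 - I_edge)`,
#' `w_center = I_center (1 - I_edge)(1 - I_cliff)`, remainder basal. The
#' result is `tanh` of the weighted `atanh` concentrations, monotone in each
#' component and bounded by the largest of them.
#'
#' @param k State index (or vector of indices; recycled against influences).
#' @param I_cliff,I_edge,I_center Influences in `[0, 1]` (vectorised).
#' @param params [cliff_hmm_params()].
#' @return Effective concentration(s) in `[0, 1)`.
#' @export
effective_rho <- function(k, I_cliff, I_edge, I_center, params) {
  w_edge <- I_edge
  w_cliff <- I_cliff * (1 - I_edge)
  w_center <- I_center * (1 - I_edge) * (1 - I_cliff)
  w_basal <- 1 - w_edge - w_cliff - w_center
  at <- atanh(params$rho)
  as.numeric(tanh(w_basal * at[k, "basal"] + w_cliff * at[k, "cliff"] +
                    w_edge * at[k, "edge"] + w_center * at[k, "center"]))
}

#' Turning-increment log density for one state
#'
#' Wrapped-Cauchy log density centred at 0 with the effective concentration
#' from [effective_rho()].
#'
#' @param phi Turning increment(s) in `(-pi, pi]`.
#' @param k State index.
#' @param I_cliff,I_edge,I_center Influences at the step.
#' @param params [cliff_hmm_params()].
#' @return Log density values.
#' @export
angle_logpdf <- function(phi, k, I_cliff, I_edge, I_center, params) {
  rho <- effective_rho(k, I_cliff, I_edge, I_center, params)
  dwrapped_cauchy(phi, rho, log = TRUE)
}

#' Covariate-dependent transition matrix
#'
#' Multinomial-logit rows with the diagonal as reference category: for row
#' `i` the score of staying is 0 and the score of moving to an adjacent state
#' `j` is `alpha_ij + beta_ij . (I_cliff, I_edge, I_center)`; the row is the
#' softmax over the allowed entries. Transitions between non-adjacent states
#' are structurally zero.
#'
#' @param I_cliff,I_edge,I_center Influence values at one step.
#' @param params [cliff_hmm_params()].
#' @return A `K x K` row-stochastic matrix.
#' @export
build_tpm <- function(I_cliff, I_edge, I_center, params) {
  K <- params$K
  G <- matrix(0, K, K)
  for (i in seq_len(K)) {
    js <- intersect(c(i - 1L, i, i + 1L), seq_len(K))
    eta <- vapply(js, function(j) {
      if (j == i) 0
      else params$tpm_alpha[i, j] +
          params$tpm_beta[i, j, "cliff"] * I_cliff +
          params$tpm_beta[i, j, "edge"] * I_edge +
          params$tpm_beta[i, j, "center"] * I_center
    }, 0)
    w <- exp(eta - max(eta))
    G[i, js] <- w / sum(w)
  }
  G
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi Gamma = pi`, `sum(pi) = 1` by a linear solve. The chain must be
#' irreducible over the banded structure (all adjacent transitions positive).
#'
#' @param Gamma A row-stochastic `K x K` matrix.
#' @return The stationary probability vector.
#' @export
stationary <- function(Gamma) {
  K <- nrow(Gamma)
  adj <- cbind(seq_len(K - 1L), seq_len(K - 1L) + 1L)
  dead <- c(adj[Gamma[adj] <= 0, 2L], adj[Gamma[adj[, 2:1, drop = FALSE]] <= 0, 1L])
  if (length(dead))
    stop("reducible transition matrix; absorbing around state(s) ",
         paste(sort(unique(dead)), collapse = ", "))
  A <- t(diag(K) - Gamma)
  A[K, ] <- 1                      # replace one equation with the normalisation
  pi <- solve(A, c(rep(0, K - 1L), 1))
  pmax(pi, 0) / sum(pmax(pi, 0))
}

## ---- internal: emission and TPM series for a movement series ----

# T x K matrix of per-step log emission densities (weighted: zero-weight
# components contribute 0)
emission_logprob <- function(series, params) {
  K <- params$K
  Tn <- nrow(series)
  lp <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    sl <- rep(0, Tn)
    ok <- series$w_step > 0 & series$l > 0
    sl[ok] <- step_logpdf(series$l[ok], k, params)
    al <- rep(0, Tn)
    ok2 <- series$w_angle > 0
    if (any(ok2))
      al[ok2] <- angle_logpdf(series$phi[ok2], k, series$I_cliff[ok2],
                              series$I_edge[ok2], series$I_center[ok2], params)
    lp[, k] <- sl + al
  }
  lp
}

# K x K x T array of per-step transition matrices
tpm_series <- function(series, params) {
  Tn <- nrow(series)
  G <- array(0, c(params$K, params$K, Tn))
  for (t in seq_len(Tn))
    G[, , t] <- build_tpm(series$I_cliff[t], series$I_edge[t],
                          series$I_center[t], params)
  G
}

# influences recomputed from distances under `params`'s influence functions
series_influences <- function(series, params) {
  ip <- params$infl
  list(I_cliff = influence(series$d_cliff, ip$cliff["x"], ip$cliff["beta"]),
       I_edge = influence(series$d_edge, ip$edge["x"], ip$edge["beta"]),
       I_center = influence(series$d_center, ip$center["x"], ip$center["beta"]))
}

# replace stored influence columns by ones implied by `params`
refresh_influences <- function(series, params) {
  I <- series_influences(series, params)
  series$I_cliff <- I$I_cliff; series$I_edge <- I$I_edge; series$I_center <- I$I_center
  series
}

as_series_list <- function(series) {
  if (inherits(series, "movement_series") || is.data.frame(series)) list(series)
  else series
}

#' Marginal log-likelihood by the forward algorithm
#'
#' Exact HMM log-likelihood via the scaled forward recursion, computed in
#' compiled code. The initial state distribution is the stationary
#' distribution of the transition matrix at the first step's covariates.
#' Influence covariates are recomputed from the stored distances under the
#' parameter set's own influence functions.
#'
#' @param series A `movement_series` or a list of them (sessions/segments are
#'   independent chains).
#' @param params [cliff_hmm_params()].
#' @return The total log-likelihood (`-Inf` if any step is impossible under
#'   all states).
#' @export
forward_loglik <- function(series, params) {
  dat <- flatten_series(as_series_list(series))
  K <- params$K
  bmat <- function(f) matrix(params$tpm_beta[, , f], K, K)
  cpp_forward_loglik(dat$l, dat$logl, dat$cosphi, dat$w_step, dat$w_angle,
                     dat$d_edge, dat$d_center, dat$I_cliff,
                     dat$sess_start, dat$sess_len,
                     params$step_mean, params$step_shape, params$rho,
                     params$tpm_alpha,
                     bmat("cliff"), bmat("edge"), bmat("center"),
                     params$infl$edge[["x"]], params$infl$edge[["beta"]],
                     params$infl$center[["x"]], params$infl$center[["beta"]])
}

# concatenate sessions into flat vectors + 0-based session offsets
flatten_series <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  lens <- vapply(series_list, nrow, 1L)
  cat1 <- function(col) unlist(lapply(series_list, `[[`, col), use.names = FALSE)
  l <- cat1("l")
  list(l = l,
       logl = ifelse(l > 0, log(l), 0),
       cosphi = cos(cat1("phi")),
       w_step = cat1("w_step") * as.numeric(l > 0),
       w_angle = cat1("w_angle"),
       d_edge = cat1("d_edge"), d_center = cat1("d_center"),
       I_cliff = cat1("I_cliff"),
       sess_start = as.integer(cumsum(c(0L, lens[-length(lens)]))),
       sess_len = as.integer(lens))
}

# pure-R scaled forward recursion; independent reference route for tests and
# the engine behind smoothing/decoding
forward_r <- function(series, params, return_filter = FALSE) {
  series <- refresh_influences(series, params)
  lp <- emission_logprob(series, params)
  G <- tpm_series(series, params)
  Tn <- nrow(series); K <- params$K
  alpha <- matrix(0, Tn, K)
  ll <- 0
  b <- exp(lp[1, ])
  a <- stationary(G[, , 1]) * b
  s <- sum(a)
  if (s <= 0) return(list(loglik = -Inf))
  alpha[1, ] <- a / s; ll <- log(s)
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% G[, , t])[1, ] * exp(lp[t, ])
    s <- sum(a)
    if (s <= 0 || !is.finite(s)) return(list(loglik = -Inf))
    alpha[t, ] <- a / s
    ll <- ll + log(s)
  }
  out <- list(loglik = ll)
  if (return_filter) { out$alpha <- alpha; out$logprob <- lp; out$tpm <- G }
  out
}

#' Decode behavioural states
#'
#' Local mode returns the per-step posterior state probabilities from the
#' forward-backward recursion and their argmax; global mode returns the
#' jointly most probable state path (dynamic-programming maximisation).
#' Posterior probabilities are returned in both modes. Ties break toward the
#' lowest-numbered state.
#'
#' @param series A `movement_series` or list of them.
#' @param params [cliff_hmm_params()].
#' @param mode `"local"` or `"global"`.
#' @return A `state_sequence` data frame (one row per step, concatenated over
#'   sessions) with `session`, `state` and posterior columns `p1..pK`.
#' @export
decode <- function(series, params, mode = c("local", "global")) {
  mode <- match.arg(mode)
  sl <- as_series_list(series)
  out <- lapply(seq_along(sl), function(si) {
    s <- sl[[si]]
    fw <- forward_r(s, params, return_filter = TRUE)
    if (!is.finite(fw$loglik)) stop("series impossible under the model")
    post <- backward_smooth(fw)
    st <- if (mode == "local") max.col(post, ties.method = "first")
          else viterbi_path(fw)
    cbind(data.frame(session = si, state = st),
          setNames(as.data.frame(post), paste0("p", seq_len(params$K))))
  })
  structure(do.call(rbind, out), class = c("state_sequence", "data.frame"))
}

backward_smooth <- function(fw) {
  alpha <- fw$alpha; G <- fw$tpm; lp <- fw$logprob
  Tn <- nrow(alpha); K <- ncol(alpha)
  beta <- matrix(1, Tn, K)
  if (Tn > 1) for (t in (Tn - 1):1) {
    b <- G[, , t + 1] %*% (exp(lp[t + 1, ]) * beta[t + 1, ])
    beta[t, ] <- b / max(b)
  }
  post <- alpha * beta
  post / rowSums(post)
}

viterbi_path <- function(fw) {
  lp <- fw$logprob; G <- fw$tpm
  Tn <- nrow(lp); K <- ncol(lp)
  lG <- log(G)
  delta <- matrix(-Inf, Tn, K)
  back <- matrix(1L, Tn, K)
  delta[1, ] <- log(stationary(G[, , 1])) + lp[1, ]
  if (Tn > 1) for (t in 2:Tn) {
    for (j in seq_len(K)) {
      cand <- delta[t - 1, ] + lG[, j, t]
      back[t, j] <- which.max(cand)           # first maximum: lowest state
      delta[t, j] <- cand[back[t, j]] + lp[t, j]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}
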