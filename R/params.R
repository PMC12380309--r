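#' HMM parameter set
#'
#' All parameters of the covariate-modulated movement HMM with `K` states
#' (default 3: 1 = Resting, 2 = Exploring, 3 = Navigating):
#'
#' * per-state gamma step-length emissions with mean `step_mean` (cm) and
#'   shape `step_shape` (the rate is `shape / mean`);
#' * per-state wrapped-Cauchy angular concentrations under basal conditions
#'   and under full cliff / edge / centre influence (`rho`, a `K x 4` matrix
#'   with columns `basal`, `cliff`, `edge`, `center`, entries in `[0, 1)`);
#' * transition-matrix regression coefficients: an intercept and one slope
#'   per influence for every allowed off-diagonal transition (only adjacent
#'   states may exchange: `|i - j| > 1` entries are structurally zero);
#' * the logistic influence parameters ([influence_params()]), with the cliff
#'   pair fixed at 6 cm / -1.
#'
#' State labels are anchored by the ordering constraint
#' `step_mean[1] < ... < step_mean[K]`.
#'
#' @param step_mean,step_shape Numeric length `K`.
#' @param rho `K x 4` matrix (columns basal, cliff, edge, center) in `[0, 1)`.
#' @param tpm_alpha `K x K` matrix of intercepts; used only on the banded
#'   off-diagonal.
#' @param tpm_beta `K x K x 3` array of influence slopes, third dimension
#'   named `cliff`, `edge`, `center`.
#' @param infl [influence_params()].
#' @return A `cliffhmm_pars` object.
#' @export
cliff_hmm_params <- function(step_mean, step_shape, rho,
                             tpm_alpha = NULL, tpm_beta = NULL,
                             infl = influence_params()) {
  K <- length(step_mean)
  stopifnot(K >= 1, length(step_shape) == K)
  if (is.null(dim(rho))) rho <- matrix(rho, K, 4)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == K, ncol(rho) == 4)
  colnames(rho) <- c("basal", "cliff", "edge", "center")
  if (is.null(tpm_alpha)) tpm_alpha <- matrix(0, K, K)
  if (is.null(tpm_beta)) tpm_beta <- array(0, c(K, K, 3))
  dimnames(tpm_beta) <- list(NULL, NULL, c("cliff", "edge", "center"))
  p <- structure(list(K = K,
                      step_mean = as.numeric(step_mean),
                      step_shape = as.numeric(step_shape),
                      rho = rho,
                      tpm_alpha = as.matrix(tpm_alpha),
                      tpm_beta = tpm_beta,
                      infl = infl),
                 class = "cliffhmm_pars")
  validate_params(p)
  p
}

validate_params <- function(p) {
  with(p, {
    if (any(diff(step_mean) <= 0))
      stop("state step means must be strictly increasing (label-ordering constraint)")
    if (any(step_mean <= 0) || any(step_shape <= 0))
      stop("gamma means and shapes must be positive")
    if (any(rho < 0 | rho >= 1))
      stop("angular concentrations must lie in [0, 1)")
    band <- abs(row(tpm_alpha) - col(tpm_alpha)) > 1
    if (any(tpm_alpha[band] != 0) ||
        any(apply(tpm_beta, 3, function(m) any(m[band] != 0))))
      stop("transitions beyond adjacent states carry no parameters")
  })
  invisible(p)
}

#' @export
print.cliffhmm_pars <- function(x, ...) {
  cat(sprintf("Movement HMM parameters (K = %d states)\n", x$K))
  tab <- data.frame(mean_cm = x$step_mean, shape = x$step_shape,
                    round(x$rho, 3))
  rownames(tab) <- state_labels(x$K)
  print(tab)
  cat("Influence functions (offset cm / slope 1/cm):\n")
  for (f in names(x$infl))
    cat(sprintf("  %-6s x = %6.3f  beta = %6.3f\n", f,
                x$infl[[f]]["x"], x$infl[[f]]["beta"]))
  invisible(x)
}

state_labels <- function(K) {
  if (K == 3) c("Resting", "Exploring", "Navigating") else paste0("state", seq_len(K))
}

# ordered list of allowed off-diagonal transitions (i, j), |i - j| == 1
allowed_transitions <- function(K) {
  out <- NULL
  for (i in seq_len(K)) for (j in c(i - 1L, i + 1L))
    if (j >= 1L && j <= K) out <- rbind(out, c(i, j))
  out
}

#' Packaged default parameter sets
#'
#' Generating parameter sets used by the simulator, emulating the three
#' study conditions: sighted mice over a visual cliff (`"WT"`), behaviourally
#' blind retinal-degeneration mice (`"RD"`), and an open field without depth
#' cues (`"OF"`). Step means (0.3 / 1.2 / 2.2 cm), the Exploring-state cliff
#' concentration (0.8), and the edge/centre influence offsets (WT 3.2 / 6.1
#' cm, RD 3.0 / 23.6 cm, OF 4.4 / 12 cm) follow the reported estimates; the
#' cliff pair is fixed at 6 cm / -1. Cliff terms (transition slopes and cliff
#' concentrations) are zeroed in the RD and OF sets, which have no depth cue
#' response. Transition intercepts were calibrated once so that the
#' unconditional state occupancy is roughly 0.4 / 0.35 / 0.25 with
#' Resting-dominant dwell near the edge, and the WT cliff slopes so that the
#' circular-path cliff effect on Resting and Navigating is in the 2-4% band.
#'
#' @param preset One of `"WT"`, `"RD"`, `"OF"`.
#' @return A [cliff_hmm_params()] object.
#' @export
cliff_params_preset <- function(preset = c("WT", "RD", "OF")) {
  preset <- match.arg(preset)
  K <- 3
  m <- c(0.3, 1.2, 2.2)
  a <- c(2, 4, 6)
  rho_basal <- c(0.2, 0.5, 0.8)
  rho_edge <- c(0.5, 0.8, 0.9)
  alpha <- matrix(0, K, K)
  alpha[1, 2] <- -1.25; alpha[2, 1] <- -1.65
  alpha[2, 3] <- -1.65; alpha[3, 2] <- -1.35
  beta <- array(0, c(K, K, 3), dimnames = list(NULL, NULL, c("cliff", "edge", "center")))
  # edge: hold in Resting near the wall
  beta[1, 2, "edge"] <- -0.8; beta[2, 1, "edge"] <- 1.2
  beta[2, 3, "edge"] <- -0.4; beta[3, 2, "edge"] <- 0.7
  # centre: promotes directed movement away from the wall
  beta[1, 2, "center"] <- 0.5; beta[2, 3, "center"] <- 1.0
  if (preset == "WT") {
    rho_cliff <- c(0.3, 0.8, 0.85)
    rho_center <- c(0.2, 0.6, 0.85)
    infl <- influence_params(x_edge = 3.2, x_center = 6.1,
                             beta_edge = -2, beta_center = -2)
    # cliff: slight shift out of Resting toward Navigating near the boundary
    beta[1, 2, "cliff"] <- 0.09; beta[2, 1, "cliff"] <- -0.04
    beta[2, 3, "cliff"] <- 0.24; beta[3, 2, "cliff"] <- -0.12
  } else if (preset == "RD") {
    rho_cliff <- rho_basal
    rho_center <- c(0.2, 0.5, 0.8)
    infl <- influence_params(x_edge = 3.0, x_center = 23.6,
                             beta_edge = -2, beta_center = -2)
  } else {
    rho_cliff <- rho_basal
    rho_center <- c(0.2, 0.6, 0.85)
    infl <- influence_params(x_edge = 4.4, x_center = 12,
                             beta_edge = -2, beta_center = -2)
  }
  cliff_hmm_params(step_mean = m, step_shape = a,
                   rho = cbind(basal = rho_basal, cliff = rho_cliff,
                               edge = rho_edge, center = rho_center),
                   tpm_alpha = alpha, tpm_beta = beta, infl = infl)
}

#' Serialize / restore a parameter set as JSON
#'
#' @param params A [cliff_hmm_params()] object.
#' @param path JSON file path.
#' @return `path` (write) or a [cliff_hmm_params()] (read).
#' @export
write_params <- function(params, path) {
  x <- list(K = params$K, step_mean_cm = params$step_mean,
            step_shape = params$step_shape,
            rho = as.data.frame(params$rho),
            tpm_alpha = params$tpm_alpha,
            tpm_beta = list(cliff = params$tpm_beta[, , "cliff"],
                            edge = params$tpm_beta[, , "edge"],
                            center = params$tpm_beta[, , "center"]),
            influence = lapply(params$infl, as.list))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- x$K
  beta <- array(0, c(K, K, 3), dimnames = list(NULL, NULL, c("cliff", "edge", "center")))
  for (f in c("cliff", "edge", "center"))
    beta[, , f] <- as.matrix(x$tpm_beta[[f]])
  cliff_hmm_params(
    step_mean = x$step_mean_cm, step_shape = x$step_shape,
    rho = as.matrix(x$rho), tpm_alpha = as.matrix(x$tpm_alpha), tpm_beta = beta,
    infl = influence_params(x_cliff = x$influence$cliff$x,
                            beta_cliff = x$influence$cliff$beta,
                            x_edge = x$influence$edge$x,
                            beta_edge = x$influence$edge$beta,
                            x_center = x$influence$center$x,
                            beta_center = x$influence$center$beta))
}

## ---- unconstrained parameterization used by the optimizer ----

pack_params <- function(p) {
  tr <- allowed_transitions(p$K)
  c(log(c(p$step_mean[1], diff(p$step_mean))),      # ordered means
    log(p$step_shape),
    qlogis(as.numeric(p$rho)),                      # column-major K x 4
    p$tpm_alpha[tr],
    as.numeric(apply(p$tpm_beta, 3, function(m) m[tr])),
    log(p$infl$edge["x"]), log(p$infl$center["x"]),
    log(-p$infl$edge["beta"]), log(-p$infl$center["beta"]))
}

unpack_params <- function(theta, K, infl_cliff = c(x = 6, beta = -1)) {
  nt <- 2L * (K - 1L)
  i <- 0L
  take <- function(n) { v <- theta[(i + 1L):(i + n)]; i <<- i + n; v }
  m <- cumsum(exp(take(K)))
  a <- exp(take(K))
  # clamp away from 1 so extreme draws on the unconstrained scale stay valid
  rho <- matrix(pmin(plogis(take(4L * K)), 1 - 1e-12), K, 4,
                dimnames = list(NULL, c("basal", "cliff", "edge", "center")))
  tr <- allowed_transitions(K)
  alpha <- matrix(0, K, K); alpha[tr] <- take(nt)
  beta <- array(0, c(K, K, 3), dimnames = list(NULL, NULL, c("cliff", "edge", "center")))
  for (f in 1:3) { b <- matrix(0, K, K); b[tr] <- take(nt); beta[, , f] <- b }
  x_edge <- exp(take(1L)); x_center <- exp(take(1L))
  b_edge <- -exp(take(1L)); b_center <- -exp(take(1L))
  cliff_hmm_params(step_mean = m, step_shape = a, rho = rho,
                   tpm_alpha = alpha, tpm_beta = beta,
                   infl = influence_params(x_cliff = infl_cliff["x"],
                                           beta_cliff = infl_cliff["beta"],
                                           x_edge = x_edge, beta_edge = b_edge,
                                           x_center = x_center, beta_center = b_center))
}

n_pack <- function(K) K + K + 4L * K + 4L * 2L * (K - 1L) + 4L
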