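#' Fit the phylogenetic meta-analytic multilevel model
#'
#' Gaussian multilevel meta-analysis of record-level effect sizes with
#' known per-record sampling variance:
#' \deqn{y_k \sim N(x_{s(k)}'\beta + a_{s(k)} + u_{s(k)} + b_{g(k)},\ se_k^2)}
#' with phylogenetic species effects \eqn{a \sim MVN(0, \sigma_p^2 C)},
#' independent species effects \eqn{u_i \sim N(0, \sigma_s^2)} and study
#' effects \eqn{b_g \sim N(0, \tau^2)}.  Coefficients get Normal(0, 1)
#' priors (appropriate for standardized predictors and responses bounded
#' in \[-1, 1\]); the three SDs get half-Cauchy(0, 0.05) priors.  Sampling
#' is by Gibbs updates on all conditionally Gaussian blocks with
#' stepping-out slice updates on the log SDs.
#'
#' @param frame A `phm_frame` from [build_model_frame()].
#' @param C Phylogenetic correlation matrix covering (at least) the frame's
#'   species; rows are matched by name.
#' @param chains Number of independent chains (default 2).
#' @param iter Total iterations per chain (default 12000).
#' @param warmup Warmup iterations discarded per chain (default 4000).
#' @param seed Integer seed; chain seeds are derived deterministically.
#' @param prior_beta_sd Prior SD for each coefficient (scalar or vector).
#' @param prior_sd_scale Half-Cauchy scale for the three SDs.
#' @param sigma_fixed Length-3 numeric `(sigma_p, sigma_s, tau)`; non-`NA`
#'   entries freeze that SD (0 disables the effect block) — used for
#'   conjugate closed-form checks.
#' @param jitter Diagonal jitter added to `C` before inversion.
#' @return Object of class `phm_fit` holding all retained draws (matrices
#'   with one row per draw), the per-record pointwise log-likelihood, chain
#'   ids, and the inputs needed downstream.
#' @export
fit_phylo_meta <- function(frame, C, chains = 2, iter = 12000, warmup = 4000,
                           seed = 1, prior_beta_sd = 1,
                           prior_sd_scale = 0.05,
                           sigma_fixed = c(NA, NA, NA), jitter = 1e-8) {
  stopifnot(inherits(frame, "phm_frame"), warmup < iter, chains >= 1)
  sp <- frame$species_levels
  missing <- setdiff(sp, rownames(C))
  if (length(missing))
    stop("C lacks species: ", paste(missing, collapse = ", "))
  C <- C[sp, sp, drop = FALSE]
  Cj <- C + diag(jitter, nrow(C))
  ch <- tryCatch(chol(Cj), error = function(e)
    stop("Cholesky of phylogenetic correlation failed; ",
         "increase `jitter`: ", conditionMessage(e)))
  Cinv <- chol2inv(ch)

  p <- ncol(frame$X)
  pb <- rep_len(prior_beta_sd, p)
  draws <- vector("list", chains)
  for (cc in seq_len(chains)) {
    set.seed((as.numeric(seed) * 1009 + cc * 7919) %% 2147483629)
    draws[[cc]] <- gibbs_phylo_meta_cpp(
      frame$y, frame$se^2, frame$X,
      as.integer(frame$species - 1L), as.integer(frame$study - 1L),
      Cinv, as.integer(iter), as.integer(warmup),
      pb, prior_sd_scale, as.numeric(sigma_fixed))
  }
  bind <- function(name) do.call(rbind, lapply(draws, `[[`, name))
  cat1 <- function(name) unlist(lapply(draws, `[[`, name), use.names = FALSE)
  beta <- bind("beta"); colnames(beta) <- colnames(frame$X)
  a <- bind("a"); colnames(a) <- sp
  u <- bind("u"); colnames(u) <- sp
  b <- bind("b"); colnames(b) <- frame$study_levels
  nk <- iter - warmup
  structure(list(beta = beta, a = a, u = u, b = b,
                 sigma_p = cat1("sigma_p"), sigma_s = cat1("sigma_s"),
                 tau = cat1("tau"), loglik = bind("loglik"),
                 chain = rep(seq_len(chains), each = nk),
                 n_draws = chains * nk, chains = chains,
                 iter = iter, warmup = warmup, seed = seed,
                 prior_beta_sd = pb, prior_sd_scale = prior_sd_scale,
                 sigma_fixed = sigma_fixed,
                 frame = frame, C = C),
            class = "phm_fit")
}

#' Record-level linear predictor draws
#'
#' @param fit A `phm_fit`.
#' @param include Character subset of `c("fixed", "species", "study")`.
#' @return Draws-by-records matrix of linear predictors.
#' @export
linpred <- function(fit, include = c("fixed", "species", "study")) {
  eta <- matrix(0, fit$n_draws, length(fit$frame$y))
  if ("fixed" %in% include) eta <- eta + fit$beta %*% t(fit$frame$X)
  if ("species" %in% include)
    eta <- eta + (fit$a + fit$u)[, fit$frame$species, drop = FALSE]
  if ("study" %in% include)
    eta <- eta + fit$b[, fit$frame$study, drop = FALSE]
  eta
}

#' Phylogenetic signal (Lynch's h2)
#'
#' Per-draw ratio of the phylogenetic variance to the total latent
#' among-species/among-study variance,
#' \eqn{h^2 = \sigma_p^2 / (\sigma_p^2 + \sigma_s^2 + \tau^2)} — the
#' phylogenetic mixed-model analogue of Pagel's lambda.  The known
#' per-study sampling variances are excluded from the denominator; setting
#' `include_tau = FALSE` uses \eqn{\sigma_p^2/(\sigma_p^2+\sigma_s^2)}.
#'
#' @param fit A `phm_fit`.
#' @param include_tau Include the between-study variance in the denominator.
#' @return Numeric vector of posterior draws of h2.
#' @export
lynch_h2 <- function(fit, include_tau = TRUE) {
  den <- fit$sigma_p^2 + fit$sigma_s^2 + if (include_tau) fit$tau^2 else 0
  fit$sigma_p^2 / den
}

#' Bayesian multilevel R2
#'
#' Per-draw explained-variance ratio Var(pred) / (Var(pred) + residual
#' variance).  `fixed_only` uses the fixed-effect predictor with residual
#' variance \eqn{\sigma_p^2+\sigma_s^2+\tau^2 + \overline{se^2}};
#' `conditional` uses the full linear predictor with residual variance
#' \eqn{\overline{se^2}}.
#'
#' @param fit A `phm_fit`.
#' @param mode `"fixed_only"` or `"conditional"`.
#' @return Numeric vector of posterior draws of R2.
#' @export
bayes_r2 <- function(fit, mode = c("fixed_only", "conditional")) {
  mode <- match.arg(mode)
  if (length(fit$frame$y) < 2) stop("R2 undefined for a single record")
  mse2 <- mean(fit$frame$se^2)
  if (mode == "fixed_only") {
    pred <- linpred(fit, "fixed")
    vres <- fit$sigma_p^2 + fit$sigma_s^2 + fit$tau^2 + mse2
  } else {
    pred <- linpred(fit)
    vres <- rep(mse2, fit$n_draws)
  }
  vpred <- apply(pred, 1, var)
  vpred / (vpred + vres)
}

.split_chain_matrix <- function(x, chain) {
  # draws vector + chain ids -> iterations x (2 * chains) split-chain matrix
  chs <- split(x, chain)
  n <- min(lengths(chs))
  n2 <- floor(n / 2)
  do.call(cbind, lapply(chs, function(v)
    cbind(v[seq_len(n2)], v[(n - n2 + 1):n])))
}

.rank_normalize <- function(m) {
  z <- qnorm((rank(m, ties.method = "average") - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

.rhat_basic <- function(m) {
  n <- nrow(m); M <- ncol(m)
  mu <- colMeans(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(mu)
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Split R-hat convergence diagnostic
#'
#' Rank-normalized split-chain potential scale reduction factor.  Values
#' near 1 indicate well-mixed chains.
#'
#' @param x Draws: vector (with `chain`), or iterations-by-chains matrix.
#' @param chain Chain id per draw when `x` is a vector.
#' @return R-hat (scalar); `NaN` for a constant sequence.
#' @export
rhat <- function(x, chain = NULL) {
  m <- if (is.matrix(x)) {
    n2 <- floor(nrow(x) / 2)
    cbind(x[seq_len(n2), , drop = FALSE],
          x[(nrow(x) - n2 + 1):nrow(x), , drop = FALSE])
  } else .split_chain_matrix(x, chain %||% rep(1, length(x)))
  if (diff(range(m)) == 0) return(NaN)
  .rhat_basic(.rank_normalize(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.acov_fft <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  M <- 2^ceiling(log2(2 * n))
  f <- fft(c(v, rep(0, M - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / M
  ac / n  # biased autocovariance (divided by n)
}

.ess_basic <- function(m) {
  n <- nrow(m); M <- ncol(m)
  if (n < 4 || diff(range(m)) == 0) return(NaN)
  acov <- vapply(seq_len(M), function(j) .acov_fft(m[, j]), numeric(n))
  acov <- matrix(acov, n, M)
  chain_mean <- colMeans(m)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n + if (M > 1) var(chain_mean) else 0
  if (!is.finite(var_plus) || var_plus <= 0) return(NaN)
  # Geyer: sum lagged correlations over initial positive pairs, then
  # enforce monotone decrease of the pair sums
  rho <- rep(0, n)
  rho[1] <- 1
  rho[2] <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  t <- 0
  even <- rho[1]; odd <- rho[2]
  while (t < n - 5 && is.finite(even + odd) && even + odd > 0) {
    t <- t + 2
    even <- 1 - (mean_var - mean(acov[t + 1, ])) / var_plus
    odd <- 1 - (mean_var - mean(acov[t + 2, ])) / var_plus
    if (even + odd > 0) {
      rho[t + 1] <- even
      rho[t + 2] <- odd
    }
  }
  max_t <- t
  t <- 0
  while (t <= max_t - 4) {
    t <- t + 2
    if (rho[t + 1] + rho[t + 2] > rho[t - 1] + rho[t]) {
      rho[t + 1] <- (rho[t - 1] + rho[t]) / 2
      rho[t + 2] <- rho[t + 1]
    }
  }
  tau_hat <- -1 + 2 * sum(rho[seq_len(max(max_t, 2))])
  tau_hat <- max(tau_hat, 1e-12)
  n * M / tau_hat
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size.  `kind = "bulk"` computes
#' the ESS of the rank-normalized draws; `kind = "tail"` the minimum ESS of
#' the 5% and 95% exceedance indicators.
#'
#' @param x Draws: vector (with `chain`) or iterations-by-chains matrix.
#' @param kind `"bulk"` or `"tail"`.
#' @param chain Chain id per draw when `x` is a vector.
#' @return ESS (scalar); `NaN` for a constant sequence.
#' @export
ess <- function(x, kind = c("bulk", "tail"), chain = NULL) {
  kind <- match.arg(kind)
  m <- if (is.matrix(x)) {
    n2 <- floor(nrow(x) / 2)
    cbind(x[seq_len(n2), , drop = FALSE],
          x[(nrow(x) - n2 + 1):nrow(x), , drop = FALSE])
  } else .split_chain_matrix(x, chain %||% rep(1, length(x)))
  if (diff(range(m)) == 0) return(NaN)
  if (kind == "bulk") return(.ess_basic(.rank_normalize(m)))
  qs <- quantile(m, c(0.05, 0.95))
  lo <- .ess_basic(matrix(as.numeric(m <= qs[1]), nrow(m), ncol(m)))
  hi <- .ess_basic(matrix(as.numeric(m >= qs[2]), nrow(m), ncol(m)))
  min(lo, hi)
}

#' Species-level posterior estimates
#'
#' Posterior of the species-level trait value
#' \eqn{x_s'\beta + a_s + u_s} for each species, with 95% credible
#' intervals and a credible-direction flag (interval excluding zero).
#'
#' @param fit A `phm_fit`.
#' @param prob Interval mass (default 0.95).
#' @return Data frame sorted by estimate.
#' @export
species_estimates <- function(fit, prob = 0.95) {
  mu <- fit$beta %*% t(fit$frame$X_species) + fit$a + fit$u
  al <- (1 - prob) / 2
  out <- data.frame(species = fit$frame$species_levels,
                    estimate = colMeans(mu),
                    lower = apply(mu, 2, quantile, al),
                    upper = apply(mu, 2, quantile, 1 - al))
  out$credible <- out$lower > 0 | out$upper < 0
  out[order(out$estimate), ]
}

#' Posterior-parameter summary table
#'
#' @param object A `phm_fit`.
#' @param prob Interval mass.
#' @param ... Unused.
#' @return Object of class `phm_summary`: data frame with posterior
#'   mean/median/interval, R-hat and bulk/tail ESS per parameter, plus `h2`
#'   and `R2` rows.
#' @export
summary.phm_fit <- function(object, prob = 0.95, ...) {
  al <- (1 - prob) / 2
  pars <- cbind(object$beta,
                sigma_p = object$sigma_p, sigma_s = object$sigma_s,
                tau = object$tau, h2 = lynch_h2(object),
                R2_fixed = bayes_r2(object, "fixed_only"),
                R2_conditional = bayes_r2(object, "conditional"))
  diag_par <- !colnames(pars) %in% c("h2", "R2_fixed", "R2_conditional")
  out <- data.frame(
    parameter = colnames(pars),
    mean = colMeans(pars),
    median = apply(pars, 2, median),
    sd = apply(pars, 2, sd),
    lower = apply(pars, 2, quantile, al),
    upper = apply(pars, 2, quantile, 1 - al),
    rhat = ifelse(diag_par, apply(pars, 2, rhat, chain = object$chain), NA),
    ess_bulk = ifelse(diag_par,
                      apply(pars, 2, ess, kind = "bulk", chain = object$chain), NA),
    ess_tail = ifelse(diag_par,
                      apply(pars, 2, ess, kind = "tail", chain = object$chain), NA),
    row.names = NULL)
  out$credible <- out$lower > 0 | out$upper < 0
  class(out) <- c("phm_summary", "data.frame")
  out
}

#' @export
print.phm_fit <- function(x, ...) {
  cat("phylogenetic meta-analytic fit: ", x$frame$response, "\n", sep = "")
  cat("  ", length(x$frame$y), " records, ",
      length(x$frame$species_levels), " species, ",
      x$chains, " chains x ", x$iter - x$warmup, " retained draws\n", sep = "")
  print(summary(x), digits = 3)
  invisible(x)
}

#' @export
print.phm_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Posterior predictive check on summary statistics
#'
#' Simulates replicate record sets from the fitted model (redrawing the
#' observation noise at each record's standard error) and compares the
#' observed mean and SD of the effects against the simulated reference
#' distribution.
#'
#' @param fit A `phm_fit`.
#' @param n_sim Number of simulated datasets (default 1000).
#' @return Data frame with observed value and posterior predictive p-value
#'   for the mean and SD.
#' @export
ppc_stat <- function(fit, n_sim = 1000) {
  ix <- sample.int(fit$n_draws, n_sim, replace = n_sim > fit$n_draws)
  eta <- linpred(fit)[ix, , drop = FALSE]
  nrec <- ncol(eta)
  yrep <- eta + matrix(rnorm(n_sim * nrec, 0, rep(fit$frame$se, each = n_sim)),
                       n_sim, nrec)
  obs <- c(mean = mean(fit$frame$y), sd = sd(fit$frame$y))
  sim_mean <- rowMeans(yrep)
  sim_sd <- apply(yrep, 1, sd)
  data.frame(stat = c("mean", "sd"), observed = obs,
             sim_mean = c(mean(sim_mean), mean(sim_sd)),
             p_value = c(mean(sim_mean >= obs["mean"]),
                         mean(sim_sd >= obs["sd"])),
             row.names = NULL)
}
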