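#' Fit a generalized Pareto distribution to tail exceedances
#'
#' Profile-likelihood estimator (Zhang & Stephens 2009 style) of the shape
#' `k` and scale `sigma` of a generalized Pareto distribution fitted to a
#' sample of positive exceedances.
#'
#' @param x Positive exceedances (need not be sorted).
#' @return List with `k` and `sigma`.
#' @export
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  khat <- vapply(b, function(bj) mean(log1p(-bj * x)), 0)
  l <- n * (log(-b / khat) - khat - 1)
  w <- exp(l - max(l)); w <- w / sum(w)
  bstar <- sum(b * w)
  k <- mean(log1p(-bstar * x))   # positive for heavy tails (bstar < 0)
  list(k = k, sigma = -k / bstar)
}

.qgpd <- function(p, mu, sigma, k) {
  if (abs(k) < 1e-12) mu + sigma * (-log1p(-p))
  else mu + sigma * ((1 - p)^(-k) - 1) / k
}

.logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Smooth one vector of log importance ratios; returns the smoothed log
# weights and the Pareto shape diagnostic.
.psis_smooth <- function(lw, tail_frac = 0.2) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(tail_frac * S)
  if (M < 5) return(list(lw = lw, k = -Inf))
  ord <- order(lw)
  tail_ix <- ord[(S - M + 1):S]
  cutoff <- exp(lw[ord[S - M]])
  exc <- exp(lw[tail_ix]) - cutoff
  if (all(exc <= 0)) return(list(lw = lw, k = -Inf))
  fit <- gpd_fit(exc[exc > 0])
  if (!is.finite(fit$k)) return(list(lw = lw, k = Inf))
  # replace the tail by expected order statistics of the fitted GPD
  q <- .qgpd((seq_len(M) - 0.5) / M, cutoff, fit$sigma, fit$k)
  q <- pmin(q, exp(max(lw)))
  lw[tail_ix[order(lw[tail_ix])]] <- log(q)
  list(lw = lw - max(lw), k = fit$k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out predictive density for every record
#' from a single posterior sample, stabilizing the importance ratios of
#' each left-out record by fitting a generalized Pareto distribution to
#' their largest 20%.  Records whose Pareto shape diagnostic exceeds
#' `k_threshold` are unreliable under importance sampling and are
#' re-evaluated by an exact refit without that record when `refit_hook` is
#' supplied.
#'
#' @param fit A `phm_fit` (its `loglik` matrix is draws by records).
#' @param refit_hook Optional `function(i)` returning the vector of
#'   per-draw log predictive densities of record `i` under a fit that
#'   excluded record `i`.
#' @param k_threshold Pareto-k above which an exact refit is requested.
#' @return Object of class `phm_loo`: `elpd`, `se_elpd`, `pointwise`,
#'   `pareto_k`, `n_refit`.
#' @export
psis_loo <- function(fit, refit_hook = NULL, k_threshold = 0.7) {
  ll <- fit$loglik
  n <- ncol(ll)
  pointwise <- numeric(n)
  kvec <- numeric(n)
  for (i in seq_len(n)) {
    sm <- .psis_smooth(-ll[, i])
    kvec[i] <- sm$k
    pointwise[i] <- .logsumexp(sm$lw + ll[, i]) - .logsumexp(sm$lw)
  }
  bad <- which(kvec > k_threshold)
  n_refit <- 0L
  if (length(bad)) {
    if (is.null(refit_hook)) {
      warning(length(bad), " record(s) with Pareto k > ", k_threshold,
              " and no refit hook; their elpd contributions are unreliable")
    } else {
      for (i in bad) {
        ll_i <- refit_hook(i)
        pointwise[i] <- .logsumexp(ll_i) - log(length(ll_i))
        n_refit <- n_refit + 1L
      }
    }
  }
  structure(list(elpd = sum(pointwise),
                 se_elpd = sqrt(n * var(pointwise)),
                 pointwise = pointwise, pareto_k = kvec,
                 n_refit = n_refit),
            class = "phm_loo")
}

#' @export
print.phm_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd =", format(x$elpd, digits = 5),
      "(se", paste0(format(x$se_elpd, digits = 3), ")"),
      "| max Pareto k =", format(max(x$pareto_k), digits = 3),
      "|", x$n_refit, "exact refit(s)\n")
  invisible(x)
}

#' Compare models by LOO expected log predictive density
#'
#' Ranks models by `elpd`; pairwise differences against the best model use
#' the pointwise vectors, and a "no meaningful winner" flag is set when the
#' best-vs-second difference is both < 4 and < 2 of its standard errors.
#'
#' @param loos Named list of `phm_loo` objects over identical record sets.
#' @return Data frame (class `phm_loo_compare`) sorted by elpd with columns
#'   `elpd`, `se_elpd`, `elpd_diff`, `se_diff`; attribute
#'   `no_meaningful_winner`.
#' @export
compare_loo <- function(loos) {
  stopifnot(length(loos) >= 1)
  ns <- vapply(loos, function(l) length(l$pointwise), 0L)
  if (length(unique(ns)) != 1) stop("models were fitted to different record sets")
  if (is.null(names(loos)))
    names(loos) <- paste0("model", seq_along(loos))
  ord <- order(vapply(loos, `[[`, 0, "elpd"), decreasing = TRUE)
  loos <- loos[ord]
  best <- loos[[1]]
  n <- ns[1]
  diffs <- vapply(loos, function(l) l$elpd - best$elpd, 0)
  se_diffs <- vapply(loos, function(l) {
    d <- l$pointwise - best$pointwise
    sqrt(n * var(d))
  }, 0)
  out <- data.frame(model = names(loos),
                    elpd = vapply(loos, `[[`, 0, "elpd"),
                    se_elpd = vapply(loos, `[[`, 0, "se_elpd"),
                    elpd_diff = diffs, se_diff = se_diffs,
                    row.names = NULL)
  nmw <- if (nrow(out) > 1) {
    d2 <- abs(out$elpd_diff[2])
    d2 < 4 && d2 <= 2 * out$se_diff[2]
  } else NA
  attr(out, "no_meaningful_winner") <- nmw
  class(out) <- c("phm_loo_compare", "data.frame")
  out
}

.credible_table <- function(fit, prob = 0.95) {
  s <- summary(fit, prob = prob)
  s <- s[s$parameter %in% colnames(fit$beta) & s$parameter != "(Intercept)", ]
  s$ratio <- abs(s$median) / s$sd
  s
}

#' Iterative model reduction by credibility
#'
#' Starting from an initial covariate set, repeatedly refits the model and
#' removes the single least-supported non-credible predictor (smallest
#' |posterior median| / SD across its design columns) until every remaining
#' predictor is credible (95% interval excluding zero) or none remain.  A
#' categorical predictor is only removable when every one of its dummy
#' levels is non-credible, and is removed as a block.
#'
#' @param records,traits,response Passed to [build_model_frame()].
#' @param covariates Initial covariate names.
#' @param C Phylogenetic correlation matrix.
#' @param exclude_species Optional species excluded throughout.
#' @param prob Credibility level.
#' @param ... Passed to [fit_phylo_meta()] (chains, iter, warmup, seed...).
#' @return List with the final `fit`, final `covariates`, and `trace`
#'   (character vector of removals in order).
#' @export
reduce_model <- function(records, traits, response, covariates, C,
                         exclude_species = NULL, prob = 0.95, ...) {
  covs <- covariates
  trace <- character()
  repeat {
    frame <- build_model_frame(records, traits, response, covs,
                               exclude_species = exclude_species)
    fit <- fit_phylo_meta(frame, C, ...)
    if (length(covs) == 0) return(list(fit = fit, covariates = covs,
                                       trace = trace))
    tab <- .credible_table(fit, prob)
    tab$group <- fit$frame$groups[tab$parameter]
    by_group <- split(tab, tab$group)
    removable <- vapply(by_group, function(g) all(!g$credible), TRUE)
    if (!any(removable)) return(list(fit = fit, covariates = covs,
                                     trace = trace))
    scores <- vapply(by_group[removable], function(g) min(g$ratio), 0)
    drop_cov <- names(scores)[which.min(scores)]
    covs <- setdiff(covs, drop_cov)
    trace <- c(trace, drop_cov)
  }
}

#' Load a hypothesis battery from YAML
#'
#' The battery file maps hypothesis names to covariate sets and the
#' response(s) they apply to; the engine treats it purely as data, so the
#' sets can be edited freely.
#'
#' @param path YAML file; defaults to the battery shipped with the package.
#' @return Named list of `list(covariates, applies_to)`.
#' @export
load_battery <- function(path = system.file("extdata", "battery.yaml",
                                            package = "phylohand")) {
  bat <- yaml::read_yaml(path)
  for (nm in names(bat)) {
    if (is.null(bat[[nm]]$covariates) || !length(bat[[nm]]$covariates))
      stop("hypothesis '", nm, "' has no covariates")
    bat[[nm]]$applies_to <- bat[[nm]]$applies_to %||% "both"
  }
  bat
}

#' Run a hypothesis battery across a tree set
#'
#' Fits every hypothesis (covariate set) for one response over each tree in
#' `trees`, averaging per-tree posterior summaries (not pooling draws), and
#' compares hypotheses by PSIS-LOO computed on the maximum clade
#' credibility tree.
#'
#' @param records,traits Data (see [load_dataset()]).
#' @param trees List of `phylo` objects.
#' @param battery Battery list from [load_battery()].
#' @param response `"MHI"` or `"MABSHI"`.
#' @param exclude_species Optional species excluded from all fits.
#' @param seed Master seed; per-tree child seeds are derived from it.
#' @param ... Passed to [fit_phylo_meta()].
#' @return List with `summaries` (per hypothesis, tree-averaged summary
#'   data frame), `comparison` (from [compare_loo()], over hypotheses with
#'   at least one credible predictor, or all if none), and `loos`.
#' @export
run_battery <- function(records, traits, trees, battery, response,
                        exclude_species = NULL, seed = 1, ...) {
  mcc <- mcc_tree(trees)
  summaries <- list(); loos <- list(); any_credible <- logical()
  for (nm in names(battery)) {
    hyp <- battery[[nm]]
    if (!hyp$applies_to %in% c("both", response)) next
    per_tree <- vector("list", length(trees))
    for (ti in seq_along(trees)) {
      C <- phylo_corr(trees[[ti]])
      frame <- build_model_frame(records, traits, response, hyp$covariates,
                                 exclude_species = exclude_species)
      fit <- fit_phylo_meta(frame, C,
                            seed = (as.numeric(seed) * 131071 + ti) %%
                              2147483629, ...)
      per_tree[[ti]] <- summary(fit)
    }
    avg <- per_tree[[1]]
    num <- vapply(avg, is.numeric, TRUE)
    for (cn in names(avg)[num])
      avg[[cn]] <- rowMeans(vapply(per_tree, function(s) s[[cn]],
                                   numeric(nrow(avg))))
    avg$credible <- avg$lower > 0 | avg$upper < 0
    summaries[[nm]] <- avg
    fixed <- avg$parameter %in% setdiff(colnames(fit$beta), "(Intercept)")
    any_credible[nm] <- any(avg$credible[fixed])
    Cm <- phylo_corr(mcc)
    frame <- build_model_frame(records, traits, response, hyp$covariates,
                               exclude_species = exclude_species)
    fit_mcc <- fit_phylo_meta(frame, Cm, seed = seed, ...)
    loos[[nm]] <- psis_loo(fit_mcc)
  }
  cmp_set <- if (any(any_credible)) loos[any_credible] else loos
  list(summaries = summaries,
       comparison = if (length(cmp_set) > 1) compare_loo(cmp_set) else NULL,
       loos = loos, any_credible = any_credible)
}
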