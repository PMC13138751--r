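#' Conditional Brownian-motion draw for unobserved tips
#'
#' Given per-draw fitted phylogenetic effects for observed species, returns
#' per-draw conditional means and the (draw-independent) conditional
#' correlation structure for a set of target tips:
#' \deqn{a^* \mid a \sim N(C_{*o} C_{oo}^{-1} a,\ \sigma_p^2 (C_{**} -
#'   C_{*o} C_{oo}^{-1} C_{o*}))}
#'
#' @param C_full Phylogenetic correlation matrix over observed + target
#'   tips (targets may have diagonal < 1 on fossil-bearing trees).
#' @param obs Observed tip labels (order must match columns of `a`).
#' @param targets Target tip labels.
#' @return List with `K` (targets-by-obs kriging weights) and `Sigma`
#'   (targets-by-targets conditional correlation, to be scaled by
#'   `sigma_p^2`).
#' @keywords internal
.bm_condition <- function(C_full, obs, targets) {
  C_oo <- C_full[obs, obs, drop = FALSE] + diag(1e-10, length(obs))
  C_to <- C_full[targets, obs, drop = FALSE]
  C_tt <- C_full[targets, targets, drop = FALSE]
  K <- C_to %*% solve(C_oo)
  Sigma <- C_tt - K %*% t(C_to)
  Sigma <- (Sigma + t(Sigma)) / 2
  list(K = K, Sigma = Sigma)
}

.summarize_prediction <- function(taxon, draws, observed = NULL, prob = 0.95) {
  al <- (1 - prob) / 2
  ci <- quantile(draws, c(al, 1 - al))
  out <- list(taxon = taxon, draws = draws, mean = mean(draws),
              lower = ci[[1]], upper = ci[[2]], observed = observed,
              percentile_of_observed = if (!is.null(observed))
                mean(draws <= observed) else NULL,
              outlier = if (!is.null(observed))
                observed < ci[[1]] || observed > ci[[2]] else NA)
  class(out) <- "phm_prediction"
  out
}

#' @export
print.phm_prediction <- function(x, ...) {
  cat("posterior predictive for ", x$taxon, ": mean ",
      format(x$mean, digits = 3), " [", format(x$lower, digits = 3), ", ",
      format(x$upper, digits = 3), "]\n", sep = "")
  if (!is.null(x$observed))
    cat("  observed ", format(x$observed, digits = 3), " (percentile ",
        format(x$percentile_of_observed, digits = 3), ") -> ",
        if (isTRUE(x$outlier)) "OUTLIER" else "within interval", "\n", sep = "")
  invisible(x)
}

#' Phylogenetic outlier test
#'
#' Posterior predictive distribution of the response for a species that
#' was excluded from fitting, given its position in the tree, its
#' covariates (projected with the fit's stored transform constants), and a
#' meta-analytic error at `se_target`.  Per retained draw the target's
#' phylogenetic effect is drawn from its conditional Brownian-motion
#' distribution given the fitted species effects, a fresh non-phylogenetic
#' species effect is added, and observation noise at `se_target` is
#' applied.  An observed value outside the 95% predictive interval marks
#' the species as an evolutionary outlier: more change than its
#' phylogenetic position and covariates can explain.
#'
#' @param fit A `phm_fit` whose data exclude `target`.
#' @param tree_with_target Tree containing the fitted species and `target`.
#' @param target Tip label of the held-out species.
#' @param x_target Named vector/1-row data frame of the target's raw
#'   covariates (same columns as the fit's covariates).
#' @param se_target Standard error for the meta-analytic component.
#' @param observed Optional observed value of the response.
#' @param prob Interval mass for the outlier flag.
#' @return A `phm_prediction`.
#' @export
phylo_outlier_test <- function(fit, tree_with_target, target, x_target,
                               se_target, observed = NULL, prob = 0.95) {
  target <- normalize_labels(target)
  obs_sp <- fit$frame$species_levels
  if (target %in% obs_sp) stop("target species was part of the fitted data")
  C_full <- phylo_corr(tree_with_target, c(obs_sp, target))
  cond <- .bm_condition(C_full, obs_sp, target)
  x_row <- .project_covariates(fit, x_target, target)
  s2_cond <- max(cond$Sigma[1, 1], 0)
  nd <- fit$n_draws
  astar <- as.vector(fit$a %*% t(cond$K)) +
    fit$sigma_p * sqrt(s2_cond) * rnorm(nd)
  ustar <- fit$sigma_s * rnorm(nd)
  draws <- as.vector(fit$beta %*% x_row) + astar + ustar +
    rnorm(nd, 0, se_target)
  .summarize_prediction(target, draws, observed, prob)
}

# Project a new species' raw covariates onto the fitted design scale.
.project_covariates <- function(fit, x_target, taxon) {
  covs <- fit$frame$covariates
  if (length(covs) == 0) return(c("(Intercept)" = 1))
  df <- as.data.frame(as.list(x_target))
  df$species <- taxon
  tc <- transform_covariates(df, covs, constants = fit$frame$constants)
  x <- c("(Intercept)" = 1,
         setNames(as.vector(tc$X[1, , drop = FALSE]), colnames(tc$X)))
  miss <- setdiff(colnames(fit$frame$X), names(x))
  if (length(miss)) stop("covariates required by the fit are missing: ",
                         paste(miss, collapse = ", "))
  xr <- x[colnames(fit$frame$X)]
  cont <- intersect(covs, c(CONTINUOUS_TRAITS, PROPORTION_TRAITS))
  extreme <- cont[abs(xr[cont]) > 3]
  if (length(extreme))
    warning("covariate(s) far outside the training range (|z| > 3): ",
            paste(extreme, collapse = ", "))
  xr
}

#' Predict trait values for fossil taxa on a grafted tree
#'
#' Joint conditional Brownian-motion prediction of the response for extinct
#' tips grafted onto the fitted phylogeny.  Per posterior draw the fossil
#' phylogenetic effects are drawn jointly from their conditional
#' distribution given the fitted extant species effects (fossil tips have
#' diagonal entries < 1, having had less time to accrue variance), fixed
#' effects are added from the fossils' covariates transformed with the
#' extant fit's constants, and fresh non-phylogenetic species effects and
#' measurement error at `se_assumption` are marginalized over.
#' Predictions are reported on the Gaussian modeling scale and are not
#' truncated to the response bounds; values outside them trigger a
#' warning.
#'
#' @param fit A `phm_fit` on extant species.
#' @param grafted_tree Tree containing the fitted species plus fossil tips
#'   (see [graft_clade()]).
#' @param fossil_traits Data frame with `species` plus the raw covariates
#'   required by the fit.
#' @param se_assumption Standard error for the meta-analytic component
#'   (e.g., the pooled human-level SE from [pooled_se()]).
#' @param prob Interval mass.
#' @return List of `phm_prediction`, one per fossil, plus a `table`
#'   attribute with the per-taxon summaries.
#' @export
predict_fossils <- function(fit, grafted_tree, fossil_traits, se_assumption,
                            prob = 0.95) {
  fossils <- normalize_labels(fossil_traits$species)
  obs_sp <- fit$frame$species_levels
  overlap <- intersect(fossils, obs_sp)
  if (length(overlap)) stop("fossil taxa already in the fitted data: ",
                            paste(overlap, collapse = ", "))
  C_full <- phylo_corr(grafted_tree, c(obs_sp, fossils))
  cond <- .bm_condition(C_full, obs_sp, fossils)
  nf <- length(fossils)
  ev <- eigen(cond$Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nf)

  Xf <- t(vapply(seq_len(nf), function(i)
    .project_covariates(fit,
                        fossil_traits[i, setdiff(names(fossil_traits),
                                                 "species"), drop = FALSE],
                        fossils[i]),
    numeric(ncol(fit$frame$X))))

  nd <- fit$n_draws
  astar <- fit$a %*% t(cond$K) +
    (matrix(rnorm(nd * nf), nd, nf) %*% t(L)) * fit$sigma_p
  ystar <- fit$beta %*% t(Xf) + astar +
    matrix(rnorm(nd * nf, 0, fit$sigma_s), nd, nf) +
    matrix(rnorm(nd * nf, 0, se_assumption), nd, nf)

  preds <- lapply(seq_len(nf), function(i)
    .summarize_prediction(fossils[i], ystar[, i], prob = prob))
  names(preds) <- fossils
  tab <- data.frame(taxon = fossils,
                    mean = vapply(preds, `[[`, 0, "mean"),
                    lower = vapply(preds, `[[`, 0, "lower"),
                    upper = vapply(preds, `[[`, 0, "upper"),
                    row.names = NULL)
  if (fit$frame$response == "MHI" && any(abs(tab$mean) > 1) ||
      fit$frame$response == "MABSHI" && any(tab$mean < 0 | tab$mean > 1))
    warning("some predictions fall outside the response bounds; ",
            "reported untruncated")
  attr(preds, "table") <- tab
  preds
}

#' Precision-weighted pooled standard error
#'
#' Pools the standard errors of one species' records by inverse-variance
#' weighting: `1 / sqrt(sum(1 / se^2))`.  Used to set the "human-level"
#' meta-analytic error when predicting fossils.
#'
#' @param records Record data frame.
#' @param species Species label.
#' @param response Response to pool over.
#' @return Pooled SE (scalar).
#' @export
pooled_se <- function(records, species, response) {
  species <- normalize_labels(species)
  se <- records$se[normalize_labels(records$species) == species &
                   records$response == response]
  if (!length(se)) stop("no records for ", species, " / ", response)
  1 / sqrt(sum(1 / se^2))
}
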