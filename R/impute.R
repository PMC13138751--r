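#' Multivariate Brownian-motion log-likelihood with missing cells
#'
#' Log density of the observed cells of a species-by-trait matrix under a
#' multivariate Brownian-motion model on a phylogeny: the vectorized data
#' are jointly Gaussian with covariance `R_bm %x% C` (trait rate matrix
#' Kronecker the shared-path-length matrix) and mean `root_mean` replicated
#' across species.  Missing cells are marginalized by row/column deletion.
#'
#' @param tree Rooted `phylo`; row names of `X` must be tip labels.
#' @param X Numeric species-by-trait matrix with `NA` for missing cells.
#' @param R_bm Symmetric positive-definite trait rate matrix (per unit
#'   branch length).
#' @param root_mean Length-`ncol(X)` vector of ancestral means.
#' @return The log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, X, R_bm, root_mean) {
  X <- as.matrix(X)
  S <- nrow(X); p <- ncol(X)
  stopifnot(length(root_mean) == p, nrow(R_bm) == p)
  if (any(colSums(!is.na(X)) == 0)) stop("trait with no observed values")
  C <- phylo_corr(tree, rownames(X), scale = FALSE)
  Rl <- tryCatch(chol(R_bm), error = function(e) NULL)
  if (is.null(Rl)) stop("R_bm is not positive definite")
  V <- kronecker(R_bm, C)          # cell (t-1)*S+i  <->  species i, trait t
  mu <- rep(root_mean, each = S)
  x <- as.vector(X)
  obs <- !is.na(x)
  Vo <- V[obs, obs, drop = FALSE]
  L <- chol(Vo + diag(1e-10, sum(obs)))
  z <- backsolve(L, x[obs] - mu[obs], transpose = TRUE)
  -0.5 * sum(obs) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

.theta_to_R <- function(theta, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

#' Fit a multivariate Brownian-motion model and impute missing cells
#'
#' Maximizes the [bm_loglik()] over the trait rate matrix (log-Cholesky
#' parameterization, so the optimization is unconstrained) and the root
#' means, then fills every missing cell with its conditional expectation
#' given all observed cells under the fitted joint Gaussian, recording the
#' conditional variance of each imputed cell.  This is the standard
#' phylogenetic imputation used to complete sparsely measured species
#' covariates (e.g., intermembral index from body mass).
#'
#' @param tree Rooted `phylo`.
#' @param X Species-by-trait matrix with `NA`s; row names are tip labels.
#' @param max_restarts Extra optimizer starts if convergence fails.
#' @return Object of class `bm_imputation`: list with `completed`,
#'   `predictive_variance` (0 at observed cells), `loglik`, `R_bm`,
#'   `root_mean`, `convergence`.
#' @export
fit_and_impute <- function(tree, X, max_restarts = 2) {
  X <- as.matrix(X)
  S <- nrow(X); p <- ncol(X)
  C <- phylo_corr(tree, rownames(X), scale = FALSE)
  depth <- mean(diag(C))

  # moment-based start: pairwise-complete trait covariance per unit depth
  R0 <- cov(X, use = "pairwise.complete.obs") / depth
  R0[!is.finite(R0)] <- 0
  ev <- eigen(R0, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-4 * max(abs(ev$values), 1e-8))
  R0 <- ev$vectors %*% diag(ev$values, p) %*% t(ev$vectors)
  L0 <- t(chol(R0))
  diag(L0) <- log(diag(L0))
  theta0 <- c(L0[lower.tri(L0, diag = TRUE)], colMeans(X, na.rm = TRUE))
  nq <- p * (p + 1) / 2

  nll <- function(theta) {
    R <- .theta_to_R(theta[seq_len(nq)], p)
    mu <- theta[nq + seq_len(p)]
    ll <- tryCatch(bm_loglik(tree, X, R, mu), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  for (r in 0:max_restarts) {
    start <- if (r == 0) theta0 else theta0 + rnorm(length(theta0), 0, 0.3)
    opt <- optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    opt <- optim(opt$par, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0) break
  }
  if (best$convergence != 0)
    warning("BM optimizer did not formally converge; using best value found")

  R <- .theta_to_R(best$par[seq_len(nq)], p)
  mu <- best$par[nq + seq_len(p)]
  dimnames(R) <- list(colnames(X), colnames(X))

  completed <- X
  pv <- matrix(0, S, p, dimnames = dimnames(X))
  x <- as.vector(X)
  obs <- !is.na(x)
  if (any(!obs)) {
    V <- kronecker(R, C)
    m <- rep(mu, each = S)
    Voo <- V[obs, obs, drop = FALSE] + diag(1e-10, sum(obs))
    Vmo <- V[!obs, obs, drop = FALSE]
    K <- Vmo %*% solve(Voo)
    cond_mean <- m[!obs] + K %*% (x[obs] - m[obs])
    cond_var <- diag(V[!obs, !obs, drop = FALSE] - K %*% t(Vmo))
    miss_idx <- which(!obs)
    completed[miss_idx] <- cond_mean
    pv[miss_idx] <- pmax(cond_var, 0)
  }

  structure(list(completed = completed, predictive_variance = pv,
                 loglik = -best$value, R_bm = R, root_mean = setNames(mu, colnames(X)),
                 convergence = best$convergence),
            class = "bm_imputation")
}

#' @export
print.bm_imputation <- function(x, ...) {
  cat("Multivariate Brownian-motion imputation\n")
  cat("  traits:", paste(colnames(x$completed), collapse = ", "), "\n")
  cat("  imputed cells:", sum(x$predictive_variance > 0), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Impute missing species covariates on a phylogeny
#'
#' Convenience wrapper completing the covariate table used by the handedness
#' models: the target traits (by default the intermembral index `IMI` and
#' body-mass sexual dimorphism `DIM`) are imputed jointly with the auxiliary
#' trait (`BM`, body mass) under multivariate Brownian motion on the
#' supplied tree.  Imputation is done on the log10 scale and the imputed
#' values are back-transformed; all other columns pass through untouched.
#'
#' @param traits Data frame with a `species` column and numeric covariates.
#' @param tree Rooted `phylo` covering all species (typically the maximum
#'   clade credibility tree).
#' @param targets Columns to impute.
#' @param aux Auxiliary (always observed) column.
#' @return List with `traits` (completed data frame) and `report`
#'   (data frame of imputed cells with predictive variances on log10 scale).
#' @export
impute_traits <- function(traits, tree, targets = c("IMI", "DIM"), aux = "BM") {
  stopifnot("species" %in% names(traits))
  cols <- c(aux, intersect(targets, names(traits)))
  X <- as.matrix(traits[, cols, drop = FALSE])
  if (any(X <= 0, na.rm = TRUE)) stop("log10 imputation needs positive traits")
  rownames(X) <- normalize_labels(traits$species)
  lX <- log10(X)
  if (!anyNA(lX)) {
    return(list(traits = traits,
                report = data.frame(species = character(), trait = character(),
                                    value = numeric(), variance = numeric())))
  }
  fit <- fit_and_impute(tree, lX)
  miss <- which(is.na(lX), arr.ind = TRUE)
  report <- data.frame(species = rownames(lX)[miss[, 1]],
                       trait = cols[miss[, 2]],
                       value = 10^fit$completed[miss],
                       variance = fit$predictive_variance[miss])
  out <- traits
  for (i in seq_len(nrow(miss)))
    out[[cols[miss[i, 2]]]][miss[i, 1]] <- 10^fit$completed[miss[i, 1], miss[i, 2]]
  list(traits = out, report = report)
}
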