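# Shared fixtures and independent oracles for the test suite.

# A minimal record table: one row per (species, study).
make_records <- function(species, effect, se, study = NULL, n = 20,
                         response = "MHI") {
  data.frame(species = species,
             study_id = study %||% paste0("st", seq_along(species)),
             response = response, effect = effect, se = se, n = n,
             task = "tube", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

identity_C <- function(labels) {
  C <- diag(length(labels))
  dimnames(C) <- list(labels, labels)
  C
}

# Closed-form Gaussian posterior for beta with all variance components
# fixed at zero: y ~ N(X beta, se^2), beta ~ N(0, diag(prior_sd^2)).
conjugate_beta_posterior <- function(X, y, se, prior_sd = 1) {
  W <- diag(1 / se^2, length(y))
  P <- t(X) %*% W %*% X + diag(1 / prior_sd^2, ncol(X))
  V <- solve(P)
  list(mean = as.vector(V %*% t(X) %*% W %*% y), cov = V)
}

# Dense MVN log density (independent of the package's internals).
dmvnorm_log <- function(x, mu, V) {
  L <- chol(V)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# Brute-force phylogenetic covariance: shared root-to-MRCA path length for
# every tip pair, by summing edges along enumerated root-to-tip paths.
bruteforce_shared_paths <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(nt), path_edges)
  V <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(tree$edge.length[shared])
  }
  V
}

# Per-draw log predictive density of record i of `frame` under a fit
# (used by exact-LOO oracles and refit hooks).  Requires the record's
# study to be present in the fit.
record_loglik <- function(fit, frame, i) {
  sp <- frame$species_levels[frame$species[i]]
  stu <- frame$study_levels[frame$study[i]]
  eta <- as.vector(fit$beta %*% frame$X[i, ]) +
    fit$a[, sp] + fit$u[, sp] +
    (if (stu %in% colnames(fit$b)) fit$b[, stu] else
       rnorm(fit$n_draws, 0, fit$tau))
  dnorm(frame$y[i], eta, frame$se[i], log = TRUE)
}

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

quick_iter <- list(chains = 1, iter = 1500, warmup = 500)
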