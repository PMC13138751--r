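test_that("ridge limit: C = identity, one precise record per species,
           fixed variances reproduce the closed-form posterior", {
  set.seed(41)
  n <- 25
  tra <- data.frame(species = paste0("s", 1:n), BM = exp(rnorm(n, 3, 1)),
                    ECV = exp(rnorm(n, 5, 0.7)))
  rec <- make_records(tra$species, rnorm(n, 0.1, 0.3), rep(0.02, n))
  fr <- build_model_frame(rec, tra, "MHI", c("BM", "ECV"))
  fit <- fit_phylo_meta(fr, identity_C(fr$species_levels), chains = 2,
                        iter = 4000, warmup = 500, seed = 7,
                        sigma_fixed = c(0, 0, 0))
  oracle <- conjugate_beta_posterior(fr$X, fr$y, fr$se)
  for (j in 1:3) {
    mcse <- sd(fit$beta[, j]) / sqrt(ess(fit$beta[, j], chain = fit$chain))
    expect_lt(abs(mean(fit$beta[, j]) - oracle$mean[j]), 3 * mcse)
    expect_equal(sd(fit$beta[, j]), sqrt(oracle$cov[j, j]), tolerance = 0.05)
  }
})

test_that("lynch_h2 computes the latent variance share", {
  fake <- structure(list(sigma_p = c(1, 2), sigma_s = c(1, 0),
                         tau = c(1, 0)), class = "phm_fit")
  expect_equal(lynch_h2(fake), c(1 / 3, 1))
  expect_equal(lynch_h2(fake, include_tau = FALSE), c(1 / 2, 1))
})

test_that("bayes_r2 behaves at the degenerate corners", {
  set.seed(42)
  n <- 12
  tra <- data.frame(species = paste0("s", 1:n), BM = exp(rnorm(n, 3, 1)))
  # strong linear signal, tiny noise, conditional R2 -> 1
  rec <- make_records(tra$species, scale(log10(tra$BM))[, 1] * 0.5,
                      rep(0.01, n))
  fr <- build_model_frame(rec, tra, "MHI", "BM")
  fit <- fit_phylo_meta(fr, identity_C(fr$species_levels),
                        chains = 1, iter = 1200, warmup = 400, seed = 2,
                        sigma_fixed = c(0, 0, 0))
  expect_gt(median(bayes_r2(fit, "conditional")), 0.95)
  expect_gt(median(bayes_r2(fit, "fixed_only")), 0.9)

  # intercept-only fit has zero fixed-effect variance
  fr0 <- build_model_frame(rec, tra, "MHI")
  fit0 <- fit_phylo_meta(fr0, identity_C(fr0$species_levels),
                         chains = 1, iter = 800, warmup = 300, seed = 2,
                         sigma_fixed = c(0, 0, 0))
  expect_equal(max(bayes_r2(fit0, "fixed_only")), 0, tolerance = 1e-12)
})

test_that("rhat separates converged from non-mixing chains", {
  set.seed(43)
  x <- matrix(rnorm(8000), 4000, 2)
  expect_lt(abs(rhat(x) - 1), 0.01)
  x2 <- x; x2[, 2] <- x2[, 2] + 10
  expect_gt(rhat(x2), 1.1)
  expect_true(is.nan(rhat(matrix(1, 100, 2))))
})

test_that("ess matches analytic values for white noise and AR(1)", {
  set.seed(44)
  v <- rnorm(4000)
  expect_equal(ess(matrix(v, ncol = 1)), 4000, tolerance = 0.15)
  rho <- 0.9
  ar <- numeric(4000); ar[1] <- rnorm(1)
  for (i in 2:4000) ar[i] <- rho * ar[i - 1] + rnorm(1, 0, sqrt(1 - rho^2))
  expect_equal(ess(matrix(ar, ncol = 1)), 4000 * (1 - rho) / (1 + rho),
               tolerance = 0.25)
  expect_true(is.nan(ess(matrix(1, 100, 1))))
})

test_that("species estimates track precise concordant studies", {
  # single species, three precise agreeing studies: the species-level
  # estimate collapses onto the measured effect (shrinkage-free limit)
  tra <- data.frame(species = "A")
  rec <- make_records(rep("A", 3), rep(0.6, 3), rep(0.01, 3))
  fr <- build_model_frame(rec, tra, "MHI")
  fit <- fit_phylo_meta(fr, identity_C("A"), chains = 1,
                        iter = 2000, warmup = 500, seed = 3)
  est <- species_estimates(fit)
  expect_equal(est$estimate, 0.6, tolerance = 0.05)
  expect_true(est$credible)
})

test_that("inflating all standard errors cannot sharpen the posterior", {
  cfg <- sim_config(seed = 51, n_species = 15, n_trees = 1)
  tr <- simulate_trees(cfg)[[1]]
  d <- simulate_dataset(cfg, tr)
  fr1 <- build_model_frame(d$records, d$traits, "MHI", "ECV")
  rec10 <- d$records; rec10$se <- rec10$se * 10
  fr10 <- build_model_frame(rec10, d$traits, "MHI", "ECV")
  C <- phylo_corr(tr)
  f1 <- fit_phylo_meta(fr1, C, chains = 1, iter = 2000, warmup = 500, seed = 5)
  f10 <- fit_phylo_meta(fr10, C, chains = 1, iter = 2000, warmup = 500, seed = 5)
  expect_gt(sd(f10$beta[, "ECV"]), sd(f1$beta[, "ECV"]))
})

test_that("h2 and R2 are invariant to record order and species relabeling", {
  cfg <- sim_config(seed = 52, n_species = 12, n_trees = 1)
  tr <- simulate_trees(cfg)[[1]]
  d <- simulate_dataset(cfg, tr)
  C <- phylo_corr(tr)
  fr <- build_model_frame(d$records, d$traits, "MHI", "ECV")
  fit <- fit_phylo_meta(fr, C, chains = 1, iter = 2000, warmup = 1000, seed = 9)

  perm <- sample(nrow(d$records))
  frp <- build_model_frame(d$records[perm, ], d$traits, "MHI", "ECV")
  fitp <- fit_phylo_meta(frp, C, chains = 1, iter = 2000, warmup = 1000,
                         seed = 9)
  expect_equal(mean(lynch_h2(fitp)), mean(lynch_h2(fit)), tolerance = 0.05)
  expect_equal(mean(bayes_r2(fitp, "fixed_only")),
               mean(bayes_r2(fit, "fixed_only")), tolerance = 0.05)

  relab <- setNames(sprintf("zz%02d", seq_along(tr$tip.label)), tr$tip.label)
  tr2 <- tr; tr2$tip.label <- unname(relab[tr$tip.label])
  rec2 <- d$records; rec2$species <- unname(relab[rec2$species])
  tra2 <- d$traits; tra2$species <- unname(relab[tra2$species])
  fr2 <- build_model_frame(rec2, tra2, "MHI", "ECV")
  fit2 <- fit_phylo_meta(fr2, phylo_corr(tr2), chains = 1, iter = 2000,
                         warmup = 1000, seed = 9)
  expect_equal(mean(lynch_h2(fit2)), mean(lynch_h2(fit)), tolerance = 0.05)
})

test_that("posterior predictive checks bracket the observed summaries", {
  cfg <- sim_config(seed = 53, n_species = 20, n_trees = 1)
  tr <- simulate_trees(cfg)[[1]]
  d <- simulate_dataset(cfg, tr)
  fr <- build_model_frame(d$records, d$traits, "MHI", "ECV")
  fit <- fit_phylo_meta(fr, phylo_corr(tr), chains = 1, iter = 2500,
                        warmup = 500, seed = 7)
  set.seed(1)
  ppc <- ppc_stat(fit, n_sim = 1000)
  expect_true(all(ppc$p_value > 0.01 & ppc$p_value < 0.99))
})

test_that("summary reports coherent intervals and diagnostics", {
  cfg <- sim_config(seed = 54, n_species = 10, n_trees = 1)
  tr <- simulate_trees(cfg)[[1]]
  d <- simulate_dataset(cfg, tr)
  fr <- build_model_frame(d$records, d$traits, "MHI", "ECV")
  fit <- fit_phylo_meta(fr, phylo_corr(tr), chains = 2, iter = 1500,
                        warmup = 500, seed = 5)
  s <- summary(fit)
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  h2row <- s[s$parameter == "h2", ]
  expect_true(h2row$lower >= 0 && h2row$upper <= 1)
  expect_true(all(s$rhat[s$parameter %in% c("(Intercept)", "ECV")] < 1.05))
  expect_true(all(fit$sigma_p > 0) && all(fit$sigma_s > 0) &&
                all(fit$tau > 0))
  expect_equal(fit$n_draws, 2 * 1000)
})
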