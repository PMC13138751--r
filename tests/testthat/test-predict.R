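test_that("the conditioning step equals dense joint-Gaussian conditioning", {
  set.seed(81)
  for (rep in 1:5) {
    tr <- ape::rcoal(6)
    # shorten one tip to emulate a fossil
    e <- which(tr$edge[, 2] == 1)
    tr$edge.length[e] <- tr$edge.length[e] * 0.4
    C <- phylo_corr(tr)
    obs <- tr$tip.label[3:6]
    tgt <- tr$tip.label[1:2]
    cond <- phylohand:::.bm_condition(C, obs, tgt)
    # oracle: direct partitioned formulas on the full covariance
    Coo <- C[obs, obs]; Cto <- C[tgt, obs]; Ctt <- C[tgt, tgt]
    K_or <- Cto %*% solve(Coo + diag(1e-10, 4))
    S_or <- Ctt - K_or %*% t(Cto)
    expect_equal(cond$K, K_or, tolerance = 1e-8)
    expect_equal(cond$Sigma, (S_or + t(S_or)) / 2, tolerance = 1e-8)
    # conditional mean for a random effect vector matches too
    a <- rnorm(4)
    expect_equal(as.vector(cond$K %*% a), as.vector(K_or %*% a),
                 tolerance = 1e-8)
  }
})

test_that("with no phylogenetic pull the predictive centers on the
           intercept", {
  set.seed(82)
  n <- 15
  tra <- data.frame(species = paste0("s", 1:n))
  rec <- make_records(tra$species, rnorm(n, 0.4, 0.05), rep(0.05, n))
  fr <- build_model_frame(rec, tra, "MHI")
  tr <- simulate_trees(sim_config(seed = 1, n_species = n + 1,
                                  n_trees = 1))[[1]]
  tr$tip.label <- c(tra$species, "target")
  fit <- fit_phylo_meta(fr, phylo_corr(tr), chains = 1, iter = 2000,
                        warmup = 500, seed = 3,
                        sigma_fixed = c(0, 0.01, 0.01))
  ot <- phylo_outlier_test(fit, tr, "target", NULL, se_target = 0.01)
  expect_equal(ot$mean, mean(fit$beta[, 1]), tolerance = 0.01)
})

test_that("a zero-divergence clone collapses onto its twin's value", {
  set.seed(83)
  base <- simulate_trees(sim_config(seed = 2, n_species = 8, n_trees = 1))[[1]]
  # attach a clone at (essentially) zero distance from tip sp01
  twin <- which(base$tip.label == "sp01")
  tr <- ape::bind.tree(base, ape::read.tree(text = "(clone:0.001);"),
                       where = twin, position = 0.001)
  e <- which(tr$edge[, 2] == which(tr$tip.label == "sp01"))
  cfg <- sim_config(seed = 2, n_species = 8, n_trees = 1,
                    beta_true = c("(Intercept)" = 0.1),
                    studies_per_species = c(3, 3))
  d <- simulate_dataset(cfg, base)
  fr <- build_model_frame(d$records, d$traits, "MHI")
  fit <- fit_phylo_meta(fr, phylo_corr(base), chains = 1, iter = 2000,
                        warmup = 500, seed = 5,
                        sigma_fixed = c(0.3, 1e-4, NA))
  ot <- phylo_outlier_test(fit, tr, "clone", NULL, se_target = 1e-4)
  est <- species_estimates(fit)
  expect_equal(ot$mean, est$estimate[est$species == "sp01"],
               tolerance = 0.05)
  # the clone inherits (nearly) all of its twin's posterior spread and adds
  # almost nothing on top of it
  twin_width <- est$upper[est$species == "sp01"] -
    est$lower[est$species == "sp01"]
  expect_lt(ot$upper - ot$lower, twin_width + 0.1)
})

test_that("the predictive interval narrows as the target SE shrinks", {
  cfg <- sim_config(seed = 84, n_species = 12, n_trees = 1)
  tr <- simulate_trees(cfg)[[1]]
  d <- simulate_dataset(cfg, tr)
  fr <- build_model_frame(d$records, d$traits, "MHI", "ECV",
                          exclude_species = "sp03")
  fit <- fit_phylo_meta(fr, phylo_corr(tr), chains = 1, iter = 2000,
                        warmup = 500, seed = 7)
  x3 <- d$traits[d$traits$species == "sp03", "ECV", drop = FALSE]
  set.seed(1)
  wide <- phylo_outlier_test(fit, tr, "sp03", x3, se_target = 0.5)
  set.seed(1)
  narrow <- phylo_outlier_test(fit, tr, "sp03", x3, se_target = 0.01)
  expect_lt(narrow$upper - narrow$lower, wide$upper - wide$lower)
  expect_error(phylo_outlier_test(fit, tr, "sp05",
                                  d$traits[3, "ECV", drop = FALSE], 0.1),
               "part of the fitted data")
})

test_that("fossil predictions are continuous at zero divergence and joint
           across taxa", {
  set.seed(85)
  cfg <- sim_config(seed = 12, n_species = 10, n_trees = 1,
                    beta_true = c("(Intercept)" = 0.2, ECV = 0.3))
  base <- simulate_trees(cfg)[[1]]
  d <- simulate_dataset(cfg, base)
  fr <- build_model_frame(d$records, d$traits, "MHI", "ECV")
  # pin the non-phylogenetic species SD near zero: fossil predictions
  # marginalize u afresh, so continuity with the species estimate (which
  # conditions on u) only holds in the small-sigma_s limit
  fit <- fit_phylo_meta(fr, phylo_corr(base), chains = 1, iter = 2000,
                        warmup = 500, seed = 9,
                        sigma_fixed = c(NA, 0.01, NA))

  # graft a twin of sp02 at near-zero divergence with sp02's covariates
  twin <- which(base$tip.label == "sp02")
  tr <- ape::bind.tree(base, ape::read.tree(text = "(fossil_twin:0.001);"),
                       where = twin, position = 0.001)
  ftr <- data.frame(species = "fossil_twin",
                    ECV = d$traits$ECV[d$traits$species == "sp02"])
  preds <- predict_fossils(fit, tr, ftr, se_assumption = 1e-3)
  est <- species_estimates(fit)
  expect_equal(preds$fossil_twin$mean,
               est$estimate[est$species == "sp02"], tolerance = 0.1)
  tab <- attr(preds, "table")
  expect_equal(nrow(tab), 1)
  expect_error(predict_fossils(fit, tr,
                               data.frame(species = "sp02", ECV = 100), 0.1),
               "already in the fitted data")
})

test_that("fossil draws match a per-draw dense conditional oracle", {
  set.seed(86)
  tr <- ape::rcoal(6)
  tr$tip.label <- paste0("s", 1:6)
  e <- which(tr$edge[, 2] <= 2)
  tr$edge.length[e] <- tr$edge.length[e] * 0.5  # two fossil-like tips
  C <- phylo_corr(tr)
  obs <- paste0("s", 3:6); tgt <- paste0("s", 1:2)
  cond <- phylohand:::.bm_condition(C, obs, tgt)
  # oracle via the joint precision matrix instead of the covariance
  P <- solve(C + diag(1e-10, 6), tol = 0)
  rownames(P) <- colnames(P) <- tr$tip.label
  Ptt <- P[tgt, tgt]; Pto <- P[tgt, obs]
  S_prec <- solve(Ptt)
  K_prec <- -S_prec %*% Pto
  expect_equal(cond$K, K_prec, tolerance = 1e-6)
  expect_equal(cond$Sigma, (S_prec + t(S_prec)) / 2, tolerance = 1e-6)
})

test_that("outlier flags are calibrated and detect an injected shift", {
  # compact version of the calibration study (the acceptance suite runs
  # the full replicate counts)
  base_cfg <- function(seed, shift = NULL)
    sim_config(seed = seed, n_species = 15, n_trees = 1,
               sigma_p = 0.2, sigma_s = 0.1, tau_true = 0.08,
               se_const = 0.5, studies_per_species = c(2, 3),
               individuals_per_study = c(20, 40),
               outlier_species = if (!is.null(shift))
                 list(label = "sp05", shift = shift))
  run_once <- function(seed, shift = NULL) {
    cfg <- base_cfg(seed, shift)
    tr <- simulate_trees(cfg)[[1]]
    d <- simulate_dataset(cfg, tr)
    fr <- build_model_frame(d$records, d$traits, "MHI", "ECV",
                            exclude_species = "sp05")
    fit <- fit_phylo_meta(fr, phylo_corr(tr), chains = 1, iter = 1500,
                          warmup = 500, seed = seed)
    rec5 <- d$records[d$records$species == "sp05", ]
    obs <- sum(rec5$effect / rec5$se^2) / sum(1 / rec5$se^2)
    ot <- phylo_outlier_test(fit, tr, "sp05",
                             d$traits[d$traits$species == "sp05", "ECV",
                                      drop = FALSE],
                             se_target = pooled_se(d$records, "sp05", "MHI"),
                             observed = obs)
    ot$outlier
  }
  flags_shift <- vapply(1:8, function(s) run_once(1000 + s, 0.7), TRUE)
  expect_gte(sum(flags_shift), 7)
  flags_null <- vapply(1:12, function(s) run_once(2000 + s), TRUE)
  expect_lte(sum(flags_null), 3)
})
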