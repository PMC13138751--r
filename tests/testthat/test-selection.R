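test_that("gpd_fit recovers the shape of simulated Pareto tails", {
  set.seed(61)
  for (k_true in c(0.2, 0.5)) {
    u <- runif(2000)
    x <- ((1 - u)^(-k_true) - 1) / k_true  # GPD(sigma = 1, k = k_true)
    f <- gpd_fit(x)
    expect_equal(f$k, k_true, tolerance = 0.12)
    expect_equal(f$sigma, 1, tolerance = 0.15)
  }
})

make_loo_world <- function(seed = 62, n_sp = 10, beta = 0.3,
                           rec_per_study = 2) {
  set.seed(seed)
  tra <- data.frame(species = paste0("s", seq_len(n_sp)),
                    BM = exp(rnorm(n_sp, 3, 1)),
                    ECV = exp(rnorm(n_sp, 5, 0.8)))
  z <- scale(log10(tra$ECV))[, 1]
  reps <- 2 * rec_per_study
  eff <- rep(0.1 + beta * z, reps) + rnorm(reps * n_sp, 0, 0.1)
  blocks <- rep(seq_len(reps), each = n_sp)
  study <- paste0("st", rep(seq_len(n_sp), reps),
                  ifelse(blocks <= rec_per_study, "a", "b"))
  rec <- make_records(rep(tra$species, reps), eff,
                      rep(0.08, reps * n_sp), study = study)
  list(rec = rec, tra = tra)
}

test_that("psis_loo matches brute-force exact leave-one-out", {
  # two studies of two records per species: no record is individually
  # influential, so the importance ratios are well-behaved (the k > 0.7
  # refit path is exercised by the outlier-record test below)
  w <- make_loo_world(62, rec_per_study = 2)
  fr <- build_model_frame(w$rec, w$tra, "MHI", "ECV")
  C <- identity_C(fr$species_levels)
  fit <- fit_phylo_meta(fr, C, chains = 1, iter = 4000, warmup = 1000,
                        seed = 11)
  loo <- suppressWarnings(psis_loo(fit))
  expect_equal(sum(loo$pointwise), loo$elpd)
  expect_true(all(is.finite(loo$pareto_k)))

  hook <- function(i) {
    fr_i <- build_model_frame(w$rec[-i, ], w$tra, "MHI", "ECV")
    fit_i <- fit_phylo_meta(fr_i, C, chains = 1, iter = 4000, warmup = 1000,
                            seed = 11)
    record_loglik(fit_i, fr, i)
  }
  loo_h <- psis_loo(fit, refit_hook = hook)
  exact <- vapply(seq_along(fr$y), function(i) logmeanexp(hook(i)), 0)
  d <- loo_h$pointwise - exact
  se_d <- sqrt(length(d) * var(d))
  expect_lt(abs(loo_h$elpd - sum(exact)), 2 * se_d)
})

test_that("elpd is additive over records: duplicating the pointwise
           log-likelihoods doubles it exactly", {
  w <- make_loo_world(63)
  fr <- build_model_frame(w$rec, w$tra, "MHI", "ECV")
  C <- identity_C(fr$species_levels)
  fit <- fit_phylo_meta(fr, C, chains = 1, iter = 2000, warmup = 500,
                        seed = 3)
  loo1 <- suppressWarnings(psis_loo(fit))
  fit2 <- fit
  fit2$loglik <- cbind(fit$loglik, fit$loglik)
  loo2 <- suppressWarnings(psis_loo(fit2))
  expect_equal(loo2$elpd, 2 * loo1$elpd, tolerance = 1e-10)
})

test_that("a gross outlier record gets the largest Pareto k and can be
           refit exactly", {
  w <- make_loo_world(64)
  rec <- w$rec
  rec$effect[5] <- rec$effect[5] + 3   # far outside the response scale
  rec$se[5] <- 0.02
  fr <- build_model_frame(rec, w$tra, "MHI", "ECV")
  C <- identity_C(fr$species_levels)
  fit <- fit_phylo_meta(fr, C, chains = 1, iter = 2000, warmup = 500,
                        seed = 13)
  expect_warning(loo <- psis_loo(fit), "Pareto k")
  expect_equal(which.max(loo$pareto_k), 5L)
  expect_gt(max(loo$pareto_k), 0.7)

  hook <- function(i) {
    fr_i <- build_model_frame(rec[-i, ], w$tra, "MHI", "ECV")
    fit_i <- fit_phylo_meta(fr_i, C, chains = 1, iter = 2000, warmup = 500,
                            seed = 13)
    record_loglik(fit_i, fr, i)
  }
  loo_r <- psis_loo(fit, refit_hook = hook)
  expect_gte(loo_r$n_refit, 1L)
})

test_that("compare_loo ranks the generative model above pure noise", {
  set.seed(65)
  w <- make_loo_world(65, n_sp = 15, beta = 0.5)
  w$tra$DIM <- exp(rnorm(15, 0.3, 0.2))  # pure noise covariate
  fr_true <- build_model_frame(w$rec, w$tra, "MHI", "ECV")
  fr_noise <- build_model_frame(w$rec, w$tra, "MHI", "DIM")
  C <- identity_C(fr_true$species_levels)
  fit_t <- fit_phylo_meta(fr_true, C, chains = 1, iter = 2000, warmup = 500,
                          seed = 7)
  fit_n <- fit_phylo_meta(fr_noise, C, chains = 1, iter = 2000, warmup = 500,
                          seed = 7)
  loo_t <- suppressWarnings(psis_loo(fit_t))
  loo_n <- suppressWarnings(psis_loo(fit_n))
  cmp <- compare_loo(list(true = loo_t, noise = loo_n))
  expect_equal(cmp$model[1], "true")

  cmp_self <- compare_loo(list(a = loo_t, b = loo_t))
  expect_equal(cmp_self$elpd_diff[2], 0)
  expect_true(attr(cmp_self, "no_meaningful_winner"))

  loo_short <- suppressWarnings(psis_loo(fit_phylo_meta(
    build_model_frame(w$rec[-1, ], w$tra, "MHI", "ECV"),
    C, chains = 1, iter = 600, warmup = 200, seed = 1)))
  expect_error(compare_loo(list(a = loo_t, b = loo_short)),
               "different record sets")
})

test_that("reduce_model drops noise and keeps the strong predictor", {
  set.seed(66)
  cfg <- sim_config(seed = 31, n_species = 30, n_trees = 1,
                    beta_true = c("(Intercept)" = 0, ECV = 0.45),
                    sigma_p = 0.1, sigma_s = 0.08, tau_true = 0.05,
                    studies_per_species = c(2, 3))
  tr <- simulate_trees(cfg)[[1]]
  d <- simulate_dataset(cfg, tr)
  d$traits$DIM <- exp(rnorm(30, 0.3, 0.2))  # replace with pure noise
  red <- reduce_model(d$records, d$traits, "MHI", c("ECV", "DIM"),
                      phylo_corr(tr), chains = 1, iter = 2000, warmup = 500,
                      seed = 5)
  expect_true("ECV" %in% red$covariates)
  expect_false("DIM" %in% red$covariates)
  expect_true("DIM" %in% red$trace)
  # monotone shrinking covariate set, deterministic under the seed
  red2 <- reduce_model(d$records, d$traits, "MHI", c("ECV", "DIM"),
                       phylo_corr(tr), chains = 1, iter = 2000, warmup = 500,
                       seed = 5)
  expect_identical(red$trace, red2$trace)

  # all-credible start is the identity
  red3 <- reduce_model(d$records, d$traits, "MHI", "ECV",
                       phylo_corr(tr), chains = 1, iter = 2000, warmup = 500,
                       seed = 5)
  expect_identical(red3$trace, character(0))
  expect_identical(red3$covariates, "ECV")
})

test_that("the battery runner averages summaries across trees", {
  cfg <- sim_config(seed = 71, n_species = 12, n_trees = 3)
  trees <- simulate_trees(cfg)
  d <- simulate_dataset(cfg, trees[[1]])
  bat <- list(brain = list(covariates = "ECV", applies_to = "both"),
              loco = list(covariates = "IMI", applies_to = "both"),
              strength_only = list(covariates = "BM", applies_to = "MABSHI"))
  out <- run_battery(d$records, d$traits, trees, bat, "MHI",
                     seed = 3, chains = 1, iter = 1200, warmup = 400)
  expect_named(out$summaries, c("brain", "loco"))
  expect_true(all(c("mean", "lower", "upper") %in%
                    names(out$summaries$brain)))
  expect_length(out$loos, 2)
})

test_that("the shipped hypothesis battery loads and is well-formed", {
  bat <- load_battery()
  expect_length(bat, 10)
  expect_true(all(vapply(bat, function(h) length(h$covariates) > 0, TRUE)))
  known <- c(CONTINUOUS_TRAITS <- c("BM", "ECV", "IMI", "DIM"),
             "FRUIT", "DIET", "TOOL", "EXT", "SOC_LEARN", "SUBS",
             "SOC_SYS", "CL")
  expect_true(all(unlist(lapply(bat, `[[`, "covariates")) %in% known))
})
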