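#' Synthetic-study configuration
#'
#' Bundles every knob of the synthetic-data generator.  The defaults
#' emulate the structure of the anthropoid handedness corpus: 41 species,
#' about two tube-task studies per species with 10-40 individuals each
#' (~2,000 individuals total), per-study standard errors of
#' `0.6 / sqrt(individuals)` (an individual handedness-score SD of about
#' 0.6), and latent variance shares of (0.5, 0.3, 0.2) for the
#' phylogenetic, non-phylogenetic and between-study components — i.e., a
#' phylogenetic signal h2 of 0.5 on a total latent SD of about 0.35.
#'
#' @param n_species Number of extant species.
#' @param n_trees Number of trees to simulate.
#' @param birth_rate,death_rate Birth-death rates per lineage per unit time.
#' @param root_depth Depth to which trees are rescaled (arbitrary units;
#'   think millions of years).
#' @param beta_true Named coefficient vector over design columns (must
#'   include `"(Intercept)"`; other names must match transformed design
#'   columns, e.g. `ECV`, `IMI`, `SUBS_terrestrial`).
#' @param sigma_p,sigma_s,tau_true SDs of the phylogenetic species,
#'   non-phylogenetic species and study effects.
#' @param studies_per_species Integer range (inclusive) sampled uniformly.
#' @param individuals_per_study Integer range sampled uniformly.
#' @param se_const Per-study SE is `se_const / sqrt(individuals)`.
#' @param missing_fraction Named fractions of species masked per covariate
#'   (applied by [make_missing()]).
#' @param outlier_species Optional list `list(label =, shift =)`; the
#'   species' latent mean is shifted post hoc by `shift`.
#' @param response Simulated response label.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 41, n_trees = 10,
                       birth_rate = 0.1, death_rate = 0.05,
                       root_depth = 40,
                       beta_true = c("(Intercept)" = 0, ECV = 0.2,
                                     IMI = -0.15),
                       sigma_p = 0.25, sigma_s = 0.19, tau_true = 0.16,
                       studies_per_species = c(1, 3),
                       individuals_per_study = c(10, 40),
                       se_const = 0.6,
                       missing_fraction = c(IMI = 0.15, DIM = 0.2),
                       outlier_species = NULL,
                       response = "MHI", seed = 1) {
  stopifnot(birth_rate >= 0, death_rate >= 0,
            sigma_p >= 0, sigma_s >= 0, tau_true >= 0,
            all(missing_fraction >= 0), all(missing_fraction < 1),
            "(Intercept)" %in% names(beta_true))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate birth-death trees
#'
#' Simulates rooted binary birth-death trees conditioned on the configured
#' number of extant tips, rescaled to a common root depth, with tips
#' labelled `sp01, sp02, ...`.
#'
#' @param cfg A [sim_config()].
#' @return List of `phylo` objects of length `cfg$n_trees`.
#' @export
simulate_trees <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$birth_rate <= cfg$death_rate)
    stop("birth rate must exceed death rate")
  set.seed(cfg$seed %% 2147483629L)
  labs <- sprintf("sp%02d", seq_len(cfg$n_species))
  lapply(seq_len(cfg$n_trees), function(i) {
    tr <- ape::rphylo(cfg$n_species, cfg$birth_rate, cfg$death_rate)
    tr$edge.length <- tr$edge.length * cfg$root_depth /
      max(ape::node.depth.edgelength(tr))
    tr$tip.label <- labs
    tr
  })
}

# sample() treats a scalar as 1:x; guard the degenerate range
.sample_range <- function(rng, n) {
  v <- seq(rng[1], rng[2])
  if (length(v) == 1) rep(v, n) else sample(v, n, replace = TRUE)
}

.rmvn_chol <- function(mu, V) {
  L <- chol(V + diag(1e-10, nrow(V)))
  as.vector(mu + t(L) %*% rnorm(nrow(V)))
}

# Discrete trait via a symmetric 2-rate Markov switch along branches.
.sim_discrete <- function(tree, states, rate = 0.03) {
  k <- length(states)
  x <- ape::rTraitDisc(tree, model = "ER", k = k, rate = rate,
                       states = states, ancestor = FALSE)
  as.character(x)
}

#' Simulate a complete record-level dataset with known truth
#'
#' Generates species covariates (continuous traits by correlated Brownian
#' motion on the tree, categorical traits by Markov switches along
#' branches), latent species trait values
#' `x' beta + a + u` with `a ~ MVN(0, sigma_p^2 C)` and
#' `u ~ N(0, sigma_s^2)`, and per-study records
#' `effect = species mean + b_g + N(0, se^2)` with study effects
#' `b_g ~ N(0, tau^2)` and `se = se_const / sqrt(individuals)`.  Effects
#' are clipped to the response bounds (clip events logged in the truth
#' ledger).  An optional outlier species receives a fixed post-hoc shift.
#'
#' @param cfg A [sim_config()].
#' @param tree A `phylo` whose tips are the species (e.g., from
#'   [simulate_trees()]).
#' @return List with `records`, `traits` (data frames in the standard CSV
#'   schemas) and `truth` (ledger of every latent quantity).
#' @export
simulate_dataset <- function(cfg, tree) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed((cfg$seed * 48271L) %% 2147483629L)
  sp <- tree$tip.label
  S <- length(sp)
  C <- phylo_corr(tree)[sp, sp]

  # continuous covariates: correlated BM on log10 scale around field-like
  # anchors (body mass ~10 kg, brain ~80 cm3, IMI ~85, dimorphism ~1.3)
  lBM <- .rmvn_chol(rep(1.0, S), 0.35^2 * C)
  lECV <- .rmvn_chol(0.7 * (lBM - 1) + log10(80), 0.25^2 * C)
  lIMI <- .rmvn_chol(0.2 * (lBM - 1) + log10(85), 0.06^2 * C)
  lDIM <- .rmvn_chol(0.15 * (lBM - 1) + log10(1.3), 0.08^2 * C)
  fruit <- plogis(.rmvn_chol(rep(0.3, S), 0.8^2 * C))
  diet <- pmin(fruit + plogis(.rmvn_chol(rep(-1.5, S), 0.5^2 * C)) *
                 (1 - fruit), 1)

  traits <- data.frame(
    species = sp, BM = 10^lBM, ECV = 10^lECV, FRUIT = fruit, DIET = diet,
    IMI = 10^lIMI, DIM = 10^lDIM,
    TOOL = as.integer(.sim_discrete(tree, c("0", "1"))),
    SUBS = .sim_discrete(tree, c("arboreal", "both", "terrestrial")),
    SOC_SYS = .sim_discrete(tree, c("solitary", "pair", "group")),
    CL = .sim_discrete(tree, c("low", "medium", "high")),
    EXT = as.integer(.sim_discrete(tree, c("0", "1"))),
    SOC_LEARN = as.integer(.sim_discrete(tree, c("0", "1"))),
    stringsAsFactors = FALSE)

  # design on the transformed scale, matching what the fit will use
  need <- setdiff(names(cfg$beta_true), "(Intercept)")
  base_cov <- unique(ifelse(need %in% names(traits), need,
                            sub("_[^_]+$", "", need)))
  tc <- transform_covariates(traits, base_cov)
  Xs <- cbind("(Intercept)" = 1, tc$X)
  bad <- setdiff(names(cfg$beta_true), colnames(Xs))
  if (length(bad)) stop("beta_true names not in design: ",
                        paste(bad, collapse = ", "))
  beta <- setNames(numeric(ncol(Xs)), colnames(Xs))
  beta[names(cfg$beta_true)] <- cfg$beta_true

  a <- .rmvn_chol(rep(0, S), cfg$sigma_p^2 * C)
  u <- rnorm(S, 0, cfg$sigma_s)
  species_mean <- as.vector(Xs %*% beta) + a + u
  names(species_mean) <- sp

  shift <- setNames(rep(0, S), sp)
  if (!is.null(cfg$outlier_species)) {
    ol <- normalize_labels(cfg$outlier_species$label)
    if (!ol %in% sp) stop("outlier species not a tip: ", ol)
    shift[ol] <- cfg$outlier_species$shift
  }

  n_studies <- .sample_range(cfg$studies_per_species, S)
  rec <- list(); b_all <- numeric(); gid <- 0L
  n_clip <- 0L
  for (i in seq_len(S)) {
    for (j in seq_len(n_studies[i])) {
      gid <- gid + 1L
      n_ind <- .sample_range(cfg$individuals_per_study, 1)
      se <- cfg$se_const / sqrt(n_ind)
      b <- rnorm(1, 0, cfg$tau_true)
      b_all[gid] <- b
      eff <- species_mean[i] + shift[i] + b + rnorm(1, 0, se)
      lo <- if (cfg$response == "MHI") -1 else 0
      eff_c <- min(max(eff, lo), 1)
      if (eff_c != eff) n_clip <- n_clip + 1L
      rec[[gid]] <- data.frame(
        species = sp[i], study_id = sprintf("study%03d", gid),
        response = cfg$response, effect = eff_c, se = se, n = n_ind,
        task = "tube", stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec)
  truth <- list(beta = beta, a = setNames(a, sp), u = setNames(u, sp),
                b = setNames(b_all, sprintf("study%03d", seq_len(gid))),
                species_mean = species_mean, shift = shift,
                sigma_p = cfg$sigma_p, sigma_s = cfg$sigma_s,
                tau = cfg$tau_true,
                h2 = if (cfg$sigma_p + cfg$sigma_s + cfg$tau_true > 0)
                  cfg$sigma_p^2 / (cfg$sigma_p^2 + cfg$sigma_s^2 +
                                     cfg$tau_true^2) else NA,
                design = Xs, n_clipped = n_clip,
                total_individuals = sum(records$n))
  list(records = records, traits = traits, truth = truth)
}

#' Mask covariate cells completely at random
#'
#' Applies the configured missingness fractions to the covariate table
#' (body mass, the imputation anchor, is never masked).
#'
#' @param traits Covariate data frame.
#' @param cfg A [sim_config()] (uses `missing_fraction` and `seed`).
#' @return List with `traits` (masked) and `mask` (logical matrix ledger).
#' @export
make_missing <- function(traits, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed((cfg$seed * 69621L + 7L) %% 2147483629L)
  mf <- cfg$missing_fraction
  if ("BM" %in% names(mf)) stop("body mass is the imputation anchor and ",
                                "cannot be masked")
  S <- nrow(traits)
  mask <- matrix(FALSE, S, length(mf), dimnames = list(traits$species,
                                                       names(mf)))
  for (v in names(mf)) {
    k <- round(mf[[v]] * S)
    if (S - k < 3) stop("masking would leave fewer than 3 observed ", v,
                        " values")
    ix <- sample.int(S, k)
    traits[[v]][ix] <- NA
    mask[ix, v] <- TRUE
  }
  list(traits = traits, mask = mask)
}
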