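CONTINUOUS_TRAITS <- c("BM", "ECV", "IMI", "DIM")
PROPORTION_TRAITS <- c("FRUIT", "DIET")
BINARY_TRAITS <- c("TOOL", "EXT", "SOC_LEARN")
FACTOR_TRAITS <- list(SUBS = c("arboreal", "both", "terrestrial"),
                      SOC_SYS = c("solitary", "pair", "group"),
                      CL = c("low", "medium", "high"))

#' Load record-level handedness data and species covariates
#'
#' Reads the meta-analytic record table (one row per published measurement
#' of MHI or MABSHI for one species) and the species covariate table,
#' normalizes species names, restricts records to the tube task, drops rows
#' lacking an effect or its standard error, and rejects duplicated
#' (study, species, response) rows as probable double-counting across
#' source compilations.
#'
#' @param records_csv Path to the record CSV with columns
#'   `species, study_id, response, effect, se, n, task`.
#' @param traits_csv Path to the covariate CSV with a `species` column.
#' @param aliases Optional named character vector mapping data species
#'   names to tree tip names (e.g., `c(Pongo_sp = "Pongo_pygmaeus")`).
#' @return List with data frames `records` and `traits` and a `dropped`
#'   count summary.
#' @export
load_dataset <- function(records_csv, traits_csv, aliases = NULL) {
  rec <- read.csv(records_csv, stringsAsFactors = FALSE)
  need <- c("species", "study_id", "response", "effect", "se", "n", "task")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("records CSV missing columns: ",
                         paste(miss, collapse = ", "))
  traits <- read.csv(traits_csv, stringsAsFactors = FALSE)
  if (!"species" %in% names(traits)) stop("traits CSV missing 'species' column")

  rec$species <- normalize_labels(rec$species)
  traits$species <- normalize_labels(traits$species)
  if (!is.null(aliases)) {
    al <- setNames(normalize_labels(aliases), normalize_labels(names(aliases)))
    hit <- rec$species %in% names(al)
    rec$species[hit] <- al[rec$species[hit]]
    hit <- traits$species %in% names(al)
    traits$species[hit] <- al[traits$species[hit]]
  }

  n0 <- nrow(rec)
  rec <- rec[tolower(trimws(rec$task)) == "tube", , drop = FALSE]
  n_task <- n0 - nrow(rec)
  keep <- is.finite(rec$effect) & is.finite(rec$se)
  n_na <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  dup <- duplicated(rec[, c("study_id", "species", "response")])
  n_dup <- sum(dup)
  if (n_dup) warning(n_dup, " duplicated (study, species, response) rows ",
                     "dropped as probable double-counting")
  rec <- rec[!dup, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records survive filtering")

  if (any(rec$se <= 0)) stop("non-positive standard errors in records")
  if (any(rec$n < 1)) stop("records with n < 1")
  bad <- (rec$response == "MHI" & (rec$effect < -1 | rec$effect > 1)) |
         (rec$response == "MABSHI" & (rec$effect < 0 | rec$effect > 1))
  if (any(bad)) stop("effect sizes outside the admissible range for ",
                     "their response in rows: ",
                     paste(head(which(bad)), collapse = ", "))
  message("loaded ", nrow(rec), " records (dropped ", n_task,
          " non-tube, ", n_na, " incomplete, ", n_dup, " duplicated)")
  list(records = rec, traits = traits,
       dropped = c(non_tube = n_task, incomplete = n_na, duplicated = n_dup))
}

#' Transform species covariates to the modeling scale
#'
#' Continuous covariates are log10-transformed then centered and scaled to
#' unit variance; proportions are clamped away from 0/1, logit-transformed,
#' then scaled; categorical covariates become 0/1 dummies against declared
#' reference levels (arboreal substrate, solitary social system, absence
#' for binaries, lowest level for competition level).  The transform
#' constants are stored so new species (e.g., fossils) can be projected
#' onto exactly the fitted scale.
#'
#' @param traits Data frame with a `species` column.
#' @param covariates Character vector of covariate names to include.
#' @param constants Optional constants from a previous call, reused instead
#'   of being recomputed (for out-of-sample species).
#' @param clamp_eps Clamp proportions to `[eps, 1-eps]` before the logit.
#' @return List with `X` (species-by-column numeric matrix), `constants`,
#'   and `groups` (map from design column to source covariate).
#' @export
transform_covariates <- function(traits, covariates,
                                 constants = NULL, clamp_eps = 5e-4) {
  sp <- normalize_labels(traits$species)
  cols <- list(); groups <- character()
  consts <- if (is.null(constants)) list(eps = clamp_eps) else constants
  for (v in covariates) {
    if (!v %in% names(traits)) stop("unknown covariate: ", v)
    raw <- traits[[v]]
    if (v %in% CONTINUOUS_TRAITS || v %in% PROPORTION_TRAITS) {
      if (v %in% CONTINUOUS_TRAITS) {
        if (any(raw <= 0, na.rm = TRUE))
          stop("non-positive value of ", v, " for species ",
               paste(sp[which(raw <= 0)], collapse = ", "))
        z <- log10(raw)
      } else {
        eps <- consts$eps
        z <- qlogis(pmin(pmax(raw, eps), 1 - eps))
      }
      if (is.null(constants)) {
        consts[[v]] <- c(mean = mean(z), sd = sd(z))
      }
      cs <- consts[[v]]
      if (is.null(cs)) stop("no stored constants for ", v)
      cols[[v]] <- (z - cs["mean"]) / cs["sd"]
      groups[v] <- v
    } else if (v %in% BINARY_TRAITS) {
      cols[[v]] <- as.numeric(raw)
      groups[v] <- v
    } else if (v %in% names(FACTOR_TRAITS)) {
      levs <- FACTOR_TRAITS[[v]]
      val <- as.character(raw)
      if (all(grepl("^[0-9]+$", val))) val <- levs[as.integer(val) + 1]
      bad <- !val %in% levs
      if (any(bad)) stop("invalid level of ", v, ": ",
                         paste(unique(val[bad]), collapse = ", "))
      for (l in levs[-1]) {
        cn <- paste0(v, "_", l)
        cols[[cn]] <- as.numeric(val == l)
        groups[cn] <- v
      }
    } else stop("unknown covariate type: ", v)
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(0, length(sp), 0)
  rownames(X) <- sp
  list(X = X, constants = consts, groups = groups)
}

#' Invert the continuous covariate transform
#'
#' @param z Standardized values.
#' @param name Covariate name.
#' @param constants Constants from [transform_covariates()].
#' @return Raw-scale values.
#' @export
invert_covariate <- function(z, name, constants) {
  cs <- constants[[name]]
  if (is.null(cs)) stop("no stored constants for ", name)
  y <- z * cs["sd"] + cs["mean"]
  if (name %in% CONTINUOUS_TRAITS) 10^y else plogis(y)
}

#' Build the record-level model frame
#'
#' Assembles the design matrix (intercept plus transformed covariates,
#' expanded to record rows), the species and study index maps, and the
#' response/standard-error vectors for one response variable, optionally
#' excluding a species (records and phylogenetic index both dropped, and
#' standardization constants recomputed on the analysis set actually
#' fitted).
#'
#' @param records Record data frame (see [load_dataset()]).
#' @param traits Species covariate data frame.
#' @param response `"MHI"` or `"MABSHI"`.
#' @param covariates Covariate names (may be empty: intercept-only).
#' @param exclude_species Optional species label to drop.
#' @return Object of class `phm_frame`.
#' @export
build_model_frame <- function(records, traits, response,
                              covariates = character(),
                              exclude_species = NULL) {
  rec <- records[records$response == response, , drop = FALSE]
  rec$species <- normalize_labels(rec$species)
  traits$species <- normalize_labels(traits$species)
  if (!is.null(exclude_species)) {
    exclude_species <- normalize_labels(exclude_species)
    if (!exclude_species %in% rec$species)
      stop("species to exclude not present in data: ", exclude_species)
    rec <- rec[rec$species != exclude_species, , drop = FALSE]
    traits <- traits[traits$species != exclude_species, , drop = FALSE]
  }
  species_levels <- sort(unique(rec$species))
  traits <- traits[match(species_levels, traits$species), , drop = FALSE]
  if (anyNA(traits$species))
    stop("species without covariate rows: ",
         paste(setdiff(species_levels, traits$species), collapse = ", "))
  tc <- transform_covariates(traits, covariates)
  Xs <- cbind("(Intercept)" = 1, tc$X)
  sp_ix <- match(rec$species, species_levels)
  study_levels <- sort(unique(as.character(rec$study_id)))
  st_ix <- match(as.character(rec$study_id), study_levels)
  structure(list(y = rec$effect, se = rec$se, n = rec$n,
                 X = Xs[sp_ix, , drop = FALSE], X_species = Xs,
                 species = sp_ix, study = st_ix,
                 species_levels = species_levels,
                 study_levels = study_levels,
                 response = response, covariates = covariates,
                 groups = c("(Intercept)" = "(Intercept)", tc$groups),
                 constants = tc$constants, records = rec),
            class = "phm_frame")
}

#' @export
print.phm_frame <- function(x, ...) {
  cat("phylogenetic meta-analysis model frame: ", x$response, "\n", sep = "")
  cat("  ", length(x$y), " records, ", length(x$species_levels), " species, ",
      length(x$study_levels), " studies\n", sep = "")
  cat("  fixed effects:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
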