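## Per-haplogroup association models, PCA effective number of tests,
## and multiplicity adjustment.

#' Model specification for a single haplogroup association test
#'
#' @param outcome cohort column name of the dependent variable (for
#'   `family = "cox"` the columns `<outcome>_entry`, `<outcome>_event` and
#'   `<outcome>_dead` are used)
#' @param family `"linear"`, `"logistic"` or `"cox"`
#' @param covariate_set `"robust"` (age + age^2, north/east coordinates at
#'   assessment and birth, area deprivation at assessment and birth, all
#'   genetic PCs present, genotyping batch; age terms dropped for Cox),
#'   `"minimal"` (age, PCs, batch) or `"eales"` (age, BMI, first 5 PCs,
#'   batch, plus heritable/lifestyle covariates present in the cohort)
#' @param haplogroup group label to test
#' @param parent `"subject"` (default), `"father"`, `"mother"` or
#'   `"brother"`; parent models substitute the parent age terms
#' @param extra_covariates additional cohort column names forced into the
#'   model (e.g. a family-history covariate)
#' @return a `model_spec` object
#' @export
model_spec <- function(outcome, family = c("linear", "logistic", "cox"),
                       covariate_set = c("robust", "minimal", "eales"),
                       haplogroup, parent = "subject",
                       extra_covariates = character()) {
  family <- match.arg(family)
  covariate_set <- match.arg(covariate_set)
  structure(list(outcome = outcome, family = family,
                 covariate_set = covariate_set, haplogroup = haplogroup,
                 parent = parent, extra_covariates = extra_covariates),
            class = "model_spec")
}

# Columns of the eales-style covariate set beyond age/BMI/PCs/batch; only
# those present in the cohort are used (simulated cohorts typically carry a
# generic `risk_factor` column standing in for the heritable covariates).
EALES_EXTRA <- c("hypertension_num", "risk_factor", "exercise", "income",
                 "smoking", "education", "employment", "alcohol",
                 "father_cad_num", "mother_cad_num")

# Build the covariate data frame for a spec. Returns a data.frame; factors
# (batch) expand later via model.matrix.
covariate_frame <- function(cohort, spec) {
  age_col <- switch(spec$parent,
                    subject = "age", brother = "age",
                    father = "father_age", mother = "mother_age")
  pcs <- grep("^PC[0-9]+$", names(cohort), value = TRUE)
  pcs <- pcs[order(as.integer(sub("PC", "", pcs)))]
  cv <- list()
  if (spec$covariate_set == "robust") {
    if (spec$family != "cox") {
      cv$age <- cohort[[age_col]]
      cv$age_sq <- cohort[[age_col]]^2
    }
    for (v in c("north_assess", "east_assess", "north_birth", "east_birth",
                "depr_assess", "depr_birth")) {
      cv[[v]] <- cohort[[v]]
    }
    for (p in pcs) cv[[p]] <- cohort[[p]]
  } else if (spec$covariate_set == "minimal") {
    if (spec$family != "cox") cv$age <- cohort[[age_col]]
    for (p in pcs) cv[[p]] <- cohort[[p]]
  } else { # eales
    if (spec$family != "cox") cv$age <- cohort[[age_col]]
    if ("bmi" %in% names(cohort)) cv$bmi <- cohort[["bmi"]]
    for (p in utils::head(pcs, 5)) cv[[p]] <- cohort[[p]]
    for (v in intersect(EALES_EXTRA, names(cohort))) cv[[v]] <- cohort[[v]]
  }
  for (v in spec$extra_covariates) cv[[v]] <- cohort[[v]]
  if ("batch" %in% names(cohort)) cv$batch <- factor(cohort$batch)
  as.data.frame(cv)
}

# Binary outcome columns may be factors (control/case) or 0/1 numerics.
outcome_numeric <- function(y, family) {
  if (family == "logistic" && is.factor(y)) {
    return(as.numeric(y == "case"))
  }
  as.numeric(y)
}

#' Fit a single per-haplogroup association model
#'
#' Fits the outcome on the covariate set plus a binary carrier indicator for
#' one haplogroup, on complete cases, and returns the Wald estimate of the
#' haplogroup coefficient (mm Hg for linear models, log-odds for logistic,
#' log-hazard for Cox). Estimation is delegated to [stats::glm.fit()]
#' (linear/logistic) or [survival::coxph()] (Cox, age timescale with entry
#' at assessment and the fixed censoring date baked into the survival
#' columns). Non-converged or degenerate fits (e.g. zero carriers) are
#' returned flagged with `NA` estimates rather than dropped.
#'
#' @param spec a [model_spec()]
#' @param cohort analysis cohort data frame
#' @param indicators a `HaplogroupMatrix`
#' @return one-row data frame (class `AssocResult`): `haplogroup`,
#'   `outcome`, `family`, `covariate_set`, `gamma`, `se`, `ci_lo`, `ci_hi`,
#'   `p_raw`, `p_adj` (`NA` until adjusted), `n`, `n_cases`, `converged`,
#'   `note`
#' @export
fit_haplogroup_model <- function(spec, cohort, indicators) {
  ykc_assert(inherits(spec, "model_spec"), "spec must be a model_spec")
  ykc_assert(spec$haplogroup %in% indicators$groups,
             "unknown haplogroup: ", spec$haplogroup)
  z <- indicators$indicators[, spec$haplogroup]
  cv <- covariate_frame(cohort, spec)

  if (spec$family == "cox") {
    entry <- cohort[[paste0(spec$outcome, "_entry")]]
    exit <- cohort[[paste0(spec$outcome, "_event")]]
    dead <- cohort[[paste0(spec$outcome, "_dead")]]
    ykc_assert(!is.null(entry) && !is.null(exit) && !is.null(dead),
               "cox outcome needs columns ", spec$outcome,
               "_{entry,event,dead}")
    cc <- stats::complete.cases(cv) & !is.na(entry) & !is.na(exit) &
      !is.na(dead) & exit > entry
    y <- NULL
  } else {
    y <- outcome_numeric(cohort[[spec$outcome]], spec$family)
    ykc_assert(!is.null(y), "outcome column not found: ", spec$outcome)
    cc <- stats::complete.cases(cv) & !is.na(y)
  }

  zs <- z[cc]
  n <- sum(cc)
  base <- data.frame(haplogroup = spec$haplogroup, outcome = spec$outcome,
                     family = spec$family, covariate_set = spec$covariate_set,
                     parent = spec$parent,
                     gamma = NA_real_, se = NA_real_, ci_lo = NA_real_,
                     ci_hi = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                     n = n, n_cases = NA_real_, converged = FALSE,
                     note = "", stringsAsFactors = FALSE)
  fail <- function(note) {
    base$note <- note
    warning("fit_haplogroup_model [", spec$haplogroup, " ~ ", spec$outcome,
            "]: ", note, call. = FALSE)
    class(base) <- c("AssocResult", class(base))
    base
  }
  if (n < 10L) return(fail("insufficient complete cases"))
  if (length(unique(zs)) < 2L) return(fail("no carriers (or no non-carriers)"))

  X <- stats::model.matrix(~ ., data = cv[cc, , drop = FALSE])

  if (spec$family == "cox") {
    sv <- survival::Surv(entry[cc], exit[cc], dead[cc])
    fit <- tryCatch(
      suppressWarnings(survival::coxph(sv ~ zs + X[, -1, drop = FALSE])),
      error = function(e) NULL)
    if (is.null(fit)) return(fail("cox fit failed"))
    gamma <- unname(stats::coef(fit)["zs"])
    se <- sqrt(diag(fit$var))[match("zs", names(stats::coef(fit)))]
    base$n_cases <- sum(dead[cc])
    if (!is.finite(gamma) || !is.finite(se) || se > 100) {
      return(fail("non-converged cox fit"))
    }
  } else {
    fam <- if (spec$family == "linear") stats::gaussian() else
      stats::binomial()
    Xz <- cbind(X, .z = zs)
    fit <- suppressWarnings(
      stats::glm.fit(Xz, y[cc], family = fam,
                     control = list(maxit = 100)))
    p <- fit$rank
    if (!fit$converged && spec$family == "logistic") {
      return(fail("logistic fit did not converge"))
    }
    cov_unscaled <- tryCatch(
      chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
      error = function(e) NULL)
    if (is.null(cov_unscaled)) return(fail("singular design matrix"))
    dispersion <- if (spec$family == "linear") {
      sum(fit$residuals^2 * fit$weights) / fit$df.residual
    } else 1
    coefs <- fit$coefficients
    j <- match(".z", colnames(Xz)[fit$qr$pivot[seq_len(p)]])
    if (is.na(j) || is.na(coefs[".z"])) return(fail("carrier term aliased"))
    gamma <- unname(coefs[".z"])
    se <- sqrt(cov_unscaled[j, j] * dispersion)
    if (spec$family == "logistic") {
      base$n_cases <- sum(y[cc] == 1)
      if (abs(gamma) > 15 || se > 50) return(fail("probable separation"))
    }
  }

  zstat <- gamma / se
  base$gamma <- gamma
  base$se <- se
  base$ci_lo <- gamma - Z95 * se
  base$ci_hi <- gamma + Z95 * se
  base$p_raw <- 2 * stats::pnorm(-abs(zstat))
  base$converged <- TRUE
  class(base) <- c("AssocResult", class(base))
  base
}

#' Fit one model per haplogroup
#'
#' @inheritParams fit_haplogroup_model
#' @param outcome,family,covariate_set,parent,extra_covariates passed to
#'   [model_spec()] per group
#' @param groups which groups to test (default: all in `indicators`)
#' @return data frame with one `AssocResult` row per haplogroup
#' @export
fit_haplogroup_models <- function(cohort, indicators, outcome,
                                  family = "linear",
                                  covariate_set = "robust",
                                  parent = "subject",
                                  extra_covariates = character(),
                                  groups = indicators$groups) {
  rows <- lapply(groups, function(g) {
    fit_haplogroup_model(
      model_spec(outcome, family, covariate_set, g, parent,
                 extra_covariates),
      cohort, indicators)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effective number of independent tests
#'
#' Y haplogroup indicators are strongly correlated through the hierarchy of
#' the phylogeny, so a raw Bonferroni correction is too stringent. This
#' eigendecomposes the Pearson correlation matrix of the indicator columns
#' and returns the smallest m such that the top-m eigenvalues account for at
#' least `variance_fraction` of the total variance (the trace, i.e. the
#' number of columns).
#'
#' @param indicators a `HaplogroupMatrix` or a numeric matrix of indicator
#'   columns
#' @param variance_fraction target cumulative variance fraction (default 0.95)
#' @return integer count of independent components
#' @export
effective_tests <- function(indicators, variance_fraction = 0.95) {
  m <- if (inherits(indicators, "HaplogroupMatrix")) {
    indicators$indicators
  } else {
    as.matrix(indicators)
  }
  v <- apply(m, 2, stats::var)
  if (any(v == 0 | is.na(v))) {
    warning("dropping ", sum(v == 0 | is.na(v)),
            " zero-variance indicator column(s)", call. = FALSE)
    m <- m[, v > 0 & !is.na(v), drop = FALSE]
  }
  if (ncol(m) < 2L) ykc_stop("need at least 2 usable indicator columns")
  ev <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  # small tolerance so an exact boundary (e.g. identity correlation at
  # m/k == variance_fraction) is not missed through eigenvalue round-off
  which(cumsum(ev) / ncol(m) >= variance_fraction - 1e-9)[1]
}

#' Multiply-adjust P values by effective test counts
#'
#' @param p_raw numeric vector of raw P values in `[0, 1]`
#' @param n_eff_groups effective number of independent haplogroups
#' @param n_eff_phenotypes effective number of independent phenotypes
#'   (default 1)
#' @return adjusted P values, capped at 1
#' @export
adjust_pvalues <- function(p_raw, n_eff_groups, n_eff_phenotypes = 1) {
  ykc_assert(n_eff_groups >= 1 && n_eff_phenotypes >= 1,
             "effective test counts must be >= 1")
  ok <- is.na(p_raw) | (p_raw >= 0 & p_raw <= 1)
  if (!all(ok)) ykc_stop("p_raw values must lie in [0, 1]")
  pmin(1, p_raw * n_eff_groups * n_eff_phenotypes)
}

#' Bonferroni-style significance threshold on effective test counts
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param n_eff_groups effective number of independent haplogroups
#' @param n_eff_phenotypes effective number of independent phenotypes
#'   (default 1)
#' @return the threshold `alpha / (n_eff_groups * n_eff_phenotypes)`;
#'   summaries report it at two significant figures
#' @export
significance_threshold <- function(alpha = 0.05, n_eff_groups,
                                   n_eff_phenotypes = 1) {
  ykc_assert(n_eff_groups >= 1 && n_eff_phenotypes >= 1,
             "effective test counts must be >= 1")
  alpha / (n_eff_groups * n_eff_phenotypes)
}

#' Run a full association battery for one outcome
#'
#' Filters groups on carrier (continuous) or carrier-case (binary) counts,
#' fits one model per retained haplogroup, computes the effective number of
#' tests on the complete-case analysis sample, and adjusts P values.
#'
#' @inheritParams fit_haplogroup_models
#' @param min_carriers,min_cases carrier thresholds (defaults 100 / 40)
#' @param n_eff_phenotypes effective number of phenotypes in this category
#' @param variance_fraction PCA variance fraction for [effective_tests()]
#' @return data frame of `AssocResult` rows with `p_adj` filled; attributes
#'   `"n_eff"` and `"threshold"` carry the multiplicity accounting
#' @export
run_association <- function(cohort, indicators, outcome, family = "linear",
                            covariate_set = "robust", parent = "subject",
                            extra_covariates = character(),
                            min_carriers = 100, min_cases = 40,
                            n_eff_phenotypes = 1, variance_fraction = 0.95) {
  case_ind <- if (family == "logistic") {
    outcome_numeric(cohort[[outcome]], "logistic")
  } else {
    NULL
  }
  kept <- filter_groups(indicators, min_carriers = min_carriers,
                        case_indicator = case_ind, min_cases = min_cases)
  if (length(kept$groups) == 0L) {
    message("run_association: no groups pass the carrier filter")
    return(NULL)
  }
  res <- fit_haplogroup_models(cohort, kept, outcome, family, covariate_set,
                               parent, extra_covariates)
  # effective tests on the complete-case analysis sample; non-converged
  # fits are excluded from the multiplicity accounting
  conv <- res$converged
  spec1 <- model_spec(outcome, family, covariate_set,
                      kept$groups[1], parent, extra_covariates)
  cv <- covariate_frame(cohort, spec1)
  cc <- stats::complete.cases(cv)
  if (family != "cox") {
    yv <- outcome_numeric(cohort[[outcome]], family)
    cc <- cc & !is.na(yv)
  }
  usable <- kept$indicators[cc, conv, drop = FALSE]
  n_eff <- if (ncol(usable) >= 2) effective_tests(usable, variance_fraction)
           else max(1L, ncol(usable))
  res$p_adj <- adjust_pvalues(res$p_raw, n_eff, n_eff_phenotypes)
  attr(res, "n_eff") <- n_eff
  attr(res, "threshold") <- signif(
    significance_threshold(0.05, n_eff, n_eff_phenotypes), 2)
  res
}
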