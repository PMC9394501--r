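## Seeded synthetic cohort generator. Emulates the statistical structure the
## analysis modules assume: geographically structured Y-lineage frequencies,
## geography-correlated deprivation and genetic-PC surrogates, lineage
## effects shared between father and son, mother phenotypes independent of
## the Y by construction, code-bearing health records (so the CAD
## classification algorithm itself sits on the test path), Gompertz survival
## for subjects and parents, and an optional collider scenario.

#' Default atomic lineage frequencies for the fixture phylogeny
#'
#' Roughly emulates the lineage composition of a British cohort (R1b
#' dominant, I1 next, a tail of rarer lineages, and a small class of men
#' whose most-derived call stops at an internal node). Normalised to sum
#' to 1.
#' @param tree a `YPhylogeny`; defaults to the fixture tree
#' @return named numeric vector over tree nodes
#' @export
default_base_freqs <- function(tree = ykc_fixture_tree()) {
  f <- c(
    "R1b-M343" = 0.470, "I1-M253" = 0.130, "R1a-M420" = 0.050,
    "I2-M223" = 0.050, "J2-M172" = 0.030, "J1-M267" = 0.010,
    "E1b-M215" = 0.030, "G-M201" = 0.050, "H-M69" = 0.005,
    "Q-M242" = 0.005, "C-M130" = 0.003, "A-M91" = 0.002,
    "NO-M214" = 0.005, "I-M170" = 0.020, "J-M304" = 0.005,
    "R-M207" = 0.040, "P-M45" = 0.010, "K2-M526" = 0.005,
    "IJK-S137" = 0.020, "GH-F871" = 0.005, "F-M89" = 0.020, "Y" = 0.005
  )
  missing <- setdiff(tree$nodes, names(f))
  if (length(missing)) {
    f <- c(f[intersect(names(f), tree$nodes)],
           stats::setNames(rep(0.002, length(missing)), missing))
  } else {
    f <- f[tree$nodes]
  }
  f / sum(f)
}

#' Default geographic frequency gradients for the fixture phylogeny
#'
#' Per-node log-frequency slopes on scaled north/east birth coordinates,
#' emulating lineages whose prevalence rises towards one end of the island
#' (e.g. I1 towards the south, R1a towards the north).
#' @return named list of `c(north, east)` slope pairs
#' @export
default_geo_gradient <- function() {
  list(
    "I1-M253" = c(north = -0.8, east = 0.4),
    "R1a-M420" = c(north = 0.6, east = -0.3),
    "E1b-M215" = c(north = 0.2, east = -0.6),
    "IJK-S137" = c(north = 0.5, east = 0.2),
    "R1b-M343" = c(north = 0.15, east = -0.15)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects number of male subjects
#' @param tree a `YPhylogeny` (default: the packaged fixture tree)
#' @param base_freqs named atomic-node frequencies (sum to 1); default
#'   [default_base_freqs()]
#' @param geo_gradient named list of per-node `c(north, east)` log-frequency
#'   slopes on scaled birth coordinates; default [default_geo_gradient()]
#' @param snp_error_rate per-call allele flip probability (default 0)
#' @param snp_missing_rate per-call missing probability (default 0.02)
#' @param n_pcs number of genetic-PC surrogate columns (default 10; the
#'   simulated structure is two-dimensional, so a handful of noisy
#'   surrogates spans it)
#' @param pc_geo_loading correlation of the first two PCs with the
#'   north/east axes (default 0.7)
#' @param effect_map list of true lineage effects; each element is
#'   `list(haplogroup = <atomic node>, outcome = <"map"|"sbp"|"dbp"|"cad"|
#'   "hypertension"|"mortality">, effect = <natural-scale size>)`:
#'   mm Hg for BP outcomes, log-odds for binary, log-hazard for mortality.
#'   Binary and mortality effects are shared with the father (same lineage);
#'   BP effects apply to subjects only (parents have no measured BP).
#' @param confounding list of geography-to-outcome slopes per unit scaled
#'   north coordinate: `bp_north` (mm Hg), `cad_north` (log-odds),
#'   `mort_north` (log-hazard), `depr_north` (deprivation units)
#' @param shared_env_corr fraction of residual outcome variance shared
#'   within a household (father-son-mother), default 0.1
#' @param collider_scenario if `TRUE`, the lineage effect is routed entirely
#'   into a heritable risk factor that is also caused by an unmeasured
#'   cause of CAD; the lineage has no causal path to CAD (see the methods
#'   vignette)
#' @param collider_group atomic node carrying the collider-scenario effect
#' @param bp_med_rate,lipid_med_rate medication prevalences
#' @param cad_base_rate baseline CAD probability at the cohort centre
#' @param gompertz `list(shape, rate)` of the baseline Gompertz hazard
#' @param emit_genotypes,emit_records,simulate_parents,simulate_survival
#'   switch off expensive components not needed for a given experiment
#' @param brother_rate fraction of subjects with exactly one male sibling
#' @param seed integer seed; the seed fully determines the output
#' @return a `SimConfig` object
#' @export
sim_config <- function(n_subjects = 2000,
                       tree = NULL,
                       base_freqs = NULL,
                       geo_gradient = NULL,
                       snp_error_rate = 0,
                       snp_missing_rate = 0.02,
                       n_pcs = 10,
                       pc_geo_loading = 0.7,
                       effect_map = list(),
                       confounding = list(),
                       shared_env_corr = 0.1,
                       collider_scenario = FALSE,
                       collider_group = "R1b-M343",
                       bp_med_rate = 0.2,
                       lipid_med_rate = 0.25,
                       cad_base_rate = 0.10,
                       gompertz = list(shape = 0.09, rate = 5e-5),
                       emit_genotypes = TRUE,
                       emit_records = TRUE,
                       simulate_parents = TRUE,
                       simulate_survival = TRUE,
                       brother_rate = 0.25,
                       seed = 1) {
  if (is.null(tree)) tree <- ykc_fixture_tree()
  if (is.null(base_freqs)) base_freqs <- default_base_freqs(tree)
  if (is.null(geo_gradient)) geo_gradient <- default_geo_gradient()
  ykc_assert(all(names(base_freqs) %in% tree$nodes),
             "base_freqs names must be tree nodes")
  ykc_assert(all(base_freqs >= 0) && sum(base_freqs) > 0,
             "base_freqs must be non-negative and not all zero")
  if (abs(sum(base_freqs) - 1) > 1e-6) base_freqs <- base_freqs / sum(base_freqs)
  ykc_assert(all(names(geo_gradient) %in% tree$nodes),
             "geo_gradient names must be tree nodes")
  for (e in effect_map) {
    ykc_assert(is.list(e) && all(c("haplogroup", "outcome", "effect") %in%
                                   names(e)),
               "each effect_map entry needs haplogroup, outcome, effect")
    ykc_assert(e$haplogroup %in% tree$nodes,
               "effect_map haplogroup must be a tree node: ", e$haplogroup)
  }
  conf_def <- list(bp_north = 2, cad_north = 0.2, mort_north = 0.1,
                   depr_north = 1)
  conf_def[names(confounding)] <- confounding
  ykc_assert(shared_env_corr >= 0 && shared_env_corr < 1,
             "shared_env_corr must be in [0, 1)")
  structure(list(
    n_subjects = n_subjects, tree = tree, base_freqs = base_freqs,
    geo_gradient = geo_gradient, snp_error_rate = snp_error_rate,
    snp_missing_rate = snp_missing_rate, n_pcs = n_pcs,
    pc_geo_loading = pc_geo_loading, effect_map = effect_map,
    confounding = conf_def, shared_env_corr = shared_env_corr,
    collider_scenario = collider_scenario, collider_group = collider_group,
    bp_med_rate = bp_med_rate, lipid_med_rate = lipid_med_rate,
    cad_base_rate = cad_base_rate, gompertz = gompertz,
    emit_genotypes = emit_genotypes, emit_records = emit_records,
    simulate_parents = simulate_parents,
    simulate_survival = simulate_survival,
    brother_rate = brother_rate, seed = seed
  ), class = "SimConfig")
}

#' The packaged fixture Y phylogeny
#' @return a `YPhylogeny` of ~20 nodes with its branch-defining SNPs
#' @export
ykc_fixture_tree <- function() {
  load_phylogeny(
    system.file("extdata", "fixture_tree.nwk", package = "ykincohort"),
    system.file("extdata", "fixture_snp_map.tsv", package = "ykincohort"))
}

#' The packaged fixture composite/paragroup definitions
#' @return definition list for [build_indicator_matrix()]
#' @export
ykc_fixture_groups <- function() {
  read_group_defs(
    system.file("extdata", "fixture_groups.yaml", package = "ykincohort"))
}

# sum of effect_map effects for `outcome` as a per-individual vector,
# given the vector of assigned atomic nodes
effect_vector <- function(cfg, outcome, hap) {
  out <- numeric(length(hap))
  for (e in cfg$effect_map) {
    if (identical(e$outcome, outcome)) {
      out <- out + e$effect * (hap == e$haplogroup)
    }
  }
  out
}

# conditional Gompertz draw: age at death given survival to `entry`;
# `rate` may be a vector (proportional-hazards effects fold into it)
rgompertz_cond <- function(n, shape, rate, entry) {
  p_entry <- flexsurv::pgompertz(entry, shape = shape, rate = rate)
  u <- stats::runif(n)
  flexsurv::qgompertz(p_entry + u * (1 - p_entry), shape = shape,
                      rate = rate)
}

#' Simulate a synthetic kin cohort
#'
#' Generates a cohort with the structure described in [sim_config()] and a
#' true-parameter ledger for recovery tests. The same seed yields identical
#' output.
#'
#' @param cfg a [sim_config()]
#' @return a `ykc_sim` list: `cohort` (raw per-subject table including true
#'   assignments), `panel` (a `GenotypePanel`, or `NULL`), `records` /
#'   `meds` (coded health records, or `NULL`), `tree`, `config`, `ledger`
#' @export
simulate_cohort <- function(cfg) {
  ykc_assert(inherits(cfg, "SimConfig"), "cfg must be a SimConfig")
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  tree <- cfg$tree
  id <- sprintf("S%05d", seq_len(n))

  ## geography and deprivation
  north_birth <- stats::runif(n, 0, 1000)
  east_birth <- stats::runif(n, 0, 700)
  north_assess <- pmin(pmax(north_birth + stats::rnorm(n, 0, 40), 0), 1000)
  east_assess <- pmin(pmax(east_birth + stats::rnorm(n, 0, 40), 0), 700)
  nscale <- (north_birth - 500) / 500
  escale <- (east_birth - 350) / 350
  depr_birth <- cfg$confounding$depr_north * nscale + stats::rnorm(n)
  depr_assess <- 0.8 * depr_birth + stats::rnorm(n, 0, 0.6)

  ## lineage assignment from location-tilted frequencies (Gumbel-max)
  nodes <- names(cfg$base_freqs)
  logw <- matrix(log(pmax(cfg$base_freqs, 1e-12)), n, length(nodes),
                 byrow = TRUE, dimnames = list(id, nodes))
  for (nm in names(cfg$geo_gradient)) {
    g <- cfg$geo_gradient[[nm]]
    logw[, nm] <- logw[, nm] + g[["north"]] * nscale + g[["east"]] * escale
  }
  gum <- -log(-log(stats::runif(n * length(nodes))))
  hap <- nodes[max.col(logw + matrix(gum, n, length(nodes)))]

  ## genotypes along the tree path
  panel <- NULL
  if (cfg$emit_genotypes) {
    bs <- tree$branch_snps
    snp_node <- stats::setNames(bs$node, bs$snp_id)
    P <- path_membership(tree, snp_node)      # snps x nodes
    D <- t(P[, hap, drop = FALSE]) > 0        # n x snps derived state
    if (cfg$snp_error_rate > 0) {
      flip <- matrix(stats::runif(length(D)) < cfg$snp_error_rate,
                     nrow(D), ncol(D))
      D <- xor(D, flip)
    }
    calls <- matrix(NA_character_, n, nrow(bs),
                    dimnames = list(id, bs$snp_id))
    for (j in seq_len(nrow(bs))) {
      calls[, j] <- ifelse(D[, j], bs$derived[j], bs$ancestral[j])
    }
    if (cfg$snp_missing_rate > 0) {
      calls[matrix(stats::runif(length(calls)) < cfg$snp_missing_rate,
                   n, ncol(calls))] <- NA_character_
    }
    panel <- genotype_panel(calls)
  }

  ## genetic-PC surrogates and batch
  l <- cfg$pc_geo_loading
  pcs <- matrix(stats::rnorm(n * cfg$n_pcs), n, cfg$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(cfg$n_pcs))))
  sn <- as.numeric(scale(nscale)); se <- as.numeric(scale(escale))
  if (cfg$n_pcs >= 1) pcs[, 1] <- l * sn + sqrt(1 - l^2) * pcs[, 1]
  if (cfg$n_pcs >= 2) pcs[, 2] <- l * se + sqrt(1 - l^2) * pcs[, 2]
  batch <- sample(c("axiom", "bileve"), n, TRUE, c(0.8, 0.2))

  ## demographics
  age <- sample(40:69, n, TRUE)
  assess_date <- as.Date("2008-06-01") + sample(-365:365, n, TRUE)
  dob <- assess_date - round(age * 365.25) - sample(0:180, n, TRUE)
  bmi <- 27 + 0.05 * (age - 55) + stats::rnorm(n, 0, 4)
  house <- stats::rnorm(n)   # shared household environment
  sh <- sqrt(cfg$shared_env_corr)
  ih <- sqrt(1 - cfg$shared_env_corr)

  ## blood pressure (latent, then measured under treatment)
  eff_bp <- effect_vector(cfg, "map", hap)
  sbp_lat <- 125 + 0.45 * (age - 55) + cfg$confounding$bp_north * nscale +
    effect_vector(cfg, "sbp", hap) + eff_bp +
    14 * (sh * house + ih * stats::rnorm(n))
  dbp_lat <- 78 + 0.20 * (age - 55) + 0.6 * cfg$confounding$bp_north * nscale +
    effect_vector(cfg, "dbp", hap) + eff_bp +
    9 * (sh * house + ih * stats::rnorm(n))
  on_bp_med <- stats::runif(n) < cfg$bp_med_rate
  sbp_meas <- sbp_lat - 15 * on_bp_med
  dbp_meas <- dbp_lat - 10 * on_bp_med
  sbp_r1 <- sbp_meas + stats::rnorm(n, 0, 1.5)
  sbp_r2 <- sbp_meas + stats::rnorm(n, 0, 1.5)
  dbp_r1 <- dbp_meas + stats::rnorm(n, 0, 1.0)
  dbp_r2 <- dbp_meas + stats::rnorm(n, 0, 1.0)

  ## lipids
  ldl_lat <- 3.6 + 0.01 * (age - 55) + 0.1 * depr_assess +
    effect_vector(cfg, "ldl", hap) + stats::rnorm(n, 0, 0.85)
  hdl <- pmax(0.4, 1.35 + stats::rnorm(n, 0, 0.30))
  trig <- exp(stats::rnorm(n, log(1.5), 0.45))
  tc_lat <- ldl_lat + hdl + trig / 2.2 + stats::rnorm(n, 0, 0.2)
  on_lipid_med <- stats::runif(n) < cfg$lipid_med_rate
  ldl_meas <- ifelse(on_lipid_med, ldl_lat * 0.7, ldl_lat)
  tc_meas <- ifelse(on_lipid_med, tc_lat * 0.8, tc_lat)

  ## CAD (optionally the collider scenario) and the heritable risk factor
  U <- stats::rnorm(n)
  if (cfg$collider_scenario) {
    zc <- as.numeric(hap == cfg$collider_group)
    risk_factor <- 0.5 * zc + 0.8 * U + stats::rnorm(n, 0, 0.6)
    cad_logit <- stats::qlogis(cfg$cad_base_rate) + 0.9 * U +
      cfg$confounding$cad_north * nscale
  } else {
    risk_factor <- 0.3 * U + stats::rnorm(n, 0, 0.8)
    cad_logit <- stats::qlogis(cfg$cad_base_rate) + 0.04 * (age - 55) +
      cfg$confounding$cad_north * nscale + effect_vector(cfg, "cad", hap) +
      0.9 * (sh * house)
  }
  cad_true <- stats::runif(n) < stats::plogis(cad_logit)
  angina <- !cad_true & stats::runif(n) < 0.04
  excl_med <- !cad_true & !angina & stats::runif(n) < 0.02

  records <- meds <- NULL
  if (cfg$emit_records) {
    rec <- list()
    if (any(cad_true)) {
      src <- sample(c("hospital_icd10", "operation_opcs",
                      "death_icd10_primary_or_secondary"),
                    sum(cad_true), TRUE, c(0.75, 0.18, 0.07))
      code <- character(sum(cad_true))
      code[src == "hospital_icd10"] <-
        sample(c("I21.0", "I21.4", "I21.9", "I22.0", "I23.1", "I25.2"),
               sum(src == "hospital_icd10"), TRUE)
      code[src == "operation_opcs"] <-
        sample(c("K49.1", "K50.2", "K40.3", "K45.1", "K75.1"),
               sum(src == "operation_opcs"), TRUE)
      code[src == "death_icd10_primary_or_secondary"] <-
        sample(c("I21.9", "I25.1", "I24.8"),
               sum(src == "death_icd10_primary_or_secondary"), TRUE)
      rec$case <- data.frame(id = id[cad_true], source = src, code = code)
    }
    if (any(angina)) {
      rec$angina <- data.frame(
        id = id[angina], source = "hospital_icd10",
        code = sample(c("I20.0", "I20.1", "I20.8", "I20.9"),
                      sum(angina), TRUE))
    }
    records <- do.call(rbind, rec)
    if (any(excl_med)) {
      meds <- data.frame(
        id = id[excl_med],
        medication = sample(c("aspirin 75mg tablet",
                              "glyceryl trinitrate spray",
                              "isosorbide mononitrate m/r",
                              "nicorandil 10mg"),
                            sum(excl_med), TRUE))
    }
  }

  ## hypertension effects enter through the parent/brother latents below;
  ## the subject's own hypertension status is classified from measured BP,
  ## so a lineage BP effect propagates into it mechanically. A direct
  ## log-odds effect ("hypertension") additionally shifts parent/brother
  ## latents which have no measured BP.

  cohort <- data.frame(
    id = id, dob = dob, assess_date = assess_date, age = age,
    north_birth = north_birth, east_birth = east_birth,
    north_assess = north_assess, east_assess = east_assess,
    depr_birth = depr_birth, depr_assess = depr_assess,
    batch = batch, bmi = bmi,
    on_bp_med = on_bp_med, sbp_r1 = sbp_r1, sbp_r2 = sbp_r2,
    dbp_r1 = dbp_r1, dbp_r2 = dbp_r2,
    on_lipid_med = on_lipid_med, total_chol_meas = tc_meas,
    ldl_meas = ldl_meas, hdl_meas = hdl, trig_meas = trig,
    risk_factor = risk_factor, cad_true = as.numeric(cad_true),
    haplogroup_true = hap,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(pcs))

  ## subject survival
  if (cfg$simulate_survival) {
    gom <- cfg$gompertz
    rate_subj <- gom$rate * exp(effect_vector(cfg, "mortality", hap) +
                                  cfg$confounding$mort_north * nscale)
    t_death <- rgompertz_cond(n, gom$shape, rate_subj, age)
    death_date <- dob + round(t_death * 365.25)
    censor <- as.Date("2021-11-01")
    death_date[death_date > censor] <- NA
    sv <- subject_survival(dob, assess_date, death_date, censor)
    cohort$mortality_entry <- sv$entry_age
    cohort$mortality_event <- sv$event_age
    cohort$mortality_dead <- sv$dead
  }

  ## parents and brother
  if (cfg$simulate_parents) {
    fa_b <- pmax(16, round(stats::rnorm(n, 29, 5)))   # father age at birth
    ma_b <- pmax(16, round(stats::rnorm(n, 27, 5)))
    gom <- cfg$gompertz
    eff_mort <- effect_vector(cfg, "mortality", hap)
    rate_f <- gom$rate * exp(eff_mort + cfg$confounding$mort_north * nscale)
    rate_m <- gom$rate * exp(cfg$confounding$mort_north * nscale)
    t_f <- rgompertz_cond(n, gom$shape, rate_f, fa_b)
    t_m <- rgompertz_cond(n, gom$shape, rate_m, ma_b)
    f_cur <- fa_b + age                  # father age now, were he alive
    m_cur <- ma_b + age
    father_dead <- t_f < f_cur
    mother_dead <- t_m < m_cur
    father_age <- ifelse(father_dead, NA, floor(f_cur))
    mother_age <- ifelse(mother_dead, NA, floor(m_cur))
    father_age_at_death <- ifelse(father_dead, floor(t_f), NA)
    mother_age_at_death <- ifelse(mother_dead, floor(t_m), NA)

    eff_cad <- effect_vector(cfg, "cad", hap)
    eff_htn <- effect_vector(cfg, "hypertension", hap)
    f_age_eff <- ifelse(father_dead, father_age_at_death, father_age)
    m_age_eff <- ifelse(mother_dead, mother_age_at_death, mother_age)
    f_cad_logit <- stats::qlogis(0.15) + 0.04 * (f_age_eff - 65) +
      cfg$confounding$cad_north * nscale + eff_cad + 0.9 * sh * house
    m_cad_logit <- stats::qlogis(0.12) + 0.04 * (m_age_eff - 65) +
      cfg$confounding$cad_north * nscale + 0.9 * sh * house
    f_htn_logit <- stats::qlogis(0.30) + 0.03 * (f_age_eff - 65) +
      0.05 * cfg$confounding$bp_north * nscale + eff_htn + 0.9 * sh * house
    m_htn_logit <- stats::qlogis(0.35) + 0.03 * (m_age_eff - 65) +
      0.05 * cfg$confounding$bp_north * nscale + 0.9 * sh * house
    f_hd <- stats::runif(n) < stats::plogis(f_cad_logit)
    m_hd <- stats::runif(n) < stats::plogis(m_cad_logit)
    f_hbp <- stats::runif(n) < stats::plogis(f_htn_logit)
    m_hbp <- stats::runif(n) < stats::plogis(m_htn_logit)

    cond_str <- function(hd, hbp, pna) {
      out <- rep("none", n)
      out[hd & !hbp] <- "heart disease"
      out[!hd & hbp] <- "high blood pressure"
      out[hd & hbp] <- "heart disease;high blood pressure"
      out[pna] <- "prefer not to answer"
      out
    }
    pna_f <- stats::runif(n) < 0.02
    pna_m <- stats::runif(n) < 0.02
    cohort$father_conditions <- cond_str(f_hd, f_hbp, pna_f)
    cohort$mother_conditions <- cond_str(m_hd, m_hbp, pna_m)
    cohort$father_age <- father_age
    cohort$father_dead <- father_dead
    cohort$father_age_at_death <- father_age_at_death
    cohort$mother_age <- mother_age
    cohort$mother_dead <- mother_dead
    cohort$mother_age_at_death <- mother_age_at_death
    cohort$father_age_at_birth <- fa_b

    ## brother hypertension (subjects with exactly one male sibling)
    has_bro <- stats::runif(n) < cfg$brother_rate
    b_htn_logit <- stats::qlogis(0.25) + 0.03 * (age - 55) +
      0.05 * cfg$confounding$bp_north * nscale + eff_htn + 0.9 * sh * house
    bro <- ifelse(has_bro,
                  as.numeric(stats::runif(n) < stats::plogis(b_htn_logit)),
                  NA)
    cohort$brother_hypertension <- bro
  }

  ledger <- list(
    seed = cfg$seed, n_subjects = n, base_freqs = cfg$base_freqs,
    geo_gradient = cfg$geo_gradient, effect_map = cfg$effect_map,
    confounding = cfg$confounding, shared_env_corr = cfg$shared_env_corr,
    collider_scenario = cfg$collider_scenario,
    collider_group = cfg$collider_group,
    snp_error_rate = cfg$snp_error_rate,
    snp_missing_rate = cfg$snp_missing_rate,
    gompertz = cfg$gompertz, censor_date = "2021-11-01")

  structure(list(cohort = cohort, panel = panel, records = records,
                 meds = meds, tree = tree, config = cfg, ledger = ledger),
            class = "ykc_sim")
}

#' @export
print.ykc_sim <- function(x, ...) {
  cat("ykc_sim:", nrow(x$cohort), "subjects; seed", x$config$seed, "\n")
  invisible(x)
}

#' Assemble the analysis-ready phenotype table from a simulated cohort
#'
#' Runs the package's own phenotype constructors over the raw simulated
#' measurements: technical BP replicates are averaged, the iterative Tukey
#' filter is applied, medicated BP is adjusted (+15/+10 mm Hg), MAP is
#' computed with the standard formula, hypertension is classified on
#' measured values, lipids are medication-adjusted/log-transformed/
#' filtered, CAD is classified from the emitted coded records (or taken
#' from the generator's flag when records were not emitted), and parental
#' proxy phenotypes and survival records are built from the simulated
#' questionnaire reports.
#'
#' @param sim a `ykc_sim` from [simulate_cohort()]
#' @return the analysis cohort data frame (one row per subject)
#' @export
build_cohort_phenotypes <- function(sim) {
  ykc_assert(inherits(sim, "ykc_sim"), "sim must be a ykc_sim")
  d <- sim$cohort
  sbp <- rowMeans(cbind(d$sbp_r1, d$sbp_r2))
  dbp <- rowMeans(cbind(d$dbp_r1, d$dbp_r2))
  ms <- tukey_filter(sbp)
  md <- tukey_filter(dbp)
  sbp[!is.na(ms) & !ms] <- NA
  dbp[!is.na(md) & !md] <- NA
  adj <- adjust_blood_pressure(sbp, dbp, d$on_bp_med)
  d$sbp <- adj$sbp
  d$dbp <- adj$dbp
  d$map <- as.numeric(mean_arterial_pressure(adj$sbp, adj$dbp))
  d$hypertension <- classify_hypertension(sbp, dbp, d$on_bp_med)
  d$hypertension_num <- as.numeric(d$hypertension == "case")

  lip <- adjust_lipids(d$total_chol_meas, d$ldl_meas, d$hdl_meas,
                       d$trig_meas, d$on_lipid_med)
  d$total_chol <- lip$total_chol
  d$ldl <- lip$ldl
  d$hdl <- lip$hdl
  d$log_trig <- lip$log_trig

  if (!is.null(sim$records) || !is.null(sim$meds)) {
    cls <- classify_cad(sim$records, sim$meds, ids = d$id)
    d$cad <- ifelse(cls == "excluded", NA, as.numeric(cls == "case"))
    d$cad_class <- cls
  } else {
    d$cad <- d$cad_true
  }

  if (!is.null(d$father_conditions)) {
    pp <- build_parent_phenotypes(d)
    d$father_cad <- pp$father_cad
    d$father_cad_num <- as.numeric(pp$father_cad == "case")
    d$mother_cad <- pp$mother_cad
    d$mother_cad_num <- as.numeric(pp$mother_cad == "case")
    d$father_hypertension <- pp$father_htn
    d$mother_hypertension <- pp$mother_htn
    fs <- pp$father_survival
    i <- match(d$id, fs$id)
    d$father_mortality_entry <- fs$entry_age[i]
    d$father_mortality_event <- fs$event_age[i]
    d$father_mortality_dead <- fs$dead[i]
    ms2 <- pp$mother_survival
    j <- match(d$id, ms2$id)
    d$mother_mortality_entry <- ms2$entry_age[j]
    d$mother_mortality_event <- ms2$event_age[j]
    d$mother_mortality_dead <- ms2$dead[j]
  }
  d
}

#' Simulate father-son pair records for pedigree inference tests
#'
#' Creates father individuals for a subset of simulated subjects, a pairwise
#' kinship table (true pairs near the parent-offspring kinship expectation
#' of 0.25, decoy pairs below the 0.2 threshold), subject-reported father
#' ages (optionally jittered), and father health records constructed so
#' that a configurable number of the reported-heart-disease fathers meet
#' CAD criteria.
#'
#' @param sim a `ykc_sim` (parents must have been simulated)
#' @param n_pairs number of true father-son pairs (default 301)
#' @param n_hd number of sons reporting father heart disease (default 37)
#' @param n_hd_cad number of those fathers meeting CAD criteria (default 26)
#' @param kinship_noise_sd SD of noise on true-pair kinship (default 0.01)
#' @param age_jitter_days jitter on the implied father date of birth used
#'   for the son's reported father age (default 0)
#' @param n_decoys number of sub-threshold decoy pairs (default 200)
#' @param background_cad_rate CAD rate among non-reported fathers
#' @return list: `pairs_truth` (son_id, father_id), `kinship` (id1, id2,
#'   kinship), `people` (id, dob, assess_date, father_age rows for sons and
#'   fathers, ready for [infer_father_son_pairs()]), `father_records`,
#'   `reported_hd` and `father_cad` (logical, aligned to `pairs_truth`)
#' @export
simulate_father_son_records <- function(sim, n_pairs = 301, n_hd = 37,
                                        n_hd_cad = 26,
                                        kinship_noise_sd = 0.01,
                                        age_jitter_days = 0,
                                        n_decoys = 200,
                                        background_cad_rate = 0.10) {
  ykc_assert(inherits(sim, "ykc_sim"), "sim must be a ykc_sim")
  d <- sim$cohort
  ykc_assert(!is.null(d$father_age_at_birth),
             "simulate_cohort must be run with simulate_parents = TRUE")
  ykc_assert(n_pairs <= nrow(d), "n_pairs exceeds cohort size")
  ykc_assert(n_hd_cad <= n_hd && n_hd <= n_pairs,
             "need n_hd_cad <= n_hd <= n_pairs")

  sons <- sample(d$id, n_pairs)
  i <- match(sons, d$id)
  father_id <- paste0("F", sons)
  father_dob <- d$dob[i] - round(d$father_age_at_birth[i] * 365.25)
  # the son reports the father's age in years at the son's assessment;
  # rounding to the nearest year keeps the implied DOB within the 6-month
  # interval when no jitter is applied
  implied <- as.numeric(d$assess_date[i] - father_dob) + age_jitter_days
  reported_father_age <- round(implied / 365.25)

  people <- rbind(
    data.frame(id = sons, dob = d$dob[i], assess_date = d$assess_date[i],
               father_age = reported_father_age, stringsAsFactors = FALSE),
    data.frame(id = father_id, dob = father_dob,
               assess_date = as.Date(NA), father_age = NA_real_,
               stringsAsFactors = FALSE))

  kin_true <- data.frame(
    id1 = sons, id2 = father_id,
    kinship = 0.25 + stats::rnorm(n_pairs, 0, kinship_noise_sd))
  decoy1 <- sample(sons, n_decoys, TRUE)
  decoy2 <- sample(father_id, n_decoys, TRUE)
  ok <- decoy2 != paste0("F", decoy1)
  kin_decoy <- data.frame(id1 = decoy1[ok], id2 = decoy2[ok],
                          kinship = stats::runif(sum(ok), 0, 0.15))
  kinship <- rbind(kin_true, kin_decoy)

  hd_idx <- sample(n_pairs, n_hd)
  reported_hd <- seq_len(n_pairs) %in% hd_idx
  cad_idx <- sample(hd_idx, n_hd_cad)
  bg_idx <- which(!reported_hd &
                    stats::runif(n_pairs) < background_cad_rate)
  cad_fathers <- father_id[sort(unique(c(cad_idx, bg_idx)))]
  father_records <- if (length(cad_fathers)) {
    data.frame(id = cad_fathers, source = "hospital_icd10",
               code = sample(c("I21.0", "I21.9", "I22.0", "I25.2"),
                             length(cad_fathers), TRUE),
               stringsAsFactors = FALSE)
  } else {
    NULL
  }
  father_cad_cls <- classify_cad(father_records, NULL, ids = father_id)

  list(pairs_truth = data.frame(son_id = sons, father_id = father_id,
                                stringsAsFactors = FALSE),
       kinship = kinship,
       people = people,
       father_records = father_records,
       reported_hd = reported_hd,
       father_cad = father_cad_cls == "case")
}
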