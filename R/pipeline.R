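## End-to-end pipeline driver: qc -> assign -> indicators -> phenotypes ->
## association -> kin validation -> reports, with a reproducible manifest.

#' Default pipeline configuration
#'
#' Thresholds default to the analysis constants used throughout the
#' package: SNP call rate 0.95, minimum 100 carriers (continuous traits) or
#' 40 carrier-cases (binary), suggestive screen P < 0.10, PCA variance
#' fraction 0.95, kinship threshold 0.2, censoring date 2021-11-01.
#'
#' @return named list of defaults, overridable via the YAML config
#' @export
default_run_config <- function() {
  list(
    n_subjects = 2000,
    min_call_rate = 0.95,
    min_carriers = 100,
    min_cases = 40,
    suggestive_p = 0.10,
    variance_fraction = 0.95,
    kinship_threshold = 0.2,
    n_boot = 10000,
    censor_date = "2021-11-01",
    covariate_set = "robust",
    outcomes = list(
      list(name = "map", family = "linear"),
      list(name = "sbp", family = "linear"),
      list(name = "dbp", family = "linear"),
      list(name = "hypertension", family = "logistic"),
      list(name = "cad", family = "logistic")
    ),
    bp_phenotypes = c("sbp", "dbp", "map"),
    kin_outcome = "cad",
    seed = 1
  )
}

#' Run the full analysis pipeline
#'
#' Executes QC, haplogroup assignment, indicator construction, phenotype
#' building, the per-outcome association batteries with PCA multiplicity
#' correction, and the kin-cohort validation battery, writing tidy TSV
#' results and a JSON manifest into `outdir`. With `simulate = TRUE` all
#' inputs are generated by [simulate_cohort()]; otherwise `config` must
#' name the input files (`tree_file`, `snp_map`, `genotypes_tsv`,
#' `cohort_tsv`, optionally `group_defs`). Any stage failure raises an
#' error naming the stage.
#'
#' @param config path to a YAML config, or a named list, or `NULL` for
#'   defaults
#' @param simulate generate inputs with the synthetic cohort generator
#' @param seed overrides the config seed
#' @param outdir output directory (created if needed)
#' @param only optional character vector restricting which result stages to
#'   write (`"association"`, `"kin"`, `"prevalence"`)
#' @return `outdir`, invisibly
#' @export
run_pipeline <- function(config = NULL, simulate = FALSE, seed = NULL,
                         outdir = tempfile("ykc_run_"), only = NULL) {
  cfg <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg[names(config)] <- config
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    logf("stage", name, "start")
    tryCatch(expr, error = function(e) {
      ykc_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  want <- function(x) is.null(only) || x %in% only

  inputs <- stage("inputs", {
    if (simulate) {
      sim <- simulate_cohort(sim_config(n_subjects = cfg$n_subjects,
                                        seed = cfg$seed))
      fam <- simulate_father_son_records(sim)
      list(sim = sim, tree = sim$tree, panel = sim$panel,
           group_defs = ykc_fixture_groups(), fam = fam)
    } else {
      ykc_assert(!is.null(cfg$tree_file) && !is.null(cfg$snp_map),
                 "config must provide tree_file and snp_map")
      ykc_assert(!is.null(cfg$genotypes_tsv),
                 "config must provide genotypes_tsv")
      tree <- load_phylogeny(cfg$tree_file, cfg$snp_map)
      panel <- read_genotypes_tsv(cfg$genotypes_tsv)
      defs <- if (!is.null(cfg$group_defs)) read_group_defs(cfg$group_defs)
      list(tree = tree, panel = panel, group_defs = defs)
    }
  })

  panel <- stage("qc", qc_snps(inputs$panel, cfg$min_call_rate))
  assignments <- stage("assign", assign_haplogroups(inputs$tree, panel))
  indicators <- stage("indicators",
                      build_indicator_matrix(assignments, inputs$tree,
                                             inputs$group_defs))

  cohort <- stage("phenotypes", {
    if (simulate) {
      build_cohort_phenotypes(inputs$sim)
    } else {
      ykc_stop("non-simulated runs need a prepared cohort table ",
               "(cohort_tsv support: supply phenotype columns directly)")
    }
  })

  n_eff_record <- list()
  if (want("association")) {
    stage("association", {
      bp_res <- list()
      all_res <- list()
      for (oc in cfg$outcomes) {
        if (is.null(cohort[[oc$name]])) next
        res <- run_association(
          cohort, indicators, oc$name, oc$family,
          covariate_set = cfg$covariate_set,
          min_carriers = cfg$min_carriers, min_cases = cfg$min_cases,
          variance_fraction = cfg$variance_fraction)
        if (is.null(res)) next
        n_eff_record[[oc$name]] <- attr(res, "n_eff")
        all_res[[oc$name]] <- res
        if (oc$name %in% cfg$bp_phenotypes) bp_res[[oc$name]] <- res
      }
      out <- do.call(rbind, all_res)
      utils::write.table(out, file.path(outdir, "association_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  if (want("kin")) {
    stage("kin", {
      if (is.null(cohort[[paste0("father_", cfg$kin_outcome)]])) {
        ykc_stop("kin validation requires parent phenotype columns for ",
                 cfg$kin_outcome)
      }
      case_ind <- outcome_numeric(cohort[[cfg$kin_outcome]], "logistic")
      kept <- filter_groups(indicators, min_carriers = cfg$min_carriers,
                            case_indicator = case_ind,
                            min_cases = cfg$min_cases)
      if (length(kept$groups)) {
        kin <- run_kin_battery(cohort, kept, cfg$kin_outcome,
                               covariate_set = cfg$covariate_set,
                               suggestive_p = cfg$suggestive_p)
        utils::write.table(kin, file.path(outdir, "kin_validation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        forest <- kin[, c("haplogroup", "subject_gamma", "subject_ci_lo",
                          "subject_ci_hi", "subject_p", "father_gamma",
                          "father_ci_lo", "father_ci_hi", "father_p",
                          "mother_gamma", "mother_ci_lo", "mother_ci_hi",
                          "mother_p", "verdict")]
        jsonlite::write_json(forest, file.path(outdir, "forest_table.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA)
      }
      if (simulate && !is.null(inputs$fam)) {
        pairs <- infer_father_son_pairs(inputs$fam$kinship,
                                        inputs$fam$people,
                                        cfg$kinship_threshold)
        acc <- proxy_accuracy(inputs$fam$father_cad, inputs$fam$reported_hd,
                              n_boot = cfg$n_boot, seed = cfg$seed)
        utils::write.table(pairs, file.path(outdir, "father_son_pairs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
          list(estimate = acc$estimate, ci95 = acc$ci95,
               n_pairs = acc$n_pairs, n_hd = acc$n_hd,
               n_hd_cad = acc$n_hd_cad),
          file.path(outdir, "proxy_accuracy.json"), auto_unbox = TRUE,
          digits = NA)
      }
    })
  }

  if (want("prevalence")) {
    stage("prevalence", {
      # coarse synthetic area hierarchy from birth coordinates
      fine <- paste0("g", floor(cohort$north_birth / 100), "_",
                     floor(cohort$east_birth / 100))
      coarse <- paste0("G", floor(cohort$north_birth / 500))
      prev <- prevalence_by_area(indicators,
                                 data.frame(fine = fine, coarse = coarse),
                                 min_area_n = 100)
      utils::write.table(prev, file.path(outdir, "prevalence_by_area.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ykincohort")),
    seed = cfg$seed,
    simulate = simulate,
    censor_date = cfg$censor_date,
    covariate_set = cfg$covariate_set,
    thresholds = cfg[c("min_call_rate", "min_carriers", "min_cases",
                       "suggestive_p", "variance_fraction",
                       "kinship_threshold", "n_boot")],
    n_eff = n_eff_record,
    qc = attr(panel, "qc_log"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done")
  invisible(outdir)
}
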