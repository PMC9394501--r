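## Kin-cohort validation: subject/father/mother (and brother) batteries,
## genetic father-son pair inference, and heart-disease-as-CAD-proxy
## accuracy by bootstrap.

#' Kin-cohort verdict for one haplogroup
#'
#' Pure decision rule combining the subject, father, and mother results:
#' a subject association is *suggestive* when its raw P is below
#' `suggestive_p`; the father result *replicates* when its effect sign
#' agrees with the subject's (fathers share the son's Y lineage); the
#' mother result is *null* when its 95% CI spans zero (mothers cannot carry
#' the son's Y, so any maternal signal indicates bias). The verdict is
#' `validated` iff suggestive AND father-concordant AND mother-null,
#' `not_supported` iff suggestive but either kin check fails, and
#' `inconclusive` otherwise (including when a needed kin estimate is
#' missing).
#'
#' @param p_subject subject raw P value
#' @param gamma_subject,gamma_father subject and father effect estimates
#' @param mother_ci_lo,mother_ci_hi mother 95% CI bounds
#' @param suggestive_p screening threshold (default 0.10)
#' @return list with `suggestive`, `father_concordant`, `mother_null`,
#'   `verdict`
#' @export
kin_verdict <- function(p_subject, gamma_subject, gamma_father,
                        mother_ci_lo, mother_ci_hi, suggestive_p = 0.10) {
  suggestive <- !is.na(p_subject) && p_subject < suggestive_p
  father_concordant <- if (is.na(gamma_subject) || is.na(gamma_father)) {
    NA
  } else {
    sign(gamma_subject) == sign(gamma_father)
  }
  mother_null <- if (is.na(mother_ci_lo) || is.na(mother_ci_hi)) {
    NA
  } else {
    mother_ci_lo <= 0 && mother_ci_hi >= 0
  }
  verdict <- if (!suggestive) {
    "inconclusive"
  } else if (is.na(father_concordant) || is.na(mother_null)) {
    "inconclusive"
  } else if (father_concordant && mother_null) {
    "validated"
  } else {
    "not_supported"
  }
  list(suggestive = suggestive, father_concordant = father_concordant,
       mother_null = mother_null, verdict = verdict)
}

#' Run the subject/father/mother (and brother) kin-cohort battery
#'
#' For each haplogroup, fits the subject model on `outcome`, the father
#' model on `father_<outcome>`, the mother model on `mother_<outcome>`, and
#' a brother model on `brother_<outcome>` when that column exists. Parent
#' models reuse the same covariate set with parent age terms. Results are
#' combined into a validation verdict by [kin_verdict()].
#'
#' @param cohort analysis cohort with the parent phenotype columns
#' @param indicators a `HaplogroupMatrix` (already carrier-filtered)
#' @param outcome subject outcome column (binary; parent columns are its
#'   `father_`/`mother_`/`brother_` counterparts)
#' @param family model family for all fits (default `"logistic"`)
#' @param covariate_set covariate set (default `"robust"`)
#' @param suggestive_p subject screening threshold (default 0.10)
#' @return data frame, one row per haplogroup: subject/father/mother
#'   (/brother) estimates, CIs and P values, the three flags and the
#'   verdict; full per-model results in attribute `"fits"`
#' @export
run_kin_battery <- function(cohort, indicators, outcome,
                            family = "logistic", covariate_set = "robust",
                            suggestive_p = 0.10) {
  for (side in c("father", "mother")) {
    col <- paste0(side, "_", outcome)
    if (is.null(cohort[[col]])) {
      ykc_stop("missing parent phenotype column: ", col)
    }
  }
  has_brother <- !is.null(cohort[[paste0("brother_", outcome)]])

  fit_side <- function(parent, col) {
    fit_haplogroup_models(cohort, indicators, col, family, covariate_set,
                          parent = parent)
  }
  subj <- fit_side("subject", outcome)
  fath <- fit_side("father", paste0("father_", outcome))
  moth <- fit_side("mother", paste0("mother_", outcome))
  brot <- if (has_brother) fit_side("brother", paste0("brother_", outcome))

  rows <- lapply(seq_along(indicators$groups), function(i) {
    v <- kin_verdict(subj$p_raw[i], subj$gamma[i], fath$gamma[i],
                     moth$ci_lo[i], moth$ci_hi[i], suggestive_p)
    data.frame(
      haplogroup = indicators$groups[i], outcome = outcome,
      subject_gamma = subj$gamma[i], subject_ci_lo = subj$ci_lo[i],
      subject_ci_hi = subj$ci_hi[i], subject_p = subj$p_raw[i],
      father_gamma = fath$gamma[i], father_ci_lo = fath$ci_lo[i],
      father_ci_hi = fath$ci_hi[i], father_p = fath$p_raw[i],
      mother_gamma = moth$gamma[i], mother_ci_lo = moth$ci_lo[i],
      mother_ci_hi = moth$ci_hi[i], mother_p = moth$p_raw[i],
      brother_gamma = if (has_brother) brot$gamma[i] else NA_real_,
      brother_p = if (has_brother) brot$p_raw[i] else NA_real_,
      suggestive = v$suggestive,
      father_concordant = v$father_concordant,
      mother_null = v$mother_null,
      verdict = v$verdict,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- list(subject = subj, father = fath, mother = moth,
                            brother = brot)
  out
}

#' Infer father-son pairs from kinship and reported father ages
#'
#' A pair of men with genetic kinship coefficient strictly above
#' `kinship_threshold` is an inferred father-son pair when exactly one
#' member's date of birth falls inside the other's reported-father
#' date-of-birth interval: subtracting the reported father age (years) from
#' the subject's assessment date and allowing six months (183 days) on
#' either side, closed at both ends. That member is oriented as the father.
#' Pairs matching in both directions are ambiguous and dropped (logged).
#'
#' @param kinship data frame with columns `id1`, `id2`, `kinship`
#' @param cohort data frame with columns `id`, `dob` (`Date`),
#'   `assess_date` (`Date`) and `father_age` (reported years, `NA` when the
#'   father is dead or unreported)
#' @param kinship_threshold strict lower bound (default 0.2; the
#'   parent-offspring kinship coefficient expectation is 0.25)
#' @param halfwidth_days interval half-width (default 183)
#' @return data frame with `son_id`, `father_id`, `kinship`
#' @export
infer_father_son_pairs <- function(kinship, cohort, kinship_threshold = 0.2,
                                   halfwidth_days = 183) {
  ykc_assert(all(c("id1", "id2", "kinship") %in% names(kinship)),
             "kinship table needs columns id1, id2, kinship")
  ykc_assert(all(c("id", "dob", "assess_date", "father_age") %in%
                   names(cohort)),
             "cohort needs columns id, dob, assess_date, father_age")
  kin <- kinship[kinship$kinship > kinship_threshold, , drop = FALSE]
  if (nrow(kin) == 0L) {
    return(data.frame(son_id = character(), father_id = character(),
                      kinship = numeric()))
  }
  idx <- function(ids) match(ids, cohort$id)
  # centre of the father-DOB interval implied by the subject's report
  centre <- cohort$assess_date - round(cohort$father_age * 365.25)
  in_interval <- function(son, cand_father) {
    i <- idx(son); j <- idx(cand_father)
    ok <- !is.na(i) & !is.na(j) & !is.na(centre[i]) & !is.na(cohort$dob[j])
    delta <- abs(as.numeric(cohort$dob[j] - centre[i]))
    ok & !is.na(delta) & delta <= halfwidth_days
  }
  a <- in_interval(kin$id1, kin$id2)  # id2 candidate father of id1
  b <- in_interval(kin$id2, kin$id1)  # id1 candidate father of id2
  ambiguous <- a & b
  if (any(ambiguous)) {
    message("infer_father_son_pairs: dropped ", sum(ambiguous),
            " ambiguous pair(s) matching in both directions")
  }
  one <- xor(a, b)
  data.frame(
    son_id = ifelse(a[one], kin$id1[one], kin$id2[one]),
    father_id = ifelse(a[one], kin$id2[one], kin$id1[one]),
    kinship = kin$kinship[one],
    stringsAsFactors = FALSE)
}

#' Proxy accuracy of reported heart disease for CAD
#'
#' Among inferred father-son pairs, estimates the proportion of fathers
#' reported (by their sons) to have heart disease who meet CAD inclusion
#' criteria, with a percentile bootstrap CI over resamples of the full pair
#' list.
#'
#' @param father_cad logical per pair: father meets CAD criteria
#' @param reported_hd logical per pair: son reported father heart disease
#' @param n_boot bootstrap iterations (default 100000)
#' @param seed optional integer seed for the bootstrap
#' @return list with `estimate` (proportion), `ci95` (length-2), `n_pairs`,
#'   `n_hd`, `n_hd_cad`, `n_boot`
#' @export
proxy_accuracy <- function(father_cad, reported_hd, n_boot = 100000,
                           seed = NULL) {
  ykc_assert(length(father_cad) == length(reported_hd),
             "flag vectors must align")
  father_cad <- as.logical(father_cad)
  reported_hd <- as.logical(reported_hd)
  n <- length(father_cad)
  n_hd <- sum(reported_hd, na.rm = TRUE)
  if (n_hd == 0L) ykc_stop("no reported-heart-disease fathers; proportion undefined")
  n_a <- sum(reported_hd & father_cad, na.rm = TRUE)
  est <- n_a / n_hd
  if (!is.null(seed)) set.seed(seed)
  # Resampling n pairs with replacement is a draw of category counts from a
  # multinomial over (HD&CAD, HD&!CAD, !HD); the proportion only depends on
  # those counts.
  counts <- stats::rmultinom(n_boot, n, c(n_a, n_hd - n_a, n - n_hd) / n)
  denom <- counts[1, ] + counts[2, ]
  prop <- counts[1, ][denom > 0] / denom[denom > 0]
  ci <- unname(stats::quantile(prop, c(0.025, 0.975), type = 7))
  list(estimate = est, ci95 = ci, n_pairs = n, n_hd = n_hd,
       n_hd_cad = n_a, n_boot = n_boot)
}
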