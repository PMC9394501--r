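## Cardiovascular phenotype construction: iterative Tukey outlier removal,
## medication-adjusted blood pressure and lipids, hypertension and CAD
## classification from code lists, parental proxies, and survival records.

#' Iterative modified-Tukey outlier filter
#'
#' Flags values strictly below Q1 - k*IQR or strictly above Q3 + k*IQR,
#' recomputes the quartiles on the survivors, and repeats until a pass
#' removes nothing. Quartiles use the default linear-interpolation
#' convention (type 7).
#'
#' @param values numeric vector; missing values are ignored and come back as
#'   `NA` in the mask
#' @param k IQR multiplier (default 3)
#' @return logical mask of survivors (`NA` where the input was missing) with
#'   attribute `"passes"` giving per-pass removal counts
#' @export
tukey_filter <- function(values, k = 3) {
  mask <- !is.na(values)
  if (sum(mask) < 4L) {
    warning("fewer than 4 non-missing values; no outlier removal performed",
            call. = FALSE)
    mask[is.na(values)] <- NA
    attr(mask, "passes") <- integer(0)
    return(mask)
  }
  removed <- integer(0)
  repeat {
    x <- values[which(mask)]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    out <- !is.na(values) & mask &
      (values < q[1] - k * iqr | values > q[2] + k * iqr)
    out[is.na(out)] <- FALSE
    if (!any(out)) break
    removed <- c(removed, sum(out))
    mask[out] <- FALSE
  }
  mask[is.na(values)] <- NA
  attr(mask, "passes") <- removed
  mask
}

#' Medication adjustment for measured blood pressure
#'
#' Individuals on antihypertensive medication have 15 mm Hg added to their
#' measured SBP and 10 mm Hg to their measured DBP; others are unchanged.
#'
#' @param sbp_measured,dbp_measured measured pressures, mm Hg
#' @param on_med logical: on antihypertensive medication
#' @return data frame with columns `sbp` and `dbp` (adjusted, mm Hg)
#' @export
adjust_blood_pressure <- function(sbp_measured, dbp_measured, on_med) {
  on_med <- as.logical(on_med)
  data.frame(sbp = sbp_measured + ifelse(!is.na(on_med) & on_med, 15, 0),
             dbp = dbp_measured + ifelse(!is.na(on_med) & on_med, 10, 0))
}

#' Mean arterial pressure
#'
#' The standard formula is DBP + (SBP - DBP)/3, i.e. diastolic plus a third
#' of the pulse pressure. A `"printed"` mode evaluating DBP + (DBP + SBP)/3
#' is provided for comparison with sources that print that expression; it
#' exceeds SBP for physiological inputs and is flagged as implausible.
#'
#' @param sbp,dbp pressures in mm Hg
#' @param formula `"standard"` (default) or `"printed"`
#' @return MAP in mm Hg, with the mode recorded in attribute `"formula"`
#' @export
mean_arterial_pressure <- function(sbp, dbp,
                                   formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  out <- switch(formula,
                standard = dbp + (sbp - dbp) / 3,
                printed = dbp + (dbp + sbp) / 3)
  if (formula == "printed") {
    message("mean_arterial_pressure: 'printed' formula exceeds SBP for ",
            "physiological inputs; values are not plausible pressures")
  }
  attr(out, "formula") <- formula
  out
}

#' Classify hypertension
#'
#' Case if on antihypertensive medication, or measured SBP >= 140, or
#' measured DBP >= 90 (thresholds are applied to measured, not
#' medication-adjusted, values). Missing input gives a missing outcome.
#'
#' @param sbp_measured,dbp_measured measured pressures, mm Hg
#' @param on_med logical medication flag
#' @return factor with levels `control`, `case` (`NA` where undetermined)
#' @export
classify_hypertension <- function(sbp_measured, dbp_measured, on_med) {
  on_med <- as.logical(on_med)
  case <- on_med | sbp_measured >= 140 | dbp_measured >= 90
  # on_med TRUE decides regardless of missing BP
  case[is.na(case) & !is.na(on_med) & on_med] <- TRUE
  factor(ifelse(case, "case", "control"), levels = c("control", "case"))
}

#' Medication adjustment and transformation of lipid measures
#'
#' Individuals on lipid-lowering medication have measured LDL divided by 0.7
#' and total cholesterol divided by 0.8; triglycerides are log-transformed
#' (non-positive values become missing); every trait is then passed through
#' [tukey_filter()] and outliers are set to `NA`.
#'
#' @param total_chol,ldl,hdl,trig measured concentrations (e.g. mmol/L)
#' @param on_med logical lipid-lowering medication flag
#' @param k Tukey IQR multiplier (default 3)
#' @return data frame with columns `total_chol`, `ldl`, `hdl`, `log_trig`
#' @export
adjust_lipids <- function(total_chol, ldl, hdl, trig, on_med, k = 3) {
  on_med <- !is.na(as.logical(on_med)) & as.logical(on_med)
  ldl_adj <- ifelse(on_med, ldl / 0.7, ldl)
  tc_adj <- ifelse(on_med, total_chol / 0.8, total_chol)
  trig[!is.na(trig) & trig <= 0] <- NA
  log_trig <- log(trig)
  out <- data.frame(total_chol = tc_adj, ldl = ldl_adj, hdl = hdl,
                    log_trig = log_trig)
  for (v in names(out)) {
    m <- tukey_filter(out[[v]], k = k)
    out[[v]][!is.na(m) & !m] <- NA
  }
  out
}

## ---- CAD classification ---------------------------------------------------

#' Default coronary artery disease code lists
#'
#' Myocardial infarction (ICD-9 4109/4129; ICD-10 I21-I23, I25.2), PCI
#' (OPCS K49/K50/K75), CABG (OPCS K40-K46), CAD death codes (ICD-10 I20,
#' I21, I24, I25.1, I25.2, I25.5, I25.8, I25.9), angina exclusions (ICD-9
#' 4139; ICD-10 I20.0/I20.1/I20.8/I20.9) and exclusion medication classes
#' (aspirin, glyceryl trinitrate, isosorbide mono-/dinitrate, nicorandil).
#' Codes are matched by prefix after removing dots, so `I21` covers all
#' `I21.x` subcodes.
#'
#' @return named list of code vectors
#' @export
cad_code_lists <- function() {
  list(
    mi_icd9 = c("4109", "4129"),
    mi_icd10 = c(expand_code_range("I21-I23"), "I25.2"),
    pci_opcs = c("K49", "K50", "K75"),
    cabg_opcs = expand_code_range("K40-K46"),
    death_icd10 = c("I20", "I21", "I24", "I25.1", "I25.2", "I25.5",
                    "I25.8", "I25.9"),
    angina_icd9 = "4139",
    angina_icd10 = c("I20.0", "I20.1", "I20.8", "I20.9"),
    exclusion_medications = c("aspirin", "glyceryl trinitrate",
                              "isosorbide mononitrate",
                              "isosorbide dinitrate", "nicorandil")
  )
}

#' Read CAD code lists from YAML
#'
#' The YAML mirrors the structure of [cad_code_lists()]; range entries such
#' as `"I21-I23"` are expanded at load time.
#'
#' @param path YAML file path
#' @return named list of code vectors
#' @export
read_code_lists <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- cad_code_lists()
  out <- lapply(names(defaults), function(nm) {
    v <- y[[nm]]
    if (is.null(v)) defaults[[nm]] else
      if (nm == "exclusion_medications") unlist(v) else
        expand_code_range(unlist(v))
  })
  names(out) <- names(defaults)
  out
}

#' Classify coronary artery disease from coded health records
#'
#' Applies a code-list algorithm: an individual is a case on any qualifying
#' MI / PCI / CABG / CAD-death code; otherwise excluded on any angina code
#' or use of an exclusion medication; otherwise a control. Self-reported and
#' hospital ICD-10 codes are matched against the MI list; ICD-9 sources
#' against the ICD-9 lists; OPCS operations against PCI/CABG; death codes
#' (primary or secondary) against the CAD-death list. The partition is
#' exhaustive and exclusive over `ids`.
#'
#' @param records data frame with columns `id`, `source` (one of
#'   `self_report`, `hospital_icd9`, `hospital_icd10`, `operation_opcs`,
#'   `death_icd10_primary_or_secondary`) and `code`
#' @param meds optional data frame with columns `id`, `medication`
#'   (free-text medication/class name, matched case-insensitively against
#'   the exclusion classes)
#' @param ids character vector: the full cohort (individuals without records
#'   become controls)
#' @param codelists code lists as from [cad_code_lists()]
#' @return factor per id with levels `control`, `case`, `excluded`
#' @export
classify_cad <- function(records, meds = NULL, ids,
                         codelists = cad_code_lists()) {
  ids <- as.character(ids)
  out <- factor(rep("control", length(ids)),
                levels = c("control", "case", "excluded"))
  names(out) <- ids
  if (!is.null(records) && nrow(records)) {
    ykc_assert(all(c("id", "source", "code") %in% names(records)),
               "records need columns id, source, code")
    bad <- is.na(records$code) | !nzchar(trimws(records$code))
    if (any(bad)) {
      message("classify_cad: ignoring ", sum(bad), " unparseable code(s)")
      records <- records[!bad, , drop = FALSE]
    }
    src <- records$source
    code <- records$code
    is_case <-
      (src %in% c("self_report", "hospital_icd10") &
         match_any_prefix(code, codelists$mi_icd10)) |
      (src == "hospital_icd9" &
         match_any_prefix(code, codelists$mi_icd9)) |
      (src == "operation_opcs" &
         match_any_prefix(code, c(codelists$pci_opcs, codelists$cabg_opcs))) |
      (src == "death_icd10_primary_or_secondary" &
         match_any_prefix(code, codelists$death_icd10))
    is_angina <-
      (src %in% c("self_report", "hospital_icd10") &
         match_any_prefix(code, codelists$angina_icd10)) |
      (src %in% c("self_report", "hospital_icd9") &
         match_any_prefix(code, codelists$angina_icd9))
    case_ids <- unique(records$id[is_case])
    angina_ids <- unique(records$id[is_angina])
    out[ids %in% angina_ids] <- "excluded"
    out[ids %in% case_ids] <- "case"
  }
  if (!is.null(meds) && nrow(meds)) {
    med_norm <- tolower(meds$medication)
    hit <- Reduce(`|`, lapply(cad_med_patterns(codelists),
                              function(p) grepl(p, med_norm, fixed = TRUE)))
    med_ids <- unique(meds$id[hit])
    out[ids %in% med_ids & out == "control"] <- "excluded"
  }
  out
}

# lower-cased fixed patterns for exclusion-medication matching
cad_med_patterns <- function(codelists) {
  tolower(codelists$exclusion_medications)
}

## ---- Parental phenotypes --------------------------------------------------

#' Build parental proxy phenotypes and parent survival records
#'
#' From subject-reported parental illness questionnaires: selection of
#' "heart disease" makes a parent a CAD-proxy case, "high blood pressure" a
#' hypertension case, any other answered selection a control, and "prefer
#' not to answer" missing. Parent survival uses the reported parent age and
#' vital status at subject assessment on the age timescale with delayed
#' entry at 40; parents with reported age at death before 40 are excluded
#' (deaths from accident or injury dominate below that age).
#'
#' @param reports data frame with columns `id`, `father_conditions`,
#'   `mother_conditions` (`";"`-separated selection strings, `"none"`, or
#'   `"prefer not to answer"`), `father_age`, `father_dead`,
#'   `father_age_at_death`, and the `mother_*` equivalents
#' @return list with per-subject factors `father_cad`, `father_htn`,
#'   `mother_cad`, `mother_htn` and data frames `father_survival`,
#'   `mother_survival` (`id`, `entry_age`, `event_age`, `dead`)
#' @export
build_parent_phenotypes <- function(reports) {
  parse_side <- function(cond) {
    cond <- tolower(ifelse(is.na(cond), "prefer not to answer", cond))
    missing <- grepl("prefer not to answer", cond, fixed = TRUE)
    hd <- !missing & grepl("heart disease", cond, fixed = TRUE)
    hbp <- !missing & grepl("high blood pressure", cond, fixed = TRUE)
    cad <- factor(ifelse(missing, NA, ifelse(hd, "case", "control")),
                  levels = c("control", "case"))
    htn <- factor(ifelse(missing, NA, ifelse(hbp, "case", "control")),
                  levels = c("control", "case"))
    list(cad = cad, htn = htn)
  }
  surv_side <- function(age, dead, age_at_death) {
    dead <- !is.na(dead) & as.logical(dead)
    event_age <- ifelse(dead, age_at_death, age)
    keep <- !is.na(event_age) & !(dead & age_at_death < 40) & event_age > 40
    data.frame(id = reports$id[keep],
               entry_age = 40,
               event_age = event_age[keep],
               dead = dead[keep])
  }
  f <- parse_side(reports$father_conditions)
  m <- parse_side(reports$mother_conditions)
  list(
    father_cad = f$cad, father_htn = f$htn,
    mother_cad = m$cad, mother_htn = m$htn,
    father_survival = surv_side(reports$father_age, reports$father_dead,
                                reports$father_age_at_death),
    mother_survival = surv_side(reports$mother_age, reports$mother_dead,
                                reports$mother_age_at_death)
  )
}

#' Subject survival records on the age timescale
#'
#' Entry at age at assessment; exit at death or at the fixed cohort-wide
#' censoring date, whichever is earlier.
#'
#' @param dob,assess_date,death_date `Date` vectors (`death_date` `NA` for
#'   survivors)
#' @param censor_date single `Date`; defaults to `"2021-11-01"`
#' @return data frame with `entry_age`, `event_age`, `dead`
#' @export
subject_survival <- function(dob, assess_date, death_date,
                             censor_date = as.Date("2021-11-01")) {
  yrs <- function(a, b) as.numeric(b - a) / 365.25
  entry <- yrs(dob, assess_date)
  died <- !is.na(death_date) & death_date <= censor_date
  exit <- ifelse(died, yrs(dob, death_date), yrs(dob, censor_date))
  data.frame(entry_age = entry, event_age = exit, dead = died)
}
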