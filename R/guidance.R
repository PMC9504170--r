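#' The dose-guidance knowledge base
#'
#' Loads the packaged YAML knowledge base of printed, source-attributed dose
#' recommendations and risk statements. Every record carries the primary
#' study it came from; this module is a curated lookup table with a rules
#' engine, not a pharmacokinetic simulator.
#'
#' @param path optional alternative knowledge-base YAML file.
#' @return nested list mirroring the YAML structure.
#' @export
guidance_kb <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_env$kb))
      .pkg_env$kb <- yaml::read_yaml(pkg_extdata("dosing_kb.yaml"))
    return(.pkg_env$kb)
  }
  yaml::read_yaml(path)
}

# normalize a phenotype argument (phenotype_call object or string)
.phenotype_name <- function(phenotype) {
  if (inherits(phenotype, "phenotype_call")) phenotype <- phenotype$phenotype
  if (!is.character(phenotype) || length(phenotype) != 1L ||
      !phenotype %in% PHENOTYPES)
    stop("phenotype must be one of: ", paste(PHENOTYPES, collapse = ", "),
         call. = FALSE)
  phenotype
}

.PM_IM <- c("poor", "likely-poor", "intermediate", "likely-intermediate")
.RM_UM <- c("rapid", "ultra-rapid")

dose_recommendation <- function(drug, source_model, dose_value, units,
                                qualifiers = character(), citation,
                                range = NULL) {
  stopifnot(nzchar(citation))
  structure(list(drug = drug, source_model = source_model,
                 dose_value = dose_value, units = units,
                 qualifiers = qualifiers, range = range, citation = citation),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  dv <- if (is.character(x$dose_value)) x$dose_value
        else if (length(x$dose_value) == 2L)
          paste0(x$dose_value[1L], "-", x$dose_value[2L])
        else as.character(x$dose_value)
  cat(x$drug, " [", x$source_model, "]: ", dv, " ", x$units, "\n", sep = "")
  if (!is.null(x$range))
    cat("  published range: ", x$range[1L], "-", x$range[2L], " ", x$units, "\n",
        sep = "")
  for (q in x$qualifiers) cat("  - ", q, "\n", sep = "")
  cat("  source: ", x$citation, "\n", sep = "")
  invisible(x)
}

#' Phenotype- and covariate-conditioned voriconazole dose
#'
#' Looks up the published voriconazole dose for a CYP2C19 phenotype under
#' one of the encoded source models:
#' * `takahashi-2021` - weight-banded normal-metabolizer base dose
#'   (16 mg/kg under 15 kg, 12 mg/kg from 15 to under 30 kg, 10 mg/kg from
#'   30 kg) with published percent adjustments returned as intervals:
#'   0.50-0.67 of base for poor/intermediate, 1.25-1.50 for
#'   rapid/ultra-rapid. Requires `weight_kg`.
#' * `tian-2021` - age-banded twice-daily dose by phenotype group
#'   (ultra-rapid/rapid/normal vs poor/intermediate; rapid metabolizers are
#'   mapped to the UM/EM group with a caveat). Requires `age_years`;
#'   exactly 12 years falls in the older band.
#' * `chen-2022` - published median daily dose with its range per phenotype
#'   group.
#' * `package-insert` - age-banded loading/maintenance label dosing.
#'   Requires `age_years`.
#'
#' @param model source-model identifier (see above).
#' @param phenotype a [phenotype_call][diplotype_to_phenotype()] or
#'   phenotype string.
#' @param weight_kg body weight in kg (Takahashi model).
#' @param age_years age in years (Tian and package-insert models).
#' @return a `dose_recommendation` record with source provenance.
#' @export
vcz_dose <- function(model, phenotype, weight_kg = NULL, age_years = NULL) {
  kb <- guidance_kb()$voriconazole
  phenotype <- .phenotype_name(phenotype)
  if (!model %in% setdiff(names(kb), "hicks-2020"))
    stop("unknown voriconazole dose model \"", model, "\"; available: ",
         paste(setdiff(names(kb), "hicks-2020"), collapse = ", "), call. = FALSE)
  rec <- kb[[model]]
  if (phenotype == "indeterminate" && model != "package-insert")
    stop("no dose recommendation encoded for indeterminate metabolizers",
         call. = FALSE)
  switch(model,
    "takahashi-2021" = {
      if (is.null(weight_kg))
        stop("the takahashi-2021 model requires weight_kg", call. = FALSE)
      band <- Find(function(b)
        (is.null(b$lower_kg) || weight_kg >= b$lower_kg) &&
        (is.null(b$upper_kg) || weight_kg < b$upper_kg), rec$nm_weight_bands)
      base <- band$dose
      if (phenotype == "normal")
        dose_recommendation("voriconazole", model, base, rec$units,
                            qualifiers = "normal metabolizer, weight-banded base dose",
                            citation = rec$citation)
      else if (phenotype %in% .PM_IM)
        dose_recommendation("voriconazole", model,
                            base * unlist(rec$pm_im_multiplier), rec$units,
                            qualifiers = "33-50% below the normal-metabolizer base dose",
                            citation = rec$citation)
      else
        dose_recommendation("voriconazole", model,
                            base * unlist(rec$rm_um_multiplier), rec$units,
                            qualifiers = "25-50% above the normal-metabolizer base dose",
                            citation = rec$citation)
    },
    "tian-2021" = {
      if (is.null(age_years))
        stop("the tian-2021 model requires age_years", call. = FALSE)
      grp <- if (phenotype %in% .PM_IM) "pm_im" else "um_em"
      dose <- if (age_years < 12) rec[[grp]]$under_12y else rec[[grp]]$over_12y
      quals <- c(paste0("phenotype group ",
                        if (grp == "pm_im") "PM/IM" else "UM/EM",
                        ", age ", if (age_years < 12) "under" else "12 or over",
                        " 12 years"),
                 if (phenotype == "rapid")
                   "rapid metabolizers mapped to the UM/EM group (assignment not stated by the source)")
      dose_recommendation("voriconazole", model, dose, rec$units,
                          qualifiers = quals, citation = rec$citation)
    },
    "chen-2022" = {
      grp <- if (phenotype %in% c("poor", "likely-poor")) "pm"
             else if (phenotype %in% c("intermediate", "likely-intermediate")) "im"
             else if (phenotype == "normal") "nm"
             else stop("chen-2022 publishes doses for NM/IM/PM groups only",
                       call. = FALSE)
      dose_recommendation("voriconazole", model, rec[[grp]]$median, rec$units,
                          qualifiers = paste0("median dose to reach the therapeutic range, ",
                                              toupper(grp), " group"),
                          citation = rec$citation, range = unlist(rec[[grp]]$range))
    },
    "package-insert" = {
      if (is.null(age_years))
        stop("the package-insert rule requires age_years", call. = FALSE)
      band <- if (age_years < 2) rec$under_2y
              else if (age_years <= 12) rec$age_2_to_12y
              else rec$over_12y
      dose_recommendation("voriconazole", model, unlist(band$dose), rec$units,
                          qualifiers = band$qualifier, citation = rec$citation)
    })
}

#' Named trough-concentration window
#'
#' @param name `"default"` (1.5-5.0 mg/L) or `"garcia-garcia"`
#'   (1.0-5.5 mg/L).
#' @return numeric `c(lower, upper)` in mg/L with a `citation` attribute.
#' @export
trough_window <- function(name = c("default", "garcia-garcia")) {
  name <- match.arg(name)
  w <- guidance_kb()$trough_windows[[name]]
  structure(c(w$lower, w$upper), citation = w$citation)
}

#' Classify a voriconazole trough concentration
#'
#' Strict comparison against a therapeutic window: below the lower bound is
#' subtherapeutic (treatment-failure risk), above the upper bound is
#' supratherapeutic (adverse-effect risk), otherwise therapeutic.
#'
#' @param concentration_mg_per_L measured trough in mg/L, non-negative.
#' @param window numeric `c(lower, upper)` in mg/L; defaults to the 1.5-5.0
#'   window, with the Garcia-Garcia 1.0-5.5 window selectable via
#'   [trough_window()].
#' @return list with `concentration_mg_per_L`, `window` and `class` (ordered
#'   factor subtherapeutic < therapeutic < supratherapeutic).
#' @export
classify_trough <- function(concentration_mg_per_L, window = trough_window()) {
  if (!is.numeric(concentration_mg_per_L) || length(concentration_mg_per_L) != 1L ||
      is.na(concentration_mg_per_L) || concentration_mg_per_L < 0)
    stop("concentration must be a single non-negative number (mg/L)",
         call. = FALSE)
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be c(lower, upper) with lower < upper", call. = FALSE)
  cls <- if (concentration_mg_per_L < window[1L]) "subtherapeutic"
         else if (concentration_mg_per_L > window[2L]) "supratherapeutic"
         else "therapeutic"
  list(concentration_mg_per_L = concentration_mg_per_L,
       window = as.numeric(window),
       class = factor(cls, levels = c("subtherapeutic", "therapeutic",
                                      "supratherapeutic"), ordered = TRUE))
}

#' Genotype-guided voriconazole prophylaxis policy
#'
#' Encodes the prophylaxis policy of Hicks et al. 2020: rapid metabolizers
#' receive 300 mg twice daily, ultra-rapid metabolizers avoid voriconazole
#' (alternative agent), everyone else receives the standard 200 mg twice
#' daily.
#'
#' @param phenotype a phenotype call or string.
#' @return a `dose_recommendation`; for ultra-rapid metabolizers
#'   `dose_value` is `"avoid"` and a qualifier recommends an alternative
#'   agent.
#' @export
vcz_prophylaxis_policy <- function(phenotype) {
  phenotype <- .phenotype_name(phenotype)
  rec <- guidance_kb()$voriconazole[["hicks-2020"]]
  if (phenotype == "rapid")
    dose_recommendation("voriconazole", "hicks-2020", rec$rapid, rec$units,
                        qualifiers = "interventional prophylactic dose for rapid metabolizers",
                        citation = rec$citation)
  else if (phenotype == "ultra-rapid")
    dose_recommendation("voriconazole", "hicks-2020", "avoid", rec$units,
                        qualifiers = "use an alternative antifungal agent",
                        citation = rec$citation)
  else
    dose_recommendation("voriconazole", "hicks-2020", rec$standard, rec$units,
                        qualifiers = "standard prophylactic dose",
                        citation = rec$citation)
}

#' Exposure-equivalent SSRI dose by CYP2C19 phenotype
#'
#' Published doses producing exposure equivalent to the standard
#' normal-metabolizer dose (Strawn et al. 2019 pharmacokinetic modeling):
#' escitalopram 10/20/30 mg/day for poor/normal/ultra-rapid metabolizers
#' (ultra-rapid flagged for a twice-daily split), sertraline 100/150/200
#' mg/day for poor/normal/rapid-or-ultra-rapid. Phenotypes without a
#' published equivalent raise an error rather than interpolating.
#'
#' @param drug `"escitalopram"` or `"sertraline"`.
#' @param phenotype a phenotype call or string.
#' @return a `dose_recommendation`.
#' @export
ssri_equivalent_dose <- function(drug = c("escitalopram", "sertraline"),
                                 phenotype) {
  drug <- match.arg(drug)
  phenotype <- .phenotype_name(phenotype)
  rec <- guidance_kb()$ssri[["strawn-2019"]]
  doses <- rec[[drug]]
  if (!phenotype %in% names(doses))
    stop("no published ", drug, " exposure-equivalent dose for ", phenotype,
         " metabolizers (encoded: ", paste(names(doses), collapse = ", "), ")",
         call. = FALSE)
  quals <- if (drug == "escitalopram" && phenotype == "ultra-rapid")
    rec$escitalopram_um_note else character()
  dose_recommendation(drug, "strawn-2019", doses[[phenotype]], rec$units,
                      qualifiers = quals, citation = rec$citation)
}

#' Qualitative phenotype-conditioned risk flags
#'
#' Emits the qualitative risk statements encoded in the knowledge base when
#' their condition holds: CYP2C19*17 carriers on PPIs (reduced exposure,
#' therapy-failure risk), poor/intermediate metabolizers on clopidogrel
#' (reduced active-metabolite formation, extrapolated from adult data) and
#' poor metabolizers on SSRIs (elevated adverse-effect risk). Returns an
#' empty list when no condition is met.
#'
#' @param drug_class `"PPI"`, `"clopidogrel"` or `"SSRI"`.
#' @param diplotype a [diplotype()] or diplotype string (used for the *17
#'   carrier condition); optional for the other classes.
#' @param phenotype a phenotype call or string; derived from `diplotype`
#'   when omitted.
#' @return list of risk-flag records (`drug_class`, `condition`, `flag`,
#'   `citation`).
#' @export
risk_flags <- function(drug_class = c("PPI", "clopidogrel", "SSRI"),
                       diplotype = NULL, phenotype = NULL) {
  drug_class <- match.arg(drug_class)
  kb <- guidance_kb()$risk_flags
  if (is.character(diplotype)) diplotype <- parse_diplotype(diplotype)
  if (is.null(phenotype) && !is.null(diplotype))
    phenotype <- diplotype_to_phenotype(diplotype)
  phenotype <- if (is.null(phenotype)) NA_character_ else .phenotype_name(phenotype)
  flags <- list()
  emit <- function(id, condition) {
    rec <- kb[[id]]
    c(flags, list(list(drug_class = drug_class, condition = condition,
                       flag = rec$flag, citation = rec$citation)))
  }
  if (drug_class == "PPI" && !is.null(diplotype) &&
      "*17" %in% diplotype$alleles)
    flags <- emit("ppi-star17-carrier", "CYP2C19*17 carrier")
  if (drug_class == "clopidogrel" && !is.na(phenotype) &&
      phenotype %in% .PM_IM)
    flags <- emit("clopidogrel-reduced-activation",
                  "poor or intermediate metabolizer")
  if (drug_class == "SSRI" && !is.na(phenotype) &&
      phenotype %in% c("poor", "likely-poor"))
    flags <- emit("ssri-poor-metabolizer", "poor metabolizer")
  flags
}

#' Voriconazole co-medication flags
#'
#' Qualitative drug-drug interaction flags for co-medications with a
#' published directional effect on voriconazole trough concentration
#' (omeprazole raises it by competitive CYP2C19 inhibition; rifampicin
#' lowers it by enzyme induction). No quantitative effect sizes are encoded.
#'
#' @param comedications character vector of co-medication names.
#' @return list of flag records for recognized co-medications.
#' @export
vcz_comedication_flags <- function(comedications) {
  kb <- guidance_kb()$comedication
  hits <- intersect(tolower(comedications), names(kb))
  lapply(hits, function(m)
    list(comedication = m, effect = kb[[m]]$effect, flag = kb[[m]]$flag,
         citation = kb[[m]]$citation))
}
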