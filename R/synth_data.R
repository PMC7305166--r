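#' Specify a synthetic OAI-like cohort
#'
#' Builds the parameter object for [generate_cohort()]. Defaults emulate the
#' structure of the OAI progression subcohort the pipeline targets: n = 678
#' subjects with 290 female / 388 male, age uniform on 45--79 years, BMI drawn
#' from a two-component mixture straddling the 30 kg/m2 obesity cut (so the
#' obese / non-obese strata land near 341 / 337), nine strictly positive
#' serum biomarkers drawn log-normally with coefficient of variation about
#' 0.5, a planted correlation of 0.58 between log HMW and log LMW adiponectin
#' (both forms of the same molecule), and an IPFP volume generated as a linear
#' function of gender, BMI, age and the adipsin/CRP ratio plus Gaussian noise,
#' with a positive male offset.
#'
#' Per-biomarker location parameters are placeholders at plausible serum
#' magnitudes (the source distributions are not published); only their
#' qualitative structure (positivity, right skew, the HMW--LMW correlation)
#' matters downstream.
#'
#' @param n_subjects number of subjects.
#' @param female_fraction expected fraction of females in (0, 1).
#' @param age_range two-element numeric, years.
#' @param bmi_params list with `means`, `sds` (two-component normal mixture,
#'   kg/m2) and `weight` of the first (non-obese) component.
#' @param biomarker_params named list (one entry per biomarker in canonical
#'   order) of lists with `meanlog` and `sdlog` on the log-concentration scale.
#' @param adiponectin_hmw_lmw_corr planted correlation between log adiponectin
#'   HMW and log adiponectin LMW, in [-1, 1].
#' @param effect_coefs named numeric: `intercept` (mm3), `gender` (mm3 added
#'   for males), `bmi` (mm3 per kg/m2), `age` (mm3 per year), `ratio` (mm3 per
#'   unit of the generating ratio).
#' @param ratio_feature name of the generating ratio, `"num/den"` over
#'   biomarker names; default `"adipsin/CRP"`.
#' @param noise_sd Gaussian noise standard deviation, mm3.
#' @param seed integer seed; fixes the cohort bit-for-bit.
#' @param id_prefix prefix for subject identifiers.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 100, seed = 1)
#' cohort <- generate_cohort(spec)
#' nrow(cohort)
cohort_spec <- function(n_subjects = 678L,
                        female_fraction = 290 / 678,
                        age_range = c(45, 79),
                        bmi_params = list(means = c(26, 34), sds = c(2.5, 3),
                                          weight = 0.5),
                        biomarker_params = default_biomarker_params(),
                        adiponectin_hmw_lmw_corr = 0.58,
                        effect_coefs = c(intercept = 20000, gender = 9000,
                                         bmi = 450, age = -150, ratio = 1500),
                        ratio_feature = "adipsin/CRP",
                        noise_sd = 2500,
                        seed = 1L,
                        id_prefix = "OAI-S") {
  if (length(n_subjects) != 1L || !is.finite(n_subjects) || n_subjects < 1)
    stopf("n_subjects must be a positive integer")
  if (female_fraction < 0 || female_fraction > 1)
    stopf("female_fraction must lie in [0, 1]")
  if (abs(adiponectin_hmw_lmw_corr) > 1)
    stopf("adiponectin_hmw_lmw_corr must lie in [-1, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(age_range) != 2L || diff(age_range) < 0)
    stopf("age_range must be an increasing pair of years")
  stopifnot(setequal(names(biomarker_params), BIOMARKERS))
  needed <- c("intercept", "gender", "bmi", "age", "ratio")
  if (!all(needed %in% names(effect_coefs)))
    stopf("effect_coefs must name %s", paste(needed, collapse = ", "))
  parts <- strsplit(ratio_feature, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(parts %in% BIOMARKERS))
    stopf("ratio_feature must be 'num/den' over biomarker names")

  structure(
    list(n_subjects = as.integer(n_subjects),
         female_fraction = female_fraction,
         age_range = as.numeric(age_range),
         bmi_params = bmi_params,
         biomarker_params = biomarker_params,
         adiponectin_hmw_lmw_corr = adiponectin_hmw_lmw_corr,
         effect_coefs = effect_coefs[needed],
         ratio_feature = ratio_feature,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         id_prefix = id_prefix),
    class = "cohort_spec")
}

#' Default log-normal biomarker parameters
#'
#' Placeholder locations at plausible serum magnitudes; `sdlog` = 0.472 gives
#' a coefficient of variation of about 0.5 for every marker.
#'
#' @return Named list of `meanlog` / `sdlog` pairs in canonical order.
#' @export
default_biomarker_params <- function() {
  medians <- c(adiponectin_HMW = 4, adiponectin_LMW = 3, adipsin = 2,
               chemerin = 150, leptin = 15, visfatin = 3, CRP = 2,
               IL8 = 8, MCP1 = 250)
  sdlog <- sqrt(log(1 + 0.5^2))  # CV = 0.5
  lapply(medians, function(m) list(meanlog = log(m), sdlog = sdlog))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: n = %d, female fraction = %.3f, seed = %d\n",
              x$n_subjects, x$female_fraction, x$seed))
  cat(sprintf("  planted model: ipfp ~ gender + bmi + age + %s, noise sd %.0f mm3\n",
              x$ratio_feature, x$noise_sd))
  invisible(x)
}

#' Generate a synthetic cohort table
#'
#' Draws a per-subject table with the statistical structure the downstream
#' analysis assumes: demographics, nine positive serum biomarkers, and an IPFP
#' volume equal to the planted linear model in gender, BMI, age and one
#' biomarker ratio plus Gaussian noise. Deterministic for a fixed seed.
#'
#' Gender is coded 0 = female, 1 = male; males receive the (positive, by
#' default) `gender` effect so male IPFP volumes exceed female ones, matching
#' the anatomy the model targets. The HMW--LMW adiponectin correlation is
#' induced through a shared latent Gaussian factor on the log scale; all other
#' biomarkers are independent.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` of class `cohort_table` with columns `subject_id`,
#'   `age`, `gender`, `bmi`, the nine biomarkers, and `ipfp_volume` (mm3).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    gender <- stats::rbinom(n, 1L, 1 - spec$female_fraction)  # 1 = male
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])

    bp <- spec$bmi_params
    comp <- stats::rbinom(n, 1L, 1 - bp$weight) + 1L  # 1 = lean, 2 = obese
    bmi <- stats::rnorm(n, bp$means[comp], bp$sds[comp])
    bmi <- pmin(pmax(bmi, 16), 60)

    rho <- spec$adiponectin_hmw_lmw_corr
    z_shared <- stats::rnorm(n)
    biom <- matrix(NA_real_, n, length(BIOMARKERS),
                   dimnames = list(NULL, BIOMARKERS))
    for (b in BIOMARKERS) {
      p <- spec$biomarker_params[[b]]
      z <- if (b %in% c("adiponectin_HMW", "adiponectin_LMW")) {
        sign(rho) * sqrt(abs(rho)) * z_shared +
          sqrt(1 - abs(rho)) * stats::rnorm(n)
      } else stats::rnorm(n)
      biom[, b] <- exp(p$meanlog + p$sdlog * z)
    }

    parts <- strsplit(spec$ratio_feature, "/", fixed = TRUE)[[1]]
    ratio <- biom[, parts[1]] / biom[, parts[2]]
    ec <- spec$effect_coefs
    vol <- ec[["intercept"]] + ec[["gender"]] * gender + ec[["bmi"]] * bmi +
      ec[["age"]] * age + ec[["ratio"]] * ratio +
      stats::rnorm(n, 0, spec$noise_sd)
    if (any(vol <= 0)) {
      warning("clamping ", sum(vol <= 0), " non-positive IPFP volumes to 1 mm3")
      vol <- pmax(vol, 1)
    }

    out <- data.frame(subject_id = sprintf("%s%05d", spec$id_prefix, seq_len(n)),
                      age = age, gender = gender, bmi = bmi,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(biom))
    out$ipfp_volume <- vol
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}

#' Generate a held-out validation cohort
#'
#' Same generator as [generate_cohort()] but with clinical-trial-like defaults:
#' 80 subjects, 57 female / 23 male, and a BMI profile shifted upwards to mimic
#' a higher-severity symptomatic population. Intended strictly for external
#' validation; [validate_external()] refuses cohorts whose subjects overlap the
#' training table.
#'
#' @param spec a [cohort_spec()]; defaults via `...` overrides of
#'   [validation_cohort_spec()].
#' @return A `cohort_table`, as [generate_cohort()].
#' @export
generate_validation_cohort <- function(spec = validation_cohort_spec()) {
  generate_cohort(spec)
}

#' Default spec for the external validation cohort
#'
#' @param ... overrides passed to [cohort_spec()].
#' @param bmi_shift kg/m2 added to both BMI mixture components (severity shift).
#' @return A `cohort_spec`.
#' @export
validation_cohort_spec <- function(..., bmi_shift = 2) {
  args <- list(...)
  defaults <- list(n_subjects = 80L, female_fraction = 57 / 80, seed = 2L,
                   id_prefix = "TRIAL-S")
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  sp <- do.call(cohort_spec, args)
  sp$bmi_params$means <- sp$bmi_params$means + bmi_shift
  sp
}

#' Read / write a cohort table as CSV
#'
#' The CSV header is the documented column order: `subject_id`, `age`,
#' `gender` (0 = female, 1 = male), `bmi`, the nine biomarkers in canonical
#' order, `ipfp_volume`.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `read_cohort()` returns a `cohort_table`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Validate a raw data frame as a cohort table
#'
#' Checks column presence, missingness, gender coding, biomarker positivity and
#' positive IPFP volume, then stamps the `cohort_table` class.
#'
#' @param df a data frame.
#' @return A `cohort_table`.
#' @export
validate_cohort <- function(df) {
  need <- c("subject_id", RISK_FACTORS, BIOMARKERS, "ipfp_volume")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("cohort is missing columns: %s",
                             paste(missing, collapse = ", "))
  if (anyNA(df[need])) stopf("cohort contains missing values")
  if (!all(df$gender %in% c(0, 1))) stopf("gender must be coded 0/1")
  if (any(as.matrix(df[BIOMARKERS]) <= 0))
    stopf("all biomarker concentrations must be strictly positive")
  if (any(df$ipfp_volume <= 0)) stopf("ipfp_volume must be positive")
  class(df) <- c("cohort_table", "data.frame")
  df
}
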