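#' @name pipeline
#' @title End-to-end IPFP-volume study orchestration
#' @description
#' Stratification of the cohort by BMI and gender, per-group variable
#' selection, the five-variable "model #5" fits, the ablation grid, the
#' gender-separation and inverse-ratio studies, external validation on a
#' held-out cohort, and export of the trained rule base as a portable
#' "pseudocode" artifact. One master seed fixes every random choice.
NULL

#' Stratify a cohort by BMI and (optionally) gender
#'
#' `Total` is the whole cohort; `HighBMI` is BMI at or above the cut
#' (inclusive: a subject exactly at 30 kg/m2 is obese), `LowBMI` below it.
#' With `by_gender = TRUE` each group is further split into `_female` (code 0)
#' and `_male` (code 1) strata.
#'
#' @param cohort a `cohort_table`.
#' @param bmi_cut kg/m2, default 30.
#' @param by_gender also emit per-gender strata.
#' @return Named list of `cohort_table`s. Empty strata are dropped with a
#'   warning.
#' @export
stratify <- function(cohort, bmi_cut = 30, by_gender = FALSE) {
  cohort <- validate_cohort(as.data.frame(cohort))
  if (bmi_cut <= 0) stopf("bmi_cut must be positive")
  keep_class <- function(df) { class(df) <- c("cohort_table", "data.frame"); df }
  out <- list(Total = cohort,
              HighBMI = keep_class(cohort[cohort$bmi >= bmi_cut, ]),
              LowBMI = keep_class(cohort[cohort$bmi < bmi_cut, ]))
  if (by_gender) {
    for (g in names(out)) {
      out[[paste0(g, "_female")]] <- keep_class(out[[g]][out[[g]]$gender == 0, ])
      out[[paste0(g, "_male")]] <- keep_class(out[[g]][out[[g]]$gender == 1, ])
    }
  }
  empty <- vapply(out, nrow, integer(1)) == 0L
  if (any(empty)) {
    warning("dropping empty strata: ", paste(names(out)[empty], collapse = ", "))
    out <- out[!empty]
  }
  out
}

#' The published five-variable model compositions
#'
#' Each group's selected "model #5": age, gender, BMI and adipsin/CRP, plus
#' one group-specific fifth variable (Total: adipsin/chemerin; HighBMI:
#' chemerin/adiponectin HMW; LowBMI: IL-8). These defaults let the ablation
#' and gender studies run without a prior selection pass; pass a fresh
#' [select_subsets()] winner to override.
#'
#' @param group one of `"Total"`, `"HighBMI"`, `"LowBMI"`.
#' @return Character vector of five feature names.
#' @export
model5_features <- function(group = c("Total", "HighBMI", "LowBMI")) {
  group <- match.arg(group)
  fifth <- switch(group,
                  Total = "adipsin/chemerin",
                  HighBMI = "chemerin/adiponectin_HMW",
                  LowBMI = "IL8")
  c("age", "gender", "bmi", "adipsin/CRP", fifth)
}

#' Run PSOBVS selection on one subcohort
#'
#' Builds the 48-column design, runs Monte-Carlo PSO selection at each
#' requested size, and picks the AIC winner. Deterministic under `cfg$seed`.
#'
#' @param subcohort a `cohort_table`.
#' @param sizes subset sizes to search.
#' @param cfg a [swarm_config()].
#' @return A `selection_result` (see [select_subsets()]), with the feature
#'   matrix attached as attribute `"features"`.
#' @export
run_selection <- function(subcohort, sizes = 1:8, cfg = swarm_config()) {
  fm <- build_features(subcohort)
  res <- select_subsets(fm, sizes, cfg)
  attr(res, "features") <- fm
  res
}

## Seeded 70/30 train/test split on a feature matrix
split_70_30 <- function(n, seed) {
  tr <- with_seed(seed, sample.int(n, size = floor(0.7 * n)))
  list(train = sort(tr), test = sort(setdiff(seq_len(n), tr)))
}

## Fit an ANFIS-FCM on the training rows of `fm` restricted to `features`,
## evaluate on the test rows; the single-model workhorse for the studies.
fit_and_eval <- function(fm, features, split, n_rules = 2L,
                         cfg = train_config(), with_uncertainty = FALSE) {
  features <- canonical_features(fm, features)
  X <- fm$X[, features, drop = FALSE]
  y <- fm$target
  model <- anfis_fcm(X[split$train, , drop = FALSE], y[split$train],
                     n_rules = n_rules, cfg = cfg)
  model$training_ids <- fm$subject_id[split$train]
  pred_te <- evaluate_fis(model, X[split$test, , drop = FALSE])
  pred_tr <- evaluate_fis(model, X[split$train, , drop = FALSE])
  out <- list(model = model, features = features,
              train = compute_metrics(y[split$train], pred_tr),
              test = compute_metrics(y[split$test], pred_te),
              taylor = taylor_stats(y[split$test], pred_te))
  if (with_uncertainty)
    out$uncertainty <- uncertainty_band(y[split$test], pred_te)
  out
}

#' Ablation grid over sub-models of a five-variable model
#'
#' Enumerates every subset of sizes 2 to 5 of the base model (1 + 5 + 10 + 10
#' = 26 models), trains an ANFIS-FCM per subset on a common 70/30 split, and
#' reports test metrics and Taylor coordinates per model. `M1` is the full
#' five-variable model. The conventional 25-model labelling of this grid keeps
#' only 9 of the 10 three-variable models; `compat_view = TRUE` relabels
#' accordingly and flags which subset the 25-model table cannot accommodate.
#'
#' @param subcohort a `cohort_table`.
#' @param base_subset character vector of exactly 5 feature names.
#' @param n_rules rules per ANFIS fit.
#' @param cfg a [train_config()].
#' @param seed split seed.
#' @param compat_view drop the last three-variable model to mimic the 25-row
#'   labelling (flagged in the result).
#' @return A list of class `ablation_grid`: `table` (one row per model:
#'   label, size, features, metrics), `models` (fitted objects), `split`,
#'   `omitted` (the subset a 25-model labelling omits, if `compat_view`).
#' @export
run_ablation <- function(subcohort, base_subset = model5_features("Total"),
                         n_rules = 2L, cfg = train_config(), seed = 1L,
                         compat_view = FALSE) {
  if (length(base_subset) != 5L) stopf("base_subset must have 5 features")
  fm <- build_features(subcohort)
  base <- canonical_features(fm, base_subset)
  subsets <- list(base)
  for (sz in 4:2) subsets <- c(subsets, enumerate_subsets(base, sz))
  omitted <- NULL
  if (compat_view) {
    ## a 25-row table holds only 9 of the C(5,3)=10 three-variable models;
    ## drop the last in enumeration order and record it
    idx3 <- which(vapply(subsets, length, integer(1)) == 3L)
    omitted <- subsets[[idx3[length(idx3)]]]
    subsets <- subsets[-idx3[length(idx3)]]
  }
  split <- split_70_30(nrow(fm$X), derive_seed(seed, 31L))
  fits <- lapply(subsets, function(s)
    fit_and_eval(fm, s, split, n_rules = n_rules, cfg = cfg))
  rows <- lapply(seq_along(fits), function(i)
    metrics_row(fits[[i]]$test, taylor = fits[[i]]$taylor,
                model = paste0("M", i),
                size = length(subsets[[i]]),
                features = paste(subsets[[i]], collapse = "+")))
  structure(list(table = do.call(rbind, rows), models = fits,
                 subsets = subsets, split = split, omitted = omitted),
            class = "ablation_grid")
}

#' Gender-separation study
#'
#' Fits one pooled model and two gender-specific models on identical row-level
#' splits of the subcohort and reports, per gender, the pooled and separated
#' test MAPE together with the relative improvement
#' `100 * (MAPE_pooled - MAPE_separate) / MAPE_pooled`.
#'
#' @param subcohort a `cohort_table` containing both genders.
#' @param subset feature names for the model.
#' @param n_rules rules per fit.
#' @param cfg a [train_config()].
#' @param seed split seed.
#' @param min_stratum minimum per-gender training rows.
#' @return A list of class `gender_comparison`: per gender the pooled and
#'   separated `metric_set`s and `mape_improvement_pct`; plus the shared
#'   `split` (the leakage audit trail).
#' @export
run_gender_comparison <- function(subcohort, subset = model5_features("Total"),
                                  n_rules = 2L, cfg = train_config(),
                                  seed = 1L, min_stratum = 20L) {
  fm <- build_features(subcohort)
  gender <- fm$X[, "gender"]
  if (length(unique(gender)) < 2L) stopf("both genders must be present")
  split <- split_70_30(nrow(fm$X), derive_seed(seed, 37L))
  for (g in 0:1)
    if (sum(gender[split$train] == g) < min_stratum)
      stopf("gender stratum %d has fewer than %d training rows", g, min_stratum)

  features <- canonical_features(fm, subset)
  X <- fm$X[, features, drop = FALSE]
  y <- fm$target
  pooled <- anfis_fcm(X[split$train, , drop = FALSE], y[split$train],
                      n_rules = n_rules, cfg = cfg)

  out <- list(split = split, features = features)
  for (g in 0:1) {
    gname <- if (g == 0) "female" else "male"
    tr_g <- split$train[gender[split$train] == g]
    te_g <- split$test[gender[split$test] == g]
    sep_feats <- setdiff(features, "gender")  # constant within a stratum
    mod_g <- anfis_fcm(X[tr_g, sep_feats, drop = FALSE], y[tr_g],
                       n_rules = n_rules, cfg = cfg)
    m_pooled <- compute_metrics(y[te_g],
                                evaluate_fis(pooled, X[te_g, , drop = FALSE]))
    m_sep <- compute_metrics(y[te_g],
                             evaluate_fis(mod_g, X[te_g, sep_feats, drop = FALSE]))
    out[[gname]] <- list(
      pooled = m_pooled, separated = m_sep,
      mape_improvement_pct = 100 * (m_pooled$MAPE - m_sep$MAPE) / m_pooled$MAPE)
  }
  class(out) <- "gender_comparison"
  out
}

#' @export
print.gender_comparison <- function(x, ...) {
  for (g in c("female", "male"))
    cat(sprintf("%s: pooled MAPE %.2f%%, separated %.2f%%, improvement %.1f%%\n",
                g, x[[g]]$pooled$MAPE, x[[g]]$separated$MAPE,
                x[[g]]$mape_improvement_pct))
  invisible(x)
}

#' Main-form vs inverse-form ratio study
#'
#' Trains twin models on the main-form and inverted-form designs with
#' identical seeds and row-level splits and reports side-by-side test metrics.
#' A subset with no ratio features yields two identical runs.
#'
#' @param subcohort a `cohort_table`.
#' @param subset feature names (main-form orientation).
#' @param n_rules rules per fit.
#' @param cfg a [train_config()].
#' @param seed split seed.
#' @return A list of class `inverse_ratio_study`: `main` and `inverse`
#'   fit-and-eval results on the same test indices, and `split`.
#' @export
run_inverse_ratio_study <- function(subcohort,
                                    subset = model5_features("Total"),
                                    n_rules = 2L, cfg = train_config(),
                                    seed = 1L) {
  fm <- build_features(subcohort)
  fm_inv <- invert_ratios(fm)
  split <- split_70_30(nrow(fm$X), derive_seed(seed, 41L))
  main_feats <- canonical_features(fm, subset)
  inv_feats <- vapply(main_feats, function(f) {
    i <- match(f, fm$ratios$name)
    if (is.na(i)) f else fm_inv$ratios$name[i]
  }, character(1), USE.NAMES = FALSE)
  structure(list(
    main = fit_and_eval(fm, main_feats, split, n_rules = n_rules, cfg = cfg),
    inverse = fit_and_eval(fm_inv, inv_feats, split, n_rules = n_rules,
                           cfg = cfg),
    split = split),
    class = "inverse_ratio_study")
}

#' Validate a trained model on an external cohort
#'
#' Pure evaluation, no refitting. Leakage is guarded at run time: any overlap
#' between the external cohort's subject identifiers and those the model was
#' trained on is a hard error (pass the training identifiers via
#' `training_ids` or rely on the ids recorded on the model).
#'
#' @param model a trained `fis_model`.
#' @param cohort the external `cohort_table`.
#' @param training_ids subject ids used in training (for the disjointness
#'   assertion); defaults to the model's `training_ids` field if present.
#' @return A list of class `external_validation`: `metrics` (a `metric_set`),
#'   `uncertainty` (an `uncertainty_report`), and `scatter` (observed /
#'   predicted pairs for scatter plots).
#' @export
validate_external <- function(model, cohort, training_ids = model$training_ids) {
  stopifnot(inherits(model, "fis_model"))
  cohort <- validate_cohort(as.data.frame(cohort))
  if (!is.null(training_ids) && any(cohort$subject_id %in% training_ids))
    stopf("external cohort shares %d subject(s) with the training data",
          sum(cohort$subject_id %in% training_ids))
  fm <- build_features(cohort)
  pred <- predict(model, fm)
  structure(list(metrics = compute_metrics(fm$target, pred),
                 uncertainty = uncertainty_band(fm$target, pred),
                 scatter = data.frame(subject_id = cohort$subject_id,
                                      observed = fm$target, predicted = pred)),
            class = "external_validation")
}

#' Export a trained model as a pseudocode artifact
#'
#' Writes (a) the JSON rule base (see [write_fis()]) and (b) a human-readable
#' algorithm listing, one block per rule: IF each input is near its Gaussian
#' center (with width) THEN the rule's linear volume formula; plus the firing
#' and averaging steps. The pair is sufficient for independent re-evaluation;
#' reloading the JSON reproduces predictions bit-for-bit.
#'
#' @param model a trained `fis_model`.
#' @param path output path stem; `<path>.json` and `<path>.txt` are written.
#' @return Invisibly, the two file paths.
#' @export
export_pseudocode <- function(model, path) {
  stopifnot(inherits(model, "fis_model"))
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  write_fis(model, json_path)

  nm <- model$input_names
  lines <- c("ALGORITHM: IPFP volume prediction (first-order Takagi-Sugeno)",
             sprintf("INPUTS: %s", paste(nm, collapse = ", ")))
  if (!is.null(model$scaler))
    lines <- c(lines, "STEP 0: z-score each input:",
               sprintf("  z_%s = (%s - %.10g) / %.10g", nm, nm,
                       model$scaler$center, model$scaler$scale))
  for (k in seq_along(model$rules)) {
    r <- model$rules[[k]]
    cond <- paste(sprintf("z_%s IS gaussian(center=%.10g, width=%.10g)",
                          nm, r$center, r$sigma), collapse = " AND ")
    consequent <- paste0(sprintf("%.10g", r$coef[1]),
                         paste(sprintf(" + %.10g * z_%s", r$coef[-1], nm),
                               collapse = ""))
    lines <- c(lines, sprintf("RULE %d:", k),
               sprintf("  IF %s", cond),
               sprintf("  THEN volume_%d = %s", k, consequent))
  }
  lines <- c(lines,
             "FIRING: w_k = product over inputs of exp(-0.5 * ((z - center)/width)^2)",
             "OUTPUT: volume = sum_k w_k * volume_k / sum_k w_k   [mm3]")
  writeLines(lines, txt_path)
  invisible(c(json = json_path, text = txt_path))
}
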