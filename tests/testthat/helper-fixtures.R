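## Small cohorts and hand-built models shared across test files.

small_cohort <- function(n = 120, seed = 1, ...) {
  generate_cohort(cohort_spec(n_subjects = n, seed = seed, ...))
}

## Noiseless cohort: IPFP volume is exactly linear in the planted variables.
noiseless_cohort <- function(n = 200, seed = 2, ...) {
  generate_cohort(cohort_spec(n_subjects = n, noise_sd = 0, seed = seed, ...))
}

## A one-rule FIS with known premise and consequent, no scaler.
single_rule_fis <- function(center = c(0, 0), sigma = c(1, 1),
                            coef = c(5, 2, -1)) {
  structure(list(rules = list(list(center = center, sigma = sigma,
                                   coef = coef)),
                 input_names = paste0("x", seq_along(center)),
                 scaler = NULL, fuzziness = 2),
            class = "fis_model")
}

## Data from a known 2-rule first-order Takagi-Sugeno system.
ts2_data <- function(n = 1000, noise_sd = 0, seed = 4) {
  truth <- structure(list(
    rules = list(
      list(center = c(-2), sigma = c(1.2), coef = c(1, 3)),
      list(center = c(2), sigma = c(1.2), coef = c(-4, -2))),
    input_names = "x", scaler = NULL, fuzziness = 2),
    class = "fis_model")
  ipfpfis:::with_seed(seed, {
    X <- matrix(runif(n, -4, 4), ncol = 1, dimnames = list(NULL, "x"))
    y <- evaluate_fis(truth, X) + rnorm(n, 0, noise_sd)
    list(X = X, y = y, truth = truth)
  })
}
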