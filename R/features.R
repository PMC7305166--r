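#' Build the 48-variable design space
#'
#' Expands a cohort into the full design the selection stage searches:
#' 12 dimensional variables (age, gender, BMI and the nine serum biomarkers)
#' plus the 36 pairwise biomarker ratios, C(9,2) unordered pairs. Each stored
#' ratio column is oriented earlier/later in the canonical biomarker order;
#' the reverse orientation (e.g. `"chemerin/adiponectin_HMW"`) is addressable
#' through [resolve_feature()], which returns the reciprocal on demand.
#'
#' @param cohort a `cohort_table` (all biomarker values strictly positive).
#' @return An object of class `feature_matrix`: a list with `X` (numeric
#'   matrix, one named column per feature), `target` (IPFP volume, mm3),
#'   `dimensional` (the 12 dimensional names), `ratios` (data frame of
#'   `name`, `numerator`, `denominator`), `subject_id`, and `inverted` flag.
#' @export
#' @examples
#' fm <- build_features(generate_cohort(cohort_spec(n_subjects = 50, seed = 1)))
#' ncol(fm$X)  # 48
build_features <- function(cohort) {
  cohort <- validate_cohort(as.data.frame(cohort))
  B <- as.matrix(cohort[BIOMARKERS])
  if (any(!is.finite(B)) || any(B <= 0))
    stopf("biomarker concentrations must be finite and strictly positive")

  dimensional <- c(RISK_FACTORS, BIOMARKERS)
  pairs <- utils::combn(BIOMARKERS, 2)
  ratio_names <- paste(pairs[1, ], pairs[2, ], sep = "/")
  R <- B[, pairs[1, ], drop = FALSE] / B[, pairs[2, ], drop = FALSE]
  colnames(R) <- ratio_names

  X <- cbind(as.matrix(cohort[dimensional]), R)
  structure(
    list(X = X,
         target = cohort$ipfp_volume,
         dimensional = dimensional,
         ratios = data.frame(name = ratio_names,
                             numerator = pairs[1, ],
                             denominator = pairs[2, ],
                             stringsAsFactors = FALSE),
         subject_id = cohort$subject_id,
         inverted = FALSE),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d subjects x %d features (%d dimensional + %d ratios)%s\n",
              nrow(x$X), ncol(x$X), length(x$dimensional), nrow(x$ratios),
              if (x$inverted) ", inverse-ratio form" else ""))
  invisible(x)
}

#' Invert every ratio column
#'
#' Dimensional columns are untouched; each ratio column is replaced by its
#' reciprocal and the orientation metadata flipped. Applying the operation
#' twice recovers the original matrix up to floating-point round-trip.
#'
#' @param fm a `feature_matrix`.
#' @return A `feature_matrix` in the inverse-ratio form.
#' @export
invert_ratios <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- fm
  rn <- fm$ratios$name
  out$X[, rn] <- 1 / fm$X[, rn]
  out$ratios <- data.frame(name = paste(fm$ratios$denominator,
                                        fm$ratios$numerator, sep = "/"),
                           numerator = fm$ratios$denominator,
                           denominator = fm$ratios$numerator,
                           stringsAsFactors = FALSE)
  colnames(out$X) <- c(fm$dimensional, out$ratios$name)
  out$inverted <- !fm$inverted
  out
}

#' Resolve a feature name to a column
#'
#' Dimensional names resolve directly. Ratio names resolve whichever way they
#' are oriented: `"adipsin/CRP"` and `"CRP/adipsin"` both resolve, the latter
#' to the reciprocal of the stored column. This is the rename map that lets
#' ratios named as in the source literature address the canonical columns.
#'
#' @param fm a `feature_matrix`.
#' @param name feature name.
#' @return A list with `values` (numeric vector), `stored` (the stored column
#'   name) and `inverted` (`TRUE` if the reciprocal was taken).
#' @export
resolve_feature <- function(fm, name) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (name %in% colnames(fm$X))
    return(list(values = fm$X[, name], stored = name, inverted = FALSE))
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    flipped <- paste(parts[2], parts[1], sep = "/")
    if (flipped %in% colnames(fm$X))
      return(list(values = 1 / fm$X[, flipped], stored = flipped,
                  inverted = TRUE))
  }
  stopf("feature '%s' not present in the design (in either orientation)", name)
}

#' Canonicalise a set of feature names
#'
#' Maps each name to the stored column name (flipping ratio orientation where
#' needed) so subsets quoted in either orientation index the same columns.
#'
#' @param fm a `feature_matrix`.
#' @param names character vector of feature names.
#' @return Character vector of stored column names.
#' @export
canonical_features <- function(fm, names) {
  vapply(names, function(nm) resolve_feature(fm, nm)$stored, character(1),
         USE.NAMES = FALSE)
}

#' Exact binomial coefficient
#'
#' Number of size-`M` subsets of `N` items, computed by the multiplicative
#' formula with exact integer intermediates (every value involved stays below
#' 2^53, so doubles carry them exactly; no floating-point factorials).
#'
#' @param N non-negative integer.
#' @param M non-negative integer, `M <= N`.
#' @return The exact count as a double.
#' @export
#' @examples
#' count_combinations(48, 5)      # 1712304
#' sum(sapply(1:48, count_combinations, N = 48))  # 2^48 - 1
count_combinations <- function(N, M) {
  if (length(N) != 1L || length(M) != 1L || N < 0 || M < 0 || M > N ||
      N != floor(N) || M != floor(M))
    stopf("need integers 0 <= M <= N")
  M <- min(M, N - M)
  acc <- 1
  for (i in seq_len(M)) {
    ## exact at every step: acc * (N - M + i) is a multiple of i
    acc <- acc * (N - M + i) / i
    if (acc != round(acc)) stopf("intermediate lost exactness at i = %d", i)
  }
  acc
}

#' Enumerate all size-M feature subsets
#'
#' Exhaustive enumeration in deterministic (lexicographic) order; the oracle
#' against which the swarm search is certified on small design spaces.
#'
#' @param names character vector of candidate feature names.
#' @param M subset size.
#' @param cap refuse enumeration when the count exceeds this.
#' @return A list of character vectors, each a size-`M` subset; length
#'   `count_combinations(length(names), M)`.
#' @export
enumerate_subsets <- function(names, M, cap = 1e6) {
  if (anyDuplicated(names)) stopf("feature names must be unique")
  if (M > length(names)) stopf("M exceeds the number of candidates")
  n_sub <- count_combinations(length(names), M)
  if (n_sub > cap)
    stopf("%.0f subsets exceed the enumeration cap (%g)", n_sub, cap)
  m <- utils::combn(names, M)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}
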