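test_that("the design has 12 dimensional and 36 ratio columns, each pair once", {
  fm <- build_features(small_cohort(n = 40))
  expect_equal(ncol(fm$X), 48)
  expect_length(fm$dimensional, 12)
  expect_equal(nrow(fm$ratios), 36)

  ## brute-force enumeration of unordered biomarker pairs
  pairs <- t(combn(ipfpfis:::BIOMARKERS, 2))
  expect_equal(nrow(pairs), 36)
  got <- fm$ratios[, c("numerator", "denominator")]
  expect_setequal(paste(got$numerator, got$denominator),
                  paste(pairs[, 1], pairs[, 2]))
  ## no self-ratios
  expect_false(any(got$numerator == got$denominator))

  ## every ratio column equals numerator / denominator elementwise
  for (i in seq_len(36))
    expect_equal(fm$X[, fm$ratios$name[i]],
                 fm$X[, fm$ratios$numerator[i]] / fm$X[, fm$ratios$denominator[i]])
})

test_that("a subject with all biomarkers equal to 1 has unit ratios", {
  co <- small_cohort(n = 10)
  co[1, ipfpfis:::BIOMARKERS] <- 1
  fm <- build_features(co)
  expect_equal(unname(fm$X[1, fm$ratios$name]), rep(1, 36))
})

test_that("the selected ratios of the published models are addressable", {
  fm <- build_features(small_cohort(n = 20))
  for (nm in c("adipsin/CRP", "adipsin/chemerin", "chemerin/adiponectin_HMW")) {
    res <- resolve_feature(fm, nm)
    expect_length(res$values, 20)
    parts <- strsplit(nm, "/")[[1]]
    expect_equal(unname(res$values),
                 unname(fm$X[, parts[1]] / fm$X[, parts[2]]))
  }
  expect_error(resolve_feature(fm, "adipsin/unknown"), "not present")
})

test_that("ratio inversion is an involution and multiplies to one", {
  fm <- build_features(small_cohort(n = 25, seed = 3))
  inv <- invert_ratios(fm)
  ## dimensional columns untouched
  expect_identical(inv$X[, fm$dimensional], fm$X[, fm$dimensional])
  ## elementwise product of main and inverse ratio columns is 1
  prod <- fm$X[, fm$ratios$name] * inv$X[, inv$ratios$name]
  expect_equal(unname(prod), matrix(1, nrow(prod), ncol(prod)))
  ## invert twice: round trip
  back <- invert_ratios(inv)
  expect_equal(back$X, fm$X, tolerance = 1e-12)
  expect_identical(back$ratios, fm$ratios)

  ## worked arithmetic: adipsin 2, CRP 4
  co <- small_cohort(n = 5)
  co$adipsin <- 2; co$CRP <- 4
  f2 <- build_features(co)
  expect_equal(unname(f2$X[, "adipsin/CRP"]), rep(0.5, 5))
  expect_equal(unname(invert_ratios(f2)$X[, "CRP/adipsin"]), rep(2, 5))
})

test_that("rescaling one biomarker touches exactly its incident ratios", {
  co <- small_cohort(n = 15, seed = 6)
  fm0 <- build_features(co)
  co$leptin <- co$leptin * 10
  fm1 <- build_features(co)
  changed <- colnames(fm0$X)[vapply(colnames(fm0$X), function(cn)
    !isTRUE(all.equal(fm0$X[, cn], fm1$X[, cn])), logical(1))]
  incident <- c("leptin", fm0$ratios$name[fm0$ratios$numerator == "leptin" |
                                            fm0$ratios$denominator == "leptin"])
  expect_setequal(changed, incident)
  expect_length(setdiff(incident, "leptin"), 8)
})

test_that("binomial coefficients are exact and satisfy Pascal's rule", {
  expect_equal(count_combinations(48, 5), 1712304)
  expect_equal(count_combinations(10, 0), 1)
  expect_equal(count_combinations(10, 10), 1)
  expect_equal(sum(vapply(1:48, function(M) count_combinations(48, M),
                          numeric(1))),
               2^48 - 1)
  for (N in 2:48)
    for (M in seq_len(N - 1))
      expect_identical(count_combinations(N, M),
                       count_combinations(N - 1, M - 1) +
                         count_combinations(N - 1, M))
  expect_error(count_combinations(5, 6))
  expect_error(count_combinations(-1, 0))
})

test_that("subset enumeration is complete, unique and capped", {
  s <- enumerate_subsets(letters[1:12], 3)
  expect_length(s, 220)
  expect_equal(length(unique(vapply(s, paste, "", collapse = ""))), 220)
  expect_length(enumerate_subsets(letters[1:3], 3), 1)
  for (case in list(c(8, 2), c(10, 4), c(6, 5))) {
    nm <- paste0("f", seq_len(case[1]))
    expect_length(enumerate_subsets(nm, case[2]),
                  count_combinations(case[1], case[2]))
  }
  expect_error(enumerate_subsets(paste0("f", 1:40), 15), "cap")
})
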