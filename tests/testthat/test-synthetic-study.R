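test_that("MDL censoring substitutes, flags and passes through correctly", {
  r <- apply_mdl_censoring(c(0.01, 0.05, 1.3), 0.05)
  expect_equal(r$value, c(0.05, 0.05, 1.3))
  expect_equal(r$censored, c(TRUE, FALSE, FALSE))
  expect_error(apply_mdl_censoring(1, -0.05), "positive")
  expect_error(apply_mdl_censoring(1, 0), "positive")
})

test_that("generated dataset has one record per subject x period x analyte", {
  s <- generate_study(study_design(), quiet_params())
  expect_equal(nrow(s), 32 * 4 * 7)
  expect_equal(nrow(unique(s[, c("subject_id", "period", "analyte")])), nrow(s))
  s8 <- generate_study(small_design(), quiet_params())
  expect_equal(nrow(s8), 8 * 4 * 7)
})

test_that("degenerate noise reproduces the configured true means exactly", {
  s <- generate_study(small_design(), quiet_params())
  for (a in c("nicotine", "propylene_glycol", "glycerin")) {
    d <- s[s$analyte == a, ]
    means <- tapply(d$product_value_ug, d$product, unique)
    expect_equal(as.numeric(means[c("A", "B", "C", "D")]),
                 unname(default_true_means()[a, ]))
  }
})

test_that("generation is a deterministic function of the seed", {
  d <- small_design()
  s1 <- generate_study(d, quiet_params(seed = 7, cv_between = 0.5,
                                       cv_within = 0.5))
  s2 <- generate_study(d, quiet_params(seed = 7, cv_between = 0.5,
                                       cv_within = 0.5))
  s3 <- generate_study(d, quiet_params(seed = 8, cv_between = 0.5,
                                       cv_within = 0.5))
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(s1$product_value_ug, s3$product_value_ug)))
})

test_that("generation does not depend on subject ordering in the design", {
  d <- small_design()
  d2 <- d
  d2$subjects <- d2$subjects[rev(seq_len(nrow(d2$subjects))), ]
  p <- quiet_params(seed = 3, cv_between = 0.4, cv_within = 0.4)
  expect_identical(generate_study(d, p), generate_study(d2, p))
})

test_that("session records respect design and censoring invariants", {
  s <- generate_study(study_design(), generation_params(seed = 11))
  expect_true(all(s$product_value_ug >= default_mdl()[s$analyte]))
  expect_true(all(s$sham_value_ug >= default_mdl()[s$analyte]))
  expect_true(all(s$consumed_mg > 0))
  # product must match the subject's sequence at that period
  expect_true(all(substr(s$sequence, s$period, s$period) == s$product))
  # each product exactly once per subject within an analyte
  tab <- table(s$subject_id, s$product, s$analyte)
  expect_true(all(tab == 1))
})

test_that("menthol censoring is higher for non-mentholated products", {
  s <- generate_study(study_design(), generation_params(seed = 5))
  men <- s[s$analyte == "menthol", ]
  menth_prods <- default_products()$product[default_products()$mentholated]
  f_non <- mean(men$censored_product[!men$product %in% menth_prods])
  f_men <- mean(men$censored_product[men$product %in% menth_prods])
  expect_gt(f_non, f_men)
})

test_that("invalid designs and parameters are rejected", {
  expect_error(study_design(n_subjects = 30), "multiple")
  expect_error(study_design(sequences = c("ABCD", "AABC", "CDBA", "DACB")),
               "permutation")
  expect_error(generation_params(cv_between = -1), "nonnegative")
  m <- default_true_means(); m[1, 1] <- -5
  expect_error(generation_params(true_means = m), "nonnegative")
  expect_error(generation_params(mdl = c(nicotine = 0)), "positive")
})

test_that("sessions CSV round-trips through the package readers", {
  s <- generate_study(small_design(), generation_params(seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(s, path)
  s2 <- read_sessions(path)
  expect_equal(as.data.frame(s), as.data.frame(s2), tolerance = 1e-12)
})
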