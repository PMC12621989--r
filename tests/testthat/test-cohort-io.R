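test_that("taxonomy carries exactly the 30 bilateral tracts", {
  tx <- tract_taxonomy()
  expect_equal(nrow(tx), 30)
  expect_equal(anyDuplicated(tx$acronym), 0L)
  expect_equal(sum(tx$pathway == "association"), 10)  # 7 association + 3 limbic
  expect_equal(sum(tx$pathway == "projection"), 20)
  expect_equal(sum(tx$subcategory == "thalamic"), 7)
  expect_equal(sum(tx$subcategory == "striatal"), 7)
  expect_equal(sum(tx$subcategory == "limbic"), 3)
  expect_equal(tx$full_name[tx$acronym == "AF"], "Arcuate Fasciculus")
  expect_equal(tx$pathway[tx$acronym == "AF"], "association")
})

test_that("bilateral tables load from comma and tab dialects", {
  df <- make_bilateral_df()
  for (sep in c(",", "\t")) {
    got <- load_bilateral_table(write_tmp_table(df, sep))
    expect_equal(nrow(got), 8)
    expect_equal(got$value, df$value)
  }
  # 2-row minimal file
  two <- df[1:2, ]
  expect_equal(nrow(load_bilateral_table(write_tmp_table(two))), 2)
})

test_that("strict loading rejects invalid rows; lenient drops and counts", {
  df <- make_bilateral_df()
  df$value[3] <- -1  # negative volume/FA
  path <- write_tmp_table(df)
  expect_error(load_bilateral_table(path, strict = TRUE),
               class = "wmasym_validation_error")
  expect_message(got <- load_bilateral_table(path, strict = FALSE), "dropped 1")
  expect_equal(nrow(got), 7)
  expect_equal(attr(got, "n_dropped"), 1)

  # unknown sex strings are invalid, not coerced
  df2 <- make_bilateral_df(); df2$sex <- "unknown"
  expect_error(load_bilateral_table(write_tmp_table(df2), strict = TRUE),
               class = "wmasym_validation_error")
  # case-insensitive sex is accepted
  df3 <- make_bilateral_df(); df3$sex <- toupper(df3$sex)
  expect_equal(nrow(load_bilateral_table(write_tmp_table(df3))), 8)

  # duplicate key names the offending key
  df4 <- rbind(make_bilateral_df(), make_bilateral_df()[1, ])
  expect_error(load_bilateral_table(write_tmp_table(df4)),
               regexp = "subject=s1", class = "wmasym_validation_error")

  # missing column is a format error
  df5 <- make_bilateral_df(); df5$hemisphere <- NULL
  expect_error(load_bilateral_table(write_tmp_table(df5)),
               class = "wmasym_format_error")
  expect_error(load_bilateral_table(tempfile()), class = "wmasym_format_error")
})

test_that("table writing round-trips the row multiset", {
  df <- make_bilateral_df()
  p1 <- tempfile(fileext = ".tsv")
  write_bilateral_table(df, p1)
  again <- load_bilateral_table(p1)
  expect_equal(again[order(again$subject_id, again$tract, again$hemisphere), ],
               df[order(df$subject_id, df$tract, df$hemisphere), ],
               ignore_attr = TRUE)
  # LI table dialect
  li <- suppressMessages(build_li_table(df))
  p2 <- tempfile(fileext = ".tsv")
  write_li_table(li, p2)
  li2 <- read_li_table(p2)
  expect_equal(li2$li, li$li)
  bad <- li; bad$li[1] <- 2
  p3 <- tempfile(fileext = ".tsv")
  write_li_table(bad, p3)
  expect_error(read_li_table(p3), class = "wmasym_validation_error")
})

test_that("fit artifacts round-trip field-for-field at full precision", {
  truth <- linear_truth(n = 300, seed = 8101, n_cohorts = 3)
  tab <- simulate_li_table(truth)
  fit <- fit_model(tab, model_spec(fp_spec(c(0, 1)), fp_spec(1)))
  path <- tempfile(fileext = ".json")
  write_artifact(fit, path)
  back <- read_artifact(path)
  expect_s3_class(back, "wmasym_fit")
  expect_equal(back$beta_mu, fit$beta_mu, tolerance = 1e-15)
  expect_equal(back$beta_sigma, fit$beta_sigma, tolerance = 1e-15)
  expect_equal(back$u_mu, fit$u_mu, tolerance = 1e-15)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-15)
  expect_equal(back$bic, fit$bic, tolerance = 1e-15)
  expect_equal(as.numeric(back$spec$mu_fp), as.numeric(fit$spec$mu_fp))
  expect_identical(back$spec$cohort_effect, fit$spec$cohort_effect)
  # predictions from the restored fit are identical
  expect_equal(predict_mu_sigma(back, c(1, 50), "male"),
               predict_mu_sigma(fit, c(1, 50), "male"), tolerance = 1e-14)
})

test_that("chart artifacts preserve a dense grid exactly", {
  fit <- fit_from_truth(scenario("flat_symmetric"))
  ch <- centile_curves(fit, ages = seq(0, 100, by = 0.25))
  expect_equal(length(ch$ages), 401)
  path <- tempfile(fileext = ".json")
  write_artifact(ch, path)
  back <- read_artifact(path)
  expect_s3_class(back, "wmasym_chart")
  expect_equal(back$ages, ch$ages, tolerance = 1e-15)
  expect_equal(back$values, ch$values, tolerance = 1e-15)
  expect_equal(back$levels, ch$levels)
})

test_that("truth and summary-table artifacts round-trip; bad schema errors", {
  truth <- scenario("heteroscedastic_u_shape")
  path <- tempfile(fileext = ".json")
  write_artifact(truth, path)
  back <- read_artifact(path)
  expect_s3_class(back, "wmasym_truth")
  expect_equal(back$mu_coef, truth$mu_coef, tolerance = 1e-15)
  expect_equal(as.numeric(back$sigma_fp), as.numeric(truth$sigma_fp))
  expect_identical(simulate_li_table(back), simulate_li_table(truth))

  mil <- milestone_summary(fit_from_truth(truth))
  p2 <- tempfile(fileext = ".json")
  write_artifact(mil, p2)
  mil2 <- read_artifact(p2)
  expect_equal(mil2, mil, tolerance = 1e-15)

  wrong <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other.thing/9"), wrong, auto_unbox = TRUE)
  expect_error(read_artifact(wrong), class = "wmasym_format_error")
  expect_error(write_artifact(1:3, tempfile()), class = "wmasym_format_error")
})
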