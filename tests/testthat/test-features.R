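# 2 patients x 8 days x 3 features with hand-checkable structure
make_small_panel <- function() {
  v <- array(NA_real_, dim = c(2, 8, 3))
  v[1, , 1] <- c(5, 5, 5, 5, 5, 5, 5, 5)        # constant
  v[1, , 2] <- 1:8                              # linear ramp
  v[1, , 3] <- c(2, NA, 4, NA, 6, NA, 8, NA)    # gappy
  v[2, , 1] <- c(5, 5, 5, 5, 5, 5, 5, 5)
  v[2, , 2] <- 8:1
  v[2, , 3] <- c(NA, 3, NA, 5, NA, 7, NA, 9)
  feature_panel(v, patients = c("a", "b"),
                features = c("const", "ramp", "gappy"),
                tags = c("sensor", "sensor", "sensor"))
}

test_that("deviation features follow the prior-window definition", {
  p <- deviation_features(make_small_panel(), window = 7)
  expect_equal(p$features[4:6], c("const_dev7", "ramp_dev7", "gappy_dev7"))
  expect_equal(p$tags[4:6], rep("deviation", 3))
  # constant series: deviation 0 from day 2 on, missing day 1
  expect_true(is.na(p$values[1, 1, 4]))
  expect_equal(p$values[1, 2:8, 4], rep(0, 7))
  # 1..8 with window 7: day 8 deviation = 8 - mean(1:7) = 4
  expect_equal(p$values[1, 8, 5], 4)
  # day 2 deviation = 2 - 1 = 1
  expect_equal(p$values[1, 2, 5], 1)
  # missing base days give missing deviations
  expect_true(all(is.na(p$values[1, c(2, 4, 6, 8), 6])))
  # deviation at an observed day uses only observed priors: day 3 = 4 - 2
  expect_equal(p$values[1, 3, 6], 2)
})

test_that("all-missing base features yield all-missing deviations", {
  v <- array(NA_real_, dim = c(1, 5, 1))
  p <- deviation_features(feature_panel(v, tags = "sensor"), window = 3)
  expect_true(all(is.na(p$values[1, , 2])))
})

test_that("filters drop exactly the hand-enumerated columns", {
  v <- array(stats::rnorm(2 * 10 * 4, sd = 5), dim = c(2, 10, 4))
  v[, , 2] <- 7                                  # zero variance
  v[1, c(1, 3:10), 3] <- NA; v[2, 2:10, 3] <- NA # 18/20 = 90% missing
  v[2, 1, 4] <- NA                               # missing on day 1
  panel <- feature_panel(v, features = c("ok", "flat", "holey", "lateonset"))
  f <- filter_features(panel, drop_if_first_day_missing = TRUE)
  expect_identical(f$features, "ok")
  expect_setequal(f$log$feature, c("flat", "holey", "lateonset"))
  expect_match(f$log$reason[f$log$feature == "holey"], "missing fraction")
  expect_match(f$log$reason[f$log$feature == "flat"], "variance")
  expect_match(f$log$reason[f$log$feature == "lateonset"], "day 1")
  # bookkeeping: kept + dropped = input feature count
  expect_equal(length(f$features) + nrow(f$log), 4L)
  # day-1 rule off keeps the late-onset column
  f2 <- filter_features(panel, drop_if_first_day_missing = FALSE)
  expect_setequal(f2$features, c("ok", "lateonset"))
  # an 81%-missing column goes, an 80% one stays (strict threshold)
  v3 <- array(stats::rnorm(1 * 100 * 2, sd = 5), dim = c(1, 100, 2))
  v3[1, 1:81, 1] <- NA
  v3[1, 1:80, 2] <- NA
  p3 <- filter_features(feature_panel(v3, features = c("f81", "f80")),
                        drop_if_first_day_missing = FALSE)
  expect_identical(p3$features, "f80")
  expect_error(filter_features(feature_panel(array(1, c(2, 5, 1)))), "dropped")
})

test_that("moving-average imputation reproduces hand-computed cells", {
  v <- array(NA_real_, dim = c(1, 6, 2))
  v[1, , 1] <- c(1, 2, NA, NA, 5, NA)
  v[1, , 2] <- c(NA, NA, 3, NA, NA, NA)
  p <- impute_moving_average(feature_panel(v), k_prev = 2)
  # mean of previous two observed (1, 2) -> 1.5; observed values only, so
  # day 4 also averages (1, 2); after day 5 the pool is (2, 5)
  expect_equal(p$values[1, , 1], c(1, 2, 1.5, 1.5, 5, 3.5))
  # leading missings have no observed predecessor -> fill constant
  expect_equal(p$values[1, 1:2, 2], c(-1, -1))
  expect_equal(p$values[1, 4:6, 2], rep(3, 3))
  expect_true(all(p$imputed[1, c(3, 4, 6), 1]))
  expect_true(all(p$filled[1, 1:2, 2]))
})

test_that("imputation is idempotent and the identity on complete panels", {
  co <- tiny_cohort(n = 4, seed = 9, missing = 0.3)
  p1 <- impute_moving_average(co$panel, k_prev = 2)
  p2 <- impute_moving_average(p1, k_prev = 2)
  expect_equal(p2$values, p1$values)
  full <- tiny_cohort(n = 3, seed = 9, missing = 0)$panel
  expect_equal(impute_moving_average(full, k_prev = 2)$values[, , ],
               full$values[, , ])
  # k_prev = 0 goes straight to the constant
  v <- array(c(1, NA, 3, 4), dim = c(1, 4, 1))
  expect_equal(impute_moving_average(feature_panel(v), k_prev = 0)$values[1, , 1],
               c(1, -1, 3, 4))
})

test_that("min-max normalization is the affine map with pooled extremes", {
  v <- array(NA_real_, dim = c(2, 3, 3))
  v[1, , 1] <- c(-1, 1, 3); v[2, , 1] <- c(0, 2, -1)   # range [-1, 3]
  v[1, , 2] <- c(0, 0.5, 1); v[2, , 2] <- c(1, 0, 0.25)
  v[1, , 3] <- 4; v[2, , 3] <- 4                        # constant
  p <- normalize_minmax(impute_moving_average(feature_panel(v)))
  expect_equal(p$values[1, , 1], c(0, 0.5, 1))
  expect_equal(p$values[2, , 1], c(0.25, 0.75, 0))
  expect_equal(p$values[1, , 2], c(0, 0.5, 1))          # already [0,1]
  expect_true(all(p$values[, , 3] == 0))                # degenerate range
  expect_equal(unname(p$norm$min[1]), -1)
  expect_equal(unname(p$norm$max[1]), 3)
  expect_error(normalize_minmax(feature_panel(array(NA_real_, c(1, 2, 1)))),
               "impute")
})

test_that("constant-filled cells stay at -1 through normalization", {
  v <- array(NA_real_, dim = c(1, 4, 1))
  v[1, , 1] <- c(NA, 10, 20, 30)    # day 1 unobservable -> -1
  p <- normalize_minmax(impute_moving_average(feature_panel(v), k_prev = 2))
  expect_equal(p$values[1, 1, 1], -1)
  expect_equal(p$values[1, 2:4, 1], c(0, 0.5, 1))
})

test_that("pipeline output stays within [-1, 1]", {
  co <- tiny_cohort(n = 5, seed = 77, missing = 0.25)
  p <- preprocess_panel(co$panel, co$metas)
  act <- outer(seq_along(p$patients), seq_len(dim(p$values)[2]),
               function(i, j) j <= p$lengths[i])
  for (j in seq_along(p$features)) {
    x <- p$values[, , j][act]
    expect_true(all(x >= -1 - 1e-12 & x <= 1 + 1e-12))
  }
})

test_that("auxiliary columns append the documented values", {
  v <- array(stats::runif(2 * 5 * 1), dim = c(2, 5, 1))
  panel <- feature_panel(v, patients = c("a", "b"))
  p <- attach_auxiliary(panel, date_index = TRUE)
  expect_equal(p$values[1, , 2], (1:5) / 5)
  expect_identical(p$tags[2], "date_index")
  labels <- list(a = c(0.5, 0.4, 0.3, 0.2, 0.1), b = c(0.9, 0.8, 0.7, 0.6, 0.5))
  p2 <- attach_auxiliary(panel, probabilities = labels)
  # day 1 carries the initial probability, later days the previous label
  expect_equal(p2$values[1, , 2], c(0.5, 0.5, 0.4, 0.3, 0.2))
  expect_equal(p2$values[2, , 2], c(0.9, 0.9, 0.8, 0.7, 0.6))
  expect_identical(p2$tags[2], "injected_probability")
  expect_identical(attach_auxiliary(panel), panel)   # both off: unchanged
  expect_error(attach_auxiliary(panel, probabilities = list(a = 1:3 / 10,
                                                            b = 1:5 / 10)),
               "3 days")
})

test_that("data-range settings truncate readmitted patients as enumerated", {
  co <- tiny_cohort(n = 6, seed = 5)
  readm <- vapply(co$metas, `[[`, TRUE, "readmitted")
  expect_true(any(readm))     # the seed yields a mixed cohort
  full <- select_data_range(co$panel, co$metas, "full_60")
  expect_equal(full$lengths, co$panel$lengths)
  for (setting in c("post_discharge_to_event", "exclude_post_readmission",
                    "post_op_to_event")) {
    cut <- select_data_range(co$panel, co$metas, setting)
    for (i in seq_along(cut$patients)) {
      m <- co$metas[[cut$patients[i]]]
      expect_equal(cut$lengths[i],
                   if (m$readmitted) m$readmission_day else 60L)
    }
  }
})

test_that("feature panel CSV round-trips with missing cells", {
  co <- tiny_cohort(n = 3, seed = 21, missing = 0.3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_panel(co$panel, f)
  back <- read_feature_panel(f, horizon = 60)
  expect_equal(back$values[, , ], co$panel$values[, , ])
  expect_identical(back$features, co$panel$features)
  # symptom columns are re-tagged from their names
  expect_identical(back$tags[grepl("^symptom", back$features)],
                   rep("symptom", sum(grepl("^symptom", back$features))))
})
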