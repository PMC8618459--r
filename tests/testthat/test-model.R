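test_that("model construction follows the configuration", {
  m <- build_lstm(lstm_config(seed = 4), n_features = 30)
  expect_equal(m$hidden, 30)                      # auto width = feature count
  expect_length(m$params$W, 2)
  expect_equal(dim(m$params$W[[1]]), c(120, 30))
  expect_equal(dim(m$params$U[[2]]), c(120, 30))
  m1 <- build_lstm(lstm_config(n_layers = 1, hidden_units = 7, seed = 4), 5)
  expect_length(m1$params$W, 1)
  expect_equal(dim(m1$params$W[[1]]), c(28, 5))
  # forget-gate bias starts at 1, others at 0
  expect_equal(m1$params$b[[1]], c(rep(0, 7), rep(1, 7), rep(0, 14)))
  expect_error(lstm_config(n_layers = 3), "n_layers")
  expect_error(lstm_config(learning_rate = 0), "learning_rate")
})

test_that("weight initialization is a pure function of the seed", {
  a <- build_lstm(lstm_config(seed = 11), 6)
  b <- build_lstm(lstm_config(seed = 11), 6)
  c <- build_lstm(lstm_config(seed = 12), 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$W[[1]], c$params$W[[1]]))
  # building a model does not disturb the session RNG stream
  set.seed(123); before <- stats::runif(3)
  set.seed(123); invisible(build_lstm(lstm_config(seed = 5), 4))
  expect_identical(stats::runif(3), before)
})

test_that("the C++ forward pass matches a literal R reimplementation", {
  set.seed(31)
  m <- build_lstm(lstm_config(n_layers = 2, hidden_units = 4, seed = 31), 3)
  X <- array(stats::rnorm(3 * 2 * 5), dim = c(3, 2, 5))
  yhat_cpp <- readmitrisk:::lstm_forward_cpp(m$params, X)
  expect_equal(yhat_cpp, oracle_lstm_forward(m$params, X), tolerance = 1e-12)
  m1 <- build_lstm(lstm_config(n_layers = 1, hidden_units = 3, seed = 8), 3)
  expect_equal(readmitrisk:::lstm_forward_cpp(m1$params, X),
               oracle_lstm_forward(m1$params, X), tolerance = 1e-12)
})

test_that("training reduces the loss and early stopping keeps the best", {
  co <- tiny_cohort(n = 5, seed = 14)
  panel <- preprocess_panel(co$panel, co$metas)
  labels <- trajectory_labels(co$trajectories)
  aug <- attach_auxiliary(panel, date_index = TRUE, probabilities = labels)
  m <- build_lstm(lstm_config(max_epochs = 60, seed = 14),
                  length(aug$features))
  fit <- train_lstm(m, aug, labels)
  expect_true(fit$trained)
  expect_lt(fit$best_loss, fit$loss_history[1])
  expect_equal(fit$best_loss, min(fit$loss_history))
  expect_equal(fit$loss_history[fit$best_epoch], fit$best_loss)
})

test_that("actual-probability injection suffices for an autoregressive label", {
  # labels follow p_{t+1} = 0.9 p_t exactly; with the previous-day label
  # injected, training error must become small
  H <- 30
  ids <- paste0("p", 1:4)
  labels <- lapply(c(0.9, 0.7, 0.5, 0.3), function(p0) p0 * 0.9^(0:(H - 1)))
  names(labels) <- ids
  v <- array(stats::runif(4 * H), dim = c(4, H, 1))   # one noise feature
  panel <- feature_panel(v, patients = ids, features = "noise")
  aug <- attach_auxiliary(panel, probabilities = labels)
  m <- build_lstm(lstm_config(max_epochs = 400, patience = 100, seed = 2,
                              injection = "actual_prev",
                              include_date_index = FALSE),
                  length(aug$features))
  fit <- train_lstm(m, aug, labels)
  expect_lt(fit$best_loss, 0.02)
})

test_that("leave-one-patient-out trains one model per held-out patient", {
  co <- tiny_cohort(n = 3, seed = 6)
  panel <- preprocess_panel(co$panel, co$metas)
  fit <- train_lopo(panel, co$trajectories,
                    lstm_config(max_epochs = 25, seed = 6))
  expect_length(fit$models, 3)
  expect_setequal(names(fit$models), panel$patients)
  expect_equal(sort(unique(fit$predictions$fold)), 1:3)
  expect_equal(nrow(fit$predictions), 3 * 60)
  # sigmoid output keeps predictions strictly inside (0, 1); day 1 carries
  # the known initial probability
  later <- fit$predictions$day > 1
  expect_true(all(fit$predictions$y_pred[later] > 0 &
                  fit$predictions$y_pred[later] < 1))
  day1 <- fit$predictions$day == 1
  expect_equal(fit$predictions$y_pred[day1], fit$predictions$y_true[day1])
  expect_error(train_lopo(feature_panel(array(1, c(1, 5, 1))),
                          co$trajectories), "two patients")
})

test_that("the full train/predict cycle is reproducible from the seed", {
  co <- tiny_cohort(n = 3, seed = 8)
  panel <- preprocess_panel(co$panel, co$metas)
  cfg <- lstm_config(max_epochs = 20, seed = 8)
  f1 <- train_lopo(panel, co$trajectories, cfg)
  f2 <- train_lopo(panel, co$trajectories, cfg)
  expect_equal(f1$predictions$y_pred, f2$predictions$y_pred, tolerance = 1e-12)
})

test_that("a constant-output model rolls out its constant", {
  co <- tiny_cohort(n = 3, seed = 13)
  panel <- preprocess_panel(co$panel, co$metas)
  labels <- trajectory_labels(co$trajectories)
  aug <- attach_auxiliary(panel, probabilities = labels)
  m <- build_lstm(lstm_config(injection = "predicted_prev",
                              include_date_index = FALSE, seed = 13),
                  length(aug$features))
  m$params$v[] <- 0
  m$params$c0 <- stats::qlogis(0.3)
  m$trained <- TRUE
  yhat <- predict_trajectory(m, aug, aug$patients[1], initial = 0.8)
  expect_equal(yhat[1], 0.8)                 # seeded with the initial
  expect_equal(yhat[-1], rep(0.3, 59))       # stubbed sigmoid output
})

test_that("autoregressive rollout consumes its own outputs", {
  co <- tiny_cohort(n = 4, seed = 19)
  panel <- preprocess_panel(co$panel, co$metas)
  labels <- trajectory_labels(co$trajectories)
  aug <- attach_auxiliary(panel, probabilities = labels)
  pid <- aug$patients[1]

  mp <- build_lstm(lstm_config(injection = "predicted_prev", max_epochs = 25,
                               include_date_index = FALSE, seed = 19),
                   length(aug$features))
  mp <- train_lstm(mp, aug, labels, patients = aug$patients[-1])
  y_a <- predict_trajectory(mp, aug, pid, initial = 0.5)
  y_b <- predict_trajectory(mp, aug, pid, initial = 0.9)
  # perturbing the day-1 probability must propagate into day 2 when the
  # model feeds back its own input column
  expect_gt(abs(y_a[2] - y_b[2]), 0)

  ma <- mp
  ma$config$injection <- "actual_prev"
  z_a <- predict_trajectory(ma, aug, pid, initial = 0.5)
  z_b <- predict_trajectory(ma, aug, pid, initial = 0.9)
  # with the actual previous-day label as input, day 2 ignores `initial`
  expect_equal(z_a[2], z_b[2], tolerance = 1e-12)
  expect_equal(z_a[1], 0.5)
})

test_that("predictions beat the constant-mean predictor on a learnable cohort", {
  co <- tiny_cohort(n = 6, seed = 23, noise = 0.25)
  panel <- preprocess_panel(co$panel, co$metas)
  fit <- train_lopo(panel, co$trajectories,
                    lstm_config(max_epochs = 120, seed = 23))
  y <- fit$predictions$y_true
  null_mse <- mean((y - mean(y))^2)
  expect_lt(mse(y, fit$predictions$y_pred), null_mse)
})

test_that("prediction CSV and training log are written", {
  co <- tiny_cohort(n = 3, seed = 4)
  panel <- preprocess_panel(co$panel, co$metas)
  fit <- train_lopo(panel, co$trajectories, lstm_config(max_epochs = 10,
                                                        seed = 4))
  csv <- withr::local_tempfile(fileext = ".csv")
  logf <- withr::local_tempfile(fileext = ".csv")
  write_predictions(fit, csv, log_path = logf)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(fit$predictions))
  logs <- utils::read.csv(logf)
  expect_setequal(unique(logs$patient_id), panel$patients)
  expect_true(all(logs$loss > 0))
})
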