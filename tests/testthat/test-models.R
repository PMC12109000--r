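# synthetic modelling frame: latent pressure drives every feature linearly
# (the generator's coupling structure at zero noise)
linear_frame <- function(n, seed = 1, noise_sd = 0) {
  cols <- feature_column_order("calibration_free")
  set.seed(seed)
  bp <- runif(n, 100, 180)
  a <- rnorm(32)
  b <- rnorm(32, 0, 0.02)
  X <- vapply(1:32, function(j) a[j] + b[j] * bp, numeric(n))
  colnames(X) <- cols
  X[, "pat"] <- 0.35 - 0.001 * bp
  df <- as.data.frame(X)
  df$target_sbp <- bp + rnorm(n, 0, noise_sd)
  df$target_dbp <- 0.5 * bp + 20
  df$subject_id <- as.character(rep(seq_len(ceiling(n / 10)),
                                    each = 10)[seq_len(n)])
  df
}

test_that("lasso recovers a linear pressure relation within 2 SE of OLS", {
  # SBP = a * pat + b + noise; the other 31 slots are uninformative
  cols <- feature_column_order("calibration_free")
  set.seed(4)
  n <- 2000
  X <- matrix(rnorm(n * 32), n, 32, dimnames = list(NULL, cols))
  X[, "pat"] <- runif(n, 0.15, 0.30)
  df <- as.data.frame(X)
  df$target_sbp <- 160 - 250 * df$pat + rnorm(n, 0, 5)
  df$target_dbp <- 0.6 * df$target_sbp
  df$subject_id <- as.character(rep(1:200, each = 10))
  m <- suppressWarnings(train_estimator(
    df, model_spec("lasso", "sbp", "calibration_free", seed = 2)
  ))
  ols <- lm(target_sbp ~ pat, df)
  se <- coef(summary(ols))
  # effective slope probed by varying only the PAT slot
  x0 <- df[1, ]
  x1 <- df[1, ]
  x0$pat <- 0.20
  x1$pat <- 0.25
  slope_hat <- (predict(m, x1) - predict(m, x0)) / 0.05
  expect_lt(abs(slope_hat - coef(ols)["pat"]), 2 * se["pat", 2])
  b_hat <- as.matrix(coef(m$fit, s = "lambda.min"))[1]
  expect_lt(abs(b_hat - coef(ols)["(Intercept)"]),
            2 * se["(Intercept)", 2])
})

test_that("constant targets are reproduced by every family", {
  df <- linear_frame(400, seed = 6)
  df$target_sbp <- 117
  for (fam in c("lasso", "boosted_trees", "residual_net")) {
    m <- suppressWarnings(train_estimator(
      df[1:320, ],
      model_spec(fam, "sbp", "calibration_free", cv_folds = 0, seed = 2)
    ))
    p <- predict(m, df[321:400, ])
    expect_lt(max(abs(p - 117)), 1.0)
  }
})

test_that("training is deterministic under a fixed seed", {
  df <- linear_frame(400, seed = 8, noise_sd = 3)
  for (fam in c("lasso", "boosted_trees", "residual_net")) {
    m1 <- suppressWarnings(train_estimator(
      df, model_spec(fam, "sbp", "calibration_free", cv_folds = 0,
                     seed = 42)
    ))
    m2 <- suppressWarnings(train_estimator(
      df, model_spec(fam, "sbp", "calibration_free", cv_folds = 0,
                     seed = 42)
    ))
    expect_equal(predict(m1, df), predict(m2, df), tolerance = 1e-9)
  }
})

test_that("prediction enforces the slot contract", {
  df <- linear_frame(300, seed = 10)
  m <- suppressWarnings(train_estimator(
    df, model_spec("lasso", "sbp", "calibration_free", seed = 1)
  ))
  expect_length(predict(m, df[0, ]), 0)
  expect_error(predict(m, df[, 1:10]), "missing feature slots")
  bad <- df[1:5, ]
  bad$pat[2] <- Inf
  expect_error(predict(m, bad), "non-finite")

  # training rows re-fed reproduce the stored training residuals
  expect_equal(
    predict(m, df) - df$target_sbp,
    m$training$train_residuals,
    tolerance = 1e-9
  )
})

test_that("non-finite training features name the offending rows", {
  df <- linear_frame(200, seed = 12)
  df$heart_rate[7] <- NaN
  expect_error(
    suppressWarnings(train_estimator(
      df, model_spec("lasso", "sbp", "calibration_free", seed = 1)
    )),
    "rows: 7"
  )
})

test_that("boosted trees are invariant to monotone feature transforms", {
  df <- linear_frame(600, seed = 14, noise_sd = 2)
  hp <- default_hyperparameters("boosted_trees")
  hp$n_rounds <- 80
  sp <- model_spec("boosted_trees", "sbp", "calibration_free",
                   hyperparameters = hp, cv_folds = 0, seed = 3)
  # quantile-based split candidates are preserved under strictly monotone
  # transforms, so the induced trees should coincide up to bin-edge ties
  m1 <- suppressWarnings(train_estimator(df, sp))
  df2 <- df
  df2$pat <- exp(5 * df2$pat) # strictly monotone transform
  m2 <- suppressWarnings(train_estimator(df2, sp))
  p1 <- predict(m1, df)
  p2 <- predict(m2, df2)
  expect_lt(mean(abs(p1 - p2)), 0.3)
})

test_that("the residual network honours its parameter budget rule", {
  w34 <- residual_net_width(34)
  w32 <- residual_net_width(32)
  expect_gte(w34$width, 8)
  # no width >= 8 gets closer to 840 parameters
  count <- function(d, w) (d + 1) * w + 4 * (w^2 + w) + 10 * w + w + 1
  for (w in 8:20) {
    expect_gte(
      abs(count(34, w) - 840), abs(w34$n_params - 840)
    )
    expect_gte(
      abs(count(32, w) - 840), abs(w32$n_params - 840)
    )
  }
})

test_that("grouped cross-validation keeps subjects within one fold", {
  ids <- rep(sprintf("S%02d", 1:20), each = 6)
  f <- cufflessbp:::group_folds(ids, 5, seed = 3)
  expect_true(all(tapply(f, ids, function(v) length(unique(v))) == 1))
  expect_equal(sort(unique(f)), 1:5)

  df <- linear_frame(300, seed = 16, noise_sd = 2)
  m <- suppressWarnings(train_estimator(
    df, model_spec("lasso", "sbp", "calibration_free", cv_folds = 10,
                   seed = 2)
  ))
  expect_equal(nrow(m$training$cv), 10)
  expect_true(all(is.finite(m$training$cv$loss)))
})

test_that("estimator bundles round-trip through a single file", {
  df <- linear_frame(300, seed = 18, noise_sd = 2)
  for (fam in c("lasso", "boosted_trees", "residual_net")) {
    m <- suppressWarnings(train_estimator(
      df, model_spec(fam, "sbp", "calibration_free", cv_folds = 0,
                     seed = 7)
    ))
    f <- withr::local_tempfile(fileext = ".rds")
    save_estimator(m, f)
    back <- load_estimator(f)
    expect_equal(predict(back, df), predict(m, df), tolerance = 1e-9)
  }
})
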