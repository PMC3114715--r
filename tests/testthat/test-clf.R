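test_that("logistic regression satisfies its optimality conditions", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60)
  y <- as.numeric(X %*% c(1, -2, 0.5, 0) + 0.3 * rnorm(60) > 0)
  lam <- 0.3
  fit <- fitLogregL2(X, y, lam)
  expect_true(fit@converged)
  expect_lt(fit@gradNorm, 1e-7)
  ## finite-difference oracle for the stated objective
  obj <- function(wb) {
    z <- (2 * y - 1) * (X %*% wb[1:4] + wb[5])
    mean(log1p(exp(-pmin(z, 700)))) + lam / 2 * sum(wb[1:4]^2)
  }
  wb <- c(fit@w, fit@b)
  g <- vapply(1:5, function(j) {
    h <- 1e-6
    e <- rep(0, 5); e[j] <- h
    (obj(wb + e) - obj(wb - e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("extreme regularization shrinks to the majority class", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3), 50)
  y <- c(rep(0, 30), rep(1, 20))
  fit <- fitLogregL2(X, y, 1e9)
  expect_lt(sqrt(sum(fit@w^2)), 1e-6)
  expect_true(all(predictLogreg(fit, X) == 0))   # majority class (b < 0)
})

test_that("a separable toy problem is fit perfectly at small lambda", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
  y <- c(0, 0, 1, 1)
  fit <- fitLogregL2(X, y, 1e-4)
  expect_equal(predictLogreg(fit, X), y)
  expect_error(fitLogregL2(X, rep(1, 4), 1), "two classes")
  X[1, 1] <- NA
  expect_error(fitLogregL2(X, y, 1), "non-finite")
})

test_that("McNemar against the majority class follows the stated recipe", {
  ## classifier identical to the majority predictor: no discordance, p = 1
  y <- rep(c(1, 2), c(20, 10))
  r <- mcnemarVsMajority(rep(1, 30), y)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
  ## b = 15, c = 0: exact two-sided binomial p = 2 * 0.5^15
  y <- rep(c(1, 2), c(20, 15))
  r <- mcnemarVsMajority(y, y)   # all correct; majority ("1") wrong on 15
  expect_equal(r$b, 15)
  expect_equal(r$c, 0)
  expect_equal(r$p, 2 * 0.5^15)
  ## b = c = 10: symmetric discordance, exact p capped at 1
  y <- rep(c(1, 2), c(30, 20))
  pred <- y
  pred[y == 2][1:10] <- 1          # only 10 of class 2 correct -> b = 10
  pred[y == 1][1:10] <- 2          # 10 of class 1 wrong -> c = 10
  r <- mcnemarVsMajority(pred, y)
  expect_equal(c(r$b, r$c), c(10, 10))
  expect_equal(r$p, 1)
  ## large discordance switches to the continuity-corrected chi-squared
  y <- rep(c(1, 2), c(40, 40))
  pred <- ifelse(seq_along(y) %% 2 == 0, y, ifelse(y == 1, 2, 1))
  r <- mcnemarVsMajority(pred, y, tieClass = 1)
  expect_gte(r$b + r$c, 25)
  stat <- (abs(r$b - r$c) - 1)^2 / (r$b + r$c)
  expect_equal(r$p, pchisq(stat, 1, lower.tail = FALSE))
})

test_that("nested CV partitions trials correctly and is deterministic", {
  set.seed(8)
  X <- matrix(rnorm(60 * 5), 60)
  y <- rep(c(2, 5), 30)
  r1 <- nestedCV(X, y, lambdaGrid = fxGrid(), seed = 9)
  r2 <- nestedCV(X, y, lambdaGrid = fxGrid(), seed = 9)
  expect_identical(r1@predictions, r2@predictions)
  expect_identical(r1@lambdaPerFold, r2@lambdaPerFold)
  ## outer folds are disjoint and cover every trial exactly once
  expect_equal(sort(r1@predictions$trial_id), 1:60)
  expect_equal(as.integer(table(r1@predictions$fold)), rep(6L, 10))
  ## folds are stratified
  byFold <- table(r1@predictions$fold, r1@predictions$actual)
  expect_true(all(byFold == 3))
  expect_equal(r1@pair, c(2L, 5L))
  expect_error(nestedCV(X, y, lambdaGrid = numeric()), "empty")
  expect_error(nestedCV(X[1:12, ], y[1:12]), "at least 10")
})

test_that("inner grid ties resolve to the smallest lambda", {
  ## constant features: every lambda yields the same inner accuracy
  X <- matrix(1, 40, 3)
  y <- rep(c(0, 1), 20)
  r <- nestedCV(X, y, lambdaGrid = c(1.0, 0.1), seed = 2)
  expect_true(all(r@lambdaPerFold == 0.1))
})

test_that("outer-fold normalization uses training statistics only", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40)
  y <- rep(c(0, 1), 20)
  r <- nestedCV(X, y, lambdaGrid = c(0.1, 1), outerFolds = 5, seed = 33)
  ## replay the fold assignment and recompute fold 1 by hand
  covertAlpha:::.withSeed(33, {
    outer <- covertAlpha:::.stratifiedFolds(as.numeric(y == 1), 5)
    tr <- which(outer != 1); te <- which(outer == 1)
    mu <- colMeans(X[tr, ]); sd <- apply(X[tr, ], 2, sd)
    Xtr <- sweep(sweep(X[tr, ], 2, mu), 2, sd, "/")
    Xte <- sweep(sweep(X[te, ], 2, mu), 2, sd, "/")
    inner <- covertAlpha:::.stratifiedFolds(as.numeric(y[tr] == 1), 5)
    acc <- covertAlpha:::.lrCvAccCpp(Xtr, as.numeric(y[tr] == 1),
                                     as.integer(inner), c(0.1, 1))
    lam <- c(0.1, 1)[which.max(acc)]
    fit <- covertAlpha:::.lrFitCpp(Xtr, as.numeric(y[tr] == 1), lam,
                                   1e-7, 1000)
    manual <- as.numeric(Xte %*% fit$w + fit$b > 0)
    got <- r@predictions$predicted[r@predictions$fold == 1]
    expect_equal(got, manual)
    expect_equal(r@lambdaPerFold[1], lam)
  })
})

test_that("label permutation yields chance-level accuracy", {
  set.seed(12)
  X <- matrix(rnorm(40 * 5), 40)
  accs <- vapply(1:10, function(s) {
    covertAlpha:::.withSeed(1000 + s,
      y <- sample(rep(c(0, 1), 20)))
    accuracy(nestedCV(X, y, lambdaGrid = fxGrid(), seed = s))
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("all-pairs analysis yields 15 results with sensible structure", {
  big <- fxBigCsd()
  ap <- allPairsAnalysis(big, lambdaGrid = fxGrid(), seed = 1)
  expect_length(ap$results, 15)
  expect_equal(nrow(ap$summary), 15)
  expect_equal(ap$peakAccuracy, max(ap$summary$accuracy))
  expect_true(all(ap$summary$accuracy >= 0 & ap$summary$accuracy <= 1))
  ## every unordered pair appears once
  expect_identical(unname(as.matrix(ap$summary[, 1:2])), t(combn(1:6, 2)))
  sub <- fxBigEpochs()
  sub@data <- sub@data[trialInfo(sub)$direction != 3, , ]
  sub@trials <- sub@trials[sub@trials$direction != 3, ]
  expect_error(allPairsAnalysis(sub), "six directions")
})

test_that("strongly lateralized subjects are best decoded on a left-right pair", {
  pd <- pooledDirections()
  isLR <- vapply(1:4, function(s) {
    p <- subjectParams("lat", effectKappa = 1.5, hemiAsym = 0.75,
                       eogConfound = 0, seed = 40L + s)
    ap <- allPairsAnalysis(fxSubjectCsd(p), lambdaGrid = fxGrid(),
                           seed = 40L + s)
    (ap$bestPair[1] %in% pd$left & ap$bestPair[2] %in% pd$right) |
      (ap$bestPair[1] %in% pd$right & ap$bestPair[2] %in% pd$left)
  }, TRUE)
  expect_gte(sum(isLR), 2)
})
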