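test_that("noiseless linear data is fitted exactly", {
  d <- data.frame(x = 1:5)
  d$y <- 1 + 2 * d$x
  m <- suppressWarnings(qsar_mlr(d, "x"))
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-10)
  expect_equal(m$s, 0, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  pr <- predict(m, data.frame(x = 3), check_ad = FALSE)
  expect_equal(pr$halfwidth, 0, tolerance = 1e-10)
})

test_that("degenerate and deficient designs are rejected with diagnosis", {
  d <- data.frame(x = 1:2, y = c(1, 2))   # n = p + 1: zero residual df
  expect_error(qsar_mlr(d, "x"), "n >= p \\+ 2")
  d2 <- data.frame(a = 1:8, b = 2 * (1:8), y = rnorm(8))
  expect_error(qsar_mlr(d2, c("a", "b")), "collinear.*a.*b")
})

test_that("fit matches the explicit normal-equations and hat-matrix oracle", {
  set.seed(7)
  for (rep in 1:5) {
    rd <- random_mlr_data(n = 20, p = 3)
    m <- qsar_mlr(rd$data, rd$names)
    orc <- oracle_ols(rd$X, rd$y)
    expect_equal(unname(coef(m)), unname(orc$beta), tolerance = 1e-8)
    expect_equal(m$s, orc$s, tolerance = 1e-8)
    expect_equal(m$hat_diag, orc$hat, tolerance = 1e-8)
  }
})

test_that("leverage honours the closed form and the centroid property", {
  d <- data.frame(x = c(1, 2, 3, 4))
  d$y <- c(1.1, 1.9, 3.2, 3.8)
  m <- suppressWarnings(qsar_mlr(d, "x"))   # cutoff > 1 warns, by design
  # closed form 1/n + (x - xbar)^2 / Sxx at x = 1
  expect_equal(leverage(m, c(x = 1)), 1 / 4 + (1 - 2.5)^2 / 5,
               tolerance = 1e-12)
  expect_equal(leverage(m, c(x = 1)), 0.7, tolerance = 1e-12)
  # training rows reproduce the hat diagonal
  for (i in 1:4)
    expect_equal(leverage(m, d[i, "x", drop = FALSE]), m$hat_diag[i],
                 tolerance = 1e-10)
  # descriptor centroid has the minimum possible leverage 1/n
  expect_equal(leverage(m, c(x = mean(d$x))), 1 / 4, tolerance = 1e-12)
})

test_that("leverage cutoff follows 3(p+1)/n and warns when unreachable", {
  set.seed(1)
  rd <- random_mlr_data(n = 30, p = 3)
  expect_equal(leverage_cutoff(qsar_mlr(rd$data, rd$names)), 0.4)
  d <- data.frame(x = c(1, 2, 3, 4), y = c(0, 1, 2, 4))
  expect_warning(m <- qsar_mlr(d, "x"), "cutoff")
  expect_equal(leverage_cutoff(m), 1.5)
})

test_that("prediction intervals match the textbook oracle and predict.lm", {
  set.seed(11)
  rd <- random_mlr_data(n = 20, p = 2)
  m <- qsar_mlr(rd$data, rd$names)
  orc <- oracle_ols(rd$X, rd$y)
  lmfit <- lm(y ~ d1 + d2, data = rd$data)
  for (i in 1:10) {
    x <- rnorm(2); names(x) <- rd$names
    pr <- predict(m, x, check_ad = FALSE)
    expect_equal(pr$halfwidth, oracle_halfwidth(orc, x), tolerance = 1e-8)
    ci <- predict(lmfit, as.data.frame(as.list(x)),
                  interval = "prediction", level = 0.95)
    expect_equal(pr$lwr, unname(ci[, "lwr"]), tolerance = 1e-8)
    expect_equal(pr$upr, unname(ci[, "upr"]), tolerance = 1e-8)
  }
})

test_that("halfwidth is minimal at the descriptor centroid", {
  set.seed(12)
  rd <- random_mlr_data(n = 25, p = 2)
  m <- qsar_mlr(rd$data, rd$names)
  centroid <- colMeans(rd$X)
  hw0 <- predict(m, centroid, check_ad = FALSE)$halfwidth
  grid <- as.data.frame(matrix(rnorm(100 * 2, sd = 2), 100, 2,
                               dimnames = list(NULL, rd$names)))
  hw <- predict(m, grid, check_ad = FALSE)$halfwidth
  expect_true(all(hw >= hw0 - 1e-12))
})

test_that("prediction at a training point reproduces the fitted value", {
  set.seed(13)
  rd <- random_mlr_data(n = 20, p = 3)
  m <- qsar_mlr(rd$data, rd$names)
  tq <- qt(0.975, m$df)
  for (i in c(1, 7, 20)) {
    pr <- predict(m, rd$data[i, rd$names], check_ad = FALSE)
    expect_equal(pr$value, m$fitted[i], tolerance = 1e-10)
    expect_equal(pr$halfwidth, tq * m$s * sqrt(1 + m$hat_diag[i]),
                 tolerance = 1e-10)
  }
})

test_that("structural domain: boundary leverage is out, centroid is in", {
  set.seed(14)
  rd <- random_mlr_data(n = 30, p = 3)
  m <- qsar_mlr(rd$data, rd$names)
  centroid <- colMeans(rd$X)
  expect_true(structural_ad(m, centroid)$in_ad)     # h = 1/n < 3(p+1)/n

  far <- centroid + 10 * apply(rd$X, 2, sd)
  v <- structural_ad(m, far)
  expect_false(v$in_ad)
  expect_match(v$reasons, "leverage")

  # boundary convention: h exactly equal to the cutoff is OUT
  x <- rnorm(3); names(x) <- rd$names
  m2 <- m; m2$leverage_cutoff <- leverage(m, x)
  expect_false(structural_ad(m2, x)$in_ad)
})

test_that("endpoint domain applies the three rules with documented boundaries", {
  set.seed(15)
  rd <- random_mlr_data(n = 20, p = 2)
  m <- qsar_mlr(rd$data, rd$names)

  # benign in-range prediction without observed y: rule (a) not applicable
  v <- endpoint_ad(m, value = mean(m$y_range),
                   halfwidth = mean(m$halfwidth_range))
  expect_true(v$in_ad)
  expect_identical(unname(v$criteria["std_residual"]), "not_applicable")

  # out on both the experimental range and the interval range, both reported
  v2 <- endpoint_ad(m, value = m$y_range[2] + 10,
                    halfwidth = m$halfwidth_range[2] * 3)
  expect_false(v2$in_ad)
  expect_length(v2$reasons, 2)
  expect_identical(unname(v2$criteria["experimental_range"]), "fail")
  expect_identical(unname(v2$criteria["interval_range"]), "fail")

  # standardized-residual boundary: build an exactly dyadic case, s = 1
  mfake <- m; mfake$s <- 1
  den <- 1 * sqrt(1 - 0.75)   # = 0.5 exactly
  at <- function(delta) endpoint_ad(mfake, value = 0, halfwidth =
                                      mean(halfwidth_range(mfake)),
                                    leverage = 0.75, y_observed = delta)
  v3 <- at(2.5 * den)     # |r'| = 2.5 exactly -> in ("greater than 2.5")
  expect_identical(unname(v3$criteria["std_residual"]), "pass")
  v4 <- at(2.5 * den + 1e-9)
  expect_identical(unname(v4$criteria["std_residual"]), "fail")
})

test_that("strict conjunctive endpoint reading only fails on joint violation", {
  set.seed(16)
  rd <- random_mlr_data(n = 20, p = 2)
  m <- qsar_mlr(rd$data, rd$names)
  hw <- mean(m$halfwidth_range)
  # outside experimental range but residual rule inapplicable -> in under AND
  v <- endpoint_ad(m, value = m$y_range[2] + 5, halfwidth = hw,
                   strict_and = TRUE)
  expect_true(v$in_ad)
  # default independent reading flags it
  expect_false(endpoint_ad(m, value = m$y_range[2] + 5, halfwidth = hw)$in_ad)
})

test_that("standardized residuals equal the element-wise formula oracle", {
  set.seed(17)
  rd <- random_mlr_data(n = 20, p = 3)
  m <- qsar_mlr(rd$data, rd$names)
  orc <- oracle_ols(rd$X, rd$y)
  expect_equal(rstandard(m), orc$resid / (orc$s * sqrt(1 - orc$hat)),
               tolerance = 1e-10)
  # training-chemical residual via endpoint_ad matches the same oracle
  i <- 5
  pr <- predict(m, rd$data[i, rd$names], check_ad = FALSE)
  v <- endpoint_ad(m, value = pr$value, halfwidth = pr$halfwidth,
                   leverage = pr$leverage, y_observed = rd$y[i])
  expect_equal(unname(v$details["std_residual"]),
               orc$resid[i] / (orc$s * sqrt(1 - orc$hat[i])),
               tolerance = 1e-10)
  # noiseless model: all standardized residuals are zero by convention
  d0 <- data.frame(x = 1:6); d0$y <- 2 * d0$x
  m0 <- qsar_mlr(d0, "x")
  expect_identical(rstandard(m0), numeric(6))
})

test_that("hat-matrix conservation holds on random fixtures", {
  set.seed(18)
  for (rep in 1:10) {
    n <- sample(10:40, 1); p <- sample(1:4, 1)
    rd <- random_mlr_data(n = n, p = p)
    m <- qsar_mlr(rd$data, rd$names)
    expect_equal(sum(m$hat_diag), p + 1, tolerance = 1e-8)
    expect_true(all(m$hat_diag >= 1 / n - 1e-10))
    expect_true(all(m$hat_diag <= 1 + 1e-10))
  }
})

test_that("missing descriptor values at prediction are named", {
  set.seed(19)
  rd <- random_mlr_data(n = 15, p = 2)
  m <- qsar_mlr(rd$data, rd$names)
  expect_error(predict(m, data.frame(d1 = 1)), "d2")
})

test_that("simulate() reproduces the fitted noise scale", {
  set.seed(20)
  rd <- random_mlr_data(n = 30, p = 2, noise_sd = 1)
  m <- qsar_mlr(rd$data, rd$names)
  sims <- simulate(m, nsim = 200, seed = 99)
  resid_sd <- sd(as.matrix(sims) - m$fitted)
  expect_equal(resid_sd, m$s, tolerance = 0.1)
})
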