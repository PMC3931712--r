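test_that("sigmoid is stable and symmetric", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1000), 1)     # no overflow
  expect_equal(sigmoid(-1000), 0)
  set.seed(20)
  z <- rnorm(50, 0, 10)
  expect_equal(sigmoid(z) + sigmoid(-z), rep(1, 50), tolerance = 1e-12)
})

test_that("cost at theta = 0 is ln 2 and the gradient matches finite differences", {
  set.seed(21)
  X <- cbind(1, matrix(rnorm(40), 20, 2))
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  expect_identical(lrc_cost(rep(0, 3), X, y)$J, log(2))
  for (k in 1:10) {
    m <- sample(10:40, 1); d <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(m * d), m, d))
    y <- rbinom(m, 1, 0.5)
    th <- rnorm(d + 1)
    lam <- sample(c(0, 0.5), 1)
    g <- lrc_cost(th, X, y, lam)$grad
    gfd <- fd_gradient(th, X, y, lam)
    expect_lt(max(abs(g - gfd)) / max(1, max(abs(gfd))), 1e-6)
  }
  expect_error(lrc_cost(0, matrix(nrow = 0, ncol = 1), numeric(0)))
})

test_that("training separates simulated near/far distance classes", {
  set.seed(22)
  d <- c(pmax(rnorm(200, 100, 30), 0), pmax(rnorm(200, 2000, 300), 0))
  y <- rep(c(1, 0), each = 200)
  fit <- lrc(cbind(dist = d), y)
  expect_true(fit$converged)
  expect_lt(coef(fit)["dist"], 0)  # closer nucleosome -> higher probability
  expect_gte(auc(predict(fit, cbind(dist = d)), y), 0.99)
  # monotone decreasing in the single negative-weight feature
  p <- predict(fit, cbind(dist = c(50, 500, 5000)))
  expect_true(all(diff(p) < 0))
})

test_that("labels independent of features give chance-level held-out AUC", {
  set.seed(23)
  X <- matrix(rnorm(3000), ncol = 1, dimnames = list(NULL, "f"))
  y <- rbinom(3000, 1, 0.25)
  tr <- 1:1000
  fit <- lrc(X[tr, , drop = FALSE], y[tr])
  a <- auc(predict(fit, X[-tr, , drop = FALSE]), y[-tr])
  expect_gt(a, 0.45)
  expect_lt(a, 0.55)
})

test_that("standardization is idempotent and stored on the model", {
  set.seed(24)
  X <- matrix(rnorm(400, 50, 9), 200, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- rbinom(200, 1, sigmoid(scale(X) %*% c(1, -1)))
  f1 <- lrc(X, y)
  Xs <- scale(X)
  f2 <- lrc(Xs, y)
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-6)
  # mean feature vector predicts sigmoid(theta_0)
  expect_equal(unname(predict(f1, matrix(colMeans(X), 1,
                                         dimnames = list(NULL, c("a", "b"))))),
               unname(sigmoid(coef(f1)[1])), tolerance = 1e-12)
})

test_that("the convex cost reaches the same optimum from random starts", {
  set.seed(25)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, sigmoid(X %*% c(0.5, -1, 0.2)))
  Xa <- cbind(1, scale(X))
  fn <- function(th) lrc_cost(th, Xa, y)$J
  gr <- function(th) lrc_cost(th, Xa, y)$grad
  j0 <- optim(rep(0, 4), fn, gr, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12))$value
  for (k in 1:5) {
    jr <- optim(rnorm(4, 0, 3), fn, gr, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-12))$value
    expect_lt(abs(jr - j0), 1e-6)
  }
})

test_that("parameters of a known logistic model are recovered", {
  set.seed(26)
  m <- 5000
  X <- matrix(rnorm(3 * m), m, 3, dimnames = list(NULL, c("a", "b", "c")))
  theta_true <- c(0.4, 1.5, -2.0, 0.8)
  y <- rbinom(m, 1, sigmoid(cbind(1, X) %*% theta_true))
  fit <- lrc(X, y)
  expect_equal(unname(coef(fit)), theta_true, tolerance = 0.15)
  p <- predict(fit, X)
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
})

test_that("the fit agrees with glm as an independent reference", {
  set.seed(27)
  X <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(300, 1, sigmoid(X %*% c(1, -0.5)))
  fit <- lrc(X, y)
  ref <- glm(y ~ scale(X), family = binomial)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
})

test_that("degenerate training inputs are rejected, constants dropped", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(lrc(X, rep(1, 10)), "both classes")
  expect_error(lrc(X, c(1, rep(NA, 9))))
  Xb <- cbind(X, const = 5)
  y <- rep(c(0, 1), 5)
  expect_warning(fit <- lrc(Xb, y), "zero-variance")
  expect_equal(fit$feature_names, c("a", "b"))
  expect_length(predict(fit, Xb), 10)  # extra constant column is ignored
  Xn <- X; Xn[1] <- Inf
  expect_error(lrc(Xn, y), "finite")
})

test_that("formula and training-set interfaces match the matrix interface", {
  set.seed(28)
  d <- data.frame(a = rnorm(100), b = rnorm(100))
  d$y <- rbinom(100, 1, sigmoid(d$a - d$b))
  f1 <- lrc(y ~ a + b, data = d)
  f2 <- lrc(as.matrix(d[c("a", "b")]), d$y)
  expect_equal(coef(f1), coef(f2))
  s <- summary(f1)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
  expect_equal(residuals(f1, type = "response"),
               d$y - fitted(f1), tolerance = 1e-12)
  sim <- simulate(f1, nsim = 2, seed = 1, newdata = d)
  expect_true(all(unlist(sim) %in% 0:1))
})

test_that("serialized models reproduce probabilities bit-identically", {
  set.seed(29)
  X <- matrix(rnorm(200, 1000, 250), 100, 2,
              dimnames = list(NULL, c("mnn_H3K4me3", "mnn_H2A.Z")))
  y <- rbinom(100, 1, sigmoid(scale(X) %*% c(-2, -0.5)))
  fit <- lrc(X, y)
  f <- withr::local_tempfile(fileext = ".json")
  write_lrc(fit, f)
  fit2 <- read_lrc(f)
  expect_identical(predict(fit2, X), predict(fit, X))
  expect_error(predict(fit2, X[, 1, drop = FALSE]), "feature")
})
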