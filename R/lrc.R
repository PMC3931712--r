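# Logistic regression classifier, written out in full: sigmoid hypothesis
# h_theta(x) = g(theta' x), average cross-entropy cost J(theta) with analytic
# gradient, minimized by a quasi-Newton method (BFGS) from theta = 0.
# Features are z-scored with training statistics stored on the model.

#' Logistic (sigmoid) function, numerically stable for large |z|
#'
#' @param z Numeric vector.
#' @return `1 / (1 + exp(-z))`, computed without overflow.
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out[is.na(z)] <- NA_real_
  out
}

#' Cross-entropy cost and gradient of the logistic model
#'
#' \deqn{J(\theta) = -\frac1m \sum_i [y_i \ln h_\theta(x_i) +
#'       (1-y_i)\ln(1-h_\theta(x_i))]}
#' with gradient \eqn{\frac1m X^\top(h - y)}. An optional L2 penalty
#' `lambda/(2m) * sum(theta[-1]^2)` (intercept excluded) is available for
#' ill-conditioned feature combinations; it is off by default.
#'
#' Computed in the stable form `J_i = log(1 + exp(z_i)) - y_i z_i`, so
#' `J(0) = log(2)` exactly and large |z| cannot overflow.
#'
#' @param theta Parameter vector (intercept first), length `ncol(X)`.
#' @param X Design matrix, already standardized and intercept-augmented.
#' @param y Binary labels (0/1), length `nrow(X)`.
#' @param lambda L2 penalty weight (default 0).
#' @return List with `J` (scalar cost) and `grad` (gradient vector).
#' @export
lrc_cost <- function(theta, X, y, lambda = 0) {
  m <- nrow(X)
  if (is.null(m) || m == 0L) stop("empty training set")
  if (length(theta) != ncol(X)) stop("theta/X dimension mismatch")
  z <- drop(X %*% theta)
  # log(1 + exp(z)) computed branch-wise to avoid overflow
  lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  J <- sum(lse - y * z) / m
  h <- sigmoid(z)
  grad <- drop(crossprod(X, h - y)) / m
  if (lambda > 0) {
    pen <- c(0, theta[-1L])
    J <- J + lambda / (2 * m) * sum(pen^2)
    grad <- grad + lambda / m * pen
  }
  list(J = J, grad = grad)
}

#' Fit a logistic regression classifier
#'
#' The model maps a feature vector (MNN distances and/or MNO counts) to the
#' probability that a region is a binding site. Features are standardized to
#' zero mean and unit variance (statistics stored on the model and re-applied
#' at prediction); the cost [lrc_cost()] is minimized by BFGS with the
#' analytic gradient, initialized at `theta = 0`. The cost is convex, so the
#' optimum does not depend on initialization.
#'
#' @param x Feature matrix (rows = training regions), a `training_set` from
#'   [build_training_set()], or a formula.
#' @param ... Passed between methods.
#' @return Object of class `lrc` with elements `theta` (named, intercept
#'   first), `center`/`scale` (standardization statistics), `feature_names`,
#'   `dropped` (zero-variance features removed), `cost`, `gradient_norm`,
#'   `converged`, `n`, `n_pos`, `lambda`, `call`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(dist = c(rnorm(50, 100, 30), rnorm(50, 2000, 300)),
#'                 y = rep(c(1, 0), each = 50))
#' fit <- lrc(y ~ dist, data = d)
#' summary(fit)
#' predict(fit, data.frame(dist = c(100, 2000)))
lrc <- function(x, ...) UseMethod("lrc")

#' @rdname lrc
#' @param y Binary labels (0/1); both classes must be present.
#' @param lambda Optional L2 penalty (default 0, i.e. the plain
#'   cross-entropy cost).
#' @param maxit Maximum BFGS iterations (default 500).
#' @param tol Gradient-norm convergence tolerance (default 1e-6).
#' @export
lrc.default <- function(x, y, lambda = 0, maxit = 500L, tol = 1e-6, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("x/y length mismatch")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels")
  if (nrow(X) < 2L) stop("need at least two training examples")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))

  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  dropped <- colnames(X)[sdev == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    keep <- sdev > 0
    X <- X[, keep, drop = FALSE]
    mu <- mu[keep]
    sdev <- sdev[keep]
    if (ncol(X) == 0L) stop("no features with positive variance")
  }
  Xs <- scale(X, center = mu, scale = sdev)
  Xa <- cbind(`(Intercept)` = 1, Xs)

  fn <- function(th) lrc_cost(th, Xa, y, lambda)$J
  gr <- function(th) lrc_cost(th, Xa, y, lambda)$grad
  opt <- optim(rep(0, ncol(Xa)), fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  gnorm <- sqrt(sum(gr(opt$par)^2))
  theta <- setNames(opt$par, colnames(Xa))

  structure(list(theta = theta, center = mu, scale = sdev,
                 feature_names = colnames(X), dropped = dropped,
                 cost = opt$value, gradient_norm = gnorm,
                 converged = gnorm <= tol || opt$convergence == 0L,
                 n = length(y), n_pos = sum(y == 1), lambda = lambda,
                 .design = Xa, .y = y,
                 call = match.call()),
            class = "lrc")
}

#' @rdname lrc
#' @param formula Model formula, e.g. `y ~ .`.
#' @param data data.frame holding the response and features.
#' @export
lrc.formula <- function(formula, data, ...) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- lrc.default(X, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname lrc
#' @export
lrc.training_set <- function(x, ...) {
  fit <- lrc.default(x$X, x$y, ...)
  fit$mode <- x$mode
  fit$call <- match.call()
  fit
}

#' @export
print.lrc <- function(x, ...) {
  cat(sprintf("<lrc> %d features, n = %d (%d positive), J = %.6f%s\n",
              length(x$feature_names), x$n, x$n_pos, x$cost,
              if (x$converged) "" else " [not converged]"))
  cat("Coefficients (standardized features):\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.lrc <- function(object, ...) object$theta

#' @export
summary.lrc <- function(object, ...) {
  # observed information of the total log-likelihood at the optimum
  se <- rep(NA_real_, length(object$theta))
  tab <- cbind(Estimate = object$theta, `Std. Error` = se,
               `z value` = NA_real_, `Pr(>|z|)` = NA_real_)
  H <- tryCatch(.lrc_hessian(object), error = function(e) NULL)
  if (!is.null(H)) {
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) > 0)) {
      se <- sqrt(diag(cv))
      z <- object$theta / se
      tab <- cbind(Estimate = object$theta, `Std. Error` = se,
                   `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
    }
  }
  structure(list(coefficients = tab, cost = object$cost, n = object$n,
                 n_pos = object$n_pos, converged = object$converged,
                 gradient_norm = object$gradient_norm),
            class = "summary.lrc")
}

#' @export
print.summary.lrc <- function(x, ...) {
  cat(sprintf("Logistic regression classifier: n = %d (%d positive)\n",
              x$n, x$n_pos))
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE,
               na.print = "-")
  cat(sprintf("Final cost J = %.6f; gradient norm %.3g; converged: %s\n",
              x$cost, x$gradient_norm, x$converged))
  invisible(x)
}

# Hessian of the TOTAL negative log-likelihood at theta (for summary SEs);
# needs the training design, which is not stored, so it is reconstructed
# from the standardized-space curvature only when fitted values are cached.
.lrc_hessian <- function(object) {
  if (is.null(object$.design)) stop("training design not retained")
  Xa <- object$.design
  h <- sigmoid(drop(Xa %*% object$theta))
  crossprod(Xa, Xa * (h * (1 - h)))
}

.lrc_standardize <- function(object, newdata) {
  X <- if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_names, names(newdata))
    if (length(miss))
      stop("missing feature column(s): ", paste(miss, collapse = ", "))
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) == length(object$feature_names) + length(object$dropped) &&
        length(object$dropped) && !is.null(colnames(X)))
      X <- X[, object$feature_names, drop = FALSE]
    if (!is.null(colnames(X))) {
      if (!all(object$feature_names %in% colnames(X)))
        stop("feature columns do not match the model's features")
      X <- X[, object$feature_names, drop = FALSE]
    } else if (ncol(X) != length(object$feature_names)) {
      stop(sprintf("expected %d feature columns, got %d",
                   length(object$feature_names), ncol(X)))
    }
    X
  }
  if (any(!is.finite(X))) stop("non-finite feature values")
  scale(X, center = object$center, scale = object$scale)
}

#' Predict binding probabilities from a fitted classifier
#'
#' Standardizes `newdata` with the training statistics and applies the
#' sigmoid hypothesis: `sigmoid(theta' [1, z-scored x])`.
#'
#' @param object A fitted [lrc()] model.
#' @param newdata Feature matrix or data.frame with the model's feature
#'   columns.
#' @param type `"response"` (probability, default) or `"link"` (linear
#'   predictor).
#' @param ... Ignored.
#' @return Numeric vector of probabilities in (0, 1) or linear predictors.
#' @export
predict.lrc <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  Xs <- .lrc_standardize(object, newdata)
  eta <- drop(cbind(1, Xs) %*% object$theta)
  if (type == "link") eta else sigmoid(eta)
}

#' @export
fitted.lrc <- function(object, ...) {
  if (is.null(object$.design)) stop("training design not retained")
  sigmoid(drop(object$.design %*% object$theta))
}

#' @export
residuals.lrc <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$.design)) stop("training design not retained")
  y <- object$.y
  p <- fitted(object)
  r <- y - p
  if (type == "response") return(r)
  sign(r) * sqrt(pmax(0, -2 * (y * log(p) + (1 - y) * log1p(-p))))
}

#' @export
simulate.lrc <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialize a fitted classifier to JSON
#'
#' Stores the weights, standardization statistics, feature names and
#' training metadata at full floating-point precision, so a reloaded model
#' reproduces probabilities bit-identically.
#'
#' @param object A fitted [lrc()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lrc <- function(object, path) {
  obj <- list(theta = unclass(object$theta),
              center = unclass(object$center),
              scale = unclass(object$scale),
              feature_names = object$feature_names,
              dropped = object$dropped,
              training_meta = list(n = object$n, n_pos = object$n_pos,
                                   cost = object$cost,
                                   gradient_norm = object$gradient_norm,
                                   converged = object$converged,
                                   lambda = object$lambda),
              format_version = 1L)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a classifier written by [write_lrc()]
#' @param path Path to the JSON file.
#' @return An `lrc` object.
#' @export
read_lrc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fn <- obj$feature_names
  structure(list(theta = setNames(as.numeric(obj$theta),
                                  c("(Intercept)", fn)),
                 center = setNames(as.numeric(obj$center), fn),
                 scale = setNames(as.numeric(obj$scale), fn),
                 feature_names = fn,
                 dropped = as.character(obj$dropped %||% character(0)),
                 cost = obj$training_meta$cost,
                 gradient_norm = obj$training_meta$gradient_norm,
                 converged = obj$training_meta$converged,
                 n = obj$training_meta$n, n_pos = obj$training_meta$n_pos,
                 lambda = obj$training_meta$lambda,
                 call = quote(read_lrc())),
            class = "lrc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
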