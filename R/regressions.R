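#' Ordinary least squares linear and quadratic fits
#'
#' Wrappers around [stats::lm()] returning the quantities the bin-level
#' analyses report: coefficients, r-squared, the overall F-test p-value, and
#' AIC from the profiled Gaussian likelihood (k = coefficients + 1 for the
#' error variance), so that linear and quadratic fits on the same response
#' are AIC-comparable.
#'
#' @param x,y numeric vectors (finite; `n >= 3` for linear, `>= 4` for
#'   quadratic; `x` must vary).
#' @return object of class `"reg_fit"`: list with `kind`, `coefficients`
#'   (intercept, slope, and `x2` for the quadratic term), `r2`, `F`, `p`,
#'   `AIC`, `n`.
#' @export
#' @examples
#' f <- linfit(1:10, 2 * (1:10))
#' f$coefficients[["x"]]  # 2
linfit <- function(x, y) {
  .ols_fit(x, y, quadratic = FALSE)
}

#' @rdname linfit
#' @export
quadfit <- function(x, y) {
  .ols_fit(x, y, quadratic = TRUE)
}

.ols_fit <- function(x, y, quadratic) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("non-finite values in x or y", call. = FALSE)
  kmin <- if (quadratic) 4L else 3L
  if (length(x) < kmin) stop("need n >= ", kmin, call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  d <- data.frame(x = x, y = y)
  fit <- if (quadratic) stats::lm(y ~ x + I(x^2), data = d) else stats::lm(y ~ x, data = d)
  sm <- summary(fit)
  fs <- sm$fstatistic
  p <- if (is.null(fs)) NA_real_ else {
    stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  }
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", "x", if (quadratic) "x2")
  structure(list(kind = if (quadratic) "quadratic" else "linear",
                 coefficients = cf,
                 r2 = sm$r.squared,
                 F = if (is.null(fs)) NA_real_ else unname(fs[["value"]]),
                 p = unname(p),
                 AIC = stats::AIC(fit),
                 n = length(x)),
            class = "reg_fit")
}

#' @export
print.reg_fit <- function(x, ...) {
  cat(sprintf("%s OLS fit (n = %d): r2 = %.4f, F = %.4g, p = %.4g, AIC = %.4f\n",
              x$kind, x$n, x$r2, x$F, x$p, x$AIC))
  print(x$coefficients)
  invisible(x)
}

#' Compare two fits by AIC
#'
#' Lower AIC is preferred; an exact tie goes to the fit with fewer
#' coefficients. The fits must be on the same response (equal `n`).
#'
#' @param fit_a,fit_b `"reg_fit"` objects.
#' @return list with `preferred` (the winning fit's kind), `dAIC`
#'   (`AIC_a - AIC_b`).
#' @export
compare_aic <- function(fit_a, fit_b) {
  if (fit_a$n != fit_b$n) stop("fits have different n", call. = FALSE)
  d <- fit_a$AIC - fit_b$AIC
  pref <- if (d < 0) fit_a else if (d > 0) fit_b else {
    if (length(fit_a$coefficients) <= length(fit_b$coefficients)) fit_a else fit_b
  }
  list(preferred = pref$kind, dAIC = d)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `y ~ x` across the tips of a tree with error covariance proportional
#' to the lambda-scaled Brownian-motion matrix of the tree:
#' `V(lambda)` has BM off-diagonals multiplied by `lambda` and the BM
#' diagonal. `lambda = 1` is the Brownian default; `lambda = 0` reduces to
#' (diagonally weighted) OLS; `lambda = "ML"` profiles lambda over `[0, 1]`.
#' The slope p-value is a two-sided t test with `n - 2` degrees of freedom.
#'
#' @param phy a `"phylo"` object.
#' @param x,y per-tip predictor and response, named by tip label.
#' @param lambda a number in `[0, 1]` or `"ML"`.
#' @return object of class `"pgls_fit"`: list with `coefficients`, `se`,
#'   `t`, `p` (slope), `r2` (GLS), `lambda`, `lnL`, `n`.
#' @export
pgls <- function(phy, x, y, lambda = 1) {
  x <- .match_trait(phy, x)
  y <- .match_trait(phy, y)
  n <- length(y)
  if (n < 5L) stop("pgls needs >= 5 tips", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  C <- ape::vcv.phylo(phy)
  gls_at <- function(lam) {
    V <- lam * C
    diag(V) <- diag(C)
    U <- tryCatch(chol(V), error = function(e) {
      stop("singular phylogenetic covariance in pgls", call. = FALSE)
    })
    X <- cbind(intercept = 1, x = x)
    Xw <- backsolve(U, X, transpose = TRUE)
    yw <- backsolve(U, y, transpose = TRUE)
    qr_x <- qr(Xw)
    if (qr_x$rank < 2L) stop("singular design in pgls", call. = FALSE)
    beta <- qr.coef(qr_x, yw)
    res <- yw - Xw %*% beta
    rss <- sum(res^2)
    # profiled Gaussian lnL for lambda selection
    s2ml <- rss / n
    lnl <- -0.5 * (n * (log(2 * pi * s2ml) + 1) + 2 * sum(log(diag(U))))
    list(beta = beta, rss = rss, U = U, Xw = Xw, yw = yw, lnl = lnl)
  }
  if (identical(lambda, "ML")) {
    f <- function(l) gls_at(l)$lnl
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    lambda <- cand[which.max(c(opt$objective, f(0), f(1)))]
  }
  stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  g <- gls_at(lambda)
  s2 <- g$rss / (n - 2)
  XtX_inv <- chol2inv(qr.R(qr(g$Xw)))
  se <- sqrt(diag(XtX_inv) * s2)
  tval <- as.numeric(g$beta) / se
  p_slope <- 2 * stats::pt(abs(tval[2]), df = n - 2, lower.tail = FALSE)
  # GLS r2 against the intercept-only GLS fit
  onew <- backsolve(g$U, rep(1, n), transpose = TRUE)
  mu <- sum(onew * g$yw) / sum(onew^2)
  tss <- sum((g$yw - mu * onew)^2)
  structure(list(coefficients = stats::setNames(as.numeric(g$beta),
                                                c("intercept", "x")),
                 se = stats::setNames(se, c("intercept", "x")),
                 t = stats::setNames(tval, c("intercept", "x")),
                 p = unname(p_slope),
                 r2 = 1 - g$rss / tss,
                 lambda = lambda,
                 lnL = g$lnl,
                 n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d, lambda = %.3f): slope = %.4g, p = %.4g, r2 = %.4f\n",
              x$n, x$lambda, x$coefficients[["x"]], x$p, x$r2))
  invisible(x)
}
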