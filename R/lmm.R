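# Null linear mixed model for kinship-adjusted score tests.
#
# Model: y = X b + g + e, g ~ N(0, sigma2_g * A), e ~ N(0, sigma2_e * I),
# where A is the GRM on the 2x-kinship scale (unit diagonal for outbred
# samples). Variance components are estimated by REML via a spectral
# decomposition of A and a 1-D profile search over the heritability ratio
# h2 = sigma2_g / (sigma2_g + sigma2_e).

#' Precompute the spectral decomposition of a kinship matrix
#'
#' Repeated null-model fits against the same kinship (e.g. across traits or
#' simulation replicates) can share this decomposition.
#' @param kinship a `kinship_matrix` or plain symmetric matrix (GRM scale).
#' @return list(U, lambda) with eigenvalues clipped at zero.
#' @export
kinship_eigen <- function(kinship) {
  A <- if (inherits(kinship, "kinship_matrix")) kinship$matrix else kinship
  if (!isSymmetric(unname(A), tol = 1e-8)) {
    A <- (A + t(A)) / 2
  }
  e <- eigen(A, symmetric = TRUE)
  # mildly negative eigenvalues (e.g. from a replaced self-kinship
  # diagonal) are clipped; structural indefiniteness is an error
  if (min(e$values) < -0.05 * max(abs(e$values))) {
    stop("kinship matrix is not positive semi-definite; ",
         "consider projecting to the nearest PSD matrix or adding a ridge",
         call. = FALSE)
  }
  list(U = e$vectors, lambda = pmax(e$values, 0))
}

#' Fit the null mixed model by REML
#'
#' Restricted maximum likelihood estimation of the polygenic and residual
#' variance components by spectral decomposition of the kinship matrix and
#' Brent search over the heritability ratio. With a zero kinship matrix the
#' fit reduces exactly to ordinary least squares.
#'
#' @param trait numeric response vector.
#' @param covariates optional covariate matrix or data.frame (an intercept
#'   is always added).
#' @param kinship a `kinship_matrix` or plain matrix on the GRM (2x kinship)
#'   scale; `NULL` for unrelated samples.
#' @param eig optional precomputed [kinship_eigen()] of `kinship`.
#' @return object of class `null_lmm` with REML estimates `sigma2_g`,
#'   `sigma2_e`, heritability ratio `h2`, fixed effects and the rotated-basis
#'   quantities needed by the score tests.
#' @export
fit_null_lmm <- function(trait, covariates = NULL, kinship = NULL,
                         eig = NULL) {
  y <- as.numeric(trait)
  n <- length(y)
  if (anyNA(y)) stop("trait contains missing values; complete cases only",
                     call. = FALSE)
  if (n < 30L) stop("need at least 30 complete-case samples", call. = FALSE)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariates misaligned with trait", call. = FALSE)
    if (any(apply(C, 2, stats::sd) == 0)) {
      stop("constant covariate supplied", call. = FALSE)
    }
    X <- cbind(X, C)
  }
  p <- ncol(X)

  if (is.null(kinship) && is.null(eig)) {
    eig <- list(U = diag(n), lambda = rep(0, n))
  } else if (is.null(eig)) {
    A <- if (inherits(kinship, "kinship_matrix")) kinship$matrix else kinship
    if (nrow(A) != n) stop("kinship misaligned with samples", call. = FALSE)
    eig <- kinship_eigen(kinship)
  }
  U <- eig$U; lam <- eig$lambda
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  neg2_reml <- function(h2) {
    delta <- h2 * lam + (1 - h2)
    w <- 1 / delta
    XtWX <- crossprod(Xt * w, Xt)
    b <- solve(XtWX, crossprod(Xt, w * yt))
    rss <- sum(w * (yt - Xt %*% b)^2)
    (n - p) * log(rss) + sum(log(delta)) +
      determinant(XtWX, logarithm = TRUE)$modulus[1]
  }
  if (all(lam == 0)) {
    h2 <- 0
  } else {
    opt <- stats::optimize(neg2_reml, c(0, 1 - 1e-6), tol = 1e-9)
    h2 <- opt$minimum
    # flatten to the boundary when the profile is flat there
    if (neg2_reml(0) <= opt$objective + 1e-9) h2 <- 0
    if (h2 > 1 - 1e-4 &&
        neg2_reml(1 - 1e-6) <= opt$objective + 1e-9) {
      h2 <- 1 - 1e-6
      warning("REML estimate at the h2 boundary", call. = FALSE)
    }
  }
  delta <- h2 * lam + (1 - h2)
  w <- 1 / delta
  XtWX <- crossprod(Xt * w, Xt)
  XtWX_inv <- solve(XtWX)
  b <- drop(XtWX_inv %*% crossprod(Xt, w * yt))
  resid_t <- drop(yt - Xt %*% b)
  sigma2_tot <- sum(w * resid_t^2) / (n - p)

  fit <- structure(list(
    n = n, p = p, coefficients = stats::setNames(b, colnames(X)),
    h2 = h2, sigma2_g = h2 * sigma2_tot, sigma2_e = (1 - h2) * sigma2_tot,
    sigma2_tot = sigma2_tot,
    U = U, lambda = lam, delta = delta, w = w,
    Xt = Xt, yt = yt, resid_t = resid_t, XtWX_inv = XtWX_inv,
    X = X, y = y,
    reml_neg2 = if (all(lam == 0)) neg2_reml(0) else neg2_reml(h2)
  ), class = "null_lmm")
  fit
}

# P-operator pieces in the rotated basis, for a matrix of genotype columns.
# Returns list(score = t(G) %*% P %*% y, Phi = t(G) %*% P %*% G).
p_operator <- function(fit, G) {
  Gt <- crossprod(fit$U, G)
  wGt <- Gt * fit$w
  s2 <- fit$sigma2_tot
  GtWX <- crossprod(wGt, fit$Xt)
  score <- drop(crossprod(wGt, fit$resid_t)) / s2
  Phi <- (crossprod(wGt, Gt) - GtWX %*% tcrossprod(fit$XtWX_inv, GtWX)) / s2
  list(score = score, Phi = (Phi + t(Phi)) / 2)
}

#' @export
print.null_lmm <- function(x, ...) {
  cat("<null_lmm> REML kinship mixed model\n")
  cat(sprintf("  n = %d, fixed effects = %d\n", x$n, x$p))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f (h2 = %.3f)\n",
              x$sigma2_g, x$sigma2_e, x$h2))
  invisible(x)
}

#' @export
summary.null_lmm <- function(object, ...) {
  se <- sqrt(diag(object$XtWX_inv) * object$sigma2_tot)
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, h2 = object$h2,
              sigma2_g = object$sigma2_g, sigma2_e = object$sigma2_e,
              n = object$n)
  class(out) <- "summary.null_lmm"
  out
}

#' @export
print.summary.null_lmm <- function(x, ...) {
  cat("Kinship-adjusted null mixed model (REML)\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nVariance components: sigma2_g = %.4f, sigma2_e = %.4f, h2 = %.3f (n = %d)\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$n))
  invisible(x)
}

#' @export
coef.null_lmm <- function(object, ...) object$coefficients

#' @export
residuals.null_lmm <- function(object, ...) {
  drop(object$y - object$X %*% object$coefficients)
}

#' @export
fitted.null_lmm <- function(object, ...) {
  drop(object$X %*% object$coefficients)
}

#' @export
predict.null_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  X <- cbind(1, as.matrix(newdata))
  drop(X %*% object$coefficients)
}

#' @export
logLik.null_lmm <- function(object, ...) {
  ll <- -0.5 * object$reml_neg2
  attr(ll, "df") <- object$p + 2
  class(ll) <- "logLik"
  ll
}

#' @export
simulate.null_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    n <- object$n
    sd_t <- sqrt(object$sigma2_tot * object$delta)
    mu <- fitted(object)
    out <- replicate(nsim, mu + drop(object$U %*% stats::rnorm(n, sd = sd_t)))
    as.data.frame(out)
  })
}
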