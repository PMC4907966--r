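#' Mean-center a calibration set
#'
#' Subtracts the channelwise mean spectrum and the mean concentration —
#' the only pretreatment applied before latent-variable extraction (no
#' variance scaling).
#'
#' @param X Matrix of spectra, one row per calibration sample.
#' @param y Concentration vector (mg/L), one per row of `X`.
#'
#' @return List with `Xc`, `yc`, `x_mean`, `y_mean`.
#' @export
mean_center <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    stop("need at least 2 calibration rows to center", call. = FALSE)
  }
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  list(Xc = sweep(X, 2, x_mean), yc = y - y_mean,
       x_mean = x_mean, y_mean = y_mean)
}

# solve M s = q; pseudo-inverse with relative singular-value cutoff 1e-10
# when M is numerically singular
.solve_or_pinv <- function(M, q) {
  s <- tryCatch(solve(M, q), error = function(e) NULL)
  if (!is.null(s) && all(is.finite(s))) return(s)
  sv <- svd(M)
  keep <- sv$d > 1e-10 * max(sv$d)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], q)) / sv$d[keep]))
}

# NIPALS PLS1 on an already-centered (Xc, yc).
# Per component: w = X'y/||X'y||; t = Xw; p = X't/t't; q = y't/t't;
# deflate X <- X - t p', y <- y - q t. Stops early (with a flag) when the
# residual covariance ||X'y|| vanishes relative to the initial scale.
.nipals_pls1 <- function(Xc, yc, ncomp) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  W <- matrix(0, p, 0)
  P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  scale0 <- sqrt(sum(Xc^2)) * sqrt(sum(yc^2))
  tol <- 1e-12 * max(scale0, .Machine$double.eps)
  X <- Xc
  y <- yc
  early <- FALSE
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw <= tol) {
      early <- TRUE
      break
    }
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    if (tt <= tol^2) {
      early <- TRUE
      break
    }
    pv <- drop(crossprod(X, t)) / tt
    qa <- sum(y * t) / tt
    X <- X - tcrossprod(t, pv)
    y <- y - qa * t
    W <- cbind(W, w)
    P <- cbind(P, pv)
    Tm <- cbind(Tm, t)
    q <- c(q, qa)
  }
  list(W = W, P = P, q = q, scores = Tm, ncomp = ncol(W),
       early_stop = early)
}

# regression coefficient using the first `a` latent variables:
# b = W (P'W)^-1 q  (P'W is unit upper triangular for PLS1)
.pls_coef <- function(dec, a = dec$ncomp) {
  if (a < 1L) return(NULL)
  W <- dec$W[, seq_len(a), drop = FALSE]
  P <- dec$P[, seq_len(a), drop = FALSE]
  drop(W %*% .solve_or_pinv(crossprod(P, W), dec$q[seq_len(a)]))
}

#' Choose the number of latent variables by leave-one-out cross-validation
#'
#' Each calibration row (one averaged sample spectrum) is left out in turn;
#' the model refitted on the rest predicts it, for every candidate component
#' count up to `max_ncomp`. The selected count minimizes RMSECV, with ties
#' broken toward the smaller (more parsimonious) model.
#'
#' @param X Calibration matrix (rows = samples).
#' @param y Concentration vector (mg/L).
#' @param max_ncomp Largest candidate count; capped at
#'   `min(nrow(X) - 2, ncol(X))`.
#'
#' @return List with `ncomp` (the selection) and `rmsecv` (the full RMSECV
#'   curve over 1..max_ncomp).
#' @export
select_ncomp_cv <- function(X, y, max_ncomp = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) {
    stop("leave-one-out selection needs at least 3 rows", call. = FALSE)
  }
  max_ncomp <- min(max_ncomp, n - 2L, ncol(X))
  preds <- matrix(NA_real_, n, max_ncomp)
  for (i in seq_len(n)) {
    mc <- mean_center(X[-i, , drop = FALSE], y[-i])
    dec <- .nipals_pls1(mc$Xc, mc$yc, max_ncomp)
    xc_new <- X[i, ] - mc$x_mean
    for (a in seq_len(max_ncomp)) {
      aa <- min(a, dec$ncomp)
      preds[i, a] <- if (aa < 1L) {
        mc$y_mean
      } else {
        sum(xc_new * .pls_coef(dec, aa)) + mc$y_mean
      }
    }
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  best <- min(rmsecv)
  # counts whose RMSECV is numerically indistinguishable from the minimum
  # (relative to the response scale) tie; ties go to the smaller model
  tie_tol <- max(1e-12, 1e-9 * best, 1e-10 * stats::sd(y))
  ncomp <- which(rmsecv <= best + tie_tol)[1]
  list(ncomp = ncomp, rmsecv = rmsecv)
}

#' Fit a PLS1 calibration model to spectra
#'
#' From-scratch univariate-response partial least squares regression by the
#' NIPALS algorithm. Spectra and concentrations are mean-centered; latent
#' variables are extracted in sequence, each one the unit direction of the
#' deflated spectra matrix maximizing covariance with the (deflated)
#' concentrations; the regression coefficient `b` maps a centered spectrum
#' to a concentration, and a prediction is `(x - x_mean) . b + y_mean`.
#'
#' @param x A `feature_matrix` from [extract_windows()] (then `y` is taken
#'   from it), or a plain matrix with one spectrum per row.
#' @param y Concentration vector (mg/L); ignored when `x` is a
#'   `feature_matrix`.
#' @param ncomp Number of latent variables. When `NULL` (default) it is
#'   chosen by [select_ncomp_cv()].
#' @param max_ncomp Cap on the candidate component counts.
#'
#' @return An object of class `sers_plsr` with components `coefficients`
#'   (b), `x_mean`, `y_mean`, `weights` (W, unit columns), `loadings` (P),
#'   `y_loadings` (q), `scores` (T), `ncomp`, `rmsecv` (when CV-selected),
#'   `fitted.values`, `residuals`, plus the window/channel metadata needed
#'   to check prediction inputs.
#' @seealso [predict.sers_plsr()], [select_ncomp_cv()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X[, 2] * 3 + rnorm(10, sd = 0.01)
#' fit <- plsr_fit(X, y, ncomp = 2)
#' coef(fit)
#' @export
plsr_fit <- function(x, y = NULL, ncomp = NULL, max_ncomp = 10) {
  cl <- match.call()
  wavenumbers <- NULL
  windows <- NULL
  target <- NULL
  sample_ids <- NULL
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    wavenumbers <- x$wavenumbers
    windows <- x$windows
    target <- x$target
    sample_ids <- x$sample_ids
    X <- x$X
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop("`y` is required when `x` is a matrix", call. = FALSE)
  }
  if (nrow(X) < 2L) stop("need at least 2 calibration rows", call. = FALSE)
  a_cap <- min(nrow(X) - 1L, ncol(X))
  rmsecv <- NULL
  if (is.null(ncomp)) {
    sel <- select_ncomp_cv(X, y, max_ncomp)
    ncomp <- sel$ncomp
    rmsecv <- sel$rmsecv
  }
  if (ncomp < 1L || ncomp > a_cap) {
    stop("`ncomp` must lie in [1, ", a_cap, "]", call. = FALSE)
  }
  mc <- mean_center(X, y)
  dec <- .nipals_pls1(mc$Xc, mc$yc, ncomp)
  if (dec$ncomp < 1L) {
    stop("spectra carry no covariance with the response; nothing to fit",
         call. = FALSE)
  }
  b <- .pls_coef(dec)
  fitted <- drop(mc$Xc %*% b) + mc$y_mean
  structure(list(coefficients = b,
                 x_mean = mc$x_mean, y_mean = mc$y_mean,
                 weights = dec$W, loadings = dec$P, y_loadings = dec$q,
                 scores = dec$scores,
                 ncomp = dec$ncomp, ncomp_requested = ncomp,
                 early_stop = dec$early_stop,
                 rmsecv = rmsecv,
                 fitted.values = fitted, residuals = y - fitted, y = y,
                 wavenumbers = wavenumbers, windows = windows,
                 target = target, sample_ids = sample_ids,
                 call = cl),
            class = "sers_plsr")
}

#' Predict concentrations from a fitted calibration model
#'
#' A prediction is the centered spectrum times the regression coefficient
#' plus the mean calibration concentration; predictions are not clipped at
#' zero, so blanks may come out slightly negative.
#'
#' @param object A `sers_plsr` fit.
#' @param newdata A matrix of spectra restricted to the model's channels, a
#'   `feature_matrix`, or a full `spectrum_set` (restricted internally using
#'   the model's windows).
#' @param ... Unused.
#'
#' @return Numeric vector of predicted concentrations (mg/L).
#' @export
predict.sers_plsr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "spectrum_set")) {
    if (is.null(object$windows)) {
      stop("model carries no window definition; supply restricted spectra",
           call. = FALSE)
    }
    newdata <- extract_windows(newdata, object$windows, object$target)
  }
  wn <- NULL
  if (inherits(newdata, "feature_matrix")) {
    wn <- newdata$wavenumbers
    Xn <- newdata$X
  } else {
    Xn <- as.matrix(newdata)
    if (!is.null(colnames(Xn))) wn <- as.numeric(colnames(Xn))
  }
  p <- length(object$coefficients)
  if (ncol(Xn) != p) {
    stop("channel mismatch: model has ", p, " channels, input has ",
         ncol(Xn), call. = FALSE)
  }
  if (!is.null(wn) && !is.null(object$wavenumbers) &&
      !isTRUE(all.equal(wn, object$wavenumbers))) {
    bad <- which(wn != object$wavenumbers)[1]
    stop("channel mismatch at position ", bad, ": model expects ",
         object$wavenumbers[bad], " cm^-1, input has ", wn[bad], " cm^-1",
         call. = FALSE)
  }
  drop(sweep(Xn, 2, object$x_mean) %*% object$coefficients) + object$y_mean
}

#' @export
coef.sers_plsr <- function(object, ...) object$coefficients

#' @export
fitted.sers_plsr <- function(object, ...) object$fitted.values

#' @export
residuals.sers_plsr <- function(object, ...) object$residuals

#' @export
print.sers_plsr <- function(x, ...) {
  cat("PLS1 calibration model",
      if (!is.null(x$target)) paste0("for ", x$target) else "", "\n")
  cat("  latent variables:", x$ncomp,
      if (x$early_stop) "(early stop: residual covariance vanished)" else "",
      "\n")
  cat("  channels:", length(x$coefficients), "\n")
  cat(sprintf("  calibration RMSE: %.4g mg/L, R^2: %.4f\n",
              rmse(x$fitted.values, x$y),
              r_squared(x$fitted.values, x$y)))
  invisible(x)
}

#' @export
summary.sers_plsr <- function(object, ...) {
  out <- list(ncomp = object$ncomp,
              nchan = length(object$coefficients),
              target = object$target,
              cal_rmse = rmse(object$fitted.values, object$y),
              cal_r2 = r_squared(object$fitted.values, object$y),
              rmsecv = object$rmsecv,
              early_stop = object$early_stop)
  class(out) <- "summary.sers_plsr"
  out
}

#' @export
print.summary.sers_plsr <- function(x, ...) {
  cat("PLS1 calibration summary",
      if (!is.null(x$target)) paste0("(target ", x$target, ")") else "", "\n")
  cat("  channels:", x$nchan, "  latent variables:", x$ncomp, "\n")
  cat(sprintf("  calibration: R^2 = %.4f, RMSE = %.4g mg/L\n",
              x$cal_r2, x$cal_rmse))
  if (!is.null(x$rmsecv)) {
    cat("  RMSECV by component count:\n")
    print(round(stats::setNames(x$rmsecv, seq_along(x$rmsecv)), 4))
  }
  invisible(x)
}

#' Diagnostic plots for a fitted calibration model
#'
#' Predicted-versus-actual concentrations for the calibration set and, when
#' the component count was cross-validated, the RMSECV curve.
#'
#' @param x A `sers_plsr` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sers_plsr <- function(x, ...) {
  has_cv <- !is.null(x$rmsecv)
  if (has_cv) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  graphics::plot(x$y, x$fitted.values,
                 xlab = "actual concentration (mg/L)",
                 ylab = "predicted concentration (mg/L)",
                 main = "Calibration", ...)
  graphics::abline(0, 1, lty = 2)
  if (has_cv) {
    graphics::plot(seq_along(x$rmsecv), x$rmsecv, type = "b",
                   xlab = "latent variables", ylab = "RMSECV (mg/L)",
                   main = "Component selection")
    graphics::abline(v = x$ncomp, lty = 3)
  }
  invisible(x)
}
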