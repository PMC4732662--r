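#' Fit the RR-BLUP mixed model by REML
#'
#' Model: `y = W beta + X a + e` with intercept (and optional fixed
#' covariates) in `W`, marker effects `a_j ~ N(0, sigma2_a)` sharing one
#' common variance (`sigma2_a = sigma2_G / N_m`) and residuals
#' `e ~ N(0, sigma2_e I)`. Writing `K = X X'` and `delta = sigma2_e /
#' sigma2_a`, the restricted likelihood is profiled over the single ratio
#' `delta` using the spectral decomposition of `K` projected onto the
#' complement of the fixed-effect space (an N x N eigenproblem, efficient
#' when lines are far fewer than markers). Given the REML `delta`, fixed
#' effects are estimated by GLS and marker effects by their BLUP
#' `a = X' (K + delta I)^{-1} (y - W beta_hat)` — identical to ridge
#' regression with penalty `lambda = delta`.
#'
#' @param y numeric response per line (GCA values or BLUEs).
#' @param X genotype matrix for those lines ([genotype_matrix()] or numeric
#'   matrix, imputed, rows aligned to `y`).
#' @param covariates optional numeric matrix of fixed covariates (one row per
#'   line); an intercept is always added.
#' @return object of class `rrblup_model`: `mu`, `beta` (covariate
#'   coefficients, `NULL` if none), `effects` (named per-marker BLUPs),
#'   `sigma2_a`, `sigma2_e`, `lambda` (`= sigma2_e / sigma2_a`),
#'   `reml_loglik`, `marker_ids`, `covariate_names`.
#' @export
fit_rrblup <- function(y, X, covariates = NULL) {
  Xm <- coded_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  abort_if(nrow(Xm) != n, "rows of X (%d) do not match length of y (%d)",
           nrow(Xm), n)
  abort_if(n < 3, "need at least 3 lines")
  abort_if(anyNA(Xm) || anyNA(y), "X and y must be fully observed")
  abort_if(var(y) == 0, "constant y: no genetic variance to model")

  W <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    abort_if(nrow(covariates) != n, "covariate rows do not match y")
    W <- cbind(W, covariates)
  }
  p <- ncol(W)
  abort_if(qr(W)$rank < p, "rank-deficient fixed-effect design")

  K <- tcrossprod(Xm)
  # restricted likelihood on the complement of the fixed-effect space;
  # decomposing S(K + I)S (instead of SKS) keeps the fixed-effect null space
  # out of the retained eigenvectors: its eigenvalues are exactly 0 while
  # every complement direction gets eigenvalue xi + 1 >= 1
  S <- diag(n) - W %*% solve(crossprod(W), t(W))
  SKS <- S %*% (K + diag(n)) %*% S
  SKS <- (SKS + t(SKS)) / 2
  ee <- eigen(SKS, symmetric = TRUE)
  q <- n - p
  xi <- pmax(ee$values[seq_len(q)] - 1, 0)
  U <- ee$vectors[, seq_len(q), drop = FALSE]
  eta <- drop(crossprod(U, y))

  reml <- function(logd) {
    d <- exp(logd)
    r <- sum(eta^2 / (xi + d))
    0.5 * (q * log(q / (2 * pi)) - q - q * log(r) - sum(log(xi + d)))
  }
  opt <- optimize(reml, interval = c(-10, 10), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)

  sigma2_a <- sum(eta^2 / (xi + delta)) / q
  sigma2_e <- delta * sigma2_a

  H <- K + delta * diag(n)
  Hi_y <- solve(H, cbind(y, W))
  WtHiW <- crossprod(W, Hi_y[, -1, drop = FALSE])
  beta <- solve(WtHiW, crossprod(W, Hi_y[, 1]))
  resid <- y - W %*% beta
  effects <- drop(crossprod(Xm, solve(H, resid)))
  names(effects) <- colnames(Xm)

  structure(list(mu = beta[1],
                 beta = if (p > 1) setNames(beta[-1], colnames(W)[-1]) else NULL,
                 effects = effects,
                 sigma2_a = sigma2_a,
                 sigma2_e = sigma2_e,
                 lambda = delta,
                 reml_loglik = opt$objective,
                 marker_ids = colnames(Xm),
                 covariate_names = if (p > 1) colnames(W)[-1] else NULL),
            class = "rrblup_model")
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf(paste0("<rrblup_model> %d markers; sigma2_a = %.4g, ",
                     "sigma2_e = %.4g, lambda = %.4g\n"),
              length(x$effects), x$sigma2_a, x$sigma2_e, x$lambda))
  invisible(x)
}

#' Predict line performance from a fitted RR-BLUP model
#'
#' `y_hat = mu + W_new beta + X_new a`. Marker columns of `X_new` are matched
#' to the model's marker ids by name (order-corrected); missing markers are
#' an error.
#'
#' @param object an `rrblup_model`.
#' @param X_new genotype matrix of the lines to predict.
#' @param covariates_new covariate matrix matching the model's covariates.
#' @param ... unused.
#' @return a data frame with `line_id` and `predicted`.
#' @export
predict.rrblup_model <- function(object, X_new, covariates_new = NULL, ...) {
  Xm <- coded_matrix(X_new)
  if (!is.null(colnames(Xm))) {
    missing_ids <- setdiff(object$marker_ids, colnames(Xm))
    abort_if(length(missing_ids) > 0, "missing marker columns: %s",
             paste(utils::head(missing_ids, 5), collapse = ", "))
    Xm <- Xm[, object$marker_ids, drop = FALSE]
  } else {
    abort_if(ncol(Xm) != length(object$effects),
             "X_new has %d markers, model has %d", ncol(Xm),
             length(object$effects))
  }
  pred <- drop(object$mu + Xm %*% object$effects)
  if (!is.null(object$beta)) {
    abort_if(is.null(covariates_new),
             "model has covariates; supply covariates_new")
    covariates_new <- as.matrix(covariates_new)
    pred <- pred + drop(covariates_new %*% object$beta)
  }
  data.frame(line_id = if (is.null(rownames(Xm)))
               sprintf("line%d", seq_len(nrow(Xm))) else rownames(Xm),
             predicted = pred,
             stringsAsFactors = FALSE)
}

#' Ridge regression with a fixed penalty (closed form)
#'
#' Exact solution of `min ||y - 1 mu - X a||^2 + lambda ||a||^2` with an
#' unpenalised intercept, computed in line space via the kernel form on
#' column-centred `X`. No variance estimation. Serves as an algebraic
#' cross-check for [fit_rrblup()] at its converged `lambda`.
#'
#' @param y numeric response.
#' @param X genotype matrix (rows aligned to `y`).
#' @param lambda ridge penalty, `> 0`.
#' @return list with `mu` and `effects`.
#' @export
ridge_fixed_lambda <- function(y, X, lambda) {
  abort_if(!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0,
           "lambda must be a single positive number")
  Xm <- coded_matrix(X)
  y <- as.numeric(y)
  abort_if(nrow(Xm) != length(y), "rows of X do not match y")
  xbar <- colMeans(Xm)
  Xc <- sweep(Xm, 2, xbar)
  yc <- y - mean(y)
  n <- length(y)
  a <- drop(crossprod(Xc, solve(tcrossprod(Xc) + lambda * diag(n), yc)))
  names(a) <- colnames(Xm)
  list(mu = mean(y) - sum(xbar * a), effects = a)
}

#' Serialize / restore an RR-BLUP model as JSON
#'
#' @param model an `rrblup_model`.
#' @param path output JSON path.
#' @export
write_rrblup_model <- function(model, path) {
  stopifnot(inherits(model, "rrblup_model"))
  jsonlite::write_json(
    list(mu = model$mu,
         beta = as.list(model$beta),
         effects = as.list(model$effects),
         sigma2_a = model$sigma2_a, sigma2_e = model$sigma2_e,
         lambda = model$lambda, reml_loglik = model$reml_loglik,
         marker_ids = model$marker_ids,
         covariate_names = model$covariate_names),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rrblup_model
#' @export
read_rrblup_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = j$mu,
                 beta = if (length(j$beta)) unlist(j$beta) else NULL,
                 effects = unlist(j$effects),
                 sigma2_a = j$sigma2_a, sigma2_e = j$sigma2_e,
                 lambda = j$lambda, reml_loglik = j$reml_loglik,
                 marker_ids = j$marker_ids,
                 covariate_names = j$covariate_names),
            class = "rrblup_model")
}
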