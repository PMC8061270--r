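#' Assemble the pairwise regression table
#'
#' One row per unordered locale pair, with the genetic distance response
#' (pairwise FST or cGD), the geographic distance covariate, and one
#' predictor per supplied per-pair landscape summary. Predictors are
#' z-score standardized (standardization parameters are recorded for
#' back-transformation); the response stays on its natural scale.
#' Zero-variance predictors are dropped with a warning. Rows with a
#' missing response are not allowed.
#'
#' @param genetic symmetric locale x locale response matrix (e.g. from
#'   [pairwise_fst_matrix()] or [cgd_matrix()]).
#' @param geo symmetric geographic-distance matrix on the same locales.
#' @param layer_summaries named list of additional symmetric predictor
#'   matrices on the same locales (e.g. per-pair transect means from
#'   [pair_stat_matrix()] via [edge_resistance_summary()]).
#' @return data.frame of class `pair_table` with columns locale_a,
#'   locale_b, response, geo, and one column per layer summary; attribute
#'   `scaling` records each predictor's centre/sd.
#' @export
build_pair_table <- function(genetic, geo, layer_summaries = list()) {
  ids <- rownames(genetic)
  if (is.null(ids)) stop_popland("response matrix needs locale dimnames")
  check <- function(m, nm) {
    if (!identical(rownames(m), ids))
      stop_popland("locale set mismatch in predictor '%s'", nm)
    m
  }
  geo <- check(geo, "geo")
  layer_summaries <- if (length(layer_summaries))
    mapply(check, layer_summaries, names(layer_summaries), SIMPLIFY = FALSE)
  else list()
  k <- length(ids)
  idx <- pair_index(k)
  resp <- genetic[idx]
  if (anyNA(resp) || any(!is.finite(resp)))
    stop_popland("missing response rows: response must be defined for every pair")
  df <- data.frame(locale_a = ids[idx[, 1]], locale_b = ids[idx[, 2]],
                   response = resp)
  preds <- c(list(geo = geo), layer_summaries)
  scaling <- list()
  for (nm in names(preds)) {
    v <- preds[[nm]][idx]
    if (anyNA(v)) stop_popland("missing pair summaries in predictor '%s'", nm)
    s <- stats::sd(v)
    if (s == 0) {
      warning(sprintf("predictor '%s' has zero variance; dropped", nm))
      next
    }
    scaling[[nm]] <- c(center = mean(v), sd = s)
    df[[nm]] <- (v - mean(v)) / s
  }
  structure(df, scaling = scaling, class = c("pair_table", "data.frame"))
}

# Indicator matrix A over pair rows: A[r, s] = 1 iff rows r and s share
# exactly one locale. Built from pair membership.
pair_sharing_matrix <- function(table) {
  mem <- cbind(table$locale_a, table$locale_b)
  n <- nrow(mem)
  ids <- sort(unique(as.vector(mem)))
  z <- matrix(0, n, length(ids))
  z[cbind(seq_len(n), match(mem[, 1], ids))] <- 1
  z[cbind(seq_len(n), match(mem[, 2], ids))] <- 1
  shared <- tcrossprod(z)       # number of shared locales between rows
  a <- (shared == 1) * 1
  diag(a) <- 0
  a
}

#' Fit an MLPE distance-matrix regression
#'
#' Gaussian maximum likelihood for a pairwise-distance response with the
#' maximum-likelihood-population-effects covariance: V[r, s] = sigma^2 *
#' (1\{r = s\} + rho * 1\{rows r, s share exactly one locale\}). The
#' pair-sharing correlation rho corrects the nonindependence of distance
#' matrices (every locale appears in K - 1 rows). The likelihood is
#' profiled over rho using one eigendecomposition of the sharing matrix;
#' sigma^2 and the coefficients are closed-form GLS given rho. ML (not
#' REML) is used so AIC comparisons across fixed-effect structures are
#' valid. Positive definiteness bounds rho strictly below
#' -1/min(eigenvalue); for a complete pair table this is 1/2.
#'
#' @param table a `pair_table`.
#' @param predictors character vector of predictor columns (default: all
#'   non-membership columns except the response).
#' @param rho fix the pair correlation instead of estimating it (e.g.
#'   `rho = 0` reduces the fit to ordinary least squares).
#' @return object of class `mlpe_fit`: coefficients (intercept first),
#'   rho, sigma2, logLik, aic (2k - 2 logLik counting coefficients, rho
#'   when estimated, and sigma^2), pseudo_r2 (squared Pearson correlation
#'   of fitted vs observed), fitted, residuals, n, predictors.
#' @export
fit_mlpe <- function(table, predictors = NULL, rho = NULL) {
  stopifnot(inherits(table, "pair_table"))
  predictors <- predictors %||%
    setdiff(names(table), c("locale_a", "locale_b", "response"))
  if (!all(predictors %in% names(table)))
    stop_popland("unknown predictors: %s",
                 paste(setdiff(predictors, names(table)), collapse = ", "))
  y <- table$response
  n <- length(y)
  x <- cbind(`(Intercept)` = 1,
             as.matrix(table[, predictors, drop = FALSE]))
  if (n < ncol(x) + 3) stop_popland("need at least predictors + 3 rows")
  if (qr(x)$rank < ncol(x)) stop_popland("singular design matrix")
  a <- pair_sharing_matrix(table)
  ea <- eigen(a, symmetric = TRUE)
  lam <- ea$values
  qty <- crossprod(ea$vectors, y)
  qtx <- crossprod(ea$vectors, x)
  # profile log-likelihood in rho: GLS with V0 = I + rho * A diagonalized
  prof <- function(r) {
    d <- 1 + r * lam
    if (any(d <= 1e-12)) return(list(ll = -Inf))
    w <- 1 / d
    xtvx <- crossprod(qtx, qtx * w)
    xtvy <- crossprod(qtx, qty * w)
    beta <- solve(xtvx, xtvy)
    res <- qty - qtx %*% beta
    rss <- sum(res^2 * w)
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(d)) + n)
    list(ll = ll, beta = beta, sigma2 = sigma2)
  }
  rho_max <- if (min(lam) < 0) -1 / min(lam) - 1e-6 else 0.999
  estimated_rho <- is.null(rho)
  if (estimated_rho) {
    opt <- stats::optimize(function(r) prof(r)$ll, c(0, rho_max), maximum = TRUE,
                           tol = 1e-8)
    # compare against the rho = 0 boundary (optimize can miss boundaries)
    rho <- if (prof(0)$ll >= opt$objective) 0 else opt$maximum
  } else {
    if (rho < 0 || rho >= 1) stop_popland("rho must lie in [0, 1)")
    if (rho >= rho_max) stop_popland("rho = %.3f exceeds the pd bound %.3f", rho, rho_max)
  }
  fit <- prof(rho)
  if (!is.finite(fit$ll)) stop_popland("likelihood not finite at rho = %.3f", rho)
  beta <- drop(fit$beta)
  names(beta) <- colnames(x)
  fitted <- drop(x %*% beta)
  k_par <- length(beta) + 1L + as.integer(estimated_rho)  # + sigma2 (+ rho)
  structure(
    list(coefficients = beta, rho = rho, sigma2 = fit$sigma2,
         logLik = fit$ll, aic = 2 * k_par - 2 * fit$ll,
         pseudo_r2 = stats::cor(fitted, y)^2,
         fitted = fitted, residuals = y - fitted, n = n,
         predictors = predictors, rho_estimated = estimated_rho,
         response_hash = digest_vector(y)),
    class = "mlpe_fit"
  )
}

digest_vector <- function(y) {
  paste0(length(y), ":", format(sum(y), digits = 15), ":",
         format(sum(y^2), digits = 15))
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("MLPE fit: %d pairs, rho = %.3f%s, sigma2 = %.4g\n",
              x$n, x$rho, if (x$rho_estimated) "" else " (fixed)", x$sigma2))
  cat(sprintf("  logLik = %.3f, AIC = %.2f, pseudo-R2 = %.3f\n",
              x$logLik, x$aic, x$pseudo_r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Rank MLPE fits by AIC
#'
#' @param fits a (possibly named) list of `mlpe_fit` objects fit to the
#'   same response rows.
#' @return data.frame sorted by ascending AIC with `delta_aic` relative to
#'   the best model.
#' @export
compare_models_aic <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "mlpe_fit")))
  hashes <- vapply(fits, `[[`, character(1), "response_hash")
  if (length(unique(hashes)) != 1)
    stop_popland("fits were made on different response rows")
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  nm[nm == ""] <- paste0("model", which(nm == ""))
  df <- data.frame(
    model = nm,
    predictors = vapply(fits, function(f) paste(f$predictors, collapse = "+"),
                        character(1)),
    k = vapply(fits, function(f) length(f$coefficients) + 1L +
                 as.integer(f$rho_estimated), integer(1)),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    rho = vapply(fits, `[[`, numeric(1), "rho"),
    pseudo_r2 = vapply(fits, `[[`, numeric(1), "pseudo_r2"),
    row.names = NULL
  )
  df <- df[order(df$aic), ]
  df$delta_aic <- df$aic - df$aic[1]
  rownames(df) <- NULL
  df
}
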