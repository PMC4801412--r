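# VIF diagnostics, spatially filtered partial (semipartial) regression and
# AICc all-subsets model selection.

# Assemble aligned response / predictor / filter rows with complete cases.
align_rows <- function(response, predictors, filters) {
  y <- if (inherits(response, "cell_field")) response$values else as.numeric(response)
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  Fm <- if (is.null(filters)) matrix(numeric(0), length(y), 0)
        else if (inherits(filters, "pcnm_filters")) filters$vectors
        else as.matrix(filters)
  if (nrow(X) != length(y) || nrow(Fm) != length(y))
    stop("response, predictors and filters are not aligned")
  ok <- !is.na(y) & stats::complete.cases(X) &
        (ncol(Fm) == 0 | stats::complete.cases(Fm))
  list(y = y[ok], X = X[ok, , drop = FALSE],
       Fm = Fm[ok, , drop = FALSE], ok = ok)
}

rss_of <- function(y, M) {
  if (ncol(M) == 0) return(sum((y - mean(y))^2))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, M), y)
  if (any(is.na(fit$coefficients)))
    stop(sprintf("rank-deficient design; dependent columns: %s",
                 paste(names(fit$coefficients)[is.na(fit$coefficients)],
                       collapse = ", ")))
  sum(fit$residuals^2)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' j on the remaining predictors (and on the conditioning filters, when
#' supplied). Values below 10 are conventionally read as low
#' collinearity. Exactly collinear predictors get `Inf`.
#'
#' @param predictors numeric matrix or data.frame (cells x p, p >= 2).
#' @param filters optional conditioning filter matrix or
#'   `pcnm_filters`.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(predictors, filters = NULL) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2) stop("need at least two predictors")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  Fm <- if (is.null(filters)) matrix(numeric(0), nrow(X), 0)
        else if (inherits(filters, "pcnm_filters")) filters$vectors
        else as.matrix(filters)
  ok <- stats::complete.cases(X) & (ncol(Fm) == 0 | stats::complete.cases(Fm))
  X <- X[ok, , drop = FALSE]; Fm <- Fm[ok, , drop = FALSE]
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    yj <- X[, j]
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) stop(sprintf("predictor '%s' has zero variance", colnames(X)[j]))
    M <- cbind(X[, -j, drop = FALSE], Fm)
    fit <- stats::lm.fit(cbind(1, M), yj)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) {
      warning(sprintf("predictor '%s' is exactly collinear with the others",
                      colnames(X)[j]))
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2)
  }
  out
}

#' Partial regression with spatial-filter conditioning
#'
#' Fits the global least-squares model `response ~ filters + all
#' predictors` and, for each predictor, the model with that predictor
#' removed. Each predictor's independent (semipartial) contribution is
#' `R2(full) - R2(without j)`, with a parametric extra-sum-of-squares F
#' test; the global environmental contribution is reported both on the
#' raw scale (against total variance) and conditioned on the filters
#' (against the variance the filters leave unexplained).
#'
#' @param response a [cell_field()] or numeric vector.
#' @param predictors matrix or data.frame (cells x p).
#' @param filters optional spatial filter matrix or `pcnm_filters`
#'   (conditioning variables, always included).
#' @return An object of class `partial_lm` with the global and
#'   per-predictor R2 and F values, degrees of freedom and `n`.
#' @export
partial_regression <- function(response, predictors, filters = NULL) {
  d <- align_rows(response, predictors, filters)
  n <- length(d$y); p <- ncol(d$X); k <- ncol(d$Fm)
  if (n <= p + k + 2) stop("too few complete cells for the design")
  tss <- sum((d$y - mean(d$y))^2)
  if (tss == 0) stop("undefined statistic: response has zero variance")

  rss_full <- rss_of(d$y, cbind(d$Fm, d$X))
  rss_filt <- rss_of(d$y, d$Fm)
  df_resid <- n - 1 - k - p

  r2_full_raw <- 1 - rss_full / tss
  r2_filters <- 1 - rss_filt / tss
  r2_env_raw <- r2_full_raw - r2_filters
  r2_env_partial <- if (rss_filt > 0) (rss_filt - rss_full) / rss_filt else 0
  f_global <- ((rss_filt - rss_full) / p) / (rss_full / df_resid)

  sp <- data.frame(predictor = colnames(d$X),
                   semipartial_r2 = NA_real_, f = NA_real_,
                   stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    rss_j <- rss_of(d$y, cbind(d$Fm, d$X[, -j, drop = FALSE]))
    sp$semipartial_r2[j] <- (rss_j - rss_full) / tss
    sp$f[j] <- ((rss_j - rss_full) / 1) / (rss_full / df_resid)
  }
  structure(list(n = n, p = p, k_filters = k,
                 global_r2_raw = r2_full_raw,
                 global_r2_filters_only = r2_filters,
                 global_r2 = r2_env_raw,
                 global_r2_partial = r2_env_partial,
                 global_f = f_global,
                 df = c(predictors = p, residual = df_resid),
                 predictors = sp), class = "partial_lm")
}

#' @export
print.partial_lm <- function(x, digits = 4, ...) {
  cat(sprintf("Partial regression (n = %d, %d spatial filters)\n",
              x$n, x$k_filters))
  cat(sprintf("Global model: R2 = %.*g (filter-conditioned %.*g), F = %.*g on %d and %d df\n",
              digits, x$global_r2, digits, x$global_r2_partial,
              digits, x$global_f, x$df["predictors"], x$df["residual"]))
  tab <- x$predictors
  tab$semipartial_r2 <- signif(tab$semipartial_r2, digits)
  tab$f <- signif(tab$f, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.partial_lm <- function(object, ...) object

#' @export
coef.partial_lm <- function(object, ...) {
  stats::setNames(object$predictors$semipartial_r2,
                  object$predictors$predictor)
}

#' AICc all-subsets model selection
#'
#' Enumerates every nonempty subset of the predictors, always keeping the
#' spatial filters in the model, and ranks the fits by the small-sample
#' Akaike criterion `AICc = n log(RSS/n) + 2K + 2K(K+1)/(n - K - 1)`,
#' where `K` counts all regression coefficients (intercept, filters and
#' the subset's predictors). Response and predictors are z-scored first,
#' so the reported coefficients are standardized; filters enter as-is.
#' Akaike weights are normalized over the full candidate set.
#'
#' @inheritParams partial_regression
#' @param max_p all-subsets guard: error if more than this many
#'   predictors (default 15).
#' @return An object of class `aicc_set`: a data.frame with one row per
#'   candidate model (standardized coefficients, `r2`, `aicc`,
#'   `delta_aicc`, `weight`), sorted by AICc, plus attributes `n` and
#'   `k_filters`.
#' @export
model_selection <- function(response, predictors, filters = NULL,
                            max_p = 15) {
  d <- align_rows(response, predictors, filters)
  p <- ncol(d$X)
  if (p > max_p) stop(sprintf("all-subsets over %d predictors refused", p))
  n <- length(d$y); k <- ncol(d$Fm)
  sy <- stats::sd(d$y)
  if (is.na(sy) || sy == 0) stop("undefined statistic: response has zero variance")
  y <- (d$y - mean(d$y)) / sy
  X <- scale(d$X)
  if (any(attr(X, "scaled:scale") == 0))
    stop("a predictor has zero variance")
  pn <- colnames(d$X)

  subsets <- unlist(lapply(seq_len(p), function(m)
    utils::combn(p, m, simplify = FALSE)), recursive = FALSE)
  rows <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    idx <- subsets[[s]]
    K <- 1 + k + length(idx)
    if (n <= K + 2) {
      warning(sprintf("subset {%s} skipped: n too small",
                      paste(pn[idx], collapse = ",")))
      next
    }
    M <- cbind(1, d$Fm, X[, idx, drop = FALSE])
    fit <- stats::lm.fit(M, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    aicc <- n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
    cf <- stats::setNames(rep(NA_real_, p), pn)
    cf[idx] <- fit$coefficients[(1 + k + 1):(1 + k + length(idx))]
    rows[[s]] <- c(list(model = paste(pn[idx], collapse = "+")),
                   as.list(cf),
                   list(r2 = 1 - rss / tss, aicc = aicc, K = K))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("no fittable candidate model")
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  ew <- exp(-tab$delta_aicc / 2)
  tab$weight <- ew / sum(ew)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  attr(tab, "n") <- n
  attr(tab, "k_filters") <- k
  class(tab) <- c("aicc_set", class(tab))
  tab
}

#' @export
print.aicc_set <- function(x, digits = 3, max_rows = 10, ...) {
  cat(sprintf("AICc model selection: %d candidate models, n = %d, %d spatial filters\n",
              nrow(x), attr(x, "n"), attr(x, "k_filters")))
  y <- as.data.frame(x)[seq_len(min(nrow(x), max_rows)), ]
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits)
  print(y, row.names = FALSE)
  if (nrow(x) > max_rows) cat(sprintf("... and %d more\n", nrow(x) - max_rows))
  invisible(x)
}

#' Standardized coefficients of the best AICc model
#'
#' @param object an `aicc_set`.
#' @param ... unused.
#' @return named numeric vector (predictors absent from the best model
#'   are `NA`).
#' @export
coef.aicc_set <- function(object, ...) {
  best <- as.data.frame(object)[1, ]
  drop_cols <- c("model", "r2", "aicc", "K", "delta_aicc", "weight")
  unlist(best[setdiff(names(best), drop_cols)])
}

#' Pearson correlation between two cell fields
#'
#' Sample Pearson correlation over the cells where both fields are
#' defined. Latitude or longitude can be supplied as a field built from
#' [grid_centers()] (latitude in signed degrees, negative in the southern
#' hemisphere).
#'
#' @param x,y [cell_field()]s or numeric vectors of equal length.
#' @return numeric scalar.
#' @export
pearson_r <- function(x, y) {
  xv <- if (inherits(x, "cell_field")) x$values else as.numeric(x)
  yv <- if (inherits(y, "cell_field")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("x and y have different lengths")
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < 3) stop("need at least 3 jointly defined values")
  if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0)
    stop("undefined statistic: zero variance")
  stats::cor(xv[ok], yv[ok])
}
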