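#' Fit a multiple linear regression QSA(P)R model
#'
#' Ordinary least squares with an intercept, plus everything needed to apply
#' the model transparently to new chemicals: residual standard error
#' `s = sqrt(sum(r^2)/(n - p - 1))`, training leverages (hat-matrix
#' diagonal), the structural applicability-domain cutoff `3(p+1)/n`, the
#' training endpoint range, and the range of training prediction-interval
#' halfwidths used by the endpoint-domain rule.
#'
#' The leverage of a chemical with (intercept-augmented) descriptor row `x`
#' is `h = x (X'X)^{-1} x'` where `X` is the intercept-augmented training
#' matrix; with this convention the training leverages sum to `p + 1` and the
#' `3(p+1)/n` cutoff applies directly.
#'
#' @param training data frame with one row per training chemical: descriptor
#'   columns named as in `descriptors`, a response column, and optionally
#'   `id` and `smiles` columns.
#' @param descriptors character vector of descriptor names, or a spec data
#'   frame with columns `name`, `source` (`"computed"` or `"supplied"`) and
#'   optional `description`.
#' @param response name of the response column (default `"y"`).
#' @param metadata optional named list (`model_id`, `endpoint_name`, `units`,
#'   `group`, `subgroup`, `citation`) carried into reports.
#' @return an object of class `qsar_mlr`.
#' @seealso [predict.qsar_mlr()], [leverage()], [structural_ad()],
#'   [endpoint_ad()], [plot.qsar_mlr()] (Williams plot)
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
#' d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(20, sd = 0.3)
#' m <- qsar_mlr(d, c("x1", "x2"))
#' coef(m)
#' predict(m, data.frame(x1 = 0.5, x2 = -0.2))
qsar_mlr <- function(training, descriptors, response = "y",
                     metadata = list()) {
  specs <- .as_specs(descriptors)
  p <- nrow(specs)
  miss <- setdiff(c(specs$name, response), names(training))
  if (length(miss))
    stop("training data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(training[, specs$name, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(training[[response]])
  n <- nrow(X)
  if (anyNA(X) || anyNA(y))
    stop("missing values in training descriptors or response", call. = FALSE)
  if (n < p + 2L)
    stop(sprintf("need n >= p + 2 for a residual degree of freedom (n=%d, p=%d)",
                 n, p), call. = FALSE)

  Xt <- cbind(`(Intercept)` = 1, X)
  sv <- svd(Xt, nu = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10) {
    v <- svd(Xt)$v[, ncol(Xt)]
    bad <- colnames(Xt)[abs(v) > 1e-6]
    stop("rank-deficient design (condition number > 1e10); ",
         "collinear terms: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  qx <- qr(Xt)
  beta <- qr.coef(qx, y)
  fitted <- drop(Xt %*% beta)
  resid <- y - fitted
  df <- n - p - 1L
  rss <- sum(resid^2)
  s <- sqrt(rss / df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  Q <- qr.Q(qx)
  hat_diag <- rowSums(Q^2)
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(Xt), colnames(Xt))
  q2_loo <- if (tss > 0) 1 - sum((resid / (1 - hat_diag))^2) / tss
            else NA_real_
  cutoff <- 3 * (p + 1) / n
  if (cutoff > 1)
    warning(sprintf("leverage cutoff 3(p+1)/n = %.3f exceeds 1; no chemical can ever be flagged out of the structural domain", cutoff), call. = FALSE)

  ids <- if ("id" %in% names(training)) as.character(training$id)
         else sprintf("train%03d", seq_len(n))
  tr <- data.frame(id = ids, stringsAsFactors = FALSE)
  if ("smiles" %in% names(training)) tr$smiles <- as.character(training$smiles)
  tr <- cbind(tr, as.data.frame(X)); tr$y <- y

  obj <- list(specs = specs, training = tr, beta = beta, s = s, r2 = r2,
              q2_loo = q2_loo, hat_diag = hat_diag, residuals = resid,
              fitted = fitted, df = df, n = n, p = p,
              leverage_cutoff = cutoff, xtx_inv = xtx_inv,
              y_range = range(y), alpha = 0.05,
              metadata = .as_metadata(metadata))
  class(obj) <- "qsar_mlr"
  obj$halfwidth_range <- halfwidth_range(obj, alpha = 0.05)
  obj
}

.as_specs <- function(descriptors) {
  if (is.data.frame(descriptors)) {
    stopifnot("name" %in% names(descriptors))
    specs <- data.frame(name = as.character(descriptors$name),
                        source = if ("source" %in% names(descriptors))
                          as.character(descriptors$source) else "supplied",
                        description = if ("description" %in% names(descriptors))
                          as.character(descriptors$description) else "",
                        stringsAsFactors = FALSE)
  } else {
    specs <- data.frame(name = as.character(descriptors),
                        source = ifelse(as.character(descriptors) %in%
                                          descriptor_names(),
                                        "computed", "supplied"),
                        description = "", stringsAsFactors = FALSE)
  }
  if (any(!nzchar(specs$name)) || anyDuplicated(specs$name))
    stop("descriptor names must be non-empty and unique", call. = FALSE)
  if (!all(specs$source %in% c("computed", "supplied")))
    stop("descriptor source must be 'computed' or 'supplied'", call. = FALSE)
  specs
}

.as_metadata <- function(metadata) {
  def <- list(model_id = "unnamed", endpoint_name = "", units = "",
              group = "", subgroup = "", citation = "")
  def[names(metadata)] <- metadata
  def
}

# newdata (data.frame / named vector / matrix) -> descriptor matrix aligned
# to model specs; errors name the missing descriptor
.align_newdata <- function(model, newdata) {
  nm <- model$specs$name
  if (is.null(dim(newdata))) {
    if (is.null(names(newdata)) && length(newdata) == length(nm))
      names(newdata) <- nm
    newdata <- as.data.frame(as.list(newdata))
  }
  newdata <- as.data.frame(newdata)
  miss <- setdiff(nm, names(newdata))
  if (length(miss))
    stop("missing descriptor value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  M <- as.matrix(newdata[, nm, drop = FALSE])
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    bad <- nm[apply(is.na(M), 2, any)]
    stop("missing descriptor value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  M
}

#' Leverage of new chemicals under a fitted MLR model
#'
#' `h = x (X'X)^{-1} x'` with intercept-augmented `x` and training matrix
#' `X`; measures distance from the training descriptor centroid in the model
#' metric. A chemical exactly at the centroid has `h = 1/n`.
#'
#' @param model a `qsar_mlr` object.
#' @param newdata descriptor values: data frame, named vector, or matrix.
#' @return numeric vector of leverages.
#' @export
leverage <- function(model, newdata) {
  stopifnot(inherits(model, "qsar_mlr"))
  M <- cbind(1, .align_newdata(model, newdata))
  unname(rowSums((M %*% model$xtx_inv) * M))
}

#' Structural applicability-domain leverage cutoff
#'
#' `3 p'/n` with `p' = p + 1` (descriptors plus intercept); a chemical with
#' leverage greater than or equal to the cutoff is out of the structural
#' domain.
#'
#' @param model a `qsar_mlr` object.
#' @return the cutoff value.
#' @export
leverage_cutoff <- function(model) {
  stopifnot(inherits(model, "qsar_mlr"))
  model$leverage_cutoff
}

#' Training prediction-interval halfwidth range
#'
#' Minimum and maximum of `t(1-alpha/2, df) * s * sqrt(1 + h_ii)` over the
#' training set; a target chemical whose own halfwidth falls outside this
#' range is out of the endpoint domain.
#'
#' @param model a `qsar_mlr` object.
#' @param alpha two-sided interval level (default 0.05).
#' @return length-2 numeric `c(min, max)`.
#' @export
halfwidth_range <- function(model, alpha = 0.05) {
  tq <- stats::qt(1 - alpha / 2, model$df)
  tq * model$s * sqrt(1 + range(model$hat_diag))
}

#' Predict endpoint values with prediction intervals and domain verdicts
#'
#' The prediction interval halfwidth is `t(1-alpha/2, n-p-1) * s *
#' sqrt(1 + h)`; the single-item random variation is included, so intervals
#' are wider than confidence intervals for the mean response.
#'
#' @param object a `qsar_mlr` model.
#' @param newdata descriptor values (data frame, named vector, matrix).
#' @param alpha two-sided interval level; default 0.05 (2.5% per tail).
#' @param y_observed optional observed endpoint values for the standardized
#'   residual domain rule.
#' @param strict_and if `TRUE`, the endpoint domain fails only when both the
#'   standardized-residual and experimental-range rules fail (literal
#'   conjunctive reading); default treats every applicable rule independently.
#' @param check_ad compute applicability-domain verdicts (default `TRUE`).
#' @param ... unused.
#' @return data frame with one row per query: `value`, `halfwidth`, `lwr`,
#'   `upr`, `leverage`, `structural_in_ad`, `endpoint_in_ad`, `in_ad`,
#'   `reasons` (semicolon-joined), with the per-row verdict objects in
#'   attribute `"verdicts"`.
#' @export
predict.qsar_mlr <- function(object, newdata, alpha = object$alpha,
                             y_observed = NULL, strict_and = FALSE,
                             check_ad = TRUE, ...) {
  M <- .align_newdata(object, newdata)
  Xt <- cbind(1, M)
  value <- unname(drop(Xt %*% object$beta))
  h <- unname(rowSums((Xt %*% object$xtx_inv) * Xt))
  tq <- stats::qt(1 - alpha / 2, object$df)
  halfwidth <- tq * object$s * sqrt(1 + h)
  m <- nrow(M)
  if (!is.null(y_observed)) y_observed <- rep_len(y_observed, m)

  out <- data.frame(value = value, halfwidth = halfwidth,
                    lwr = value - halfwidth, upr = value + halfwidth,
                    leverage = h)
  if (check_ad) {
    verdicts <- vector("list", m)
    out$structural_in_ad <- out$endpoint_in_ad <- out$in_ad <- NA
    out$reasons <- ""
    for (i in seq_len(m)) {
      sv <- structural_ad(object, M[i, , drop = FALSE])
      ev <- endpoint_ad(object, value = value[i], halfwidth = halfwidth[i],
                        leverage = h[i],
                        y_observed = if (is.null(y_observed)) NULL
                                     else y_observed[i],
                        alpha = alpha, strict_and = strict_and)
      out$structural_in_ad[i] <- sv$in_ad
      out$endpoint_in_ad[i] <- ev$in_ad
      out$in_ad[i] <- sv$in_ad && ev$in_ad
      out$reasons[i] <- paste(c(sv$reasons, ev$reasons), collapse = "; ")
      verdicts[[i]] <- list(structural = sv, endpoint = ev)
    }
    attr(out, "verdicts") <- verdicts
  }
  attr(out, "alpha") <- alpha
  rownames(out) <- rownames(newdata)
  out
}

#' Prediction interval for a single chemical
#'
#' Convenience wrapper around [predict.qsar_mlr()] for one query.
#'
#' @inheritParams predict.qsar_mlr
#' @param model a `qsar_mlr` object.
#' @param x descriptor values for one chemical (named vector or 1-row data
#'   frame).
#' @return list with `value`, `halfwidth`, `interval`, `leverage`,
#'   `structural_in_ad`, `endpoint_in_ad`, `reasons`.
#' @export
prediction_interval <- function(model, x, alpha = model$alpha,
                                y_observed = NULL, strict_and = FALSE) {
  pr <- predict(model, x, alpha = alpha, y_observed = y_observed,
                strict_and = strict_and)
  if (nrow(pr) != 1L) stop("'x' must describe a single chemical", call. = FALSE)
  list(value = pr$value, halfwidth = pr$halfwidth,
       interval = c(pr$lwr, pr$upr), leverage = pr$leverage,
       structural_in_ad = pr$structural_in_ad,
       endpoint_in_ad = pr$endpoint_in_ad,
       reasons = strsplit(pr$reasons, "; ", fixed = TRUE)[[1]])
}

.verdict <- function(criteria, details, reasons) {
  applicable <- criteria[criteria != "not_applicable"]
  structure(list(in_ad = all(applicable == "pass"), criteria = criteria,
                 details = details, reasons = reasons),
            class = "qsar_ad_verdict")
}

#' @export
print.qsar_ad_verdict <- function(x, ...) {
  cat("Applicability-domain verdict:",
      if (x$in_ad) "IN domain" else "OUT of domain", "\n")
  for (nm in names(x$criteria))
    cat(sprintf("  %-22s %s\n", nm, x$criteria[[nm]]))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Structural applicability domain check
#'
#' For MLR models: out of domain when the leverage is greater than or equal
#' to `3(p+1)/n` (the boundary itself is out). For LDA models: out of domain
#' when the cosine-similarity score against the training centroid falls
#' below the model's training-score percentile cutoff.
#'
#' @param model a fitted `qsar_mlr` or `qsar_lda` model.
#' @param newdata descriptor values for one chemical.
#' @param ... passed to methods.
#' @return a `qsar_ad_verdict` object with the numeric evidence in
#'   `$details`.
#' @export
structural_ad <- function(model, newdata, ...) UseMethod("structural_ad")

#' @rdname structural_ad
#' @export
structural_ad.qsar_mlr <- function(model, newdata, ...) {
  h <- leverage(model, newdata)
  if (length(h) != 1L) stop("one chemical at a time", call. = FALSE)
  cutoff <- model$leverage_cutoff
  ok <- h < cutoff
  .verdict(criteria = c(leverage = if (ok) "pass" else "fail"),
           details = c(leverage = h, cutoff = cutoff),
           reasons = if (ok) character() else
             sprintf("leverage %.4g >= cutoff %.4g", h, cutoff))
}

#' Endpoint applicability domain check
#'
#' Three rules for MLR predictions: (a) the standardized residual
#' `(y_obs - value) / (s * sqrt(1 - h))` exceeds 2.5 in absolute value
#' (not applicable without an observed endpoint or when `h >= 1`);
#' (b) the predicted value falls outside the training experimental range;
#' (c) the prediction-interval halfwidth falls outside the range of training
#' halfwidths. By default every applicable failing rule puts the chemical
#' out of the domain; `strict_and = TRUE` requires rules (a) and (b) to fail
#' jointly (rule (c) always acts independently).
#'
#' For LDA predictions, see [endpoint_ad_lda()]: out of domain when the
#' event-class posterior lies strictly between 0.25 and 0.75.
#'
#' @param model a `qsar_mlr` model.
#' @param value predicted endpoint value.
#' @param halfwidth prediction-interval halfwidth of the query.
#' @param leverage leverage of the query (used by rule (a)).
#' @param y_observed observed endpoint value, or `NULL`.
#' @param alpha interval level used for the training halfwidth range.
#' @param strict_and conjunctive reading of rules (a) and (b).
#' @param ... unused.
#' @return a `qsar_ad_verdict`.
#' @export
endpoint_ad <- function(model, ...) UseMethod("endpoint_ad")

#' @rdname endpoint_ad
#' @export
endpoint_ad.qsar_mlr <- function(model, value, halfwidth, leverage = NULL,
                                 y_observed = NULL, alpha = model$alpha,
                                 strict_and = FALSE, ...) {
  crit <- c(std_residual = "not_applicable", experimental_range = "pass",
            interval_range = "pass")
  det <- c(value = value, halfwidth = halfwidth)
  reasons <- character()

  rp <- NA_real_
  if (!is.null(y_observed) && !is.na(y_observed)) {
    if (is.null(leverage) || leverage >= 1 - 1e-10 || model$s == 0) {
      crit["std_residual"] <- "not_applicable"
    } else {
      rp <- (y_observed - value) / (model$s * sqrt(1 - leverage))
      det["std_residual"] <- rp
      if (abs(rp) > 2.5) {          # exactly 2.5 is in ("greater than 2.5")
        crit["std_residual"] <- "fail"
        reasons <- c(reasons, sprintf("|std residual| %.3g > 2.5", abs(rp)))
      } else crit["std_residual"] <- "pass"
    }
  }

  yr <- model$y_range
  det["y_min"] <- yr[1]; det["y_max"] <- yr[2]
  if (value < yr[1] || value > yr[2]) {
    crit["experimental_range"] <- "fail"
    reasons <- c(reasons,
                 sprintf("prediction %.4g outside experimental range [%.4g, %.4g]",
                         value, yr[1], yr[2]))
  }

  hw <- halfwidth_range(model, alpha = alpha)
  det["halfwidth_min"] <- hw[1]; det["halfwidth_max"] <- hw[2]
  if (halfwidth < hw[1] || halfwidth > hw[2]) {
    crit["interval_range"] <- "fail"
    reasons <- c(reasons,
                 sprintf("interval halfwidth %.4g outside training range [%.4g, %.4g]",
                         halfwidth, hw[1], hw[2]))
  }

  if (strict_and) {
    # literal conjunctive reading: rules (a) and (b) must fail jointly
    ab_fail <- crit[["std_residual"]] == "fail" &&
      crit[["experimental_range"]] == "fail"
    in_ad <- !ab_fail && crit[["interval_range"]] != "fail"
    return(structure(list(in_ad = in_ad, criteria = crit, details = det,
                          reasons = if (in_ad) character() else reasons,
                          combination = "strict_and"),
                     class = "qsar_ad_verdict"))
  }
  .verdict(crit, det, reasons)
}

#' Standardized residuals of a fitted MLR model
#'
#' `r'_i = r_i / (s * sqrt(1 - h_ii))`; the diagnostics axis of the Williams
#' plot. Chemicals with `h_ii` numerically at 1 (saturated directions) get
#' `NA` with a warning instead of a division blow-up; a noiseless model
#' (`s = 0`) has all-zero residuals and returns zeros.
#'
#' @param model a `qsar_mlr` object.
#' @param ... unused.
#' @return numeric vector of standardized residuals, one per training
#'   chemical.
#' @export
rstandard.qsar_mlr <- function(model, ...) {
  if (model$s == 0) return(numeric(model$n))
  sat <- model$hat_diag >= 1 - 1e-10
  if (any(sat))
    warning(sum(sat), " training chemical(s) with leverage ~ 1; ",
            "standardized residual undefined there", call. = FALSE)
  out <- model$residuals / (model$s * sqrt(pmax(0, 1 - model$hat_diag)))
  out[sat] <- NA_real_
  out
}

#' @export
coef.qsar_mlr <- function(object, ...) object$beta

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' @export
fitted.qsar_mlr <- function(object, ...) object$fitted

#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(object$n, 0, object$s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.qsar_mlr <- function(x, ...) {
  cat(sprintf("MLR QSA(P)R model '%s' (%s%s)\n", x$metadata$model_id,
              x$metadata$endpoint_name,
              if (nzchar(x$metadata$units)) paste0(", ", x$metadata$units)
              else ""))
  cat(sprintf("  n = %d training chemicals, p = %d descriptors\n", x$n, x$p))
  cat("  coefficients:\n")
  print(round(x$beta, 6))
  cat(sprintf("  s = %.6g, R2 = %.4f, Q2(LOO) = %.4f\n", x$s, x$r2, x$q2_loo))
  cat(sprintf("  leverage cutoff 3(p+1)/n = %.4g\n", x$leverage_cutoff))
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  print(object)
  cat(sprintf("  experimental range: [%.4g, %.4g]\n",
              object$y_range[1], object$y_range[2]))
  hw <- object$halfwidth_range
  cat(sprintf("  training halfwidth range (alpha=%.2f): [%.4g, %.4g]\n",
              object$alpha, hw[1], hw[2]))
  cat(sprintf("  training leverages: min %.4g, max %.4g (trace = %.4g)\n",
              min(object$hat_diag), max(object$hat_diag),
              sum(object$hat_diag)))
  invisible(object)
}

#' Williams plot of a fitted MLR model
#'
#' Standardized residuals against leverage for the training set, with the
#' `3(p+1)/n` leverage cutoff and the ±2.5 residual bands; optional new
#' chemicals are overplotted (their residual axis requires `y_observed`).
#'
#' @param x a `qsar_mlr` object.
#' @param newdata optional query descriptor values.
#' @param y_observed optional observed endpoints for `newdata`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qsar_mlr <- function(x, newdata = NULL, y_observed = NULL, ...) {
  h <- x$hat_diag
  r <- rstandard.qsar_mlr(x)
  xmax <- max(h, x$leverage_cutoff * 1.1, na.rm = TRUE)
  graphics::plot(h, r, xlab = "leverage h", ylab = "standardized residual",
                 xlim = c(0, xmax), ylim = range(c(r, -3, 3), na.rm = TRUE),
                 pch = 19, ...)
  graphics::abline(v = x$leverage_cutoff, lty = 2)
  graphics::abline(h = c(-2.5, 2.5), lty = 3)
  if (!is.null(newdata)) {
    pr <- predict(x, newdata, check_ad = FALSE)
    rq <- if (!is.null(y_observed))
      (y_observed - pr$value) / (x$s * sqrt(pmax(1e-12, 1 - pr$leverage)))
    else rep(0, nrow(pr))
    graphics::points(pr$leverage, rq, pch = 17, col = 2)
  }
  invisible(x)
}
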