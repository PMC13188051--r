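#' Fit a linear discriminant analysis QSA(P)R classifier
#'
#' Standard LDA with pooled within-class covariance and empirical priors.
#' Beyond the discriminant itself, the fit stores everything the
#' applicability-domain machinery needs: per-descriptor training mean/SD
#' (the autoscaling parameters), a cosine-similarity score for every
#' training chemical against the training centroid, and the percentile
#' cutoff on those scores used by the structural domain rule.
#'
#' The similarity score of a chemical is the cosine between its descriptor
#' vector and the training centroid, both divided component-wise by the
#' training standard deviations (scaling only, no centering — centering
#' would collapse the centroid to the zero vector and leave the cosine
#' undefined). A chemical exactly at the centroid therefore scores 1, the
#' maximum. The default domain cutoff keeps ~95% of the training set inside
#' its own domain (5th percentile of training scores); the literal
#' 95th-percentile reading is available via `literal_percentile = TRUE` at
#' check time. Percentiles use the linear-interpolation convention
#' (`quantile` type 7).
#'
#' @param training data frame with descriptor columns and a class-label
#'   column; optional `id`, `smiles` columns.
#' @param descriptors descriptor names or spec data frame (see
#'   [qsar_mlr()]).
#' @param response name of the class-label column (default `"class"`).
#' @param event_class class treated as "the event" by the posterior-band
#'   endpoint rule; default is the first declared class.
#' @param percentile training-score percentile retained inside the domain
#'   (default 0.95, i.e. cutoff at the 5th percentile of training scores).
#' @param metadata optional named list as in [qsar_mlr()].
#' @return an object of class `qsar_lda`.
#' @export
qsar_lda <- function(training, descriptors, response = "class",
                     event_class = NULL, percentile = 0.95,
                     metadata = list()) {
  specs <- .as_specs(descriptors)
  p <- nrow(specs)
  miss <- setdiff(c(specs$name, response), names(training))
  if (length(miss))
    stop("training data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(training[, specs$name, drop = FALSE])
  storage.mode(X) <- "double"
  cls <- as.character(training[[response]])
  if (anyNA(X) || anyNA(cls))
    stop("missing values in training descriptors or class labels",
         call. = FALSE)
  classes <- unique(cls)               # declared order = order of appearance
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  nk <- table(factor(cls, levels = classes))
  if (any(nk < 2L))
    stop("every class needs at least 2 members; offending: ",
         paste(classes[nk < 2L], collapse = ", "), call. = FALSE)
  n <- nrow(X)

  class_means <- matrix(0, K, p, dimnames = list(classes, specs$name))
  for (k in classes)
    class_means[k, ] <- colMeans(X[cls == k, , drop = FALSE])

  Sw <- matrix(0, p, p)
  for (k in classes) {
    Xi <- X[cls == k, , drop = FALSE]
    Xi <- sweep(Xi, 2, class_means[k, ])
    Sw <- Sw + crossprod(Xi)
  }
  pooled_cov <- Sw / (n - K)
  sv <- svd(pooled_cov, nu = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10) {
    v <- svd(pooled_cov)$v[, p]
    bad <- specs$name[abs(v) > 1e-6]
    stop("singular pooled within-class covariance; ",
         "offending descriptor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pooled_cov_inv <- solve(pooled_cov)
  priors <- as.numeric(nk) / n
  names(priors) <- classes

  scaler <- list(mean = colMeans(X),
                 sd = apply(X, 2, stats::sd))
  if (any(scaler$sd == 0))
    stop("constant descriptor(s): ",
         paste(specs$name[scaler$sd == 0], collapse = ", "), call. = FALSE)

  centroid_scaled <- scaler$mean / scaler$sd
  if (sum(centroid_scaled^2) == 0)
    stop("training descriptor centroid at the origin; ",
         "cosine-similarity scores are undefined", call. = FALSE)
  train_scores <- apply(X, 1, function(x)
    .cosine_to(x / scaler$sd, centroid_scaled))
  if (anyNA(train_scores))
    stop("zero descriptor vector(s) in training set: ",
         paste(ids <- which(is.na(train_scores)), collapse = ", "),
         "; cosine-similarity scores undefined", call. = FALSE)
  sim_cutoff <- as.numeric(stats::quantile(train_scores, 1 - percentile,
                                           type = 7))

  ids <- if ("id" %in% names(training)) as.character(training$id)
         else sprintf("train%03d", seq_len(n))
  tr <- data.frame(id = ids, stringsAsFactors = FALSE)
  if ("smiles" %in% names(training)) tr$smiles <- as.character(training$smiles)
  tr <- cbind(tr, as.data.frame(X)); tr$class <- cls

  obj <- list(specs = specs, training = tr, classes = classes,
              class_means = class_means, pooled_cov = pooled_cov,
              pooled_cov_inv = pooled_cov_inv, priors = priors,
              scaler = scaler, train_scores = train_scores,
              sim_cutoff = sim_cutoff, percentile = percentile,
              event_class = if (is.null(event_class)) classes[1]
                            else as.character(event_class),
              n = n, p = p, K = K, metadata = .as_metadata(metadata))
  if (!obj$event_class %in% classes)
    stop("event_class not among training classes", call. = FALSE)
  class(obj) <- "qsar_lda"
  obj
}

.cosine_to <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Cosine similarity between two real vectors
#'
#' `a.b / (|a||b|)`; both vectors must be non-zero and of equal length.
#'
#' @param a,b numeric vectors.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  out <- .cosine_to(as.numeric(a), as.numeric(b))
  if (is.na(out)) stop("cosine similarity undefined for zero vectors",
                       call. = FALSE)
  out
}

#' Shannon entropy of class posteriors
#'
#' `-sum(p * log(p, base))` with the `0 * log 0 = 0` convention; reported in
#' bits by default so a binary classifier's maximum is 1.
#'
#' @param posteriors numeric probabilities summing to 1.
#' @param base logarithm base (default 2).
#' @return entropy (non-negative).
#' @export
shannon_entropy <- function(posteriors, base = 2) {
  p <- as.numeric(posteriors)
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("posteriors must be non-negative and sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Predict class membership with posteriors, entropy and domain verdicts
#'
#' Posterior probabilities are the softmax of the linear discriminant scores
#' `x' S^{-1} mu_k - mu_k' S^{-1} mu_k / 2 + log pi_k`; the predicted label
#' is the argmax, with ties broken by declared class order and flagged.
#'
#' @param object a `qsar_lda` model.
#' @param newdata descriptor values (data frame, named vector, matrix).
#' @param check_ad compute domain verdicts (default `TRUE`).
#' @param literal_percentile use the literal reading of the similarity rule
#'   (cutoff at the 95th percentile of training scores) instead of the
#'   default 5th-percentile cutoff.
#' @param ... unused.
#' @return data frame with `label`, one `posterior_<class>` column per
#'   class, `entropy` (bits), `similarity`, `structural_in_ad`,
#'   `endpoint_in_ad`, `in_ad`, `tie`, `reasons`.
#' @export
predict.qsar_lda <- function(object, newdata, check_ad = TRUE,
                             literal_percentile = FALSE, ...) {
  M <- .align_newdata(object, newdata)
  m <- nrow(M)
  A <- object$pooled_cov_inv %*% t(object$class_means)      # p x K
  const <- -0.5 * colSums(t(object$class_means) * A) + log(object$priors)
  scores <- M %*% A + matrix(const, m, object$K, byrow = TRUE)
  scores <- scores - apply(scores, 1, max)
  post <- exp(scores) / rowSums(exp(scores))
  colnames(post) <- object$classes

  top <- apply(post, 1, max)
  tie <- apply(post, 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1L)
  label <- object$classes[apply(post, 1, which.max)]
  ent <- apply(post, 1, shannon_entropy)

  out <- data.frame(label = label, stringsAsFactors = FALSE)
  for (k in object$classes) out[[paste0("posterior_", k)]] <- post[, k]
  out$entropy <- ent
  out$tie <- tie
  if (check_ad) {
    out$similarity <- NA_real_
    out$structural_in_ad <- out$endpoint_in_ad <- out$in_ad <- NA
    out$reasons <- ""
    for (i in seq_len(m)) {
      sv <- structural_ad(object, M[i, , drop = FALSE],
                          literal_percentile = literal_percentile)
      ev <- endpoint_ad_lda(object, post[i, object$event_class])
      out$similarity[i] <- sv$details[["similarity"]]
      out$structural_in_ad[i] <- sv$in_ad
      out$endpoint_in_ad[i] <- ev$in_ad
      out$in_ad[i] <- sv$in_ad && ev$in_ad
      out$reasons[i] <- paste(c(if (tie[i]) "tie in argmax (maximal entropy)",
                                sv$reasons, ev$reasons), collapse = "; ")
    }
  }
  rownames(out) <- rownames(newdata)
  out
}

#' @rdname structural_ad
#' @param literal_percentile for LDA models: use the verbatim
#'   "below the 95th percentile of training scores" cutoff instead of the
#'   default 5th-percentile cutoff (see [qsar_lda()]).
#' @export
structural_ad.qsar_lda <- function(model, newdata,
                                   literal_percentile = FALSE, ...) {
  M <- .align_newdata(model, newdata)
  if (nrow(M) != 1L) stop("one chemical at a time", call. = FALSE)
  sc <- .cosine_to(M[1, ] / model$scaler$sd,
                   model$scaler$mean / model$scaler$sd)
  cutoff <- if (literal_percentile)
    as.numeric(stats::quantile(model$train_scores, model$percentile,
                               type = 7))
  else model$sim_cutoff
  if (is.na(sc))
    return(.verdict(c(similarity = "fail"),
                    c(similarity = NA_real_, cutoff = cutoff),
                    "similarity undefined (zero descriptor vector)"))
  ok <- sc >= cutoff                   # out iff strictly below the cutoff
  .verdict(c(similarity = if (ok) "pass" else "fail"),
           c(similarity = sc, cutoff = cutoff),
           if (ok) character() else
             sprintf("similarity %.4g below cutoff %.4g", sc, cutoff))
}

#' Posterior-band endpoint domain check for LDA predictions
#'
#' Out of domain when the event-class posterior lies strictly between 0.25
#' and 0.75 (an uncommitted prediction); the boundary values themselves are
#' inside the domain.
#'
#' @param model a `qsar_lda` model.
#' @param posterior event-class posterior probability.
#' @return a `qsar_ad_verdict`.
#' @export
endpoint_ad_lda <- function(model, posterior) {
  stopifnot(posterior >= 0, posterior <= 1)
  inside_band <- posterior > 0.25 && posterior < 0.75
  .verdict(c(posterior_band = if (inside_band) "fail" else "pass"),
           c(posterior = posterior, lower = 0.25, upper = 0.75),
           if (inside_band)
             sprintf("event posterior %.3f in uncertain band (0.25, 0.75)",
                     posterior)
           else character())
}

#' @export
coef.qsar_lda <- function(object, ...) {
  if (object$K == 2L)
    drop(object$pooled_cov_inv %*%
           (object$class_means[1, ] - object$class_means[2, ]))
  else object$pooled_cov_inv %*% t(object$class_means)
}

#' @export
print.qsar_lda <- function(x, ...) {
  cat(sprintf("LDA QSA(P)R classifier '%s' (%s)\n", x$metadata$model_id,
              x$metadata$endpoint_name))
  cat(sprintf("  n = %d training chemicals, p = %d descriptors, classes: %s\n",
              x$n, x$p, paste(x$classes, collapse = ", ")))
  cat(sprintf("  priors: %s\n",
              paste(sprintf("%s=%.3f", x$classes, x$priors), collapse = ", ")))
  cat(sprintf("  event class: %s; similarity cutoff %.4g (%g%% of training in-domain)\n",
              x$event_class, x$sim_cutoff, 100 * x$percentile))
  invisible(x)
}

#' @export
summary.qsar_lda <- function(object, ...) {
  print(object)
  pr <- predict(object, object$training[, object$specs$name, drop = FALSE],
                check_ad = FALSE)
  acc <- mean(pr$label == object$training$class)
  cat(sprintf("  training accuracy: %.3f; mean entropy: %.3f bits\n",
              acc, mean(pr$entropy)))
  cat(sprintf("  training similarity scores: [%.4g, %.4g]\n",
              min(object$train_scores), max(object$train_scores)))
  invisible(object)
}
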