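#' Inverse-variance consensus of several predictions
#'
#' Combines N predictions of the same endpoint (same units) into a weighted
#' average with weights `w_i = 1/sigma_i^2`: combined value
#' `sum(w*y)/sum(w)`, combined uncertainty `sqrt(1/sum(w))`. The combined
#' value always lies within the member extremes and the combined uncertainty
#' is below every member's for N >= 2.
#'
#' Only regression (MLR) predictions can enter: a classification entropy is
#' not a standard deviation and has no place in `1/sigma^2` weighting.
#'
#' @param values predicted values, or a data frame with columns `value` and
#'   `uncertainty` (and optionally `model_id`).
#' @param uncertainties prediction-interval halfwidths `sigma_i`, all
#'   strictly positive.
#' @param model_ids optional member identifiers.
#' @return object of class `qsar_consensus`: list with `value`,
#'   `uncertainty`, `weights`, `members` (data frame), `n`.
#' @export
combine_predictions <- function(values, uncertainties = NULL,
                                model_ids = NULL) {
  if (is.data.frame(values)) {
    df <- values
    stopifnot(all(c("value", "uncertainty") %in% names(df)))
    uncertainties <- df$uncertainty
    model_ids <- if ("model_id" %in% names(df)) df$model_id else model_ids
    values <- df$value
  }
  values <- as.numeric(values); uncertainties <- as.numeric(uncertainties)
  n <- length(values)
  if (n < 1L) stop("no predictions to combine", call. = FALSE)
  if (length(uncertainties) != n)
    stop("values and uncertainties must have equal length", call. = FALSE)
  if (any(!is.finite(uncertainties)) || any(uncertainties <= 0))
    stop("every uncertainty must be a positive finite number (degenerate model otherwise)",
         call. = FALSE)
  if (is.null(model_ids)) model_ids <- sprintf("model%02d", seq_len(n))

  w <- 1 / uncertainties^2
  value <- sum(w * values) / sum(w)
  uncertainty <- sqrt(1 / sum(w))
  structure(list(value = value, uncertainty = uncertainty, weights = w,
                 members = data.frame(model_id = model_ids, value = values,
                                      uncertainty = uncertainties,
                                      weight = w, stringsAsFactors = FALSE),
                 n = n),
            class = "qsar_consensus")
}

#' @export
print.qsar_consensus <- function(x, ...) {
  cat(sprintf("Consensus of %d prediction(s): %.6g +/- %.6g\n",
              x$n, x$value, x$uncertainty))
  print(x$members, row.names = FALSE)
  if (!is.null(x$excluded) && nrow(x$excluded))
    cat("excluded:", paste(sprintf("%s (%s)", x$excluded$model_id,
                                   x$excluded$reason), collapse = "; "), "\n")
  invisible(x)
}

#' Consensus over the MLR models of a registry subgroup
#'
#' Applies every MLR model of a subgroup to one target chemical and combines
#' the resulting predictions by inverse-variance weighting. The policy
#' controls membership: `"user_selected"` takes the models named in
#' `selected`, `"all"` takes every applicable model, `"in_ad_only"` drops
#' members whose prediction is out of the applicability domain (recorded
#' with reasons, never silently).
#'
#' @param registry a `qsar_registry` from [load_registry()].
#' @param subgroup subgroup name.
#' @param target descriptor values for the target (named vector or 1-row
#'   data frame covering every member model's descriptors), or a
#'   `qsar_chem` structure for models with computed descriptors.
#' @param policy `"user_selected"` (default), `"all"`, or `"in_ad_only"`.
#' @param selected model ids for `policy = "user_selected"`.
#' @param alpha prediction-interval level passed to the member models.
#' @return a `qsar_consensus` with an `excluded` data frame (member
#'   `model_id`, `reason`), or `NULL` (with a warning) when no member is
#'   applicable.
#' @export
consensus_for_subgroup <- function(registry, subgroup, target,
                                   policy = c("user_selected", "all",
                                              "in_ad_only"),
                                   selected = NULL, alpha = 0.05) {
  policy <- match.arg(policy)
  stopifnot(inherits(registry, "qsar_registry"))
  tab <- registry$table
  cand <- tab[tab$subgroup == subgroup & tab$type == "mlr", , drop = FALSE]
  if (policy == "user_selected") {
    if (is.null(selected))
      stop("policy 'user_selected' needs 'selected' model ids", call. = FALSE)
    cand <- cand[cand$model_id %in% selected, , drop = FALSE]
  }
  excluded <- data.frame(model_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  vals <- numeric(); uncs <- numeric(); ids <- character()
  for (mid in cand$model_id) {
    model <- registry$models[[mid]]
    pr <- tryCatch(
      predict(model, .target_descriptors(model, target), alpha = alpha),
      error = function(e) e)
    if (inherits(pr, "error")) {
      excluded <- rbind(excluded, data.frame(
        model_id = mid, reason = conditionMessage(pr),
        stringsAsFactors = FALSE))
      next
    }
    if (policy == "in_ad_only" && !pr$in_ad[1]) {
      excluded <- rbind(excluded, data.frame(
        model_id = mid, reason = paste("out of AD:", pr$reasons[1]),
        stringsAsFactors = FALSE))
      next
    }
    vals <- c(vals, pr$value[1]); uncs <- c(uncs, pr$halfwidth[1])
    ids <- c(ids, mid)
  }
  if (!length(vals)) {
    warning("no applicable MLR model in subgroup '", subgroup, "'",
            call. = FALSE)
    return(NULL)
  }
  out <- combine_predictions(vals, uncs, model_ids = ids)
  out$excluded <- excluded
  out$subgroup <- subgroup
  out
}

# resolve a target (qsar_chem or descriptor vector/table row) to the
# descriptor values a given model needs
.target_descriptors <- function(model, target, descriptor_row = NULL) {
  nm <- model$specs$name
  if (inherits(target, "qsar_chem")) {
    vals <- compute_descriptors(target, model$specs)
    if (anyNA(vals)) {
      supplied_nm <- nm[is.na(vals)]
      if (is.null(descriptor_row))
        stop("descriptor(s) must be supplied externally: ",
             paste(supplied_nm, collapse = ", "), call. = FALSE)
      for (d in supplied_nm) {
        if (!d %in% names(descriptor_row))
          stop("descriptor(s) must be supplied externally: ", d,
               call. = FALSE)
        vals[d] <- as.numeric(descriptor_row[[d]])
      }
    }
    return(as.data.frame(as.list(vals)))
  }
  .align_newdata(model, target)
}
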