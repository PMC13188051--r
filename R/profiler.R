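#' Profile target chemicals against every model of a registry
#'
#' Applies each registered model to each target chemical and assembles the
#' report tables: one prediction row per (target, model) pair — inapplicable
#' pairs get a row with a machine-readable skip reason, never a silent drop
#' — plus long-format applicability-domain evidence, per-model neighbor
#' tables, and optional consensus rows per subgroup. Profiling is a pure
#' function of its inputs: repeated runs produce byte-identical exports.
#'
#' @param targets targets in any of these forms: a named character vector of
#'   SMILES, a data frame with `id` and `smiles` columns (optionally
#'   `parent_id`), a list of `qsar_chem` structures, or the result of
#'   [read_smi_file()]. May be `NULL` when every model descriptor is served
#'   from `descriptor_table` (ids then come from the table).
#' @param registry a `qsar_registry` from [load_registry()].
#' @param descriptor_table optional data frame from
#'   [read_descriptor_table()] supplying external descriptor values by
#'   target id.
#' @param alpha prediction-interval level for MLR models (default 0.05).
#' @param neighbors_k neighbors reported per (target, model) (default 5).
#' @param fingerprint fingerprint kind for neighbor detection (see
#'   [compute_fingerprint()]).
#' @param similarity similarity index for neighbor detection.
#' @param consensus consensus policy: `"none"` (default), `"all"`, or
#'   `"in_ad_only"`.
#' @param strict_and conjunctive endpoint-domain reading, see
#'   [endpoint_ad()].
#' @param literal_percentile literal similarity-percentile rule for LDA
#'   models, see [predict.qsar_lda()].
#' @return object of class `qsar_profile`: list of data frames
#'   `predictions`, `ad_details`, `neighbors`, `consensus`, plus `options`.
#' @export
profile_chemicals <- function(targets, registry, descriptor_table = NULL,
                              alpha = 0.05, neighbors_k = 5L,
                              fingerprint = "hashed_path",
                              similarity = "tanimoto",
                              consensus = c("none", "all", "in_ad_only"),
                              strict_and = FALSE,
                              literal_percentile = FALSE) {
  consensus <- match.arg(consensus)
  stopifnot(inherits(registry, "qsar_registry"))
  tl <- .as_targets(targets, descriptor_table)
  if (!length(tl)) stop("no targets", call. = FALSE)
  if (!length(registry$models)) stop("no models in registry", call. = FALSE)

  preds <- list(); addet <- list(); nbrs <- list()
  fp_cache <- new.env(parent = emptyenv())

  for (tg in tl) {
    drow <- if (!is.null(descriptor_table) &&
                tg$id %in% descriptor_table$id)
      descriptor_table[descriptor_table$id == tg$id, , drop = FALSE]
    else NULL
    for (mid in names(registry$models)) {
      model <- registry$models[[mid]]
      md <- model$metadata
      base_row <- data.frame(
        target_id = tg$id,
        parent_id = if (is.null(tg$parent_id)) "" else tg$parent_id,
        smiles = if (is.null(tg$chem)) "" else tg$chem$canonical_smiles,
        model_id = mid, group = md$group, subgroup = md$subgroup,
        model_type = if (inherits(model, "qsar_mlr")) "mlr" else "lda",
        endpoint = md$endpoint_name, units = md$units,
        stringsAsFactors = FALSE)

      if (!is.null(tg$error)) {
        preds[[length(preds) + 1L]] <- cbind(base_row, .empty_pred_cols(
          sprintf("target parse error: %s", tg$error)))
        next
      }
      xv <- tryCatch(
        .target_descriptors(model, if (is.null(tg$chem)) drow else tg$chem,
                            descriptor_row = drow),
        error = function(e) e)
      if (inherits(xv, "error")) {
        preds[[length(preds) + 1L]] <- cbind(base_row, .empty_pred_cols(
          sprintf("skipped: %s", conditionMessage(xv))))
        next
      }

      if (inherits(model, "qsar_mlr")) {
        pr <- predict(model, xv, alpha = alpha, strict_and = strict_and)
        row <- cbind(base_row, data.frame(
          status = "ok", prediction = sprintf("%.17g", pr$value),
          value = pr$value, uncertainty = pr$halfwidth,
          uncertainty_type = "sigma", entropy = NA_real_,
          leverage = pr$leverage, similarity_score = NA_real_,
          structural_in_ad = pr$structural_in_ad,
          endpoint_in_ad = pr$endpoint_in_ad, in_ad = pr$in_ad,
          reasons = pr$reasons, stringsAsFactors = FALSE))
        v <- attr(pr, "verdicts")[[1]]
        addet[[length(addet) + 1L]] <- .verdict_rows(tg$id, mid, v)
      } else {
        pr <- predict(model, xv, literal_percentile = literal_percentile)
        row <- cbind(base_row, data.frame(
          status = "ok", prediction = pr$label, value = NA_real_,
          uncertainty = pr$entropy, uncertainty_type = "entropy_bits",
          entropy = pr$entropy, leverage = NA_real_,
          similarity_score = pr$similarity,
          structural_in_ad = pr$structural_in_ad,
          endpoint_in_ad = pr$endpoint_in_ad, in_ad = pr$in_ad,
          reasons = pr$reasons, stringsAsFactors = FALSE))
        addet[[length(addet) + 1L]] <- data.frame(
          target_id = tg$id, model_id = mid,
          criterion = c("similarity", "posterior_band"),
          status = c(if (pr$structural_in_ad) "pass" else "fail",
                     if (pr$endpoint_in_ad) "pass" else "fail"),
          statistic = c(pr$similarity,
                        pr[[paste0("posterior_", model$event_class)]]),
          stringsAsFactors = FALSE)
      }
      preds[[length(preds) + 1L]] <- row

      nb <- .model_neighbors(model, tg, mid, fp_cache, fingerprint,
                             similarity, neighbors_k, alpha)
      if (!is.null(nb)) nbrs[[length(nbrs) + 1L]] <- nb
    }
  }

  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  ad_details <- if (length(addet)) do.call(rbind, addet) else
    data.frame(target_id = character(), model_id = character(),
               criterion = character(), status = character(),
               statistic = numeric(), stringsAsFactors = FALSE)
  rownames(ad_details) <- NULL
  neighbors <- if (length(nbrs)) do.call(rbind, nbrs) else
    data.frame(target_id = character(), model_id = character(),
               rank = integer(), training_id = character(),
               training_smiles = character(), similarity = numeric(),
               y_experimental = numeric(), y_predicted = numeric(),
               stringsAsFactors = FALSE)
  rownames(neighbors) <- NULL

  cons <- .profile_consensus(predictions, consensus)

  structure(list(predictions = predictions, ad_details = ad_details,
                 neighbors = neighbors, consensus = cons,
                 options = list(alpha = alpha, neighbors_k = neighbors_k,
                                fingerprint = fingerprint,
                                similarity = similarity,
                                consensus = consensus,
                                strict_and = strict_and,
                                literal_percentile = literal_percentile)),
            class = "qsar_profile")
}

.empty_pred_cols <- function(status) {
  data.frame(status = status, prediction = "", value = NA_real_,
             uncertainty = NA_real_, uncertainty_type = "",
             entropy = NA_real_, leverage = NA_real_,
             similarity_score = NA_real_, structural_in_ad = NA,
             endpoint_in_ad = NA, in_ad = NA, reasons = "",
             stringsAsFactors = FALSE)
}

.verdict_rows <- function(target_id, model_id, v) {
  rows <- list()
  for (side in c("structural", "endpoint")) {
    vd <- v[[side]]
    for (crit in names(vd$criteria)) {
      stat <- switch(crit,
                     leverage = vd$details[["leverage"]],
                     std_residual = if ("std_residual" %in% names(vd$details))
                       vd$details[["std_residual"]] else NA_real_,
                     experimental_range = vd$details[["value"]],
                     interval_range = vd$details[["halfwidth"]],
                     NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = target_id, model_id = model_id, criterion = crit,
        status = vd$criteria[[crit]], statistic = stat,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.model_neighbors <- function(model, tg, mid, fp_cache, kind, index, k,
                             alpha) {
  if (is.null(tg$chem)) return(NULL)
  if (!"smiles" %in% names(model$training)) return(NULL)
  key <- paste(mid, kind, sep = "|")
  if (is.null(fp_cache[[key]])) {
    tr_fp <- list()
    for (i in seq_len(nrow(model$training))) {
      smi <- model$training$smiles[i]
      if (!nzchar(smi)) next
      ch <- tryCatch(parse_smiles(smi, model$training$id[i]),
                     error = function(e) NULL)
      if (!is.null(ch))
        tr_fp[[model$training$id[i]]] <- compute_fingerprint(ch, kind)
    }
    fp_cache[[key]] <- tr_fp
  }
  tr_fp <- fp_cache[[key]]
  if (!length(tr_fp)) return(NULL)
  target_fp <- compute_fingerprint(tg$chem, kind)
  hits <- find_neighbors(target_fp, tr_fp, index = index, k = k)
  idx <- match(hits$training_id, model$training$id)
  if (inherits(model, "qsar_mlr")) {
    y_exp <- model$training$y[idx]
    y_pred <- model$fitted[idx]
  } else {
    y_exp <- model$training$class[idx]
    y_pred <- predict(model, model$training[idx, model$specs$name,
                                            drop = FALSE],
                      check_ad = FALSE)$label
  }
  data.frame(target_id = tg$id, model_id = mid, rank = hits$rank,
             training_id = hits$training_id,
             training_smiles = model$training$smiles[idx],
             similarity = hits$similarity,
             y_experimental = y_exp, y_predicted = y_pred,
             stringsAsFactors = FALSE)
}

.profile_consensus <- function(predictions, policy) {
  empty <- data.frame(target_id = character(), subgroup = character(),
                      value = numeric(), uncertainty = numeric(),
                      n_members = integer(), members = character(),
                      excluded = character(), stringsAsFactors = FALSE)
  if (policy == "none") return(empty)
  rows <- list()
  mlr <- predictions[predictions$model_type == "mlr" &
                       predictions$status == "ok", , drop = FALSE]
  for (tid in unique(predictions$target_id)) {
    for (sg in unique(mlr$subgroup[mlr$target_id == tid])) {
      mem <- mlr[mlr$target_id == tid & mlr$subgroup == sg, , drop = FALSE]
      excl <- character()
      if (policy == "in_ad_only") {
        out <- mem[!mem$in_ad, , drop = FALSE]
        excl <- sprintf("%s (out of AD: %s)", out$model_id, out$reasons)
        mem <- mem[mem$in_ad, , drop = FALSE]
      }
      if (!nrow(mem)) {
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = tid, subgroup = sg, value = NA_real_,
          uncertainty = NA_real_, n_members = 0L, members = "",
          excluded = paste(excl, collapse = "; "), stringsAsFactors = FALSE)
        next
      }
      cc <- combine_predictions(mem$value, mem$uncertainty,
                                model_ids = mem$model_id)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tid, subgroup = sg, value = cc$value,
        uncertainty = cc$uncertainty, n_members = cc$n,
        members = paste(mem$model_id, collapse = ";"),
        excluded = paste(excl, collapse = "; "), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

.as_targets <- function(targets, descriptor_table = NULL) {
  if (is.null(targets)) {
    if (is.null(descriptor_table))
      stop("either targets or a descriptor table is required", call. = FALSE)
    return(lapply(descriptor_table$id, function(id)
      list(id = id, chem = NULL, error = NULL, parent_id = NULL)))
  }
  if (is.list(targets) && !is.data.frame(targets) &&
      all(c("chemicals", "failures") %in% names(targets))) {
    ok <- lapply(targets$chemicals, function(ch)
      list(id = ch$id, chem = ch, error = NULL, parent_id = NULL))
    bad <- lapply(seq_len(nrow(targets$failures)), function(i)
      list(id = targets$failures$id[i], chem = NULL,
           error = targets$failures$error[i], parent_id = NULL))
    return(c(ok, bad))
  }
  if (is.character(targets)) {
    ids <- names(targets)
    if (is.null(ids)) ids <- targets
    targets <- data.frame(id = ids, smiles = unname(targets),
                          stringsAsFactors = FALSE)
  }
  if (is.data.frame(targets)) {
    stopifnot(all(c("id", "smiles") %in% names(targets)))
    return(lapply(seq_len(nrow(targets)), function(i) {
      ch <- tryCatch(parse_smiles(targets$smiles[i], targets$id[i]),
                     error = function(e) e)
      if (inherits(ch, "error"))
        list(id = targets$id[i], chem = NULL,
             error = conditionMessage(ch),
             parent_id = if ("parent_id" %in% names(targets))
               targets$parent_id[i] else NULL)
      else
        list(id = targets$id[i], chem = ch, error = NULL,
             parent_id = if ("parent_id" %in% names(targets))
               targets$parent_id[i] else NULL)
    }))
  }
  if (is.list(targets)) {
    stopifnot(all(vapply(targets, inherits, logical(1), "qsar_chem")))
    return(lapply(targets, function(ch)
      list(id = ch$id, chem = ch, error = NULL, parent_id = NULL)))
  }
  stop("unsupported targets form", call. = FALSE)
}

#' @export
print.qsar_profile <- function(x, ...) {
  cat(sprintf("Profile: %d prediction row(s), %d consensus row(s), %d neighbor row(s)\n",
              nrow(x$predictions), nrow(x$consensus), nrow(x$neighbors)))
  ok <- sum(x$predictions$status == "ok")
  cat(sprintf("  %d ok, %d skipped/errored\n", ok,
              nrow(x$predictions) - ok))
  invisible(x)
}

#' Expand targets with metabolites from a pluggable hook
#'
#' The hook is an external-process boundary: any function mapping a parent
#' SMILES to its predicted metabolites (for instance an adapter around a
#' metabolism simulator run as a subprocess). It must be a pure function
#' returning a data frame with columns `smiles` and `reaction` (or a list
#' of such pairs). Metabolites are appended as new targets with the parent
#' linkage recorded; a hook failure leaves the parent profiled alone with a
#' warning. No hook is bundled.
#'
#' @param targets data frame with `id` and `smiles` columns (or a named
#'   SMILES vector).
#' @param hook function `smiles -> data.frame(smiles, reaction)`, or `NULL`
#'   (targets returned unchanged).
#' @return data frame with columns `id`, `smiles`, `parent_id`, `reaction`
#'   (empty strings for parents).
#' @export
expand_metabolites <- function(targets, hook = NULL) {
  if (is.character(targets)) {
    ids <- names(targets); if (is.null(ids)) ids <- targets
    targets <- data.frame(id = ids, smiles = unname(targets),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(targets), all(c("id", "smiles") %in% names(targets)))
  out <- data.frame(id = targets$id, smiles = targets$smiles,
                    parent_id = "", reaction = "", stringsAsFactors = FALSE)
  if (is.null(hook)) return(out)
  stopifnot(is.function(hook))
  extra <- list()
  for (i in seq_len(nrow(targets))) {
    mets <- tryCatch(hook(targets$smiles[i]), error = function(e) e)
    if (inherits(mets, "error")) {
      warning(sprintf("metabolite hook failed for '%s': %s; parent profiled alone",
                      targets$id[i], conditionMessage(mets)), call. = FALSE)
      next
    }
    if (is.null(mets) || !length(mets)) next
    if (!is.data.frame(mets))
      mets <- do.call(rbind, lapply(mets, function(m)
        data.frame(smiles = m[[1]], reaction = m[[2]],
                   stringsAsFactors = FALSE)))
    for (j in seq_len(nrow(mets)))
      extra[[length(extra) + 1L]] <- data.frame(
        id = sprintf("%s_M%d", targets$id[i], j), smiles = mets$smiles[j],
        parent_id = targets$id[i], reaction = mets$reaction[j],
        stringsAsFactors = FALSE)
  }
  rbind(out, if (length(extra)) do.call(rbind, extra))
}

#' Export profile tables as report-ready files
#'
#' Writes four tables — predictions, consensus, neighbors and
#' applicability-domain details — with the traceability columns a QSAR
#' prediction reporting format (QPRF) needs: model citation, units and
#' endpoint names echoed verbatim, domain criteria with numeric evidence,
#' uncertainties, and neighbor experimental values. CSV is the canonical,
#' bit-exact format.
#'
#' @param profile a `qsar_profile` object.
#' @param dir output directory (created if needed).
#' @param format export format; `"csv"` is supported.
#' @param registry optional registry used to add the model citation column.
#' @return invisibly, the paths of the written files.
#' @export
export_report <- function(profile, dir, format = "csv", registry = NULL) {
  stopifnot(inherits(profile, "qsar_profile"))
  if (!identical(format, "csv"))
    stop("unsupported format '", format, "'; supported: csv", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  preds <- profile$predictions
  if (!is.null(registry)) {
    cit <- vapply(preds$model_id, function(mid)
      if (mid %in% names(registry$models))
        registry$models[[mid]]$metadata$citation else "", character(1))
    preds$citation <- unname(cit)
  }
  paths <- file.path(dir, c("predictions.csv", "consensus.csv",
                            "neighbors.csv", "ad_details.csv"))
  utils::write.csv(preds, paths[1], row.names = FALSE)
  utils::write.csv(profile$consensus, paths[2], row.names = FALSE)
  utils::write.csv(profile$neighbors, paths[3], row.names = FALSE)
  utils::write.csv(profile$ad_details, paths[4], row.names = FALSE)
  invisible(paths)
}
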