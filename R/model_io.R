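#' Parse a QSA(P)R model definition from XML
#'
#' Reads the package's documented XML dialect (see Details) and returns a
#' fully fitted model: fit statistics are always recomputed from the
#' embedded training data, and if the document also carries published
#' coefficients they are verified against the recomputed fit to a tolerance
#' of 1e-6 (a mismatch is a validation error, not a silent override).
#' Coefficients without training data are rejected: every applicability
#' domain statistic requires the training descriptor matrix.
#'
#' @details
#' Document structure (`type` is `"mlr"` or `"lda"`):
#' ```
#' <qsar_model type="mlr" version="1">
#'   <metadata id=".." endpoint=".." units=".." group=".." subgroup=".."
#'             citation=".."/>
#'   <descriptors>
#'     <descriptor name="d1" source="supplied|computed">description</descriptor>
#'   </descriptors>
#'   <training>
#'     <chemical id="c1" smiles="CCO">
#'       <value d="d1">1.2345</value>
#'       <endpoint>3.4</endpoint>          <!-- class label for type="lda" -->
#'     </chemical>
#'   </training>
#'   <coefficients intercept="..">          <!-- optional, mlr only -->
#'     <coef d="d1">..</coef>
#'   </coefficients>
#'   <lda_settings event_class=".." percentile="0.95"/>  <!-- optional -->
#' </qsar_model>
#' ```
#' Real numbers are serialized with 17 significant digits so a
#' write/parse round-trip reproduces every double exactly.
#'
#' @param x path to an XML file, or a single string of XML text.
#' @return a fitted `qsar_mlr` or `qsar_lda` model.
#' @export
parse_model_xml <- function(x) {
  doc <- tryCatch({
    if (length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x))
      xml2::read_xml(x)
    else xml2::read_xml(paste(x, collapse = "\n"))
  }, error = function(e)
    stop("not well-formed XML: ", conditionMessage(e), call. = FALSE))

  root <- xml2::xml_name(doc)
  if (root != "qsar_model")
    stop("schema violation at <", root, ">: root element must be <qsar_model>",
         call. = FALSE)
  type <- xml2::xml_attr(doc, "type")
  if (!type %in% c("mlr", "lda"))
    stop("schema violation at <qsar_model>: type must be 'mlr' or 'lda'",
         call. = FALSE)

  meta_node <- xml2::xml_find_first(doc, "./metadata")
  if (is.na(meta_node))
    stop("schema violation: missing <metadata>", call. = FALSE)
  meta <- list(
    model_id = xml2::xml_attr(meta_node, "id"),
    endpoint_name = xml2::xml_attr(meta_node, "endpoint"),
    units = xml2::xml_attr(meta_node, "units"),
    group = xml2::xml_attr(meta_node, "group"),
    subgroup = xml2::xml_attr(meta_node, "subgroup"),
    citation = xml2::xml_attr(meta_node, "citation"))
  meta <- lapply(meta, function(v) if (is.na(v)) "" else v)
  if (!nzchar(meta$model_id))
    stop("schema violation at <metadata>: 'id' attribute required",
         call. = FALSE)

  desc_nodes <- xml2::xml_find_all(doc, "./descriptors/descriptor")
  if (!length(desc_nodes))
    stop("schema violation: at least one <descriptor> required",
         call. = FALSE)
  specs <- data.frame(
    name = xml2::xml_attr(desc_nodes, "name"),
    source = xml2::xml_attr(desc_nodes, "source"),
    description = xml2::xml_text(desc_nodes),
    stringsAsFactors = FALSE)
  specs$source[is.na(specs$source)] <- "supplied"
  if (anyNA(specs$name) || any(!nzchar(specs$name)))
    stop("schema violation at <descriptor>: 'name' attribute required",
         call. = FALSE)
  if (anyDuplicated(specs$name))
    stop("schema violation: duplicated descriptor name '",
         specs$name[duplicated(specs$name)][1], "'", call. = FALSE)

  chem_nodes <- xml2::xml_find_all(doc, "./training/chemical")
  coef_node <- xml2::xml_find_first(doc, "./coefficients")
  if (!length(chem_nodes)) {
    if (!is.na(coef_node))
      stop("coefficients without training data are not accepted: ",
           "applicability-domain statistics require the training matrix",
           call. = FALSE)
    stop("schema violation: missing <training> chemicals", call. = FALSE)
  }

  p <- nrow(specs)
  n <- length(chem_nodes)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, specs$name))
  ids <- character(n); smi <- character(n); yv <- character(n)
  for (i in seq_len(n)) {
    ch <- chem_nodes[[i]]
    id <- xml2::xml_attr(ch, "id")
    if (is.na(id) || !nzchar(id))
      stop("schema violation at <chemical> #", i, ": 'id' required",
           call. = FALSE)
    ids[i] <- id
    smi[i] <- xml2::xml_attr(ch, "smiles")
    vals <- xml2::xml_find_all(ch, "./value")
    dnames <- xml2::xml_attr(vals, "d")
    if (length(vals) != p || !setequal(dnames, specs$name) ||
        anyDuplicated(dnames))
      stop(sprintf("chemical '%s': expected one <value> per descriptor (%s), got: %s",
                   id, paste(specs$name, collapse = ", "),
                   paste(dnames, collapse = ", ")), call. = FALSE)
    v <- as.numeric(xml2::xml_text(vals))
    if (anyNA(v))
      stop(sprintf("chemical '%s': non-numeric descriptor value", id),
           call. = FALSE)
    X[i, dnames] <- v
    ep <- xml2::xml_find_first(ch, "./endpoint")
    if (is.na(ep))
      stop(sprintf("chemical '%s': missing <endpoint>", id), call. = FALSE)
    yv[i] <- xml2::xml_text(ep)
  }
  if (anyDuplicated(ids))
    stop("schema violation: duplicated chemical id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)

  training <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!all(is.na(smi))) training$smiles <- ifelse(is.na(smi), "", smi)
  training <- cbind(training, as.data.frame(X))

  if (type == "mlr") {
    training$y <- as.numeric(yv)
    if (anyNA(training$y))
      stop("non-numeric <endpoint> value in an mlr model", call. = FALSE)
    model <- qsar_mlr(training, specs, response = "y", metadata = meta)
    if (!is.na(coef_node)) {
      b0 <- as.numeric(xml2::xml_attr(coef_node, "intercept"))
      coefs <- xml2::xml_find_all(coef_node, "./coef")
      cd <- xml2::xml_attr(coefs, "d")
      cv <- as.numeric(xml2::xml_text(coefs))
      if (is.na(b0) || anyNA(cv) || !setequal(cd, specs$name))
        stop("schema violation at <coefficients>: intercept attribute and one <coef> per descriptor required",
             call. = FALSE)
      declared <- c(b0, cv[match(specs$name, cd)])
      if (max(abs(declared - unname(model$beta))) > 1e-6)
        stop(sprintf("validation error: declared coefficients disagree with the training-data fit (max abs diff %.3g > 1e-6)",
                     max(abs(declared - unname(model$beta)))), call. = FALSE)
    }
    model
  } else {
    if (!is.na(coef_node))
      stop("schema violation: <coefficients> is only valid for type='mlr'",
           call. = FALSE)
    training$class <- yv
    set_node <- xml2::xml_find_first(doc, "./lda_settings")
    ev <- pct <- NULL
    if (!is.na(set_node)) {
      ev <- xml2::xml_attr(set_node, "event_class")
      if (is.na(ev)) ev <- NULL
      pct <- as.numeric(xml2::xml_attr(set_node, "percentile"))
      if (is.na(pct)) pct <- 0.95
    } else pct <- 0.95
    qsar_lda(training, specs, response = "class", event_class = ev,
             percentile = pct, metadata = meta)
  }
}

#' Serialize a fitted model to XML
#'
#' Writes the training data (the authoritative content: every statistic can
#' be recomputed from it), the descriptor specification, metadata and — for
#' MLR models — the fitted coefficients. Reals use 17 significant digits so
#' that `parse_model_xml(write_model_xml(m))` reproduces `m` exactly.
#'
#' @param model a `qsar_mlr` or `qsar_lda` object.
#' @param path optional file path; when given the document is also written
#'   there.
#' @return the XML document as a single string (invisibly when `path` is
#'   given).
#' @export
write_model_xml <- function(model, path = NULL) {
  stopifnot(inherits(model, "qsar_mlr") || inherits(model, "qsar_lda"))
  type <- if (inherits(model, "qsar_mlr")) "mlr" else "lda"
  num <- function(x) sprintf("%.17g", x)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  md <- model$metadata
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<qsar_model type="%s" version="1">', type),
    sprintf('  <metadata id="%s" endpoint="%s" units="%s" group="%s" subgroup="%s" citation="%s"/>',
            esc(md$model_id), esc(md$endpoint_name), esc(md$units),
            esc(md$group), esc(md$subgroup), esc(md$citation)),
    "  <descriptors>",
    sprintf('    <descriptor name="%s" source="%s">%s</descriptor>',
            esc(model$specs$name), esc(model$specs$source),
            esc(model$specs$description)),
    "  </descriptors>",
    "  <training>")
  has_smiles <- "smiles" %in% names(model$training)
  resp <- if (type == "mlr") "y" else "class"
  for (i in seq_len(nrow(model$training))) {
    row <- model$training[i, ]
    out <- c(out, sprintf('    <chemical id="%s"%s>', esc(row$id),
                          if (has_smiles && nzchar(row$smiles))
                            sprintf(' smiles="%s"', esc(row$smiles)) else ""))
    for (d in model$specs$name)
      out <- c(out, sprintf('      <value d="%s">%s</value>', esc(d),
                            num(row[[d]])))
    ep <- if (type == "mlr") num(row$y) else esc(row$class)
    out <- c(out, sprintf("      <endpoint>%s</endpoint>", ep),
             "    </chemical>")
  }
  out <- c(out, "  </training>")
  if (type == "mlr") {
    out <- c(out,
             sprintf('  <coefficients intercept="%s">', num(model$beta[1])),
             sprintf('    <coef d="%s">%s</coef>', esc(model$specs$name),
                     num(model$beta[-1])),
             "  </coefficients>")
  } else {
    out <- c(out, sprintf('  <lda_settings event_class="%s" percentile="%s"/>',
                          esc(model$event_class), num(model$percentile)))
  }
  out <- c(out, "</qsar_model>")
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = FALSE)
    return(invisible(txt))
  }
  txt
}

#' Load a model registry from a configuration file
#'
#' The configuration is a plain key-value text file (lines `key = value`,
#' `#` comments). Recognized keys:
#' * `dir = <path>` (repeatable) — directory scanned for `*.xml` model
#'   files; relative paths resolve against the config file's location.
#' * `assign <model_id> = <group> / <subgroup>` — overrides the
#'   group/subgroup carried in a model's metadata.
#'
#' Every load decision is logged; unparseable model files are reported as
#' diagnostics but are not fatal. An empty registry is a warning, not an
#' error.
#'
#' @param config path to the configuration file.
#' @param quiet suppress per-file messages (default `FALSE`).
#' @return object of class `qsar_registry`: list with `models` (named list),
#'   `table` (data frame: `model_id`, `type`, `group`, `subgroup`, `file`),
#'   `failures` (data frame: `file`, `error`), `log` (character).
#' @export
load_registry <- function(config, quiet = FALSE) {
  lines <- readLines(config, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  base <- dirname(normalizePath(config))
  dirs <- character()
  assigns <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "dir") {
      d <- if (grepl("^(/|[A-Za-z]:)", val)) val else file.path(base, val)
      dirs <- c(dirs, d)
    } else if (startsWith(key, "assign ")) {
      mid <- trimws(sub("^assign ", "", key))
      gs <- trimws(strsplit(val, "/", fixed = TRUE)[[1]])
      if (length(gs) != 2L)
        stop("bad assignment (want 'group / subgroup'): ", ln, call. = FALSE)
      assigns[[mid]] <- gs
    } else stop("unknown config key: ", key, call. = FALSE)
  }

  models <- list()
  log <- character()
  failures <- data.frame(file = character(), error = character(),
                         stringsAsFactors = FALSE)
  tab <- data.frame(model_id = character(), type = character(),
                    group = character(), subgroup = character(),
                    file = character(), stringsAsFactors = FALSE)
  note <- function(msg) {
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  for (d in dirs) {
    files <- sort(list.files(d, pattern = "\\.xml$", full.names = TRUE))
    if (!length(files)) { note(sprintf("directory '%s': no model files", d)); next }
    for (f in files) {
      m <- tryCatch(parse_model_xml(f), error = function(e) e)
      if (inherits(m, "error")) {
        failures <- rbind(failures, data.frame(
          file = f, error = conditionMessage(m), stringsAsFactors = FALSE))
        note(sprintf("SKIP %s: %s", basename(f), conditionMessage(m)))
        next
      }
      mid <- m$metadata$model_id
      if (mid %in% names(models)) {
        failures <- rbind(failures, data.frame(
          file = f, error = paste("duplicate model id", mid),
          stringsAsFactors = FALSE))
        note(sprintf("SKIP %s: duplicate model id '%s'", basename(f), mid))
        next
      }
      if (mid %in% names(assigns)) {
        m$metadata$group <- assigns[[mid]][1]
        m$metadata$subgroup <- assigns[[mid]][2]
      }
      models[[mid]] <- m
      tab <- rbind(tab, data.frame(
        model_id = mid, type = if (inherits(m, "qsar_mlr")) "mlr" else "lda",
        group = m$metadata$group, subgroup = m$metadata$subgroup,
        file = f, stringsAsFactors = FALSE))
      note(sprintf("LOAD %s: %s model '%s' [%s / %s]", basename(f),
                   toupper(tab$type[nrow(tab)]), mid, m$metadata$group,
                   m$metadata$subgroup))
    }
  }
  if (!length(models))
    warning("registry is empty: no model could be loaded", call. = FALSE)
  structure(list(models = models, table = tab, failures = failures,
                 log = log),
            class = "qsar_registry")
}

#' @export
print.qsar_registry <- function(x, ...) {
  cat(sprintf("QSA(P)R model registry: %d model(s), %d failure(s)\n",
              length(x$models), nrow(x$failures)))
  if (nrow(x$table)) print(x$table[, c("model_id", "type", "group",
                                       "subgroup")], row.names = FALSE)
  invisible(x)
}
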