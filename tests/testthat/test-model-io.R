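minimal_mlr_xml <- function() {
  paste0(
    '<qsar_model type="mlr" version="1">',
    '<metadata id="mini" endpoint="logK" units="log" group="G" subgroup="S" citation="c"/>',
    '<descriptors><descriptor name="x" source="supplied">a descriptor</descriptor></descriptors>',
    '<training>',
    '<chemical id="c1"><value d="x">1</value><endpoint>2</endpoint></chemical>',
    '<chemical id="c2"><value d="x">2</value><endpoint>4.1</endpoint></chemical>',
    '<chemical id="c3"><value d="x">3</value><endpoint>5.9</endpoint></chemical>',
    '<chemical id="c4"><value d="x">4</value><endpoint>8</endpoint></chemical>',
    '</training></qsar_model>')
}

model_fields_equal <- function(a, b, tol = 1e-12) {
  expect_identical(class(a), class(b))
  expect_identical(a$specs, b$specs)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$training$id, b$training$id)
  if (inherits(a, "qsar_mlr")) {
    expect_equal(a$beta, b$beta, tolerance = tol)
    expect_equal(a$s, b$s, tolerance = tol)
    expect_equal(a$hat_diag, b$hat_diag, tolerance = tol)
    expect_equal(a$y_range, b$y_range, tolerance = tol)
    expect_equal(a$halfwidth_range, b$halfwidth_range, tolerance = tol)
  } else {
    expect_equal(a$class_means, b$class_means, tolerance = tol)
    expect_equal(a$priors, b$priors, tolerance = tol)
    expect_equal(a$train_scores, b$train_scores, tolerance = tol)
    expect_equal(a$sim_cutoff, b$sim_cutoff, tolerance = tol)
    expect_identical(a$event_class, b$event_class)
  }
}

test_that("a minimal 1-descriptor document parses into a fitted model", {
  m <- suppressWarnings(parse_model_xml(minimal_mlr_xml()))
  expect_s3_class(m, "qsar_mlr")
  expect_equal(m$p, 1); expect_equal(m$n, 4)
  expect_equal(unname(coef(m)), c(0, 2), tolerance = 0.1)
})

test_that("schema violations are reported with the offending element", {
  bad <- sub('<value d="x">2</value>',
             '<value d="x">2</value><value d="zz">9</value>',
             minimal_mlr_xml(), fixed = TRUE)
  expect_error(parse_model_xml(bad), "c2")
  expect_error(parse_model_xml("<nope/>"), "qsar_model")
  expect_error(parse_model_xml("<qsar_model type='svm'/>"), "mlr")
  expect_error(parse_model_xml("<qsar_model type='mlr'>not closed"),
               "well-formed")
  no_train <- paste0(
    '<qsar_model type="mlr"><metadata id="m"/>',
    '<descriptors><descriptor name="x"/></descriptors>',
    '<coefficients intercept="0"><coef d="x">1</coef></coefficients>',
    '</qsar_model>')
  expect_error(parse_model_xml(no_train), "training")
})

test_that("declared coefficients are verified against the training fit", {
  fx <- make_mlr_fixture(n = 20, p = 2, seed = 40)
  txt <- write_model_xml(fx$model)
  # round-trip keeps the declared coefficients consistent
  m2 <- parse_model_xml(txt)
  model_fields_equal(fx$model, m2)
  # a perturbed coefficient beyond 1e-6 is a validation error
  b1 <- sprintf("%.17g", fx$model$beta[2])
  corrupted <- sub(b1, sprintf("%.17g", fx$model$beta[2] + 1e-4),
                   txt, fixed = TRUE)
  expect_error(parse_model_xml(corrupted), "disagree")
})

test_that("write/parse round-trips 100 random models exactly", {
  set.seed(41)
  for (rep in 1:100) {
    if (rep %% 2 == 0) {
      fx <- make_mlr_fixture(n = sample(13:25, 1), p = sample(1:3, 1),
                             noise_sd = runif(1, 0, 2), seed = 1000 + rep)
    } else {
      fx <- make_lda_fixture(n = sample(10:25, 1), p = sample(1:3, 1),
                             class_separation = runif(1, 1, 8),
                             seed = 1000 + rep)
    }
    m2 <- parse_model_xml(write_model_xml(fx$model))
    model_fields_equal(fx$model, m2)
  }
})

test_that("unicode metadata survives the round-trip", {
  fx <- make_mlr_fixture(n = 12, p = 1, seed = 42)
  fx$model$metadata$endpoint_name <- "log Kₒᴄ (µg/L) — toxé"
  fx$model$metadata$citation <- "Müller & Ł 2020 <i>&amp;</i>"
  m2 <- parse_model_xml(write_model_xml(fx$model))
  expect_identical(m2$metadata$endpoint_name, fx$model$metadata$endpoint_name)
  expect_identical(m2$metadata$citation, fx$model$metadata$citation)
})

test_that("registry loading isolates corrupt files and mirrors assignments", {
  dirp <- withr::local_tempdir()
  mdir <- file.path(dirp, "models"); dir.create(mdir)
  for (i in 1:3) {
    fx <- make_mlr_fixture(n = 15, p = 2, seed = 50 + i)
    write_model_xml(fx$model, file.path(mdir, sprintf("ok%d.xml", i)))
  }
  writeLines("<qsar_model type='mlr'>broken", file.path(mdir, "bad.xml"))
  cfg <- file.path(dirp, "reg.cfg")
  writeLines(c("# test registry", "dir = models",
               "assign synthetic-mlr-52 = Regrouped / Special"), cfg)
  reg <- load_registry(cfg, quiet = TRUE)
  expect_length(reg$models, 3)
  expect_equal(nrow(reg$failures), 1)
  expect_match(reg$failures$file, "bad.xml")
  tab <- reg$table
  expect_identical(tab$subgroup[tab$model_id == "synthetic-mlr-52"], "Special")
  expect_identical(tab$group[tab$model_id == "synthetic-mlr-52"], "Regrouped")

  empt <- file.path(dirp, "empty"); dir.create(empt)
  cfg2 <- file.path(dirp, "reg2.cfg")
  writeLines("dir = empty", cfg2)
  expect_warning(reg2 <- load_registry(cfg2, quiet = TRUE), "empty")
  expect_length(reg2$models, 0)
})
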