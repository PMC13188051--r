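# a small registry of two MLR models (shared subgroup) and one LDA model,
# all on computed descriptors so SMILES targets can be profiled directly
make_profiler_registry <- function(dirp) {
  mdir <- file.path(dirp, "models"); dir.create(mdir)
  chems <- toy_chemical_set()
  desc <- c("molecular_weight", "heavy_atom_count")
  X <- t(vapply(chems, function(ch) compute_descriptors(ch, desc),
                numeric(2)))
  smiles <- vapply(chems, function(ch) ch$smiles, character(1))
  set.seed(60)
  tr <- data.frame(id = names(chems), smiles = smiles, X,
                   stringsAsFactors = FALSE)
  tr$y <- 0.02 * tr$molecular_weight + 0.1 * tr$heavy_atom_count +
    rnorm(nrow(tr), sd = 0.1)
  m1 <- qsar_mlr(tr, desc, metadata = list(
    model_id = "mlr-a", endpoint_name = "toy logP", units = "log",
    group = "Properties", subgroup = "Toy", citation = "fixture A"))
  tr2 <- tr; tr2$y <- tr$y + rnorm(nrow(tr), sd = 0.05)
  m2 <- qsar_mlr(tr2, desc, metadata = list(
    model_id = "mlr-b", endpoint_name = "toy logP", units = "log",
    group = "Properties", subgroup = "Toy", citation = "fixture B"))
  tr3 <- tr
  tr3$class <- ifelse(tr$molecular_weight > stats::median(tr$molecular_weight),
                      "heavy", "light")
  m3 <- qsar_lda(tr3, desc, metadata = list(
    model_id = "lda-a", endpoint_name = "toy class",
    group = "Properties", subgroup = "Toy classification",
    citation = "fixture C"))
  write_model_xml(m1, file.path(mdir, "m1.xml"))
  write_model_xml(m2, file.path(mdir, "m2.xml"))
  write_model_xml(m3, file.path(mdir, "m3.xml"))
  cfg <- file.path(dirp, "registry.cfg")
  writeLines("dir = models", cfg)
  load_registry(cfg, quiet = TRUE)
}

test_that("profiling yields the full target x model cross product", {
  dirp <- withr::local_tempdir()
  reg <- make_profiler_registry(dirp)
  targets <- c(tol = "Cc1ccccc1", eth = "CCO")
  prof <- profile_chemicals(targets, reg, consensus = "all")
  expect_equal(nrow(prof$predictions), 2 * 3)
  expect_true(all(prof$predictions$status == "ok"))
  # rows carry uncertainty labelled by type
  expect_setequal(unique(prof$predictions$uncertainty_type),
                  c("sigma", "entropy_bits"))
  # consensus over the 2-member MLR subgroup for each target
  expect_equal(nrow(prof$consensus), 2)
  expect_equal(prof$consensus$n_members, c(2L, 2L))
  # neighbors: k rows per (target, model)
  expect_equal(nrow(prof$neighbors), 2 * 3 * 5)
  expect_true(all(prof$neighbors$similarity >= 0 &
                    prof$neighbors$similarity <= 1))
})

test_that("an unparsable target is isolated; others are unaffected", {
  dirp <- withr::local_tempdir()
  reg <- make_profiler_registry(dirp)
  targets <- data.frame(id = c("good", "bad"),
                        smiles = c("CCO", "C1CC"),
                        stringsAsFactors = FALSE)
  prof <- profile_chemicals(targets, reg)
  bad_rows <- prof$predictions[prof$predictions$target_id == "bad", ]
  expect_equal(nrow(bad_rows), 3)
  expect_true(all(grepl("parse error", bad_rows$status)))
  good_rows <- prof$predictions[prof$predictions$target_id == "good", ]
  expect_true(all(good_rows$status == "ok"))
})

test_that("profiling is deterministic: reruns export byte-identical files", {
  dirp <- withr::local_tempdir()
  reg <- make_profiler_registry(dirp)
  targets <- c(a = "CCCC", b = "c1ccccc1")
  out1 <- file.path(dirp, "out1"); out2 <- file.path(dirp, "out2")
  p1 <- profile_chemicals(targets, reg, consensus = "all")
  p2 <- profile_chemicals(targets, reg, consensus = "all")
  f1 <- export_report(p1, out1, registry = reg)
  f2 <- export_report(p2, out2, registry = reg)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})

test_that("CSV export round-trips and carries the QPRF evidence columns", {
  dirp <- withr::local_tempdir()
  reg <- make_profiler_registry(dirp)
  prof <- profile_chemicals(c(x = "CCO"), reg, consensus = "all")
  files <- export_report(prof, file.path(dirp, "rep"), registry = reg)
  expect_length(files, 4)
  back <- read.csv(files[1], stringsAsFactors = FALSE)
  expect_equal(back$value, prof$predictions$value)
  expect_equal(back$model_id, prof$predictions$model_id)
  expect_true("citation" %in% names(back))
  ad <- read.csv(files[4], stringsAsFactors = FALSE)
  expect_true(all(c("leverage", "experimental_range", "interval_range") %in%
                    ad$criterion[ad$model_id == "mlr-a"]))
  expect_error(export_report(prof, dirp, format = "xlsx"), "csv")
})

test_that("externally supplied descriptor tables feed models lacking SMILES", {
  # model on a descriptor the built-in set cannot compute
  set.seed(61)
  tr <- data.frame(id = sprintf("t%02d", 1:15),
                   zeta = rnorm(15), y = rnorm(15))
  tr$y <- 1 + 2 * tr$zeta + rnorm(15, sd = 0.2)
  m <- qsar_mlr(tr, data.frame(name = "zeta", source = "supplied"),
                metadata = list(model_id = "ext", group = "G",
                                subgroup = "S"))
  dirp <- withr::local_tempdir()
  mdir <- file.path(dirp, "models"); dir.create(mdir)
  write_model_xml(m, file.path(mdir, "ext.xml"))
  writeLines("dir = models", file.path(dirp, "cfg"))
  reg <- load_registry(file.path(dirp, "cfg"), quiet = TRUE)

  dt <- data.frame(id = "q1", zeta = 0.5, stringsAsFactors = FALSE)
  prof <- profile_chemicals(NULL, reg, descriptor_table = dt)
  expect_equal(nrow(prof$predictions), 1)
  expect_identical(prof$predictions$status, "ok")
  expect_equal(prof$predictions$value, 1 + 2 * 0.5, tolerance = 0.5)

  # a SMILES target without the supplied descriptor gets a skip reason
  prof2 <- profile_chemicals(c(q2 = "CCO"), reg)
  expect_match(prof2$predictions$status, "skipped.*zeta")
})

test_that("metabolite expansion records lineage and tolerates hook failure", {
  targets <- data.frame(id = c("p1", "p2"), smiles = c("CCO", "CCC"),
                        stringsAsFactors = FALSE)
  hook <- function(smiles) data.frame(
    smiles = c(sub("O$", "", smiles), "C"),
    reaction = c("dealkylation", "demethylation"),
    stringsAsFactors = FALSE)
  out <- expand_metabolites(targets, hook)
  expect_equal(nrow(out), 6)
  expect_identical(out$parent_id, c("", "", "p1", "p1", "p2", "p2"))
  expect_identical(out$id[3], "p1_M1")
  expect_identical(out$reaction[4], "demethylation")
  # no hook: unchanged
  expect_equal(nrow(expand_metabolites(targets)), 2)
  # failing hook: parents survive with a warning
  boom <- function(smiles) stop("external tool crashed")
  expect_warning(expect_warning(out2 <- expand_metabolites(targets, boom),
                                "profiled alone"))   # once per parent
  expect_equal(nrow(out2), 2)
})
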