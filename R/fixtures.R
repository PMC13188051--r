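#' Synthetic MLR model fixture with known ground truth
#'
#' Generates a training set with independent standard-Gaussian descriptors
#' and `y = beta0 + X beta + N(0, noise_sd)`, fits a [qsar_mlr()] model to
#' it, and returns labelled held-out queries: in-distribution points drawn
#' from the same Gaussian and deliberately extrapolated points placed 10
#' training-SDs from the descriptor centroid (guaranteed beyond the leverage
#' cutoff for any reasonable n).
#'
#' Everything is reproducible from the seed: the same seed always yields an
#' identical fixture.
#'
#' @param n training-set size (default 30).
#' @param p number of descriptors (default 3).
#' @param beta_true coefficient vector, intercept first (length `p + 1`);
#'   default intercept 1 and unit slopes.
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param n_query number of in-distribution held-out queries (default 5).
#' @param n_extrapolated number of extrapolated queries (default 2).
#' @param seed RNG seed (default 1).
#' @return list with `model` (a `qsar_mlr`), `queries` (data frame with
#'   descriptor columns, `y_true`, `kind` in `{"interpolated",
#'   "extrapolated"}`), `beta_true`, `noise_sd`.
#' @export
make_mlr_fixture <- function(n = 30L, p = 3L, beta_true = c(1, rep(1, p)),
                             noise_sd = 1, n_query = 5L,
                             n_extrapolated = 2L, seed = 1L) {
  stopifnot(n >= p + 2L, length(beta_true) == p + 1L, noise_sd >= 0)
  set.seed(seed)
  nm <- paste0("d", seq_len(p))
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nm))
  y <- drop(cbind(1, X) %*% beta_true) + stats::rnorm(n, 0, noise_sd)
  training <- data.frame(id = sprintf("chem%03d", seq_len(n)), X, y = y,
                         stringsAsFactors = FALSE)
  model <- qsar_mlr(training, nm,
                    metadata = list(model_id = sprintf("synthetic-mlr-%d", seed),
                                    endpoint_name = "synthetic endpoint",
                                    units = "log units",
                                    group = "Synthetic",
                                    subgroup = "Toy endpoint",
                                    citation = "synthetic fixture"))

  Xq <- matrix(stats::rnorm(n_query * p), n_query, p,
               dimnames = list(NULL, nm))
  centroid <- colMeans(X); sds <- apply(X, 2, stats::sd)
  Xe <- matrix(rep(centroid + 10 * sds, each = max(n_extrapolated, 1L)),
               nrow = max(n_extrapolated, 1L))[seq_len(n_extrapolated), ,
                                               drop = FALSE]
  if (n_extrapolated > 1L)  # spread extrapolated points on both sides
    Xe[seq(2, n_extrapolated, by = 2), ] <-
      matrix(rep(centroid - 10 * sds,
                 each = length(seq(2, n_extrapolated, by = 2))),
             ncol = p)
  colnames(Xe) <- nm
  Xall <- rbind(Xq, Xe)
  yq <- drop(cbind(1, Xall) %*% beta_true) +
    stats::rnorm(nrow(Xall), 0, noise_sd)
  queries <- data.frame(Xall, y_true = yq,
                        kind = rep(c("interpolated", "extrapolated"),
                                   c(n_query, n_extrapolated)),
                        stringsAsFactors = FALSE)
  list(model = model, queries = queries, beta_true = beta_true,
       noise_sd = noise_sd)
}

#' Synthetic LDA classifier fixture
#'
#' Two Gaussian classes with identity covariance, centered at plus/minus
#' `class_separation / 2` along a random unit direction in descriptor space;
#' balanced class sizes.
#'
#' @param n total training size (default 30, split evenly).
#' @param p number of descriptors (default 3).
#' @param class_separation distance between class means in pooled-SD units
#'   (default 6).
#' @param n_query held-out queries per class (default 5).
#' @param seed RNG seed (default 1).
#' @return list with `model` (a `qsar_lda`), `queries` (data frame with
#'   descriptor columns and `class_true`), `direction`, `class_separation`.
#' @export
make_lda_fixture <- function(n = 30L, p = 3L, class_separation = 6,
                             n_query = 5L, seed = 1L) {
  stopifnot(n >= 4L, class_separation >= 0)
  set.seed(seed)
  nm <- paste0("d", seq_len(p))
  u <- stats::rnorm(p); u <- u / sqrt(sum(u^2))
  n1 <- n %/% 2L; n2 <- n - n1
  mu1 <- u * class_separation / 2; mu2 <- -mu1
  X <- rbind(
    matrix(stats::rnorm(n1 * p), n1, p) + matrix(mu1, n1, p, byrow = TRUE),
    matrix(stats::rnorm(n2 * p), n2, p) + matrix(mu2, n2, p, byrow = TRUE))
  colnames(X) <- nm
  cls <- rep(c("active", "inactive"), c(n1, n2))
  training <- data.frame(id = sprintf("chem%03d", seq_len(n)), X,
                         class = cls, stringsAsFactors = FALSE)
  model <- qsar_lda(training, nm, event_class = "active",
                    metadata = list(model_id = sprintf("synthetic-lda-%d", seed),
                                    endpoint_name = "synthetic class",
                                    group = "Synthetic",
                                    subgroup = "Toy classification",
                                    citation = "synthetic fixture"))
  nq <- 2L * n_query
  Xq <- rbind(
    matrix(stats::rnorm(n_query * p), n_query, p) +
      matrix(mu1, n_query, p, byrow = TRUE),
    matrix(stats::rnorm(n_query * p), n_query, p) +
      matrix(mu2, n_query, p, byrow = TRUE))
  colnames(Xq) <- nm
  queries <- data.frame(Xq, class_true = rep(c("active", "inactive"),
                                             each = n_query),
                        stringsAsFactors = FALSE)
  list(model = model, queries = queries, direction = u,
       class_separation = class_separation)
}

#' Hard-coded toy chemical set
#'
#' A fixed, version-stable set of ~20 small molecules (alkanes, alcohols,
#' aromatics, simple functional groups) used throughout the test-suite and
#' examples. Purely synthetic convenience data; no real endpoint is
#' emulated.
#'
#' @param parse if `TRUE` (default) return parsed `qsar_chem` structures;
#'   otherwise the named SMILES vector.
#' @return named list of `qsar_chem` objects (or named character vector).
#' @export
toy_chemical_set <- function(parse = TRUE) {
  smiles <- c(
    methane       = "C",
    ethane        = "CC",
    propane       = "CCC",
    butane        = "CCCC",
    isobutane     = "CC(C)C",
    pentane       = "CCCCC",
    cyclohexane   = "C1CCCCC1",
    benzene       = "c1ccccc1",
    toluene       = "Cc1ccccc1",
    phenol        = "Oc1ccccc1",
    methanol      = "CO",
    ethanol       = "CCO",
    acetic_acid   = "CC(=O)O",
    acetone       = "CC(C)=O",
    ethylamine    = "CCN",
    diethyl_ether = "CCOCC",
    chloroform    = "ClC(Cl)Cl",
    chlorobenzene = "Clc1ccccc1",
    pyridine      = "c1ccncc1",
    naphthalene   = "c1ccc2ccccc2c1",
    styrene       = "C=Cc1ccccc1")
  if (!parse) return(smiles)
  out <- lapply(names(smiles), function(id) parse_smiles(smiles[[id]], id))
  names(out) <- names(smiles)
  out
}
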