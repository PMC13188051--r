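make_two_class <- function(n_per = 10, p = 2, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p) + sep / 2,
             matrix(rnorm(n_per * p), n_per, p) - sep / 2)
  colnames(X) <- paste0("d", seq_len(p))
  data.frame(X, class = rep(c("pos", "neg"), each = n_per),
             stringsAsFactors = FALSE)
}

test_that("well-separated 1-D classes put the decision boundary at zero", {
  set.seed(2)
  d <- data.frame(d1 = c(rnorm(2000) - 5, rnorm(2000) + 5),
                  class = rep(c("lo", "hi"), each = 2000))
  m <- qsar_lda(d, "d1")
  # the decision boundary is the midpoint of the class means, which for
  # balanced symmetric classes converges on 0
  boundary <- unname((m$class_means["lo", 1] + m$class_means["hi", 1]) / 2)
  expect_lt(abs(boundary), 0.1)
  prb <- predict(m, data.frame(d1 = boundary), check_ad = FALSE)
  expect_equal(prb$posterior_lo, 0.5, tolerance = 1e-8)
  expect_equal(predict(m, data.frame(d1 = -1), check_ad = FALSE)$label, "lo")
  expect_equal(predict(m, data.frame(d1 = 1), check_ad = FALSE)$label, "hi")
})

test_that("degenerate class structure is rejected", {
  d <- data.frame(d1 = 1:5, class = c("a", "a", "a", "a", "b"))
  expect_error(qsar_lda(d, "d1"), "at least 2 members")
  d2 <- data.frame(d1 = rnorm(8), class = rep("a", 8))
  expect_error(qsar_lda(d2, "d1"), "at least 2 classes")
  d3 <- make_two_class(p = 2)
  d3$d2 <- 2 * d3$d1
  expect_error(qsar_lda(d3, c("d1", "d2")), "singular")
})

test_that("discriminant direction matches the closed-form two-class oracle", {
  set.seed(3)
  for (rep in 1:5) {
    d <- make_two_class(n_per = 15, p = 3, sep = 3, seed = rep)
    m <- qsar_lda(d, c("d1", "d2", "d3"))
    X <- as.matrix(d[, 1:3]); cls <- d$class
    mu1 <- colMeans(X[cls == "pos", ]); mu2 <- colMeans(X[cls == "neg", ])
    S <- (crossprod(sweep(X[cls == "pos", ], 2, mu1)) +
            crossprod(sweep(X[cls == "neg", ], 2, mu2))) / (nrow(X) - 2)
    w_oracle <- solve(S, mu1 - mu2)
    expect_equal(unname(coef(m)), unname(w_oracle), tolerance = 1e-8)
  }
})

test_that("posteriors agree with the MASS::lda cross-check", {
  skip_if_not_installed("MASS")
  set.seed(4)
  d <- make_two_class(n_per = 20, p = 3, sep = 2)
  m <- qsar_lda(d, c("d1", "d2", "d3"))
  ref <- MASS::lda(class ~ d1 + d2 + d3, data = d)
  q <- data.frame(d1 = rnorm(20), d2 = rnorm(20), d3 = rnorm(20))
  mine <- predict(m, q, check_ad = FALSE)
  theirs <- predict(ref, q)$posterior
  expect_equal(mine$posterior_pos, unname(theirs[, "pos"]), tolerance = 1e-6)
  expect_equal(mine$posterior_neg, unname(theirs[, "neg"]), tolerance = 1e-6)
})

test_that("posteriors behave: normalization, symmetry, confidence at means", {
  set.seed(5)
  d <- make_two_class(n_per = 25, p = 2, sep = 10)
  m <- qsar_lda(d, c("d1", "d2"))
  # at a class mean of a 10-SD-separated model the posterior is essentially 1
  pr <- predict(m, t(m$class_means["pos", ]), check_ad = FALSE)
  expect_gt(pr$posterior_pos, 0.99)
  # midpoint between the class means (equal priors) splits evenly
  mid <- (m$class_means["pos", ] + m$class_means["neg", ]) / 2
  prm <- predict(m, t(mid), check_ad = FALSE)
  expect_equal(prm$posterior_pos, 0.5, tolerance = 1e-8)
  # random queries always normalize
  q <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("d1", "d2")))
  post <- predict(m, q, check_ad = FALSE)
  expect_true(all(abs(post$posterior_pos + post$posterior_neg - 1) < 1e-10))
  # training accuracy 100% at this separation
  acc <- mean(predict(m, d[, 1:2], check_ad = FALSE)$label == d$class)
  expect_equal(acc, 1)
})

test_that("predictions are invariant under affine descriptor rescaling", {
  set.seed(6)
  d <- make_two_class(n_per = 15, p = 3, sep = 3)
  m1 <- qsar_lda(d, c("d1", "d2", "d3"))
  d2 <- d
  d2$d1 <- 100 * d$d1 - 7; d2$d3 <- 0.01 * d$d3 + 2
  m2 <- qsar_lda(d2, c("d1", "d2", "d3"))
  q <- data.frame(d1 = rnorm(10), d2 = rnorm(10), d3 = rnorm(10))
  q2 <- transform(q, d1 = 100 * d1 - 7, d3 = 0.01 * d3 + 2)
  expect_equal(predict(m1, q, check_ad = FALSE)$posterior_pos,
               predict(m2, q2, check_ad = FALSE)$posterior_pos,
               tolerance = 1e-8)
})

test_that("Shannon entropy evaluates the printed constants", {
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(0.25, 0.75)), 0.811278, tolerance = 1e-6)
  expect_error(shannon_entropy(c(0.5, 0.6)), "sum to 1")
  # entropy shrinks to zero as separation grows
  ents <- vapply(c(1, 4, 10), function(sep) {
    d <- make_two_class(n_per = 15, p = 2, sep = sep, seed = 7)
    m <- qsar_lda(d, c("d1", "d2"))
    mean(predict(m, d[, 1:2], check_ad = FALSE)$entropy)
  }, numeric(1))
  expect_true(all(diff(ents) < 0))
  expect_lt(ents[3], 1e-4)
})

test_that("cosine similarity evaluates the closed-form examples", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)), 0.974632,
               tolerance = 1e-6)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(1:2, 1:3), "length")
})

test_that("similarity domain: centroid scores 1; cutoff keeps ~95% in", {
  fx <- make_lda_fixture(n = 1000, p = 3, seed = 8)
  m <- fx$model
  centroid <- m$scaler$mean
  v <- structural_ad(m, t(centroid))
  expect_equal(unname(v$details["similarity"]), 1, tolerance = 1e-12)
  expect_true(v$in_ad)
  # default cutoff: ~5% of the training set scores strictly below it
  frac_out <- mean(m$train_scores < m$sim_cutoff)
  expect_equal(frac_out, 0.05, tolerance = 0.005)
  # the worst-scoring training chemical is always out under any cutoff
  # above the minimum score
  worst <- which.min(m$train_scores)
  vx <- structural_ad(m, m$training[worst, m$specs$name, drop = FALSE])
  expect_false(vx$in_ad)
  # literal percentile reading: ~95% of the training set is out
  scores <- m$train_scores
  lit_cut <- quantile(scores, 0.95, type = 7)
  expect_equal(mean(scores < lit_cut), 0.95, tolerance = 0.005)
  vlit <- structural_ad(m, m$training[worst, m$specs$name, drop = FALSE],
                        literal_percentile = TRUE)
  expect_false(vlit$in_ad)
})

test_that("posterior-band endpoint rule uses exclusive bounds", {
  fx <- make_lda_fixture(seed = 9)
  m <- fx$model
  expect_false(endpoint_ad_lda(m, 0.5)$in_ad)
  expect_true(endpoint_ad_lda(m, 0.9)$in_ad)
  expect_true(endpoint_ad_lda(m, 0.75)$in_ad)   # boundary in, documented
  expect_true(endpoint_ad_lda(m, 0.25)$in_ad)
  expect_false(endpoint_ad_lda(m, 0.7499999)$in_ad)
})

test_that("argmax ties are broken by declared order and flagged", {
  set.seed(10)
  # at the midpoint between the class means (equal priors) the
  # discriminant scores agree to machine precision
  d <- make_two_class(n_per = 10, p = 2, sep = 4)
  m <- qsar_lda(d, c("d1", "d2"))
  mid <- (m$class_means["pos", ] + m$class_means["neg", ]) / 2
  pr <- predict(m, t(mid))
  expect_true(pr$tie)
  expect_equal(pr$label, m$classes[1])
  expect_match(pr$reasons, "tie")
})
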