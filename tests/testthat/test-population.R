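pop_table <- function() {
  tibble::tibble(
    individual = rep(c("f1", "f2", "f3"), each = 2),
    trial = rep(1:2, 3),
    `GA:o1` = c(1, 3, 2, 2, 5, 7),
    `GA:o2` = c(0, 2, NA, 4, 1, 1),
    `GB:o1` = c(2, 2, 3, 3, 4, 4))
}

test_that("mean imputation and trial averaging behave as stated", {
  out <- impute_and_average(pop_table())
  expect_equal(nrow(out), 3)
  # no-missing feature: plain trial means
  expect_equal(out$`GA:o1`, c(2, 2, 6))
  # the missing cell takes the feature mean over non-missing values
  imputed <- mean(c(0, 2, 4, 1, 1))
  expect_equal(out$`GA:o2`[2], (imputed + 4) / 2)
  # one missing among values {1, 3} imputes to 2
  t2 <- tibble::tibble(individual = c("a", "b", "c"),
                       x = c(1, NA, 3))
  expect_equal(impute_and_average(t2)$x[2], 2)

  allna <- pop_table(); allna$`GB:o1` <- NA_real_
  expect_error(impute_and_average(allna), "missing for all")
  expect_error(impute_and_average(pop_table()[1:2, ]), "2 individuals")
})

test_that("PCA matches an eigendecomposition oracle", {
  set.seed(7)
  X <- matrix(rnorm(24), 4, 6)
  colnames(X) <- sprintf("G%d:o%d", rep(1:2, each = 3), 1:3)
  pca <- pca_responses(X)
  ev <- eigen(cov(X))
  expect_equal(abs(pca$loadings[, 1:3]), abs(ev$vectors[, 1:3]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(pca$variance_fraction[1:3],
               ev$values[1:3] / sum(ev$values), tolerance = 1e-9)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)

  # reconstruction from all PCs reproduces the centered matrix
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(recon, sweep(X, 2, colMeans(X)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # deterministic sign convention: largest-|loading| entry positive
  expect_true(all(apply(pca$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))

  # rank-1 input concentrates all variance on PC1
  R1 <- outer(c(1, 2, 3, 4), c(2, 1, 3))
  expect_equal(pca_responses(R1)$variance_fraction[1], 1,
               tolerance = 1e-9)
  expect_error(pca_responses(matrix(1, 4, 3)), "constant")
})

test_that("the glomerular organization index hits its boundary cases", {
  # loadings constant within each glomerulus -> 1
  set.seed(8)
  n_g <- 4; n_o <- 5
  blocks <- rep(sprintf("G%d", 1:n_g), each = n_o)
  X <- matrix(rnorm(30 * n_g * n_o), 30)  # base observations
  mk_pca <- function(loadings) {
    # wrap a fabricated loading matrix into the al_pca structure
    structure(list(loadings = loadings,
                   scores = matrix(0, 2, ncol(loadings)),
                   variance_fraction =
                     rep(1 / ncol(loadings), ncol(loadings)),
                   feature_names = blocks, observations = NULL),
              class = "al_pca")
  }
  const <- matrix(rep(rnorm(n_g), each = n_o), ncol = 1)
  expect_equal(glomerular_organization_index(mk_pca(const), blocks, K = 1),
               1)
  balanced <- matrix(rep(c(1, -1, 0.5, -0.5, 0), n_g), ncol = 1)
  expect_equal(glomerular_organization_index(mk_pca(balanced), blocks,
                                             K = 1), 0)

  # independent standard-normal loadings: expectation ~ 1/n_odors
  vals <- vapply(1:1000, function(i) {
    glomerular_organization_index(mk_pca(matrix(rnorm(n_g * n_o))),
                                  blocks, K = 1)
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1 / n_o), 3 * se)
})

test_that("GOI is invariant to odor permutations and sign flips", {
  set.seed(9)
  X <- matrix(rnorm(40 * 12), 40)
  colnames(X) <- sprintf("G%d:o%d", rep(1:3, each = 4), rep(1:4, 3))
  pca <- pca_responses(X)
  g0 <- glomerular_organization_index(pca, K = 3)

  # permute odors within each glomerulus block
  perm <- c(sample(1:4), 4 + sample(1:4), 8 + sample(1:4))
  pca_p <- pca_responses(X[, perm])
  expect_equal(glomerular_organization_index(pca_p, K = 3), g0,
               tolerance = 1e-9)

  # global sign flip of a PC's loadings
  pca2 <- pca
  pca2$loadings[, 1] <- -pca2$loadings[, 1]
  expect_equal(glomerular_organization_index(pca2, K = 3), g0,
               tolerance = 1e-9)
})

test_that("linear preference models apply the printed coefficients", {
  m <- preference_model(beta0 = -0.058, beta1 = -0.081, predictor = "PC2")
  expect_equal(apply_preference_model(m, c(0, 1)), c(-0.058, -0.139))
  scores <- matrix(c(1, 2, 0.5, -1), 2,
                   dimnames = list(NULL, c("PC1", "PC2")))
  expect_equal(apply_preference_model(m, scores),
               -0.058 - 0.081 * c(0.5, -1))

  # affine: prediction differences proportional to score differences
  s <- rnorm(10)
  pred <- apply_preference_model(m, s)
  expect_equal(diff(pred), -0.081 * diff(s), tolerance = 1e-12)

  # beta1 = 0 -> constant
  expect_equal(apply_preference_model(preference_model(0.3, 0), s),
               rep(0.3, 10))

  # named contrast resolves over glomerulus blocks
  feats <- matrix(1:8, 2,
                  dimnames = list(NULL, c("DM2:o1", "DM2:o2",
                                          "DC2:o1", "DC2:o2")))
  mc <- preference_model(0, 1, predictor = "DM2-DC2")
  expect_equal(apply_preference_model(mc, feats),
               rowMeans(feats[, 1:2]) - rowMeans(feats[, 3:4]))
  expect_error(apply_preference_model(preference_model(0, 1, "PC9"),
                                      scores), "resolve")
})

test_that("preference models round-trip through JSON", {
  m <- preference_model(-0.058, -0.081, "PC2")
  p <- withr::local_tempfile(fileext = ".json")
  write_preference_model(m, p)
  back <- read_preference_model(p)
  expect_equal(back$beta0, m$beta0)
  expect_equal(back$beta1, m$beta1)
  expect_equal(back$predictor, "PC2")
})

test_that("twofold logistic decoding separates what is separable", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, mean = 0), 20),
             matrix(rnorm(40, mean = 6), 20))
  y <- rep(c("A", "B"), each = 20)
  expect_equal(classify_individuals(X, y, seed = 1), 1)

  # shuffled labels sit at chance
  accs <- vapply(1:200, function(s) {
    classify_individuals(X, sample(y), seed = s)
  }, numeric(1))
  se <- sqrt(0.25 / 40)
  expect_lt(abs(mean(accs) - 0.5), 3 * se / sqrt(200) * 10)
  expect_lt(abs(mean(accs) - 0.5), 0.05)

  expect_error(classify_individuals(X, rep("A", 40)), "2 classes")
})

test_that("within- and across-individual distances behave geometrically", {
  # identical trials -> within 0, across reflects the separation
  proj <- rbind(matrix(0, 4, 2), matrix(3, 4, 2))
  ind <- rep(c("f1", "f2"), each = 4)
  hemi <- rep(c("L", "L", "R", "R"), 2)
  d <- response_distances(proj, ind, hemi)
  expect_equal(d$within, c(0, 0))
  expect_true(all(d$across > 0))

  # across/within grows with the individual spread
  mk <- function(sig_i) {
    set.seed(12)
    centers <- matrix(rnorm(10 * 2, sd = sig_i), 10)
    trials <- centers[rep(1:10, each = 4), ] + rnorm(80, sd = 0.1)
    response_distances(trials, rep(sprintf("f%d", 1:10), each = 4),
                       rep(c("L", "L", "R", "R"), 10))
  }
  tight <- mk(0.2); spread <- mk(5)
  expect_gt(mean(spread$across / spread$within),
            mean(tight$across / tight$within))
})

test_that("population GOI separates circuit-variation sources", {
  # fabricate populations with and without glomerular organization
  set.seed(13)
  n <- 40; blocks <- rep(sprintf("G%d", 1:4), each = 5)
  glom_shift <- matrix(rnorm(n * 4), n)[, rep(1:4, each = 5)]
  organized <- tibble::as_tibble(
    as.data.frame(glom_shift + 0.2 * matrix(rnorm(n * 20), n)))
  names(organized) <- paste0(blocks, ":o", rep(1:5, 4))
  organized$individual <- sprintf("s%02d", 1:n)
  disorganized <- organized
  disorganized[, 1:20] <- matrix(rnorm(n * 20), n)

  g_org <- population_goi(organized)
  g_dis <- population_goi(disorganized)
  expect_gt(g_org$goi - g_dis$goi,
            3 * sqrt(g_org$se^2 + g_dis$se^2))
})
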