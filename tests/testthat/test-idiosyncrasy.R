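test_that("bootstrapping preserves pools and original connectivity", {
  cf <- cached_canonical()
  src <- cf$weights
  boot <- bootstrap_population(src, "ORN", seed = 3)

  # per-glomerulus ORN counts identical before and after
  tab0 <- table(src$roster$glomerulus[src$roster$cell_class == "ORN"])
  tab1 <- table(boot$roster$glomerulus[boot$roster$cell_class == "ORN"])
  expect_equal(as.vector(tab1), as.vector(tab0))
  # non-ORN rows untouched
  expect_identical(boot$roster$id[boot$roster$cell_class != "ORN"],
                   src$roster$id[src$roster$cell_class != "ORN"])

  # sampled neurons carry their source's synapses: every connected pair in
  # the bootstrap maps to a connected pair of the source
  nz <- which(boot$counts > 0, arr.ind = TRUE)
  pre_src <- boot$roster$source_id[nz[, 1]]
  post_src <- boot$roster$source_id[nz[, 2]]
  expect_true(all(src$counts[cbind(pre_src, post_src)] > 0))
  expect_equal(boot$counts[nz],
               unname(src$counts[cbind(pre_src, post_src)]))
})

test_that("a single-neuron pool always resamples to itself", {
  roster <- tibble::tibble(
    id = c("o1", "p1"), cell_class = c("ORN", "uPN"),
    glomerulus = "DA1", polarity = 1)
  edges <- tibble::tibble(pre_id = "o1", post_id = "p1", synapse_count = 4)
  circ <- load_circuit(roster, edges)
  for (s in 1:5) {
    b <- bootstrap_population(circ, "ORN", seed = s)
    expect_identical(b$counts, circ$counts)
  }
})

test_that("bootstrap exclusion frequency approaches 1 - 1/e", {
  n <- 24
  roster <- tibble::tibble(
    id = c(sprintf("o%02d", 1:n), "p1"),
    cell_class = c(rep("ORN", n), "uPN"),
    glomerulus = "DA1", polarity = 1)
  edges <- tibble::tibble(pre_id = sprintf("o%02d", 1:n), post_id = "p1",
                          synapse_count = 1)
  circ <- load_circuit(roster, edges)
  excl <- vapply(1:1000, function(s) {
    b <- bootstrap_population(circ, "ORN", seed = s)
    kept <- unique(b$roster$source_id[b$roster$cell_class == "ORN"])
    1 - length(kept) / n
  }, numeric(1))
  expected <- (1 - 1 / n)^n            # -> e^-1 for large n
  se <- sd(excl) / sqrt(length(excl))
  expect_lt(abs(mean(excl) - expected), 3 * se)
})

test_that("LNs resample from one common pool", {
  cf <- cached_canonical()
  boot <- bootstrap_population(cf$weights, "LN", seed = 9)
  n_ln <- sum(cf$weights$roster$cell_class == "LN")
  expect_equal(sum(boot$roster$cell_class == "LN"), n_ln)
  # over seeds, some draw must duplicate an LN (single pool of 16)
  dup <- vapply(1:20, function(s) {
    b <- bootstrap_population(cf$weights, "LN", seed = s)
    anyDuplicated(b$roster$source_id[b$roster$cell_class == "LN"]) > 0
  }, logical(1))
  expect_true(any(dup))
})

test_that("the volume-synapse fit is exact in the noiseless limit", {
  v <- c(1e3, 3e3, 1e4, 5e4, 2e5)
  s <- 8.98 * v^0.73
  fit <- fit_volume_synapse_model(v, s)
  expect_equal(fit$a, 8.98, tolerance = 1e-9)
  expect_equal(fit$d, 0.73, tolerance = 1e-12)
  expect_equal(fit$sigma, 0, tolerance = 1e-9)
  expect_error(fit_volume_synapse_model(c(-1, 2, 3), c(1, 2, 3)),
               "positive")
  expect_error(fit_volume_synapse_model(v[1:2], s[1:2]), "at least 3")
})

test_that("the MLE equals log-log least squares on any dataset", {
  set.seed(11)
  v <- exp(runif(40, log(500), log(8e4)))
  s <- exp(2 + 0.6 * log(v) + rnorm(40, 0, 0.5))
  fit <- fit_volume_synapse_model(v, s)
  ls <- lm(log(s) ~ log(v))
  expect_equal(fit$d, unname(coef(ls)[2]), tolerance = 1e-12)
  expect_equal(log(fit$a), unname(coef(ls)[1]), tolerance = 1e-12)
  expect_equal(fit$sigma, sqrt(mean(residuals(ls)^2)), tolerance = 1e-12)
})

test_that("the printed power-law parameters are recovered from samples", {
  set.seed(21)
  v <- exp(runif(500, log(1e3), log(1e5)))
  s <- exp(log(8.98 * v^0.73) + rnorm(500, 0, 0.38))
  fit <- fit_volume_synapse_model(v, s)
  se_d <- summary(lm(log(s) ~ log(v)))$coefficients[2, 2]
  expect_lt(abs(fit$d - 0.73), 3 * se_d)
  expect_lt(abs(fit$sigma - 0.38), 3 * 0.38 / sqrt(2 * 500))
})

test_that("density resampling rescales glomeruli by a single scalar", {
  cf <- cached_canonical()
  w <- cf$weights
  model <- volume_synapse_model(a = 8.98, d = 0.73, sigma = 0)

  # sigma = 0: totals land exactly on a * V^d
  out <- resample_synapse_density(w, cf$volumes, model, seed = 1)
  tot <- pn_input_synapses(out)
  v <- setNames(cf$volumes$volume_um3, cf$volumes$glomerulus)
  expect_equal(unname(tot$pn_input_synapses),
               unname(8.98 * v[tot$glomerulus]^0.73), tolerance = 1e-9)

  # within a glomerulus, ratios between individual PN inputs are unchanged
  out2 <- resample_synapse_density(w, cf$volumes,
                                   volume_synapse_model(sigma = 0.38),
                                   seed = 5)
  g <- cf$volumes$glomerulus[1]
  cols <- which(w$roster$glomerulus %in% g & w$roster$cell_class == "uPN")
  pre <- which(w$counts[, cols[1]] > 0)
  ratio <- out2$counts[pre, cols[1]] / w$counts[pre, cols[1]]
  expect_lt(diff(range(ratio)), 1e-12)

  # effective weights scale together with the counts
  expect_equal(out2$effective[pre, cols[1]] / w$effective[pre, cols[1]],
               ratio, ignore_attr = TRUE)
})

test_that("log residual of resampled totals is Normal(0, sigma^2)", {
  cf <- cached_canonical()
  model <- volume_synapse_model(sigma = 0.38)
  v <- setNames(cf$volumes$volume_um3, cf$volumes$glomerulus)
  g <- cf$volumes$glomerulus[1]
  draws <- vapply(1:1000, function(s) {
    out <- resample_synapse_density(cf$weights, cf$volumes, model, seed = s)
    tot <- pn_input_synapses(out)
    log(tot$pn_input_synapses[tot$glomerulus == g]) -
      log(8.98 * v[[g]]^0.73)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(draws, "pnorm", 0, 0.38))
  expect_gt(ks$p.value, 0.01)
})

test_that("identity mode leaves the circuit untouched and modes compose", {
  cf <- cached_canonical()
  same <- idiosyncratic_circuit(cf$weights, "poisson", seed = 1)
  expect_identical(same$counts, cf$weights$counts)
  expect_identical(same$effective, cf$weights$effective)
  expect_error(idiosyncratic_circuit(cf$weights, c("poisson", "orn")),
               "combine")
  expect_error(idiosyncratic_circuit(cf$weights, "density"), "volume")

  combo <- idiosyncratic_circuit(cf$weights, c("orn", "density"),
                                 volumes = cf$volumes, seed = 2)
  expect_equal(nrow(combo$roster), nrow(cf$weights$roster))
  expect_false(identical(combo$counts, cf$weights$counts))
})

test_that("fit -> resample -> refit recovers the generating law", {
  set.seed(31)
  v <- exp(runif(300, log(1e3), log(1e5)))
  s <- exp(log(8.98 * v^0.73) + rnorm(300, 0, 0.38))
  fit <- fit_volume_synapse_model(v, s)
  # draw new totals from the fitted law and refit (closure property)
  s2 <- exp(log(fit$a * v^fit$d) + rnorm(300, 0, fit$sigma))
  refit <- fit_volume_synapse_model(v, s2)
  se_d <- summary(lm(log(s2) ~ log(v)))$coefficients[2, 2]
  expect_lt(abs(refit$d - fit$d), 3 * se_d)
  expect_lt(abs(refit$sigma - fit$sigma), 3 * fit$sigma / sqrt(2 * 300))
})
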