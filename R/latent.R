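#' PCA-based repeatability of a multidimensional measurement
#'
#' Estimates how much of the variance of a trial-level glomerulus-odor
#' response matrix is repeatable signal rather than measurement noise. The
#' eigenvalues of the real data PCA are compared to those of shuffled data
#' (an independent permutation of the feature values of each individual,
#' applied jointly to that individual's trials, preserving each
#' individual's multiset of feature values). The repeatability `R^2` is
#' the cumulative variance fraction of the leading PCs whose eigenvalue
#' exceeds the rank-matched mean shuffled eigenvalue; later PCs are read
#' as noise. Uncertainty comes from bootstrapping individuals.
#'
#' @param table tibble with `individual` (and optional `trial`,
#'   `hemisphere`) metadata plus numeric feature columns, or a plain
#'   numeric matrix with `individual` supplied separately.
#' @param individual individual id per row when `table` is a matrix.
#' @param n_shuffles shuffled datasets per estimate (default 20).
#' @param n_boot bootstrap resamples of individuals (default 100; 0 for a
#'   point estimate only).
#' @param seed integer seed.
#' @param source label recording what was measured (e.g. `"calcium-PCA"`,
#'   `"behavior-retest"`).
#' @return A `repeatability_estimate`: list with `r2` (point value),
#'   `samples` (bootstrap vector, in \[0, 1\]), `n_signal_pcs`, `source`.
#' @export
pca_repeatability <- function(table, individual = NULL, n_shuffles = 20,
                              n_boot = 100, seed = 1,
                              source = "calcium-PCA") {
  if (is.data.frame(table)) {
    meta <- intersect(c("individual", "trial", "hemisphere"), names(table))
    individual <- as.character(table$individual)
    X <- as.matrix(table[setdiff(names(table), meta)])
  } else {
    X <- as.matrix(table)
    individual <- as.character(individual)
  }
  storage.mode(X) <- "double"
  if (ncol(X) < 2) abort("need at least 2 features")
  if (nrow(X) < 3) abort("need at least 3 observations")

  point <- NULL
  samples <- numeric(0)
  withr::with_seed(seed, {
    point <- r2_cc_once(X, individual, n_shuffles)
    if (n_boot > 0) {
      inds <- unique(individual)
      samples <- vapply(seq_len(n_boot), function(b) {
        take <- sample(inds, length(inds), replace = TRUE)
        rows <- unlist(lapply(take, function(i) which(individual == i)))
        # resampled flies get distinct ids so duplicates shuffle separately
        ids <- rep(seq_along(take),
                   vapply(take, function(i) sum(individual == i),
                          integer(1)))
        r2_cc_once(X[rows, , drop = FALSE], as.character(ids),
                   n_shuffles)$r2
      }, numeric(1))
    }
  })
  structure(list(r2 = point$r2, samples = samples,
                 n_signal_pcs = point$k, source = source),
            class = "repeatability_estimate")
}

# one repeatability estimate: eigenvalues vs rank-matched shuffled
# eigenvalues (parallel analysis; the 95th percentile keeps pure noise at
# R^2 ~ 0)
r2_cc_once <- function(X, individual, n_shuffles) {
  ev <- pca_eigenvalues(X)
  shuf <- replicate(n_shuffles, pca_eigenvalues(shuffle_within(X, individual)))
  shuf <- matrix(shuf, nrow = length(ev))
  thresh <- apply(shuf, 1, quantile, probs = 0.95, names = FALSE)
  above <- ev > thresh
  k <- if (!above[1]) 0L else {
    w <- which(!above)
    if (length(w)) w[1] - 1L else length(ev)
  }
  r2 <- if (k == 0) 0 else sum(ev[seq_len(k)]) / sum(ev)
  list(r2 = r2, k = k)
}

pca_eigenvalues <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc, nu = 0, nv = 0)$d^2 / (nrow(X) - 1)
}

# permute feature assignment independently per individual (same permutation
# across that individual's trials)
shuffle_within <- function(X, individual) {
  for (i in unique(individual)) {
    rows <- which(individual == i)
    X[rows, ] <- X[rows, sample.int(ncol(X)), drop = FALSE]
  }
  X
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("<repeatability_estimate> %s: R^2 = %.3f (%d signal PCs, %d bootstrap samples)\n",
              x$source, x$r2, x$n_signal_pcs, length(x$samples)))
  invisible(x)
}

#' @rdname pca_repeatability
#' @param r2 point repeatability in \[0, 1\].
#' @param samples bootstrap samples (defaults to a point mass at `r2`).
#' @param source label, e.g. `"behavior-retest"`.
#' @export
repeatability_estimate <- function(r2, samples = r2,
                                   source = "behavior-retest") {
  if (any(samples < 0 | samples > 1) || r2 < 0 || r2 > 1) {
    abort("repeatability values must lie in [0, 1]")
  }
  structure(list(r2 = r2, samples = samples, n_signal_pcs = NA_integer_,
                 source = source),
            class = "repeatability_estimate")
}

#' Simulate one observed calcium-behavior R^2
#'
#' Draws latent states for `N` individuals - `X_c` standard normal and
#' `X_b = r_latent * X_c + sqrt(1 - r_latent^2) * Z` so that
#' `corr(X_c, X_b) = r_latent` - then noisy readouts `X_c'` with
#' `corr(X_c, X_c') = r_c` and `X_b'` with `corr(X_b, X_b') = r_b` by the
#' same mixing construction, and returns `corr(X_c', X_b')^2`. Over many
#' draws, `E[corr(X_c', X_b')] = r_latent * r_c * r_b`.
#'
#' @param r_latent,r_c,r_b correlations in \[0, 1\].
#' @param N number of simulated individuals (>= 3).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return One simulated squared correlation.
#' @export
simulate_observed_r2 <- function(r_latent, r_c, r_b, N, seed = NULL) {
  if (any(c(r_latent, r_c, r_b) < 0) || any(c(r_latent, r_c, r_b) > 1)) {
    abort("r_latent, r_c and r_b must lie in [0, 1]")
  }
  if (N < 3) abort("N must be at least 3")
  draw <- function() {
    X_c <- rnorm(N)
    X_b <- r_latent * X_c + sqrt(1 - r_latent^2) * rnorm(N)
    X_c1 <- r_c * X_c + sqrt(1 - r_c^2) * rnorm(N)
    X_b1 <- r_b * X_b + sqrt(1 - r_b^2) * rnorm(N)
    cor(X_c1, X_b1)^2
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Infer the latent calcium-behavior correlation
#'
#' Simulation-based inversion of measurement attenuation. `r_latent` is
#' varied over a grid from 0 to 1; for each grid value and each
#' simulation, repeatabilities are drawn from their bootstrap samples
#' (paired with simulation iterations by index cycling), converted to
#' mixing correlations `(R^2)^(1/4)`, and an observed calcium-behavior
#' `R^2` is simulated via [simulate_observed_r2()]. Each bootstrap draw of
#' the observed model `R^2` then contributes the marginal distribution of
#' `r_latent` consistent with it (equal prior weight per grid point), and
#' the summed posterior is transformed from `r_latent` to `R^2_latent` by
#' quantile matching (`P(r_latent <= q) = P(R^2_latent <= q^2)`).
#'
#' @param observed_r2 numeric vector: bootstrap samples of the observed
#'   model `R^2` (a single value gives a point mass).
#' @param calcium,behavior [repeatability_estimate()] objects (`R^2_c,c`
#'   and `R^2_b,b` with bootstrap samples).
#' @param N number of individuals behind the observed `R^2`.
#' @param grid_step grid increment for `r_latent` (default 0.01).
#' @param n_sims simulations per grid point (default 10000).
#' @param bin_width half-width of the window used to match simulated to
#'   observed `R^2` when accumulating marginals.
#' @param seed integer seed.
#' @return A `latent_inference`: list with `grid` (r_latent values),
#'   `posterior` (weights over the grid), `median`, `ci90` (5th-95th
#'   quantiles of `R^2_latent`), `N`, `n_sims`.
#' @export
infer_latent <- function(observed_r2, calcium, behavior, N,
                         grid_step = 0.01, n_sims = 10000,
                         bin_width = 0.02, seed = 1) {
  observed_r2 <- as.numeric(observed_r2)
  if (!length(observed_r2)) abort("observed_r2 must be nonempty")
  if (any(observed_r2 > 1 | observed_r2 < 0)) {
    abort("observed R^2 must lie in [0, 1]")
  }
  rc_samp <- if (length(calcium$samples)) calcium$samples else calcium$r2
  rb_samp <- if (length(behavior$samples)) behavior$samples else behavior$r2
  grid <- seq(0, 1, by = grid_step)

  sims <- matrix(NA_real_, length(grid), n_sims)
  withr::with_seed(seed, {
    rc <- rc_samp[((seq_len(n_sims) - 1) %% length(rc_samp)) + 1]^(1 / 4)
    rb <- rb_samp[((seq_len(n_sims) - 1) %% length(rb_samp)) + 1]^(1 / 4)
    for (gi in seq_along(grid)) {
      for (s in seq_len(n_sims)) {
        sims[gi, s] <- simulate_observed_r2(grid[gi], rc[s], rb[s], N)
      }
    }
  })

  # accumulate marginal distributions of r_latent across observed draws
  posterior <- numeric(length(grid))
  for (obs in observed_r2) {
    lik <- rowMeans(abs(sims - obs) <= bin_width)
    if (sum(lik) > 0) posterior <- posterior + lik / sum(lik)
  }
  if (sum(posterior) == 0) {
    abort("no simulated R^2 fell near the observed values; widen bin_width")
  }
  posterior <- posterior / sum(posterior)

  # quantile matching r_latent -> R^2_latent: the R^2_latent posterior is
  # the pushforward of the r_latent posterior through squaring
  qs <- weighted_quantile(grid^2, posterior, c(0.05, 0.5, 0.95))
  structure(list(grid = grid, posterior = posterior,
                 median = qs[2], ci90 = c(qs[1], qs[3]),
                 N = N, n_sims = n_sims),
            class = "latent_inference")
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' @export
print.latent_inference <- function(x, ...) {
  cat(sprintf("<latent_inference> median R^2_latent = %.3f (90%% CI %.3f-%.3f), N = %d\n",
              x$median, x$ci90[1], x$ci90[2], x$N))
  invisible(x)
}
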