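#' Impute missing entries of a glomerulus-by-odor response matrix
#'
#' Missing odorant-response values (about 40% of a DoOR-style matrix) are
#' infilled by low-rank matrix completion via alternating least squares
#' (ALS). Each repeat runs ALS from a random start; the final matrix is the
#' elementwise mean over `n_repeats` infills, which tracks held-out values
#' more closely than a single run. The completion rank is the smallest
#' number of components explaining at least `var_target` of the variance of
#' the mean-infilled matrix. Imputed values are clamped to \[0, 1\]; observed
#' entries are never altered.
#'
#' @param D numeric matrix (glomeruli x odors) with entries in \[0, 1\] or
#'   `NA`; may also be a data frame whose first column holds glomerulus
#'   labels (as written by [write_response_matrix()]).
#' @param n_repeats number of ALS restarts to average (default 1000).
#' @param seed integer seed.
#' @param var_target variance fraction retained when choosing the rank.
#' @param tol relative-change convergence tolerance per repeat.
#' @param max_iter maximum ALS iterations per repeat.
#' @return Completed matrix of the same shape, dimnames preserved.
#' @export
impute_missing_responses <- function(D, n_repeats = 1000, seed = 1,
                                     var_target = 0.75, tol = 1e-6,
                                     max_iter = 200) {
  D <- as_response_matrix(D)
  if (nrow(D) < 2 || ncol(D) < 2) abort("matrix must be at least 2 x 2")
  obs <- !is.na(D)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) {
    abort("a row or column is entirely missing; nothing to impute from")
  }
  rng <- range(D[obs])
  if (rng[1] < 0 || rng[2] > 1) abort("observed entries must lie in [0, 1]")
  if (all(obs)) return(D)

  # rank from the variance spectrum of the mean-infilled matrix
  col_mean <- colMeans(D, na.rm = TRUE)
  D0 <- D
  for (j in seq_len(ncol(D))) D0[!obs[, j], j] <- col_mean[j]
  ev <- prcomp(D0, center = TRUE)$sdev^2
  vf <- cumsum(ev) / sum(ev)
  rank <- which(vf >= var_target)[1]
  rank <- max(1L, min(rank, nrow(D) - 1L, ncol(D) - 1L))

  acc <- matrix(0, nrow(D), ncol(D))
  withr::with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      acc <- acc + als_complete_once(D, obs, rank, tol, max_iter)
    }
  })
  out <- acc / n_repeats
  out <- pmin(pmax(out, 0), 1)
  out[obs] <- D[obs]
  out
}

# one ALS completion from a random start: model D ~ mu_col + U V' on observed
# cells, alternating ridge-free least squares on the infilled matrix
als_complete_once <- function(D, obs, rank, tol, max_iter) {
  n <- nrow(D); m <- ncol(D)
  X <- D
  col_mean <- colMeans(D, na.rm = TRUE)
  for (j in seq_len(m)) X[!obs[, j], j] <- col_mean[j]
  # random start for the missing cells
  X[!obs] <- X[!obs] + rnorm(sum(!obs), 0, 0.25)
  prev <- X
  for (it in seq_len(max_iter)) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = rank, nv = rank)
    low <- sv$u %*% (diag(sv$d[seq_len(rank)], rank) %*% t(sv$v))
    fit <- sweep(low, 2, mu, `+`)
    X[!obs] <- fit[!obs]
    delta <- sqrt(sum((X - prev)^2)) / max(sqrt(sum(prev^2)), 1e-12)
    if (delta < tol) break
    prev <- X
  }
  X
}

#' Odor-evoked ORN firing rate with adaptation
#'
#' Evaluates `FR = FR_max * D * (f_a + (1 - f_a) * exp(-t / t_a))`: the
#' instantaneous odor-evoked rate of ORNs of a glomerulus with DoOR-style
#' response `D`, `t` milliseconds after odor onset. With defaults the onset
#' rate at `D = 1` is 400 Hz, adapting with timescale 110 ms to 75% of the
#' initial value (300 Hz).
#'
#' @param D odorant response value(s) in \[0, 1\].
#' @param t_since_onset time(s) since odor onset (ms), nonnegative.
#' @param params a [drive_params()].
#' @return Firing rate(s) in Hz.
#' @export
odor_firing_rate <- function(D, t_since_onset, params = drive_params()) {
  if (any(D < 0 | D > 1, na.rm = TRUE)) abort("D must lie in [0, 1]")
  if (any(t_since_onset < 0)) abort("t_since_onset must be nonnegative")
  params$FR_max * D *
    (params$f_a + (1 - params$f_a) * exp(-t_since_onset / params$t_a))
}

#' Sample spike times from an inhomogeneous Poisson rate profile
#'
#' Per-time-step Bernoulli thinning: a spike falls in step k with
#' probability `rate[k] * dt` (rate in Hz, dt in ms). The discretization
#' must satisfy `max(rate) * dt < 0.1` spikes per step.
#'
#' @param rate_profile nonnegative rate per time step (Hz), length
#'   `duration / dt`, or a single constant rate.
#' @param duration total duration (ms).
#' @param dt time step (ms).
#' @param seed integer seed.
#' @return Numeric vector of spike times (ms, left edge of the step).
#' @export
sample_orn_spike_times <- function(rate_profile, duration, dt = 0.1, seed = 1) {
  n_steps <- as.integer(round(duration / dt))
  if (length(rate_profile) == 1) rate_profile <- rep(rate_profile, n_steps)
  stopifnot(length(rate_profile) == n_steps)
  if (any(rate_profile < 0)) abort("rate profile must be nonnegative")
  p <- rate_profile * dt / 1000  # Hz * ms -> expected spikes per step
  if (any(p >= 1)) abort("rate * dt >= 1: invalid discretization")
  if (length(p) && max(p) >= 0.1) {
    abort("max(rate) * dt must be < 0.1 spikes per step")
  }
  withr::with_seed(seed, {
    hit <- runif(n_steps) < p
  })
  (which(hit) - 1) * dt
}

#' Build per-ORN firing-rate profiles for an odor panel
#'
#' During an odor window, ORNs of a glomerulus with response `D > 0` fire
#' at the adapting evoked rate (which replaces, rather than adds to, the
#' spontaneous process); glomeruli with `D = 0` and all off-odor epochs use
#' the spontaneous rate. Adaptation resets at each odor onset.
#'
#' @param glomeruli character vector: glomerulus of each ORN.
#' @param door complete response matrix (glomeruli x odors).
#' @param protocol a [stimulus_protocol()].
#' @param params a [drive_params()].
#' @param dt time step (ms).
#' @return Matrix of rates (Hz), time steps x ORNs.
#' @export
orn_rate_profiles <- function(glomeruli, door, protocol,
                              params = drive_params(), dt = 0.1) {
  missing_odors <- setdiff(protocol$odors, colnames(door))
  if (length(missing_odors)) {
    abort(paste0("protocol odors absent from response matrix: ",
                 paste(missing_odors, collapse = ", ")))
  }
  n_steps <- as.integer(round(protocol$total_duration / dt))
  t_ms <- (seq_len(n_steps) - 1) * dt
  # per unique glomerulus, build the rate profile once
  gl <- unique(glomeruli)
  prof <- matrix(params$spontaneous_rate, n_steps, length(gl),
                 dimnames = list(NULL, gl))
  for (w in seq_len(nrow(protocol$windows))) {
    odor <- protocol$windows$odor[w]
    on <- protocol$windows$onset[w]; off <- protocol$windows$offset[w]
    steps <- which(t_ms >= on & t_ms < off)
    for (g in gl) {
      Dg <- if (g %in% rownames(door)) door[g, odor] else 0
      if (!is.na(Dg) && Dg > 0) {
        prof[steps, g] <- odor_firing_rate(Dg, t_ms[steps] - on, params)
      }
    }
  }
  prof[, glomeruli, drop = FALSE]
}
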