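#' Gini coefficient of a firing-rate distribution
#'
#' Rate-uniformity score: 0 for a perfectly uniform (constant) rate vector,
#' approaching 1 as activity concentrates in a single neuron. Used to test
#' that PN odor-evoked rates are more uniformly distributed than ORN rates.
#' Scale-invariant: `uniformity_score(c * x) == uniformity_score(x)`.
#'
#' @param rates nonnegative rates (Hz), not all zero.
#' @return Gini coefficient in \[0, 1\].
#' @export
uniformity_score <- function(rates) {
  rates <- as.numeric(rates)
  if (any(rates < 0) || anyNA(rates)) abort("rates must be nonnegative")
  if (all(rates == 0)) abort("all-zero rate vector has no Gini coefficient")
  n <- length(rates)
  x <- sort(rates)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Separation of odor representations
#'
#' Mean pairwise Euclidean distance between unit-normalized per-odor
#' population rate vectors. Invariant to global rate rescaling. Used to
#' test that PN odor representations are more separated than ORN
#' representations.
#'
#' @param response glomeruli-x-odors (or neurons-x-odors) rate matrix, or
#'   an `al_response` (uses its PN matrix).
#' @return Mean pairwise distance (0 for identical representations,
#'   `sqrt(2)` for orthogonal ones).
#' @export
separation_score <- function(response) {
  m <- if (inherits(response, "al_response")) response$pn else response
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < 2) abort("need at least 2 odors")
  norms <- sqrt(colSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    warn(paste0("excluding zero-response odors: ",
                paste(colnames(m)[zero], collapse = ", ")))
    m <- m[, !zero, drop = FALSE]
    norms <- norms[!zero]
    if (ncol(m) < 2) abort("fewer than 2 nonzero odor vectors remain")
  }
  u <- sweep(m, 2, norms, `/`)
  d <- as.matrix(stats::dist(t(u)))
  mean(d[upper.tri(d)])
}

#' Exponent of the ORN-to-PN transfer function
#'
#' Least-squares slope of `log(PN + 1)` on `log(ORN + 1)` over paired
#' glomerulus-odor rates. A sublinear transfer (gain compression) yields an
#' exponent below 1.
#'
#' @param orn_rates,pn_rates paired rate vectors or matrices (same shape).
#' @return Fitted exponent.
#' @export
transfer_exponent <- function(orn_rates, pn_rates) {
  x <- as.numeric(orn_rates); y <- as.numeric(pn_rates)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 paired rates")
  unname(coef(lm(log1p(y) ~ log1p(x)))[2])
}

#' Cohen's d between two response samples
#'
#' Standardized mean difference `(mean(x) - mean(baseline)) / pooled SD`.
#' Antisymmetric under swapping the groups.
#'
#' @param x,baseline numeric vectors (e.g. all glomerulus-odor PN
#'   responses under a manipulated and the baseline configuration).
#' @return Cohen's d.
#' @export
cohens_d <- function(x, baseline) {
  x <- as.numeric(x); baseline <- as.numeric(baseline)
  n1 <- length(x); n2 <- length(baseline)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(baseline)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) abort("zero pooled SD")
  (mean(x) - mean(baseline)) / sqrt(sp2)
}

#' Validate the canonical antennal-lobe computations
#'
#' Runs the four-part battery on a simulated odor panel: (1) baseline and
#' odor-evoked rates within literature ranges, (2) PN odor-evoked rates
#' more uniform than ORN rates (lower Gini), (3) PN odor representations
#' more separated than ORN representations, and (4) a sublinear ORN-to-PN
#' transfer exponent.
#'
#' @param response an `al_response` from [run_odor_panel()].
#' @param orn_baseline_range,pn_evoked_range literature target ranges (Hz)
#'   for the mean ORN baseline rate and the mean odor-evoked PN rate.
#' @return A `validation_report`: tibble with one row per criterion
#'   (`criterion`, `value`, `reference`, `pass`).
#' @export
validate_al_model <- function(response, orn_baseline_range = c(5, 20),
                              pn_evoked_range = c(10, 200)) {
  roster <- response$roster
  orn_ids <- roster$id[roster$cell_class == "ORN"]
  pn_ids <- roster$id[roster$cell_class == "uPN"]
  orn_base <- mean(response$baseline_rates[orn_ids])
  pn_evoked <- mean(response$neuron_rates[pn_ids, ])
  pn_gini <- uniformity_score(colMeans_rates(response$neuron_rates, pn_ids))
  orn_gini <- uniformity_score(colMeans_rates(response$neuron_rates, orn_ids))
  pn_sep <- separation_score(response$pn)
  orn_sep <- separation_score(response$orn)
  exponent <- transfer_exponent(response$orn, response$pn)
  report <- tibble::tibble(
    criterion = c("orn_baseline_rate", "pn_evoked_rate",
                  "pn_more_uniform_than_orn",
                  "pn_more_separated_than_orn", "sublinear_transfer"),
    value = c(orn_base, pn_evoked, pn_gini - orn_gini, pn_sep - orn_sep,
              exponent),
    reference = c(paste(orn_baseline_range, collapse = "-"),
                  paste(pn_evoked_range, collapse = "-"),
                  "< 0 (PN Gini below ORN Gini)",
                  "> 0 (PN separation above ORN)", "< 1"),
    pass = c(orn_base >= orn_baseline_range[1] &
               orn_base <= orn_baseline_range[2],
             pn_evoked >= pn_evoked_range[1] &
               pn_evoked <= pn_evoked_range[2],
             pn_gini < orn_gini, pn_sep > orn_sep, exponent < 1))
  class(report) <- c("validation_report", class(report))
  report
}

# per-neuron mean odor-evoked rate for a subset of neurons
colMeans_rates <- function(neuron_rates, ids) {
  rowMeans(neuron_rates[ids, , drop = FALSE])
}

#' Sensitivity analysis of the class multipliers
#'
#' Scales each sensitivity multiplier independently over a grid (default
#' 1/4x to 4x of baseline), plus `n_multi` joint manipulations in which
#' every multiplier is drawn log-Normal with mean 1 and log-SD `log(2)`
#' (so +/-1 SD corresponds to a 2x or 0.5x scaling). For each manipulated
#' configuration, the odor panel is re-simulated with the same input-spike
#' seed and the effect on PN glomerulus-odor responses is summarized by
#' Cohen's d against baseline.
#'
#' @param circuit an `al_circuit` with polarities assigned (weights are
#'   rebuilt per manipulation).
#' @param door complete response matrix.
#' @param protocol a [stimulus_protocol()].
#' @param baseline_sens baseline [sensitivity_config()].
#' @param scale_grid multipliers applied to one parameter at a time.
#' @param n_multi number of joint log-Normal manipulations.
#' @param seed integer seed (spike sampling and joint draws).
#' @param ... passed to [run_odor_panel()].
#' @return Tibble `manipulation`, `parameter`, `scale`, `cohens_d`.
#' @export
sensitivity_analysis <- function(circuit, door, protocol,
                                 baseline_sens = sensitivity_config(),
                                 scale_grid = c(0.25, 0.5, 2, 4),
                                 n_multi = 10, seed = 1, ...) {
  base_resp <- run_odor_panel(build_weight_matrix(circuit, baseline_sens),
                              door, protocol, seed = seed, ...)
  base_vec <- as.numeric(base_resp$pn)
  pars <- c("a_ORN", "a_eLN", "a_iLN", "a_PN")

  run_with <- function(sens) {
    resp <- run_odor_panel(build_weight_matrix(circuit, sens), door,
                           protocol, seed = seed, ...)
    cohens_d(as.numeric(resp$pn), base_vec)
  }

  single <- purrr::map_dfr(pars, function(p) {
    purrr::map_dfr(scale_grid, function(s) {
      sens <- baseline_sens
      sens[[p]] <- sens[[p]] * s
      tibble::tibble(manipulation = "single", parameter = p, scale = s,
                     cohens_d = run_with(sens))
    })
  })

  multi <- if (n_multi > 0) {
    scales <- withr::with_seed(seed + 1L, {
      matrix(exp(rnorm(n_multi * 4, 0, log(2))), n_multi, 4,
             dimnames = list(NULL, pars))
    })
    purrr::map_dfr(seq_len(n_multi), function(k) {
      sens <- baseline_sens
      for (p in pars) sens[[p]] <- sens[[p]] * scales[k, p]
      tibble::tibble(manipulation = "joint", parameter = "all",
                     scale = NA_real_, cohens_d = run_with(sens))
    })
  } else {
    tibble::tibble(manipulation = character(0), parameter = character(0),
                   scale = numeric(0), cohens_d = numeric(0))
  }
  dplyr::bind_rows(single, multi)
}
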