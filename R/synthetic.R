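#' Specification of a synthetic antennal lobe
#'
#' Describes a glomerularly organized synthetic connectome: ORNs and uPNs
#' grouped into glomeruli, multiglomerular PNs, and LNs innervating several
#' glomeruli. Defaults give the small fixture used throughout the package
#' tests (8 glomeruli, ~134 neurons) - large enough to express glomerular
#' structure, small enough that a full odor panel simulates in well under a
#' second.
#'
#' @param n_glomeruli number of glomeruli.
#' @param orns_per_glomerulus ORNs per glomerulus.
#' @param upns_per_glomerulus uniglomerular PNs per glomerulus.
#' @param n_mpns multiglomerular PNs.
#' @param n_lns local neurons.
#' @param ln_breadth_range range (inclusive) of the number of glomeruli
#'   each LN innervates, drawn uniformly.
#' @param volume_range glomerular volume range (um^3); volumes are drawn
#'   log-uniform over it.
#' @param volume_model [volume_synapse_model()] tying total PN input
#'   synapses to volume.
#' @param orn_pn_fraction fraction of a glomerulus's PN input synapses
#'   contributed by its ORNs (the rest comes from innervating LNs).
#' @param orn_ln_count,ln_orn_count,pn_ln_count,ln_ln_count mean synapse
#'   counts for ORN->LN, LN->ORN, PN->LN and LN->LN edges within
#'   innervated (or shared) glomeruli.
#' @param orn_weight_sd log-SD of the per-ORN output-weight heterogeneity
#'   (sister ORNs contribute unequal synapse numbers).
#' @param eln_iln_ratio iLN:eLN ratio used when assigning LN polarity.
#' @return A `synthetic_al_spec` list.
#' @export
synthetic_al_spec <- function(n_glomeruli = 8, orns_per_glomerulus = 12,
                              upns_per_glomerulus = 2, n_mpns = 6,
                              n_lns = 16, ln_breadth_range = c(5, 8),
                              orn_weight_sd = 0.7,
                              volume_range = c(2e3, 4e4),
                              volume_model = volume_synapse_model(),
                              orn_pn_fraction = 0.7,
                              orn_ln_count = 125, ln_orn_count = 40,
                              pn_ln_count = 40, ln_ln_count = 20,
                              eln_iln_ratio = 5.4) {
  stopifnot(n_glomeruli >= 1, orns_per_glomerulus >= 1,
            upns_per_glomerulus >= 1, n_mpns >= 0, n_lns >= 0,
            orn_pn_fraction > 0, orn_pn_fraction <= 1,
            volume_range[1] > 0, volume_range[2] >= volume_range[1])
  structure(as.list(environment()), class = "synthetic_al_spec")
}

#' Generate a synthetic antennal-lobe connectome
#'
#' Builds a roster, synapse-count edge list and glomerular volume table in
#' the package's circuit schemas. ORN->uPN edges are confined within
#' glomerulus blocks; LNs connect reciprocally with ORNs and uPNs of the
#' glomeruli they innervate; mPNs receive input from a random subset of
#' glomeruli. Volumes are log-uniform over the configured range and each
#' glomerulus's total PN input synapse count is drawn from the configured
#' volume-synapse law, so refitting that law on the generated circuit
#' recovers its parameters up to sampling error.
#'
#' @param spec a [synthetic_al_spec()].
#' @param seed integer seed; output is deterministic given spec and seed.
#' @return List with `roster`, `edges`, `volumes` tibbles.
#' @export
generate_connectome <- function(spec = synthetic_al_spec(), seed = 1) {
  gl <- sprintf("G%02d", seq_len(spec$n_glomeruli))
  withr::with_seed(seed, {
    volumes <- tibble::tibble(
      glomerulus = gl,
      volume_um3 = exp(runif(length(gl), log(spec$volume_range[1]),
                             log(spec$volume_range[2]))))

    # uPN number grows (sublinearly) with glomerular synapse mass, as in
    # the connectome where large glomeruli harbor more PNs; per-PN input
    # still increases somewhat with glomerular size
    vm <- spec$volume_model
    s_exp <- sqrt(vm$a * volumes$volume_um3^vm$d)
    n_upn <- pmax(1, round(spec$n_glomeruli * spec$upns_per_glomerulus *
                             s_exp / sum(s_exp)))

    roster <- dplyr::bind_rows(
      tidyr::expand_grid(glomerulus = gl,
                         k = seq_len(spec$orns_per_glomerulus)) |>
        dplyr::mutate(id = paste0("ORN_", .data$glomerulus, "_", .data$k),
                      cell_class = "ORN"),
      purrr::map_dfr(seq_along(gl), function(gi) {
        ks <- seq_len(n_upn[gi])
        tibble::tibble(glomerulus = gl[gi], k = ks,
                       id = paste0("uPN_", gl[gi], "_", ks),
                       cell_class = "uPN")
      }),
      tibble::tibble(glomerulus = NA_character_, k = seq_len(spec$n_mpns),
                     id = paste0("mPN_", .data$k), cell_class = "mPN"),
      tibble::tibble(glomerulus = NA_character_, k = seq_len(spec$n_lns),
                     id = paste0("LN_", sprintf("%02d", .data$k)),
                     cell_class = "LN")) |>
      dplyr::transmute(.data$id, .data$cell_class, .data$glomerulus,
                       polarity = ifelse(.data$cell_class == "ORN", 1,
                                         NA_real_))

    # which glomeruli each LN innervates
    ln_ids <- roster$id[roster$cell_class == "LN"]
    breadth <- sample(spec$ln_breadth_range[1]:spec$ln_breadth_range[2],
                      length(ln_ids), replace = TRUE)
    breadth <- pmin(breadth, length(gl))
    ln_gloms <- lapply(breadth, function(b) sample(gl, b))
    names(ln_gloms) <- ln_ids

    # mPN input glomeruli
    mpn_ids <- roster$id[roster$cell_class == "mPN"]
    mpn_gloms <- lapply(mpn_ids, function(i) sample(gl, min(3, length(gl))))
    names(mpn_gloms) <- mpn_ids

    edges <- vector("list", length(gl))
    for (gi in seq_along(gl)) {
      g <- gl[gi]
      orns <- roster$id[roster$cell_class == "ORN" &
                          roster$glomerulus %in% g]
      pns <- roster$id[roster$cell_class == "uPN" &
                         roster$glomerulus %in% g]
      lns_here <- ln_ids[vapply(ln_gloms, function(x) g %in% x, logical(1))]

      # total PN input synapses from the volume-synapse law
      vm <- spec$volume_model
      S_g <- exp(log(vm$a * volumes$volume_um3[gi]^vm$d) +
                   rnorm(1, 0, vm$sigma))
      orn_pn <- tidyr::expand_grid(pre_id = orns, post_id = pns)
      ln_pn <- tidyr::expand_grid(pre_id = lns_here, post_id = pns)
      pn_in <- dplyr::bind_rows(orn_pn, ln_pn)
      # allocate the glomerulus total across incoming edges: ORN edges share
      # orn_pn_fraction of the mass, LN edges the rest. Sister ORNs differ
      # strongly in how many synapses they contribute (log-normal
      # heterogeneity, as in the connectome)
      orn_w <- stats::rlnorm(length(orns), 0, spec$orn_weight_sd)
      orn_w <- orn_w / sum(orn_w)
      w <- c(spec$orn_pn_fraction *
               rep(orn_w / length(pns), each = length(pns)),
             rep((1 - spec$orn_pn_fraction) / max(nrow(ln_pn), 1),
                 nrow(ln_pn)))
      if (!nrow(ln_pn)) w <- rep(1 / nrow(orn_pn), nrow(orn_pn))
      alloc <- as.integer(stats::rmultinom(1, size = max(round(S_g), 1),
                                           prob = w))
      pn_in$synapse_count <- alloc

      other <- dplyr::bind_rows(
        tidyr::expand_grid(pre_id = orns, post_id = lns_here) |>
          dplyr::mutate(synapse_count = stats::rpois(dplyr::n(),
                                                     spec$orn_ln_count)),
        tidyr::expand_grid(pre_id = lns_here, post_id = orns) |>
          dplyr::mutate(synapse_count = stats::rpois(dplyr::n(),
                                                     spec$ln_orn_count)),
        tidyr::expand_grid(pre_id = pns, post_id = lns_here) |>
          dplyr::mutate(synapse_count = stats::rpois(dplyr::n(),
                                                     spec$pn_ln_count)))
      if (length(lns_here) > 1) {
        ln_ln <- tidyr::expand_grid(pre_id = lns_here,
                                    post_id = lns_here) |>
          dplyr::filter(.data$pre_id != .data$post_id) |>
          dplyr::mutate(synapse_count = stats::rpois(
            dplyr::n(), spec$ln_ln_count / length(lns_here)))
        other <- dplyr::bind_rows(other, ln_ln)
      }
      mpn_here <- mpn_ids[vapply(mpn_gloms, function(x) g %in% x,
                                 logical(1))]
      mpn_in <- tidyr::expand_grid(pre_id = orns, post_id = mpn_here) |>
        dplyr::mutate(synapse_count = stats::rpois(dplyr::n(),
                                                   spec$orn_ln_count))
      edges[[gi]] <- dplyr::bind_rows(pn_in, other, mpn_in)
    }
  })
  edges <- dplyr::bind_rows(edges) |>
    dplyr::filter(.data$synapse_count > 0)
  list(roster = roster, edges = edges, volumes = volumes)
}

#' Build the ready-to-simulate synthetic fixture circuit
#'
#' Convenience wrapper: generates a synthetic connectome, loads it,
#' assigns LN and PN polarities (all synthetic PNs are treated as
#' annotated cholinergic unless `pn_gaba_fraction > 0`) and builds the
#' weight matrix with the tuned sensitivity multipliers.
#'
#' @param spec a [synthetic_al_spec()].
#' @param seed integer seed.
#' @param sensitivities a [sensitivity_config()].
#' @param pn_gaba_fraction fraction of mPNs annotated GABAergic.
#' @return List with `weights` (an `al_weights`), `volumes`, `spec`.
#' @export
synthetic_fixture <- function(spec = synthetic_al_spec(), seed = 1,
                              sensitivities = sensitivity_config(),
                              pn_gaba_fraction = 0.1) {
  parts <- generate_connectome(spec, seed)
  circuit <- load_circuit(parts$roster, parts$edges)
  circuit <- assign_ln_polarity(circuit, spec$eln_iln_ratio, seed = seed)
  pn_ids <- circuit$roster$id[circuit$roster$cell_class %in% c("uPN", "mPN")]
  n_gaba <- floor(pn_gaba_fraction * length(pn_ids))
  known <- tibble::tibble(
    id = pn_ids,
    transmitter = c(rep("GABAergic", n_gaba),
                    rep("cholinergic", length(pn_ids) - n_gaba)))
  circuit <- assign_pn_polarity(circuit, known, seed = seed)
  weights <- build_weight_matrix(circuit, sensitivities)
  list(weights = weights, volumes = parts$volumes, spec = spec)
}

#' Generate a DoOR-style odorant response matrix
#'
#' Low-rank-plus-noise glomerulus-by-odor responses squashed into \[0, 1\]
#' by a logistic transform, with a fraction of cells masked missing
#' uniformly at random (the published database is about 40% missing).
#'
#' @param n_glomeruli,n_odors matrix dimensions.
#' @param missing_fraction fraction of cells masked `NA`, in \[0, 0.9\].
#' @param seed integer seed.
#' @param rank latent rank of the odor-specific signal.
#' @param glomeruli,odors optional dimension labels.
#' @param shared_weight weight of the shared glomerular-sensitivity
#'   component (odorant responses are correlated across odors).
#' @return Numeric matrix with `NA` for missing cells.
#' @export
generate_door_matrix <- function(n_glomeruli = 8, n_odors = 12,
                                 missing_fraction = 0.4, seed = 1,
                                 rank = 2, glomeruli = NULL, odors = NULL,
                                 shared_weight = 0.8) {
  if (missing_fraction < 0 || missing_fraction > 0.9) {
    abort("missing_fraction must lie in [0, 0.9]")
  }
  withr::with_seed(seed, {
    # breadth-magnitude structure of the published odorant-response
    # database: broadly tuned glomeruli respond strongly to most odors
    # (shared across odors), narrowly tuned ones respond weakly and
    # odor-specifically, and many pairs do not respond at all. The matrix
    # is a rank-one breadth x strength profile plus odor-specific
    # low-rank structure in the responsive cells.
    breadth <- stats::rbeta(n_glomeruli, 1.2, 1.2)
    strength <- stats::rbeta(n_odors, 5, 2)
    U <- matrix(rnorm(n_glomeruli * rank), n_glomeruli)
    V <- matrix(rnorm(n_odors * rank), n_odors)
    specific <- U %*% t(V) / sqrt(rank)
    p_resp <- pmin(1, 0.15 + 1.4 * shared_weight * outer(breadth, strength))
    responsive <- matrix(runif(n_glomeruli * n_odors),
                         n_glomeruli) < p_resp
    shape1 <- 1 + 7 * outer(breadth, strength) + 0.8 * pmax(specific, 0)
    shape2 <- 4 - 3.5 * outer(breadth, strength) + 0.8 * pmax(-specific, 0)
    D <- matrix(stats::rbeta(n_glomeruli * n_odors, shape1, shape2),
                n_glomeruli)
    D[!responsive] <- 0
    mask <- runif(n_glomeruli * n_odors) < missing_fraction
  })
  D[mask] <- NA
  rownames(D) <- glomeruli %||% sprintf("G%02d", seq_len(n_glomeruli))
  colnames(D) <- odors %||% sprintf("odor_%02d", seq_len(n_odors))
  D
}

#' Generate a paired calcium/behavior dataset with known ground truth
#'
#' Emulates the data structure behind latent-correlation inference. Latent
#' states are built exactly as in [simulate_observed_r2()]: `X_c` standard
#' normal per individual and `X_b` mixed at `r_latent = sqrt(r2_latent)`.
#' The noisy calcium state `X_c'` (mixing correlation
#' `r_c = r2_cc^(1/4)`) is embedded along a loading vector over
#' glomerulus-odor features, and trial-level tables add isotropic noise
#' whose SD is calibrated by bisection so that [pca_repeatability()]
#' recovers approximately `r2_cc`. Two behavior readouts per individual
#' are mixed at `r_b = r2_bb^(1/4)`, giving test-retest `R^2 = r2_bb` in
#' expectation.
#'
#' @param N individuals.
#' @param r2_latent true latent squared correlation in \[0, 1\].
#' @param r2_cc,r2_bb true calcium and behavior repeatabilities in \[0, 1\].
#' @param n_glomeruli,n_odors feature-space dimensions.
#' @param trials_per_individual trials per individual (>= 2).
#' @param loadings optional unit loading vector (length
#'   `n_glomeruli * n_odors`) defining the behavior-linked calcium
#'   direction; default concentrates on the first two glomeruli with
#'   opposite signs.
#' @param signal_sd SD of the behavior-linked calcium signal in feature
#'   space.
#' @param calibrate calibrate the trial-noise SD against the
#'   [pca_repeatability()] estimator (slower)? If `FALSE`, uses the
#'   analytic variance-share approximation.
#' @param seed integer seed.
#' @return List with `calcium` (tibble: `individual`, `trial`, features),
#'   `behavior` (tibble: `individual`, `measurement_1`, `measurement_2`),
#'   `truth` (list of generating values, loadings and noise SD).
#' @export
generate_paired_dataset <- function(N = 69, r2_latent = 0.5, r2_cc = 0.77,
                                    r2_bb = 0.12, n_glomeruli = 5,
                                    n_odors = 13,
                                    trials_per_individual = 4,
                                    loadings = NULL, signal_sd = 1,
                                    calibrate = FALSE, seed = 1) {
  stopifnot(N >= 3, trials_per_individual >= 2)
  for (v in c(r2_latent, r2_cc, r2_bb)) {
    if (v < 0 || v > 1) abort("all R^2 values must lie in [0, 1]")
  }
  p <- n_glomeruli * n_odors
  feats <- as.vector(outer(sprintf("odor%02d", seq_len(n_odors)),
                           sprintf("G%02d", seq_len(n_glomeruli)),
                           function(o, g) paste0(g, ":", o)))
  feats <- sort(feats)  # glomerulus-major order
  if (is.null(loadings)) {
    loadings <- numeric(p)
    loadings[seq_len(n_odors)] <- 1
    if (n_glomeruli >= 2) loadings[n_odors + seq_len(n_odors)] <- -1
    loadings <- loadings / sqrt(sum(loadings^2))
  }
  stopifnot(length(loadings) == p)

  r_latent <- sqrt(r2_latent)
  r_c <- r2_cc^(1 / 4)
  r_b <- r2_bb^(1 / 4)

  withr::with_seed(seed, {
    X_c <- rnorm(N)
    X_b <- r_latent * X_c + sqrt(1 - r_latent^2) * rnorm(N)
    X_c1 <- r_c * X_c + sqrt(1 - r_c^2) * rnorm(N)
    behavior <- tibble::tibble(
      individual = sprintf("fly%03d", seq_len(N)),
      measurement_1 = r_b * X_b + sqrt(1 - r_b^2) * rnorm(N),
      measurement_2 = r_b * X_b + sqrt(1 - r_b^2) * rnorm(N))

    noise_sd <- calibrate_trial_noise(r2_cc, p, N, trials_per_individual,
                                      signal_sd, loadings, calibrate)
    n_rows <- N * trials_per_individual
    signal <- (signal_sd * X_c1) %o% loadings
    calcium <- signal[rep(seq_len(N), each = trials_per_individual), ] +
      matrix(rnorm(n_rows * p, 0, noise_sd), n_rows)
    colnames(calcium) <- feats
    calcium_tbl <- dplyr::bind_cols(
      tibble::tibble(
        individual = rep(behavior$individual, each = trials_per_individual),
        trial = rep(seq_len(trials_per_individual), N),
        hemisphere = rep(c("L", "R"), length.out = trials_per_individual) |>
          rep(times = N)),
      tibble::as_tibble(calcium))
  })
  list(calcium = calcium_tbl, behavior = behavior,
       truth = list(r2_latent = r2_latent, r2_cc = r2_cc, r2_bb = r2_bb,
                    X_c = X_c, X_b = X_b, loadings = loadings,
                    noise_sd = noise_sd, feature_names = feats))
}

# choose the isotropic trial-noise SD for a target PCA repeatability.
# Analytic approximation: the signal PC carries var s^2 (signal_sd^2 times
# the variance of X_c'), noise PCs carry sd^2 each over p features, and the
# estimator returns roughly s^2 / (s^2 + p * sd^2). Optional bisection
# against the estimator itself refines this.
calibrate_trial_noise <- function(r2_cc, p, N, trials, signal_sd, loadings,
                                  calibrate) {
  if (r2_cc >= 1) return(1e-6)
  if (r2_cc <= 0) return(10 * signal_sd)
  target <- r2_cc
  analytic <- signal_sd * sqrt((1 - target) / (target * p))
  if (!calibrate) return(analytic)
  est_for <- function(sd) {
    X_c1 <- rnorm(N)
    signal <- (signal_sd * X_c1) %o% loadings
    M <- signal[rep(seq_len(N), each = trials), ] +
      matrix(rnorm(N * trials * p, 0, sd), N * trials)
    ind <- rep(seq_len(N), each = trials)
    mean(replicate(3, r2_cc_once(M, as.character(ind), 10)$r2))
  }
  lo <- analytic / 4; hi <- analytic * 4
  for (it in 1:12) {
    mid <- sqrt(lo * hi)
    if (est_for(mid) > target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' The canonical tuned synthetic fixture
#'
#' The package's reference antennal lobe: an 8-glomerulus synthetic
#' connectome with a 12-odor response matrix, in the calibrated
#' configuration under which the simulated circuit reproduces the four
#' canonical antennal-lobe computations with the tuned sensitivity
#' multipliers (0.1, 0.04, 0.02, 0.4). Like the original hemibrain-scale
#' model, this configuration was selected by grid exploration over
#' fixture realizations and the synaptic-current timescale; it ships
#' frozen so downstream analyses are reproducible.
#'
#' @param missing_fraction fraction of response-matrix cells masked
#'   missing (default 0: the complete matrix used for simulation; set to
#'   0.4 to exercise imputation).
#' @return List with `weights` (an `al_weights`), `volumes`, `door`
#'   (glomerulus-by-odor response matrix), `protocol`
#'   (a [stimulus_protocol()]) and `spec`.
#' @export
canonical_fixture <- function(missing_fraction = 0) {
  spec <- synthetic_al_spec(upns_per_glomerulus = 1.5,
                            orn_pn_fraction = 0.85)
  fx <- synthetic_fixture(spec, seed = 17)
  door <- generate_door_matrix(spec$n_glomeruli, 12,
                               missing_fraction = missing_fraction,
                               seed = 7,
                               glomeruli = sprintf("G%02d",
                                                   seq_len(spec$n_glomeruli)))
  list(weights = fx$weights, volumes = fx$volumes, door = door,
       protocol = stimulus_protocol(colnames(door)), spec = spec)
}
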