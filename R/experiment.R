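#' Simulate a population of idiosyncratic antennal lobes
#'
#' Generates `n_flies` idiosyncratic circuits under one source of
#' developmental stochasticity ([idiosyncratic_circuit()]), simulates the
#' odor panel in each, and stacks the PN glomerulus-odor response vectors
#' into a population response table (one row per simulated individual,
#' one column per `glomerulus:odor` feature). Poisson input-spike timing
#' differs across individuals in every mode; circuit structure differs
#' only in the non-`"poisson"` modes.
#'
#' @param weights source `al_weights`.
#' @param door complete response matrix.
#' @param protocol a [stimulus_protocol()].
#' @param n_flies number of simulated individuals.
#' @param mode variation mode passed to [idiosyncratic_circuit()].
#' @param volumes glomerular volume table (required for `"density"`).
#' @param model [volume_synapse_model()] for `"density"`.
#' @param seed integer seed; fly k uses an independent sub-seed.
#' @param ... passed to [run_odor_panel()].
#' @return Tibble: `individual`, `mode`, then one numeric column per
#'   `glomerulus:odor` feature (mean PN rate, Hz).
#' @export
simulate_al_population <- function(weights, door, protocol, n_flies = 100,
                                   mode = "poisson", volumes = NULL,
                                   model = volume_synapse_model(),
                                   seed = 1, ...) {
  rows <- vector("list", n_flies)
  for (k in seq_len(n_flies)) {
    fly_seed <- seed + 7919L * k
    circ <- idiosyncratic_circuit(weights, mode, volumes, model,
                                  seed = fly_seed)
    resp <- run_odor_panel(circ, door, protocol, seed = fly_seed + 1L, ...)
    v <- as.numeric(t(resp$pn))
    names(v) <- as.vector(outer(colnames(resp$pn), rownames(resp$pn),
                                function(o, g) paste0(g, ":", o)))
    rows[[k]] <- tibble::tibble(
      individual = sprintf("sim%04d", k),
      mode = paste(mode, collapse = "+"), !!!v)
  }
  dplyr::bind_rows(rows)
}

#' Glomerular organization of a simulated population
#'
#' PCA of the population response table followed by the glomerular
#' organization index, with a jackknife standard error over individuals.
#'
#' @param population output of [simulate_al_population()] (or any tibble
#'   with `individual` plus `glomerulus:odor` features).
#' @param K number of leading PCs for the index.
#' @return Tibble `goi`, `se`, `n` (one row).
#' @export
population_goi <- function(population, K = 5) {
  feats <- setdiff(names(population), c("individual", "mode"))
  X <- as.matrix(population[feats])
  goi_of <- function(M) {
    glomerular_organization_index(pca_responses(M), K = K)
  }
  full <- goi_of(X)
  n <- nrow(X)
  jack <- vapply(seq_len(n), function(i) goi_of(X[-i, , drop = FALSE]),
                 numeric(1))
  se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  tibble::tibble(goi = full, se = se, n = n)
}

#' Label simulated individuals by predicted odor preference and decode
#'
#' Applies a linear preference model to the PC scores of a simulated
#' population, labels each individual OCT- or MCH-preferring by a median
#' split of the predicted preference, and reports the twofold
#' cross-validated linear-logistic accuracy of recovering those labels
#' from the first `n_pcs` PC scores, together with a shuffled-label null.
#'
#' @param population output of [simulate_al_population()].
#' @param model a [preference_model()]; its PC predictor is resolved in
#'   the population's own PC space.
#' @param n_pcs PCs used by the classifier (default 3).
#' @param n_shuffles shuffled-label replicates for the null (default 100).
#' @param seed integer seed.
#' @return Tibble with `accuracy`, `null_mean`, `null_sd`, `n`.
#' @export
preference_decoding <- function(population, model = preference_model(
                                  beta0 = -0.058, beta1 = -0.081,
                                  predictor = "PC2"),
                                n_pcs = 3, n_shuffles = 100, seed = 1) {
  feats <- setdiff(names(population), c("individual", "mode"))
  pca <- pca_responses(as.matrix(population[feats]))
  pref <- apply_preference_model(model, pca$scores)
  label <- factor(ifelse(pref > median(pref), "OCT", "MCH"))
  scores <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  acc <- classify_individuals(scores, label, seed = seed)
  null <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_shuffles), function(s) {
      classify_individuals(scores, sample(label), seed = seed + s)
    }, numeric(1))
  })
  tibble::tibble(accuracy = acc, null_mean = mean(null),
                 null_sd = sd(null), n = nrow(scores))
}
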