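#' Bootstrap a cell population to create an idiosyncratic circuit
#'
#' Resamples neurons of one class with replacement, emulating developmental
#' variation in the complement of cells of that type. ORNs (and uPNs) are
#' resampled glomerulus-by-glomerulus, preserving each pool's size; LNs are
#' resampled from the single pool of all LNs. A sampled neuron keeps its
#' original synapse counts, so duplicated neurons become distinct instances
#' sharing the original's rows and columns, and no synapse appears between
#' pairs unconnected in the source circuit. Multiglomerular PNs carry no
#' single glomerulus label and are left fixed under PN bootstrapping.
#'
#' @param circuit an `al_circuit` (or `al_weights`; the raw counts are
#'   resampled and polarity/weights carried through).
#' @param cell_class one of `"ORN"`, `"PN"`, `"LN"`.
#' @param seed integer seed.
#' @return A circuit of the same class with resampled roster and counts.
#'   Resampled neurons get ids suffixed `.b<k>`; the original id is kept in
#'   a `source_id` roster column.
#' @export
bootstrap_population <- function(circuit, cell_class = c("ORN", "PN", "LN"),
                                 seed = 1) {
  cell_class <- match.arg(cell_class)
  roster <- circuit$roster
  sel <- seq_len(nrow(roster))  # index into original rows, with replacement

  withr::with_seed(seed, {
    if (cell_class == "LN") {
      pool <- which(roster$cell_class == "LN")
      if (!length(pool)) abort("no LNs to bootstrap")
      sel[pool] <- pool[sample.int(length(pool), length(pool),
                                   replace = TRUE)]
    } else {
      target <- if (cell_class == "ORN") "ORN" else "uPN"
      rows <- which(roster$cell_class == target)
      if (!length(rows)) abort(paste0("no ", target, "s to bootstrap"))
      for (g in unique(roster$glomerulus[rows])) {
        pool <- rows[roster$glomerulus[rows] == g]
        sel[pool] <- pool[sample.int(length(pool), length(pool),
                                     replace = TRUE)]
      }
    }
  })

  new_roster <- roster[sel, , drop = FALSE]
  new_roster$source_id <- new_roster$id
  dup <- duplicated(sel) | duplicated(sel, fromLast = TRUE)
  changed <- sel != seq_len(nrow(roster))
  # give every resampled slot a unique id while keeping slot order
  new_roster$id <- ifelse(changed | dup,
                          paste0(new_roster$id, ".b", seq_along(sel)),
                          new_roster$id)
  counts <- circuit$counts[sel, sel, drop = FALSE]
  dimnames(counts) <- list(new_roster$id, new_roster$id)

  out <- circuit
  out$roster <- new_roster
  out$counts <- counts
  if (!is.null(out$effective)) {
    eff <- out$effective[sel, sel, drop = FALSE]
    dimnames(eff) <- dimnames(counts)
    out$effective <- eff
  }
  out
}

#' Fit the glomerular volume-synapse power law
#'
#' Maximum-likelihood fit of `log S_g = log(a * V_g^d) + eps_g`,
#' `eps_g ~ Normal(0, sigma^2)`: ordinary least squares of `log S` on
#' `log V`, with `sigma` the root-mean-square residual (the biased MLE
#' form, divisor n). On hemibrain-scale data this law has parameters
#' a = 8.98, d = 0.73, sigma = 0.38.
#'
#' @param volumes positive glomerular volumes (um^3), or a data frame with
#'   columns `glomerulus`, `volume_um3`.
#' @param pn_input_counts positive total PN input synapse count per
#'   glomerulus, aligned with `volumes`.
#' @return A `volume_synapse_model`: list with `a`, `d`, `sigma`, `n`.
#' @export
fit_volume_synapse_model <- function(volumes, pn_input_counts) {
  if (is.data.frame(volumes)) volumes <- volumes$volume_um3
  v <- as.numeric(volumes); s <- as.numeric(pn_input_counts)
  if (length(v) != length(s)) abort("volumes and counts must align")
  if (length(v) < 3) abort("need at least 3 glomeruli")
  if (any(v <= 0) || any(s <= 0)) {
    abort("volumes and counts must be strictly positive")
  }
  fit <- lm(log(s) ~ log(v))
  sigma <- sqrt(mean(stats::residuals(fit)^2))
  volume_synapse_model(a = exp(unname(coef(fit)[1])),
                       d = unname(coef(fit)[2]), sigma = sigma,
                       n = length(v))
}

#' @rdname fit_volume_synapse_model
#' @param a scale factor (synapses per um^(3d)); must be positive.
#' @param d power-law exponent.
#' @param sigma SD of the log residual (natural-log units); nonnegative.
#' @param n number of glomeruli behind a fit (optional).
#' @export
volume_synapse_model <- function(a = 8.98, d = 0.73, sigma = 0.38,
                                 n = NA_integer_) {
  if (a <= 0 || sigma < 0) abort("need a > 0 and sigma >= 0")
  structure(list(a = a, d = d, sigma = sigma, n = n),
            class = "volume_synapse_model")
}

#' @export
print.volume_synapse_model <- function(x, ...) {
  cat(sprintf("<volume_synapse_model> a = %.3g, d = %.3g, sigma = %.3g\n",
              x$a, x$d, x$sigma))
  invisible(x)
}

#' Total PN input synapses per glomerulus
#'
#' All synapses whose postsynaptic neuron is a uPN of the glomerulus,
#' regardless of presynaptic class.
#'
#' @param circuit an `al_circuit`.
#' @return Tibble `glomerulus`, `pn_input_synapses`.
#' @export
pn_input_synapses <- function(circuit) {
  roster <- circuit$roster
  gloms <- sort(unique(stats::na.omit(roster$glomerulus)))
  totals <- vapply(gloms, function(g) {
    cols <- which(roster$glomerulus %in% g & roster$cell_class == "uPN")
    sum(circuit$counts[, cols])
  }, numeric(1))
  tibble::tibble(glomerulus = gloms, pn_input_synapses = totals)
}

#' Resample glomerular PN input-synapse density
#'
#' For each glomerulus, draws a target total PN input synapse count from
#' the volume-synapse law `log S_g = log(a * V_g^d) + eps`,
#' `eps ~ Normal(0, sigma^2)`, and multiplies every synapse count onto that
#' glomerulus's PNs by the single scalar `target / current total`. Ratios
#' between individual PN input weights within a glomerulus are therefore
#' unchanged, and counts become real-valued.
#'
#' @param circuit an `al_circuit` or `al_weights`.
#' @param volumes data frame `glomerulus`, `volume_um3` covering every
#'   glomerulus in the roster.
#' @param model a [volume_synapse_model()].
#' @param seed integer seed.
#' @return The circuit with rescaled counts (and effective weights, when
#'   present).
#' @export
resample_synapse_density <- function(circuit, volumes,
                                     model = volume_synapse_model(),
                                     seed = 1) {
  roster <- circuit$roster
  gloms <- sort(unique(stats::na.omit(roster$glomerulus)))
  v <- setNames(volumes$volume_um3, volumes$glomerulus)
  missing_v <- setdiff(gloms, names(v))
  if (length(missing_v)) {
    abort(paste0("no volume for glomerulus: ",
                 paste(missing_v, collapse = ", ")))
  }
  counts <- circuit$counts
  eff <- circuit$effective
  withr::with_seed(seed, {
    eps <- rnorm(length(gloms), 0, model$sigma)
  })
  for (k in seq_along(gloms)) {
    g <- gloms[k]
    cols <- which(roster$glomerulus %in% g & roster$cell_class == "uPN")
    if (!length(cols)) next
    cur <- sum(counts[, cols])
    if (cur <= 0) abort(paste0("glomerulus ", g, " has no PN input synapses"))
    target <- exp(log(model$a * v[[g]]^model$d) + eps[k])
    scalar <- target / cur
    counts[, cols] <- counts[, cols] * scalar
    if (!is.null(eff)) eff[, cols] <- eff[, cols] * scalar
  }
  circuit$counts <- counts
  if (!is.null(eff)) circuit$effective <- eff
  circuit
}

#' Generate one idiosyncratic antennal lobe
#'
#' Applies the requested sources of developmental stochasticity to a source
#' circuit: bootstrapping of ORN / PN / LN populations and glomerular
#' synapse-density resampling (bootstrap first, then density rescaling when
#' combined). `"poisson"` applies no circuit change at all - variability
#' then comes solely from Poisson input-spike timing in the simulation.
#'
#' @param circuit source `al_circuit`/`al_weights`.
#' @param mode character vector drawn from
#'   `c("poisson", "orn", "pn", "ln", "density")`; `"poisson"` may not be
#'   combined with circuit modes.
#' @param volumes glomerular volume table, required for `"density"`.
#' @param model [volume_synapse_model()] used for `"density"`.
#' @param seed integer seed.
#' @return A circuit of the same class as the input.
#' @export
idiosyncratic_circuit <- function(circuit, mode = "poisson", volumes = NULL,
                                  model = volume_synapse_model(), seed = 1) {
  mode <- match.arg(mode, c("poisson", "orn", "pn", "ln", "density"),
                    several.ok = TRUE)
  if ("poisson" %in% mode && length(mode) > 1) {
    abort("'poisson' means no circuit variation; do not combine it")
  }
  out <- circuit
  k <- 0
  for (m in setdiff(mode, c("poisson", "density"))) {
    k <- k + 1
    out <- bootstrap_population(out, toupper(m), seed = seed + 104729L * k)
  }
  if ("density" %in% mode) {
    if (is.null(volumes)) abort("density resampling needs a volume table")
    out <- resample_synapse_density(out, volumes, model,
                                    seed = seed + 104729L * (k + 1))
  }
  out
}
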