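#' Load an antennal-lobe circuit from roster and edge tables
#'
#' Builds the circuit container used throughout the package from a neuron
#' roster (one row per neuron) and a synapse-count edge list. ORNs and PNs
#' belonging to non-olfactory glomeruli are removed, together with all their
#' edges, before the count matrix is assembled.
#'
#' @param roster data frame with columns `id`, `cell_class` (one of
#'   `"ORN"`, `"uPN"`, `"mPN"`, `"LN"`), `glomerulus` (`NA`/blank for LNs
#'   and mPNs) and optionally `polarity` (+1 excitatory, -1 inhibitory;
#'   `NA` if not yet assigned).
#' @param edges data frame with columns `pre_id`, `post_id`,
#'   `synapse_count` (nonnegative integers). Both endpoints must exist in
#'   the roster.
#' @param excluded_glomeruli glomerulus labels to drop;
#'   defaults to [default_excluded_glomeruli()].
#' @return An `al_circuit`: list with `roster` (tibble, row order defines
#'   the matrix order) and `counts` (pre x post numeric matrix of synapse
#'   counts with neuron ids as dimnames).
#' @export
load_circuit <- function(roster, edges,
                         excluded_glomeruli = default_excluded_glomeruli()) {
  roster <- tibble::as_tibble(roster)
  stopifnot(all(c("id", "cell_class", "glomerulus") %in% names(roster)))
  roster$id <- as.character(roster$id)
  roster$glomerulus <- as.character(roster$glomerulus)
  roster$glomerulus[!is.na(roster$glomerulus) & roster$glomerulus == ""] <- NA
  if (!"polarity" %in% names(roster)) roster$polarity <- NA_real_
  roster$polarity <- suppressWarnings(as.numeric(roster$polarity))

  if (anyDuplicated(roster$id)) {
    abort(paste0("duplicate roster ids: ",
                 paste(unique(roster$id[duplicated(roster$id)]), collapse = ", ")))
  }
  bad_class <- setdiff(unique(roster$cell_class), c("ORN", "uPN", "mPN", "LN"))
  if (length(bad_class)) {
    abort(paste0("unknown cell_class: ", paste(bad_class, collapse = ", ")))
  }
  no_glom <- roster$cell_class %in% c("ORN", "uPN") & is.na(roster$glomerulus)
  if (any(no_glom)) {
    abort(paste0("ORNs/uPNs must carry a glomerulus label; missing for: ",
                 paste(head(roster$id[no_glom], 5), collapse = ", ")))
  }
  if (any(roster$cell_class == "ORN" & !is.na(roster$polarity) &
          roster$polarity != 1)) {
    abort("ORN polarity must be +1 (excitatory)")
  }
  roster$polarity[roster$cell_class == "ORN"] <- 1

  full_ids <- roster$id

  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("pre_id", "post_id", "synapse_count") %in% names(edges)))
  edges$pre_id <- as.character(edges$pre_id)
  edges$post_id <- as.character(edges$post_id)
  unknown <- setdiff(unique(c(edges$pre_id, edges$post_id)), full_ids)
  if (length(unknown)) {
    abort(paste0("edge endpoints absent from roster: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  sc <- suppressWarnings(as.numeric(edges$synapse_count))
  if (nrow(edges) && (any(!is.finite(sc)) || any(sc < 0))) {
    abort("synapse_count must be nonnegative numbers")
  }

  # drop non-olfactory glomeruli and every edge touching them
  keep <- is.na(roster$glomerulus) | !(roster$glomerulus %in% excluded_glomeruli)
  roster <- roster[keep, , drop = FALSE]

  counts <- matrix(0, nrow(roster), nrow(roster),
                   dimnames = list(roster$id, roster$id))
  use <- edges$pre_id %in% roster$id & edges$post_id %in% roster$id
  if (any(use)) {
    agg <- dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(pre = edges$pre_id[use], post = edges$post_id[use],
                       n = sc[use]),
        .data$pre, .data$post),
      n = sum(.data$n), .groups = "drop")
    counts[cbind(match(agg$pre, roster$id), match(agg$post, roster$id))] <- agg$n
  }
  structure(list(roster = roster, counts = counts,
                 excluded_glomeruli = excluded_glomeruli),
            class = "al_circuit")
}

#' @export
print.al_circuit <- function(x, ...) {
  cls <- table(x$roster$cell_class)
  cat("<al_circuit> ", nrow(x$roster), " neurons (",
      paste(names(cls), as.integer(cls), sep = ":", collapse = ", "),
      "), ", length(unique(stats::na.omit(x$roster$glomerulus))),
      " glomeruli, ", sum(x$counts > 0), " connections\n", sep = "")
  invisible(x)
}

#' Number of glomeruli innervated by each LN
#'
#' An LN counts a glomerulus as innervated when it has at least one synapse,
#' in either direction, with any glomerulus-labeled neuron (ORN or uPN) of
#' that glomerulus.
#'
#' @param circuit an [load_circuit()] result.
#' @return Tibble `id`, `n_glomeruli` with one row per LN.
#' @export
ln_innervation_counts <- function(circuit) {
  roster <- circuit$roster
  lns <- roster$id[roster$cell_class == "LN"]
  glom_of <- setNames(roster$glomerulus, roster$id)
  labeled <- roster$id[!is.na(roster$glomerulus)]
  n_glom <- vapply(lns, function(ln) {
    touched <- labeled[circuit$counts[ln, labeled] > 0 |
                       circuit$counts[labeled, ln] > 0]
    length(unique(glom_of[touched]))
  }, numeric(1))
  tibble::tibble(id = lns, n_glomeruli = as.numeric(n_glom))
}

#' Assign excitatory/inhibitory polarity to local neurons
#'
#' A fixed fraction of LNs is excitatory: `n_eLN = round(n_LN / (1 + ratio))`
#' (round half up) with the default eLN:iLN ratio of 1:5.4, which makes 31
#' of 197 LNs excitatory. Because excitatory LNs innervate the antennal lobe
#' broadly, the eLNs are drawn uniformly at random from the top half of LNs
#' ranked by number of innervated glomeruli (ties broken by id; an odd pool
#' keeps `ceiling(n_LN / 2)` candidates). All remaining LNs are inhibitory.
#'
#' @param circuit an `al_circuit`.
#' @param eln_iln_ratio ratio of iLNs to eLNs (default 5.4, i.e. 1:5.4).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return The circuit with LN polarities filled in (+1 eLN, -1 iLN).
#' @export
assign_ln_polarity <- function(circuit, eln_iln_ratio = 5.4, seed = 1) {
  if (eln_iln_ratio <= 0) abort("eln_iln_ratio must be positive")
  roster <- circuit$roster
  is_ln <- roster$cell_class == "LN"
  n_ln <- sum(is_ln)
  if (n_ln == 0) return(circuit)
  n_eln <- floor(n_ln / (1 + eln_iln_ratio) + 0.5)
  inn <- ln_innervation_counts(circuit)
  ord <- order(-inn$n_glomeruli, inn$id)
  top_half <- inn$id[ord][seq_len(ceiling(n_ln / 2))]
  if (n_eln > length(top_half)) {
    abort("eLN count exceeds the top-half candidate pool")
  }
  elns <- withr::with_seed(seed, sample(top_half, n_eln, replace = FALSE))
  roster$polarity[is_ln] <- -1
  roster$polarity[roster$id %in% elns] <- 1
  circuit$roster <- roster
  circuit
}

#' Assign polarity to projection neurons
#'
#' PNs with a neurotransmitter annotation take their annotated polarity
#' (cholinergic = excitatory, GABAergic = inhibitory). Unannotated mPNs are
#' assigned excitatory polarity independently with probability equal to the
#' cholinergic fraction among annotated mPNs; likewise for uPNs. The draw is
#' made once per roster, reproducibly given the seed, and is intended to be
#' frozen with the roster thereafter.
#'
#' @param circuit an `al_circuit`.
#' @param known data frame with columns `id`, `transmitter` (values
#'   `"cholinergic"` or `"GABAergic"`) covering a subset of PNs.
#' @param seed integer seed.
#' @param fractions optional named list/vector giving explicit cholinergic
#'   fractions for `mPN` and/or `uPN`, required when a class has
#'   unannotated members but no annotated ones.
#' @return The circuit with PN polarities filled in.
#' @export
assign_pn_polarity <- function(circuit, known = NULL, seed = 1,
                               fractions = NULL) {
  roster <- circuit$roster
  known <- if (is.null(known)) {
    tibble::tibble(id = character(0), transmitter = character(0))
  } else tibble::as_tibble(known)
  if (nrow(known)) {
    bad <- setdiff(unique(known$transmitter), c("cholinergic", "GABAergic"))
    if (length(bad)) abort(paste0("unknown transmitter: ", bad[1]))
  }
  pol_known <- setNames(ifelse(known$transmitter == "cholinergic", 1, -1),
                        as.character(known$id))
  withr::with_seed(seed, {
    for (cls in c("mPN", "uPN")) {
      rows <- which(roster$cell_class == cls)
      if (!length(rows)) next
      ann <- intersect(roster$id[rows], names(pol_known))
      roster$polarity[match(ann, roster$id)] <- pol_known[ann]
      unknown <- rows[is.na(roster$polarity[rows])]
      if (!length(unknown)) next
      frac <- if (!is.null(fractions) && !is.null(fractions[[cls]])) {
        fractions[[cls]]
      } else if (length(ann)) {
        mean(pol_known[ann] == 1)
      } else {
        abort(paste0("no annotated ", cls,
                     "s to estimate the cholinergic fraction; supply ",
                     "`fractions$", cls, "` explicitly"))
      }
      roster$polarity[unknown] <- ifelse(runif(length(unknown)) < frac, 1, -1)
    }
  })
  circuit$roster <- roster
  circuit
}

#' Build the signed, class-scaled synaptic weight matrix
#'
#' Effective weight from presynaptic neuron j to postsynaptic neuron i is
#' `polarity(j) * synapse_count(j, i) * a_class(i)`: rows of inhibitory
#' neurons are negative, and each column is scaled by the sensitivity
#' multiplier of the postsynaptic class (eLN and iLN columns use their
#' respective multipliers).
#'
#' @param circuit an `al_circuit` with all polarities assigned.
#' @param sensitivities a [sensitivity_config()].
#' @return An `al_weights`: the circuit plus `effective` (pre x post real
#'   matrix) and the sensitivity configuration.
#' @export
build_weight_matrix <- function(circuit, sensitivities = sensitivity_config()) {
  roster <- circuit$roster
  if (any(is.na(roster$polarity))) {
    abort(paste0("unassigned polarity for: ",
                 paste(head(roster$id[is.na(roster$polarity)], 5),
                       collapse = ", ")))
  }
  a_col <- numeric(nrow(roster))
  a_col[roster$cell_class == "ORN"] <- sensitivities$a_ORN
  a_col[roster$cell_class %in% c("uPN", "mPN")] <- sensitivities$a_PN
  is_ln <- roster$cell_class == "LN"
  a_col[is_ln & roster$polarity > 0] <- sensitivities$a_eLN
  a_col[is_ln & roster$polarity < 0] <- sensitivities$a_iLN
  effective <- (roster$polarity * circuit$counts) %*% diag(a_col, nrow(roster))
  # row-multiplication via recycling: polarity * counts recycles down columns
  dimnames(effective) <- dimnames(circuit$counts)
  structure(c(unclass(circuit),
              list(effective = effective, sensitivities = sensitivities)),
            class = c("al_weights", "al_circuit"))
}

#' Read roster / edge / volume tables from delimited text
#'
#' @param path file path.
#' @return A tibble in the corresponding schema: roster
#'   (`id`, `cell_class`, `glomerulus`, `polarity`; tab-separated), edges
#'   (`pre_id`, `post_id`, `synapse_count`; tab-separated) or volumes
#'   (`glomerulus`, `volume_um3`; CSV).
#' @export
read_roster <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), cell_class = readr::col_character(),
    glomerulus = readr::col_character(), polarity = readr::col_double()))
}

#' @rdname read_roster
#' @export
read_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pre_id = readr::col_character(), post_id = readr::col_character(),
    synapse_count = readr::col_double()))
}

#' @rdname read_roster
#' @export
read_volumes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    glomerulus = readr::col_character(), volume_um3 = readr::col_double()))
}

#' Write circuit tables
#'
#' @param circuit an `al_circuit`.
#' @param roster_path,edges_path output file paths (tab-separated text).
#' @return Invisibly, the circuit.
#' @export
write_circuit <- function(circuit, roster_path, edges_path) {
  readr::write_tsv(circuit$roster, roster_path)
  nz <- which(circuit$counts > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    pre_id = rownames(circuit$counts)[nz[, 1]],
    post_id = colnames(circuit$counts)[nz[, 2]],
    synapse_count = circuit$counts[nz])
  readr::write_tsv(edges, edges_path)
  invisible(circuit)
}

#' Convert a neuprint-style neuron/connection export to package schemas
#'
#' Optional, file-based convenience for users holding a hemibrain-style
#' export: a neuron CSV with `bodyId`, `type`-derived class and glomerulus
#' columns, and a connection CSV with `bodyId_pre`, `bodyId_post`, `weight`.
#' No network access is performed.
#'
#' @param neurons_csv CSV with columns `bodyId`, `cell_class`, `glomerulus`.
#' @param connections_csv CSV with columns `bodyId_pre`, `bodyId_post`,
#'   `weight`.
#' @return List with `roster` and `edges` tibbles in the package schemas.
#' @export
convert_neuprint_export <- function(neurons_csv, connections_csv) {
  neu <- readr::read_csv(neurons_csv, show_col_types = FALSE)
  con <- readr::read_csv(connections_csv, show_col_types = FALSE)
  roster <- tibble::tibble(
    id = as.character(neu$bodyId),
    cell_class = neu$cell_class,
    glomerulus = as.character(neu$glomerulus),
    polarity = NA_real_)
  edges <- tibble::tibble(
    pre_id = as.character(con$bodyId_pre),
    post_id = as.character(con$bodyId_post),
    synapse_count = con$weight)
  list(roster = roster, edges = edges)
}
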