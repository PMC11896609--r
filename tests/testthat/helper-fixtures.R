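# small deterministic fixtures shared across test files

toy_roster <- function() {
  tibble::tibble(
    id = c("orn1", "orn2", "pn1", "pn2", "ln1", "ln2"),
    cell_class = c("ORN", "ORN", "uPN", "uPN", "LN", "LN"),
    glomerulus = c("DA1", "DM2", "DA1", "DM2", NA, NA),
    polarity = c(1, 1, 1, 1, NA, NA))
}

toy_edges <- function() {
  tibble::tibble(
    pre_id = c("orn1", "orn2", "ln1", "orn1", "pn1"),
    post_id = c("pn1", "pn2", "pn1", "ln1", "ln2"),
    synapse_count = c(10, 5, 5, 20, 8))
}

toy_circuit <- function() {
  circ <- load_circuit(toy_roster(), toy_edges())
  circ$roster$polarity[circ$roster$cell_class == "LN"] <- c(1, -1)
  circ
}

toy_weights <- function(sens = sensitivity_config()) {
  build_weight_matrix(toy_circuit(), sens)
}

# an isolated single-PN circuit for closed-form membrane tests
single_pn_weights <- function() {
  roster <- tibble::tibble(id = "pn", cell_class = "uPN",
                           glomerulus = "DA1", polarity = 1)
  edges <- tibble::tibble(pre_id = character(0), post_id = character(0),
                          synapse_count = numeric(0))
  build_weight_matrix(load_circuit(roster, edges))
}

# memoized canonical fixture artifacts (expensive to simulate)
local_fixture_env <- new.env(parent = emptyenv())

cached_canonical <- function() {
  if (is.null(local_fixture_env$cf)) {
    local_fixture_env$cf <- canonical_fixture()
  }
  local_fixture_env$cf
}

cached_canonical_response <- function() {
  if (is.null(local_fixture_env$resp)) {
    cf <- cached_canonical()
    local_fixture_env$resp <- run_odor_panel(cf$weights, cf$door,
                                             cf$protocol, seed = 1)
  }
  local_fixture_env$resp
}
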