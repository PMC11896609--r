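test_that("loading removes non-olfactory glomeruli and aligns counts", {
  roster <- toy_roster()
  roster$glomerulus[roster$id == "orn2"] <- "VP2"
  circ <- load_circuit(roster, tibble::tibble(
    pre_id = "orn1", post_id = "pn1", synapse_count = 10))
  expect_false("orn2" %in% circ$roster$id)
  expect_true(all(c("orn1", "pn1", "ln1") %in% circ$roster$id))

  # empty edge table -> all-zero counts
  circ0 <- load_circuit(toy_roster(), toy_edges()[0, ])
  expect_true(all(circ0$counts == 0))

  # 3-neuron toy: counts land exactly where the edges say
  r3 <- toy_roster()[c(1, 3, 5), ]
  e3 <- tibble::tibble(pre_id = c("orn1", "ln1"),
                       post_id = c("pn1", "pn1"),
                       synapse_count = c(7, 3))
  c3 <- load_circuit(r3, e3)
  expect_equal(sum(c3$counts > 0), 2)
  expect_equal(c3$counts["orn1", "pn1"], 7)
  expect_equal(c3$counts["ln1", "pn1"], 3)
})

test_that("loading rejects malformed inputs by name", {
  r <- toy_roster()
  expect_error(load_circuit(rbind(r, r[1, ]), toy_edges()), "duplicate")
  bad <- rbind(toy_edges(),
               tibble::tibble(pre_id = "ghost", post_id = "pn1",
                              synapse_count = 1))
  expect_error(load_circuit(r, bad), "ghost")
})

test_that("eLN counts follow the rounded pool ratio", {
  mk_ln_circuit <- function(n_ln) {
    roster <- tibble::tibble(
      id = c("orn1", "pn1", sprintf("ln%03d", seq_len(n_ln))),
      cell_class = c("ORN", "uPN", rep("LN", n_ln)),
      glomerulus = c("DA1", "DA1", rep(NA, n_ln)),
      polarity = c(1, 1, rep(NA, n_ln)))
    edges <- tibble::tibble(
      pre_id = sprintf("ln%03d", seq_len(n_ln)), post_id = "pn1",
      synapse_count = 1)
    load_circuit(roster, edges)
  }
  c197 <- assign_ln_polarity(mk_ln_circuit(197), 5.4, seed = 1)
  expect_equal(sum(c197$roster$polarity == 1 &
                     c197$roster$cell_class == "LN"), 31)
  c64 <- assign_ln_polarity(mk_ln_circuit(64), 5.4, seed = 1)
  expect_equal(sum(c64$roster$polarity == 1 &
                     c64$roster$cell_class == "LN"), 10)
  # zero LNs is fine, bad ratio is not
  no_ln <- load_circuit(toy_roster()[1:4, ], toy_edges()[1:2, ])
  expect_identical(assign_ln_polarity(no_ln, 5.4), no_ln)
  expect_error(assign_ln_polarity(mk_ln_circuit(10), -1), "positive")
})

test_that("eLNs are drawn reproducibly from the broad half of LNs", {
  # 8 LNs with distinct innervation breadths: ln innervates `i` glomeruli
  gl <- sprintf("G%d", 1:8)
  roster <- dplyr::bind_rows(
    tibble::tibble(id = paste0("orn_", gl), cell_class = "ORN",
                   glomerulus = gl, polarity = 1),
    tibble::tibble(id = paste0("pn_", gl), cell_class = "uPN",
                   glomerulus = gl, polarity = 1),
    tibble::tibble(id = sprintf("ln%d", 1:8), cell_class = "LN",
                   glomerulus = NA, polarity = NA))
  edges <- purrr::map_dfr(1:8, function(i) {
    tibble::tibble(pre_id = sprintf("ln%d", i),
                   post_id = paste0("orn_", gl[seq_len(i)]),
                   synapse_count = 1)
  })
  circ <- load_circuit(roster, edges)
  inn <- ln_innervation_counts(circ)
  expect_equal(sort(inn$n_glomeruli), as.numeric(1:8))

  a <- assign_ln_polarity(circ, 3, seed = 99)   # 2 eLNs from top 4
  b <- assign_ln_polarity(circ, 3, seed = 99)
  expect_identical(a$roster, b$roster)

  # bottom-half LNs (fewest glomeruli) are never excitatory; top-half
  # frequencies match uniform sampling
  top_half <- inn$id[order(-inn$n_glomeruli, inn$id)][1:4]
  picks <- sapply(1:400, function(s) {
    r <- assign_ln_polarity(circ, 3, seed = s)$roster
    r$id[r$cell_class == "LN" & r$polarity == 1]
  })
  expect_true(all(picks %in% top_half))
  freq <- table(factor(picks, levels = top_half)) / 400
  p <- 2 / 4
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / 400)))
})

test_that("PN polarity uses annotations, then the cholinergic fraction", {
  circ <- load_circuit(toy_roster(), toy_edges())
  known <- tibble::tibble(id = c("pn1", "pn2"),
                          transmitter = c("cholinergic", "GABAergic"))
  out <- assign_pn_polarity(circ, known, seed = 1)
  expect_equal(out$roster$polarity[out$roster$id == "pn1"], 1)
  expect_equal(out$roster$polarity[out$roster$id == "pn2"], -1)
  # seed-independent when fully annotated
  out2 <- assign_pn_polarity(circ, known, seed = 77)
  expect_identical(out$roster, out2$roster)

  # cholinergic fraction 1 -> all unknowns excitatory
  out3 <- assign_pn_polarity(
    circ, tibble::tibble(id = "pn1", transmitter = "cholinergic"), seed = 1)
  expect_true(all(out3$roster$polarity[
    out3$roster$cell_class == "uPN"] == 1))

  # no annotations but unknowns present -> explicit fraction demanded
  blank <- circ
  blank$roster$polarity[blank$roster$cell_class == "uPN"] <- NA
  expect_error(assign_pn_polarity(blank, NULL, seed = 1), "fraction")
  out4 <- assign_pn_polarity(blank, NULL, seed = 1,
                             fractions = list(uPN = 1, mPN = 1))
  expect_true(all(out4$roster$polarity[
    out4$roster$cell_class == "uPN"] == 1))
})

test_that("random PN polarity matches the binomial law at scale", {
  n <- 10000
  roster <- tibble::tibble(
    id = c("annot1", "annot2", sprintf("m%05d", seq_len(n))),
    cell_class = "mPN", glomerulus = NA_character_,
    polarity = NA_real_)
  circ <- structure(list(roster = roster,
                         counts = matrix(0, 0, 0),
                         excluded_glomeruli = character(0)),
                    class = "al_circuit")
  known <- tibble::tibble(id = c("annot1", "annot2"),
                          transmitter = c("cholinergic", "GABAergic"))
  out <- assign_pn_polarity(circ, known, seed = 42)  # fraction = 0.5
  n_exc <- sum(out$roster$polarity == 1) - 1  # minus the annotated one
  expect_lt(abs(n_exc - n / 2), 3 * sqrt(n * 0.25))
})

test_that("effective weights obey the sign and class-scaling rules", {
  w <- toy_weights()  # ln1 excitatory, ln2 inhibitory
  # ORN -> PN, 10 synapses, a_PN = 0.4 -> +4
  expect_equal(w$effective["orn1", "pn1"], 4)
  # post-LN columns use the eLN/iLN multiplier of the *postsynaptic* LN
  expect_equal(w$effective["orn1", "ln1"], 20 * 0.04)
  expect_equal(w$effective["pn1", "ln2"], 8 * 0.02)

  # inhibitory presynaptic row is never positive
  circ <- toy_circuit()
  circ$counts["ln2", "pn1"] <- 5
  w2 <- build_weight_matrix(circ)
  expect_equal(w2$effective["ln2", "pn1"], -2)
  expect_true(all(w2$effective["ln2", ] <= 0))

  # isolated neuron: zero row and column
  roster <- rbind(toy_roster(),
                  tibble::tibble(id = "lone", cell_class = "uPN",
                                 glomerulus = "DL5", polarity = 1))
  circ3 <- load_circuit(roster, toy_edges())
  circ3$roster$polarity[circ3$roster$cell_class == "LN"] <- -1
  w3 <- build_weight_matrix(circ3)
  expect_true(all(w3$effective["lone", ] == 0))
  expect_true(all(w3$effective[, "lone"] == 0))

  expect_error(build_weight_matrix(load_circuit(toy_roster(), toy_edges())),
               "polarity")
})

test_that("weights reduce to raw counts in the identity limit", {
  circ <- toy_circuit()
  circ$roster$polarity[] <- 1
  w <- build_weight_matrix(circ, sensitivity_config(1, 1, 1, 1))
  expect_equal(w$effective, circ$counts)
  # sparsity pattern always matches the raw counts
  w2 <- toy_weights()
  expect_identical(w2$effective != 0, circ$counts != 0)
})

test_that("column scaling commutes with row sign flipping", {
  circ <- toy_circuit()
  sens <- sensitivity_config(0.3, 0.07, 0.011, 0.9)
  w <- build_weight_matrix(circ, sens)
  # manual order: scale columns first, then flip inhibitory rows
  a_col <- c(0.3, 0.3, 0.9, 0.9, 0.07, 0.011)
  scaled <- sweep(circ$counts, 2, a_col, `*`)
  flipped <- circ$roster$polarity * scaled
  dimnames(flipped) <- dimnames(circ$counts)
  expect_equal(w$effective, flipped)
})

test_that("circuit tables round-trip through the delimited schemas", {
  circ <- toy_circuit()
  rp <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_circuit(circ, rp, ep)
  re <- load_circuit(read_roster(rp), read_edges(ep))
  expect_equal(re$counts, circ$counts)
  expect_equal(re$roster$polarity, circ$roster$polarity)
})
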