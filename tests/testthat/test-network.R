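test_that("packaged reduced model loads with a validated structure", {
  net <- reduced_model()
  expect_s3_class(net, "reaction_network")
  expect_identical(nrow(net$species), 37L)
  expect_identical(nrow(net$reactions), 58L)
  # the NPC autoregulation block keeps the published indexing
  expect_true(all(137:144 %in% net$reactions$index))
  blk <- net$reactions[net$reactions$index %in% 137:144, ]
  expect_true(all(blk$tag == "phosphorylation"))
  expect_true(all(net$reactions$rate_value >= 0))
  expect_true(all(net$species$initial_count >= 0))
})

test_that("two-species toy gives the textbook stoichiometric matrix", {
  net <- ab_network(kf = 1, kr = 1)
  expect_identical(unname(net$S), matrix(c(-1L, 1L, 1L, -1L), 2, 2))
})

test_that("schema violations are rejected with informative errors", {
  sp <- list(toy_species("A", 10), toy_species("B", 0))
  expect_error(build_network(toy_spec(sp,
    list(toy_rxn(1, "A", "Z", 1)))), "unknown species")
  expect_error(build_network(toy_spec(sp,
    list(toy_rxn(1, "A", "B", -2)))), "non-negative")
  expect_error(build_network(toy_spec(
    list(toy_species("A", 10), toy_species("A", 3)),
    list(toy_rxn(1, "A", "A", 1)))), "duplicate species")
  expect_error(build_network(toy_spec(
    list(toy_species("A", -5), toy_species("B", 0)),
    list(toy_rxn(1, "A", "B", 1)))), "negative initial_count")
  expect_error(build_network(toy_spec(sp, list(
    toy_rxn(1, "A", "B", 1), toy_rxn(1, "B", "A", 1)))),
    "duplicate reaction index")
  expect_error(build_network(toy_spec(sp,
    list(toy_rxn(1, c("A", "A", "B"), "B", 1)))), "order > 2")
})

test_that("NPC-regulation knockout zeroes exactly reactions 137-144", {
  net <- reduced_model()
  ko <- knockout_npc_regulation(net)
  blk <- ko$reactions$index %in% 137:144
  expect_true(all(ko$reactions$rate_value[blk] == 0))
  expect_identical(ko$reactions$rate_value[!blk],
                   net$reactions$rate_value[!blk])
  expect_identical(knockout_npc_regulation(ko)$reactions$rate_value,
                   ko$reactions$rate_value)
  expect_error(knockout_npc_regulation(ab_network()), "137")
})

test_that("mass-action rates match a per-reaction oracle", {
  net <- ab_network(a0 = 10, kf = 2)
  expect_equal(unname(reaction_rates(net, c(10, 0))), 20)

  net5 <- five_rxn_network()
  state <- c(A = 10, B = 7, C = 3, D = 5)
  # independent oracle: evaluate each law by hand
  det <- c(2.0 * 10, 0.3 * 10 * 7, 0.1 * 3^2 / 2, 0.7 * 5, 0)
  sto <- c(2.0 * 10, 0.3 * 10 * 7, 0.1 * 3 * 2 / 2, 0.7 * 5, 0)
  expect_equal(unname(reaction_rates(net5, state, "deterministic")), det)
  expect_equal(unname(reaction_rates(net5, state, "stochastic")), sto)
  expect_equal(unname(reaction_rates(net5, state)[5]), 0)

  # randomized states against the same oracle
  set.seed(11)
  for (i in 1:20) {
    s <- sample(0:50, 4, replace = TRUE)
    oracle <- c(2 * s[1], 0.3 * s[1] * s[2], 0.1 * s[3] * (s[3] - 1) / 2,
                0.7 * s[4], 0)
    expect_equal(unname(reaction_rates(net5, s, "stochastic")), oracle)
  }
  expect_error(reaction_rates(net5, c(-1, 0, 0, 0)), "negative")
})

test_that("conserved moieties include total NPC, ERK and receptor pools", {
  net <- reduced_model()
  sp <- net$species$id
  w_npc <- setNames(as.numeric(sp %in% c("NPC", "pNPC", "ppNPC",
                                         "ppERKn_NPC", "ppERKn_pNPC")), sp)
  w_erk <- setNames(as.numeric(sp %in% c("ERK_cyt", "pERK_cyt", "ppERK_cyt",
                                         "ERK_nuc", "pERK_nuc", "ppERK_nuc",
                                         "ppERKn_NPC", "ppERKn_pNPC")), sp)
  w_egfr <- setNames(rep(0, length(sp)), sp)
  w_egfr[c("EGFR", "bEGFR")] <- 1
  w_egfr[c("pEGFR", "pEGFR_Shc", "pEGFR_Shc_Grb2", "pEGFR_Shc_Grb2_Sos",
           "pEGFR_Grb2", "pEGFR_Grb2_Sos")] <- 2   # dimer carries 2 receptors
  expect_true(is_conserved(net, w_npc))
  expect_true(is_conserved(net, w_erk))
  expect_true(is_conserved(net, w_egfr))
  expect_false(is_conserved(net, setNames(as.numeric(sp == "ERK_cyt"), sp)))

  # the computed left null space spans the NPC moiety:
  # projecting w_npc onto the basis reproduces it
  basis <- conserved_moieties(net)
  proj <- basis %*% crossprod(basis, w_npc[sp])
  expect_equal(as.numeric(proj), unname(w_npc[sp]), tolerance = 1e-8)
})

test_that("load -> serialize -> load round-trips to an identical network", {
  net <- reduced_model()
  tmp <- tempfile(fileext = ".json")
  write_network(net, tmp)
  net2 <- load_network(tmp)
  expect_equal(net2$species, net$species)
  expect_equal(net2$reactions$rate_value, net$reactions$rate_value)
  expect_identical(net2$S, net$S)
  expect_identical(net2$r1, net$r1)
  expect_equal(net2$compartments, net$compartments)
})
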