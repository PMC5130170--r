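# Small networks built in code for machinery tests.

toy_spec <- function(species, reactions, name = "toy") {
  list(name = name,
       compartments = list(cytoplasm = 1e-12),
       species = species, reactions = reactions)
}
toy_species <- function(id, count, ...) {
  c(list(id = id, compartment = "cytoplasm", initial_count = count), list(...))
}
toy_rxn <- function(index, reactants, products, k,
                    tag = "phosphorylation", coefs = NULL, pcoefs = NULL) {
  side <- function(ids, cf) {
    if (is.null(cf)) cf <- rep(1, length(ids))
    mapply(function(s, co) list(species = s, coef = co), ids, cf,
           SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  list(index = index, reactants = side(reactants, coefs),
       products = side(products, pcoefs),
       rate_name = paste0("k", index), rate_value = k, tag = tag)
}

# A <-> B closed two-species exchange
ab_network <- function(a0 = 100, b0 = 0, kf = 0.05, kr = 0) {
  rx <- list(toy_rxn(1, "A", "B", kf))
  if (kr > 0) rx <- c(rx, list(toy_rxn(2, "B", "A", kr)))
  build_network(toy_spec(
    list(toy_species("A", a0), toy_species("B", b0)), rx))
}

# birth-death: 0 -> A at rate lambda, A -> 0 at rate mu per molecule
birth_death_network <- function(a0 = 0, lambda = 20, mu = 1) {
  build_network(toy_spec(list(toy_species("A", a0)), list(
    toy_rxn(1, character(0), "A", lambda),
    toy_rxn(2, "A", character(0), mu, tag = "degradation"))))
}

# five mixed-order reactions for rate-law oracle checks
five_rxn_network <- function(counts = c(A = 10, B = 7, C = 3, D = 5)) {
  build_network(toy_spec(
    list(toy_species("A", counts["A"]), toy_species("B", counts["B"]),
         toy_species("C", counts["C"]), toy_species("D", counts["D"])),
    list(
      toy_rxn(1, "A", "B", 2.0),                                  # uni
      toy_rxn(2, c("A", "B"), "C", 0.3, tag = "association"),     # bi
      toy_rxn(3, c("C", "C"), "D", 0.1, tag = "association"),     # homodimer
      toy_rxn(4, "D", c("C", "C"), 0.7, tag = "dissociation"),
      toy_rxn(5, "B", "A", 0.0, tag = "dephosphorylation")        # zero rate
    )))
}

# nonlinear 3-species toy with ~1000-molecule counts for ODE-SSA agreement
cascade_toy_network <- function(scale = 1) {
  build_network(toy_spec(
    list(toy_species("S", round(1000 * scale)),
         toy_species("E", round(1200 * scale)),
         toy_species("P", 0)),
    list(
      toy_rxn(1, c("S", "E"), c("P", "E"), 2e-5 / scale),
      toy_rxn(2, "P", "S", 0.01, tag = "dephosphorylation"))))
}

noiseless_hill_curve <- function(n = 2, K = 1, rmin = 0, rmax = 1,
                                 doses = c(0, 10^seq(-2, 2, length.out = 20))) {
  list(doses = doses,
       responses = rmin + (rmax - rmin) * ifelse(doses > 0,
         doses^n / (K^n + doses^n), 0))
}

reduced_model <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- load_network(reduced_egf_model_path())
    net
  }
})
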