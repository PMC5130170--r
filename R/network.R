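#' Load a mass-action reaction network from a model-definition file
#'
#' Reads a JSON model definition with three sections in the tabular layout
#' commonly used to distribute kinetic models in this field: a species
#' table (id, compartment, initial molecule count, optional protein-group and
#' observable annotations), a reaction table (index, reactants, products,
#' named rate constant, tag), and compartment volumes. All state is in
#' molecule counts; bimolecular rate constants are already volume-scaled
#' (per molecule per second), so compartment volumes are metadata only.
#'
#' @param path Path to a model-definition JSON file.
#' @return A `reaction_network` object: list with `species` (data.frame),
#'   `reactions` (data.frame with list-columns `reactants`/`products`),
#'   `compartments`, the integer stoichiometric matrix `S` (species x
#'   reactions), internal reactant-slot encodings, and EGF-dose metadata.
#' @export
load_network <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  build_network(spec)
}

#' Construct a reaction network from an in-memory definition list
#'
#' Same schema as [load_network()] but takes the parsed list directly; used
#' to build small test networks programmatically.
#'
#' @param spec A list with elements `species`, `reactions`, `compartments`,
#'   and optionally `name`, `egf_species`, `egf_molecules_per_ngml`.
#' @return A `reaction_network`.
#' @export
build_network <- function(spec) {
  sp <- do.call(rbind, lapply(spec$species, function(s) {
    data.frame(
      id            = as.character(s$id),
      compartment   = as.character(s$compartment),
      initial_count = as.numeric(s$initial_count),
      protein       = if (is.null(s$protein)) NA_character_ else as.character(s$protein),
      perk_weight   = if (is.null(s$perk_weight)) 0 else as.numeric(s$perk_weight),
      nerk_weight   = if (is.null(s$nerk_weight)) 0 else as.numeric(s$nerk_weight),
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(sp$id))
    stop("duplicate species id(s): ",
         paste(unique(sp$id[duplicated(sp$id)]), collapse = ", "))
  if (any(sp$initial_count < 0))
    stop("negative initial_count for: ",
         paste(sp$id[sp$initial_count < 0], collapse = ", "))
  if (any(sp$initial_count != round(sp$initial_count)))
    stop("initial counts must be integers (molecule numbers)")
  if (!all(sp$compartment %in% c("membrane", "cytoplasm", "nucleus")))
    stop("compartment must be one of membrane/cytoplasm/nucleus")

  tags <- c("association", "dissociation", "phosphorylation",
            "dephosphorylation", "degradation", "translocation")
  parse_side <- function(side) {
    if (is.null(side) || length(side) == 0)
      return(data.frame(species = character(0), coef = numeric(0)))
    do.call(rbind, lapply(side, function(p)
      data.frame(species = as.character(p$species),
                 coef = if (is.null(p$coef)) 1 else as.numeric(p$coef),
                 stringsAsFactors = FALSE)))
  }
  rx_list <- lapply(spec$reactions, function(r) {
    list(index = as.integer(r$index),
         reactants = parse_side(r$reactants),
         products = parse_side(r$products),
         rate_name = as.character(r$rate_name),
         rate_value = as.numeric(r$rate_value),
         tag = as.character(r$tag))
  })
  idx <- vapply(rx_list, `[[`, integer(1), "index")
  if (anyDuplicated(idx))
    stop("duplicate reaction index(es): ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  rx_list <- rx_list[order(idx)]

  n <- nrow(sp); m <- length(rx_list)
  S <- matrix(0L, n, m, dimnames = list(sp$id, NULL))
  r1 <- integer(m); r2 <- integer(m)
  for (j in seq_len(m)) {
    r <- rx_list[[j]]
    for (side in c("reactants", "products")) {
      tab <- r[[side]]
      unknown <- setdiff(tab$species, sp$id)
      if (length(unknown))
        stop("reaction ", r$index, " references unknown species: ",
             paste(unknown, collapse = ", "))
      if (nrow(tab) && any(tab$coef <= 0 | tab$coef != round(tab$coef)))
        stop("reaction ", r$index, ": stoichiometric coefficients must be positive integers")
    }
    if (is.na(r$rate_value) || r$rate_value < 0)
      stop("reaction ", r$index, ": rate constant must be non-negative")
    if (!r$tag %in% tags)
      stop("reaction ", r$index, ": unknown tag '", r$tag, "'")
    order_j <- sum(r$reactants$coef)
    if (order_j > 2)
      stop("reaction ", r$index, ": order > 2 not allowed under mass action here")
    # reactant slots for the simulation core (-1 = empty, 0-based indices)
    slots <- rep(match(r$reactants$species, sp$id), times = r$reactants$coef)
    r1[j] <- if (length(slots) >= 1) slots[1] - 1L else -1L
    r2[j] <- if (length(slots) >= 2) slots[2] - 1L else -1L
    for (i in seq_len(nrow(r$reactants)))
      S[r$reactants$species[i], j] <- S[r$reactants$species[i], j] - as.integer(r$reactants$coef[i])
    for (i in seq_len(nrow(r$products)))
      S[r$products$species[i], j] <- S[r$products$species[i], j] + as.integer(r$products$coef[i])
  }

  reactions <- data.frame(
    index = vapply(rx_list, `[[`, integer(1), "index"),
    rate_name = vapply(rx_list, `[[`, character(1), "rate_name"),
    rate_value = vapply(rx_list, `[[`, numeric(1), "rate_value"),
    tag = vapply(rx_list, `[[`, character(1), "tag"),
    stringsAsFactors = FALSE
  )
  reactions$reactants <- lapply(rx_list, `[[`, "reactants")
  reactions$products <- lapply(rx_list, `[[`, "products")
  colnames(S) <- as.character(reactions$index)

  net <- structure(list(
    name = if (is.null(spec$name)) "unnamed" else spec$name,
    species = sp,
    reactions = reactions,
    compartments = spec$compartments,
    S = S, r1 = r1, r2 = r2,
    egf_species = if (is.null(spec$egf_species)) NA_character_ else spec$egf_species,
    egf_molecules_per_ngml = if (is.null(spec$egf_molecules_per_ngml)) NA_real_
                             else as.numeric(spec$egf_molecules_per_ngml)
  ), class = "reaction_network")
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network '", x$name, "': ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Serialize a reaction network back to the model-definition JSON schema
#'
#' @param network A `reaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly. `load_network(write_network(net, p))` recovers
#'   an identical network.
#' @export
write_network <- function(network, path) {
  sp <- network$species
  species <- lapply(seq_len(nrow(sp)), function(i) {
    s <- list(id = sp$id[i], compartment = sp$compartment[i],
              initial_count = sp$initial_count[i])
    if (!is.na(sp$protein[i])) s$protein <- sp$protein[i]
    if (sp$perk_weight[i] != 0) s$perk_weight <- sp$perk_weight[i]
    if (sp$nerk_weight[i] != 0) s$nerk_weight <- sp$nerk_weight[i]
    s
  })
  rx <- network$reactions
  side_list <- function(tab) lapply(seq_len(nrow(tab)), function(i)
    list(species = tab$species[i], coef = tab$coef[i]))
  reactions <- lapply(seq_len(nrow(rx)), function(j) {
    list(index = rx$index[j],
         reactants = side_list(rx$reactants[[j]]),
         products = side_list(rx$products[[j]]),
         rate_name = rx$rate_name[j],
         rate_value = rx$rate_value[j],
         tag = rx$tag[j])
  })
  out <- list(name = network$name,
              compartments = network$compartments,
              egf_species = network$egf_species,
              egf_molecules_per_ngml = network$egf_molecules_per_ngml,
              species = species, reactions = reactions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Path to the packaged reduced EGF-ERK-NPC model
#'
#' A reduced, calibrated EGFR to Ras to Raf to MEK to ERK cascade with
#' explicit two-step ERK-mediated phosphorylation of the nuclear pore complex
#' (NPC) and state-dependent nucleocytoplasmic shuttling of ERK. This is not
#' a transcription of the published 78-species/150-reaction model (whose
#' parameter tables are distributed as spreadsheets); it is a smaller network
#' with the same architecture, calibrated so that the pathway's qualitative
#' behaviors hold: transient pERK/nERK dynamics, graded pERK vs switch-like
#' nERK dose response, loss of switching when the NPC-phosphorylation block
#' (reactions 137-144) is zeroed, and a basal intrinsic fold-change CV of
#' about 0.35%.
#'
#' @return Path to the JSON model file.
#' @export
reduced_egf_model_path <- function() {
  system.file("extdata", "egf_erk_npc_reduced.json", package = "erknoise",
              mustWork = TRUE)
}

#' Zero out ERK-mediated NPC phosphorylation (reactions 137-144)
#'
#' Returns a copy of the network in which the rate constants of the
#' NPC-regulation block are set to zero, removing the negative autoregulation
#' of nuclear ERK; all other parameters are untouched. Idempotent.
#'
#' @param network A `reaction_network` containing reactions indexed 137-144.
#' @param indices Reaction indices to zero (default `137:144`).
#' @return A modified copy of `network` with variant attribute "NPC-knockout".
#' @export
knockout_npc_regulation <- function(network, indices = 137:144) {
  pos <- match(indices, network$reactions$index)
  if (anyNA(pos))
    stop("network lacks reaction index(es): ",
         paste(indices[is.na(pos)], collapse = ", "))
  network$reactions$rate_value[pos] <- 0
  network$name <- paste0(network$name, " [NPC-knockout]")
  attr(network, "variant") <- "NPC-knockout"
  network
}

#' Evaluate per-reaction mass-action rates at a state
#'
#' Unimolecular rate is k*n_A; heterobimolecular k*n_A*n_B (k already
#' volume-scaled); homodimerization uses n(n-1)/2 in stochastic propensity
#' mode and n^2/2 deterministically.
#'
#' @param network A `reaction_network`.
#' @param state Numeric vector of species counts (network species order).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @return Numeric vector of per-reaction rates (1/s), in reaction order.
#' @export
reaction_rates <- function(network, state,
                           mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  if (length(state) != nrow(network$species))
    stop("state length must equal number of species")
  if (any(state < 0)) stop("negative species count")
  r <- .cpp_propensities(as.numeric(state), network$reactions$rate_value,
                         network$r1, network$r2, mode == "stochastic")
  names(r) <- as.character(network$reactions$index)
  r
}

#' Conserved moieties of a reaction network
#'
#' Computes an orthonormal basis of the left null space of the stoichiometric
#' matrix via singular-value decomposition. Any vector `c` in this space
#' satisfies `c %*% state = const` along every trajectory of the network.
#'
#' @param network A `reaction_network`.
#' @param tol Singular values below `tol * max(sv)` count as zero.
#' @return Matrix with one conserved vector per column (rownames = species).
#' @export
conserved_moieties <- function(network, tol = 1e-10) {
  S <- network$S
  n <- nrow(S)
  sv <- svd(S, nu = n)
  rank <- sum(sv$d > tol * max(sv$d, 1))
  basis <- sv$u[, seq_len(n) > rank, drop = FALSE]
  rownames(basis) <- network$species$id
  basis
}

#' Test whether a weight vector is conserved by the network
#'
#' @param network A `reaction_network`.
#' @param weights Named or ordered numeric vector over species.
#' @param tol Absolute tolerance on `t(w) %*% S`.
#' @return TRUE if the weighted total is invariant under every reaction.
#' @export
is_conserved <- function(network, weights, tol = 1e-9) {
  if (!is.null(names(weights)))
    weights <- weights[network$species$id]
  all(abs(as.numeric(crossprod(weights, network$S))) < tol)
}

#' Initial molecule-count state for a given EGF dose
#'
#' @param network A `reaction_network` with EGF metadata.
#' @param egf_dose EGF concentration in ng/mL (>= 0). Converted to a molecule
#'   count via the model's `egf_molecules_per_ngml` factor; EGF is catalytic
#'   in the packaged model (no ligand depletion).
#' @param base_counts Optional replacement for the nominal initial counts
#'   (e.g. one row of [sample_initials()]).
#' @return Named numeric state vector.
#' @export
initial_state <- function(network, egf_dose = 0, base_counts = NULL) {
  if (egf_dose < 0) stop("egf_dose must be >= 0")
  x <- if (is.null(base_counts)) network$species$initial_count else as.numeric(base_counts)
  names(x) <- network$species$id
  if (!is.na(network$egf_species)) {
    x[network$egf_species] <- egf_dose * network$egf_molecules_per_ngml
  } else if (egf_dose > 0) {
    stop("network has no EGF species; cannot apply a dose")
  }
  x
}
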