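#' Simplified HOG pathway model
#'
#' A reconstruction of the two-module high-osmolarity-glycerol (HOG)
#' signalling scheme used throughout the package documentation. The
#' phosphotransfer module — Sln1 autophosphorylation requiring turgor,
#' then phosphotransfer Sln1 -> Ypd1 -> Ssk1 — is active when turgor is
#' sufficient; phosphorylated Ssk1 blocks the Ssk1--Ssk2 interaction and
#' thereby keeps the MAP kinase module (Ssk2 -> Pbs2 -> Hog1 -> Hot1)
#' inactive. Loss of turgor drains the phosphorelay, releases the
#' inhibition, and the kinase cascade fires; the pathway output feeds back
#' to restore turgor, closing a negative feedback loop that gives a
#' cyclic attractor under free-running synchronous update. `[Turgor]` is
#' both the input sensed by Sln1 and the fed-back output, so clamping it
#' opens the loop.
#'
#' The phosphatase component Ptc1 provides unregulated dephosphorylation
#' of the cascade's phosphosites; without consuming reactions the
#' irreversibly produced phosphorylation states would latch and the
#' feedback could not cycle (the same repair the full MAPK case study
#' needs, cf. [add_reverse_reactions()]).
#'
#' @return an `rxncon_model`.
#' @examples
#' m <- simplified_hog()
#' glance(m)
#' @export
simplified_hog <- function() {
  parse_quick(c(
    "Sln1_AP_Sln1; ! [Turgor]",
    "Sln1_PT_Ypd1; ! Sln1-{P}",
    "Ypd1_PT_Ssk1; ! Ypd1-{P}",
    "Ssk1_ppi_Ssk2; x Ssk1-{P}",
    "Ssk2_P+_Pbs2; ! Ssk1--Ssk2",
    "Pbs2_P+_Hog1; ! Pbs2-{P}",
    "Hog1_P+_Hot1; ! Hog1-{P}",
    "Ptc1_P-_Ssk1",
    "Ptc1_P-_Pbs2",
    "Ptc1_P-_Hog1",
    "Ptc1_P-_Hot1",
    "[Turgor]; ! Hot1-{P}"
  ))
}

#' Pheromone/osmostress crosstalk toy model
#'
#' Two MAP kinase routes sharing the kinases Ste20 and Ste11: the mating
#' (MAT) route is triggered by pheromone (`[Pher]`) and raises
#' `[MATING]`; the osmostress (HOG) route is triggered by `[Osmo]` and
#' raises `[TURGOR]`. Signal identity is carried by *where* Ste11 is
#' recruited — the Ste5 scaffold (pheromone) versus the Sho1 membrane
#' branch (osmostress) — while Ste20 phosphorylates Ste11 in either
#' context. Each downstream phosphorylation therefore requires both
#' Ste11-{P} and the route-specific recruitment bond, which is exactly
#' the contextual information a component-level collapse loses: the
#' bipartite model activates only the cognate output under a single
#' input, whereas [build_classical()] of the same network activates both.
#'
#' The contingency set (e.g. that Ste20's phosphorylation of Ste11 is
#' itself unregulated, with route gating placed on the downstream
#' kinase reactions) is a reconstruction pinned to reproduce these
#' simulation outcomes.
#'
#' @return an `rxncon_model`.
#' @examples
#' bm <- build_bipartite(toy_crosstalk())
#' at_attractor(run_sync(bm, default_init(bm, "[Pher]")))[c("[MATING]", "[TURGOR]")]
#' @export
toy_crosstalk <- function() {
  parse_quick(c(
    "Ste5_ppi_Ste11; ! [Pher]",
    "Sho1_ppi_Ste11; ! [Osmo]",
    "Ste20_P+_Ste11",
    "Ste11_P+_Ste7; ! Ste11-{P}; ! Ste5--Ste11",
    "Ste7_P+_Fus3; ! Ste7-{P}",
    "Fus3_P+_Ste12; ! Fus3-{P}",
    "Ste11_P+_Pbs2; ! Ste11-{P}; ! Sho1--Ste11",
    "Pbs2_P+_Hog1; ! Pbs2-{P}",
    "[MATING]; ! Ste12-{P}",
    "[TURGOR]; ! Hog1-{P}"
  ))
}

#' Random reaction-contingency model generator
#'
#' Draws a valid model for property testing: components `C1..Cn`,
#' reactions with types sampled from the registry's binding and
#' (de)phosphorylation chemistry, and inhibitory/requiring contingencies
#' whose effectors are states actually produced by the sampled reactions
#' (so generated models validate cleanly up to `irreversible_only`
#' notes). Reproducible per seed.
#'
#' @param n_components number of components.
#' @param n_reactions number of reactions to attempt (duplicates are
#'   merged, so the realised count can be lower).
#' @param contingency_density expected number of contingencies per
#'   reaction (each reaction receives one with this probability).
#' @param seed RNG seed.
#' @param registry reaction-type registry.
#' @return an `rxncon_model`.
#' @export
random_model <- function(n_components = 6L, n_reactions = 8L,
                         contingency_density = 0.4, seed = 1L,
                         registry = reaction_types()) {
  stopifnot(n_components >= 2L)
  comps <- paste0("C", seq_len(n_components))
  types <- c("ppi", "P+", "P-", "AP", "PT")
  if (n_reactions == 0L) return(rxncon(registry = registry))
  withr::with_seed(seed, {
    rx <- tibble::tibble(
      a = sample(comps, n_reactions, replace = TRUE),
      type = sample(types, n_reactions, replace = TRUE),
      b = sample(comps, n_reactions, replace = TRUE)
    )
    rx$a[rx$type == "AP"] -> rx$b[rx$type == "AP"]   # autoreactions
    rx$b[rx$type == "PT" & rx$a == rx$b] <-
      sample(comps, sum(rx$type == "PT" & rx$a == rx$b), replace = TRUE)
    rx <- rx[!(rx$type == "PT" & rx$a == rx$b), ]
    m0 <- rxncon(reactions = rx, registry = registry)
    produced <- unique(reaction_state_table(m0)$state[
      reaction_state_table(m0)$effect == "produce"])
    cg <- NULL
    if (length(produced)) {
      take <- stats::runif(nrow(m0$reactions)) < contingency_density
      if (any(take)) {
        cg <- tibble::tibble(
          target = m0$reactions$id[take],
          sign = sample(c("!", "x"), sum(take), replace = TRUE),
          effector = sample(produced, sum(take), replace = TRUE)
        )
      }
    }
    rxncon(reactions = rx, contingencies = cg, registry = registry)
  })
}

#' Add hypothetical reverse reactions
#'
#' For every modification state that is produced but never consumed, adds
#' an unregulated consuming reaction catalysed by a synthetic component —
#' `ukPPase` ("unknown phosphatase") for phosphorylation states, and an
#' analogous `uk<Label>ase` for other modification labels with a
#' registered consuming type. This is the standard repair for networks
#' whose curation lacks the reverse chemistry: irreversibly produced
#' states latch, so pathways cannot switch off again. Added reactions
#' carry no contingencies (no assumptions on their regulation). The
#' operation is idempotent.
#'
#' @param model an `rxncon_model`.
#' @return `list(model = <repaired rxncon_model>, added = <tibble of
#'   added reactions>)`.
#' @examples
#' rep <- add_reverse_reactions(parse_quick("A_P+_B"))
#' rep$added$id   # "ukPPase_P-_B"
#' @export
add_reverse_reactions <- function(model) {
  stopifnot(inherits(model, "rxncon_model"))
  rst <- reaction_state_table(model)
  produced <- unique(rst$state[rst$effect == "produce"])
  consumed <- unique(rst$state[rst$effect == "consume"])
  todo <- setdiff(produced, consumed)
  todo <- todo[vapply(todo, state_kind, character(1)) == "modification"]
  rows <- list()
  for (s in todo) {
    label <- sub("^.*-\\{(.*)\\}$", "\\1", s)
    comp <- state_components(s)
    # find a registered type consuming B-{label} and producing nothing
    reg <- model$registry
    hit <- which(vapply(seq_len(nrow(reg)), function(i) {
      cons <- split_templates(reg$consumes[i])
      length(split_templates(reg$produces[i])) == 0L &&
        any(cons == paste0("B-{", label, "}"))
    }, logical(1)))
    if (!length(hit)) next
    enzyme <- if (label == "P") "ukPPase" else paste0("uk", label, "ase")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      a = enzyme, type = reg$symbol[hit[1]], b = comp)
  }
  if (!length(rows)) {
    return(list(model = model,
                added = tibble::tibble(id = character(), a = character(),
                                       type = character(), b = character())))
  }
  added <- dplyr::bind_rows(rows)
  added$id <- paste(added$a, added$type, added$b, sep = "_")
  m2 <- rxncon(reactions = dplyr::bind_rows(model$reactions,
                                            added[, c("a", "type", "b")]),
               contingencies = model$contingencies,
               bool_nodes = model$bool_nodes,
               registry = model$registry)
  list(model = m2, added = added[, c("id", "a", "type", "b")])
}

#' Load the full yeast MAP kinase case-study model
#'
#' Reads a user-supplied tabular export of the curated yeast MAPK
#' reaction and contingency lists (tab- or comma-separated; see
#' [load_tabular()] for the column roles). The tables are not bundled
#' with this package and are never downloaded automatically; obtain them
#' from the original network distribution and pass the file paths.
#' Simulation defaults for this network are turgor on and pheromone,
#' Ste3 and Tec1 per `inputs_on`.
#'
#' @param reactions_path,contingencies_path paths to the two tables.
#' @param registry reaction-type registry.
#' @return `list(model = <rxncon_model>, inputs_on = <chr>)` where
#'   `inputs_on` holds the conventional starting inputs (`[Turgor]` on;
#'   pheromone and Ste3 off).
#' @export
load_mapk <- function(reactions_path, contingencies_path,
                      registry = reaction_types()) {
  for (p in c(reactions_path, contingencies_path)) {
    if (!file.exists(p)) {
      stop("MAPK case-study table not found: '", p, "'.\n",
           "These tables are distributed with the original network ",
           "curation, not with this package; export the reaction and ",
           "contingency lists to TSV/CSV and pass their paths. Nothing ",
           "is downloaded automatically.", call. = FALSE)
    }
  }
  model <- load_tabular(reactions_path, contingencies_path, registry = registry)
  list(model = model, inputs_on = intersect("[Turgor]", model$inputs))
}
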