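#' Reaction-contingency network models
#'
#' An `rxncon_model` holds a signalling network described at the level of
#' *elemental reactions* (single biochemical events between at most two
#' components, e.g. `Ssk1_ppi_Ssk2`), the *elemental states* those
#' reactions produce or consume (bonds `A--B`, modifications `A-{P}`,
#' component presence), and *contingencies* — contextual constraints saying
#' how states, inputs or Boolean combinations thereof influence reactions.
#'
#' @param reactions a data frame with either a `reaction` column of ids
#'   (`"A_type_B"`) or columns `a`, `type`, `b`.
#' @param contingencies a data frame with columns `target` (reaction id or
#'   bracketed output name), `sign` (`!`, `x`, `K+`, `K-`, `0`, `?`) and
#'   `effector` (state id, bracketed input, or `<BooleanNode>` reference).
#'   May be `NULL`.
#' @param bool_nodes named list of Boolean node definitions, each
#'   `list(op = "AND"|"OR"|"NOT", children = <character effector texts>)`.
#' @param registry reaction-type registry, see [reaction_types()].
#' @return an object of class `rxncon_model`.
#' @seealso [parse_quick()], [load_tabular()], [validate_model()],
#'   [build_bipartite()], [build_classical()]
#' @export
rxncon <- function(reactions = NULL, contingencies = NULL,
                   bool_nodes = list(), registry = reaction_types()) {
  registry <- check_registry(registry)
  if (is.null(reactions) || nrow(as.data.frame(reactions)) == 0L) {
    rx <- tibble::tibble(id = character(), a = character(),
                         type = character(), b = character())
  } else {
    reactions <- tibble::as_tibble(reactions)
    if ("reaction" %in% names(reactions) && !all(c("a", "type", "b") %in% names(reactions))) {
      rx <- dplyr::bind_rows(lapply(reactions$reaction, parse_reaction_id,
                                    registry = registry))
    } else {
      stopifnot(all(c("a", "type", "b") %in% names(reactions)))
      rx <- reactions
      for (i in seq_len(nrow(rx))) {
        check_component_name(rx$a[i]); check_component_name(rx$b[i])
        registry_entry(registry, rx$type[i])
      }
      rx$id <- paste(rx$a, rx$type, rx$b, sep = "_")
    }
    rx <- dplyr::distinct(rx[, c("id", "a", "type", "b")])
    dup <- rx$id[duplicated(rx$id)]
    if (length(dup)) stop("duplicate reaction ids: ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(contingencies) || nrow(as.data.frame(contingencies)) == 0L) {
    cg <- tibble::tibble(target = character(), sign = character(),
                         effector = character())
  } else {
    cg <- tibble::as_tibble(contingencies)[, c("target", "sign", "effector")]
    cg$sign <- vapply(cg$sign, normalise_sign, character(1), USE.NAMES = FALSE)
    cg$effector <- vapply(cg$effector, normalise_effector, character(1),
                          USE.NAMES = FALSE)
    cg <- dplyr::distinct(cg)
  }
  bool_nodes <- lapply(bool_nodes, function(n) {
    op <- toupper(n$op)
    stopifnot(op %in% c("AND", "OR", "NOT"))
    if (op == "NOT" && length(n$children) != 1L)
      stop("NOT node must have exactly one child")
    if (op != "NOT" && length(n$children) < 2L)
      stop("AND/OR nodes need at least two children")
    list(op = op, children = vapply(n$children, normalise_effector, character(1),
                                    USE.NAMES = FALSE))
  })

  bracketed_targets <- unique(cg$target[is_bracketed(cg$target)])
  eff_all <- c(cg$effector, unlist(lapply(bool_nodes, `[[`, "children"), use.names = FALSE))
  bracketed_effectors <- unique(eff_all[is_bracketed(eff_all)])

  structure(list(
    reactions = rx,
    contingencies = cg,
    bool_nodes = bool_nodes,
    registry = registry,
    components = unique(c(rx$a, rx$b)),
    outputs = bracketed_targets,
    inputs = setdiff(bracketed_effectors, bracketed_targets)
  ), class = "rxncon_model")
}

is_bracketed <- function(x) grepl("^\\[[^]]+\\]$", x)
is_node_ref <- function(x) grepl("^<[^>]+>$", x)

check_component_name <- function(name) {
  if (!nzchar(name)) stop("empty component name", call. = FALSE)
  if (grepl("[][}{;_\\s-]", name, perl = TRUE)) {
    stop("component name '", name,
         "' contains whitespace or a reserved character (_ - { } [ ] ;)",
         call. = FALSE)
  }
  invisible(name)
}

normalise_sign <- function(s) {
  s <- trimws(s)
  up <- toupper(s)
  if (up %in% c("!", "X", "K+", "K-", "0", "?")) {
    return(if (up == "X") "x" else up)
  }
  stop("invalid contingency sign '", s, "' (allowed: !, x, K+, K-, 0, ?)",
       call. = FALSE)
}

# canonicalise bond-state effectors so A--B and B--A are one state
normalise_effector <- function(e) {
  e <- trimws(e)
  if (is_bracketed(e) || is_node_ref(e)) return(e)
  if (state_kind(e) == "bond") {
    p <- strsplit(e, "--", fixed = TRUE)[[1]]
    if (length(p) != 2L || !all(nzchar(p))) stop("malformed bond state: ", e)
    return(canonical_bond(p[1], p[2]))
  }
  e
}

#' Parse an elemental-reaction identifier
#'
#' Splits `"A_type_B"` into its two components and the reaction type,
#' resolved against the registry. Reaction-type symbols may contain `+`
#' or `-` (`P+`, `Ub-`); component names may not contain underscores, so
#' the split on `_` is unambiguous.
#'
#' @param text reaction id, e.g. `"Hog1_P+_Hot1"`.
#' @param registry reaction-type registry.
#' @return one-row tibble with columns `id`, `a`, `type`, `b`.
#' @examples
#' parse_reaction_id("Hog1_P+_Hot1")
#' parse_reaction_id("Sln1_AP_Sln1")  # autoreaction: A == B
#' @export
parse_reaction_id <- function(text, registry = reaction_types()) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty reaction text", call. = FALSE)
  parts <- strsplit(text, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("cannot parse reaction '", text, "': expected A_type_B (",
         length(parts), " underscore-separated fields at position ",
         regexpr("_", text)[1], ")", call. = FALSE)
  }
  if (!nzchar(parts[2])) {
    stop("cannot parse reaction '", text, "': empty reaction type at position ",
         nchar(parts[1]) + 2L, call. = FALSE)
  }
  check_component_name(parts[1]); check_component_name(parts[3])
  entry <- registry_entry(registry, parts[2])
  tibble::tibble(id = paste(parts[1], entry$symbol, parts[3], sep = "_"),
                 a = parts[1], type = entry$symbol, b = parts[3])
}

#' States produced and consumed by a reaction
#'
#' Instantiates the reaction type's state templates with the reaction's
#' components ("skeleton" of the reaction). Bond states are canonically
#' ordered, so `A_ppi_B` and `B_ppi_A` yield the same state id.
#'
#' @param model an `rxncon_model`.
#' @param reaction_id reaction id present in the model.
#' @return `list(produced = <chr>, consumed = <chr>)`.
#' @examples
#' m <- parse_quick("Ssk1_ppi_Ssk2\nSln1_PT_Ypd1")
#' skeleton(m, "Ssk1_ppi_Ssk2")
#' skeleton(m, "Sln1_PT_Ypd1")
#' @export
skeleton <- function(model, reaction_id) {
  stopifnot(inherits(model, "rxncon_model"))
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  r <- model$reactions[i, ]
  entry <- registry_entry(model$registry, r$type)
  list(
    produced = vapply(split_templates(entry$produces), instantiate_template,
                      character(1), a = r$a, b = r$b, USE.NAMES = FALSE),
    consumed = vapply(split_templates(entry$consumes), instantiate_template,
                      character(1), a = r$a, b = r$b, USE.NAMES = FALSE)
  )
}

# Long table: one row per (reaction, state, effect in produce/consume),
# plus reversibility of the producing reaction.
reaction_state_table <- function(model) {
  if (nrow(model$reactions) == 0L) {
    return(tibble::tibble(reaction = character(), state = character(),
                          effect = character(), reversible = logical()))
  }
  rows <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    sk <- skeleton(model, r$id)
    rev <- registry_entry(model$registry, r$type)$reversible
    tibble::tibble(
      reaction = r$id,
      state = c(sk$produced, sk$consumed),
      effect = rep(c("produce", "consume"),
                   c(length(sk$produced), length(sk$consumed))),
      reversible = rev
    )
  })
  dplyr::bind_rows(rows)
}

state_effectors <- function(model) {
  eff <- c(model$contingencies$effector,
           unlist(lapply(model$bool_nodes, `[[`, "children"), use.names = FALSE))
  unique(eff[!is_bracketed(eff) & !is_node_ref(eff)])
}

#' Elemental states of a model
#'
#' All states producible or consumable by the model's reactions, together
#' with states referenced only by contingencies (the latter flagged by
#' [validate_model()] if nothing produces them).
#'
#' @param model an `rxncon_model`.
#' @return tibble with columns `state`, `kind` (`bond`/`modification`/
#'   `presence`).
#' @export
model_states <- function(model) {
  st <- unique(c(reaction_state_table(model)$state, state_effectors(model)))
  tibble::tibble(state = st,
                 kind = vapply(st, state_kind, character(1), USE.NAMES = FALSE))
}

#' Validate a reaction-contingency model
#'
#' Returns diagnostics, not exceptions: unresolvable contingency targets,
#' effector states that no reaction produces, modification states with a
#' producer but no consumer (irreversibly "latching" states — typically a
#' knowledge gap, cf. [add_reverse_reactions()]), unresolved or cyclic
#' Boolean node references, and reactions that both produce and consume
#' the same state.
#'
#' @param model an `rxncon_model`.
#' @return tibble with columns `code`, `severity` (`error`/`warning`/`note`)
#'   and `message`; zero rows for a clean model.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "rxncon_model"))
  out <- list()
  add <- function(code, severity, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(code = code, severity = severity,
                                               message = message)
  }
  rst <- reaction_state_table(model)

  known_targets <- c(model$reactions$id, model$outputs)
  for (tg in unique(model$contingencies$target)) {
    if (!tg %in% known_targets) {
      cand <- model$reactions$id[startsWith(model$reactions$id,
                                            sub("_.*$", "", tg))]
      add("unknown_target", "error",
          paste0("contingency target '", tg, "' is not a reaction or output",
                 if (length(cand)) paste0(" (candidates: ",
                                          paste(cand, collapse = ", "), ")") else ""))
    }
  }

  produced <- unique(rst$state[rst$effect == "produce"])
  for (e in state_effectors(model)) {
    if (!e %in% produced) {
      add("unproduced_state", "warning",
          paste0("effector state '", e, "' is never produced by any reaction"))
    }
  }

  consumed <- unique(rst$state[rst$effect == "consume"])
  mods <- unique(rst$state[rst$effect == "produce" &
                             vapply(rst$state, state_kind, character(1)) == "modification"])
  for (s in setdiff(mods, consumed)) {
    add("irreversible_only", "note",
        paste0("state ", s, " irreversible-only: produced but never consumed"))
  }

  node_names <- paste0("<", names(model$bool_nodes), ">")
  refs <- unique(c(model$contingencies$effector,
                   unlist(lapply(model$bool_nodes, `[[`, "children"),
                          use.names = FALSE)))
  for (r in refs[is_node_ref(refs)]) {
    if (!r %in% node_names) {
      add("unresolved_node", "error",
          paste0("Boolean node reference ", r, " is not defined"))
    }
  }
  for (nm in names(model$bool_nodes)) {
    if (!paste0("<", nm, ">") %in% refs) {
      add("dangling_node", "note",
          paste0("Boolean node <", nm, "> is defined but never used"))
    }
  }
  cyc <- find_node_cycle(model$bool_nodes)
  if (!is.null(cyc)) {
    add("node_cycle", "error",
        paste0("cyclic Boolean node references: ", paste(cyc, collapse = " -> ")))
  }

  both <- dplyr::intersect(rst[rst$effect == "produce", c("reaction", "state")],
                           rst[rst$effect == "consume", c("reaction", "state")])
  for (i in seq_len(nrow(both))) {
    add("self_consumption", "note",
        paste0("reaction ", both$reaction[i], " both produces and consumes ",
               both$state[i], "; production takes precedence"))
  }
  if (length(out) == 0L) {
    return(tibble::tibble(code = character(), severity = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}

find_node_cycle <- function(nodes) {
  state <- stats::setNames(rep(0L, length(nodes)), names(nodes))
  cycle <- NULL
  visit <- function(nm, path) {
    if (!is.null(cycle)) return()
    if (state[[nm]] == 1L) { cycle <<- c(path, nm); return() }
    if (state[[nm]] == 2L) return()
    state[[nm]] <<- 1L
    for (ch in nodes[[nm]]$children) {
      if (is_node_ref(ch)) {
        inner <- substr(ch, 2, nchar(ch) - 1L)
        if (inner %in% names(nodes)) visit(inner, c(path, nm))
      }
    }
    state[[nm]] <<- 2L
  }
  for (nm in names(nodes)) visit(nm, character())
  cycle
}

#' @export
print.rxncon_model <- function(x, ...) {
  cat("<rxncon_model> ", length(x$components), " components, ",
      nrow(x$reactions), " reactions, ", nrow(x$contingencies),
      " contingencies\n", sep = "")
  if (length(x$inputs)) cat("  inputs:  ", paste(x$inputs, collapse = ", "), "\n")
  if (length(x$outputs)) cat("  outputs: ", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reaction-contingency model into its reaction list
#'
#' @param x an `rxncon_model`.
#' @param ... unused.
#' @return tibble with one row per reaction: `id`, `a`, `type`, `b`,
#'   `reversible`, `produced`, `consumed` (comma-separated state ids).
#' @method tidy rxncon_model
#' @export
tidy.rxncon_model <- function(x, ...) {
  rx <- x$reactions
  if (nrow(rx) == 0L) {
    return(tibble::tibble(id = character(), a = character(), type = character(),
                          b = character(), reversible = logical(),
                          produced = character(), consumed = character()))
  }
  sk <- lapply(rx$id, skeleton, model = x)
  rx$reversible <- vapply(rx$type, function(tp)
    registry_entry(x$registry, tp)$reversible, logical(1), USE.NAMES = FALSE)
  rx$produced <- vapply(sk, function(s) paste(s$produced, collapse = ","), character(1))
  rx$consumed <- vapply(sk, function(s) paste(s$consumed, collapse = ","), character(1))
  rx
}

#' One-row model summary
#' @param x an `rxncon_model`.
#' @param ... unused.
#' @method glance rxncon_model
#' @export
glance.rxncon_model <- function(x, ...) {
  dg <- validate_model(x)
  tibble::tibble(
    components = length(x$components),
    reactions = nrow(x$reactions),
    states = nrow(model_states(x)),
    contingencies = nrow(x$contingencies),
    inputs = length(x$inputs),
    outputs = length(x$outputs),
    diagnostics = nrow(dg),
    errors = sum(dg$severity == "error")
  )
}
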