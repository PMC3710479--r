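#' Executable Boolean models
#'
#' A `boolean_model` is a set of Boolean variables with one update
#' expression each (time `t` on the right, `t + 1` on the left) and a role
#' per variable: `reaction`, `state`, `component`, `input` or `output`.
#' Components and inputs whose rule is their own atom are constants under
#' synchronous update. Rules are pre-compiled to R expressions over a
#' positional logical vector for fast simulation.
#'
#' @name boolean_model
NULL

new_boolean_model <- function(variables, roles, rules, scheme) {
  if (length(variables)) stopifnot(identical(names(roles), variables))
  stopifnot(setequal(names(rules), variables),
            length(rules) == length(variables))
  rules <- rules[variables]
  for (v in variables) {
    loose <- setdiff(expr_vars(rules[[v]]), variables)
    if (length(loose)) {
      stop("rule for ", v, " references undeclared variable(s): ",
           paste(loose, collapse = ", "))
    }
  }
  idx <- stats::setNames(seq_along(variables), variables)
  compiled <- lapply(rules, expr_to_lang, index = idx)
  structure(list(variables = variables, roles = roles, rules = rules,
                 compiled = compiled, scheme = scheme),
            class = "boolean_model")
}

#' Construct a Boolean model from explicit rules
#'
#' Mostly useful for small hand-written systems (toggles, feedback
#' rings); generated models come from [build_bipartite()] and
#' [build_classical()].
#'
#' @param rules named list of `bool_expr` update rules; the names declare
#'   the variables, in order.
#' @param roles optional named character vector of roles
#'   (`reaction`/`state`/`component`/`input`/`output`); default `"state"`.
#' @param scheme label for the model's origin (default `"custom"`).
#' @return a `boolean_model`.
#' @examples
#' toggle <- boolean_model(list(A = b_not(b_atom("B")), B = b_not(b_atom("A"))))
#' run_sync(toggle, c(A = TRUE, B = FALSE))$attractor$type
#' @export
boolean_model <- function(rules, roles = NULL, scheme = "custom") {
  stopifnot(is.list(rules), !is.null(names(rules)), all(nzchar(names(rules))))
  vars <- names(rules)
  if (is.null(roles)) roles <- stats::setNames(rep("state", length(vars)), vars)
  stopifnot(all(vars %in% names(roles)))
  new_boolean_model(vars, roles[vars], rules, scheme = scheme)
}

#' @export
print.boolean_model <- function(x, ...) {
  cat("<boolean_model> (", x$scheme, "), ", length(x$variables),
      " variables\n", sep = "")
  print(table(factor(x$roles, levels = c("reaction", "state", "component",
                                         "input", "output"))))
  invisible(x)
}

#' Tidy a Boolean model into its rule table
#' @param x a `boolean_model`.
#' @param ... unused.
#' @return tibble with columns `variable`, `role`, `rule` (rendered
#'   expression text) and `constant` (rule is the variable's own atom).
#' @method tidy boolean_model
#' @export
tidy.boolean_model <- function(x, ...) {
  tibble::tibble(
    variable = x$variables,
    role = unname(x$roles[x$variables]),
    rule = vapply(x$rules[x$variables], format, character(1)),
    constant = vapply(x$variables, function(v) {
      r <- x$rules[[v]]
      r$kind == "atom" && identical(r$var, v)
    }, logical(1))
  )
}

#' @method glance boolean_model
#' @export
glance.boolean_model <- function(x, ...) {
  tb <- table(x$roles)
  as_n <- function(r) as.integer(if (r %in% names(tb)) tb[[r]] else 0L)
  tibble::tibble(scheme = x$scheme, variables = length(x$variables),
                 reactions = as_n("reaction"), states = as_n("state"),
                 components = as_n("component"), inputs = as_n("input"),
                 outputs = as_n("output"))
}

#' Flatten an effector to an expression over elemental variables
#'
#' Resolves a contingency effector — a state id, a bracketed input/output
#' name, or a `<Node>` reference — into a Boolean expression whose atoms
#' are state, input or output variables only. Boolean node references are
#' expanded recursively, so no node atoms remain in generated rules.
#'
#' @param model an `rxncon_model`.
#' @param effector effector text.
#' @return a `bool_expr`.
#' @export
flatten_effector <- function(model, effector, .stack = character()) {
  effector <- normalise_effector(effector)
  if (is_node_ref(effector)) {
    nm <- substr(effector, 2, nchar(effector) - 1L)
    if (nm %in% .stack) {
      stop("cyclic Boolean node reference: ",
           paste(c(.stack, nm), collapse = " -> "), call. = FALSE)
    }
    node <- model$bool_nodes[[nm]]
    if (is.null(node)) stop("undefined Boolean node <", nm, ">", call. = FALSE)
    kids <- lapply(node$children, flatten_effector, model = model,
                   .stack = c(.stack, nm))
    return(switch(node$op,
                  AND = b_and(kids), OR = b_or(kids), NOT = b_not(kids[[1]])))
  }
  b_atom(effector)
}

#' Derive the update rule of an elemental reaction
#'
#' A reaction fires when all its components are present AND all states
#' required by its contingencies hold; inhibiting contingencies enter
#' negated. Under the default `"strict-qualitative"` policy the
#' quantitative signs are read as absolute (`K+` as `!`, `K-` as `x`),
#' which is the translation used when a qualitative model is derived from
#' a quantitatively annotated network; the `"neutral"` policy drops them.
#' Signs `0` and `?` never contribute.
#'
#' @param model an `rxncon_model`.
#' @param reaction_id reaction id in the model.
#' @param policy `"strict-qualitative"` (default) or `"neutral"`.
#' @return a `bool_expr`.
#' @examples
#' m <- parse_quick("Hog1_P+_Hot1; ! Hog1-{P}")
#' format(reaction_rule(m, "Hog1_P+_Hot1"))
#' @export
reaction_rule <- function(model, reaction_id,
                          policy = c("strict-qualitative", "neutral")) {
  policy <- match.arg(policy)
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  r <- model$reactions[i, ]
  comps <- unique(c(r$a, r$b))
  b_and(c(lapply(comps, b_atom),
          contingency_conjuncts(model, reaction_id, policy)))
}

contingency_conjuncts <- function(model, target, policy) {
  cg <- model$contingencies[model$contingencies$target == target, ]
  pos <- c("!", if (policy == "strict-qualitative") "K+")
  neg <- c("x", if (policy == "strict-qualitative") "K-")
  out <- list()
  for (j in seq_len(nrow(cg))) {
    s <- cg$sign[j]
    if (s %in% pos) out <- c(out, list(flatten_effector(model, cg$effector[j])))
    else if (s %in% neg) out <- c(out, list(b_not(flatten_effector(model, cg$effector[j]))))
  }
  out
}

#' Derive the update rule of an elemental state
#'
#' States are functions of the reactions that produce or consume them.
#' With `P_irr` the irreversible producers, `P_rev` the reversible
#' producers and `C` the consumers, the rule is
#'
#' \deqn{s(t+1) = comps \wedge ( \bigvee P_{irr} \vee ( m \wedge \neg \bigvee C ) )}
#'
#' where the maintenance term `m` is `OR(P_rev)` when reversible producers
#' exist (reversible reactions decay their products when off) and the
#' state's own atom otherwise (irreversibly produced states latch until
#' consumed). Empty disjunctions vanish, so the two canonical cases fall
#' out: a state with one irreversible producer and one consumer reads
#' `producer | (s & !consumer)`, and a state with a single reversible
#' producer and no consumer simply tracks that producer. Component
#' presence conjuncts are included by default and can be dropped to match
#' the bare printed form of the equations.
#'
#' @param model an `rxncon_model`.
#' @param state_id elemental-state id (or output name).
#' @param components_in_states conjoin the state's components into the
#'   rule (default `TRUE`; components are constant-true unless explicitly
#'   synthesised/degraded, so this changes no trajectory under defaults).
#' @return a `bool_expr`.
#' @examples
#' m <- parse_quick("Sln1_AP_Sln1\nSln1_PT_Ypd1")
#' format(state_rule(m, "Sln1-{P}", components_in_states = FALSE))
#' @export
state_rule <- function(model, state_id, components_in_states = TRUE) {
  rst <- reaction_state_table(model)
  mine <- rst[rst$state == state_id, ]
  prod <- mine[mine$effect == "produce", ]
  cons <- mine[mine$effect == "consume", ]
  # self-consumption: production takes precedence
  cons <- cons[!cons$reaction %in% prod$reaction, ]
  core <- state_core_rule(state_id,
                          p_irr = prod$reaction[!prod$reversible],
                          p_rev = prod$reaction[prod$reversible],
                          consumers = cons$reaction)
  if (!components_in_states) return(core)
  comps <- setdiff(unique(state_components(state_id)), state_id)
  b_and(c(lapply(comps, b_atom), list(core)))
}

state_core_rule <- function(state_id, p_irr, p_rev, consumers) {
  maintenance <- if (length(p_rev)) b_or(lapply(p_rev, b_atom)) else b_atom(state_id)
  decayable <- if (length(consumers)) {
    b_and(maintenance, b_not(b_or(lapply(consumers, b_atom))))
  } else maintenance
  b_or(c(lapply(p_irr, b_atom), list(decayable)))
}

#' Build the bipartite Boolean model
#'
#' Generates the executable Boolean network with one variable per
#' elemental reaction, per elemental state, per component, per input and
#' per output. Reaction rules come from [reaction_rule()], state rules
#' from [state_rule()]; components and inputs are constant (their rule is
#' their own atom) unless a synthesis/degradation reaction acts on the
#' component's presence state. Outputs are treated like states: each
#' output gets a pseudo production reaction (variable
#' `<name>_production`, reversible) whose rule is the conjunction of the
#' contingencies targeting the output, so the output tracks its
#' conditions. The construction is deterministic: the same model yields a
#' structurally identical Boolean model.
#'
#' @param model a validated `rxncon_model`.
#' @param policy contingency policy, see [reaction_rule()].
#' @param components_in_states see [state_rule()].
#' @return a `boolean_model` with scheme `"bipartite"`.
#' @examples
#' bm <- build_bipartite(simplified_hog())
#' tidy(bm)
#' @export
build_bipartite <- function(model, policy = c("strict-qualitative", "neutral"),
                            components_in_states = TRUE) {
  stopifnot(inherits(model, "rxncon_model"))
  policy <- match.arg(policy)
  dg <- validate_model(model)
  if (any(dg$severity == "error")) {
    stop("model has validation errors:\n  ",
         paste(dg$message[dg$severity == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  rst <- reaction_state_table(model)
  states <- unique(c(rst$state, state_effectors(model)))
  # presence states share their variable with the component itself
  states <- setdiff(states, model$components)
  dyn_comps <- intersect(unique(rst$state), model$components)

  pseudo <- if (length(model$outputs)) {
    stats::setNames(make.unique(paste0(gsub("[][]", "", model$outputs),
                                       "_production")), model$outputs)
  } else stats::setNames(character(), character())

  variables <- c(model$components, model$inputs, model$reactions$id,
                 unname(pseudo), states, model$outputs)
  roles <- stats::setNames(
    rep(c("component", "input", "reaction", "reaction", "state", "output"),
        c(length(model$components), length(model$inputs),
          nrow(model$reactions), length(pseudo), length(states),
          length(model$outputs))),
    variables)

  rules <- list()
  for (v in model$components) {
    rules[[v]] <- if (v %in% dyn_comps) {
      state_rule(model, v, components_in_states = components_in_states)
    } else b_atom(v)
  }
  for (v in model$inputs) rules[[v]] <- b_atom(v)
  for (v in model$reactions$id) rules[[v]] <- reaction_rule(model, v, policy)
  for (o in model$outputs) {
    cj <- contingency_conjuncts(model, o, policy)
    rules[[pseudo[[o]]]] <- b_and(cj)   # empty conjunction = constitutive
    # output = state with a single reversible pseudo producer
    rules[[o]] <- b_atom(pseudo[[o]])
  }
  unproduced <- character()
  for (s in states) {
    if (!s %in% rst$state) {
      # referenced by contingencies only: frozen at its initial value
      rules[[s]] <- b_atom(s)
      unproduced <- c(unproduced, s)
    } else {
      rules[[s]] <- state_rule(model, s, components_in_states = components_in_states)
    }
  }
  bm <- new_boolean_model(variables, roles, rules, scheme = "bipartite")
  attr(bm, "frozen_states") <- unproduced
  bm
}
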