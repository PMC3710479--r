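#' Build a component-level "classical" Boolean model
#'
#' Collapses the network to the reaction-graph topology: one Boolean
#' variable per component, input and output, with no state or reaction
#' variables. For each component the activators are the source components
#' (and positively signed input effectors) of the reactions targeting it,
#' provided the reaction's net contingency context is non-negative
#' (`!`/`K+` count +1, `x`/`K-` count -1); sources of reactions with a
#' negative net context, and of intrinsically consuming reaction types
#' (dephosphorylation, degradation and the like), become inhibitors.
#' Undirected binding reactions contribute each partner as an activator
#' of the other. Outputs take the components of their positive effector
#' states (and positive inputs) as activators. The rule is
#' `OR(activators) & !OR(inhibitors)`; inputs are constant, a component
#' with inhibitors but no activators keeps its own value while
#' uninhibited, and a component with no incoming influence at all keeps
#' its own value (a constant, flagged in the attached diagnostics).
#'
#' This construction is an illustrative heuristic: component-level models
#' of this kind are conventionally written by hand, and the point of
#' generating one is to expose the contextual information they lose —
#' signals passing through shared components merge, so either input
#' activates every downstream output (see [toy_crosstalk()]).
#'
#' @param model a validated `rxncon_model`.
#' @return a `boolean_model` with scheme `"classical"` and a
#'   `"diagnostics"` attribute (tibble).
#' @examples
#' cm <- build_classical(toy_crosstalk())
#' tidy(cm)
#' @export
build_classical <- function(model) {
  stopifnot(inherits(model, "rxncon_model"))
  dg <- validate_model(model)
  if (any(dg$severity == "error")) {
    stop("model has validation errors:\n  ",
         paste(dg$message[dg$severity == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  variables <- c(model$components, model$inputs, model$outputs)
  roles <- stats::setNames(
    rep(c("component", "input", "output"),
        c(length(model$components), length(model$inputs), length(model$outputs))),
    variables)

  acts <- stats::setNames(vector("list", length(variables)), variables)
  inhs <- acts
  push <- function(store, tgt, who) {
    for (w in who) if (!w %in% store[[tgt]]) store[[tgt]] <- c(store[[tgt]], w)
    store
  }

  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    entry <- registry_entry(model$registry, r$type)
    pairs <- if (entry$directed) list(c(r$a, r$b)) else
      list(c(r$a, r$b), c(r$b, r$a))
    cg <- model$contingencies[model$contingencies$target == r$id, ]
    net <- sum((cg$sign %in% c("!", "K+")) - (cg$sign %in% c("x", "K-")))
    consuming_only <- length(split_templates(entry$consumes)) > 0L &&
      length(split_templates(entry$produces)) == 0L
    pos_inputs <- cg$effector[cg$sign %in% c("!", "K+") & is_bracketed(cg$effector)]
    neg_inputs <- cg$effector[cg$sign %in% c("x", "K-") & is_bracketed(cg$effector)]
    for (p in pairs) {
      src <- p[1]; tgt <- p[2]
      if (src == tgt) next
      if (consuming_only || net < 0L) inhs <- push(inhs, tgt, src)
      else acts <- push(acts, tgt, src)
      acts <- push(acts, tgt, pos_inputs)
      inhs <- push(inhs, tgt, neg_inputs)
    }
  }
  for (o in model$outputs) {
    cg <- model$contingencies[model$contingencies$target == o, ]
    for (j in seq_len(nrow(cg))) {
      eff <- flatten_effector(model, cg$effector[j])
      who <- unlist(lapply(expr_vars(eff), function(v) {
        if (is_bracketed(v)) v else intersect(state_components(v), model$components)
      }))
      if (cg$sign[j] %in% c("!", "K+")) acts <- push(acts, o, who)
      else if (cg$sign[j] %in% c("x", "K-")) inhs <- push(inhs, o, who)
    }
  }

  notes <- list()
  rules <- list()
  for (v in variables) {
    if (roles[[v]] == "input") { rules[[v]] <- b_atom(v); next }
    a <- acts[[v]]; h <- inhs[[v]]
    if (length(a) == 0L && length(h) == 0L) {
      rules[[v]] <- b_atom(v)
      notes[[length(notes) + 1L]] <- tibble::tibble(
        code = "no_incoming", severity = "note",
        message = paste0("'", v, "' has no incoming reactions; kept constant"))
      next
    }
    act <- if (length(a)) b_or(lapply(a, b_atom)) else b_atom(v)
    rules[[v]] <- if (length(h)) b_and(act, b_not(b_or(lapply(h, b_atom)))) else act
  }
  bm <- new_boolean_model(variables, roles, rules, scheme = "classical")
  attr(bm, "diagnostics") <- if (length(notes)) dplyr::bind_rows(notes) else
    tibble::tibble(code = character(), severity = character(), message = character())
  bm
}
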