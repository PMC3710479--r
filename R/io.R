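#' Regulatory graph of a model
#'
#' The bipartite regulatory graph has elemental reactions and elemental
#' states (plus inputs and outputs) as nodes; reaction-to-state edges of
#' class `produce` (blue) or `consume` (purple), and state-to-reaction
#' contingency edges of class `activate` (green; `!`/`K+`) or `inhibit`
#' (red; `x`/`K-`). Every contingency contributes exactly one
#' state-to-reaction edge (Boolean node effectors are flattened to their
#' elemental atoms first).
#'
#' @param model an `rxncon_model`.
#' @return an igraph object; vertices carry `kind`
#'   (`reaction`/`state`/`input`/`output`), edges `class` and `color`.
#' @export
regulatory_graph <- function(model) {
  stopifnot(inherits(model, "rxncon_model"))
  rst <- reaction_state_table(model)
  edge_rows <- list()
  if (nrow(rst)) {
    edge_rows[[1]] <- tibble::tibble(from = rst$reaction, to = rst$state,
                                     class = rst$effect)
  }
  pseudo <- if (length(model$outputs)) {
    stats::setNames(paste0(gsub("[][]", "", model$outputs), "_production"),
                    model$outputs)
  } else stats::setNames(character(), character())
  cg <- model$contingencies
  for (j in seq_len(nrow(cg))) {
    tgt <- cg$target[j]
    rnode <- if (tgt %in% names(pseudo)) pseudo[[tgt]] else tgt
    if (tgt %in% names(pseudo)) {
      edge_rows[[length(edge_rows) + 1L]] <-
        tibble::tibble(from = rnode, to = tgt, class = "produce")
    }
    cls <- if (cg$sign[j] %in% c("!", "K+")) "activate"
           else if (cg$sign[j] %in% c("x", "K-")) "inhibit" else NA_character_
    if (is.na(cls)) next
    for (v in expr_vars(flatten_effector(model, cg$effector[j]))) {
      edge_rows[[length(edge_rows) + 1L]] <-
        tibble::tibble(from = v, to = rnode, class = cls)
    }
  }
  edges <- if (length(edge_rows)) dplyr::distinct(dplyr::bind_rows(edge_rows)) else
    tibble::tibble(from = character(), to = character(), class = character())
  nodes <- unique(c(model$reactions$id, unname(pseudo), rst$state,
                    state_effectors(model), model$inputs, model$outputs,
                    edges$from, edges$to))
  kind <- function(v) {
    if (v %in% c(model$reactions$id, pseudo)) "reaction"
    else if (v %in% model$inputs) "input"
    else if (v %in% model$outputs) "output"
    else "state"
  }
  if (length(nodes) == 0L) return(igraph::make_empty_graph(directed = TRUE))
  vdf <- tibble::tibble(name = nodes,
                        kind = vapply(nodes, kind, character(1), USE.NAMES = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vdf)
  pal <- c(produce = "blue", consume = "purple", activate = "green",
           inhibit = "red")
  igraph::E(g)$color <- unname(pal[igraph::E(g)$class])
  igraph::V(g)$color <- unname(c(reaction = "red", state = "skyblue",
                                 input = "grey", output = "grey")[igraph::V(g)$kind])
  g
}

#' Export the regulatory graph to GraphML or DOT
#' @param model an `rxncon_model`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_regulatory_graph <- function(model, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(regulatory_graph(model), path, format = format)
  invisible(path)
}

#' Sanitise variable ids for downstream Boolean tools
#'
#' Many Boolean-network file consumers reject punctuation in identifiers.
#' The mapping is: `--` becomes `_bnd_`, remaining `-` becomes `_d_`,
#' braces are dropped, brackets wrap as leading/trailing underscores, and
#' anything else non-alphanumeric becomes `_`; clashes are disambiguated
#' with numeric suffixes.
#'
#' @param ids character vector of variable ids.
#' @return tibble with columns `id`, `alias`.
#' @export
sanitise_ids <- function(ids) {
  alias <- ids
  alias <- gsub("--", "_bnd_", alias, fixed = TRUE)
  alias <- gsub("-", "_d_", alias, fixed = TRUE)
  alias <- gsub("[{}]", "", alias)
  alias <- gsub("\\[([^]]*)\\]", "_\\1_", alias)
  alias <- gsub("[^A-Za-z0-9_]", "_", alias)
  alias <- gsub("^([0-9])", "x\\1", alias)
  alias <- make.unique(alias, sep = "_")
  tibble::tibble(id = ids, alias = alias)
}

#' Write a Boolean model in .bnet (targets/factors) format
#'
#' Renders each update rule as `<target>, <factors>` with `&`, `|`, `!`
#' and parentheses, after id sanitisation ([sanitise_ids()]); the alias
#' table is written alongside as `<path>.aliases.csv` and also returned.
#' Constant variables appear with themselves as factor.
#'
#' @param bm a `boolean_model`.
#' @param path output file (conventionally `.bnet`).
#' @return the alias tibble, invisibly.
#' @export
write_bnet <- function(bm, path) {
  stopifnot(inherits(bm, "boolean_model"))
  al <- sanitise_ids(bm$variables)
  rename <- function(e) {
    if (e$kind == "atom") return(b_atom(al$alias[match(e$var, al$id)]))
    if (e$kind == "not") return(new_bexpr("not", child = rename(e$child)))
    if (e$kind %in% c("and", "or")) {
      return(new_bexpr(e$kind, children = lapply(e$children, rename)))
    }
    e
  }
  lines <- c("targets, factors",
             vapply(seq_along(bm$variables), function(i) {
               ex <- rename(bm$rules[[bm$variables[i]]])
               paste0(al$alias[i], ", ", gsub("! ", "!", format(ex), fixed = TRUE))
             }, character(1)))
  writeLines(lines, path)
  utils::write.csv(al, paste0(path, ".aliases.csv"), row.names = FALSE)
  invisible(al)
}

#' Clustered time-course matrix of a trajectory
#'
#' Rows are variables, columns time steps (0/1). Variables constant over
#' the whole time course are dropped; the remaining rows are ordered by
#' hierarchical clustering of their binary profiles (Hamming distance,
#' average linkage by default), so entities with similar state evolution
#' sit together — pathway modules typically co-cluster.
#'
#' @param traj a `trajectory`.
#' @param cluster reorder rows by clustering (default `TRUE`).
#' @param method linkage method passed to [stats::hclust()].
#' @param file optional CSV path to write the ordered matrix to.
#' @return integer matrix (variables x time), invisibly if `file` given.
#' @export
trajectory_heatmap <- function(traj, cluster = TRUE, method = "average",
                               file = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  m <- t(traj$assignments) * 1L
  colnames(m) <- seq_len(ncol(m)) - 1L
  keep <- apply(m, 1L, function(r) length(unique(r)) > 1L)
  m <- m[keep, , drop = FALSE]
  if (cluster && nrow(m) > 2L) {
    ord <- stats::hclust(stats::dist(m, method = "manhattan"),
                         method = method)$order
    m <- m[ord, , drop = FALSE]
  }
  if (!is.null(file)) {
    utils::write.csv(m, file)
    return(invisible(m))
  }
  m
}

#' Write a trajectory as CSV
#'
#' Rows are variables, columns time steps, cells 0/1.
#' @param traj a `trajectory`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  m <- t(traj$assignments) * 1L
  colnames(m) <- paste0("t", seq_len(ncol(m)) - 1L)
  utils::write.csv(m, path)
  invisible(path)
}

#' Write a mean-activity matrix as CSV
#' @param activity an `activity` object from [run_async()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  m <- unclass(activity)
  colnames(m) <- paste0("t", seq_len(ncol(m)) - 1L)
  utils::write.csv(m, path)
  invisible(path)
}

#' Read/write a perturbation schedule as JSON
#'
#' The on-disk form is a list of `{t, var, value, clamp}` objects.
#' @param schedule a schedule tibble, see [perturbations()].
#' @param path JSON file.
#' @return `read_schedule()` returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(schedule, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- jsonlite::fromJSON(path)
  perturbations(t = df$t, var = df$var, value = df$value,
                clamp = if (!is.null(df$clamp)) df$clamp else FALSE)
}

#' Heat-map plot of a synchronous trajectory
#'
#' Active steps are drawn yellow, inactive blue, matching the usual
#' Boolean time-course rendering; rows follow the clustered ordering of
#' [trajectory_heatmap()].
#'
#' @param object a `trajectory`.
#' @param cluster reorder rows by clustering.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(object, cluster = TRUE, ...) {
  m <- trajectory_heatmap(object, cluster = cluster)
  if (nrow(m) == 0L) m <- t(object$assignments) * 1L
  df <- tibble::tibble(
    time = rep(as.integer(colnames(m) %||% (seq_len(ncol(m)) - 1L)),
               each = nrow(m)),
    variable = factor(rep(rownames(m), times = ncol(m)),
                      levels = rev(rownames(m))),
    value = factor(ifelse(as.integer(m) == 1L, "active", "inactive"),
                   levels = c("inactive", "active"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$variable,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(inactive = "#27408B",
                                          active = "#FFD700"), name = NULL) +
    ggplot2::labs(x = "time step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Line plot of asynchronous mean activities
#'
#' @param object an `activity` object from [run_async()].
#' @param drop_constant hide variables whose mean never changes.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot activity
#' @export
autoplot.activity <- function(object, drop_constant = TRUE, ...) {
  df <- tidy(object)
  if (drop_constant) {
    keep <- tapply(df$activity, df$variable, function(v) length(unique(v)) > 1L)
    df <- df[df$variable %in% names(keep)[keep], ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$activity,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = "mean activity") +
    ggplot2::theme_minimal()
}

#' Plot the regulatory graph
#'
#' Convenience wrapper drawing [regulatory_graph()] with the conventional
#' edge colours (produce blue, consume purple, activate green, inhibit
#' red).
#' @param model an `rxncon_model`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot_regulatory_graph <- function(model, ...) {
  g <- regulatory_graph(model)
  igraph::plot.igraph(g, vertex.label.cex = 0.7, edge.arrow.size = 0.4, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
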