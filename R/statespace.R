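#' State-transition graphs and attractors
#'
#' Under synchronous update every global state has exactly one successor,
#' so the transition graph is a functional graph whose terminal cycles
#' are the attractors (period 1 = point attractor) and whose weakly
#' connected components partition the states into basins.
#'
#' @name transition_graph
NULL

new_transition_graph <- function(keys, nxt, free_vars, fixed, mode) {
  cl <- classify_functional(nxt)
  attractors <- lapply(seq_along(cl$cycles), function(i) {
    mem <- cl$cycles[[i]]
    list(id = i,
         type = if (length(mem) == 1L) "point" else "cycle",
         period = length(mem),
         members = keys[mem],
         basin = sum(cl$attr_id == i))
  })
  structure(list(keys = keys, nxt = nxt, attractor_of = cl$attr_id,
                 attractors = attractors, free_vars = free_vars,
                 fixed = fixed, mode = mode),
            class = "transition_graph")
}

# attractor classification on a functional graph (out-degree exactly 1)
classify_functional <- function(nxt) {
  n <- length(nxt)
  state <- integer(n)          # 0 unvisited, 1 on current path, 2 done
  attr_id <- integer(n)
  cycles <- list()
  for (v in seq_len(n)) {
    if (state[v] != 0L) next
    path <- integer(0)
    u <- v
    while (state[u] == 0L) {
      state[u] <- 1L
      path[length(path) + 1L] <- u
      u <- nxt[u]
    }
    if (state[u] == 1L) {
      pos <- match(u, path)
      cyc <- path[pos:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      attr_id[path] <- length(cycles)
    } else {
      attr_id[path] <- attr_id[u]
    }
    state[path] <- 2L
  }
  list(attr_id = attr_id, cycles = cycles)
}

state_key <- function(bits) {
  # hex-encode the free-variable bit-vector, low-order variable first
  n <- length(bits)
  nyb <- ceiling(n / 4)
  length(bits) <- nyb * 4L
  bits[is.na(bits)] <- FALSE
  paste(rev(vapply(seq_len(nyb), function(k) {
    sprintf("%X", sum(bits[(4L * (k - 1L) + 1L):(4L * k)] * c(1L, 2L, 4L, 8L)))
  }, character(1))), collapse = "")
}

free_variable_set <- function(bm, free_vars) {
  if (is.null(free_vars)) {
    free_vars <- bm$variables[!bm$roles %in% c("component", "input")]
  }
  unknown <- setdiff(free_vars, bm$variables)
  if (length(unknown)) stop("not model variables: ", paste(unknown, collapse = ", "))
  free_vars
}

#' Enumerate the complete state space
#'
#' Expands all `2^k` assignments of the free variables (components and
#' inputs are constants and are excluded by default, their values coming
#' from `fixed`), computes every synchronous successor, and classifies
#' attractors and basin sizes. Complete enumeration is only feasible for
#' small models; beyond the cap, use [reachable()] from a set of starting
#' states.
#'
#' @param bm a `boolean_model`.
#' @param free_vars variables to enumerate over (default: all non-constant
#'   roles, i.e. reactions, states and outputs).
#' @param fixed named logical assignment for the remaining variables
#'   (default [default_init()] values).
#' @param cap refuse to enumerate more than `2^cap` states (default 20).
#' @return a `transition_graph`.
#' @examples
#' bm <- build_bipartite(parse_quick("A_ppi_B"))
#' tg <- enumerate_full(bm)
#' glance(tg)
#' @export
enumerate_full <- function(bm, free_vars = NULL, fixed = NULL, cap = 20L) {
  stopifnot(inherits(bm, "boolean_model"))
  free_vars <- free_variable_set(bm, free_vars)
  k <- length(free_vars)
  if (k > cap) {
    stop("refusing to enumerate 2^", k, " states (cap 2^", cap,
         "); use reachable() from a limited set of starting states",
         call. = FALSE)
  }
  base <- default_init(bm)
  if (!is.null(fixed)) base[names(fixed)] <- fixed
  fi <- match(free_vars, bm$variables)
  n <- as.integer(2^k)
  pow <- 2^(seq_len(k) - 1L)
  nxt <- integer(n)
  keys <- character(n)
  s0 <- unname(base[bm$variables])
  for (code in 0:(n - 1L)) {
    bits <- bitwAnd(code %/% pow, 1L) == 1L
    s <- s0
    s[fi] <- bits
    out <- vapply(bm$compiled, function(ex) eval(ex, list(s = s)), logical(1))
    nxt[code + 1L] <- sum(out[fi] * pow) + 1L
    keys[code + 1L] <- state_key(bits)
  }
  new_transition_graph(keys, nxt, free_vars, base[setdiff(bm$variables, free_vars)],
                       mode = "full")
}

#' Reachable state space from starting states
#'
#' Breadth-first closure of a set of starting assignments under the
#' synchronous successor relation, with the same attractor classification
#' as [enumerate_full()] (the closure is successor-closed, so every state
#' still has out-degree one within it).
#'
#' @param bm a `boolean_model`.
#' @param starts a single named logical assignment or a list of them.
#' @param free_vars variables defining the state key (default as in
#'   [enumerate_full()]); non-free variables are read from the first
#'   start.
#' @param max_states safety bound on the closure size.
#' @return a `transition_graph`.
#' @export
reachable <- function(bm, starts, free_vars = NULL, max_states = 2^20) {
  stopifnot(inherits(bm, "boolean_model"))
  if (!is.list(starts)) starts <- list(starts)
  stopifnot(length(starts) >= 1L)
  free_vars <- free_variable_set(bm, free_vars)
  fi <- match(free_vars, bm$variables)
  index <- new.env(parent = emptyenv())
  keys <- character(0)
  states <- list()
  nxt <- integer(0)
  intern <- function(s) {
    key <- state_key(unname(s[fi]))
    i <- index[[key]]
    if (is.null(i)) {
      i <- length(keys) + 1L
      keys[i] <<- key
      states[[i]] <<- s
      nxt[i] <<- NA_integer_
      index[[key]] <- i
    }
    i
  }
  queue <- vapply(starts, function(s) intern(s[bm$variables]), integer(1))
  qi <- 1L
  while (qi <= length(keys)) {
    if (length(keys) > max_states) stop("reachable closure exceeds max_states")
    if (is.na(nxt[qi])) {
      succ <- sync_step(bm, states[[qi]])
      nxt[qi] <- intern(succ)
    }
    qi <- qi + 1L
  }
  first <- states[[1]]
  new_transition_graph(keys, nxt, free_vars,
                       first[setdiff(bm$variables, free_vars)],
                       mode = "reachable")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("<transition_graph> (", x$mode, ") ", length(x$keys), " states over ",
      length(x$free_vars), " free variables; ", length(x$attractors),
      " attractor(s)\n", sep = "")
  for (a in x$attractors) {
    cat("  #", a$id, " ", a$type, " (period ", a$period, "), basin ",
        a$basin, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a transition graph into its edge list
#' @param x a `transition_graph`.
#' @param ... unused.
#' @return tibble with columns `from`, `to` (hex state keys),
#'   `attractor_id`, `is_attractor_state`.
#' @method tidy transition_graph
#' @export
tidy.transition_graph <- function(x, ...) {
  on_cycle <- logical(length(x$keys))
  for (a in x$attractors) on_cycle[match(a$members, x$keys)] <- TRUE
  tibble::tibble(from = x$keys, to = x$keys[x$nxt],
                 attractor_id = x$attractor_of,
                 is_attractor_state = on_cycle)
}

#' Attractor summary of a transition graph
#' @param x a `transition_graph`.
#' @param ... unused.
#' @return tibble with one row per attractor: `id`, `type`, `period`,
#'   `basin`.
#' @method glance transition_graph
#' @export
glance.transition_graph <- function(x, ...) {
  dplyr::bind_rows(lapply(x$attractors, function(a)
    tibble::tibble(id = a$id, type = a$type, period = a$period,
                   basin = a$basin)))
}

#' Convert a transition graph to igraph
#' @param tg a `transition_graph`.
#' @return an igraph object; nodes carry `attractor` (id) and `on_cycle`
#'   attributes.
#' @export
as_igraph <- function(tg) {
  stopifnot(inherits(tg, "transition_graph"))
  ed <- tidy(tg)
  g <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = TRUE,
                                     vertices = tibble::tibble(name = tg$keys))
  igraph::V(g)$attractor <- tg$attractor_of
  igraph::V(g)$on_cycle <- as.integer(ed$is_attractor_state)
  g
}

#' Export a transition graph to GraphML or DOT
#' @param tg a `transition_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_transition_graph <- function(tg, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(tg), path, format = format)
  invisible(path)
}
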