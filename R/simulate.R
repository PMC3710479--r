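#' Default initial assignment for a Boolean model
#'
#' For bipartite models: components present (`TRUE`), inputs off unless
#' named in `inputs_on`, and all reactions, states and outputs `FALSE`.
#' For classical models everything starts `FALSE` except the inputs named
#' in `inputs_on` (components there encode activity, not presence).
#'
#' @param bm a `boolean_model`.
#' @param inputs_on character vector of input (or other) variables to set
#'   `TRUE` at t = 0.
#' @return named logical vector over `bm$variables`.
#' @export
default_init <- function(bm, inputs_on = character()) {
  stopifnot(inherits(bm, "boolean_model"))
  init <- stats::setNames(rep(FALSE, length(bm$variables)), bm$variables)
  if (bm$scheme == "bipartite") init[bm$roles == "component"] <- TRUE
  unknown <- setdiff(inputs_on, bm$variables)
  if (length(unknown)) stop("not model variables: ", paste(unknown, collapse = ", "))
  init[inputs_on] <- TRUE
  init
}

#' Build a perturbation schedule
#'
#' Events are applied at the start of their time step, before the rules
#' are evaluated. A clamped variable is excluded from rule updates and
#' held at the event value until a later non-clamp event on the same
#' variable releases it; a non-clamp event is a one-shot set (the
#' variable may immediately recover through its rule).
#'
#' @param t event times (non-negative integers).
#' @param var variable ids.
#' @param value logical values to set.
#' @param clamp logical; hold the value (default `FALSE`).
#' @return a tibble of events sorted by `t`, usable as the `schedule`
#'   argument of [run_sync()].
#' @examples
#' # turgor off at t = 27, back on at t = 50, pheromone pulse at t = 75
#' sched <- perturbations(t = c(27, 50, 75),
#'                        var = c("[Turgor]", "[Turgor]", "[MFalpha]"),
#'                        value = c(FALSE, TRUE, TRUE),
#'                        clamp = c(TRUE, TRUE, FALSE))
#' @export
perturbations <- function(t = integer(), var = character(), value = logical(),
                          clamp = FALSE) {
  ev <- tibble::tibble(t = as.integer(t), var = var, value = as.logical(value),
                       clamp = rep_len(as.logical(clamp), length(t)))
  stopifnot(all(ev$t >= 0L))
  dplyr::arrange(ev, t)
}

#' One synchronous update step
#'
#' Every non-clamped variable is updated simultaneously from the current
#' assignment; clamped variables keep their clamp value.
#'
#' @param bm a `boolean_model`.
#' @param assignment named logical vector, total over the variables.
#' @param clamps named logical vector of clamped values (may be `NULL`).
#' @return the successor assignment.
#' @export
sync_step <- function(bm, assignment, clamps = NULL) {
  s <- unname(assignment[bm$variables])
  nxt <- vapply(bm$compiled, function(ex) eval(ex, list(s = s)), logical(1))
  names(nxt) <- bm$variables
  if (length(clamps)) nxt[names(clamps)] <- clamps
  nxt
}

#' Run a synchronous simulation with attractor detection
#'
#' Iterates [sync_step()] from `init`, applying the perturbation schedule,
#' and detects revisited global states by hashing full assignments. The
#' detection window restarts after each perturbation event (events break
#' the determinism of the orbit). The first revisit fixes the attractor:
#' period 1 is a point attractor, otherwise a cyclic attractor with
#' minimal period (all states seen since the window start are distinct).
#' When future events remain scheduled the simulation keeps going so that
#' they are applied; the reported attractor is the one entered after the
#' last event.
#'
#' @param bm a `boolean_model`.
#' @param init initial assignment; default [default_init()].
#' @param schedule perturbation events, see [perturbations()]; or `NULL`.
#' @param max_steps step budget (default 1000).
#' @return a `trajectory`: assignments for t = 0..T, the events applied,
#'   and the attractor annotation (`NULL` with `converged = FALSE` if the
#'   budget ran out first).
#' @examples
#' bm <- build_bipartite(toy_crosstalk())
#' tr <- run_sync(bm, default_init(bm, inputs_on = "[Pher]"))
#' tr$attractor
#' at_attractor(tr)[c("[MATING]", "[TURGOR]")]
#' @export
run_sync <- function(bm, init = default_init(bm), schedule = NULL,
                     max_steps = 1000L) {
  stopifnot(inherits(bm, "boolean_model"), max_steps >= 1L)
  if (is.null(schedule)) {
    schedule <- perturbations()
  }
  a <- init[bm$variables]
  clamps <- stats::setNames(logical(), character())
  seen <- new.env(parent = emptyenv())
  window_start <- 0L
  traj <- matrix(NA, nrow = max_steps + 1L, ncol = length(bm$variables),
                 dimnames = list(NULL, bm$variables))
  attractor <- NULL
  t_end <- max_steps

  for (t in 0:max_steps) {
    ev <- schedule[schedule$t == t, ]
    if (nrow(ev)) {
      for (j in seq_len(nrow(ev))) {
        a[[ev$var[j]]] <- ev$value[j]
        if (ev$clamp[j]) clamps[ev$var[j]] <- ev$value[j]
        else clamps <- clamps[setdiff(names(clamps), ev$var[j])]
      }
      seen <- new.env(parent = emptyenv())
      window_start <- t
      attractor <- NULL
    }
    traj[t + 1L, ] <- a
    key <- paste(as.integer(a), collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev) && is.null(attractor)) {
      p <- t - prev
      attractor <- list(type = if (p == 1L) "point" else "cycle",
                        index = prev, period = p)
      if (max(schedule$t, -1L) <= t) { t_end <- t; break }
    }
    seen[[key]] <- t
    if (t == max_steps) { t_end <- t; break }
    a <- sync_step(bm, a, clamps)
  }
  structure(list(
    assignments = traj[seq_len(t_end + 1L), , drop = FALSE],
    roles = bm$roles,
    attractor = attractor,
    converged = !is.null(attractor),
    events = schedule
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$assignments) - 1L, " steps, ",
      ncol(x$assignments), " variables; ", sep = "")
  if (is.null(x$attractor)) cat("unconverged\n")
  else cat(x$attractor$type, " attractor (period ", x$attractor$period,
           ") entered at t = ", x$attractor$index, "\n", sep = "")
  invisible(x)
}

#' Assignment on the attractor
#'
#' The final recorded assignment, which lies on the detected attractor
#' (for a point attractor this is the steady state).
#' @param traj a `trajectory`.
#' @return named logical vector.
#' @export
at_attractor <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$assignments[nrow(traj$assignments), ]
}

#' Tidy a trajectory into long form
#' @param x a `trajectory`.
#' @param ... unused.
#' @return tibble with columns `time`, `variable`, `role`, `value`.
#' @method tidy trajectory
#' @export
tidy.trajectory <- function(x, ...) {
  m <- x$assignments
  tibble::tibble(
    time = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    variable = rep(colnames(m), each = nrow(m)),
    role = rep(unname(x$roles[colnames(m)]), each = nrow(m)),
    value = as.logical(m)
  )
}

#' @method glance trajectory
#' @export
glance.trajectory <- function(x, ...) {
  tibble::tibble(
    steps = nrow(x$assignments) - 1L,
    variables = ncol(x$assignments),
    converged = x$converged,
    attractor = if (is.null(x$attractor)) NA_character_ else x$attractor$type,
    period = if (is.null(x$attractor)) NA_integer_ else x$attractor$period,
    events = nrow(x$events)
  )
}

#' Asynchronous ensemble simulation
#'
#' Each run performs `n_steps` full passes over the variables; within a
#' pass the variables are updated one at a time in a fresh uniformly
#' random permutation, each update seeing the effects of the previous
#' ones. The returned matrix holds, per variable and time step, the
#' fraction of runs in which the variable was `TRUE` — the ensemble mean
#' activity. Reproducible for a given seed.
#'
#' @param bm a `boolean_model`.
#' @param init initial assignment (default [default_init()]).
#' @param n_runs number of independent runs (ensemble size).
#' @param n_steps number of full update passes per run.
#' @param seed RNG seed (required for reproducibility).
#' @param clamps named logical vector of variables held fixed throughout.
#' @return an `activity` object: matrix variables x time (t = 0..n_steps)
#'   with entries in `[0, 1]`; `n_runs` kept as an attribute.
#' @examples
#' bm <- build_bipartite(toy_crosstalk())
#' act <- run_async(bm, default_init(bm, "[Pher]"), n_runs = 50,
#'                  n_steps = 15, seed = 1)
#' act["[MATING]", ncol(act)]
#' @export
run_async <- function(bm, init = default_init(bm), n_runs = 100L,
                      n_steps = 30L, seed = 1L, clamps = NULL) {
  stopifnot(inherits(bm, "boolean_model"), n_runs >= 1L, n_steps >= 1L)
  nv <- length(bm$variables)
  idx_clamped <- match(names(clamps), bm$variables)
  acc <- matrix(0, nrow = nv, ncol = n_steps + 1L,
                dimnames = list(bm$variables, NULL))
  init <- init[bm$variables]
  if (length(clamps)) init[names(clamps)] <- clamps
  withr::with_seed(seed, {
    for (run in seq_len(n_runs)) {
      s <- unname(init)
      acc[, 1L] <- acc[, 1L] + s
      for (step in seq_len(n_steps)) {
        for (i in sample.int(nv)) {
          if (i %in% idx_clamped) next
          s[[i]] <- eval(bm$compiled[[i]], list(s = s))
        }
        acc[, step + 1L] <- acc[, step + 1L] + s
      }
    }
  })
  structure(acc / n_runs, n_runs = n_runs, class = c("activity", "matrix"))
}

#' @export
print.activity <- function(x, ...) {
  cat("<activity> mean of", attr(x, "n_runs"), "asynchronous runs;",
      nrow(x), "variables x", ncol(x) - 1L, "steps\n")
  invisible(x)
}

#' Tidy a mean-activity matrix into long form
#' @param x an `activity` object from [run_async()].
#' @param ... unused.
#' @return tibble with columns `time`, `variable`, `activity`.
#' @method tidy activity
#' @export
tidy.activity <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    time = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    variable = rep(rownames(m), times = ncol(m)),
    activity = as.numeric(m)
  )
}
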