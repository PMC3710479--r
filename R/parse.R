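#' Parse the "quick" text network format
#'
#' One reaction per line, optionally followed by `;`-separated contingency
#' clauses (`<sign> <effector>`), e.g.
#' `"Ssk1_ppi_Ssk2; x Ssk1-{P}"`. Signs are `!` (required), `x`
#' (inhibiting), `K+`/`K-` (quantitative positive/negative), `0` (no
#' effect) and `?` (unknown); they are case-insensitive. Bracketed tokens
#' name inputs when used as effectors and outputs when used as targets: a
#' line starting with a bracketed name (e.g. `"[MATING]; ! Ste12-{P}"`)
#' declares an output raised under the given conditions. Boolean nodes are
#' defined on their own line as `"<NAME> = AND(e1, e2, ...)"` (`OR`, `NOT`
#' likewise) and referenced as `<NAME>` in contingency clauses. Blank
#' lines and `#` comments are ignored; duplicate reaction lines are
#' merged.
#'
#' @param text the network definition (single string with newlines, or a
#'   character vector of lines).
#' @param registry reaction-type registry, see [reaction_types()].
#' @return an `rxncon_model`.
#' @examples
#' m <- parse_quick("
#'   Sln1_AP_Sln1; ! [Turgor]
#'   Ssk1_ppi_Ssk2; x Ssk1-{P}
#' ")
#' m
#' @export
parse_quick <- function(text, registry = reaction_types()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", lines)
  errors <- character()
  rx_rows <- list(); cg_rows <- list(); nodes <- list()

  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) next
    res <- tryCatch(parse_quick_line(line, registry), error = function(e)
      structure(conditionMessage(e), class = "qerr"))
    if (inherits(res, "qerr")) {
      errors <- c(errors, paste0("line ", ln, ": ", res))
      next
    }
    if (!is.null(res$node)) {
      nodes[[res$node$name]] <- res$node[c("op", "children")]
    } else {
      if (!is.null(res$reaction)) rx_rows <- c(rx_rows, list(res$reaction))
      if (nrow(res$contingencies)) cg_rows <- c(cg_rows, list(res$contingencies))
    }
  }
  if (length(errors)) {
    stop("quick-format syntax errors:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  rxncon(reactions = if (length(rx_rows)) dplyr::bind_rows(rx_rows) else NULL,
         contingencies = if (length(cg_rows)) dplyr::bind_rows(cg_rows) else NULL,
         bool_nodes = nodes, registry = registry)
}

parse_quick_line <- function(line, registry) {
  node_m <- regmatches(line, regexec(
    "^<([^>]+)>\\s*=\\s*(AND|OR|NOT)\\s*\\((.*)\\)\\s*$", line,
    ignore.case = TRUE))[[1]]
  if (length(node_m)) {
    children <- trimws(strsplit(node_m[4], ",", fixed = TRUE)[[1]])
    children <- children[nzchar(children)]
    return(list(node = list(name = node_m[2], op = toupper(node_m[3]),
                            children = children)))
  }
  segs <- trimws(strsplit(line, ";", fixed = TRUE)[[1]])
  head <- segs[1]
  if (is_bracketed(head)) {
    target <- head
    reaction <- NULL
  } else {
    reaction <- parse_reaction_id(head, registry)
    target <- reaction$id
  }
  cg <- lapply(segs[-1][nzchar(segs[-1])], function(cl) {
    m <- regmatches(cl, regexec("^(!|[xX]|[Kk][+-]|0|\\?)\\s+(\\S.*)$", cl))[[1]]
    if (!length(m)) stop("cannot parse contingency clause '", cl,
                         "' (expected '<sign> <effector>')", call. = FALSE)
    tibble::tibble(target = target, sign = m[2], effector = m[3])
  })
  list(reaction = reaction,
       contingencies = if (length(cg)) dplyr::bind_rows(cg) else
         tibble::tibble(target = character(), sign = character(),
                        effector = character()))
}

#' Serialise a model to quick text
#'
#' Inverse of [parse_quick()]: writes one line per reaction (with its
#' contingency clauses), one line per output target, and one definition
#' line per Boolean node. Reparsing the text yields an id-identical model.
#'
#' @param model an `rxncon_model`.
#' @param path optional file to write to.
#' @return the quick text, invisibly if `path` is given.
#' @export
write_quick <- function(model, path = NULL) {
  stopifnot(inherits(model, "rxncon_model"))
  clause <- function(target) {
    cg <- model$contingencies[model$contingencies$target == target, ]
    if (nrow(cg) == 0L) return("")
    paste0("; ", paste(paste(cg$sign, cg$effector), collapse = "; "))
  }
  lines <- c(
    vapply(names(model$bool_nodes), function(nm) {
      n <- model$bool_nodes[[nm]]
      sprintf("<%s> = %s(%s)", nm, n$op, paste(n$children, collapse = ", "))
    }, character(1)),
    vapply(model$reactions$id, function(id) paste0(id, clause(id)), character(1)),
    vapply(model$outputs, function(o) paste0(o, clause(o)), character(1))
  )
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

tab_col <- function(df, synonyms, required = TRUE, what = synonyms[1]) {
  hit <- match(synonyms, tolower(gsub("[^a-z]+", "_", tolower(names(df)))))
  hit <- hit[!is.na(hit)]
  if (!length(hit)) {
    if (required) stop("missing mandatory column '", what, "' (accepted names: ",
                       paste(synonyms, collapse = ", "), ")", call. = FALSE)
    return(NULL)
  }
  df[[hit[1]]]
}

#' Load a model from tabular reaction and contingency lists
#'
#' Mirrors the two-sheet tabular input convention: a reaction list defining
#' the topology and a contingency list defining the contextual constraints.
#' Column matching is case-insensitive and accepts the common synonyms
#' noted below; what is normative are the column *roles*, not positions.
#'
#' The reaction table needs either a full-id column (`reaction` /
#' `reaction_id` / `id`) or the component/type triple (`a` /
#' `component_a` / `componenta`, `type` / `reaction_type`, `b` /
#' `component_b`); in the latter case reaction ids are generated
#' automatically. The contingency table needs `target`, `sign` (or
#' `contingency`) and `effector` (or `modifier`). Rows whose target is a
#' `<Node>` reference define Boolean nodes: their sign column holds the
#' operator (`AND`/`OR`/`NOT`) and the modifier column one child per row.
#'
#' @param reaction_rows,contingency_rows data frames (or paths to
#'   tab/comma-separated files).
#' @param registry reaction-type registry.
#' @return an `rxncon_model`, identical to [parse_quick()] of the
#'   equivalent quick text.
#' @export
load_tabular <- function(reaction_rows, contingency_rows = NULL,
                         registry = reaction_types()) {
  read_any <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      sep <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
      utils::read.delim(x, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
    } else as.data.frame(x, stringsAsFactors = FALSE)
  }
  rdf <- read_any(reaction_rows)
  full <- tab_col(rdf, c("reaction", "reaction_id", "id"), required = FALSE)
  if (!is.null(full)) {
    rx <- tibble::tibble(reaction = full)
  } else {
    rx <- tibble::tibble(
      a = tab_col(rdf, c("a", "component_a", "componenta", "source"),
                  what = "component_a"),
      type = tab_col(rdf, c("type", "reaction_type", "reactiontype"),
                     what = "reaction_type"),
      b = tab_col(rdf, c("b", "component_b", "componentb", "target"),
                  what = "component_b"))
  }
  nodes <- list(); cg <- NULL
  if (!is.null(contingency_rows)) {
    cdf <- read_any(contingency_rows)
    if (nrow(cdf)) {
      ct <- tibble::tibble(
        target = tab_col(cdf, c("target", "targets")),
        sign = tab_col(cdf, c("sign", "contingency")),
        effector = tab_col(cdf, c("effector", "modifier")))
      nd <- is_node_ref(ct$target)
      for (nm in unique(ct$target[nd])) {
        rows <- ct[ct$target == nm, ]
        ops <- unique(toupper(rows$sign))
        if (length(ops) != 1L) {
          stop("Boolean node ", nm, " defined with mixed operators: ",
               paste(ops, collapse = ", "), call. = FALSE)
        }
        nodes[[substr(nm, 2, nchar(nm) - 1L)]] <-
          list(op = ops, children = rows$effector)
      }
      cg <- ct[!nd, ]
      # unresolved modifier ids: resolve against known states/inputs/nodes later,
      # but catch the obvious empty cells here
      if (any(!nzchar(trimws(cg$effector)))) {
        stop("contingency rows with empty modifier", call. = FALSE)
      }
    }
  }
  rxncon(reactions = rx, contingencies = cg, bool_nodes = nodes,
         registry = registry)
}

#' Export a model to tabular reaction and contingency lists
#'
#' @param model an `rxncon_model`.
#' @param reactions_path,contingencies_path optional TSV paths; when
#'   omitted the tibbles are returned instead.
#' @return `list(reactions = <tibble>, contingencies = <tibble>)`,
#'   invisibly if paths were given.
#' @export
write_tabular <- function(model, reactions_path = NULL,
                          contingencies_path = NULL) {
  stopifnot(inherits(model, "rxncon_model"))
  rx <- tibble::tibble(reaction = model$reactions$id,
                       component_a = model$reactions$a,
                       reaction_type = model$reactions$type,
                       component_b = model$reactions$b)
  nd <- dplyr::bind_rows(lapply(names(model$bool_nodes), function(nm) {
    n <- model$bool_nodes[[nm]]
    tibble::tibble(target = paste0("<", nm, ">"), sign = n$op,
                   effector = n$children)
  }))
  cg <- dplyr::bind_rows(nd, model$contingencies)
  if (!is.null(reactions_path)) {
    utils::write.table(rx, reactions_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(contingencies_path)) {
    utils::write.table(cg, contingencies_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  res <- list(reactions = rx, contingencies = cg)
  if (is.null(reactions_path) && is.null(contingencies_path)) res
  else invisible(res)
}
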