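#' Reaction-type registry
#'
#' Each reaction type maps a reaction `A_<type>_B` to the elemental states
#' it produces and consumes, and records whether the reaction is reversible
#' (its products decay when the reaction goes off) and directed (catalyst
#' versus substrate roles differ). Templates are written over the two
#' component slots `A` and `B`: `"A--B"` is the bond between them, `"B-{P}"`
#' a phosphorylation of B, and a bare `"B"` the presence of component B
#' itself (used by synthesis and degradation types).
#'
#' The built-in registry covers the types used by the packaged fixtures and
#' the yeast MAPK case study: reversible binding (`ppi`, `i`), kinase and
#' phosphatase chemistry (`P+`, `P-`, `AP`, `PT`), ubiquitination
#' (`Ub+`, `Ub-`), nucleotide exchange (`GEF`, `GAP`), transcriptional
#' synthesis (`TRSC`) and degradation (`DEG`). Phosphotransfer (`PT`) moves
#' the phosphate: it consumes `A-{P}` and produces `B-{P}`, and is treated
#' as irreversible by default (override via [read_registry()]).
#'
#' @return a tibble with columns `symbol`, `reversible`, `directed`,
#'   `produces`, `consumes` (the last two are comma-separated template
#'   lists, possibly empty).
#' @examples
#' reaction_types()
#' @export
reaction_types <- function() {
  tibble::tribble(
    ~symbol, ~reversible, ~directed, ~produces, ~consumes,
    "ppi",   TRUE,  FALSE, "A--B",    "",
    "i",     TRUE,  FALSE, "A--B",    "",
    "P+",    FALSE, TRUE,  "B-{P}",   "",
    "P-",    FALSE, TRUE,  "",        "B-{P}",
    "AP",    FALSE, TRUE,  "A-{P}",   "",
    "PT",    FALSE, TRUE,  "B-{P}",   "A-{P}",
    "Ub+",   FALSE, TRUE,  "B-{Ub}",  "",
    "Ub-",   FALSE, TRUE,  "",        "B-{Ub}",
    "GEF",   FALSE, TRUE,  "B-{GTP}", "",
    "GAP",   FALSE, TRUE,  "",        "B-{GTP}",
    "TRSC",  FALSE, TRUE,  "B",       "",
    "DEG",   FALSE, TRUE,  "",        "B"
  )
}

#' Read a reaction-type registry from a plain-text config
#'
#' One type per line, tab- or comma-separated fields:
#' `symbol  reversible  directed  produces  consumes`, where the template
#' fields are `;`-separated lists (empty field = no templates). Lines
#' starting with `#` are comments. Entries override or extend the default
#' registry.
#'
#' @param path path to the config file.
#' @param base registry to extend (default [reaction_types()]).
#' @return a registry tibble.
#' @export
read_registry <- function(path, base = reaction_types()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "[\t,]")[[1]]
    f <- trimws(f)
    if (length(f) < 3L) stop("registry line needs at least symbol, reversible, directed: ", l)
    length(f) <- 5L
    f[is.na(f)] <- ""
    tibble::tibble(
      symbol = f[1],
      reversible = toupper(f[2]) %in% c("TRUE", "T", "1", "YES"),
      directed = toupper(f[3]) %in% c("TRUE", "T", "1", "YES"),
      produces = gsub(";", ",", f[4]),
      consumes = gsub(";", ",", f[5])
    )
  })
  new <- dplyr::bind_rows(rows)
  check_registry(dplyr::bind_rows(new, dplyr::anti_join(base, new, by = "symbol")))
}

check_registry <- function(reg) {
  if (anyDuplicated(reg$symbol)) {
    stop("duplicate reaction-type symbols: ",
         paste(unique(reg$symbol[duplicated(reg$symbol)]), collapse = ", "))
  }
  tmpl <- function(x) unlist(strsplit(x, ","))
  for (i in seq_len(nrow(reg))) {
    tm <- c(tmpl(reg$produces[i]), tmpl(reg$consumes[i]))
    tm <- trimws(tm[nzchar(trimws(tm))])
    bad <- tm[!grepl("^(A--B|[AB](-\\{[A-Za-z0-9]+\\})?)$", tm)]
    if (length(bad)) {
      stop("invalid state template(s) for type '", reg$symbol[i], "': ",
           paste(bad, collapse = ", "))
    }
    if (reg$reversible[i] && !any(nzchar(tmpl(reg$produces[i])))) {
      stop("reversible type '", reg$symbol[i],
           "' must produce at least one state (its products decay)")
    }
  }
  reg
}

registry_entry <- function(registry, symbol) {
  i <- match(symbol, registry$symbol)
  if (is.na(i)) {
    # reaction-type symbols are conventionally case-sensitive, but tolerate
    # case slips in hand-written input
    i <- match(toupper(symbol), toupper(registry$symbol))
  }
  if (is.na(i)) {
    stop("unknown reaction type '", symbol, "'; registered types: ",
         paste(registry$symbol, collapse = ", "), call. = FALSE)
  }
  registry[i, ]
}

split_templates <- function(x) {
  t <- trimws(unlist(strsplit(x, ",")))
  t[nzchar(t)]
}

# Instantiate a state template with concrete components. Bond states are
# order-normalised lexicographically so A--B and B--A name the same state.
instantiate_template <- function(tmpl, a, b) {
  if (tmpl == "A--B") return(canonical_bond(a, b))
  slot <- substr(tmpl, 1, 1)
  comp <- if (slot == "A") a else b
  paste0(comp, substr(tmpl, 2, nchar(tmpl)))
}

canonical_bond <- function(a, b) {
  p <- sort(c(a, b))
  paste0(p[1], "--", p[2])
}

state_kind <- function(id) {
  if (grepl("--", id, fixed = TRUE)) "bond"
  else if (grepl("-\\{", id)) "modification"
  else "presence"
}

state_components <- function(id) {
  switch(state_kind(id),
    bond = strsplit(id, "--", fixed = TRUE)[[1]],
    modification = sub("-\\{.*$", "", id),
    id
  )
}
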