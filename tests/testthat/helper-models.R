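# shared helpers: independent oracles and tiny fixture builders

# naive reference evaluator for bool_expr, independent of eval_expr
ref_eval <- function(e, env) {
  k <- e$kind
  if (k == "const") return(e$value)
  if (k == "atom") return(env[[e$var]])
  if (k == "not") return(!ref_eval(e$child, env))
  vals <- sapply(e$children, ref_eval, env = env)
  if (k == "and") all(vals) else any(vals)
}

# random expression generator over a variable pool (for property tests)
random_expr <- function(vars, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.15) {
      return(if (stats::runif(1) < 0.5) b_true() else b_false())
    }
    return(b_atom(sample(vars, 1L)))
  }
  op <- sample(c("and", "or", "not"), 1L)
  if (op == "not") return(b_not(random_expr(vars, depth - 1L)))
  kids <- lapply(seq_len(sample(2:3, 1L)), function(i) random_expr(vars, depth - 1L))
  if (op == "and") b_and(kids) else b_or(kids)
}

# random executable boolean model with n variables
random_boolean_model <- function(n = 5L, seed = 1L) {
  withr::with_seed(seed, {
    vars <- paste0("V", seq_len(n))
    rules <- lapply(vars, function(v) random_expr(vars, depth = 2L))
    names(rules) <- vars
    boolean_model(rules)
  })
}

# all 2^n assignments over the given variables, as a list of named vectors
all_assignments <- function(vars) {
  n <- length(vars)
  lapply(0:(2^n - 1L), function(code) {
    stats::setNames(bitwAnd(code %/% 2^(seq_len(n) - 1L), 1L) == 1L, vars)
  })
}

# symbolic one-step substitution: plug the model's rules in for the atoms
subst_rules <- function(e, rules) {
  k <- e$kind
  if (k == "const") return(e)
  if (k == "atom") return(rules[[e$var]])
  if (k == "not") return(b_not(subst_rules(e$child, rules)))
  kids <- lapply(e$children, subst_rules, rules = rules)
  if (k == "and") b_and(kids) else b_or(kids)
}

# canonical attractor fingerprint: sorted member-key sets
attractor_fingerprint <- function(tg) {
  sort(vapply(tg$attractors, function(a)
    paste(sort(a$members), collapse = "|"), character(1)))
}
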