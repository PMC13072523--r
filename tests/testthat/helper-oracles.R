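# Independent naive oracles: plain scalar loops, no shared code with the
# engine's vectorised arithmetic.

oracle_weighted <- function(model, weights, strategy = model$weighting_strategy) {
  ids <- model$entities$id
  n <- length(ids)
  delta <- ifelse(model$entities$double, 2, 1)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- abs(model$matrix[i, j]) * weights[[ids[i]]] * delta[i]
      if (strategy == "row_col") v <- v * weights[[ids[j]]] * delta[j]
      out[i, j] <- v
    }
  }
  out
}

oracle_sums <- function(wm) {
  n <- nrow(wm)
  as_ <- numeric(n); ps_ <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      as_[i] <- as_[i] + wm[i, j]
      ps_[i] <- ps_[i] + wm[j, i]
    }
  }
  list(active = setNames(as_, rownames(wm)),
       passive = setNames(ps_, rownames(wm)))
}

oracle_total <- function(wm) {
  s <- oracle_sums(wm)
  sum(s$active) + sum(s$passive)
}

# All admissible weight combinations of a model as a data frame.
all_assessments <- function(model) {
  domains <- setNames(model$entities$weight_domain, model$entities$id)
  expand.grid(domains, KEEP.OUT.ATTRS = FALSE)
}

# Brute-force score over every admissible assessment via the scalar oracle.
oracle_all_scores <- function(model, strategy = model$weighting_strategy) {
  grid <- all_assessments(model)
  vapply(seq_len(nrow(grid)), function(k) {
    oracle_total(oracle_weighted(model, as.list(grid[k, , drop = FALSE]),
                                 strategy))
  }, 1)
}

toy3_base_assessment <- function() {
  rimeda_assessment(c(X1 = 2, X2 = 1, X3 = -3), label = "toy3 base")
}
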