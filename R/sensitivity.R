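## Exploration of the admissible weight space: exact score bounds, index
## ranges, what-if deltas, exhaustive / Monte-Carlo sweeps.
##
## Key structural facts exploited here:
##  * With a zero diagonal, the total score is multilinear in the per-entity
##    signed weights under both shipped strategies, so its extremes over the
##    admissible weight box occur with every entity at a domain endpoint.
##  * Under the `row` strategy the score is linear with nonnegative
##    per-entity coefficients 2 * delta_i * sum_j |m(i,j)|, so the extremes
##    are simply the per-entity domain extremes.
##  * Under `row`, an entity's passive sum depends only on the *other*
##    entities' weights, each through an independent term, so the exact set
##    of achievable passive sums is a Minkowski sum of tiny integer sets —
##    which makes exact Q-value ranges cheap without enumerating the
##    (possibly millions of) full assessments.

EXHAUSTIVE_CAP <- 1e6

scaled_domains <- function(model) {
  d <- entity_deltas(model)
  mapply(function(dom, dl) as.integer(dom * dl), entity_domains(model), d,
         SIMPLIFY = FALSE)
}

abs_row_sums <- function(model) rowSums(abs(unclass(model$matrix)))

n_combinations <- function(model) {
  prod(vapply(entity_domains(model), length, 1L))
}

## Evaluate total scores for a matrix of weight rows (one assessment per row).
scores_for_weights <- function(model, W, strategy = model$weighting_strategy) {
  d <- entity_deltas(model)
  X <- sweep(W, 2, d[colnames(W)], `*`)
  A <- abs(unclass(model$matrix))
  if (strategy == "row") {
    2 * drop(X %*% rowSums(A))
  } else {
    2 * rowSums((X %*% A) * X)
  }
}

endpoint_grid <- function(domains) {
  ends <- lapply(domains, function(d) unique(range(d)))
  as.matrix(expand.grid(ends, KEEP.OUT.ATTRS = FALSE))
}

#' Exact achievable bounds of the total risk score
#'
#' Computes the exact minimum and maximum total score over all admissible
#' assessments, together with assessments achieving them. Under the `row`
#' strategy this uses the linearity shortcut (per-entity domain extremes);
#' under `row_col` the score is still multilinear (zero diagonal), so exact
#' bounds come from enumerating the `2^n` per-entity endpoint corners.
#'
#' @param model a [rimeda_model()].
#' @return list with `min`, `max`, `assessment_min`, `assessment_max`
#'   (named weight vectors) and `method`.
#' @export
score_bounds <- function(model) {
  stopifnot(inherits(model, "rimeda_model"))
  domains <- entity_domains(model)
  ids <- names(domains)
  if (model$weighting_strategy == "row") {
    coef <- 2 * entity_deltas(model) * abs_row_sums(model)   # >= 0
    w_min <- vapply(domains, min, 1L)
    w_max <- vapply(domains, max, 1L)
    return(list(min = sum(coef * w_min), max = sum(coef * w_max),
                assessment_min = w_min, assessment_max = w_max,
                method = "linear"))
  }
  if (length(ids) > 20) {
    stop("endpoint enumeration over ", length(ids),
         " entities exceeds the supported size")
  }
  W <- endpoint_grid(domains)
  colnames(W) <- ids
  s <- scores_for_weights(model, W)
  i_min <- which.min(s); i_max <- which.max(s)
  list(min = s[i_min], max = s[i_max],
       assessment_min = setNames(as.integer(W[i_min, ]), ids),
       assessment_max = setNames(as.integer(W[i_max, ]), ids),
       method = "endpoint_corners")
}

## Exact set of achievable values of sum_j x_j * c_j over independent
## discrete x_j in `sets` with nonnegative integer coefficients c_j.
minkowski_values <- function(sets, coefs) {
  acc <- 0L
  for (j in seq_along(sets)) {
    if (coefs[j] == 0L) next
    acc <- unique(as.vector(outer(acc, sets[[j]] * coefs[j], `+`)))
  }
  sort(acc)
}

#' Extremes of the per-entity indices over all admissible assessments
#'
#' Returns the exact overall ranges of the active sums, passive sums and
#' Q-values attainable by any admissible assessment. Under the `row`
#' strategy the ranges are computed analytically: active sums are separable
#' per entity; a passive sum is a sum of independent per-entity terms; and
#' an entity's Q-value couples its own weight with an achievable passive
#' sum from the *other* entities, whose exact value set is computed by
#' dynamic programming (Minkowski sums). Under `row_col` the Q-values are
#' not separable, so the function enumerates all assessments when their
#' number is at most `cap` and refuses otherwise.
#'
#' @param model a [rimeda_model()].
#' @param cap maximum number of assessments for exhaustive enumeration
#'   (`row_col` only).
#' @return list with `active`, `passive`, `q` (each `c(min, max)`) and a
#'   per-entity data frame `per_entity`.
#' @export
index_ranges <- function(model, cap = EXHAUSTIVE_CAP) {
  stopifnot(inherits(model, "rimeda_model"))
  ids <- entity_ids(model)
  A <- abs(unclass(model$matrix))
  xsets <- scaled_domains(model)
  if (model$weighting_strategy == "row") {
    R <- abs_row_sums(model)
    per <- lapply(seq_along(ids), function(i) {
      as_vals <- xsets[[i]] * R[i]
      ps_set <- minkowski_values(xsets[-i], A[-i, i])
      qs <- as.vector(outer(xsets[[i]] * R[i], ps_set,
                            function(a, p) q_value(a, p, model$q_convention)))
      data.frame(entity = ids[i],
                 active_min = min(as_vals), active_max = max(as_vals),
                 passive_min = min(ps_set), passive_max = max(ps_set),
                 q_min = min(qs), q_max = max(qs))
    })
    per <- do.call(rbind, per)
  } else {
    n_comb <- n_combinations(model)
    if (n_comb > cap) {
      stop("index_ranges under strategy 'row_col' needs exhaustive ",
           "enumeration; ", format(n_comb, big.mark = ","),
           " combinations exceed the cap of ", format(cap, big.mark = ","))
    }
    W <- as.matrix(expand.grid(entity_domains(model),
                               KEEP.OUT.ATTRS = FALSE))
    colnames(W) <- ids
    X <- sweep(W, 2, entity_deltas(model)[ids], `*`)
    AS <- X * (X %*% t(A))          # AS_i = x_i * sum_j x_j |m(i,j)|
    PS <- X * (X %*% A)             # PS_i = x_i * sum_j x_j |m(j,i)|
    Q <- q_value(AS, PS, model$q_convention)
    per <- data.frame(entity = ids,
                      active_min = apply(AS, 2, min),
                      active_max = apply(AS, 2, max),
                      passive_min = apply(PS, 2, min),
                      passive_max = apply(PS, 2, max),
                      q_min = apply(Q, 2, min),
                      q_max = apply(Q, 2, max))
  }
  rownames(per) <- NULL
  list(active = c(min = min(per$active_min), max = max(per$active_max)),
       passive = c(min = min(per$passive_min), max = max(per$passive_max)),
       q = c(min = min(per$q_min), max = max(per$q_max)),
       per_entity = per)
}

#' What-if analysis: substitute weights and measure the score change
#'
#' Recomputes the risk result after replacing selected entity weights,
#' returning the new result alongside the score delta. This
#' operationalises the lever reading of the Q-values: how much does acting
#' on an entity move the total risk?
#'
#' @param model a [rimeda_model()].
#' @param assessment the baseline [rimeda_assessment()].
#' @param changes named integer vector / list mapping entity ids to new
#'   weights (must be admissible).
#' @return list with `result` (new `rimeda_result`), `old_result`,
#'   `delta` (new minus old score), and `band_transition`.
#' @export
what_if <- function(model, assessment, changes) {
  ch <- unlist(changes)
  if (length(ch) == 0) stop("no changes given")
  unknown <- setdiff(names(ch), entity_ids(model))
  if (length(unknown) > 0) {
    stop("unknown entity in changes: ", paste(unknown, collapse = ", "))
  }
  old <- compute_risk(model, assessment)
  w <- assessment$weights
  w[names(ch)] <- as.integer(ch)
  new_assessment <- rimeda_assessment(w, label = assessment$label,
                                      notes = assessment$notes)
  assert_valid_assessment(new_assessment, model)
  new <- compute_risk(model, new_assessment)
  list(result = new, old_result = old,
       delta = new$total_score - old$total_score,
       band_transition = c(from = old$band, to = new$band))
}

#' Sweep the admissible weight space
#'
#' Either enumerates every admissible assessment (`mode = "exhaustive"`,
#' refused above `cap` combinations with guidance to use Monte Carlo) or
#' samples `n` assessments with per-entity uniform, independent draws
#' (`mode = "monte_carlo"`, deterministic given `seed`). Reports the
#' score distribution, the extreme scores with achieving assessments, and
#' each entity's leverage — the largest score change obtainable by varying
#' only that entity's weight (all others at their domain maxima; under the
#' `row` strategy this is exactly `2 * delta_i * sum_j |m(i,j)| *
#' (max domain - min domain)` independent of the context).
#'
#' @param model a [rimeda_model()].
#' @param mode `"exhaustive"` or `"monte_carlo"`.
#' @param n number of Monte-Carlo draws.
#' @param seed integer seed for Monte-Carlo mode.
#' @param breaks histogram bin count hint (passed to [graphics::hist()]).
#' @param cap exhaustive-mode hard cap on combinations.
#' @return object of class `rimeda_sweep`: `mode`, `n_evaluated`,
#'   `score_min`, `score_max`, `assessment_min`, `assessment_max`,
#'   `histogram` (list of `breaks`, `counts`), `per_entity_leverage`,
#'   `seed`.
#' @export
sweep_assessments <- function(model, mode = c("monte_carlo", "exhaustive"),
                              n = 1000, seed = 1,
                              breaks = 30, cap = EXHAUSTIVE_CAP) {
  stopifnot(inherits(model, "rimeda_model"))
  mode <- match.arg(mode)
  domains <- entity_domains(model)
  ids <- names(domains)
  if (mode == "exhaustive") {
    n_comb <- n_combinations(model)
    if (n_comb > cap) {
      stop("exhaustive sweep refused: ", format(n_comb, big.mark = ","),
           " combinations exceed the cap of ", format(cap, big.mark = ","),
           "; use mode = 'monte_carlo' with a seed instead")
    }
    W <- as.matrix(expand.grid(domains, KEEP.OUT.ATTRS = FALSE))
    seed_used <- NA_integer_
  } else {
    if (n < 1) stop("monte_carlo mode needs n >= 1")
    W <- with_preserved_seed(seed, {
      vapply(domains,
             function(d) d[sample.int(length(d), n, replace = TRUE)],
             numeric(n))
    })
    if (n == 1) W <- matrix(W, nrow = 1)
    seed_used <- as.integer(seed)
  }
  colnames(W) <- ids
  s <- scores_for_weights(model, W)
  i_min <- which.min(s); i_max <- which.max(s)
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  structure(list(
    mode = mode, n_evaluated = length(s),
    score_min = s[i_min], score_max = s[i_max],
    assessment_min = setNames(as.integer(W[i_min, ]), ids),
    assessment_max = setNames(as.integer(W[i_max, ]), ids),
    histogram = list(breaks = h$breaks, counts = h$counts),
    per_entity_leverage = entity_leverage(model),
    seed = seed_used
  ), class = "rimeda_sweep")
}

#' Per-entity leverage on the total score
#'
#' The largest change of the total score achievable by varying a single
#' entity's weight over its admissible domain. Exact closed form under the
#' `row` strategy; evaluated with all other entities at their domain maxima
#' under `row_col`.
#'
#' @param model a [rimeda_model()].
#' @return named numeric vector.
#' @export
entity_leverage <- function(model) {
  domains <- entity_domains(model)
  ids <- names(domains)
  d <- entity_deltas(model)
  if (model$weighting_strategy == "row") {
    R <- abs_row_sums(model)
    span <- vapply(domains, function(x) max(x) - min(x), 1)
    return(setNames(2 * d * R * span, ids))
  }
  w_max <- vapply(domains, max, 1L)
  out <- vapply(seq_along(ids), function(i) {
    scores <- vapply(domains[[i]], function(v) {
      w <- w_max; w[i] <- v
      scores_for_weights(model, matrix(w, 1, dimnames = list(NULL, ids)))
    }, 1)
    max(scores) - min(scores)
  }, 1)
  setNames(out, ids)
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' @export
print.rimeda_sweep <- function(x, ...) {
  cat(sprintf("<rimeda_sweep %s, %d assessments>\n", x$mode, x$n_evaluated))
  cat(sprintf("  score range observed: [%s, %s]\n",
              format(x$score_min), format(x$score_max)))
  invisible(x)
}
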