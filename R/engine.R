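## Core index computation: weighted matrix, active/passive sums, Q-values,
## total risk score, factor categories.

#' Combine the influence matrix with an assessment
#'
#' The system dynamics (the influence matrix) are combined with the data
#' controller's weighting: each cell's modulus `|m(i,j)|` is scaled by the
#' signed weight of the influencing entity i (strategy `"row"`), optionally
#' also by the weight of the influenced entity j (strategy `"row_col"`).
#' Entities flagged as double impact the system with double point values; a
#' negative weight (technical/organisational inhibitors) carries its sign
#' into the cells, making risk-reducing sums representable.
#'
#' @param model a [rimeda_model()].
#' @param assessment a valid [rimeda_assessment()] for the model.
#' @param strategy weighting strategy; defaults to the model's.
#' @return object of class `rimeda_weighted`: the weighted matrix plus the
#'   weights and strategy that produced it.
#' @export
apply_weights <- function(model, assessment,
                          strategy = model$weighting_strategy) {
  stopifnot(inherits(model, "rimeda_model"))
  strategy <- match.arg(strategy, c("row", "row_col"))
  assert_valid_assessment(assessment, model)
  ids <- entity_ids(model)
  x <- assessment$weights[ids] * entity_deltas(model)[ids]
  base <- abs(unclass(model$matrix))
  values <- switch(strategy,
    row     = base * x,                 # recycles x down columns: row scaling
    row_col = base * x * rep(x, each = length(x))
  )
  dimnames(values) <- dimnames(model$matrix)
  structure(list(entity_order = ids, values = values, strategy = strategy,
                 weights = assessment$weights[ids]),
            class = "rimeda_weighted")
}

#' Active and passive sums of a weighted matrix
#'
#' The active sum of an entity is its row aggregate — the cumulative
#' influence strength the entity exerts on the system. The passive sum is
#' the column aggregate — the cumulative influence the system exerts on the
#' entity. On an unweighted matrix (unit weights) these reduce to the sums
#' of absolute cell values; on a weighted matrix the cells already carry the
#' assessment's sign.
#'
#' @param weighted a `rimeda_weighted` from [apply_weights()].
#' @param entity optional single entity id; if given, the scalar sum for
#'   that entity is returned.
#' @return named numeric vector over all entities, or a scalar.
#' @export
active_sums <- function(weighted, entity = NULL) {
  stopifnot(inherits(weighted, "rimeda_weighted"))
  s <- rowSums(weighted$values)
  pick_entity(s, entity, weighted$entity_order)
}

#' @rdname active_sums
#' @export
passive_sums <- function(weighted, entity = NULL) {
  stopifnot(inherits(weighted, "rimeda_weighted"))
  s <- colSums(weighted$values)
  pick_entity(s, entity, weighted$entity_order)
}

pick_entity <- function(s, entity, order) {
  if (is.null(entity)) return(s)
  if (!entity %in% order) stop("unknown entity id: ", entity)
  s[[entity]]
}

#' Q-value of an entity
#'
#' The Q-value measures how strongly an entity is cross-linked with the
#' rest of the system: the product of its active and passive sums. A
#' positive Q indicates a risk-increasing, a negative Q a risk-reducing
#' effect. Under the default `"active_sign"` convention Q is `|AS * PS|`
#' carrying the sign of the active sum, which preserves that interpretation
#' when both sums are negative; `"product"` is the raw product `AS * PS`.
#'
#' @param active,passive numeric vectors of active and passive sums
#'   (recycled together).
#' @param convention `"active_sign"` (default) or `"product"`.
#' @return numeric vector of Q-values.
#' @export
q_value <- function(active, passive, convention = "active_sign") {
  convention <- match.arg(convention, c("active_sign", "product"))
  switch(convention,
    product     = active * passive,
    active_sign = sign(active) * abs(active * passive)
  )
}

#' Total risk score of a weighted matrix
#'
#' The sum of all active sums plus all passive sums: the scalar measure of
#' the overall re-identification risk system. Since every cell contributes
#' once to a row sum and once to a column sum, the score equals twice the
#' sum of all weighted cells; this identity is asserted internally.
#'
#' @param weighted a `rimeda_weighted`.
#' @return scalar score.
#' @export
total_risk_score <- function(weighted) {
  stopifnot(inherits(weighted, "rimeda_weighted"))
  total <- sum(rowSums(weighted$values)) + sum(colSums(weighted$values))
  stopifnot(isTRUE(all.equal(total, 2 * sum(weighted$values))))
  total
}

#' Classify entities into system-behaviour categories
#'
#' Entities fall into four categories by the relative magnitude of their
#' active and passive sums: *active* (impulsive drivers: pronounced |AS|,
#' low |PS|), *reactive* (strongly influenced: low |AS|, pronounced |PS|),
#' *critical* (both pronounced: dynamic, strongly interconnected), and
#' *inert* (both low: buffering, near-isolated). The default scheme
#' compares each entity's |AS| and |PS| against the across-entity means;
#' ties (a magnitude exactly equal to the mean) count as "pronounced".
#' If every sum is zero, all entities are inert.
#'
#' @param active,passive numeric vectors of sums, named by entity.
#' @param scheme `"mean"` (default), `"median"`, or a list
#'   `list(active = cut, passive = cut)` of fixed cut-offs.
#' @return character vector of categories, named like `active`.
#' @export
classify_factors <- function(active, passive, scheme = "mean") {
  stopifnot(length(active) == length(passive), length(active) >= 2)
  a <- abs(active); p <- abs(passive)
  if (all(a == 0) && all(p == 0)) {
    return(setNames(rep("inert", length(a)), names(active)))
  }
  if (is.list(scheme)) {
    cut_a <- scheme$active; cut_p <- scheme$passive
  } else {
    scheme <- match.arg(scheme, c("mean", "median"))
    cut_a <- if (scheme == "mean") mean(a) else stats::median(a)
    cut_p <- if (scheme == "mean") mean(p) else stats::median(p)
  }
  cat <- ifelse(a >= cut_a & p < cut_p, "active",
         ifelse(a < cut_a & p >= cut_p, "reactive",
         ifelse(a >= cut_a & p >= cut_p, "critical", "inert")))
  setNames(cat, names(active))
}

#' Compute the full risk result for an assessment
#'
#' Orchestrates the whole pipeline: weighting, active/passive sums,
#' Q-values, factor categories, total risk score, and band stratification.
#' Stored values are exact (no display rounding); rounding-up happens only
#' in the chart renderers.
#'
#' @param model a [rimeda_model()].
#' @param assessment a valid [rimeda_assessment()].
#' @param scheme classification scheme, see [classify_factors()].
#' @return object of class `rimeda_result` with fields `indices` (data
#'   frame: entity, perspective, weight, active_sum, passive_sum, q_value,
#'   category), `total_score`, `score_bounds`, `band`, `assessment`,
#'   `model_id`, `strategy`, `q_convention`.
#' @export
compute_risk <- function(model, assessment, scheme = "mean") {
  weighted <- apply_weights(model, assessment)
  as_ <- active_sums(weighted)
  ps_ <- passive_sums(weighted)
  q <- q_value(as_, ps_, model$q_convention)
  category <- classify_factors(as_, ps_, scheme)
  total <- total_risk_score(weighted)
  indices <- data.frame(
    entity = entity_ids(model),
    perspective = model$entities$perspective,
    weight = as.integer(assessment$weights[entity_ids(model)]),
    active_sum = as.numeric(as_),
    passive_sum = as.numeric(ps_),
    q_value = as.numeric(q),
    category = as.character(category),
    row.names = NULL
  )
  structure(
    list(indices = indices, total_score = total,
         score_bounds = model$score_bounds,
         band = stratify_score(total, model$score_bounds, model$bands),
         assessment = assessment, model_id = model$id,
         strategy = weighted$strategy, q_convention = model$q_convention),
    class = "rimeda_result"
  )
}

#' @export
print.rimeda_result <- function(x, ...) {
  cat(sprintf("<rimeda_result for model '%s'>\n", x$model_id))
  cat(sprintf("  total risk score: %s of [%s, %s]  ->  band '%s'\n",
              format(x$total_score), format(x$score_bounds[["min"]]),
              format(x$score_bounds[["max"]]), x$band))
  print(x$indices, row.names = FALSE)
  invisible(x)
}
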