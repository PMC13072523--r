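## Risk-band stratification and lever / countermeasure analysis.

#' Define a risk-band scheme
#'
#' Bands stratify the total score into ordered risk classes. The default is
#' four equal-width bands over the model's achievable score range, labelled
#' low / moderate / high / critical; custom ascending edges may be supplied
#' instead (first edge = achievable minimum, last = achievable maximum).
#'
#' @param mode `"equal_width"` or `"custom"`.
#' @param n_bands number of bands (>= 2) for `equal_width`.
#' @param labels band labels, lowest first; length `n_bands`.
#' @param custom_edges ascending numeric edges (length `n_bands + 1`) for
#'   `mode = "custom"`.
#' @return object of class `rimeda_bands`.
#' @export
risk_bands <- function(mode = "equal_width", n_bands = 4,
                       labels = c("low", "moderate", "high", "critical"),
                       custom_edges = NULL) {
  mode <- match.arg(mode, c("equal_width", "custom"))
  n_bands <- as.integer(n_bands)
  if (n_bands < 2) stop("a band scheme needs at least 2 bands")
  if (length(labels) != n_bands) {
    stop(sprintf("need %d labels, got %d", n_bands, length(labels)))
  }
  if (mode == "custom") {
    if (is.null(custom_edges) || length(custom_edges) != n_bands + 1) {
      stop("custom mode needs n_bands + 1 edges")
    }
    if (any(diff(custom_edges) <= 0)) stop("edges must be strictly ascending")
  }
  structure(list(mode = mode, n_bands = n_bands,
                 labels = as.character(labels),
                 custom_edges = custom_edges),
            class = "rimeda_bands")
}

#' Band edges of a scheme over given score bounds
#'
#' @param scheme a [risk_bands()].
#' @param bounds numeric `c(min, max)` achievable score bounds.
#' @return numeric vector of `n_bands + 1` ascending edges.
#' @export
band_edges <- function(scheme, bounds) {
  stopifnot(inherits(scheme, "rimeda_bands"))
  lo <- unname(bounds[[1]]); hi <- unname(bounds[[2]])
  if (scheme$mode == "custom") {
    e <- scheme$custom_edges
    if (e[1] != lo || e[length(e)] != hi) {
      stop(sprintf("custom edges must span the achievable range [%s, %s]",
                   format(lo), format(hi)))
    }
    return(e)
  }
  seq(lo, hi, length.out = scheme$n_bands + 1)
}

#' Stratify a score into its risk band
#'
#' Bands are half-open intervals `[edge_k, edge_{k+1})`; the top band is
#' closed so the achievable maximum maps to the highest label. Higher
#' scores never map to lower bands.
#'
#' @param score total risk score.
#' @param bounds achievable `c(min, max)` of the model.
#' @param scheme a [risk_bands()].
#' @return band label (character scalar).
#' @export
stratify_score <- function(score, bounds, scheme = risk_bands()) {
  lo <- unname(bounds[[1]]); hi <- unname(bounds[[2]])
  if (score < lo || score > hi) {
    stop(sprintf(
      "score %s outside achievable bounds [%s, %s]: model/assessment mismatch",
      format(score), format(lo), format(hi)))
  }
  edges <- band_edges(scheme, bounds)
  k <- findInterval(score, edges, rightmost.closed = TRUE)
  scheme$labels[min(k, scheme$n_bands)]
}

#' Rank controllable entities as levers and pair them with countermeasures
#'
#' The higher an entity's Q-value, the more suitable it is as a "lever" for
#' influencing the system — provided the data controller can act on it.
#' Controllable entities with positive Q are risk-increasing levers, ranked
#' by descending Q and paired with the model's countermeasure hints
#' (e.g. generalisation, suppression, randomisation for data-side
#' entities); controllable entities with negative Q are protective levers
#' to maintain, ranked by ascending Q (strongest inhibitor first). Entities
#' with Q = 0 or without controllability are listed in `other` so every
#' entity appears exactly once across the three tables.
#'
#' @param result a `rimeda_result` from [compute_risk()].
#' @param model the [rimeda_model()] the result was computed with.
#' @return list of data frames `risk_levers`, `protective_levers`, `other`,
#'   each with entity, name, q_value, category and a `countermeasures`
#'   list-column.
#' @export
countermeasure_hints <- function(result, model) {
  stopifnot(inherits(result, "rimeda_result"), inherits(model, "rimeda_model"))
  idx <- merge(result$indices,
               data.frame(entity = model$entities$id,
                          name = model$entities$name,
                          controllable = model$entities$controllable),
               by = "entity", sort = FALSE)
  idx$countermeasures <- model$entities$countermeasures[
    match(idx$entity, model$entities$id)]
  cols <- c("entity", "name", "q_value", "category", "countermeasures")
  risk <- idx[idx$controllable & idx$q_value > 0, , drop = FALSE]
  prot <- idx[idx$controllable & idx$q_value < 0, , drop = FALSE]
  other <- idx[!(idx$controllable & idx$q_value != 0), , drop = FALSE]
  risk <- risk[order(-risk$q_value, risk$entity), cols]
  prot <- prot[order(prot$q_value, prot$entity), cols]
  other <- other[order(other$entity), cols]
  rownames(risk) <- rownames(prot) <- rownames(other) <- NULL
  list(risk_levers = risk, protective_levers = prot, other = other)
}
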