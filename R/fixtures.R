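## Deterministic generators: the TOY3 teaching model, random admissible
## models, and random admissible assessments. Every generated artefact
## passes the model module's full validation, and all generators are pure
## functions of their configuration and seed.

#' The fixed three-entity TOY3 model
#'
#' A minimal, fully hand-checkable system used throughout the test suite
#' and documentation: X1 (domain 0..3, double points), X2 (1..3),
#' X3 (-3 or 1..3), matrix rows X1 = (0, 2, -1), X2 = (3, 0, 2),
#' X3 = (-2, 1, 0), `row` weighting strategy. Its absolute row sums are
#' (3, 5, 3) and its achievable score bounds follow from exhaustive
#' enumeration of the 4 * 3 * 4 = 48 admissible assessments.
#'
#' @return a [rimeda_model()].
#' @export
toy3_model <- function() {
  entities <- rbind(
    entity_def("X1", "Toy driver", "T", 0:3, double = TRUE,
               controllable = TRUE),
    entity_def("X2", "Toy relay", "T", 1:3, controllable = TRUE),
    entity_def("X3", "Toy inhibitor", "T", c(-3L, 1L, 2L, 3L),
               controllable = TRUE)
  )
  rimeda_model(
    perspectives = data.frame(id = "T", name = "Toy",
                              description = "three-entity teaching system"),
    entities = entities,
    matrix = influence_matrix(rbind(c(0, 2, -1), c(3, 0, 2), c(-2, 1, 0)),
                              c("X1", "X2", "X3")),
    weighting_strategy = "row", id = "TOY3"
  )
}

#' Configuration for the random model generator
#'
#' @param n_entities number of entities (>= 2).
#' @param cell_magnitude_probs probabilities of cell moduli 0, 1, 2, 3
#'   (normalised internally).
#' @param negative_cell_prob probability that a nonzero cell is negative.
#' @param domain_palette list of admissible weight domains to draw from.
#' @param double_prob probability that an entity carries double points.
#' @param seed integer seed.
#' @return a list of class `rimeda_generator_config`.
#' @export
generator_config <- function(n_entities = 5,
                             cell_magnitude_probs = c(0.4, 0.25, 0.2, 0.15),
                             negative_cell_prob = 0.2,
                             domain_palette = list(0:3, 1:3,
                                                   c(-3L, 1L, 2L, 3L)),
                             double_prob = 0.15, seed = 1) {
  stopifnot(length(cell_magnitude_probs) == 4,
            all(cell_magnitude_probs >= 0), sum(cell_magnitude_probs) > 0,
            negative_cell_prob >= 0, negative_cell_prob <= 1,
            double_prob >= 0, double_prob <= 1)
  structure(list(
    n_entities = as.integer(n_entities),
    cell_magnitude_probs = cell_magnitude_probs / sum(cell_magnitude_probs),
    negative_cell_prob = negative_cell_prob,
    domain_palette = lapply(domain_palette, as.integer),
    double_prob = double_prob, seed = as.integer(seed)
  ), class = "rimeda_generator_config")
}

#' Generate a random admissible risk model
#'
#' Draws a zero-diagonal signed integer matrix with cells in \[-3, 3\] and
#' per-entity weight domains from the configured palette. Identical
#' configurations (including seed) yield identical models.
#'
#' @param cfg a [generator_config()].
#' @return a [rimeda_model()].
#' @export
random_model <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "rimeda_generator_config"))
  n <- cfg$n_entities
  if (n < 2) stop("random_model needs n_entities >= 2")
  with_preserved_seed(cfg$seed, {
    mags <- sample(0:3, n * n, replace = TRUE,
                   prob = cfg$cell_magnitude_probs)
    signs <- ifelse(runif(n * n) < cfg$negative_cell_prob, -1L, 1L)
    m <- matrix(mags * signs, n)
    diag(m) <- 0L
    ids <- sprintf("E%d", seq_len(n))
    entities <- do.call(rbind, lapply(seq_len(n), function(i) {
      dom <- cfg$domain_palette[[sample.int(length(cfg$domain_palette), 1)]]
      entity_def(ids[i], sprintf("Random entity %d", i), "R", dom,
                 double = runif(1) < cfg$double_prob, controllable = TRUE)
    }))
    rimeda_model(
      perspectives = data.frame(id = "R", name = "Random",
                                description = "generated perspective"),
      entities = entities,
      matrix = influence_matrix(m, ids),
      weighting_strategy = "row",
      id = sprintf("random-%d-seed%d", n, cfg$seed)
    )
  })
}

#' Draw a random admissible assessment for a model
#'
#' Each entity's weight is drawn uniformly and independently from its
#' admissible domain; the result is valid by construction and identical
#' for identical seeds.
#'
#' @param model a [rimeda_model()].
#' @param seed integer seed.
#' @param label assessment label.
#' @return a [rimeda_assessment()].
#' @export
random_assessment <- function(model, seed = 1,
                              label = sprintf("random seed %d", seed)) {
  stopifnot(inherits(model, "rimeda_model"))
  domains <- entity_domains(model)
  w <- with_preserved_seed(seed, {
    vapply(domains, function(d) d[sample.int(length(d), 1)], 1L)
  })
  rimeda_assessment(setNames(w, names(domains)), label = label)
}
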