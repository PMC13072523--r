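## Domain model: perspectives, entities, weight domains, influence matrix.

#' Construct an influence matrix
#'
#' An influence matrix is the quantitative core of the cross-impact system:
#' cell (i, j) scores how strongly entity i drives entity j. Moduli encode
#' effect strength (0 = none, 1 = weak, 2 = medium, 3 = strong); the sign
#' encodes direction (positive = parallel development, negative = opposing,
#' i.e. risk-reducing). Self-influence is excluded, so the diagonal is zero.
#'
#' @param values square integer matrix (or coercible) of cell values.
#' @param entity_order character vector of entity ids naming rows/columns;
#'   defaults to the dimnames of `values`.
#' @return an integer matrix of class `rimeda_matrix` with entity ids as
#'   dimnames.
#' @export
influence_matrix <- function(values, entity_order = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(entity_order)) {
    stop("influence matrix needs entity ids (entity_order or dimnames)")
  }
  entity_order <- as.character(entity_order)
  if (nrow(values) != ncol(values)) {
    stop(sprintf("influence matrix must be square, got %d x %d",
                 nrow(values), ncol(values)))
  }
  if (length(entity_order) != nrow(values)) {
    stop("entity_order length does not match matrix dimension")
  }
  if (anyDuplicated(entity_order)) {
    stop("duplicate entity ids in entity_order: ",
         paste(unique(entity_order[duplicated(entity_order)]), collapse = ", "))
  }
  storage <- suppressWarnings(as.numeric(values))
  if (anyNA(storage) || any(storage != round(storage))) {
    bad <- which(is.na(storage) | storage != round(storage))[1]
    stop(sprintf("non-integer cell at row %d, column %d",
                 (bad - 1L) %% nrow(values) + 1L,
                 (bad - 1L) %/% nrow(values) + 1L))
  }
  m <- matrix(as.integer(storage), nrow(values),
              dimnames = list(entity_order, entity_order))
  check_matrix_cells(m)
  class(m) <- c("rimeda_matrix", class(m))
  m
}

check_matrix_cells <- function(m) {
  out <- which(m < -3L | m > 3L, arr.ind = TRUE)
  if (nrow(out) > 0) {
    stop(sprintf("cell out of [-3,3] at (%s, %s): value %d",
                 rownames(m)[out[1, 1]], colnames(m)[out[1, 2]],
                 m[out[1, 1], out[1, 2]]))
  }
  d <- which(diag(m) != 0L)
  if (length(d) > 0) {
    stop("nonzero diagonal for entity ", rownames(m)[d[1]],
         " (self-influence is excluded)")
  }
  invisible(m)
}

#' Read / write an influence matrix as CSV
#'
#' The CSV carries a header row and a header column of entity ids and
#' integer body cells; `matrix_to_csv()` followed by `matrix_from_csv()`
#' reproduces the matrix exactly.
#'
#' @param path file path.
#' @return `matrix_from_csv()` returns a validated [influence_matrix()].
#' @export
matrix_from_csv <- function(path) {
  if (!file.exists(path)) stop("matrix CSV not found: ", path)
  df <- read.csv(path, check.names = FALSE, row.names = 1,
                 strip.white = TRUE, fill = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix CSV row ids and column ids disagree: rows [",
         paste(rownames(m), collapse = ","), "] vs columns [",
         paste(colnames(m), collapse = ","), "]")
  }
  influence_matrix(m)
}

#' @param m an [influence_matrix()].
#' @rdname matrix_from_csv
#' @export
matrix_to_csv <- function(m, path) {
  df <- as.data.frame(unclass(m), check.names = FALSE)
  write.csv(df, path, quote = FALSE, row.names = TRUE)
  invisible(path)
}

canonical_domains <- list(
  "0-3"  = 0:3,
  "1-3"  = 1:3,
  "-3;1-3" = c(-3L, 1L, 2L, 3L)
)

check_weight_domain <- function(domain, id = "?") {
  domain <- sort(unique(as.integer(domain)))
  if (length(domain) == 0 || any(domain < -3L | domain > 3L)) {
    stop("weight domain of ", id, " must be a non-empty subset of [-3,3]")
  }
  domain
}

#' Define a risk entity
#'
#' @param id short entity code (canonical scheme: D1..D3, W1..W4, A1..A3,
#'   TO1..TO3).
#' @param name human-readable name.
#' @param perspective perspective id the entity belongs to.
#' @param weight_domain admissible integer weights for the data controller's
#'   assessment (subset of -3..3).
#' @param double logical; if `TRUE` the entity impacts the system with
#'   double point values.
#' @param controllable logical; whether a data controller can act on the
#'   entity (drives lever/countermeasure partitioning).
#' @param rubric character vector of free-text grading guidance lines.
#' @param countermeasures character vector of free-text countermeasure hints.
#' @return a one-row data frame (list-columns for domain and texts).
#' @export
entity_def <- function(id, name, perspective, weight_domain,
                       double = FALSE, controllable = NA,
                       rubric = character(), countermeasures = character()) {
  if (is.na(controllable)) {
    controllable <- !grepl("^(W|A)", perspective)
  }
  data.frame(
    id = as.character(id), name = as.character(name),
    perspective = as.character(perspective),
    double = isTRUE(double), controllable = isTRUE(controllable),
    weight_domain = I(list(check_weight_domain(weight_domain, id))),
    rubric = I(list(as.character(rubric))),
    countermeasures = I(list(as.character(countermeasures))),
    stringsAsFactors = FALSE
  )
}

#' Assemble and validate a risk model
#'
#' @param perspectives data frame with columns `id`, `name` (optionally
#'   `description`).
#' @param entities data frame of entity definitions (rows from
#'   [entity_def()]).
#' @param matrix an [influence_matrix()] whose entity order equals the
#'   entity list order.
#' @param weighting_strategy `"row"` (each cell scaled by the influencing
#'   entity's signed weight) or `"row_col"` (additionally by the influenced
#'   entity's weight).
#' @param q_convention `"active_sign"` (default; `|AS*PS|` signed by the
#'   active sum) or `"product"` (raw `AS*PS`).
#' @param bands a [risk_bands()] scheme.
#' @param id model identifier string.
#' @return a validated object of class `rimeda_model`; `score_bounds` holds
#'   the exact achievable total-score range, computed on construction.
#' @export
rimeda_model <- function(perspectives, entities, matrix,
                         weighting_strategy = "row",
                         q_convention = "active_sign",
                         bands = risk_bands(), id = "model") {
  perspectives <- as.data.frame(perspectives)
  entities <- as.data.frame(entities)
  stopifnot(all(c("id", "name") %in% names(perspectives)),
            all(c("id", "name", "perspective", "double", "controllable",
                  "weight_domain") %in% names(entities)))
  if (!"description" %in% names(perspectives)) perspectives$description <- ""
  if (!"rubric" %in% names(entities)) {
    entities$rubric <- I(rep(list(character()), nrow(entities)))
  }
  if (!"countermeasures" %in% names(entities)) {
    entities$countermeasures <- I(rep(list(character()), nrow(entities)))
  }
  if (anyDuplicated(entities$id)) {
    stop("duplicate entity ids: ",
         paste(unique(entities$id[duplicated(entities$id)]), collapse = ", "))
  }
  missing_p <- setdiff(entities$perspective, perspectives$id)
  if (length(missing_p) > 0) {
    stop("entities reference undeclared perspectives: ",
         paste(missing_p, collapse = ", "))
  }
  if (!inherits(matrix, "rimeda_matrix")) matrix <- influence_matrix(matrix)
  if (!identical(rownames(matrix), entities$id)) {
    stop("matrix entity order [", paste(rownames(matrix), collapse = ","),
         "] does not match entity list [",
         paste(entities$id, collapse = ","), "]")
  }
  weighting_strategy <- match.arg(weighting_strategy, c("row", "row_col"))
  q_convention <- match.arg(q_convention, c("active_sign", "product"))
  entities$weight_domain <- I(lapply(seq_len(nrow(entities)), function(i) {
    check_weight_domain(entities$weight_domain[[i]], entities$id[i])
  }))
  m <- structure(
    list(id = as.character(id), perspectives = perspectives,
         entities = entities, matrix = matrix,
         weighting_strategy = weighting_strategy,
         q_convention = q_convention, bands = bands,
         score_bounds = NULL),
    class = "rimeda_model"
  )
  b <- score_bounds(m)
  m$score_bounds <- c(min = b$min, max = b$max)
  m
}

entity_ids <- function(model) model$entities$id

entity_deltas <- function(model) {
  setNames(ifelse(model$entities$double, 2L, 1L), model$entities$id)
}

entity_domains <- function(model) {
  setNames(model$entities$weight_domain, model$entities$id)
}

#' Create an assessment (a data controller's weight vector)
#'
#' @param weights named integer vector or named list, one weight per entity
#'   id of the model the assessment is meant for.
#' @param label,notes free-text annotation.
#' @return an object of class `rimeda_assessment`.
#' @export
rimeda_assessment <- function(weights, label = "", notes = "") {
  w <- unlist(weights)
  if (is.null(names(w)) || any(names(w) == "")) {
    stop("assessment weights must be named by entity id")
  }
  if (any(w != round(w))) stop("assessment weights must be integers")
  structure(list(weights = setNames(as.integer(w), names(w)),
                 label = as.character(label), notes = as.character(notes)),
            class = "rimeda_assessment")
}

#' Validate an assessment against a model
#'
#' Collects findings rather than raising: an empty report means every entity
#' of the model is covered exactly once and every weight lies in that
#' entity's admissible domain.
#'
#' @param assessment a [rimeda_assessment()].
#' @param model a [rimeda_model()].
#' @return data frame with columns `entity` and `problem`; zero rows iff
#'   valid.
#' @export
validate_assessment <- function(assessment, model) {
  stopifnot(inherits(assessment, "rimeda_assessment"),
            inherits(model, "rimeda_model"))
  w <- assessment$weights
  ids <- entity_ids(model)
  findings <- list()
  for (miss in setdiff(ids, names(w))) {
    findings[[length(findings) + 1L]] <-
      data.frame(entity = miss, problem = "uncovered entity: no weight given")
  }
  for (extra in setdiff(names(w), ids)) {
    findings[[length(findings) + 1L]] <-
      data.frame(entity = extra, problem = "unknown entity")
  }
  for (dup in unique(names(w)[duplicated(names(w))])) {
    findings[[length(findings) + 1L]] <-
      data.frame(entity = dup, problem = "entity weighted more than once")
  }
  domains <- entity_domains(model)
  for (id in intersect(ids, names(w))) {
    if (!w[[id]] %in% domains[[id]]) {
      findings[[length(findings) + 1L]] <- data.frame(
        entity = id,
        problem = sprintf("weight %d not admissible (%s admits {%s})",
                          w[[id]], id,
                          paste(domains[[id]], collapse = ",")))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(entity = character(), problem = character()))
  }
  do.call(rbind, findings)
}

assert_valid_assessment <- function(assessment, model) {
  rep <- validate_assessment(assessment, model)
  if (nrow(rep) > 0) {
    stop("invalid assessment:\n  ",
         paste(sprintf("%s: %s", rep$entity, rep$problem), collapse = "\n  "))
  }
  invisible(assessment)
}

## ---- model file I/O (YAML / JSON) -------------------------------------

read_structured <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    stop("unsupported model file extension (use .yaml, .yml or .json): ", path)
  }
}

write_structured <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unsupported model file extension: ", path)
  }
  invisible(path)
}

#' Read a risk model from a YAML or JSON file
#'
#' The file carries `perspectives`, `entities` (id, name, perspective,
#' weight_domain, double, controllable, rubric, countermeasures), a `matrix`
#' (inline list of rows or `csv: <path>` relative to the model file),
#' and optional `weighting_strategy`, `q_convention`, `bands`, `id` keys.
#' The model is fully validated on load and its achievable score bounds are
#' computed.
#'
#' @param path model file path.
#' @return a [rimeda_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- read_structured(path)
  for (key in c("perspectives", "entities", "matrix")) {
    if (is.null(raw[[key]])) {
      stop("model file ", path, ": missing required key '", key, "'")
    }
  }
  perspectives <- do.call(rbind, lapply(raw$perspectives, function(p) {
    data.frame(id = p$id, name = p$name,
               description = p$description %||% "")
  }))
  entities <- do.call(rbind, lapply(raw$entities, function(e) {
    if (is.null(e$id) || is.null(e$weight_domain)) {
      stop("model file ", path, ": entity entry lacks 'id' or 'weight_domain'")
    }
    entity_def(e$id, e$name %||% e$id, e$perspective %||% "",
               unlist(e$weight_domain),
               double = isTRUE(e$double),
               controllable = if (is.null(e$controllable)) NA
                              else isTRUE(e$controllable),
               rubric = unlist(e$rubric) %||% character(),
               countermeasures = unlist(e$countermeasures) %||% character())
  }))
  mat <- raw$matrix
  if (!is.null(mat$csv)) {
    csv_path <- mat$csv
    if (!file.exists(csv_path)) {
      csv_path <- file.path(dirname(path), mat$csv)
    }
    matrix <- matrix_from_csv(csv_path)
    if (!identical(rownames(matrix), entities$id)) {
      stop("model file ", path, ": matrix CSV entity order differs from ",
           "entity list")
    }
  } else {
    rows <- mat$rows %||% mat
    values <- do.call(rbind, lapply(rows, unlist))
    matrix <- influence_matrix(values, entities$id)
  }
  bands <- if (is.null(raw$bands)) risk_bands() else do.call(risk_bands, raw$bands)
  rimeda_model(
    perspectives = perspectives, entities = entities, matrix = matrix,
    weighting_strategy = raw$weighting_strategy %||% "row",
    q_convention = raw$q_convention %||% "active_sign",
    bands = bands,
    id = raw$id %||% tools::file_path_sans_ext(basename(path))
  )
}

#' Write a risk model to a YAML or JSON file
#'
#' `read_model(write_model(m, path))` reproduces the model exactly
#' (round-trip identity); the matrix is written inline.
#'
#' @param model a [rimeda_model()].
#' @param path destination (`.yaml`, `.yml` or `.json`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rimeda_model"))
  ent <- model$entities
  raw <- list(
    id = model$id,
    perspectives = lapply(seq_len(nrow(model$perspectives)), function(i) {
      as.list(model$perspectives[i, c("id", "name", "description")])
    }),
    entities = lapply(seq_len(nrow(ent)), function(i) {
      list(id = ent$id[i], name = ent$name[i],
           perspective = ent$perspective[i],
           weight_domain = as.integer(ent$weight_domain[[i]]),
           double = ent$double[i], controllable = ent$controllable[i],
           rubric = as.list(ent$rubric[[i]]),
           countermeasures = as.list(ent$countermeasures[[i]]))
    }),
    matrix = list(rows = lapply(seq_len(nrow(model$matrix)),
                                function(i) as.integer(model$matrix[i, ]))),
    weighting_strategy = model$weighting_strategy,
    q_convention = model$q_convention,
    bands = Filter(Negate(is.null), unclass(model$bands))
  )
  write_structured(raw, path)
}

#' Read / write an assessment file
#'
#' Assessment files are YAML or JSON with a `weights` mapping (entity id to
#' integer weight) and optional `label` and `notes`.
#'
#' @param path file path.
#' @return `read_assessment()` returns a [rimeda_assessment()].
#' @export
read_assessment <- function(path) {
  if (!file.exists(path)) stop("assessment file not found: ", path)
  raw <- read_structured(path)
  if (is.null(raw$weights)) stop("assessment file lacks 'weights' mapping")
  rimeda_assessment(raw$weights, label = raw$label %||% "",
                    notes = raw$notes %||% "")
}

#' @param assessment a [rimeda_assessment()].
#' @rdname read_assessment
#' @export
write_assessment <- function(assessment, path) {
  stopifnot(inherits(assessment, "rimeda_assessment"))
  write_structured(list(label = assessment$label, notes = assessment$notes,
                        weights = as.list(assessment$weights)), path)
}

#' The canonical 13-entity re-identification risk model
#'
#' Loads the model shipped with the package: 13 entities in 4 perspectives
#' (data D1-D3, knowledge W1-W4, attacker A1-A3, technical/organisational
#' TO1-TO3) with their published weight domains and the D1/TO2 doubling
#' flags. The influence-matrix cell values are a clearly labelled
#' *synthetic stand-in* curated from the published qualitative descriptions
#' of the inter-entity relationships (see the package vignette); the
#' original prototype workbook's cell values are not redistributable here,
#' so absolute scores from this model are illustrative, while the model
#' structure, weight domains and qualitative lever behaviour follow the
#' published system.
#'
#' @return a [rimeda_model()].
#' @export
canonical_model <- function() {
  read_model(system.file("extdata", "rimeda_model.yaml", package = "rimeda",
                         mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rimeda_model <- function(x, ...) {
  cat(sprintf("<rimeda_model '%s'>\n", x$id))
  cat(sprintf("  %d entities in %d perspectives; strategy '%s', Q convention '%s'\n",
              nrow(x$entities), nrow(x$perspectives),
              x$weighting_strategy, x$q_convention))
  cat(sprintf("  achievable total score: [%s, %s]\n",
              format(x$score_bounds[["min"]]), format(x$score_bounds[["max"]])))
  invisible(x)
}

#' @export
print.rimeda_assessment <- function(x, ...) {
  cat("<rimeda_assessment",
      if (nzchar(x$label)) sprintf("'%s'", x$label) else "", ">\n")
  print(x$weights)
  invisible(x)
}
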