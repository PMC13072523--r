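## Machine-readable assessment report (JSON canonical form).

#' Build a structured assessment report
#'
#' Collects everything an auditor needs to reproduce a risk assessment:
#' the model id, the echoed assessment, the exact per-entity indices, the
#' total score with its achievable bounds and band, the lever /
#' countermeasure partition, the strategy and Q-sign convention used, the
#' package version and digests of the input files. Machine fields carry
#' exact values; display rounding happens only in the chart renderers.
#'
#' @param result a `rimeda_result` from [compute_risk()].
#' @param model the [rimeda_model()] used.
#' @param input_files optional character vector of paths whose MD5 digests
#'   are recorded.
#' @return a list of class `rimeda_report`.
#' @export
build_report <- function(result, model, input_files = character()) {
  stopifnot(inherits(result, "rimeda_result"), inherits(model, "rimeda_model"))
  hints <- countermeasure_hints(result, model)
  hint_list <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(entity = df$entity[i], name = df$name[i],
           q_value = df$q_value[i], category = df$category[i],
           countermeasures = as.list(df$countermeasures[[i]]))
    })
  }
  digests <- if (length(input_files) > 0) {
    as.list(setNames(unname(tools::md5sum(input_files)),
                     basename(input_files)))
  } else {
    NULL
  }
  structure(list(
    tool = list(name = "rimeda",
                version = as.character(packageVersion("rimeda"))),
    model_id = result$model_id,
    strategy = result$strategy,
    q_convention = result$q_convention,
    assessment = list(label = result$assessment$label,
                      notes = result$assessment$notes,
                      weights = as.list(result$assessment$weights)),
    indices = result$indices,
    total_score = result$total_score,
    score_bounds = as.list(result$score_bounds),
    band = result$band,
    levers = list(risk = hint_list(hints$risk_levers),
                  protective = hint_list(hints$protective_levers)),
    input_digests = digests
  ), class = "rimeda_report")
}

#' Write / read a report as JSON
#'
#' The JSON serialisation is lossless for all machine fields and
#' byte-deterministic for fixed inputs.
#'
#' @param report a `rimeda_report`.
#' @param path destination `.json` path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "rimeda_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()` returns the parsed report list.
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  class(rep) <- "rimeda_report"
  rep
}
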