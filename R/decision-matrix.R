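#' Encode a qualitative criterion value
#'
#' Decision matrices mix numeric codes in `[0, 1]` with YES/NO flags. YES
#' maps to 1, NO to 0, and numeric codes in `[0, 1]` pass through.
#'
#' @param value `"YES"`, `"NO"` (case-insensitive) or a number in `[0, 1]`;
#'   vectorised.
#' @return Numeric vector in `[0, 1]`.
#' @export
encode_qualitative <- function(value) {
  vapply(value, function(v) {
    if (is.character(v)) {
      up <- toupper(trimws(v))
      if (up == "YES") return(1)
      if (up == "NO") return(0)
      num <- suppressWarnings(as.numeric(up))
      if (is.na(num)) stop(sprintf("unknown qualitative token '%s' (expected YES, NO or a number in [0,1])", v),
                           call. = FALSE)
      v <- num
    }
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("qualitative code %s is outside [0, 1]", format(v)), call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default ten-criterion configuration
#'
#' The ten criteria used to evaluate the classifier families, with their
#' linguistic importance labels and optimisation directions: the six
#' quantitative performance criteria (accuracy, recall, precision, F1-score,
#' ROC-AUC — Very High; and log loss — Very High, the only minimised
#' criterion, stored as negative values where lower, i.e. closer to the best
#' attainable 0, is better), and four qualitative usability criteria — number
#' of training samples needed, impact of feature scaling, impact of
#' hyper-parameter tuning (all High) and tolerance to irrelevant attributes
#' (Medium). Spreads default to `"auto"`.
#'
#' @return A [criteria_config()] of the ten criteria.
#' @export
default_criteria <- function() {
  criteria_config(
    name = c("accuracy", "recall", "precision", "f1_score", "roc_auc",
             "log_loss", "n_training_samples", "feature_scaling_impact",
             "hyperparameter_tuning_impact", "irrelevant_attribute_tolerance"),
    direction = c(rep("maximize", 5), "minimize", rep("maximize", 4)),
    weight_label = c(rep("Very High", 6), rep("High", 3), "Medium"),
    spread = "auto")
}

#' Default qualitative usability codes for the five families
#'
#' Literature-derived codes in `[0, 1]` for the four qualitative criteria
#' (a five-point coding 0.08 / 0.25 / 0.50 / 0.75 / 0.92 plus YES/NO for
#' hyper-parameter tuning), shipped as a plain-text table in
#' `extdata/qualitative_codes.csv` and treated as given constants.
#'
#' @param path Optional path to a CSV with columns `model`,
#'   `n_training_samples`, `feature_scaling_impact`,
#'   `hyperparameter_tuning_impact`, `irrelevant_attribute_tolerance`.
#' @return data.frame keyed by `model`, codes already passed through
#'   [encode_qualitative()].
#' @export
qualitative_codes <- function(path = system.file("extdata", "qualitative_codes.csv",
                                                 package = "prombench")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("model", "n_training_samples", "feature_scaling_impact",
              "hyperparameter_tuning_impact", "irrelevant_attribute_tolerance")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("qualitative code table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed[-1]) df[[col]] <- encode_qualitative(df[[col]])
  df
}

#' Assemble the full decision matrix
#'
#' Joins the per-model quantitative metrics from [bench_classifiers()] with
#' the qualitative usability codes into the ten-criterion decision matrix.
#' The five rate metrics are stored as percentages (99.0, not 0.99); log loss
#' keeps its raw negative value; qualitative cells pass through
#' [encode_qualitative()]. The auto-spread rule in [compute_flows()] makes the
#' ranking invariant to the percent-vs-fraction choice.
#'
#' @param metrics data.frame as returned by [bench_classifiers()] (fractions).
#' @param qual Qualitative code table from [qualitative_codes()]; pass `NULL`
#'   to build a quantitative-only matrix.
#' @param criteria A [criteria_config()]; defaults to [default_criteria()],
#'   automatically subset to the quantitative six when `qual` is `NULL`.
#' @return A [decision_matrix()].
#' @export
assemble_decision_matrix <- function(metrics, qual = qualitative_codes(),
                                     criteria = default_criteria()) {
  quant <- data.frame(
    accuracy = metrics$accuracy * 100,
    recall = metrics$recall * 100,
    precision = metrics$precision * 100,
    f1_score = metrics$f1 * 100,
    roc_auc = metrics$roc_auc * 100,
    log_loss = metrics$neg_log_loss,
    row.names = metrics$model, check.names = FALSE)
  if (is.null(qual)) {
    keep <- criteria$name %in% names(quant)
    criteria <- criteria[keep, ]
    criteria$weight <- criteria$weight / sum(criteria$weight)
    class(criteria) <- c("criteria_config", "data.frame")
    vals <- as.matrix(quant[, criteria$name, drop = FALSE])
    return(decision_matrix(vals, criteria))
  }
  missing_q <- setdiff(metrics$model, qual$model)
  if (length(missing_q)) {
    stop("model(s) missing from qualitative codes: ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  }
  missing_m <- setdiff(qual$model, metrics$model)
  if (length(missing_m)) {
    stop("model(s) missing from metrics: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  qrows <- qual[match(metrics$model, qual$model), , drop = FALSE]
  vals <- cbind(as.matrix(quant),
                n_training_samples = qrows$n_training_samples,
                feature_scaling_impact = qrows$feature_scaling_impact,
                hyperparameter_tuning_impact = qrows$hyperparameter_tuning_impact,
                irrelevant_attribute_tolerance = qrows$irrelevant_attribute_tolerance)
  rownames(vals) <- metrics$model
  decision_matrix(vals[, criteria$name, drop = FALSE], criteria)
}
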