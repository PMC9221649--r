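#' Read a decision matrix from CSV
#'
#' Expects a header row with `alternative` as the first column and one column
#' per criterion. Cells may be numeric (a trailing `%` is tolerated and
#' stripped) or the literals YES/NO, which are encoded 1/0. Parse errors name
#' the offending row and column.
#'
#' @param path CSV path.
#' @param criteria Optional [criteria_config()]; when `NULL`, a configuration
#'   is built from the file: if the column names are exactly the ten default
#'   criteria, [default_criteria()] is used, otherwise every column is treated
#'   as maximize with equal weights and auto spreads.
#' @return A [decision_matrix()].
#' @export
read_decision_matrix <- function(path, criteria = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!ncol(df) >= 2L || names(df)[1] != "alternative") {
    stop("decision matrix CSV needs an 'alternative' first column plus >= 1 criterion column",
         call. = FALSE)
  }
  alts <- df[[1]]
  if (anyDuplicated(alts)) {
    stop("duplicate alternative name(s): ",
         paste(unique(alts[duplicated(alts)]), collapse = ", "), call. = FALSE)
  }
  crit_names <- names(df)[-1]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(crit_names),
                 dimnames = list(alts, crit_names))
  for (j in seq_along(crit_names)) {
    raw <- trimws(df[[j + 1]])
    for (i in seq_along(raw)) {
      cell <- sub("%$", "", raw[i])
      if (cell == "" || is.na(cell)) {
        stop(sprintf("blank cell at row %d ('%s'), column '%s'",
                     i, alts[i], crit_names[j]), call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(cell))
      vals[i, j] <- if (!is.na(num)) num else tryCatch(
        encode_qualitative(cell),
        error = function(e) stop(sprintf(
          "cannot parse cell at row %d ('%s'), column '%s': %s",
          i, alts[i], crit_names[j], conditionMessage(e)), call. = FALSE))
    }
  }
  if (is.null(criteria)) {
    criteria <- if (setequal(crit_names, default_criteria()$name)) {
      default_criteria()
    } else {
      criteria_config(name = crit_names, direction = "maximize",
                      weight = rep(1, length(crit_names)), spread = "auto")
    }
  }
  decision_matrix(vals, criteria)
}

#' Write a decision matrix to CSV
#'
#' Inverse of [read_decision_matrix()] at 4-decimal precision.
#'
#' @param dm A [decision_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(dm, path) {
  df <- data.frame(alternative = rownames(dm$values),
                   formatC(dm$values, format = "fg", digits = 8),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a criteria configuration from JSON
#'
#' The file is a JSON array of objects with fields `name`, `direction`
#' (`"maximize"`/`"minimize"`), either `weight_label` (linguistic) or
#' `weight_value` (crisp), and optional `spread` (positive number or
#' `"auto"`, the default). Mixed label/value files are supported: labels are
#' defuzzified first, then all weights are normalised together.
#'
#' @param path JSON path.
#' @param defuzz_method Passed to [defuzzify()].
#' @return A [criteria_config()].
#' @export
read_criteria_config <- function(path, defuzz_method = "yager") {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(spec)) stop("criteria config is empty", call. = FALSE)
  get_or <- function(x, field, default) if (is.null(x[[field]])) default else x[[field]]
  criteria_config(
    name = vapply(spec, function(x) x$name, character(1)),
    direction = vapply(spec, function(x) get_or(x, "direction", "maximize"), character(1)),
    weight = vapply(spec, function(x) as.numeric(get_or(x, "weight_value", NA_real_)), numeric(1)),
    weight_label = vapply(spec, function(x) as.character(get_or(x, "weight_label", NA_character_)), character(1)),
    spread = lapply(spec, function(x) {
      s <- get_or(x, "spread", "auto")
      if (is.character(s)) s else as.numeric(s)
    }),
    defuzz_method = defuzz_method)
}

#' Write the flow report
#'
#' Writes the complete ranking (rank, alternative, the three flows, then one
#' `contrib_<criterion>` column per criterion holding the rainbow segment
#' \eqn{w_j \phi_j(a)}) at fixed 4-decimal formatting, a separate
#' contributions CSV, and a machine-precision JSON twin. Before writing, the
#' decomposition identity (per-row contribution sums equal the net flow) is
#' re-asserted.
#'
#' @param flows A `flow_table` from [compute_flows()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"flows"`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_flow_report <- function(flows, dir, prefix = "flows") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contrib <- flow_contributions(flows)
  resid <- rowSums(contrib) - flows$flows$phi_net
  if (any(abs(resid) > 1e-10)) {
    stop("internal error: contribution rows do not sum to the net flow", call. = FALSE)
  }
  ranking <- rank_complete(flows)
  contrib_ord <- contrib[ranking$alternative, , drop = FALSE]
  colnames(contrib_ord) <- paste0("contrib_", colnames(contrib_ord))
  rank_df <- cbind(ranking, as.data.frame(contrib_ord))
  num <- vapply(rank_df, is.numeric, logical(1)) & names(rank_df) != "rank"
  rank_df[num] <- lapply(rank_df[num], function(x) formatC(x, format = "f", digits = 4))

  ranking_path <- file.path(dir, paste0(prefix, "_ranking.csv"))
  utils::write.csv(rank_df, ranking_path, row.names = FALSE, quote = FALSE)

  contrib_df <- data.frame(alternative = rownames(contrib), contrib,
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(contrib_df)[-1] <- paste0("contrib_", colnames(contrib))
  contrib_df$phi_net <- flows$flows$phi_net[match(contrib_df$alternative,
                                                  flows$flows$alternative)]
  contrib_df[-1] <- lapply(contrib_df[-1], function(x) formatC(x, format = "f", digits = 4))
  contrib_path <- file.path(dir, paste0(prefix, "_contributions.csv"))
  utils::write.csv(contrib_df, contrib_path, row.names = FALSE, quote = FALSE)

  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(
    ranking = rank_complete(flows),
    contributions = as.data.frame(cbind(alternative = rownames(contrib),
                                        as.data.frame(contrib))),
    weights = as.list(flows$weights),
    spreads = as.list(flows$spreads)),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(c(ranking = ranking_path, contributions = contrib_path,
              json = json_path))
}

#' Read a flow table back from its JSON twin
#'
#' @param path Path written by [write_flow_report()] (`*.json`).
#' @return A `flow_table`.
#' @export
read_flow_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- unlist(x$weights)
  contrib <- as.matrix(x$contributions[, -1, drop = FALSE])
  storage.mode(contrib) <- "double"
  rownames(contrib) <- x$contributions$alternative
  uni <- sweep(contrib, 2, weights, `/`)
  ord <- match(x$contributions$alternative, x$ranking$alternative)
  structure(list(
    flows = data.frame(alternative = x$ranking$alternative[ord],
                       phi_plus = x$ranking$phi_plus[ord],
                       phi_minus = x$ranking$phi_minus[ord],
                       phi_net = x$ranking$phi_net[ord],
                       stringsAsFactors = FALSE),
    unicriterion = uni,
    weights = weights,
    spreads = unlist(x$spreads)),
    class = "flow_table")
}
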