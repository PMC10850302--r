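# Core containers: prediction tables, label sets, descriptor matrices,
# and their CSV readers/writers.  The canonical on-disk form for
# predictions is a long (tidy) CSV so that ragged model panels are
# representable; in memory the table is a dense chemical x model
# character matrix because every (chemical, model) pair must carry an
# explicit outcome (out-of-domain handling is explicit, never implied
# by absence).

OUTCOMES <- c("active", "inactive", "out_of_domain")
LABELS <- c("active", "inactive")

#' Outcome levels
#'
#' The three states a component (Q)SAR model can report for a chemical:
#' `"active"`, `"inactive"`, or `"out_of_domain"` (the chemical falls
#' outside the model's applicability domain, so no prediction exists).
#'
#' @return Character vector of the three outcome tokens.
#' @export
outcome_levels <- function() OUTCOMES

# Normalise prediction tokens; accepts 1/0 as active/inactive for
# interoperability with numeric exports, but those are never written.
normalize_outcome <- function(x, allow_ood = TRUE) {
  x <- tolower(trimws(as.character(x)))
  x[x == "1"] <- "active"
  x[x == "0"] <- "inactive"
  allowed <- if (allow_ood) OUTCOMES else LABELS
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    stop("unknown prediction/label token(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  x
}

#' Construct a prediction table
#'
#' A prediction table holds one outcome per (chemical, model) pair for a
#' panel of component models.  It is stored as a character matrix with
#' chemicals as rows and models as columns; every entry is one of the
#' tokens in [outcome_levels()].
#'
#' @param x Character matrix with unique, non-empty rownames (chemical
#'   ids) and colnames (model ids); entries are outcome tokens
#'   (case-insensitive; `"1"`/`"0"` accepted as active/inactive).
#' @return An object of class `prediction_table` (a character matrix).
#' @examples
#' m <- matrix("active", 2, 2,
#'             dimnames = list(c("c1", "c2"), c("m1", "m2")))
#' prediction_table(m)
#' @export
prediction_table <- function(x) {
  if (!is.matrix(x) || !is.character(x)) {
    stop("prediction table must be a character matrix", call. = FALSE)
  }
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop("prediction table must have at least one chemical and one model",
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("prediction table requires chemical rownames and model colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate chemical ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate model ids", call. = FALSE)
  x[] <- normalize_outcome(x)
  class(x) <- c("prediction_table", class(unclass(x)))
  x
}

#' @export
print.prediction_table <- function(x, ...) {
  cat(sprintf("<prediction_table: %d chemicals x %d models>\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more chemicals\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
`[.prediction_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) class(out) <- c("prediction_table", class(out))
  out
}

chemical_ids <- function(table) rownames(table)
model_ids <- function(table) colnames(table)

#' Construct a label set
#'
#' Observed activity calls for chemicals: a named character vector with
#' values `"active"` or `"inactive"`.
#'
#' @param x Named character vector (or coercible) of labels; names are
#'   chemical ids.
#' @return Named character vector of class `label_set`.
#' @export
label_set <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("labels must be named by chemical id", call. = FALSE)
  }
  if (anyDuplicated(names(x))) stop("duplicate chemical ids in labels",
                                    call. = FALSE)
  if (length(x) == 0L) stop("label set is empty", call. = FALSE)
  out <- normalize_outcome(x, allow_ood = FALSE)
  names(out) <- names(x)
  class(out) <- "label_set"
  out
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set: %d chemicals (%d active, %d inactive)>\n",
              length(x), sum(x == "active"), sum(x == "inactive")))
  invisible(x)
}

#' Read a long-format prediction CSV
#'
#' Reads `chemical_id,model_id,prediction` rows into a
#' [prediction_table()].  The file must be *total*: every chemical must
#' have a row for every model (out-of-domain is an explicit token, not a
#' missing row), and no (chemical, model) pair may appear twice.
#'
#' @param path Path to a CSV file with header columns `chemical_id`,
#'   `model_id`, `prediction`.
#' @return A [prediction_table()].
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("chemical_id", "model_id", "prediction")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("prediction file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("prediction file is empty", call. = FALSE)
  key <- paste(df$chemical_id, df$model_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate prediction row for chemical %s, model %s",
                 sQuote(dup$chemical_id), sQuote(dup$model_id)),
         call. = FALSE)
  }
  chems <- unique(df$chemical_id)
  models <- unique(df$model_id)
  if (nrow(df) != length(chems) * length(models)) {
    stop("prediction file is not total: every chemical needs one row per model",
         call. = FALSE)
  }
  m <- matrix(NA_character_, length(chems), length(models),
              dimnames = list(chems, models))
  m[cbind(match(df$chemical_id, chems), match(df$model_id, models))] <-
    df$prediction
  prediction_table(m)
}

#' Write a prediction table as long-format CSV
#'
#' @param table A [prediction_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(table, path) {
  stopifnot(inherits(table, "prediction_table"))
  df <- data.frame(
    chemical_id = rep(rownames(table), times = ncol(table)),
    model_id = rep(colnames(table), each = nrow(table)),
    prediction = as.vector(unclass(table)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observed-label CSV
#'
#' @param path CSV with columns `chemical_id`, `label` and labels
#'   `active`/`inactive` (case-insensitive).
#' @return A [label_set()].
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("chemical_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("label file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("label file is empty: no observed classes",
                           call. = FALSE)
  label_set(stats::setNames(df$label, df$chemical_id))
}

#' Write a label set as CSV
#' @param labels A [label_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_set"))
  df <- data.frame(chemical_id = names(labels),
                   label = as.character(unclass(labels)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a descriptor matrix CSV
#'
#' Descriptors arrive precomputed: a `chemical_id` column followed by
#' one numeric column per descriptor dimension.  No missing values are
#' allowed and every chemical's vector has the same length.
#'
#' @param path CSV path.
#' @return Numeric matrix with chemical ids as rownames.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"chemical_id" %in% names(df)) {
    stop("descriptor file missing column 'chemical_id'", call. = FALSE)
  }
  if (ncol(df) < 2L) stop("descriptor file has no descriptor columns",
                          call. = FALSE)
  ids <- as.character(df$chemical_id)
  if (anyDuplicated(ids)) stop("duplicate chemical ids in descriptors",
                               call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "chemical_id")])
  if (!is.numeric(m) || anyNA(m)) {
    stop("descriptors must be numeric with no missing values", call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write a descriptor matrix as CSV
#' @param descriptors Numeric matrix with chemical-id rownames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  stopifnot(is.matrix(descriptors), is.numeric(descriptors),
            !is.null(rownames(descriptors)))
  cn <- colnames(descriptors)
  if (is.null(cn)) cn <- paste0("d", seq_len(ncol(descriptors)))
  df <- data.frame(chemical_id = rownames(descriptors),
                   descriptors, stringsAsFactors = FALSE)
  names(df) <- c("chemical_id", cn)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

EVALUATION_COLUMNS <- c("members", "scheme", "n_members", "coverage", "sn",
                        "sp", "ba", "mod_score1", "predictivity", "modp",
                        "is_pareto", "is_optimal")

#' Write an evaluation table CSV
#'
#' One row per evaluated consensus model: the sorted, semicolon-joined
#' member ids, the combination scheme, and the performance metrics, plus
#' Pareto-front / optimal-model flags.  Metrics are fractions in
#' \eqn{[0,1]} and are written with full double precision (at least six
#' significant digits survive a round-trip).
#'
#' @param records Evaluation tibble as returned by [evaluate_all()]
#'   (optionally annotated by [annotate_pareto()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_table <- function(records, path) {
  if (nrow(records) == 0L) stop("no evaluation records to write",
                                call. = FALSE)
  if (!"is_pareto" %in% names(records)) records$is_pareto <- NA
  if (!"is_optimal" %in% names(records)) records$is_optimal <- NA
  df <- as.data.frame(records)[, EVALUATION_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an evaluation table CSV
#' @param path CSV produced by [write_evaluation_table()].
#' @return A tibble of evaluation records.
#' @export
read_evaluation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(EVALUATION_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop("evaluation table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}
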