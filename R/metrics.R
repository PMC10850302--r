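# Confusion-matrix construction and the performance metrics used
# throughout: sensitivity, specificity, balanced accuracy, coverage,
# modified score1, predictivity, and modified predictivity (ModP).
#
# Convention: out-of-domain entries are excluded from the confusion
# matrix (a discarded prediction is not a wrong prediction); coverage
# is computed separately over *all* tested chemicals.  All metrics are
# fractions in [0, 1]; percent formatting is presentation only.

#' Confusion counts for one model's predictions
#'
#' Tallies true/false positives/negatives of a per-chemical outcome
#' vector against observed labels.  `"out_of_domain"` entries contribute
#' to no cell.
#'
#' @param preds Named character vector of outcomes (one model's column
#'   of a [prediction_table()]), names are chemical ids.
#' @param labels A [label_set()] covering every chemical in `preds`.
#' @return List of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @examples
#' cc <- confusion_counts(
#'   c(c1 = "active", c2 = "out_of_domain"),
#'   label_set(c(c1 = "inactive", c2 = "active")))
#' cc$fp  # 1; the out-of-domain chemical is not counted anywhere
#' @export
confusion_counts <- function(preds, labels) {
  stopifnot(inherits(labels, "label_set"))
  if (is.null(names(preds))) stop("predictions must be named by chemical id",
                                  call. = FALSE)
  miss <- setdiff(names(preds), names(labels))
  if (length(miss) > 0) {
    stop("no observed label for chemical(s): ",
         paste(sQuote(utils::head(miss, 5L)), collapse = ", "),
         call. = FALSE)
  }
  obs <- unclass(labels)[names(preds)]
  in_dom <- preds != "out_of_domain"
  p <- preds[in_dom]
  o <- obs[in_dom]
  out <- list(
    tp = sum(p == "active" & o == "active"),
    fp = sum(p == "active" & o == "inactive"),
    tn = sum(p == "inactive" & o == "inactive"),
    fn = sum(p == "inactive" & o == "active")
  )
  class(out) <- "confusion_counts"
  out
}

#' Applicability-domain coverage
#'
#' Fraction of tested chemicals that fall inside the model's
#' applicability domain, i.e. the share of outcomes that are not
#' `"out_of_domain"`.
#'
#' @param preds Named character vector of outcomes.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
coverage <- function(preds) {
  if (length(preds) == 0L) stop("coverage of an empty prediction vector",
                                call. = FALSE)
  mean(preds != "out_of_domain")
}

#' Performance metrics from confusion counts
#'
#' Computes the full metric set from a confusion matrix and a coverage
#' fraction:
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP), \quad BA = (Sn+Sp)/2,}
#' \deqn{\mathrm{modified\ score}_1 = BA \times \mathrm{coverage},}
#' \deqn{\mathrm{predictivity} = 0.7\,BA + 0.3\,(1 - |Sn - Sp|),}
#' \deqn{\mathrm{ModP} = 0.7\,BA + 0.3\,Sn.}
#' ModP replaces the sensitivity/specificity balance term of
#' predictivity with sensitivity alone, favouring the capture of active
#' chemicals (fewer false negatives) at the cost of possible false
#' positives — the right trade-off for hazard screening.
#'
#' A class absent among the in-domain predictions (no actives, or no
#' inactives) is an error, never a silent `NaN`: degenerate metrics
#' would corrupt every weighting scheme built on them.
#'
#' @param cc A [confusion_counts()] object (or list with `tp`, `fp`,
#'   `tn`, `fn`).
#' @param coverage Coverage fraction in \eqn{[0, 1]}.
#' @return List of class `model_stats` with fields `sn`, `sp`, `ba`,
#'   `coverage`, `mod_score1`, `predictivity`, `modp`.
#' @examples
#' stats_from_counts(list(tp = 9, fn = 1, tn = 7, fp = 3), coverage = 1)
#' @export
stats_from_counts <- function(cc, coverage) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0,
            coverage >= 0, coverage <= 1)
  if (tp + fn < 1L) {
    stop("no active chemicals among in-domain predictions; ",
         "sensitivity is undefined", call. = FALSE)
  }
  if (tn + fp < 1L) {
    stop("no inactive chemicals among in-domain predictions; ",
         "specificity is undefined", call. = FALSE)
  }
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ba <- (sn + sp) / 2
  out <- list(
    sn = sn,
    sp = sp,
    ba = ba,
    coverage = coverage,
    mod_score1 = ba * coverage,
    predictivity = 0.7 * ba + 0.3 * (1 - abs(sn - sp)),
    modp = 0.7 * ba + 0.3 * sn
  )
  class(out) <- "model_stats"
  out
}

#' @export
print.model_stats <- function(x, ...) {
  cat(sprintf(paste0("<model_stats: Sn %.3f | Sp %.3f | BA %.3f | ",
                     "coverage %.3f | ModP %.3f>\n"),
              x$sn, x$sp, x$ba, x$coverage, x$modp))
  invisible(x)
}

#' Performance metrics for one outcome vector
#'
#' Convenience wrapper combining [confusion_counts()], [coverage()] and
#' [stats_from_counts()].
#'
#' @inheritParams confusion_counts
#' @return A `model_stats` list.
#' @export
model_stats <- function(preds, labels) {
  stats_from_counts(confusion_counts(preds, labels), coverage(preds))
}
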