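# Building a single consensus model: per-member weights, the
# weighted-majority applicability-domain (AD) rule, and the weighted
# vote.
#
# All six combination schemes share the same two-step mechanics; they
# differ only in where weights come from.  Majority voting gives every
# member weight 1; the four statistical schemes weight each member by a
# resubstitution performance metric (BA, modified score1, predictivity,
# or ModP) computed on the training table; the kNN scheme derives
# *per-chemical* weights from descriptor-space distances, so nearby
# (more reliable) models count for more on that chemical.

STAT_SCHEMES <- c(ba = "ba", mod_score1 = "mod_score1",
                  predictivity = "predictivity", modp = "modp")

#' Combination schemes
#'
#' The six ways member predictions are combined: plain `"majority"`
#' voting, four statistically weighted schemes (`"ba"`, `"mod_score1"`,
#' `"predictivity"`, `"modp"`), and descriptor-space `"knn"` weighting.
#'
#' @return Character vector of the six scheme names.
#' @export
all_schemes <- function() {
  c("majority", unname(STAT_SCHEMES), "knn")
}

#' Specify a consensus model
#'
#' A consensus model is a non-empty subset of component models plus one
#' combination scheme.  A single-member spec is a passthrough for the
#' component model itself.
#'
#' @param members Character vector of component model ids (non-empty,
#'   duplicate-free).
#' @param scheme One of [all_schemes()], or `"component"` for a
#'   single-member passthrough.
#' @param k Neighbour count for the kNN scheme (ignored otherwise).
#' @return List of class `consensus_spec`.
#' @export
consensus_spec <- function(members, scheme = "majority", k = 12L) {
  members <- as.character(members)
  if (length(members) == 0L) stop("a consensus needs at least one member",
                                  call. = FALSE)
  if (anyDuplicated(members)) stop("duplicate member model ids",
                                   call. = FALSE)
  scheme <- match.arg(scheme, c(all_schemes(), "component"))
  if (scheme == "component" && length(members) != 1L) {
    stop("'component' is reserved for single-member specs", call. = FALSE)
  }
  k <- as.integer(k)
  if (scheme == "knn" && k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(list(members = members, scheme = scheme, k = k),
            class = "consensus_spec")
}

#' @export
print.consensus_spec <- function(x, ...) {
  cat(sprintf("<consensus_spec: %s [%s]>\n",
              paste(x$members, collapse = " + "), x$scheme))
  invisible(x)
}

# Map member stats to scheme weights.  stats is a named list of
# model_stats, one per member.
weights_from_stats <- function(scheme, stats) {
  if (scheme %in% c("majority", "component")) {
    return(stats::setNames(rep(1, length(stats)), names(stats)))
  }
  metric <- STAT_SCHEMES[[scheme]]
  vapply(stats, function(s) s[[metric]], numeric(1))
}

#' Derive member weights for a consensus spec
#'
#' Majority voting assigns every member weight 1.  The statistical
#' schemes weight each member by its own resubstitution metric on the
#' supplied (training) prediction table: balanced accuracy, modified
#' score1 (BA x coverage), predictivity, or modified predictivity.  kNN
#' weights are per-chemical and come from [knn_weights()] instead.
#'
#' @param spec A [consensus_spec()].
#' @param table Training [prediction_table()] containing every member.
#' @param labels A [label_set()] for the training chemicals.
#' @return Named numeric vector of non-negative weights (one per
#'   member) with a positive sum.
#' @examples
#' panel <- ba_weighting_example()
#' derive_weights(consensus_spec(c("m1", "m2", "m3", "m4"), "ba"),
#'                panel$table, panel$labels)
#' @export
derive_weights <- function(spec, table, labels) {
  stopifnot(inherits(spec, "consensus_spec"))
  if (spec$scheme == "knn") {
    stop("kNN weights are per-chemical; use knn_weights()", call. = FALSE)
  }
  miss <- setdiff(spec$members, colnames(table))
  if (length(miss) > 0) {
    stop("member model(s) absent from prediction table: ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  stats <- lapply(stats::setNames(spec$members, spec$members), function(m) {
    tryCatch(model_stats(unclass(table)[, m], labels),
             error = function(e) {
               stop(sprintf("degenerate metrics for member model %s: %s",
                            sQuote(m), conditionMessage(e)), call. = FALSE)
             })
  })
  w <- weights_from_stats(spec$scheme, stats)
  if (sum(w) <= 0) stop("member weights sum to zero", call. = FALSE)
  w
}

#' Consensus applicability-domain rule
#'
#' A chemical is inside the consensus AD when the members whose ADs
#' cover it carry at least half of the total member weight ("majority
#' weighting"): \eqn{\sum_{m \in AD} w_m \ge \tfrac{1}{2}\sum_m w_m}.
#' Equality counts as inside.
#'
#' @param weights Named numeric member weights.
#' @param ad_flags Logical vector (same members, same order or named)
#'   saying whether the chemical falls in each member's AD.
#' @return `TRUE` if the chemical is inside the consensus AD.
#' @examples
#' w <- c(m1 = 0.8, m2 = 0.75, m3 = 0.65, m4 = 0.6)  # total 2.8
#' in_consensus_ad(w, c(FALSE, TRUE, FALSE, TRUE))   # 1.35 < 1.4: outside
#' in_consensus_ad(w, c(TRUE, FALSE, FALSE, TRUE))   # 1.40 >= 1.4: inside
#' @export
in_consensus_ad <- function(weights, ad_flags) {
  stopifnot(length(weights) == length(ad_flags))
  if (!is.null(names(ad_flags)) && !is.null(names(weights))) {
    ad_flags <- ad_flags[names(weights)]
  }
  sum(weights[ad_flags]) >= sum(weights) / 2
}

#' Weighted majority vote
#'
#' Sums member weights on the active and inactive sides; the heavier
#' side wins.  Members that are themselves out of domain for the
#' chemical cast no vote (their prediction does not exist).  An exact
#' tie resolves to `"active"` by default: for hazard screening the
#' conservative call is toward activity.
#'
#' @param weights Named numeric member weights.
#' @param member_preds Named character vector of member outcomes for one
#'   chemical (same members as `weights`).
#' @param tie_break `"active"` (default) or `"inactive"`.
#' @return `"active"` or `"inactive"`.
#' @export
weighted_vote <- function(weights, member_preds,
                          tie_break = c("active", "inactive")) {
  tie_break <- match.arg(tie_break)
  stopifnot(length(weights) == length(member_preds))
  if (!is.null(names(member_preds)) && !is.null(names(weights))) {
    member_preds <- member_preds[names(weights)]
  }
  voting <- member_preds != "out_of_domain"
  if (!any(voting)) {
    stop("no in-domain member prediction to vote on; the AD rule should ",
         "have excluded this chemical", call. = FALSE)
  }
  w_active <- sum(weights[voting & member_preds == "active"])
  w_inactive <- sum(weights[voting & member_preds == "inactive"])
  if (w_active > w_inactive) "active"
  else if (w_active < w_inactive) "inactive"
  else tie_break
}

#' Per-chemical kNN weights in descriptor space
#'
#' For each query chemical and each member model, computes the mean
#' Euclidean (or Manhattan) distance from the query's descriptor vector
#' to its k nearest neighbours in that member's reference (training)
#' descriptors, then transforms distance into a weight so that members
#' whose chemical space lies closer to the query count for more.  The
#' default transform is \eqn{w = 1/(1+d)}, monotone decreasing in `d`
#' with \eqn{w = 1} at distance zero.
#'
#' @param query Numeric matrix of query descriptors (rows = chemicals)
#'   or a single vector.
#' @param refs Named list of per-member reference descriptor matrices,
#'   each with at least `k` rows and the same number of columns as
#'   `query`.
#' @param k Neighbour count (default 12).
#' @param distance `"euclidean"` (default) or `"manhattan"`.
#' @param transform `"inverse_plus_one"` (default, \eqn{1/(1+d)}),
#'   `"inverse"` (\eqn{1/d}, with a small floor to avoid division by
#'   zero), or `"exp_decay"` (\eqn{e^{-d}}).
#' @return Numeric matrix of weights, chemicals x members.
#' @export
knn_weights <- function(query, refs, k = 12L,
                        distance = c("euclidean", "manhattan"),
                        transform = c("inverse_plus_one", "inverse",
                                      "exp_decay")) {
  distance <- match.arg(distance)
  transform <- match.arg(transform)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  k <- as.integer(k)
  stopifnot(k >= 1L, is.list(refs), length(refs) >= 1L)
  d_mean <- vapply(refs, function(ref) {
    if (!is.matrix(ref)) ref <- as.matrix(ref)
    if (ncol(ref) != ncol(query)) {
      stop("descriptor dimension mismatch between query and reference set",
           call. = FALSE)
    }
    if (nrow(ref) < k) {
      stop(sprintf("reference set has %d rows but k = %d", nrow(ref), k),
           call. = FALSE)
    }
    apply(query, 1L, function(q) {
      d <- if (distance == "euclidean") {
        sqrt(colSums((t(ref) - q)^2))
      } else {
        colSums(abs(t(ref) - q))
      }
      mean(sort(d, partial = k)[seq_len(k)])
    })
  }, numeric(nrow(query)))
  d_mean <- matrix(d_mean, nrow = nrow(query),
                   dimnames = list(rownames(query), names(refs)))
  w <- switch(transform,
              inverse_plus_one = 1 / (1 + d_mean),
              inverse = 1 / pmax(d_mean, .Machine$double.eps),
              exp_decay = exp(-d_mean))
  w
}

#' Per-member reference descriptors from a prediction table
#'
#' A member model's chemical space is represented by the descriptors of
#' the chemicals inside its applicability domain, so kNN weighting can
#' run from the same inputs as the rest of the pipeline.
#'
#' @param table A [prediction_table()].
#' @param descriptors Descriptor matrix covering the table's chemicals.
#' @return Named list of per-model descriptor matrices.
#' @export
refs_from_table <- function(table, descriptors) {
  miss <- setdiff(rownames(table), rownames(descriptors))
  if (length(miss) > 0) {
    stop("descriptors missing for chemical(s): ",
         paste(sQuote(utils::head(miss, 5L)), collapse = ", "),
         call. = FALSE)
  }
  lapply(stats::setNames(colnames(table), colnames(table)), function(m) {
    in_dom <- rownames(table)[unclass(table)[, m] != "out_of_domain"]
    descriptors[in_dom, , drop = FALSE]
  })
}

#' Run one consensus model over a prediction table
#'
#' Per chemical: first the weighted-majority AD rule
#' ([in_consensus_ad()]), then — only for chemicals inside the
#' consensus AD — the weighted vote ([weighted_vote()]).  Statistical
#' weights are derived from `table` and `labels` (resubstitution); with
#' `newdata` the same weights are applied to a second prediction table,
#' e.g. an external test set.
#'
#' @param spec A [consensus_spec()].
#' @param table Training [prediction_table()].
#' @param labels Training [label_set()].
#' @param descriptors Query descriptor matrix; required for the kNN
#'   scheme.
#' @param refs Optional named list of per-member reference descriptor
#'   matrices; defaults to [refs_from_table()] on `table`.
#' @param newdata Optional [prediction_table()] to predict on (defaults
#'   to `table`).
#' @param tie_break Vote tie-break, `"active"` (default) or
#'   `"inactive"`.
#' @param k,distance,transform kNN controls, see [knn_weights()].
#' @return Named character vector of consensus outcomes, one per
#'   chemical of `newdata`; `"out_of_domain"` exactly where the AD rule
#'   fails.
#' @export
run_consensus <- function(spec, table, labels, descriptors = NULL,
                          refs = NULL, newdata = NULL,
                          tie_break = c("active", "inactive"),
                          k = NULL, distance = "euclidean",
                          transform = "inverse_plus_one") {
  stopifnot(inherits(spec, "consensus_spec"))
  tie_break <- match.arg(tie_break)
  if (is.null(newdata)) newdata <- table
  miss <- setdiff(spec$members, colnames(newdata))
  if (length(miss) > 0) {
    stop("member model(s) absent from prediction table: ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  preds <- unclass(newdata)[, spec$members, drop = FALSE]
  chems <- rownames(preds)
  n_members <- length(spec$members)

  if (spec$scheme == "knn") {
    if (is.null(descriptors)) {
      stop("the kNN scheme requires query descriptors", call. = FALSE)
    }
    if (is.null(refs)) refs <- refs_from_table(table, descriptors)
    refs <- refs[spec$members]
    if (is.null(k)) k <- spec$k
    w_mat <- knn_weights(descriptors[chems, , drop = FALSE], refs, k = k,
                         distance = distance, transform = transform)
  } else {
    w <- derive_weights(spec, table, labels)
    w_mat <- matrix(w, nrow = length(chems), ncol = n_members,
                    byrow = TRUE, dimnames = list(chems, spec$members))
  }

  ad <- preds != "out_of_domain"
  w_in_ad <- rowSums(w_mat * ad)
  inside <- w_in_ad >= rowSums(w_mat) / 2
  w_active <- rowSums(w_mat * (preds == "active"))
  w_inactive <- rowSums(w_mat * (preds == "inactive"))

  out <- rep("out_of_domain", length(chems))
  vote <- ifelse(w_active > w_inactive, "active",
                 ifelse(w_active < w_inactive, "inactive", tie_break))
  out[inside] <- vote[inside]
  # inside the consensus AD at least one member votes (its weight alone
  # reaches the in-AD sum), so the tie branch never fires on zero votes
  stopifnot(all(!inside | (w_active + w_inactive > 0) |
                  rowSums(w_mat) == 0))
  stats::setNames(out, chems)
}
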