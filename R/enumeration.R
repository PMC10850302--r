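# Exhaustive enumeration of consensus models: every non-empty subset
# of component models under every combination scheme, with singletons
# counted once (a single model combined with itself is the same model
# under any scheme).  The closed-form count is
#   N = r (2^n - 1) - (r - 1) n
# for r schemes and n component models: r copies of each non-empty
# subset, minus the r-1 duplicate copies of each of the n singletons.

#' Closed-form consensus model count
#'
#' Number of distinct consensus models for `n` component models under
#' `r` combination schemes, counting each single-model passthrough
#' once: \eqn{N = r(2^n - 1) - (r-1)n}.
#'
#' @param r Number of combination schemes (>= 1).
#' @param n Number of component models (>= 1).
#' @return Integer count.
#' @examples
#' count_models(6, 6)   # 348
#' count_models(6, 10)  # 6088
#' @export
count_models <- function(r, n) {
  stopifnot(r >= 1, n >= 1)
  as.integer(r * (2^n - 1) - (r - 1) * n)
}

#' Enumerate every consensus spec
#'
#' Generates all [consensus_spec()]s for a model panel: one
#' `"component"` passthrough per model, then every subset of size two
#' or more once per scheme.  Order is deterministic: subsets by size,
#' then lexicographically by member ids; schemes in the order given.
#'
#' @param model_ids Character vector of component model ids.
#' @param schemes Character vector of schemes from [all_schemes()].
#' @param k Neighbour count forwarded to kNN specs.
#' @return List of [consensus_spec()] of length
#'   `count_models(length(schemes), length(model_ids))`.
#' @export
enumerate_specs <- function(model_ids, schemes = all_schemes(), k = 12L) {
  model_ids <- as.character(model_ids)
  if (anyDuplicated(model_ids)) stop("duplicate model ids", call. = FALSE)
  stopifnot(length(model_ids) >= 1L, length(schemes) >= 1L)
  schemes <- vapply(schemes, match.arg, "", choices = all_schemes())
  if (anyDuplicated(schemes)) stop("duplicate schemes", call. = FALSE)
  sorted <- sort(model_ids)
  specs <- lapply(sorted, consensus_spec, scheme = "component", k = k)
  n <- length(sorted)
  for (size in seq_len(n)[-1L]) {
    subsets <- utils::combn(sorted, size, simplify = FALSE)
    for (members in subsets) {
      for (s in schemes) {
        specs[[length(specs) + 1L]] <- consensus_spec(members, s, k = k)
      }
    }
  }
  specs
}

record_subtype <- function(n_members, n_total) {
  ifelse(n_members == 1L, "component",
         ifelse(n_members == n_total, "full_consensus", "other"))
}

#' Evaluate every consensus model on a panel
#'
#' Enumerates all specs with [enumerate_specs()], runs each through
#' [run_consensus()], and scores the consensus outcomes against the
#' observed labels with [model_stats()].  One row per consensus model.
#'
#' @param table Training [prediction_table()].
#' @param labels [label_set()] for the table's chemicals.
#' @param schemes Schemes to enumerate; defaults to all six when
#'   `descriptors` are supplied, otherwise the five schemes that need
#'   no descriptor space.
#' @param descriptors Optional query descriptor matrix (required if
#'   `"knn"` is among the schemes).
#' @param refs Optional per-member reference descriptors for kNN;
#'   defaults to [refs_from_table()].
#' @param k Neighbour count for kNN.
#' @param tie_break Vote tie-break, see [weighted_vote()].
#' @param verbose Log progress every 500 models.
#' @return Tibble with columns `members` (semicolon-joined, sorted),
#'   `scheme`, `n_members`, `subtype`, `coverage`, `sn`, `sp`, `ba`,
#'   `mod_score1`, `predictivity`, `modp`.
#' @export
evaluate_all <- function(table, labels, schemes = NULL, descriptors = NULL,
                         refs = NULL, k = 12L, tie_break = "active",
                         verbose = FALSE) {
  if (is.null(schemes)) {
    schemes <- if (is.null(descriptors)) setdiff(all_schemes(), "knn")
               else all_schemes()
  }
  if ("knn" %in% schemes && is.null(descriptors)) {
    stop("the kNN scheme requires descriptors", call. = FALSE)
  }
  if (!is.null(descriptors) && is.null(refs)) {
    refs <- refs_from_table(table, descriptors)
  }
  # every member must have usable resubstitution metrics before any
  # weighting scheme runs; fail with the model named
  for (m in colnames(table)) {
    tryCatch(model_stats(unclass(table)[, m], labels),
             error = function(e) {
               stop(sprintf("component model %s has degenerate metrics: %s",
                            sQuote(m), conditionMessage(e)), call. = FALSE)
             })
  }
  specs <- enumerate_specs(colnames(table), schemes, k = k)
  n_total <- ncol(table)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    pred <- run_consensus(spec, table, labels, descriptors = descriptors,
                          refs = refs, tie_break = tie_break)
    st <- model_stats(pred, labels)
    rows[[i]] <- tibble::tibble(
      members = paste(sort(spec$members), collapse = ";"),
      scheme = spec$scheme,
      n_members = length(spec$members),
      subtype = record_subtype(length(spec$members), n_total),
      coverage = st$coverage, sn = st$sn, sp = st$sp, ba = st$ba,
      mod_score1 = st$mod_score1, predictivity = st$predictivity,
      modp = st$modp
    )
    if (verbose && i %% 500L == 0L) {
      message(sprintf("evaluated %d / %d consensus models", i, length(specs)))
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == count_models(length(schemes), n_total))
  out
}
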