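# Pareto-front selection over (coverage, ModP).  Predictive power and
# applicability-domain coverage are separate objectives; the front is
# the set of consensus models not dominated in both, and the "optimal"
# model is the front member closest to the ideal point (coverage 1,
# ModP 1).  Both axes are fractions in [0,1], so Euclidean distance is
# commensurate; percent-scale coverage would silently dominate it.

#' Pareto dominance over (coverage, ModP)
#'
#' `a` dominates `b` when `a` is at least as good on both coverage and
#' ModP and strictly better on at least one.
#'
#' @param a,b Numeric length-2 vectors `c(coverage, modp)`.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  a[1] >= b[1] && a[2] >= b[2] && (a[1] > b[1] || a[2] > b[2])
}

#' Identify the Pareto front of an evaluation table
#'
#' Flags the non-dominated records: those for which no other record has
#' coverage and ModP both at least as high, with one strictly higher.
#' Records sharing an identical non-dominated (coverage, ModP) point
#' are all kept on the front.
#'
#' @param records Evaluation tibble with `coverage` and `modp` columns
#'   (e.g. from [evaluate_all()]).
#' @return Logical vector, `TRUE` for front members.
#' @export
pareto_front <- function(records) {
  n <- nrow(records)
  if (is.null(n) || n == 0L) stop("no records", call. = FALSE)
  cov <- records$coverage
  modp <- records$modp
  dominated <- logical(n)
  for (i in seq_len(n)) {
    dominated[i] <- any(cov >= cov[i] & modp >= modp[i] &
                          (cov > cov[i] | modp > modp[i]))
  }
  !dominated
}

#' Distance to the ideal solution
#'
#' Euclidean distance from a (coverage, ModP) pair to the ideal point
#' of full coverage and perfect ModP, both as fractions:
#' \eqn{\sqrt{(1-\mathrm{coverage})^2 + (1-\mathrm{ModP})^2}}.
#'
#' @param coverage,modp Numeric vectors of fractions in \eqn{[0,1]}.
#' @return Numeric vector of distances.
#' @export
ideal_distance <- function(coverage, modp) {
  sqrt((1 - coverage)^2 + (1 - modp)^2)
}

#' Pick the optimal consensus model from a front
#'
#' The optimal model is the Pareto-front record with the smallest
#' [ideal_distance()].  Ties resolve deterministically to the record
#' with fewer members, then lexicographically by member ids — smaller
#' consensus models are preferred when performance is equal.
#'
#' @param front Evaluation tibble restricted to front records (must be
#'   non-empty).
#' @return The single optimal record (one-row tibble).
#' @export
optimal_model <- function(front) {
  if (nrow(front) == 0L) stop("empty Pareto front", call. = FALSE)
  d <- ideal_distance(front$coverage, front$modp)
  ord <- order(d, front$n_members, front$members)
  front[ord[1L], , drop = FALSE]
}

#' Annotate an evaluation table with Pareto flags
#'
#' Adds `is_pareto` (front membership), `dist_ideal`, and `is_optimal`
#' (the single closest-to-ideal front member) columns.
#'
#' @param records Evaluation tibble from [evaluate_all()].
#' @return The tibble with the three columns added.
#' @export
annotate_pareto <- function(records) {
  records$is_pareto <- pareto_front(records)
  records$dist_ideal <- ideal_distance(records$coverage, records$modp)
  best <- optimal_model(records[records$is_pareto, , drop = FALSE])
  records$is_optimal <- records$is_pareto &
    records$members == best$members[1L] &
    records$scheme == best$scheme[1L]
  records
}

#' Coverage vs ModP scatter of all evaluated consensus models
#'
#' The standard diagnostic view: every consensus model as a point in
#' (coverage, ModP) space, with component models, the full consensus,
#' the Pareto front, and the optimal model distinguished.
#'
#' @param records Annotated evaluation tibble ([annotate_pareto()]).
#' @return A ggplot object.
#' @export
plot_pareto <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pareto requires the ggplot2 package", call. = FALSE)
  }
  if (!"is_pareto" %in% names(records)) records <- annotate_pareto(records)
  records$class <- ifelse(records$is_optimal, "optimal",
                    ifelse(records$is_pareto, "Pareto front",
                     ifelse(records$subtype == "component", "component",
                      ifelse(records$subtype == "full_consensus",
                             "full consensus", "other consensus"))))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = coverage, y = modp,
                               colour = class, shape = class)) +
    ggplot2::geom_point(size = 2.5, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "component" = "#E69F00", "full consensus" = "#F0E442",
      "other consensus" = "#56B4E9", "Pareto front" = "#7F7F7F",
      "optimal" = "#009E73")) +
    ggplot2::labs(x = "Coverage", y = "Modified predictivity (ModP)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
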