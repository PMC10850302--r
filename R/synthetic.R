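# Synthetic prediction panels.  Emulates the statistical structure of
# a real (Q)SAR evaluation set — binary activity with a minority of
# actives, several component models of differing sensitivity,
# specificity, and applicability-domain coverage, and optionally
# correlated errors across models (component models trained on
# overlapping chemistry rarely fail independently).  Errors are
# coupled through a shared latent Gaussian: each model's error
# indicator fires when its latent variate, correlated across models at
# `error_correlation`, falls below its own error-rate quantile, which
# preserves every model's marginal sensitivity/specificity exactly.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  code
}

default_panel_models <- function() {
  data.frame(
    model_id = c("m1", "m2", "m3", "m4"),
    sn = c(0.85, 0.80, 0.75, 0.70),
    sp = c(0.80, 0.85, 0.70, 0.75),
    coverage = c(0.95, 0.90, 0.80, 0.65),
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic prediction panel
#'
#' @param n_chemicals Number of chemicals (>= 20).
#' @param prevalence Fraction of active chemicals, strictly in (0, 1).
#' @param models Data frame with columns `model_id`, `sn`, `sp`,
#'   `coverage` (targets in \eqn{[0,1]}), one row per component model.
#'   The default is a four-model panel spanning strong/high-coverage to
#'   weak/narrow models.
#' @param error_correlation Latent correlation of prediction errors
#'   across models, in \eqn{[0, 1)}; 0 means independent errors.
#' @param seed Integer RNG seed.
#' @param descriptor_dim Descriptor-space dimension (>= 1).
#' @return List of class `panel_config`.
#' @export
panel_config <- function(n_chemicals = 2000L, prevalence = 0.2,
                         models = default_panel_models(),
                         error_correlation = 0.25, seed = 1L,
                         descriptor_dim = 8L) {
  stopifnot(n_chemicals >= 20L,
            prevalence > 0, prevalence < 1,
            is.data.frame(models), nrow(models) >= 1L,
            all(c("model_id", "sn", "sp", "coverage") %in% names(models)),
            !anyDuplicated(models$model_id),
            all(models$sn >= 0 & models$sn <= 1),
            all(models$sp >= 0 & models$sp <= 1),
            all(models$coverage >= 0 & models$coverage <= 1),
            error_correlation >= 0, error_correlation < 1,
            descriptor_dim >= 1L)
  structure(list(n_chemicals = as.integer(n_chemicals),
                 prevalence = prevalence, models = models,
                 error_correlation = error_correlation,
                 seed = as.integer(seed),
                 descriptor_dim = as.integer(descriptor_dim)),
            class = "panel_config")
}

#' Generate a synthetic prediction panel
#'
#' Draws labels Bernoulli(prevalence); per model, marks each chemical
#' out-of-domain with probability `1 - coverage`, and makes in-domain
#' predictions correct with probability `sn` (actives) or `sp`
#' (inactives).  Errors across models share a latent Gaussian factor at
#' correlation `error_correlation`.  Descriptors are drawn from two
#' Gaussian clusters (one per activity class) so kNN weighting has
#' structure to exploit; each model's reference set is the descriptors
#' of its in-domain chemicals.  Fully deterministic given the config's
#' seed.
#'
#' @param cfg A [panel_config()].
#' @return List with `table` ([prediction_table()]), `labels`
#'   ([label_set()]), `descriptors` (matrix), `refs` (per-model
#'   reference matrices), and `config`.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_chemicals
    chems <- sprintf("chem%05d", seq_len(n))
    models <- cfg$models
    active <- stats::rbinom(n, 1L, cfg$prevalence) == 1L
    if (!any(active) || all(active)) {
      stop("degenerate panel: only one activity class was drawn; ",
           "increase n_chemicals or move prevalence away from 0/1",
           call. = FALSE)
    }
    labels <- label_set(stats::setNames(
      ifelse(active, "active", "inactive"), chems))

    rho <- cfg$error_correlation
    z_shared <- stats::rnorm(n)
    preds <- matrix(NA_character_, n, nrow(models),
                    dimnames = list(chems, models$model_id))
    for (j in seq_len(nrow(models))) {
      z <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n)
      p_err <- ifelse(active, 1 - models$sn[j], 1 - models$sp[j])
      err <- stats::pnorm(z) < p_err
      pred <- ifelse(xor(active, err), "active", "inactive")
      in_ad <- stats::runif(n) < models$coverage[j]
      preds[, j] <- ifelse(in_ad, pred, "out_of_domain")
    }
    table <- prediction_table(preds)

    d <- cfg$descriptor_dim
    sep <- 2 / sqrt(d)   # inter-cluster mean distance 2, unit noise
    mu <- ifelse(active, sep, 0)
    descriptors <- matrix(stats::rnorm(n * d), n, d,
                          dimnames = list(chems,
                                          paste0("d", seq_len(d)))) + mu
    refs <- refs_from_table(table, descriptors)
    list(table = table, labels = labels, descriptors = descriptors,
         refs = refs, config = cfg)
  })
}

#' Write a synthetic panel to CSV files
#'
#' Writes `predictions.csv`, `labels.csv`, and `descriptors.csv` into a
#' directory, in the package's standard schemas.
#'
#' @param panel A [generate_panel()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(predictions = file.path(dir, "predictions.csv"),
             labels = file.path(dir, "labels.csv"),
             descriptors = file.path(dir, "descriptors.csv"))
  write_prediction_table(panel$table, paths[["predictions"]])
  write_labels(panel$labels, paths[["labels"]])
  write_descriptors(panel$descriptors, paths[["descriptors"]])
  invisible(paths)
}

#' Four-model balanced-accuracy weighting example
#'
#' A minimal, fully worked fixture for the weighted-majority mechanics:
#' a 40-chemical training panel whose four models are built to have
#' balanced accuracies of exactly 0.8, 0.75, 0.65, and 0.6 (symmetric
#' errors, so Sn = Sp = BA, and full coverage), giving BA weights
#' summing to 2.8; plus three query chemicals exercising the
#' applicability-domain rule and the weighted vote:
#' \itemize{
#'   \item `qa` is covered only by m2 and m4 (weight 1.35 < 1.4), so
#'     the consensus is out of domain;
#'   \item `qb` is covered only by m1 and m4 (weight 1.4 >= 1.4, the
#'     boundary counts as inside), so it is inside the consensus AD;
#'   \item `qc` is covered by all four, with m1 and m3 voting active
#'     (1.45) against m2 and m4 voting inactive (1.35), so the
#'     consensus is active.
#' }
#'
#' @return List with `table` (training predictions), `labels`,
#'   `weights` (the exact BA weight vector), `queries` (a 3-chemical
#'   [prediction_table()]), and `expected` (named consensus outcomes
#'   for the queries under BA weighting).
#' @export
ba_weighting_example <- function() {
  n_act <- 20L
  n_inact <- 20L
  chems <- c(sprintf("a%02d", seq_len(n_act)),
             sprintf("i%02d", seq_len(n_inact)))
  labels <- label_set(stats::setNames(
    rep(c("active", "inactive"), c(n_act, n_inact)), chems))
  ba <- c(m1 = 0.8, m2 = 0.75, m3 = 0.65, m4 = 0.6)
  preds <- matrix(NA_character_, length(chems), length(ba),
                  dimnames = list(chems, names(ba)))
  for (j in seq_along(ba)) {
    n_correct <- as.integer(round(ba[j] * n_act))  # Sn = Sp = BA
    preds[seq_len(n_act), j] <-
      rep(c("active", "inactive"), c(n_correct, n_act - n_correct))
    preds[n_act + seq_len(n_inact), j] <-
      rep(c("inactive", "active"), c(n_correct, n_inact - n_correct))
  }
  queries <- prediction_table(matrix(c(
    # m1,            m2,              m3,              m4
    "out_of_domain", "active",        "out_of_domain", "active",   # qa
    "active",        "out_of_domain", "out_of_domain", "active",   # qb
    "active",        "inactive",      "active",        "inactive"  # qc
  ), nrow = 3L, byrow = TRUE,
  dimnames = list(c("qa", "qb", "qc"), names(ba))))
  list(table = prediction_table(preds), labels = labels, weights = ba,
       queries = queries,
       expected = c(qa = "out_of_domain", qb = "active", qc = "active"))
}
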