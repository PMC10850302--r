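# Bootstrap analysis of Pareto-front composition.  The question: is
# the observed make-up of the front (which component models appear,
# and how many members the front's consensus models use) a tail event,
# or would random assignment of the same number of "Pareto" labels
# across all evaluated models produce it routinely?  Each shuffle
# draws, without replacement, a set of records of the same size as the
# observed front and recomputes the composition statistics; one-sided
# inclusive exceedance proportions ("as extreme or more extreme")
# below 5% are flagged significant.

split_members <- function(members) strsplit(members, ";", fixed = TRUE)

membership_matrix <- function(records) {
  mem <- split_members(records$members)
  models <- sort(unique(unlist(mem)))
  m <- matrix(FALSE, nrow(records), length(models),
              dimnames = list(NULL, models))
  for (i in seq_along(mem)) m[i, mem[[i]]] <- TRUE
  m
}

#' Observed Pareto-front composition
#'
#' Counts, for each component model, how many Pareto-front records
#' contain it, and the mean number of members per front record.
#'
#' @param records Evaluation tibble with an `is_pareto` column.
#' @return List with `per_model` (named integer counts over all models
#'   appearing anywhere in `records`) and `mean_size`.
#' @export
observed_composition <- function(records) {
  if (!"is_pareto" %in% names(records)) {
    stop("records lack an is_pareto column; run annotate_pareto() first",
         call. = FALSE)
  }
  front <- records[records$is_pareto, , drop = FALSE]
  if (nrow(front) == 0L) stop("no Pareto-front records", call. = FALSE)
  m_all <- membership_matrix(records)
  m_front <- m_all[records$is_pareto, , drop = FALSE]
  list(per_model = colSums(m_front), mean_size = mean(rowSums(m_front)))
}

#' Null distributions by shuffling Pareto labels
#'
#' For each iteration, uniformly samples (without replacement) as many
#' records as the observed Pareto front from all evaluated records and
#' records the same composition statistics.  Fully determined by
#' `seed`.
#'
#' @param records Evaluation tibble with `is_pareto`.
#' @param n_iter Number of shuffles (>= 1).
#' @param seed Integer RNG seed.
#' @return List with `counts` (n_iter x models matrix of per-model
#'   counts) and `mean_sizes` (length-`n_iter` vector).
#' @export
shuffle_null <- function(records, n_iter = 10000L, seed = 1L) {
  stopifnot(n_iter >= 1L)
  if (!"is_pareto" %in% names(records)) {
    stop("records lack an is_pareto column", call. = FALSE)
  }
  n_front <- sum(records$is_pareto)
  if (n_front == 0L) stop("no Pareto-front records", call. = FALSE)
  m_all <- membership_matrix(records)
  sizes <- rowSums(m_all)
  n <- nrow(records)
  counts <- matrix(0L, n_iter, ncol(m_all),
                   dimnames = list(NULL, colnames(m_all)))
  mean_sizes <- numeric(n_iter)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n, n_front)
    stopifnot(length(idx) == n_front)   # every shuffle preserves the count
    counts[i, ] <- colSums(m_all[idx, , drop = FALSE])
    mean_sizes[i] <- mean(sizes[idx])
  }
  list(counts = counts, mean_sizes = mean_sizes)
}

#' One-sided inclusive exceedance proportion
#'
#' Fraction of the null sample that is as extreme as, or more extreme
#' than, the observed value, on the given side: direction `"le"`
#' counts null values `<=` observed, `"ge"` counts `>=`.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null draws.
#' @param direction `"le"` or `"ge"`.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
exceedance <- function(observed, null, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  stopifnot(length(null) >= 1L)
  if (direction == "le") mean(null <= observed) else mean(null >= observed)
}

#' Bootstrap report on Pareto-front composition
#'
#' Runs [observed_composition()] against [shuffle_null()] and reports,
#' per component model and for the mean consensus size, the observed
#' statistic, the null mean, one-sided inclusive exceedances on both
#' sides, and a significance call at the 5% level on the side of the
#' observed deviation from the null mean.
#'
#' @param records Evaluation tibble with `is_pareto`.
#' @param n_iter Number of shuffles (default 10000).
#' @param seed Integer RNG seed.
#' @param alpha Significance level (default 0.05).
#' @return List of class `bootstrap_report` with fields `report`
#'   (tibble: `statistic`, `observed`, `null_mean`, `direction`,
#'   `exceedance`, `exceedance_le`, `exceedance_ge`, `significant`),
#'   `n_iter`, `seed`, `n_front`.
#' @export
bootstrap_pareto <- function(records, n_iter = 10000L, seed = 1L,
                             alpha = 0.05) {
  obs <- observed_composition(records)
  null <- shuffle_null(records, n_iter = n_iter, seed = seed)
  stat_names <- c(names(obs$per_model), "mean_size")
  observed <- c(obs$per_model, mean_size = obs$mean_size)
  null_cols <- c(lapply(seq_along(obs$per_model),
                        function(j) null$counts[, j]),
                 list(null$mean_sizes))
  rows <- lapply(seq_along(stat_names), function(i) {
    nv <- null_cols[[i]]
    le <- exceedance(observed[[i]], nv, "le")
    ge <- exceedance(observed[[i]], nv, "ge")
    dir <- if (observed[[i]] <= mean(nv)) "le" else "ge"
    exc <- if (dir == "le") le else ge
    tibble::tibble(statistic = stat_names[i], observed = observed[[i]],
                   null_mean = mean(nv), direction = dir,
                   exceedance = exc, exceedance_le = le,
                   exceedance_ge = ge, significant = exc < alpha)
  })
  structure(list(report = do.call(rbind, rows),
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 n_front = sum(records$is_pareto)),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report: %d shuffles, front of %d, seed %d>\n",
              x$n_iter, x$n_front, x$seed))
  print(x$report)
  invisible(x)
}

#' Write a bootstrap report CSV
#' @param report A [bootstrap_pareto()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_report <- function(report, path) {
  stopifnot(inherits(report, "bootstrap_report"))
  utils::write.csv(as.data.frame(report$report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
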