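# Shared fixtures and independent oracles used across test files.

# Brute-force non-domination check via full pairwise comparison
# matrices; independent of the package's iterate-and-compare loop.
brute_force_front <- function(cov, modp) {
  ge_cov <- outer(cov, cov, `>=`)
  ge_modp <- outer(modp, modp, `>=`)
  strict <- outer(cov, cov, `>`) | outer(modp, modp, `>`)
  dominated_by <- ge_cov & ge_modp & strict     # [i, j]: i dominates j
  colSums(dominated_by) == 0L
}

# Minimal evaluation-record tibble from raw (coverage, modp) pairs.
make_records <- function(cov, modp, members = NULL, n_members = NULL) {
  n <- length(cov)
  if (is.null(members)) members <- sprintf("m%02d", seq_len(n))
  if (is.null(n_members)) {
    n_members <- lengths(strsplit(members, ";", fixed = TRUE))
  }
  tibble::tibble(
    members = members, scheme = "majority", n_members = n_members,
    subtype = "other", coverage = cov, sn = modp, sp = modp, ba = modp,
    mod_score1 = cov * modp, predictivity = modp, modp = modp
  )
}

# A small, fast synthetic panel for integration-style tests.
small_panel <- function(seed = 11L, n = 300L) {
  generate_panel(panel_config(n_chemicals = n, seed = seed))
}
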