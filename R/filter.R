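#' Acceptance thresholds for profile-HMM hits
#'
#' The mining filter keeps a domain hit when its per-domain bit score is at
#' least `min_domain_score` (inclusive: "no less than"), its profile
#' coverage exceeds `min_profile_coverage` (strict) and its bias/score
#' ratio is below `max_bias_ratio` (strict). The defaults (30 bits, 0.75,
#' 0.1) are the standard working point for mining AA10 catalytic domains
#' out of large metagenomic protein sets.
#'
#' @param min_domain_score inclusive lower bound on the per-domain bit score.
#' @param min_profile_coverage exclusive lower bound on the fraction of
#'   profile match states covered by the hit.
#' @param max_bias_ratio exclusive upper bound on bias / score.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_domain_score = 30,
                              min_profile_coverage = 0.75,
                              max_bias_ratio = 0.1) {
  if (min_domain_score <= 0)
    stop_lpmo("lpmominer_validation", "min_domain_score must be positive")
  if (min_profile_coverage <= 0 || min_profile_coverage >= 1)
    stop_lpmo("lpmominer_validation", "min_profile_coverage must lie in (0,1)")
  if (max_bias_ratio <= 0 || max_bias_ratio >= 1)
    stop_lpmo("lpmominer_validation", "max_bias_ratio must lie in (0,1)")
  structure(list(min_domain_score = min_domain_score,
                 min_profile_coverage = min_profile_coverage,
                 max_bias_ratio = max_bias_ratio),
            class = "filter_thresholds")
}

#' Fraction of profile match states covered by a hit
#'
#' @param hits a `domain_hits` table (one or more rows).
#' @return numeric vector `(hmm_to - hmm_from + 1) / profile_length`.
#' @export
profile_coverage <- function(hits) {
  if (any(hits$profile_length <= 0))
    stop_lpmo("lpmominer_validation", "profile_length must be positive")
  (hits$hmm_to - hits$hmm_from + 1) / hits$profile_length
}

#' Apply the mining filter to domain hits
#'
#' Evaluates the three mining criteria on every hit, preserving input
#' order. A hit passes iff score >= `min_domain_score`, coverage >
#' `min_profile_coverage` and bias/score < `max_bias_ratio`. Hits with a
#' non-positive score fail with criterion token `"nonpositive_score"`
#' (the bias ratio is undefined there); metagenomic hit tables routinely
#' contain such junk rows and they must not abort a run.
#'
#' @param hits a `domain_hits` table.
#' @param thresholds a [filter_thresholds] object.
#' @return A `data.frame` with the hit columns plus `coverage`,
#'   `bias_ratio`, `passed` and `failed_criteria` (comma-separated tokens,
#'   empty iff passed).
#' @export
apply_filter <- function(hits, thresholds = filter_thresholds()) {
  validate_domain_hits(hits)
  n <- nrow(hits)
  cov <- if (n) profile_coverage(hits) else numeric()
  out <- as.data.frame(hits)
  out$coverage <- cov
  out$bias_ratio <- ifelse(hits$domain_bitscore > 0,
                           hits$bias / hits$domain_bitscore, NA_real_)
  failed <- character(n)
  for (i in seq_len(n)) {
    crit <- character()
    if (hits$domain_bitscore[i] <= 0) {
      crit <- "nonpositive_score"
    } else {
      if (hits$domain_bitscore[i] < thresholds$min_domain_score)
        crit <- c(crit, "score")
      if (!(cov[i] > thresholds$min_profile_coverage))
        crit <- c(crit, "coverage")
      if (!(out$bias_ratio[i] < thresholds$max_bias_ratio))
        crit <- c(crit, "bias_ratio")
    }
    failed[i] <- paste(crit, collapse = ",")
  }
  out$passed <- !nzchar(failed)
  out$failed_criteria <- failed
  out
}

#' Classify a candidate protein as complete or fragment
#'
#' A record is called `"complete"` when its best LPMO hit spans essentially
#' the whole profile (at most `start_slack` match states missing at the
#' profile start and `end_slack` at the end) and a mature sequence can be
#' derived for it: either the record begins with Met (an intact gene model
#' whose signal peptide is still attached) or [derive_mature()] succeeds
#' directly. Everything else is a `"fragment"`.
#'
#' @param record one-row `protein_records` table.
#' @param hit one-row `domain_hits` table belonging to that record.
#' @param reference_set reference annotations used for mature derivation.
#' @param start_slack,end_slack tolerated missing match states at the
#'   profile ends.
#' @param ... passed on to [derive_mature()].
#' @return `"complete"` or `"fragment"`.
#' @export
classify_completeness <- function(record, hit, reference_set,
                                  start_slack = 5L, end_slack = 5L, ...) {
  if (hit$hmm_from > start_slack ||
      hit$profile_length - hit$hmm_to > end_slack)
    return("fragment")
  if (substr(record$residues, 1, 1) == "M") return("complete")
  ok <- tryCatch({
    derive_mature(record, reference_set, ...)
    TRUE
  }, lpmominer_no_mature = function(e) FALSE,
     lpmominer_validation = function(e) FALSE)
  if (ok) "complete" else "fragment"
}
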