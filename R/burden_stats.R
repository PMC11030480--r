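#' Exact 2x2 association test (conditional-MLE odds ratio)
#'
#' Fisher's exact test with the conventions of the R implementation: the
#' two-sided p-value sums all tables (conditional on margins) whose
#' hypergeometric probability does not exceed the observed table's; the
#' odds ratio is the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model — not the sample cross-product ratio,
#' which is returned alongside as `or_sample`. Confidence bounds invert
#' the conditional tails exactly; boundary tables yield 0 or `Inf` bounds
#' rather than errors.
#'
#' @param x 2x2 matrix of counts (rows: cohorts; columns:
#'   carrier/non-carrier), or the count `a` with `b`, `c`, `d` supplied.
#' @param b,c,d Remaining cells when `x` is scalar `a` (row-major:
#'   `[[a, b], [c, d]]`).
#' @param confidence Confidence level for the exact interval
#'   (default 0.95).
#' @return List of class `exact_test`: `p_value`, `odds_ratio`
#'   (conditional MLE), `ci_low`, `ci_high`, `or_sample`, `table`,
#'   `method`.
#' @examples
#' fisher_exact(60, 8781, 39, 490093)$odds_ratio  # ~85.8
#' @export
fisher_exact <- function(x, b = NULL, c = NULL, d = NULL,
                         confidence = 0.95) {
  tab <- if (is.matrix(x)) x else matrix(c(x, b, c, d), nrow = 2,
                                         byrow = TRUE)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  ft <- stats::fisher.test(tab, conf.level = confidence)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 or_sample = or_sample, table = tab,
                 confidence = confidence,
                 method = "fisher_exact_conditional_mle"),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  hi <- if (is.infinite(x$ci_high)) "Inf" else format(x$ci_high,
                                                      digits = 4)
  cat(sprintf("Fisher exact test: OR = %.4g (%g%% CI %.4g-%s), p = %.3g\n",
              x$odds_ratio, 100 * x$confidence, x$ci_low, hi, x$p_value))
  invisible(x)
}

#' Carrier fraction of a cohort, in percent
#'
#' @param carriers Number of carrier probands.
#' @param total_probands Cohort size.
#' @param digits Decimal places to report (default 2; small fractions may
#'   warrant 3).
#' @return Percentage, rounded to `digits` decimals.
#' @examples
#' carrier_fraction(46, 8841)  # 0.52
#' @export
carrier_fraction <- function(carriers, total_probands, digits = 2) {
  if (total_probands <= 0) stop("total_probands must be positive")
  if (carriers < 0 || carriers > total_probands)
    stop("carriers must lie in [0, total_probands]")
  round(100 * carriers / total_probands, digits)
}

#' Extrapolate carrier prevalence to the full disease population
#'
#' An undiagnosed cohort underrepresents the full disease population when a
#' fraction of cases was already diagnosed upstream. Scaling the
#' undiagnosed denominator by `1 / (1 - prior_diagnostic_rate)` recovers
#' the full-population denominator, so the prevalence attributable to the
#' gene is `100 * carriers / (undiagnosed_total / (1 - rate))`.
#'
#' @param carriers Carrier count among undiagnosed probands.
#' @param undiagnosed_total Undiagnosed cohort size.
#' @param prior_diagnostic_rate Fraction diagnosed upstream, in \[0, 1).
#' @return Percentage, rounded to two decimals.
#' @examples
#' extrapolated_prevalence(60, 8841, 0.4)  # 0.41
#' @export
extrapolated_prevalence <- function(carriers, undiagnosed_total,
                                    prior_diagnostic_rate = 0.4) {
  if (prior_diagnostic_rate < 0 || prior_diagnostic_rate >= 1)
    stop("prior_diagnostic_rate must be in [0, 1)")
  round(100 * carriers /
          (undiagnosed_total / (1 - prior_diagnostic_rate)), 2)
}

#' Allele frequency from allele count and cohort size
#'
#' @param allele_count Alternate allele count.
#' @param n_individuals Number of sequenced individuals.
#' @param ploidy Chromosomes per individual (default 2).
#' @return Allele frequency.
#' @export
allele_frequency <- function(allele_count, n_individuals, ploidy = 2) {
  an <- ploidy * n_individuals
  if (allele_count < 0 || allele_count > an)
    stop("allele_count must lie in [0, ploidy * n_individuals]")
  allele_count / an
}

#' Allele balance at a heterozygous call
#'
#' Fraction of reads supporting the alternate allele; values near 0.5
#' support a true germline heterozygote.
#'
#' @param ref_reads,alt_reads Read counts.
#' @return `alt / (ref + alt)`.
#' @export
allele_balance <- function(ref_reads, alt_reads) {
  depth <- ref_reads + alt_reads
  if (depth <= 0) stop("zero read depth")
  alt_reads / depth
}

#' De novo burden screen across genes or regions
#'
#' For each unit (gene or sub-region) with at least `min_case_dnvs` de novo
#' variants in case probands, tests case versus control carrier counts with
#' [fisher_exact()] on `[[case, n_case - case], [control,
#' n_control - control]]`, and applies a Bonferroni threshold
#' `alpha / n_tests` where `n_tests` is the number of units tested.
#'
#' @param counts data.frame with columns `unit`, `case` (case DNV carrier
#'   count) and `control`.
#' @param n_case,n_control Cohort sizes.
#' @param min_case_dnvs Inclusion rule (default 2).
#' @param alpha Family-wise error rate (default 0.05).
#' @return data.frame of class `screen_result` (one row per tested unit:
#'   `unit`, `case`, `control`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `significant`) with attributes `n_tests` and
#'   `alpha_bonferroni`. Zero rows (and `n_tests = 0`) when no unit
#'   qualifies.
#' @export
snrna_burden_screen <- function(counts, n_case, n_control,
                                min_case_dnvs = 2, alpha = 0.05) {
  stopifnot(all(c("unit", "case", "control") %in% names(counts)))
  inc <- counts[counts$case >= min_case_dnvs, , drop = FALSE]
  n_tests <- nrow(inc)
  alpha_b <- if (n_tests > 0) alpha / n_tests else NA_real_
  res <- do.call(rbind, lapply(seq_len(n_tests), function(i) {
    ft <- fisher_exact(inc$case[i], n_case - inc$case[i],
                       inc$control[i], n_control - inc$control[i])
    data.frame(unit = inc$unit[i], case = inc$case[i],
               control = inc$control[i], odds_ratio = ft$odds_ratio,
               ci_low = ft$ci_low, ci_high = ft$ci_high,
               p_value = ft$p_value,
               significant = ft$p_value < alpha_b,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(unit = character(), case = integer(),
                      control = integer(), odds_ratio = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  attr(res, "n_tests") <- n_tests
  attr(res, "alpha_bonferroni") <- alpha_b
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Screen for recurrent de novo variants private to the case cohort
#'
#' Retains case de novo variants that are recurrent (allele count at least
#' `min_ac`), absent from every other cohort supplied, and rare in the
#' population reference (AF at most `max_pop_af`; variants missing from
#' the reference are treated as AF 0).
#'
#' @param case_dnvs data.frame with `chromosome`, `position`, `ref`,
#'   `alt`, `allele_count`.
#' @param other_cohorts Named list of data.frames with the same variant
#'   key columns; presence in any disqualifies.
#' @param population_af data.frame with the key columns plus `af`.
#' @param min_ac Minimum case allele count (default 3).
#' @param max_pop_af Maximum population AF (default 0.005).
#' @return The retained subset of `case_dnvs`, with a `pop_af` column.
#' @export
recurrent_dnv_screen <- function(case_dnvs, other_cohorts = list(),
                                 population_af = NULL, min_ac = 3,
                                 max_pop_af = 0.005) {
  key <- variant_key(case_dnvs$chromosome, case_dnvs$position,
                     case_dnvs$ref, case_dnvs$alt)
  keep <- case_dnvs$allele_count >= min_ac
  for (coh in other_cohorts) {
    if (is.null(coh) || !nrow(coh)) next
    k2 <- variant_key(coh$chromosome, coh$position, coh$ref, coh$alt)
    keep <- keep & !(key %in% k2)
  }
  pop_af <- rep(0, nrow(case_dnvs))
  if (!is.null(population_af) && nrow(population_af)) {
    kp <- variant_key(population_af$chromosome, population_af$position,
                      population_af$ref, population_af$alt)
    m <- match(key, kp)
    pop_af[!is.na(m)] <- population_af$af[m[!is.na(m)]]
  }
  keep <- keep & pop_af <= max_pop_af
  out <- case_dnvs[keep, , drop = FALSE]
  out$pop_af <- pop_af[keep]
  rownames(out) <- NULL
  out
}
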