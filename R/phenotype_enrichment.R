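#' Collapse raw phenotype term codes into phenotype groups
#'
#' Ontology annotations (HPO terms, ICD-10 codes) are collapsed into
#' analysis-level phenotype groups through an explicit code-to-group map —
#' not via ontology graph propagation. A proband is annotated with a group
#' when any of its raw codes maps to it; unmapped codes are ignored (a
#' count is reported via `message`).
#'
#' @param proband_terms data.frame with columns `proband_id`, `code`
#'   (long format, one row per assignment).
#' @param term_map data.frame with columns `code`, `group`; each code maps
#'   to at most one group.
#' @return data.frame `proband_id`, `group`, one row per distinct pair.
#' @export
collapse_terms <- function(proband_terms, term_map) {
  stopifnot(all(c("proband_id", "code") %in% names(proband_terms)),
            all(c("code", "group") %in% names(term_map)))
  if (anyDuplicated(term_map$code))
    stop("term_map assigns some code to more than one group")
  m <- match(proband_terms$code, term_map$code)
  n_unmapped <- sum(is.na(m) & !is.na(proband_terms$code))
  if (n_unmapped > 0)
    message(n_unmapped, " term assignment(s) with unmapped codes ignored")
  out <- data.frame(proband_id = proband_terms$proband_id[!is.na(m)],
                    group = term_map$group[m[!is.na(m)]],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Tabulate per-group phenotype counts for carriers versus comparators
#'
#' @param groups data.frame `proband_id`, `group` (from
#'   [collapse_terms()] or a simulator).
#' @param carrier_ids,comparator_ids Disjoint proband id vectors defining
#'   the two cohorts.
#' @return data.frame `group`, `carriers_with`, `carriers_total`,
#'   `comparators_with`, `comparators_total`.
#' @export
phenotype_counts <- function(groups, carrier_ids, comparator_ids) {
  if (length(intersect(carrier_ids, comparator_ids)))
    stop("carrier and comparator cohorts overlap")
  gl <- sort(unique(groups$group))
  cw <- vapply(gl, function(g) length(unique(
    groups$proband_id[groups$group == g &
                        groups$proband_id %in% carrier_ids])), integer(1))
  pw <- vapply(gl, function(g) length(unique(
    groups$proband_id[groups$group == g &
                        groups$proband_id %in% comparator_ids])),
    integer(1))
  data.frame(group = gl, carriers_with = cw,
             carriers_total = length(carrier_ids),
             comparators_with = pw,
             comparators_total = length(comparator_ids),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-group phenotype enrichment among carriers
#'
#' Tests each phenotype group observed in at least `min_carriers` carriers
#' with [fisher_exact()] on `[[carriers_with, carriers_without],
#' [comparators_with, comparators_without]]`. No multiple-testing
#' correction is applied; raw p-values are returned with a flag column at
#' the chosen `alpha`.
#'
#' @param counts data.frame from [phenotype_counts()].
#' @param min_carriers Minimum carrier count for a group to be tested
#'   (default 5).
#' @param alpha Flagging threshold for the `significant` column
#'   (default 0.05).
#' @return data.frame `group`, `n_carriers`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `significant`; one row per tested group.
#' @export
enrich_phenotypes <- function(counts, min_carriers = 5, alpha = 0.05) {
  inc <- counts[counts$carriers_with >= min_carriers, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(inc)), function(i) {
    ft <- fisher_exact(
      inc$carriers_with[i], inc$carriers_total[i] - inc$carriers_with[i],
      inc$comparators_with[i],
      inc$comparators_total[i] - inc$comparators_with[i])
    data.frame(group = inc$group[i], n_carriers = inc$carriers_with[i],
               odds_ratio = ft$odds_ratio, ci_low = ft$ci_low,
               ci_high = ft$ci_high, p_value = ft$p_value,
               significant = ft$p_value < alpha,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(group = character(), n_carriers = integer(),
                      odds_ratio = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
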