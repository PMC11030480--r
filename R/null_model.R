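#' Build the intergenic pool on a chromosome
#'
#' The null-region pool is the complement of all annotated transcripts
#' padded by `buffer_bp` on each side, minus any exclusion intervals
#' (e.g. the centromere), restricted to pieces at least `min_len` bp long.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param transcripts Transcript intervals: a `GRanges`, or a data.frame
#'   with `start`/`end` (and optionally `chromosome`) columns, or a
#'   GTF/GFF3/BED file path.
#' @param chromosome Chromosome to build the pool on.
#' @param chromosome_length Length of that chromosome in bp.
#' @param buffer_bp Padding around each transcript (default 10000).
#' @param min_len Minimum retained interval length (default 141).
#' @param exclusions Optional extra intervals to remove, same accepted
#'   forms as `transcripts`.
#' @return A `GRanges` of disjoint, sorted pool intervals with a
#'   `provenance` metadata string.
#' @export
build_intergenic_pool <- function(transcripts, chromosome,
                                  chromosome_length, buffer_bp = 10000,
                                  min_len = 141, exclusions = NULL) {
  tx <- .as_granges(transcripts, chromosome)
  chromosome_length <- as.integer(chromosome_length)
  pool <- GenomicRanges::GRanges(
    chromosome, IRanges::IRanges(1L, chromosome_length))
  if (length(tx)) {
    padded <- GenomicRanges::GRanges(
      chromosome,
      IRanges::IRanges(
        pmax(1L, GenomicRanges::start(tx) - as.integer(buffer_bp)),
        pmin(chromosome_length,
             GenomicRanges::end(tx) + as.integer(buffer_bp))))
    pool <- GenomicRanges::setdiff(pool, GenomicRanges::reduce(padded))
  }
  if (!is.null(exclusions)) {
    ex <- .as_granges(exclusions, chromosome)
    if (length(ex))
      pool <- GenomicRanges::setdiff(pool, GenomicRanges::reduce(ex))
  }
  pool <- pool[GenomicRanges::width(pool) >= min_len]
  pool <- GenomicRanges::sort(pool)
  S4Vectors::metadata(pool)$provenance <- sprintf(
    "complement(transcripts +/- %d bp) minus exclusions; min length %d bp",
    buffer_bp, min_len)
  pool
}

.as_granges <- function(x, chromosome) {
  if (inherits(x, "GRanges")) {
    x[as.character(GenomicRanges::seqnames(x)) == chromosome]
  } else if (is.data.frame(x)) {
    if ("chromosome" %in% names(x))
      x <- x[x$chromosome == chromosome, , drop = FALSE]
    if (!nrow(x)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chromosome,
                           IRanges::IRanges(as.integer(x$start),
                                            as.integer(x$end)))
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    gr <- rtracklayer::import(x)
    gr[as.character(GenomicRanges::seqnames(gr)) == chromosome]
  } else stop("cannot interpret intervals: supply GRanges, data.frame or ",
              "a file path")
}

#' Sample non-overlapping fixed-length regions from a pool
#'
#' Sequential rejection sampling: intervals are chosen with probability
#' proportional to the number of possible placements they admit, a start
#' is drawn uniformly, and placements overlapping earlier picks are
#' rejected. Deterministic for a given `seed`.
#'
#' @param pool `GRanges` pool from [build_intergenic_pool()].
#' @param n Number of regions (default 1000).
#' @param length Region length in bp (default 141).
#' @param seed Integer seed (optional but recommended).
#' @param max_tries Rejection budget (default `200 * n`).
#' @return A `GRanges` of `n` pairwise non-overlapping regions.
#' @export
sample_regions <- function(pool, n = 1000, length = 141, seed = NULL,
                           max_tries = 200 * n) {
  if (!length(pool)) stop("empty intergenic pool")
  widths <- GenomicRanges::width(pool)
  capacity <- sum(pmax(0L, floor(widths / length)))
  if (capacity < n)
    stop("pool capacity insufficient: at most ", capacity,
         " non-overlapping ", length, "-bp regions are achievable, ",
         n, " requested")
  starts0 <- GenomicRanges::start(pool)
  slots <- pmax(0L, widths - length + 1L)  # possible placements per piece
  chrom <- as.character(GenomicRanges::seqnames(pool)[1])
  with_seed(seed, {
    chosen_start <- integer(0)
    tries <- 0L
    while (length(chosen_start) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " non-overlapping regions in ",
             max_tries, " tries (", length(chosen_start), " placed); ",
             "achievable maximum is at most ", capacity)
      i <- sample.int(length(pool), 1L, prob = slots)
      s <- starts0[i] + sample.int(slots[i], 1L) - 1L
      e <- s + length - 1L
      if (!any(s <= chosen_start + length - 1L & e >= chosen_start))
        chosen_start <- c(chosen_start, s)
    }
    GenomicRanges::sort(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(chosen_start, width = length)))
  })
}

#' Median sliding-window observed proportion for a region
#'
#' The per-region constraint summary entering the null comparison: the
#' median across the region's sliding windows of the observed/possible SNV
#' proportion. For a [gene_locus()] the calculation matches
#' [sliding_window_profile()]; for a plain genomic region only the
#' population table is needed.
#'
#' @param x A [gene_locus()], or a `GRanges` of regions, or a data.frame
#'   with `chromosome`, `start`, `end`.
#' @param pop A [population_variants()] table.
#' @param window Window size (default 18).
#' @return Numeric vector of per-region medians.
#' @export
region_summary <- function(x, pop, window = 18L) {
  if (inherits(x, "gene_locus")) {
    prof <- sliding_window_profile(x, pop, window = window)
    return(stats::median(prof$proportion))
  }
  df <- if (inherits(x, "GRanges")) {
    data.frame(chromosome = as.character(GenomicRanges::seqnames(x)),
               start = GenomicRanges::start(x),
               end = GenomicRanges::end(x), stringsAsFactors = FALSE)
  } else as.data.frame(x)
  vapply(seq_len(nrow(df)), function(i) {
    len <- df$end[i] - df$start[i] + 1L
    if (len < window)
      stop("region ", i, " (", len, " bp) shorter than window")
    counts <- .snv_counts_by_position(pop, df$chromosome[i], df$start[i],
                                      df$end[i])
    cs <- c(0, cumsum(counts))
    offs <- seq_len(len - window + 1L)
    stats::median((cs[offs + window] - cs[offs]) / (3L * window))
  }, numeric(1))
}

#' Fisher-Pitman two-sample permutation test
#'
#' Compares two groups of continuous values by permuting group labels.
#' The statistic is the difference in group means (classical
#' Fisher-Pitman; a median-difference option is provided). The null is
#' enumerated exhaustively when the number of reassignments is at most
#' `exhaustive_cap`, otherwise sampled (Monte-Carlo) with the add-one
#' correction `p = (1 + #permuted >= observed) / (1 + n_permutations)`.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param n_permutations Monte-Carlo draws (default 1000).
#' @param alternative `"greater"` (mean of a exceeds b; default),
#'   `"less"`, or `"two.sided"`.
#' @param statistic `"mean"` or `"median"` difference.
#' @param exhaustive_cap Enumerate all reassignments when
#'   `choose(n, n_a)` is at most this (default 5000); set 0 to force
#'   Monte-Carlo.
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return List of class `permutation_test`: `statistic_observed`,
#'   `p_value`, `n_permutations`, `mode`, `alternative`, `seed`.
#' @export
fisher_pitman_mc <- function(group_a, group_b, n_permutations = 1000,
                             alternative = c("greater", "less",
                                             "two.sided"),
                             statistic = c("mean", "median"),
                             exhaustive_cap = 5000, seed = NULL) {
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  pool <- c(a, b)
  na <- length(a); nn <- length(pool)
  statfun <- if (statistic == "mean") {
    function(xa, xb) mean(xa) - mean(xb)
  } else function(xa, xb) stats::median(xa) - stats::median(xb)

  degenerate <- isTRUE(all(pool == pool[1]))
  if (degenerate)
    warning("all pooled values identical; permutation null is degenerate")

  obs <- statfun(a, b)
  score <- switch(alternative,
                  greater = function(s) s,
                  less = function(s) -s,
                  two.sided = function(s) abs(s))
  tol <- 1e-12 * max(1, abs(obs))
  hit <- function(s) score(s) >= score(obs) - tol

  n_assign <- choose(nn, na)
  if (!degenerate && n_assign <= exhaustive_cap) {
    idx <- utils::combn(nn, na)
    stats_all <- apply(idx, 2, function(i) statfun(pool[i], pool[-i]))
    p <- mean(vapply(stats_all, hit, logical(1)))
    res <- list(statistic_observed = obs, p_value = p,
                n_permutations = ncol(idx), mode = "exhaustive",
                alternative = alternative, statistic = statistic,
                seed = seed)
  } else {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(k) {
        i <- sample.int(nn, na)
        hit(statfun(pool[i], pool[-i]))
      }, logical(1)))
    })
    p <- if (degenerate) 1 else (1 + exceed) / (1 + n_permutations)
    res <- list(statistic_observed = obs, p_value = p,
                n_permutations = n_permutations, mode = "monte_carlo",
                alternative = alternative, statistic = statistic,
                seed = seed)
  }
  structure(res, class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Fisher-Pitman permutation test (%s, %s difference)\n  statistic = %.4g, p = %.4g (%s, %d permutations)\n",
    x$alternative, x$statistic, x$statistic_observed, x$p_value, x$mode,
    x$n_permutations))
  invisible(x)
}
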