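#' Proportion of possible SNVs observed in an interval
#'
#' The constraint statistic's building block: the number of distinct SNVs
#' from the population table that fall in the interval, divided by the
#' number of possible SNVs (3 per base). Indels are ignored; each distinct
#' alternate allele at a multi-allelic site contributes one unit.
#'
#' @param gene A [gene_locus()].
#' @param pop A [population_variants()] table.
#' @param n_start,n_end Transcript interval (defaults: whole gene).
#' @return Fraction in \[0, 1\].
#' @export
observed_proportion <- function(gene, pop, n_start = 1L,
                                n_end = gene_length(gene)) {
  if (n_start > n_end || n_start < 1 || n_end > gene_length(gene))
    stop("invalid transcript interval")
  g <- transcript_region_to_genomic(gene, n_start, n_end)
  counts <- .snv_counts_by_position(pop, gene$chromosome, g["start"], g["end"])
  len <- n_end - n_start + 1L
  sum(counts) / (3L * len)
}

#' Sliding-window profile of observed SNV proportions
#'
#' Splits the gene into windows of `window` bp advanced by `step` bp
#' (default 1) and computes [observed_proportion()] for each. Offsets are
#' transcript coordinates of the window start; a gene of length L yields
#' `L - window + 1` windows at step 1.
#'
#' @param gene A [gene_locus()].
#' @param pop A [population_variants()] table.
#' @param window Window size in bp (default 18).
#' @param step Step in bp (default 1).
#' @return data.frame of class `window_profile` with columns `gene_id`,
#'   `offset`, `proportion`; attributes `window`, `step`, `gene_id`.
#' @export
sliding_window_profile <- function(gene, pop, window = 18L, step = 1L) {
  L <- gene_length(gene)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1 || step < 1) stop("window and step must be >= 1")
  if (L < window)
    stop("gene ", gene$gene_id, " (", L, " bp) shorter than window (",
         window, " bp)")
  counts <- .snv_counts_by_position(pop, gene$chromosome, gene$start,
                                    gene$end)
  if (gene$strand == "-") counts <- rev(counts)  # index by transcript pos
  cs <- c(0, cumsum(counts))
  offsets <- seq.int(1L, L - window + 1L, by = step)
  prop <- (cs[offsets + window] - cs[offsets]) / (3L * window)
  out <- data.frame(gene_id = gene$gene_id, offset = offsets,
                    proportion = prop, stringsAsFactors = FALSE)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "gene_id") <- gene$gene_id
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Normalise a window profile to the per-gene median
#'
#' Subtracts the gene's median window proportion from every window, so the
#' median of the normalised values is zero and depletion appears as
#' negative values.
#'
#' @param profile A `window_profile` from [sliding_window_profile()].
#' @return The profile with an added `normalised` column.
#' @export
normalise_profile <- function(profile) {
  if (nrow(profile) < 1) stop("profile has no windows")
  profile$normalised <- profile$proportion -
    stats::median(profile$proportion)
  profile
}

#' Call depleted (constrained) regions from a normalised profile
#'
#' Windows whose normalised proportion is at or below `-threshold`
#' (strictly below when `inclusive = FALSE`) are grouped wherever they
#' overlap or abut; each group becomes one region. With
#' `extent = "union"` (default) the region spans the union of its
#' windows' extents; `extent = "intersection"` uses the bases shared by
#' all qualifying windows of the group (falling back to the most depleted
#' window's extent when the group is too wide to share any base).
#'
#' @param profile A normalised `window_profile`.
#' @param threshold Depletion magnitude (default 0.2).
#' @param inclusive Use `<= -threshold` (default) rather than `<`.
#' @param extent `"union"` or `"intersection"`.
#' @param gene Optional [gene_locus()]; if supplied, genomic coordinates
#'   are added to the output.
#' @return data.frame of class `depleted_regions` with columns `gene_id`,
#'   `n_start`, `n_end`, `min_normalised`, `n_windows` (plus `chromosome`,
#'   `start`, `end` when `gene` is given). Zero rows when nothing
#'   qualifies.
#' @export
call_depleted_regions <- function(profile, threshold = 0.2,
                                  inclusive = TRUE,
                                  extent = c("union", "intersection"),
                                  gene = NULL) {
  extent <- match.arg(extent)
  if (is.null(profile$normalised))
    stop("profile is not normalised; call normalise_profile() first")
  w <- attr(profile, "window")
  qual <- if (inclusive) profile$normalised <= -threshold
          else profile$normalised < -threshold
  empty <- data.frame(gene_id = character(), n_start = integer(),
                      n_end = integer(), min_normalised = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (!any(qual)) {
    class(empty) <- c("depleted_regions", "data.frame")
    return(empty)
  }
  q <- profile[qual, , drop = FALSE]
  # windows overlap/abut when starts differ by at most the window size
  grp <- cumsum(c(1, diff(q$offset) > w))
  out <- do.call(rbind, lapply(split(q, grp), function(d) {
    lo <- min(d$offset); hi <- max(d$offset)
    if (extent == "union") {
      n_start <- lo; n_end <- hi + w - 1L
    } else {
      n_start <- hi; n_end <- lo + w - 1L
      if (n_start > n_end) {  # no base shared by every window in the group
        best <- d$offset[which.min(d$normalised)]
        n_start <- best; n_end <- best + w - 1L
      }
    }
    data.frame(gene_id = d$gene_id[1], n_start = n_start, n_end = n_end,
               min_normalised = min(d$normalised), n_windows = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(gene)) {
    g <- t(vapply(seq_len(nrow(out)), function(i)
      transcript_region_to_genomic(gene, out$n_start[i], out$n_end[i]),
      numeric(2)))
    out$chromosome <- gene$chromosome
    out$start <- as.integer(g[, 1]); out$end <- as.integer(g[, 2])
  }
  class(out) <- c("depleted_regions", "data.frame")
  out
}

#' Minimum normalised proportion over a transcript interval
#'
#' Minimum of the normalised values among windows overlapping the interval
#' — the depth of a depleted region.
#'
#' @param profile A normalised `window_profile`.
#' @param n_start,n_end Transcript interval.
#' @return Minimum normalised value.
#' @export
min_normalised <- function(profile, n_start, n_end) {
  if (is.null(profile$normalised)) stop("profile is not normalised")
  w <- attr(profile, "window")
  sel <- profile$offset <= n_end & profile$offset + w - 1L >= n_start
  if (!any(sel)) stop("no window overlaps the interval ", n_start, "-",
                      n_end)
  min(profile$normalised[sel])
}

#' Write a window profile or depleted regions as TSV/BED
#'
#' @param x A `window_profile` or `depleted_regions` data.frame.
#' @param path Output path; for depleted regions a `.bed` extension emits
#'   0-based half-open BED (requires genomic coordinates), anything else a
#'   TSV.
#' @return `path`, invisibly.
#' @export
write_scan_output <- function(x, path) {
  if (inherits(x, "depleted_regions") && grepl("\\.bed$", path)) {
    if (is.null(x$start)) stop("no genomic coordinates on regions")
    bed <- data.frame(x$chromosome, x$start - 1L, x$end, x$gene_id,
                      stringsAsFactors = FALSE)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
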