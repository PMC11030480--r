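#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' analysis constants used throughout the package: 18-bp windows, a 0.2
#' depletion threshold, 1,000 null regions of 141 bp sampled at least
#' 10 kbp from any transcript, 1,000 permutations, a two-DNV inclusion
#' rule for the burden screen, allele count >= 3 with population
#' AF <= 0.5% for the recurrent screen, alpha 0.05 and a 40% upstream
#' diagnostic rate for the prevalence extrapolation.
#'
#' @param preset `"synthetic"` (simulate inputs from `simulation`) or
#'   `"files"` (read inputs from `inputs`).
#' @param window_size Sliding-window size in bp.
#' @param depletion_threshold Depletion magnitude for region calling.
#' @param null_region_count,null_region_length Intergenic null regions:
#'   how many, how long.
#' @param transcript_buffer Buffer around transcripts excluded from the
#'   intergenic pool (bp).
#' @param n_permutations Monte-Carlo permutations for the null test.
#' @param min_case_dnvs Burden-screen inclusion rule.
#' @param min_ac,max_pop_af Recurrent-screen thresholds.
#' @param min_carriers Phenotype-enrichment inclusion rule.
#' @param alpha Family-wise error rate.
#' @param prior_diagnostic_rate Upstream diagnostic rate for the
#'   prevalence extrapolation.
#' @param seed Master seed; stage seeds are derived from it.
#' @param simulation A [simulation_config()] (synthetic preset).
#' @param null_test_genes Gene ids whose constraint summaries form the
#'   test group of the null comparison (default: the constrained genes of
#'   the simulation).
#' @param inputs Named list of file paths for the files preset:
#'   `annotation`, `fasta`, `population`, `case_dnvs`, `control_dnvs`,
#'   optionally `phenotypes`, `carriers`, `chromosome_length`.
#' @return List of class `run_config`.
#' @export
run_config <- function(preset = c("synthetic", "files"),
                       window_size = 18L, depletion_threshold = 0.2,
                       null_region_count = 1000L,
                       null_region_length = 141L,
                       transcript_buffer = 10000L,
                       n_permutations = 1000L, min_case_dnvs = 2L,
                       min_ac = 3L, max_pop_af = 0.005,
                       min_carriers = 5L, alpha = 0.05,
                       prior_diagnostic_rate = 0.4, seed = 1L,
                       simulation = NULL, null_test_genes = NULL,
                       inputs = list()) {
  preset <- match.arg(preset)
  if (window_size < 1 || null_region_length < window_size)
    stop("need window_size >= 1 and null_region_length >= window_size")
  if (depletion_threshold < 0 || depletion_threshold > 1)
    stop("depletion_threshold must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (prior_diagnostic_rate < 0 || prior_diagnostic_rate >= 1)
    stop("prior_diagnostic_rate must lie in [0, 1)")
  if (preset == "synthetic" && is.null(simulation))
    simulation <- simulation_config(seed = seed)
  if (preset == "files") {
    req <- c("annotation", "fasta", "population", "case_dnvs",
             "control_dnvs")
    miss <- setdiff(req, names(inputs))
    if (length(miss))
      stop("files preset needs inputs: ", paste(miss, collapse = ", "))
  }
  structure(list(preset = preset, window_size = as.integer(window_size),
                 depletion_threshold = depletion_threshold,
                 null_region_count = as.integer(null_region_count),
                 null_region_length = as.integer(null_region_length),
                 transcript_buffer = as.integer(transcript_buffer),
                 n_permutations = as.integer(n_permutations),
                 min_case_dnvs = as.integer(min_case_dnvs),
                 min_ac = as.integer(min_ac), max_pop_af = max_pop_af,
                 min_carriers = as.integer(min_carriers), alpha = alpha,
                 prior_diagnostic_rate = prior_diagnostic_rate,
                 seed = as.integer(seed), simulation = simulation,
                 null_test_genes = null_test_genes, inputs = inputs),
            class = "run_config")
}

#' Run the full discovery pipeline
#'
#' Executes constraint scan, intergenic null test, de novo burden screen
#' (gene- and region-level), recurrent-DNV screen, and phenotype
#' enrichment, writing per-stage TSV/JSON outputs plus a run manifest to
#' `out_dir`. Reruns with the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report bundle: a list with the per-stage result
#'   objects and the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs -------------------------------------------------------
  if (config$preset == "synthetic") {
    simc <- config$simulation
    genes <- simc$genes
    sim <- simulate_cohorts(simc, seed = config$seed)
    pop <- sim$population
    case_dnvs <- sim$dnvs$case
    control_dnvs <- sim$dnvs$control
    phen <- sim$phenotypes
    carrier_ids <- sim$carrier_ids
    n_case <- simc$n_case; n_control <- simc$n_control
  } else {
    inp <- config$inputs
    genes <- stage("load_inputs",
                   load_annotation(inp$annotation, inp$fasta))
    pop <- stage("load_inputs", read_population_variants(inp$population))
    case_dnvs <- utils::read.delim(inp$case_dnvs,
                                   stringsAsFactors = FALSE)
    control_dnvs <- utils::read.delim(inp$control_dnvs,
                                      stringsAsFactors = FALSE)
    phen <- if (!is.null(inp$phenotypes))
      utils::read.delim(inp$phenotypes, stringsAsFactors = FALSE)
    carrier_ids <- if (!is.null(inp$carriers))
      readLines(inp$carriers)
    n_case <- inp$n_case %||% length(unique(case_dnvs$proband_id))
    n_control <- inp$n_control %||%
      length(unique(control_dnvs$proband_id))
  }
  min_len <- min(vapply(genes, gene_length, integer(1)))
  if (config$window_size > min_len)
    stop("window_size (", config$window_size,
         ") exceeds the shortest gene (", min_len, " bp)")

  ## ---- stage: constraint scan --------------------------------------
  scan <- stage("scan", {
    profiles <- lapply(genes, function(g)
      normalise_profile(sliding_window_profile(
        g, pop, window = config$window_size)))
    regions <- do.call(rbind, lapply(names(profiles), function(id) {
      r <- call_depleted_regions(profiles[[id]],
                                 threshold = config$depletion_threshold,
                                 gene = genes[[id]])
      r
    }))
    list(profiles = profiles, regions = regions)
  })

  ## ---- stage: intergenic null test ---------------------------------
  null_test <- stage("null_test", {
    chrom <- genes[[1]]$chromosome
    tx <- data.frame(
      chromosome = vapply(genes, `[[`, character(1), "chromosome"),
      start = vapply(genes, `[[`, integer(1), "start"),
      end = vapply(genes, `[[`, integer(1), "end"))
    chrom_len <- config$inputs$chromosome_length %||%
      (max(tx$end) + 2000000L)
    pool <- build_intergenic_pool(tx, chrom, chrom_len,
                                  buffer_bp = config$transcript_buffer,
                                  min_len = config$null_region_length)
    regions <- sample_regions(pool, n = config$null_region_count,
                              length = config$null_region_length,
                              seed = config$seed + 10L)
    region_pop <- if (config$preset == "synthetic")
      simulate_region_variants(regions, config$simulation$intergenic_q,
                               config$simulation,
                               seed = config$seed + 11L)
    else pop
    test_ids <- config$null_test_genes %||%
      (if (config$preset == "synthetic")
         names(config$simulation$constrained_regions)
       else names(genes))
    gene_summaries <- vapply(genes[test_ids], region_summary,
                             numeric(1), pop = pop,
                             window = config$window_size)
    region_summaries <- region_summary(regions, region_pop,
                                       window = config$window_size)
    test <- fisher_pitman_mc(gene_summaries, region_summaries,
                             n_permutations = config$n_permutations,
                             alternative = "greater",
                             exhaustive_cap = 0,
                             seed = config$seed + 12L)
    list(pool = pool, regions = regions,
         gene_summaries = gene_summaries,
         region_summaries = region_summaries, test = test)
  })

  ## ---- stage: burden screens ---------------------------------------
  burden <- stage("burden", {
    counts <- data.frame(
      unit = names(genes),
      case = vapply(names(genes), function(id)
        count_dnv_carriers(case_dnvs, genes[[id]]), integer(1)),
      control = vapply(names(genes), function(id)
        count_dnv_carriers(control_dnvs, genes[[id]]), integer(1)),
      stringsAsFactors = FALSE)
    gene_screen <- snrna_burden_screen(counts, n_case, n_control,
                                       min_case_dnvs =
                                         config$min_case_dnvs,
                                       alpha = config$alpha)
    reg <- scan$regions
    region_counts <- if (!is.null(reg) && nrow(reg)) data.frame(
      unit = sprintf("%s:n.%d-%d", reg$gene_id, reg$n_start, reg$n_end),
      case = vapply(seq_len(nrow(reg)), function(i)
        count_dnv_carriers(case_dnvs, genes[[reg$gene_id[i]]],
                           reg$n_start[i], reg$n_end[i]), integer(1)),
      control = vapply(seq_len(nrow(reg)), function(i)
        count_dnv_carriers(control_dnvs, genes[[reg$gene_id[i]]],
                           reg$n_start[i], reg$n_end[i]), integer(1)),
      stringsAsFactors = FALSE)
    else data.frame(unit = character(), case = integer(),
                    control = integer(), stringsAsFactors = FALSE)
    region_screen <- snrna_burden_screen(region_counts, n_case,
                                         n_control,
                                         min_case_dnvs =
                                           config$min_case_dnvs,
                                         alpha = config$alpha)
    list(gene_counts = counts, gene_screen = gene_screen,
         region_counts = region_counts, region_screen = region_screen)
  })

  ## ---- stage: recurrent-DNV screen ---------------------------------
  recurrent <- stage("recurrent", {
    agg <- function(d) {
      if (!nrow(d)) return(data.frame(chromosome = character(),
                                      position = integer(),
                                      ref = character(),
                                      alt = character(),
                                      allele_count = integer(),
                                      stringsAsFactors = FALSE))
      k <- variant_key(d$chromosome, d$position, d$ref, d$alt)
      u <- !duplicated(k)
      out <- d[u, c("chromosome", "position", "ref", "alt"),
               drop = FALSE]
      out$allele_count <- as.integer(table(k)[k[u]])
      rownames(out) <- NULL
      out
    }
    case_agg <- agg(case_dnvs)
    pop_af <- data.frame(chromosome = pop$chromosome,
                         position = pop$position, ref = pop$ref,
                         alt = pop$alt,
                         af = pop$allele_count / pop$allele_number,
                         stringsAsFactors = FALSE)
    recurrent_dnv_screen(case_agg,
                         other_cohorts = list(control = agg(control_dnvs)),
                         population_af = pop_af,
                         min_ac = config$min_ac,
                         max_pop_af = config$max_pop_af)
  })

  ## ---- stage: phenotype enrichment ---------------------------------
  phenotypes <- stage("phenotypes", {
    if (is.null(phen) || is.null(carrier_ids)) return(NULL)
    all_case <- if (config$preset == "synthetic")
      sprintf("case_%06d", seq_len(n_case))
    else unique(c(case_dnvs$proband_id, phen$proband_id))
    counts <- phenotype_counts(phen, carrier_ids,
                               setdiff(all_case, carrier_ids))
    list(counts = counts,
         enrichment = enrich_phenotypes(counts,
                                        min_carriers =
                                          config$min_carriers,
                                        alpha = config$alpha))
  })

  ## ---- outputs ------------------------------------------------------
  paths <- list()
  w <- function(x, file) {
    p <- file.path(out_dir, file)
    utils::write.table(as.data.frame(x), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  prof_all <- do.call(rbind, lapply(scan$profiles, as.data.frame))
  rownames(prof_all) <- NULL
  paths$profiles <- w(prof_all, "window_profiles.tsv")
  paths$regions <- w(scan$regions, "depleted_regions.tsv")
  if (nrow(scan$regions))
    paths$regions_bed <- write_scan_output(
      scan$regions, file.path(out_dir, "depleted_regions.bed"))
  paths$gene_screen <- w(burden$gene_screen, "burden_gene_screen.tsv")
  paths$region_screen <- w(burden$region_screen,
                           "burden_region_screen.tsv")
  paths$recurrent <- w(recurrent, "recurrent_dnv_screen.tsv")
  if (!is.null(phenotypes))
    paths$phenotypes <- w(phenotypes$enrichment,
                          "phenotype_enrichment.tsv")
  nt <- null_test$test
  paths$null_test <- file.path(out_dir, "null_test.json")
  jsonlite::write_json(
    list(statistic_observed = nt$statistic_observed,
         p_value = nt$p_value, n_permutations = nt$n_permutations,
         mode = nt$mode, alternative = nt$alternative,
         seed = nt$seed,
         gene_summaries = as.list(null_test$gene_summaries),
         median_region_summary =
           stats::median(null_test$region_summaries)),
    paths$null_test, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_flat <- config[setdiff(names(config), c("simulation", "inputs"))]
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(package = "snarc",
         version = as.character(utils::packageVersion("snarc")),
         seed = config$seed, preset = config$preset,
         parameters = cfg_flat,
         outputs = lapply(paths[names(paths) != "manifest"], basename)),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scan = scan, null_test = null_test, burden = burden,
                 recurrent = recurrent, phenotypes = phenotypes,
                 paths = paths))
}
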