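#' Synthetic 141-bp minus-strand snRNA-like gene fixture
#'
#' A synthetic gene locus emulating the structure of a brain-expressed
#' U4-like snRNA: 141 bp, minus strand, at chr12:120,291,763-120,291,903,
#' with a constrained region at transcript positions 62-79 and a recurrent
#' single-base insertion hotspot anchored at chr12:120,291,839 (T>TA,
#' i.e. n.64_65insT). The sequence is synthetic (seeded random bases) with
#' the handful of transcript positions referenced by the coordinate-mapping
#' conventions planted to fixed values; it is not the real U4 sequence.
#'
#' @param gene_id Identifier (default `"RNU4L2"`).
#' @param end Genomic end coordinate (default 120291903).
#' @param chromosome Chromosome (default `"chr12"`).
#' @param mutate Integer: number of positions to substitute (deterministic,
#'   outside the planted set), used to derive a homologous paralog fixture.
#' @return A [gene_locus()].
#' @export
rnu4_like_gene <- function(gene_id = "RNU4L2", end = 120291903L,
                           chromosome = "chr12", mutate = 0L) {
  L <- 141L
  base <- with_seed(420L,
    sample(c("A", "C", "G", "T"), L, replace = TRUE,
           prob = c(0.3, 0.2, 0.2, 0.3)))
  # transcript-position anchors used by the n. nomenclature conventions
  planted <- c(`61` = "T", `62` = "T", `63` = "T", `64` = "T", `65` = "A",
               `66` = "T", `67` = "A", `68` = "A", `69` = "C", `76` = "C",
               `77` = "T", `78` = "A", `79` = "G")
  base[as.integer(names(planted))] <- planted
  if (mutate > 0) {
    free <- setdiff(seq_len(L), as.integer(names(planted)))
    idx <- with_seed(77L, sample(free, mutate))
    base[idx] <- vapply(base[idx], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  }
  gene_locus(gene_id, chromosome, "-", end - L + 1L, end,
             paste(base, collapse = ""), name = gene_id,
             biotype = "snRNA")
}

#' Default simulated gene set
#'
#' Four synthetic loci: the target (constrained and case-enriched), a
#' highly homologous paralog differing by four nucleotides (constrained in
#' the population but not enriched in cases), and two unconstrained decoys
#' that give the burden screen true negatives.
#'
#' @return Named list of [gene_locus()] objects.
#' @export
default_gene_set <- function() {
  target <- rnu4_like_gene("RNU4L2", end = 120291903L)
  paralog <- rnu4_like_gene("RNU4L1", end = 120293903L, mutate = 4L)
  decoy1 <- with_seed(101L, gene_locus(
    "SNDECOY1", "chr12", "+", 120500001L, 120500141L,
    paste(sample(c("A", "C", "G", "T"), 141, replace = TRUE),
          collapse = ""), biotype = "snRNA"))
  decoy2 <- with_seed(102L, gene_locus(
    "SNDECOY2", "chr12", "-", 121000001L, 121000141L,
    paste(sample(c("A", "C", "G", "T"), 141, replace = TRUE),
          collapse = ""), biotype = "snRNA"))
  list(RNU4L2 = target, RNU4L1 = paralog, SNDECOY1 = decoy1,
       SNDECOY2 = decoy2)
}

#' Simulation configuration
#'
#' All generative parameters for the synthetic cohorts. The defaults are
#' the study conditions the analysis assumes: per-possible-SNV observation
#' probability 0.78 outside versus 0.26 inside the constrained region
#' (transcript 62-79), maximum simulated allele frequency 0.025%,
#' population of 490,640 individuals, 8,841 case (undiagnosed) and 4,776
#' comparator probands, 77.3% of in-region case de novo variants being the
#' recurrent hotspot insertion, and an average of 13% of possible SNVs
#' observed in intergenic sequence.
#'
#' @param genes Named list of [gene_locus()] (default
#'   [default_gene_set()]).
#' @param constrained_regions Named list, gene id to `c(n_start, n_end)`;
#'   genes absent from the list are unconstrained.
#' @param enriched_gene Gene id receiving the case de novo enrichment.
#' @param q_out,q_in Per-possible-SNV observation probabilities outside /
#'   inside the constrained region.
#' @param af_max Cap on simulated allele frequency.
#' @param population_size Individuals in the population cohort.
#' @param n_case,n_control Proband counts for the de novo cohorts.
#' @param dnv_rate Baseline de novo variants per proband per gene.
#' @param region_enrichment Multiplier on the case in-region de novo rate.
#' @param insertion_weight Fraction of in-region case variants that are
#'   the fixed hotspot insertion.
#' @param hotspot The recurrent insertion, a [genomic_variant()].
#' @param intergenic_q Per-possible-SNV observation probability in
#'   intergenic null regions.
#' @param ac_geom_p Geometric-tail parameter for allele counts of observed
#'   population variants (truncated at `af_max`).
#' @param phenotype_baseline Baseline per-group phenotype probability
#'   among non-carriers.
#' @param phenotype_ors Named vector of per-group carrier odds ratios.
#' @param seed Default seed carried with the configuration.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(genes = default_gene_set(),
                              constrained_regions = list(
                                RNU4L2 = c(62L, 79L),
                                RNU4L1 = c(62L, 79L)),
                              enriched_gene = "RNU4L2",
                              q_out = 0.78, q_in = 0.26,
                              af_max = 2.5e-4,
                              population_size = 490640L,
                              n_case = 8841L, n_control = 4776L,
                              dnv_rate = 3e-4,
                              region_enrichment = 100,
                              insertion_weight = 0.773,
                              hotspot = genomic_variant(
                                "chr12", 120291839L, "T", "TA"),
                              intergenic_q = 0.13,
                              ac_geom_p = 0.3,
                              phenotype_baseline = 0.2,
                              phenotype_ors = c(
                                global_developmental_delay = 3.56,
                                delayed_gross_motor = 2.55,
                                microcephaly = 6.62,
                                delayed_fine_motor = 2.61,
                                hypotonia = 3.60,
                                short_stature = 3.54,
                                drooling = 19.2,
                                absent_speech = 6.23),
                              seed = 1L) {
  probs <- c(q_out = q_out, q_in = q_in, intergenic_q = intergenic_q,
             insertion_weight = insertion_weight,
             phenotype_baseline = phenotype_baseline, af_max = af_max)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (region_enrichment < 0) stop("region_enrichment must be >= 0")
  if (any(c(population_size, n_case, n_control) < 0) || dnv_rate < 0)
    stop("counts and rates must be >= 0")
  if (any(phenotype_ors <= 0)) stop("phenotype odds ratios must be > 0")
  structure(list(genes = genes,
                 constrained_regions = constrained_regions,
                 enriched_gene = enriched_gene, q_out = q_out,
                 q_in = q_in, af_max = af_max,
                 population_size = as.integer(population_size),
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 dnv_rate = dnv_rate,
                 region_enrichment = region_enrichment,
                 insertion_weight = insertion_weight, hotspot = hotspot,
                 intergenic_q = intergenic_q, ac_geom_p = ac_geom_p,
                 phenotype_baseline = phenotype_baseline,
                 phenotype_ors = phenotype_ors,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# allele counts 1..max_ac from a geometric tail truncated at af_max
.sim_allele_counts <- function(n, p, max_ac) {
  if (n == 0) return(integer(0))
  u <- stats::runif(n) * stats::pgeom(max_ac - 1L, p)
  1L + stats::qgeom(u, p)
}

#' Simulate a population variant table over the configured genes
#'
#' Each possible SNV of each gene is observed independently with
#' probability `q_in` inside the gene's constrained region and `q_out`
#' elsewhere; observed variants receive allele counts from a geometric
#' tail truncated at `af_max` times the population allele number.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed`).
#' @return A [population_variants()] table (with a `gene_id` column).
#' @export
simulate_population <- function(config, seed = config$seed) {
  an <- 2L * config$population_size
  max_ac <- max(1L, floor(config$af_max * an))
  with_seed(seed, {
    tabs <- lapply(names(config$genes), function(id) {
      g <- config$genes[[id]]
      poss <- enumerate_possible_snvs(g)
      region <- config$constrained_regions[[id]]
      q <- rep(config$q_out, nrow(poss))
      if (!is.null(region))
        q[poss$n >= region[1] & poss$n <= region[2]] <- config$q_in
      obs <- poss[stats::runif(nrow(poss)) < q, , drop = FALSE]
      if (!nrow(obs)) return(NULL)
      obs$gene_id <- id
      obs
    })
    v <- do.call(rbind, tabs)
    if (is.null(v))
      v <- data.frame(chromosome = character(), position = integer(),
                      ref = character(), alt = character(),
                      n = integer(), gene_id = character())
    v$allele_count <- .sim_allele_counts(nrow(v), config$ac_geom_p,
                                         max_ac)
    v$allele_number <- an
    population_variants(v[, c("chromosome", "position", "ref", "alt",
                              "allele_count", "allele_number",
                              "gene_id")],
                        cohort_size = config$population_size)
  })
}

#' Simulate population variants over plain genomic regions
#'
#' Used for the intergenic null: every position admits 3 possible SNVs,
#' each observed independently with probability `q`.
#'
#' @param regions `GRanges` or data.frame with `chromosome`, `start`,
#'   `end`.
#' @param q Per-possible-SNV observation probability (e.g.
#'   `config$intergenic_q`).
#' @param config A [simulation_config()] (for allele-count parameters).
#' @param seed Seed.
#' @return A [population_variants()] table.
#' @export
simulate_region_variants <- function(regions, q, config,
                                     seed = config$seed) {
  df <- if (inherits(regions, "GRanges")) {
    data.frame(chromosome = as.character(
                 GenomicRanges::seqnames(regions)),
               start = GenomicRanges::start(regions),
               end = GenomicRanges::end(regions),
               stringsAsFactors = FALSE)
  } else as.data.frame(regions)
  an <- 2L * config$population_size
  max_ac <- max(1L, floor(config$af_max * an))
  with_seed(seed, {
    tabs <- lapply(seq_len(nrow(df)), function(i) {
      pos <- seq.int(df$start[i], df$end[i])
      cand <- data.frame(chromosome = df$chromosome[i],
                         position = rep(pos, each = 3L),
                         ref = "A",
                         alt = rep(c("C", "G", "T"), length(pos)),
                         stringsAsFactors = FALSE)
      cand[stats::runif(nrow(cand)) < q, , drop = FALSE]
    })
    v <- unique(do.call(rbind, tabs))
    v$allele_count <- .sim_allele_counts(nrow(v), config$ac_geom_p,
                                         max_ac)
    v$allele_number <- an
    population_variants(v, cohort_size = config$population_size)
  })
}

# draw k uniform de novo SNVs over transcript positions `n_range` of gene
.sim_dnv_snvs <- function(gene, n_range, k) {
  if (k == 0)
    return(data.frame(chromosome = character(), position = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  n <- n_range[sample.int(length(n_range), k, replace = TRUE)]
  poss <- enumerate_possible_snvs(gene)
  out <- do.call(rbind, lapply(n, function(ni) {
    rows <- poss[poss$n == ni, , drop = FALSE]
    rows[sample.int(3L, 1L), c("chromosome", "position", "ref", "alt"),
         drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Simulate case and control de novo variant tables
#'
#' Control probands draw de novo variants uniformly over each gene at
#' `dnv_rate` per proband per gene. Case probands draw at the baseline
#' rate outside the enriched gene's constrained region and at
#' `dnv_rate * region_enrichment` (per-bp) inside it; a fraction
#' `insertion_weight` of the in-region case variants is the fixed hotspot
#' insertion, the rest are random in-region SNVs.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed`).
#' @return List with data.frames `case` and `control` (columns
#'   `proband_id`, `gene_id`, `chromosome`, `position`, `ref`, `alt`).
#' @export
simulate_denovo_cohorts <- function(config, seed = config$seed) {
  with_seed(seed, {
    arm <- function(n_probands, prefix, enriched) {
      rows <- lapply(names(config$genes), function(id) {
        g <- config$genes[[id]]
        L <- gene_length(g)
        region <- config$constrained_regions[[id]]
        enrich_here <- enriched && identical(id, config$enriched_gene) &&
          !is.null(region)
        if (enrich_here) {
          L_in <- region[2] - region[1] + 1L
          k_out <- stats::rpois(1, n_probands * config$dnv_rate *
                                  (L - L_in) / L)
          k_in <- stats::rpois(1, n_probands * config$dnv_rate *
                                 (L_in / L) * config$region_enrichment)
          out_rng <- setdiff(seq_len(L), seq.int(region[1], region[2]))
          v_out <- .sim_dnv_snvs(g, out_rng, k_out)
          n_hot <- stats::rbinom(1, k_in, config$insertion_weight)
          v_hot <- if (n_hot > 0) {
            data.frame(chromosome = config$hotspot$chromosome,
                       position = rep(config$hotspot$position, n_hot),
                       ref = config$hotspot$ref,
                       alt = config$hotspot$alt,
                       stringsAsFactors = FALSE)
          } else NULL
          v_in <- .sim_dnv_snvs(g, seq.int(region[1], region[2]),
                                k_in - n_hot)
          v <- rbind(v_out, v_hot, v_in)
        } else {
          k <- stats::rpois(1, n_probands * config$dnv_rate)
          v <- .sim_dnv_snvs(g, seq_len(L), k)
        }
        if (!nrow(v)) return(NULL)
        v$gene_id <- id
        v
      })
      v <- do.call(rbind, rows)
      if (is.null(v))
        return(data.frame(proband_id = character(),
                          gene_id = character(),
                          chromosome = character(), position = integer(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE))
      v$proband_id <- sprintf("%s_%06d",
                              prefix, sample.int(n_probands, nrow(v),
                                                 replace = TRUE))
      rownames(v) <- NULL
      v[, c("proband_id", "gene_id", "chromosome", "position", "ref",
            "alt")]
    }
    list(case = arm(config$n_case, "case", TRUE),
         control = arm(config$n_control, "ctrl", FALSE))
  })
}

#' Simulate per-proband phenotype groups
#'
#' Non-carriers have each phenotype group with probability `p0`; carriers
#' with the probability `p1` solving `odds(p1) = OR * odds(p0)`.
#'
#' @param carrier Named logical vector: carrier status per proband id.
#' @param p0 Baseline probability.
#' @param odds_ratios Named vector of per-group odds ratios.
#' @param seed Seed.
#' @return data.frame `proband_id`, `group` (long format).
#' @export
simulate_phenotypes <- function(carrier, p0, odds_ratios, seed = NULL) {
  if (any(odds_ratios <= 0)) stop("odds ratios must be > 0")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  ids <- names(carrier)
  if (is.null(ids)) stop("carrier vector must be named by proband id")
  odds0 <- p0 / (1 - p0)
  with_seed(seed, {
    rows <- lapply(names(odds_ratios), function(g) {
      p1 <- odds_ratios[[g]] * odds0 / (1 + odds_ratios[[g]] * odds0)
      p <- ifelse(carrier, p1, p0)
      has <- stats::runif(length(ids)) < p
      if (!any(has)) return(NULL)
      data.frame(proband_id = ids[has], group = g,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(proband_id = character(), group = character(),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the full synthetic study
#'
#' Population table, case/control de novo tables, phenotype assignments
#' (carriers of the hotspot insertion versus all other case probands),
#' and the planted truth, bundled for end-to-end pipeline runs and
#' recovery tests.
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed`); the stage seeds are derived
#'   from it deterministically.
#' @return List of class `simulated_cohorts`: `population`, `dnvs`
#'   (`$case`, `$control`), `phenotypes`, `carrier_ids`, `truth`.
#' @export
simulate_cohorts <- function(config, seed = config$seed) {
  seed <- as.integer(seed)
  pop <- simulate_population(config, seed = seed)
  dnvs <- simulate_denovo_cohorts(config, seed = seed + 1L)
  hot <- config$hotspot
  hot_key <- variant_key(hot$chromosome, hot$position, hot$ref, hot$alt)
  case_keys <- variant_key(dnvs$case$chromosome, dnvs$case$position,
                           dnvs$case$ref, dnvs$case$alt)
  carrier_ids <- unique(dnvs$case$proband_id[case_keys == hot_key])
  all_case <- sprintf("case_%06d", seq_len(config$n_case))
  carrier <- stats::setNames(all_case %in% carrier_ids, all_case)
  phen <- simulate_phenotypes(carrier, config$phenotype_baseline,
                              config$phenotype_ors, seed = seed + 2L)
  truth <- list(config = config, seed = seed,
                constrained_regions = config$constrained_regions,
                enriched_gene = config$enriched_gene,
                hotspot_key = hot_key, n_carriers = length(carrier_ids))
  structure(list(population = pop, dnvs = dnvs, phenotypes = phen,
                 carrier_ids = carrier_ids, truth = truth),
            class = "simulated_cohorts")
}

#' Count distinct de novo carrier probands per gene (or sub-region)
#'
#' @param dnvs A de novo table from [simulate_denovo_cohorts()] (or the
#'   same columns read from TSV).
#' @param gene A [gene_locus()].
#' @param n_start,n_end Optional transcript sub-interval; when given, only
#'   variants whose genomic position falls inside it are counted.
#' @return Integer count of distinct probands.
#' @export
count_dnv_carriers <- function(dnvs, gene, n_start = NULL, n_end = NULL) {
  sel <- dnvs$gene_id == gene$gene_id &
    dnvs$chromosome == gene$chromosome
  if (!is.null(n_start)) {
    g <- transcript_region_to_genomic(gene, n_start, n_end)
    sel <- sel & dnvs$position >= g["start"] & dnvs$position <= g["end"]
  }
  length(unique(dnvs$proband_id[sel]))
}
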