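test_that("population simulation honours the observation probabilities", {
  g <- rnu4_like_gene()
  cfg0 <- simulation_config(genes = list(RNU4L2 = g), q_in = 0)
  pop0 <- simulate_population(cfg0, seed = 1)
  region <- transcript_region_to_genomic(g, 62, 79)
  expect_equal(sum(pop0$position >= region["start"] &
                     pop0$position <= region["end"]), 0L)

  cfg1 <- simulation_config(genes = list(RNU4L2 = g), q_out = 1)
  pop1 <- simulate_population(cfg1, seed = 1)
  out_n <- pop1$position < region["start"] | pop1$position > region["end"]
  expect_equal(sum(out_n), 3L * (141L - 18L))

  # binomial oracle: 369 out-of-region possible SNVs at q_out = 0.78
  cfg <- simulation_config(genes = list(RNU4L2 = g))
  n_out <- vapply(1:40, function(s) {
    p <- simulate_population(cfg, seed = s)
    sum(p$position < region["start"] | p$position > region["end"])
  }, numeric(1))
  mu <- 369 * 0.78
  sd3 <- 3 * sqrt(369 * 0.78 * 0.22)
  expect_true(all(abs(n_out - mu) <= sd3))
  expect_lt(abs(mean(n_out) - mu), sd3 / 4)
})

test_that("simulated allele frequencies respect the rare-variant cap", {
  cfg <- simulation_config()
  pop <- simulate_population(cfg, seed = 3)
  af <- pop$allele_count / pop$allele_number
  expect_true(all(af <= cfg$af_max))
  expect_true(all(pop$allele_count >= 1))
  expect_identical(as.data.frame(simulate_population(cfg, seed = 3)),
                   as.data.frame(pop))
})

test_that("de novo simulation plants the recurrent hotspot insertion", {
  cfg <- simulation_config(insertion_weight = 1)
  dnv <- simulate_denovo_cohorts(cfg, seed = 2)
  g <- cfg$genes[[cfg$enriched_gene]]
  region <- transcript_region_to_genomic(g, 62, 79)
  inreg <- dnv$case[dnv$case$gene_id == cfg$enriched_gene &
                      dnv$case$position >= region["start"] &
                      dnv$case$position <= region["end"], ]
  expect_gt(nrow(inreg), 0)
  expect_true(all(inreg$alt == cfg$hotspot$alt &
                    inreg$position == cfg$hotspot$position))
  # controls never receive the enrichment or the hotspot
  expect_false(any(dnv$control$alt == cfg$hotspot$alt &
                     nchar(dnv$control$alt) > 1))
})

test_that("null de novo enrichment gives calibrated odds-ratio coverage", {
  g <- rnu4_like_gene()
  cfg <- simulation_config(genes = list(RNU4L2 = g),
                           region_enrichment = 1, insertion_weight = 0,
                           n_case = 5000L, n_control = 5000L,
                           dnv_rate = 5e-3)
  covered <- 0L
  for (seed in 1:50) {
    dnv <- simulate_denovo_cohorts(cfg, seed = seed)
    region <- transcript_region_to_genomic(g, 62, 79)
    ca <- count_dnv_carriers(dnv$case, g, 62, 79)
    co <- count_dnv_carriers(dnv$control, g, 62, 79)
    ft <- fisher_exact(ca, 5000 - ca, co, 5000 - co)
    if (ft$ci_low <= 1 && ft$ci_high >= 1) covered <- covered + 1L
  }
  expect_gte(covered, 45L)
})

test_that("a planted de novo enrichment is recovered within the exact CI", {
  g <- rnu4_like_gene()
  cfg <- simulation_config(genes = list(RNU4L2 = g),
                           n_case = 8841L, n_control = 490132L,
                           region_enrichment = 100)
  L <- 141; L_in <- 18
  p_case <- 1 - exp(-cfg$dnv_rate * (L_in / L) * cfg$region_enrichment)
  p_ctrl <- 1 - exp(-cfg$dnv_rate * (L_in / L))
  or_true <- (p_case / (1 - p_case)) / (p_ctrl / (1 - p_ctrl))
  covered <- 0L
  for (seed in 1:50) {
    dnv <- simulate_denovo_cohorts(cfg, seed = seed)
    ca <- count_dnv_carriers(dnv$case, g, 62, 79)
    co <- count_dnv_carriers(dnv$control, g, 62, 79)
    ft <- fisher_exact(ca, cfg$n_case - ca, co, cfg$n_control - co)
    if (ft$ci_low <= or_true && ft$ci_high >= or_true)
      covered <- covered + 1L
  }
  expect_gte(covered, 45L)
})

test_that("phenotype simulation solves the carrier odds correctly", {
  carrier <- stats::setNames(rep(c(TRUE, FALSE), c(4000, 4000)),
                             sprintf("p%05d", 1:8000))
  ph <- simulate_phenotypes(carrier, p0 = 0.5, odds_ratios = c(g1 = 9),
                            seed = 4)
  rate_car <- mean(names(carrier)[carrier] %in% ph$proband_id)
  rate_non <- mean(names(carrier)[!carrier] %in% ph$proband_id)
  expect_lt(abs(rate_car - 0.9), 0.03)   # odds 1 -> 9 means p1 = 0.9
  expect_lt(abs(rate_non - 0.5), 0.03)

  ph1 <- simulate_phenotypes(carrier, p0 = 0.3, odds_ratios = c(g1 = 1),
                             seed = 5)
  expect_lt(abs(mean(names(carrier)[carrier] %in% ph1$proband_id) -
                  mean(names(carrier)[!carrier] %in% ph1$proband_id)),
            0.04)
  expect_error(simulate_phenotypes(carrier, 0.5, c(g1 = -2)), "> 0")
})

test_that("a planted phenotype odds ratio is recovered within the exact CI", {
  carrier <- stats::setNames(rep(c(TRUE, FALSE), c(500, 5000)),
                             sprintf("p%05d", 1:5500))
  covered <- 0L
  for (seed in 1:30) {
    ph <- simulate_phenotypes(carrier, p0 = 0.2,
                              odds_ratios = c(g1 = 3.5), seed = seed)
    counts <- phenotype_counts(ph, names(carrier)[carrier],
                               names(carrier)[!carrier])
    res <- enrich_phenotypes(counts)
    if (res$ci_low <= 3.5 && res$ci_high >= 3.5) covered <- covered + 1L
  }
  expect_gte(covered, 26L)
})

test_that("full cohort simulation is deterministic and carries its truth", {
  cfg <- simulation_config()
  a <- simulate_cohorts(cfg, seed = 11)
  b <- simulate_cohorts(cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(as.data.frame(a$population),
                         as.data.frame(simulate_cohorts(cfg, 12)$population)))
  expect_equal(a$truth$hotspot_key, "chr12:120291839:T:TA")
  expect_equal(a$truth$enriched_gene, "RNU4L2")
  expect_equal(a$truth$n_carriers, length(a$carrier_ids))
  expect_true(all(c("constrained_regions", "config", "seed") %in%
                    names(a$truth)))
  # the recurrent insertion dominates in-region case variants
  g <- cfg$genes$RNU4L2
  region <- transcript_region_to_genomic(g, 62, 79)
  inreg <- a$dnvs$case[a$dnvs$case$gene_id == "RNU4L2" &
                         a$dnvs$case$position >= region["start"] &
                         a$dnvs$case$position <= region["end"], ]
  frac_hot <- mean(inreg$alt == "TA")
  expect_lt(abs(frac_hot - 0.773), 0.15)
})
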