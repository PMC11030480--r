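test_that("observed proportion counts distinct SNVs over possible SNVs", {
  g <- toy_gene("+", L = 18L)
  # 14 distinct SNVs spread over the first 7 positions
  counts <- stats::setNames(c(3, 3, 3, 3, 1, 1, 0), as.character(1:7))
  pop <- pop_with_counts(g, counts)
  expect_equal(observed_proportion(g, pop), 14 / 54)
  expect_equal(observed_proportion(g, make_pop(data.frame())), 0)
  all54 <- pop_with_counts(g, stats::setNames(rep(3, 18),
                                              as.character(1:18)))
  expect_equal(observed_proportion(g, all54), 1)
  # indels never enter the numerator
  ins <- make_pop(data.frame(chromosome = "chrT",
                             position = g$start, ref = "A", alt = "AT"))
  expect_equal(observed_proportion(g, ins), 0)
})

test_that("window layout follows gene length, and short genes error", {
  g <- rnu4_like_gene()
  pop <- make_pop(data.frame())
  expect_equal(nrow(sliding_window_profile(g, pop)), 141 - 18 + 1)
  g18 <- toy_gene("+", L = 18L)
  expect_equal(nrow(sliding_window_profile(g18, pop)), 1L)
  expect_error(sliding_window_profile(toy_gene("+", L = 10L), pop),
               "shorter than window")
})

test_that("normalisation subtracts the per-gene median", {
  expect_equal(normalise_profile(fake_profile(c(0.5, 0.5, 0.5)))$normalised,
               c(0, 0, 0))
  expect_equal(normalise_profile(fake_profile(c(0.2, 0.8, 0.8)))$normalised,
               c(-0.6, 0, 0))
  # a 26%-observed window against a 78% gene median sits at -0.52
  p <- normalise_profile(fake_profile(c(0.26, rep(0.78, 10))))
  expect_equal(p$normalised[1], -0.52)
  expect_equal(stats::median(p$normalised), 0)
})

test_that("depleted-region calling merges qualifying windows by overlap", {
  flat <- normalise_profile(fake_profile(rep(0.5, 30)))
  expect_equal(nrow(call_depleted_regions(flat)), 0L)

  one <- fake_profile(rep(0.8, 124))
  one$proportion[62] <- 0.4
  r <- call_depleted_regions(normalise_profile(one))
  expect_equal(c(r$n_start, r$n_end), c(62L, 79L))
  expect_equal(r$n_windows, 1L)

  two <- fake_profile(rep(0.8, 124))
  two$proportion[c(10, 11)] <- 0.4
  r <- call_depleted_regions(normalise_profile(two))
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$n_start, r$n_end), c(10L, 28L))

  # brute-force union oracle over enumerated window extents
  ext <- do.call(rbind, lapply(c(10, 11), function(o)
    data.frame(lo = o, hi = o + 17)))
  expect_equal(r$n_start, min(ext$lo))
  expect_equal(r$n_end, max(ext$hi))

  # threshold inclusivity: a window exactly at -threshold qualifies by
  # default (binary-exact values so the boundary comparison is exact)
  edge <- fake_profile(c(rep(0.75, 20), 0.5))
  expect_equal(nrow(call_depleted_regions(normalise_profile(edge),
                                          threshold = 0.25)), 1L)
  expect_equal(nrow(call_depleted_regions(normalise_profile(edge),
                                          threshold = 0.25,
                                          inclusive = FALSE)), 0L)

  # intersection mode returns the shared core of the qualifying windows
  r2 <- call_depleted_regions(normalise_profile(two),
                              extent = "intersection")
  expect_equal(c(r2$n_start, r2$n_end), c(11L, 27L))
})

test_that("min_normalised is the minimum over overlapping windows", {
  p <- normalise_profile(fake_profile(c(0.7, 0.3, 0.5, 0.8, 0.8, 0.8,
                                        0.8)))
  vals <- p$normalised
  expect_equal(min_normalised(p, 1, 20), min(vals[1:3]))
  expect_equal(min_normalised(p, 2, 2), min(vals[1:2]))
  expect_error(min_normalised(p, 200, 300), "no window overlaps")
})

test_that("normalisation is a pure shift of the profile", {
  g <- rnu4_like_gene()
  cfg <- simulation_config()
  for (seed in c(3, 14, 27)) {
    pop <- simulate_population(cfg, seed = seed)
    p <- normalise_profile(sliding_window_profile(g, pop))
    expect_equal(max(p$normalised) - min(p$normalised),
                 max(p$proportion) - min(p$proportion))
  }
})

test_that("removing observed variants never increases a window proportion", {
  g <- toy_gene("-", L = 40L)
  cfg <- simulation_config(genes = list(TOY = g),
                           constrained_regions = list(),
                           enriched_gene = "TOY")
  pop <- simulate_population(cfg, seed = 5)
  base <- sliding_window_profile(g, pop)$proportion
  for (drop_n in c(1, 5, 10)) {
    idx <- with_seed_test(drop_n, sample(nrow(pop),
                                         min(drop_n, nrow(pop))))
    thinned <- population_variants(as.data.frame(pop)[-idx, ],
                                   cohort_size = 100L)
    expect_true(all(sliding_window_profile(g, thinned)$proportion <=
                      base + 1e-12))
  }
})

test_that("a planted depleted region is recovered across seeds", {
  # weaker-contrast setting than the defaults: q_out 0.7, q_in 0.3
  g <- rnu4_like_gene()
  cfg <- simulation_config(genes = list(RNU4L2 = g), q_out = 0.7,
                           q_in = 0.3)
  hits <- 0L
  for (seed in 1:100) {
    pop <- simulate_population(cfg, seed = seed)
    prof <- normalise_profile(sliding_window_profile(g, pop))
    regs <- call_depleted_regions(prof)
    if (nrow(regs) && any(regs$n_start <= 79 & regs$n_end >= 62))
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("depleted regions carry genomic coordinates when a gene is given", {
  g <- rnu4_like_gene()
  cfg <- simulation_config(genes = list(RNU4L2 = g))
  pop <- simulate_population(cfg, seed = 2)
  prof <- normalise_profile(sliding_window_profile(g, pop))
  regs <- call_depleted_regions(prof, gene = g)
  expect_true(nrow(regs) >= 1)
  expect_equal(regs$chromosome[1], "chr12")
  expect_equal(unname(transcript_region_to_genomic(
    g, regs$n_start[1], regs$n_end[1])),
    c(regs$start[1], regs$end[1]))
})
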