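test_that("annotation loading extracts strand-aware transcript sequences", {
  dir <- withr::local_tempdir()
  fa <- write_toy_fasta(dir, list(chrT = "ACGTACGGGG"))
  gdf <- data.frame(chromosome = "chrT", start = 1L, end = 6L,
                    strand = "+", gene_id = "Gp", name = "Gp",
                    biotype = "snRNA", stringsAsFactors = FALSE)
  g <- load_annotation(write_toy_annotation(dir, gdf, "gtf"), fa)
  expect_equal(g[["Gp"]]$sequence, "ACGTAC")

  gdf$strand <- "-"; gdf$gene_id <- gdf$name <- "Gm"
  g <- load_annotation(write_toy_annotation(dir, gdf, "gtf"), fa)
  expect_equal(g[["Gm"]]$sequence, "GTACGT")

  # BED is 0-based half-open: 0..6 becomes the same 1-based 1..6 interval
  gdf$strand <- "+"; gdf$gene_id <- gdf$name <- "Gb"
  g <- load_annotation(write_toy_annotation(dir, gdf, "bed"), fa)
  expect_equal(c(g[["Gb"]]$start, g[["Gb"]]$end), c(1L, 6L))
  expect_equal(g[["Gb"]]$sequence, "ACGTAC")

  # missing chromosome in FASTA is an error naming the record
  gdf$chromosome <- "chrZ"
  expect_error(load_annotation(write_toy_annotation(dir, gdf, "gtf"), fa),
               "no FASTA sequence")
})

test_that("snRNA gene selection applies strict CPM and pseudogene rules", {
  genes <- list(A = toy_gene(gene_id = "A"), B = toy_gene(gene_id = "B"),
                P = gene_locus("RNU9-90P", "chrT", "+", 1, 30,
                               toy_gene()$sequence))
  names(genes)[3] <- "RNU9-90P"
  expr <- rbind(A = c(6, 6, 6), B = c(5, 5, 5), `RNU9-90P` = c(90, 90, 90))
  kept <- select_snrna_genes(genes, expr, min_mean_cpm = 5)
  expect_equal(names(kept), "A")   # B fails the strict >5, P is a pseudogene

  # explicit exclusion list wins even for well-expressed, benignly named genes
  kept <- select_snrna_genes(genes[1:2], expr, exclude = "A")
  expect_equal(names(kept), character(0))

  # genes absent from the table are excluded with a warning
  expect_warning(
    kept <- select_snrna_genes(list(Z = toy_gene(gene_id = "Z")), expr),
    "absent from expression table")
  expect_length(kept, 0)

  # 30 candidates, 2 failing, leaves 28
  many <- lapply(sprintf("G%02d", 1:30), function(id)
    toy_gene(gene_id = id))
  names(many) <- sprintf("G%02d", 1:30)
  em <- matrix(10, 30, 3, dimnames = list(names(many), NULL))
  em[c("G07", "G21"), ] <- 1
  expect_length(select_snrna_genes(many, em), 28)
})

test_that("minus-strand mapping reproduces the reference n. nomenclature", {
  g <- rnu4_like_gene()
  expect_equal(
    genomic_to_transcript(g, genomic_variant("chr12", 120291839, "T",
                                             "TA"))$n_description,
    "n.64_65insT")
  expect_equal(
    genomic_to_transcript(g, genomic_variant("chr12", 120291841, "A",
                                             "C"))$n_description,
    "n.63T>G")
  expect_equal(
    genomic_to_transcript(g, genomic_variant("chr12", 120291826, "T",
                                             "TA"))$n_description,
    "n.77_78insT")
  expect_equal(
    genomic_to_transcript(g, genomic_variant("chr12", 120291828, "G",
                                             "A"))$n_description,
    "n.76C>T")

  gp <- toy_gene("+", L = 30, start = 100)
  tv <- genomic_to_transcript(gp, genomic_variant("chrT", 105, "A", "G"))
  expect_equal(tv$n_start, 6L)
  expect_equal(tv$n_description, "n.6A>G")

  expect_error(
    genomic_to_transcript(g, genomic_variant("chr12", 120291700, "A",
                                             "C")),
    "outside locus")
})

test_that("interval mapping is order-normalised and bounded", {
  g <- rnu4_like_gene()
  expect_equal(unname(genomic_region_to_transcript(g, 120291825,
                                                   120291842)),
               c(62L, 79L))
  expect_equal(unname(genomic_region_to_transcript(g, g$start, g$end)),
               c(1L, 141L))
  expect_equal(unname(genomic_region_to_transcript(g, 120291839,
                                                   120291839)),
               c(65L, 65L))
  expect_equal(unname(transcript_region_to_genomic(g, 62, 79)),
               c(120291825L, 120291842L))
  expect_error(genomic_region_to_transcript(g, g$start - 5, g$start + 5),
               "not contained")
})

test_that("possible-SNV enumeration yields exactly three alternates per base", {
  g <- rnu4_like_gene()
  expect_equal(nrow(enumerate_possible_snvs(g, 62, 79)), 54L)
  all_snvs <- enumerate_possible_snvs(g)
  expect_equal(nrow(all_snvs), 423L)
  expect_true(all(all_snvs$ref != all_snvs$alt))
  one <- enumerate_possible_snvs(toy_gene("+", L = 1, seed = 1), 1, 1)
  expect_setequal(one$alt, setdiff(c("A", "C", "G", "T"), one$ref[1]))
  expect_error(enumerate_possible_snvs(g, 10, 9), "empty interval")
})

test_that("sequence identity is the percent of matching positions", {
  a <- rnu4_like_gene()$sequence
  b <- rnu4_like_gene("B", mutate = 4)$sequence
  expect_equal(sequence_identity(a, b), 97.2)
  expect_equal(sequence_identity(a, a), 100.0)
  expect_equal(sequence_identity("AAAA", "TTTT"), 0.0)
  expect_error(sequence_identity("AAA", "AAAA"), "length")
})

test_that("coordinate mapping round-trips on random loci of both strands", {
  for (seed in 1:20) {
    strand <- if (seed %% 2) "+" else "-"
    g <- toy_gene(strand, L = 50L, start = 500L + seed,
                  gene_id = paste0("R", seed), seed = seed)
    poss <- enumerate_possible_snvs(g)
    rows <- with_seed_test(seed, sample(nrow(poss), 10))
    for (i in rows) {
      v <- genomic_variant(poss$chromosome[i], poss$position[i],
                           poss$ref[i], poss$alt[i])
      back <- transcript_to_genomic(g, genomic_to_transcript(g, v))
      expect_identical(back[c("chromosome", "position", "ref", "alt")],
                       v[c("chromosome", "position", "ref", "alt")])
    }
    # anchored insertions round-trip as well (not at the 3' boundary)
    pos <- with_seed_test(seed + 100, sample(g$start:(g$end - 1L), 5))
    for (p in pos) {
      off <- p - g$start + 1L
      base_plus <- if (strand == "+") substr(g$sequence, off, off)
        else chartr("ACGT", "TGCA",
                    substr(g$sequence, g$end - p + 1L, g$end - p + 1L))
      v <- genomic_variant(g$chromosome, p, base_plus,
                           paste0(base_plus, "T"))
      back <- transcript_to_genomic(g, genomic_to_transcript(g, v))
      expect_identical(back[c("position", "ref", "alt")],
                       v[c("position", "ref", "alt")])
    }
    # minus-strand coordinate identity: n(g) + g = end + 1
    if (strand == "-") {
      tv <- genomic_to_transcript(g, genomic_variant(g$chromosome,
                                                     g$start + 7L,
                                                     poss$ref[poss$position == g$start + 7L][1],
                                                     poss$alt[poss$position == g$start + 7L][1]))
      expect_equal(tv$n_start + g$start + 7L, g$end + 1L)
    }
  }
})
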