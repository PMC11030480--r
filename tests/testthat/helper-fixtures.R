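# Shared fixtures built in code: tiny genes, population tables assembled
# from explicit variant lists, and writers for toy annotation files.

toy_gene <- function(strand = "+", L = 30L, start = 1001L,
                     gene_id = "TOY", chromosome = "chrT",
                     seed = 11L) {
  seq <- with_seed_test(seed, paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  gene_locus(gene_id, chromosome, strand, start, start + L - 1L, seq)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# population table from a data.frame of SNVs (defaults AC=1, AN=2e5)
make_pop <- function(snvs, cohort_size = 100000L) {
  if (!nrow(snvs)) {
    snvs <- data.frame(chromosome = character(), position = integer(),
                       ref = character(), alt = character())
  }
  snvs$allele_count <- snvs$allele_count %||% rep(1L, nrow(snvs))
  snvs$allele_number <- snvs$allele_number %||%
    rep(2L * cohort_size, nrow(snvs))
  population_variants(snvs, cohort_size = cohort_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population in which a fixed set of transcript positions carries exactly
# `per_site` observed SNVs each (alts taken from the possible set)
pop_with_counts <- function(gene, site_counts) {
  poss <- enumerate_possible_snvs(gene)
  rows <- do.call(rbind, lapply(names(site_counts), function(n) {
    k <- site_counts[[n]]
    if (k == 0) return(NULL)
    sub <- poss[poss$n == as.integer(n), , drop = FALSE]
    sub[seq_len(k), c("chromosome", "position", "ref", "alt")]
  }))
  if (is.null(rows))
    rows <- data.frame(chromosome = character(), position = integer(),
                       ref = character(), alt = character())
  make_pop(rows)
}

# fabricate a window profile directly (for normalisation arithmetic tests)
fake_profile <- function(proportions, window = 18L, gene_id = "FAKE") {
  out <- data.frame(gene_id = gene_id,
                    offset = seq_along(proportions),
                    proportion = proportions, stringsAsFactors = FALSE)
  attr(out, "window") <- window
  attr(out, "step") <- 1L
  attr(out, "gene_id") <- gene_id
  class(out) <- c("window_profile", "data.frame")
  out
}

write_toy_annotation <- function(dir, genes_df, format = c("gtf", "bed")) {
  format <- match.arg(format)
  path <- file.path(dir, paste0("genes.", format))
  if (format == "gtf") {
    lines <- sprintf(
      '%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
      genes_df$chromosome, genes_df$start, genes_df$end, genes_df$strand,
      genes_df$gene_id, genes_df$name, genes_df$biotype)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     genes_df$chromosome, genes_df$start - 1L,
                     genes_df$end, genes_df$gene_id, genes_df$strand)
  }
  writeLines(lines, path)
  path
}

write_toy_fasta <- function(dir, seqs) {
  path <- file.path(dir, "ref.fa")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  path
}
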