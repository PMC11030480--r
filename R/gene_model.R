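#' Construct a small-gene locus
#'
#' A `gene_locus` holds everything needed to move between genomic and
#' transcript coordinates for a short, single-exon non-coding gene: the
#' genomic interval (1-based, inclusive, as in VCF), the strand, and the
#' transcript-orientation (5'->3') sequence. For a minus-strand gene the
#' stored sequence is the reverse complement of the plus-strand reference
#' over `start..end`.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name (e.g. `"chr12"`).
#' @param strand `"+"` or `"-"`.
#' @param start,end Genomic interval, 1-based inclusive, `start <= end`.
#' @param sequence Transcript-orientation nucleotide string, length
#'   `end - start + 1`, alphabet A/C/G/T.
#' @param name Display name (defaults to `gene_id`); used by the
#'   pseudogene-name heuristic in [select_snrna_genes()].
#' @param biotype Optional biotype label (e.g. `"snRNA"`).
#' @return An object of class `gene_locus`.
#' @examples
#' g <- gene_locus("G1", "chr1", "+", 101, 106, "ACGTAC")
#' gene_length(g)
#' @export
gene_locus <- function(gene_id, chromosome, strand, start, end, sequence,
                       name = gene_id, biotype = NA_character_) {
  stopifnot(is.character(gene_id), length(gene_id) == 1)
  strand <- as.character(strand)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got: ", strand)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid interval for ", gene_id, ": start must be <= end")
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) != end - start + 1L)
    stop("sequence length (", nchar(sequence), ") does not match interval ",
         "length (", end - start + 1L, ") for ", gene_id)
  if (grepl("[^ACGT]", sequence))
    stop("sequence for ", gene_id, " contains non-ACGT characters")
  structure(
    list(gene_id = gene_id, chromosome = as.character(chromosome),
         strand = strand, start = start, end = end, sequence = sequence,
         name = name, biotype = biotype),
    class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s (%s) %s:%d-%d (%s), %d bp\n",
              x$gene_id, x$name, x$chromosome, x$start, x$end, x$strand,
              gene_length(x)))
  invisible(x)
}

#' Gene length in bp
#' @param gene A [gene_locus()].
#' @export
gene_length <- function(gene) gene$end - gene$start + 1L

#' Load gene loci from an annotation file plus reference sequences
#'
#' Reads gene records from GTF/GFF3 or BED (BED's 0-based half-open
#' intervals are converted to 1-based inclusive at the boundary) and
#' attaches transcript-orientation sequences extracted from a FASTA of the
#' underlying reference (one record per chromosome/contig). Minus-strand
#' intervals are reverse complemented.
#'
#' @param annotation_file Path to a GTF, GFF3 or BED file.
#' @param sequence_file Path to a FASTA covering the annotated intervals.
#' @param feature_type For GTF/GFF3, which `type` values to keep
#'   (default `"gene"`; ignored for BED and for files without a type
#'   column).
#' @return A named list of [gene_locus()] objects.
#' @export
load_annotation <- function(annotation_file, sequence_file,
                            feature_type = "gene") {
  gr <- tryCatch(rtracklayer::import(annotation_file),
                 error = function(e)
                   stop("malformed annotation file '", annotation_file,
                        "': ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type %in% feature_type))
    gr <- gr[md$type %in% feature_type]
  if (length(gr) == 0)
    stop("no usable records in ", annotation_file)

  seqs <- Biostrings::readDNAStringSet(sequence_file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  md <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(md)) as.character(md$gene_id)
         else if ("ID" %in% names(md)) as.character(md$ID)
         else if ("name" %in% names(md)) as.character(md$name)
         else paste0("gene_", seq_along(gr))
  nms <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
         else if ("Name" %in% names(md)) as.character(md$Name)
         else ids
  bts <- if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype)
         else if ("biotype" %in% names(md)) as.character(md$biotype)
         else rep(NA_character_, length(gr))

  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    st <- GenomicRanges::start(gr)[i]
    en <- GenomicRanges::end(gr)[i]
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (strand == "*") strand <- "+"
    if (!chrom %in% names(seqs))
      stop("record ", i, " (", ids[i], "): no FASTA sequence named '",
           chrom, "'")
    if (en > Biostrings::width(seqs[chrom]))
      stop("record ", i, " (", ids[i], "): interval ", st, "-", en,
           " extends beyond sequence '", chrom, "' (",
           Biostrings::width(seqs[chrom]), " bp)")
    sq <- Biostrings::subseq(seqs[[chrom]], st, en)
    if (strand == "-") sq <- Biostrings::reverseComplement(sq)
    out[[i]] <- gene_locus(ids[i], chrom, strand, st, en,
                           as.character(sq), name = nms[i],
                           biotype = bts[i])
  }
  names(out) <- ids
  out
}

#' Select expressed, non-pseudogene snRNA genes
#'
#' Applies the two inclusion rules used for building the analysis gene set:
#' (i) drop pseudogenes, via an explicit exclusion list and/or a gene-name
#' heuristic (a trailing "P" designation, e.g. `RNU4-2P`, `RNU6-1128P`);
#' (ii) keep genes whose mean expression across samples is strictly above
#' `min_mean_cpm` (CPM). Genes missing from the expression table are
#' excluded with a warning.
#'
#' @param genes List of [gene_locus()] objects.
#' @param expression Numeric matrix or data.frame of CPM values, rows named
#'   by gene id (or gene name), columns are samples.
#' @param min_mean_cpm Strict lower bound on mean CPM (default 5).
#' @param exclude Character vector of gene ids/names curated as pseudogenes;
#'   always excluded (the list wins over the heuristic).
#' @param use_name_heuristic Apply the trailing-"P" pseudogene name rule
#'   (default `TRUE`).
#' @return The retained subset of `genes` (a named list).
#' @export
select_snrna_genes <- function(genes, expression, min_mean_cpm = 5,
                               exclude = character(),
                               use_name_heuristic = TRUE) {
  expression <- as.matrix(expression)
  if (!is.numeric(expression))
    stop("expression table must be numeric")
  if (any(expression < 0, na.rm = TRUE))
    stop("expression table contains negative CPM values")
  keep <- vapply(genes, function(g) {
    if (g$gene_id %in% exclude || g$name %in% exclude) return(FALSE)
    if (use_name_heuristic &&
        (grepl("P[0-9]*$", g$name) || grepl("P[0-9]*$", g$gene_id)))
      return(FALSE)
    row <- if (g$gene_id %in% rownames(expression)) g$gene_id
           else if (g$name %in% rownames(expression)) g$name
           else NA_character_
    if (is.na(row)) {
      warning("gene ", g$gene_id, " absent from expression table; excluded")
      return(FALSE)
    }
    mean(expression[row, ], na.rm = TRUE) > min_mean_cpm
  }, logical(1))
  genes[keep]
}

#' Construct a genomic variant record
#'
#' Alleles follow VCF conventions: SNVs have single-base `ref`/`alt`;
#' insertions and deletions are left-anchored (`alt = ref +` inserted bases
#' for an insertion) on the plus strand.
#'
#' @param chromosome,position,ref,alt VCF-style fields (1-based position).
#' @return A list of class `genomic_variant` with a derived `type` field
#'   (`"SNV"`, `"insertion"` or `"deletion"`).
#' @export
genomic_variant <- function(chromosome, position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref and alt alleles are identical")
  type <- if (nchar(ref) == 1 && nchar(alt) == 1) "SNV"
          else if (nchar(alt) > nchar(ref)) "insertion"
          else "deletion"
  structure(list(chromosome = as.character(chromosome),
                 position = as.integer(position),
                 ref = ref, alt = alt, type = type),
            class = "genomic_variant")
}

# position g -> transcript coordinate n
.g2n <- function(gene, g) {
  if (gene$strand == "-") gene$end - g + 1L else g - gene$start + 1L
}
# transcript coordinate n -> genomic position
.n2g <- function(gene, n) {
  if (gene$strand == "-") gene$end - n + 1L else gene$start + n - 1L
}

#' Map a genomic variant into transcript (n.) coordinates
#'
#' Produces an HGVS-like `n.` description. On minus-strand genes the
#' transcript coordinate of genomic position g is `end - g + 1`,
#' substitution alleles are complemented, and an insertion anchored after
#' plus-strand position g falls between transcript positions `n(g+1)` and
#' `n(g)` with the inserted bases reverse complemented. No 3'-shift
#' normalisation is applied: descriptions are by direct arithmetic, so a
#' variant in a homopolymer keeps its literal position (a deliberate
#' deviation from strict HGVS normalisation).
#'
#' @param gene A [gene_locus()].
#' @param variant A [genomic_variant()] (or list with the same fields).
#' @return A list of class `transcript_variant` with `gene_id`,
#'   `n_description`, `type` and structured coordinate/allele fields.
#' @examples
#' g <- gene_locus("G", "chr1", "+", 100, 120,
#'                 paste(rep("A", 21), collapse = ""))
#' genomic_to_transcript(g, genomic_variant("chr1", 105, "A", "G"))
#' @export
genomic_to_transcript <- function(gene, variant) {
  v <- variant
  if (v$chromosome != gene$chromosome)
    stop("variant on ", v$chromosome, " but gene ", gene$gene_id, " is on ",
         gene$chromosome)
  L <- gene_length(gene)
  minus <- gene$strand == "-"
  if (v$position < gene$start || v$position > gene$end)
    stop("position ", v$position, " outside locus ", gene$gene_id,
         " (", gene$start, "-", gene$end, ")")

  if (v$type == "SNV") {
    n <- .g2n(gene, v$position)
    ref_t <- if (minus) comp_base(v$ref) else v$ref
    alt_t <- if (minus) comp_base(v$alt) else v$alt
    tv <- list(gene_id = gene$gene_id,
               n_description = sprintf("n.%d%s>%s", n, ref_t, alt_t),
               type = "SNV", n_start = n, n_end = n,
               ref = ref_t, alt = alt_t)
  } else if (v$type == "insertion") {
    if (substr(v$alt, 1, nchar(v$ref)) != v$ref)
      stop("insertion alt is not ref-anchored: ", v$ref, ">", v$alt)
    inserted <- substr(v$alt, nchar(v$ref) + 1L, nchar(v$alt))
    anchor <- v$position + nchar(v$ref) - 1L  # insertion after this base
    if (anchor + 1L > gene$end)
      stop("insertion point outside locus ", gene$gene_id)
    if (minus) {
      n_lo <- .g2n(gene, anchor + 1L)  # = n(anchor) - 1
      ins_t <- revcomp(inserted)
    } else {
      n_lo <- .g2n(gene, anchor)
      ins_t <- inserted
    }
    tv <- list(gene_id = gene$gene_id,
               n_description = sprintf("n.%d_%dins%s", n_lo, n_lo + 1L, ins_t),
               type = "insertion", n_start = n_lo, n_end = n_lo + 1L,
               ref = "", alt = ins_t)
  } else {  # deletion: VCF-anchored, deleted bases follow the anchor
    deleted <- substr(v$ref, nchar(v$alt) + 1L, nchar(v$ref))
    g_first <- v$position + nchar(v$alt)
    g_last <- v$position + nchar(v$ref) - 1L
    if (g_last > gene$end)
      stop("deletion extends outside locus ", gene$gene_id)
    ns <- sort(c(.g2n(gene, g_first), .g2n(gene, g_last)))
    del_t <- if (minus) revcomp(deleted) else deleted
    desc <- if (ns[1] == ns[2]) sprintf("n.%ddel%s", ns[1], del_t)
            else sprintf("n.%d_%ddel%s", ns[1], ns[2], del_t)
    tv <- list(gene_id = gene$gene_id, n_description = desc,
               type = "deletion", n_start = ns[1], n_end = ns[2],
               ref = del_t, alt = "")
  }
  structure(tv, class = "transcript_variant")
}

#' Map a transcript variant back to genomic (VCF-style) coordinates
#'
#' Inverse of [genomic_to_transcript()] for variants produced by it (uses
#' the structured coordinate and allele fields, not the `n.` string).
#'
#' @param gene A [gene_locus()].
#' @param tv A `transcript_variant`.
#' @return A [genomic_variant()].
#' @export
transcript_to_genomic <- function(gene, tv) {
  minus <- gene$strand == "-"
  if (tv$type == "SNV") {
    g <- .n2g(gene, tv$n_start)
    ref <- if (minus) comp_base(tv$ref) else tv$ref
    alt <- if (minus) comp_base(tv$alt) else tv$alt
    genomic_variant(gene$chromosome, g, ref, alt)
  } else if (tv$type == "insertion") {
    # anchored after the genomic base 5' (plus strand) of the gap
    anchor <- if (minus) .n2g(gene, tv$n_end) else .n2g(gene, tv$n_start)
    base <- substr(gene$sequence, .g2n(gene, anchor), .g2n(gene, anchor))
    ref <- if (minus) comp_base(base) else base
    ins <- if (minus) revcomp(tv$alt) else tv$alt
    genomic_variant(gene$chromosome, anchor, ref, paste0(ref, ins))
  } else {
    g <- sort(c(.n2g(gene, tv$n_start), .n2g(gene, tv$n_end)))
    del <- if (minus) revcomp(tv$ref) else tv$ref
    anchor <- g[1] - 1L
    if (anchor < gene$start)
      stop("cannot anchor deletion within locus ", gene$gene_id)
    base <- substr(gene$sequence, .g2n(gene, anchor), .g2n(gene, anchor))
    ref_anchor <- if (minus) comp_base(base) else base
    genomic_variant(gene$chromosome, anchor,
                    paste0(ref_anchor, del), ref_anchor)
  }
}

#' Map a genomic interval into transcript coordinates
#'
#' @param gene A [gene_locus()].
#' @param start,end Genomic interval (1-based inclusive), contained in the
#'   gene.
#' @return Integer vector `c(n_start, n_end)` with `n_start <= n_end`.
#' @export
genomic_region_to_transcript <- function(gene, start, end) {
  if (start > end) stop("start must be <= end")
  if (start < gene$start || end > gene$end)
    stop("interval ", start, "-", end, " not contained in locus ",
         gene$gene_id, " (", gene$start, "-", gene$end, ")")
  ns <- sort(c(.g2n(gene, as.integer(start)), .g2n(gene, as.integer(end))))
  c(n_start = ns[1], n_end = ns[2])
}

#' Map a transcript interval into genomic coordinates
#' @param gene A [gene_locus()].
#' @param n_start,n_end Transcript interval, 1-based inclusive.
#' @return Integer vector `c(start, end)` in genomic coordinates.
#' @export
transcript_region_to_genomic <- function(gene, n_start, n_end) {
  L <- gene_length(gene)
  if (n_start > n_end) stop("n_start must be <= n_end")
  if (n_start < 1 || n_end > L)
    stop("transcript interval outside 1-", L)
  g <- sort(c(.n2g(gene, as.integer(n_start)), .n2g(gene, as.integer(n_end))))
  c(start = g[1], end = g[2])
}

#' Enumerate all possible SNVs over a transcript interval
#'
#' Every reference position admits exactly three alternative alleles, so an
#' interval of w bp has 3w possible SNVs. Output is in genomic (VCF)
#' coordinates with plus-strand alleles.
#'
#' @param gene A [gene_locus()].
#' @param n_start,n_end Transcript interval (defaults to the whole gene).
#' @return data.frame with columns `chromosome`, `position`, `ref`, `alt`,
#'   and `n` (transcript position); `3 * (n_end - n_start + 1)` rows.
#' @export
enumerate_possible_snvs <- function(gene, n_start = 1L,
                                    n_end = gene_length(gene)) {
  if (n_start > n_end) stop("empty interval")
  L <- gene_length(gene)
  if (n_start < 1 || n_end > L) stop("interval outside 1-", L)
  n <- seq.int(n_start, n_end)
  base_t <- strsplit(gene$sequence, "", fixed = TRUE)[[1]][n]
  g <- vapply(n, function(i) .n2g(gene, i), integer(1))
  ref <- if (gene$strand == "-") comp_base(base_t) else base_t
  nt <- c("A", "C", "G", "T")
  alts <- lapply(ref, function(r) setdiff(nt, r))
  data.frame(chromosome = gene$chromosome,
             position = rep(g, each = 3L),
             ref = rep(ref, each = 3L),
             alt = unlist(alts),
             n = rep(n, each = 3L),
             stringsAsFactors = FALSE)
}

#' Percent identity between two equal-length sequences
#'
#' @param seq_a,seq_b Nucleotide strings of equal length.
#' @return Percentage of matching positions, rounded to one decimal.
#' @examples
#' sequence_identity("ACGT", "ACGA")  # 75.0
#' @export
sequence_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  round(100 * sum(a == b) / length(a), 1)
}
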