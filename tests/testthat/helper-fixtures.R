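# In-code fixtures shared across test files.

gff3_line <- function(chrom, type, start1, end1, strand, attrs) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start1, end1, strand, attrs)
}

write_gff3_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# a three-gene annotation, two transcripts per gene, used by several tests;
# expected feature sets are hand-enumerated in test-annotation.R
three_gene_gff3 <- function() {
  write_gff3_fixture(c(
    # geneA '+': short mRNA A.1 (2 exons), long mRNA A.2 (3 exons) -> A.2 representative
    gff3_line("chr1", "gene", 1001, 3000, "+", "ID=geneA"),
    gff3_line("chr1", "mRNA", 1001, 2000, "+", "ID=geneA.1;Parent=geneA"),
    gff3_line("chr1", "exon", 1001, 1200, "+", "Parent=geneA.1"),
    gff3_line("chr1", "exon", 1801, 2000, "+", "Parent=geneA.1"),
    gff3_line("chr1", "mRNA", 1001, 3000, "+", "ID=geneA.2;Parent=geneA"),
    gff3_line("chr1", "exon", 1001, 1400, "+", "Parent=geneA.2"),
    gff3_line("chr1", "exon", 1901, 2200, "+", "Parent=geneA.2"),
    gff3_line("chr1", "exon", 2601, 3000, "+", "Parent=geneA.2"),
    gff3_line("chr1", "CDS", 1101, 1400, "+", "Parent=geneA.2"),
    gff3_line("chr1", "CDS", 1901, 2100, "+", "Parent=geneA.2"),
    # geneB '-': two equal-span mRNAs -> lexicographic tie-break picks geneB.1
    gff3_line("chr1", "gene", 5001, 6000, "-", "ID=geneB"),
    gff3_line("chr1", "mRNA", 5001, 6000, "-", "ID=geneB.2;Parent=geneB"),
    gff3_line("chr1", "exon", 5001, 6000, "-", "Parent=geneB.2"),
    gff3_line("chr1", "mRNA", 5001, 6000, "-", "ID=geneB.1;Parent=geneB"),
    gff3_line("chr1", "exon", 5001, 5400, "-", "Parent=geneB.1"),
    gff3_line("chr1", "exon", 5701, 6000, "-", "Parent=geneB.1"),
    gff3_line("chr1", "CDS", 5101, 5400, "-", "Parent=geneB.1"),
    gff3_line("chr1", "CDS", 5701, 5900, "-", "Parent=geneB.1"),
    # geneC '+': single exon, no CDS
    gff3_line("chr2", "gene", 101, 700, "+", "ID=geneC"),
    gff3_line("chr2", "mRNA", 101, 700, "+", "ID=geneC.1;Parent=geneC"),
    gff3_line("chr2", "exon", 101, 700, "+", "Parent=geneC.1")
  ))
}

# one preprocessed library wrapped as srna_libraries
toy_library <- function(starts, lengths = 24L, chrom = "chr1", strand = "+",
                        plant = "WT", time_hat = 0L, total = NULL,
                        n_sites = 1L) {
  n <- length(starts)
  reads <- tibble::tibble(
    chrom = chrom, start = as.integer(starts),
    end = as.integer(starts + lengths), read_id = sprintf("r%04d", seq_len(n)),
    strand = strand, length = as.integer(lengths), mismatches = 0L,
    n_sites = as.integer(n_sites), sequence = NA_character_,
    plant = plant, time_hat = as.integer(time_hat))
  totals <- tibble::tibble(plant = plant, time_hat = as.integer(time_hat),
                           total_processed = total %||% n)
  structure(list(reads = reads, totals = totals), class = "srna_libraries")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
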