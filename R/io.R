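#' Write SNPs to a minimal VCF (v4.2, single sample with GT)
#'
#' @param snps data.frame with `contig`, `pos` (0-based), `ref`, `alt`,
#'   `genotype` (`"het"`/`"hom"`).
#' @param path output file.
#' @param sample_name sample column name.
#' @export
write_snp_vcf <- function(snps, path, sample_name = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  ), con)
  if (nrow(snps)) {
    ord <- order(snps$contig, snps$pos, method = "radix")
    snps <- snps[ord, , drop = FALSE]
    gt <- ifelse(snps$genotype == "hom", "1/1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                       snps$contig, snps$pos + 1L, snps$ref, snps$alt, gt), con)
  }
  invisible(path)
}

#' Read biallelic SNVs from a VCF
#'
#' Multi-allelic records are split; non-SNV alleles are dropped. Genotypes
#' are taken from the first sample's GT field (0/1 -> het, 1/1 -> hom).
#'
#' @param path VCF file.
#' @return data.frame `contig`, `pos` (0-based), `ref`, `alt`, `genotype`.
#' @export
read_snp_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1]
  keep <- nchar(ref) == 1 & nchar(alt) == 1 & ref != alt &
    gt %in% c("0/1", "1/0", "0|1", "1|0", "1/1", "1|1")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep] - 1L,
    ref = ref[keep], alt = alt[keep],
    genotype = ifelse(gt[keep] %in% c("1/1", "1|1"), "hom", "het"),
    stringsAsFactors = FALSE)
}

#' Write a depth track as bedGraph (0-based half-open, run-length encoded)
#' @param track a `depth_track` (masked positions are written as-is).
#' @param path output file.
#' @export
write_depth_bedgraph <- function(track, path) {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%g", track$contig, starts, ends, r$values), con)
  invisible(path)
}

#' Read a bedGraph into per-base depth tracks
#' @param path bedGraph covering every base of each contig (zero runs
#'   included, as written by [write_depth_bedgraph()]).
#' @return named list of `depth_track`s, one per contig.
#' @export
read_depth_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- list()
  for (ctg in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[GenomicRanges::seqnames(gr) == ctg]
    g <- g[order(GenomicRanges::start(g))]
    depth <- rep(g$score, GenomicRanges::width(g))
    out[[ctg]] <- depth_track(ctg, depth)
  }
  out
}

#' Write alignments as SAM
#'
#' Minimal SAM with `AS:i:` alignment-score tags, suitable for the
#' retrogene filter.
#'
#' @param aln data.frame: `qname`, `flag`, `rname`, `pos` (1-based),
#'   `cigar`, `seq`, `score`.
#' @param refs named integer vector of reference lengths (`@SQ` lines).
#' @param path output file.
#' @export
write_sam <- function(aln, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)), con)
  if (nrow(aln)) {
    qual <- vapply(nchar(aln$seq), function(n) strrep("I", n), character(1))
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tAS:i:%d",
                       aln$qname, aln$flag, aln$rname, aln$pos, aln$cigar,
                       aln$seq, qual, as.integer(aln$score)), con)
  }
  invisible(path)
}

#' Read SAM alignments (with AS scores)
#'
#' @param path SAM file.
#' @return data.frame `qname`, `flag`, `rname`, `pos` (1-based), `cigar`,
#'   `score` (AS tag; `NA` when absent). Unmapped records are dropped.
#' @export
read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"), tag = "AS")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  score <- x$tag$AS
  if (is.null(score)) score <- rep(NA_real_, length(x$qname))
  data.frame(qname = x$qname[keep], flag = x$flag[keep],
             rname = as.character(x$rname)[keep], pos = x$pos[keep],
             cigar = x$cigar[keep], score = as.numeric(score)[keep],
             stringsAsFactors = FALSE)
}

#' Write a genome as FASTA
#' @param genome named character vector or `DNAStringSet`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA as a named character vector
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
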