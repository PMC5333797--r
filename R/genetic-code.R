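BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a codon with the standard genetic code
#'
#' @param codon character vector of 3-mers over A/C/G/T (N allowed).
#' @return One-letter amino acids; `"*"` for stop, `NA` for codons with
#'   ambiguous bases.
#' @keywords internal
codon_aa <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa[is.na(aa)] <- NA_character_
  aa
}

#' Classify a single-base codon change
#'
#' Classifies a substitution within one codon into the usual coding-effect
#' classes. The codon is given in transcript (sense-strand) space; for
#' minus-strand genes the alternate base observed on the genomic plus
#' strand is complemented before substitution.
#'
#' @param codon 3-character reference codon in transcript space.
#' @param offset 0-based position within the codon (0..2), transcript space.
#' @param alt_base alternate base. For `strand == "-"` this is the genomic
#'   plus-strand base and is complemented internally.
#' @param strand `"+"` or `"-"`.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`,
#'   `"stop_loss"`, or `"unknown"` (ambiguous bases).
#' @export
#' @examples
#' classify_codon_change("TGG", 2, "A") # nonsense: TGG -> TGA
#' classify_codon_change("GGA", 2, "G") # synonymous: Gly -> Gly
classify_codon_change <- function(codon, offset, alt_base, strand = "+") {
  stopifnot(nchar(codon) == 3, offset %in% 0:2, nchar(alt_base) == 1)
  codon <- toupper(codon)
  alt_base <- toupper(alt_base)
  if (strand == "-") alt_base <- comp_base(alt_base)
  ref_base <- substr(codon, offset + 1, offset + 1)
  if (!all(strsplit(codon, "")[[1]] %in% BASES) || !(alt_base %in% BASES)) {
    return("unknown")
  }
  if (alt_base == ref_base) {
    stop("alt base equals reference base at the given offset (after strand adjustment)")
  }
  alt_codon <- codon
  substr(alt_codon, offset + 1, offset + 1) <- alt_base
  ref_aa <- codon_aa(codon)
  alt_aa <- codon_aa(alt_codon)
  if (ref_aa == "*" && alt_aa == "*") return("synonymous")
  if (ref_aa == "*") return("stop_loss")
  if (alt_aa == "*") return("nonsense")
  if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
}

#' Is a ref/alt pair a potential deamination-damage artifact?
#'
#' Post-mortem cytosine deamination in ancient DNA manifests as apparent
#' C-to-T substitutions (G-to-A on the opposite strand). Both transition
#' pairs are flagged in both directions.
#'
#' @param ref,alt single bases in A/C/G/T.
#' @return `TRUE` iff the unordered pair is \{A,G\} or \{C,T\}.
#' @export
is_damage_pair <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(all(ref %in% BASES), all(alt %in% BASES))
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C") |
    (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
}

# Per-codon fractional synonymous site count (NG86 style): each codon
# position contributes (number of the 3 possible changes that are
# synonymous)/3. Changes creating a stop count as nonsynonymous; the three
# stop codons themselves are not counted (callers exclude them).
codon_syn_sites_table <- function() {
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  syn <- vapply(codons, function(cd) {
    if (cd %in% STOP_CODONS) return(NA_real_)
    s <- 0
    for (off in 0:2) {
      rb <- substr(cd, off + 1, off + 1)
      for (ab in setdiff(BASES, rb)) {
        if (classify_codon_change(cd, off, ab) == "synonymous") s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  names(syn) <- codons
  syn
}

.syn_sites_env <- new.env(parent = emptyenv())

syn_sites_for_codon <- function(codon) {
  if (is.null(.syn_sites_env$tab)) .syn_sites_env$tab <- codon_syn_sites_table()
  unname(.syn_sites_env$tab[codon])
}

#' Count synonymous and non-synonymous sites over gene models
#'
#' Fractional (Nei-Gojobori style) site counts: per codon, each of the three
#' positions contributes the fraction of its three possible changes that are
#' synonymous to `L_syn` and the complement to `L_nonsyn`; stop-creating
#' changes count as nonsynonymous. The terminal stop codon is excluded.
#' Genes whose CDS contains an internal stop or ambiguous codon positions
#' are skipped (internal stop) or have those codons dropped (N bases).
#'
#' @param genes list of gene models (see [gene_model()]).
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @return list with `L_syn`, `L_nonsyn`, `per_gene` (data.frame), and
#'   `skipped` (gene ids with internal stops).
#' @export
count_syn_nonsyn_sites <- function(genes, genome) {
  per <- lapply(genes, function(g) {
    cds <- transcript_seq(g, genome)
    # drop terminal stop codon if present
    nc <- nchar(cds)
    if (nc %% 3 != 0) {
      return(data.frame(gene_id = g$gene_id, L_syn = NA_real_, L_nonsyn = NA_real_,
                        skipped = TRUE))
    }
    last <- substr(cds, nc - 2, nc)
    if (last %in% STOP_CODONS) cds <- substr(cds, 1, nc - 3)
    codons <- codon_split(cds)
    syn <- syn_sites_for_codon(codons)
    if (any(codons %in% STOP_CODONS)) {
      return(data.frame(gene_id = g$gene_id, L_syn = NA_real_, L_nonsyn = NA_real_,
                        skipped = TRUE))
    }
    keep <- !is.na(syn)
    ls <- sum(syn[keep])
    ln <- 3 * sum(keep) - ls
    data.frame(gene_id = g$gene_id, L_syn = ls, L_nonsyn = ln, skipped = FALSE)
  })
  per <- do.call(rbind, per)
  skipped <- per$gene_id[per$skipped]
  if (length(skipped)) {
    message("count_syn_nonsyn_sites: skipped ", length(skipped),
            " gene(s) with internal stop codons")
  }
  ok <- !per$skipped
  list(L_syn = sum(per$L_syn[ok]), L_nonsyn = sum(per$L_nonsyn[ok]),
       per_gene = per, skipped = skipped)
}

codon_split <- function(cds) {
  n <- nchar(cds) %/% 3
  substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
}
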