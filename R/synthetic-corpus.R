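#' Configuration for the synthetic-data generator
#'
#' Defines a synthetic diploid genome with planted coding SNPs, deletions,
#' and retrocopies, plus a noisy coverage track and junction reads, at the
#' scale of low-coverage ancient-genome analyses (default mean depth 15
#' reads/base, between the 11X and 17X of the emulated libraries).
#'
#' @param genome_length contig length in bp.
#' @param n_genes number of genes to place.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_len,intron_len bp ranges `c(min, max)`.
#' @param snp_rate per-base probability of a background (noncoding) SNP.
#' @param het_fraction fraction of planted SNPs that are heterozygous.
#' @param n_syn_snps,n_nonsyn_snps,n_nonsense_snps requested planted coding
#'   SNP counts per effect class.
#' @param deletion_count number of planted deletions.
#' @param deletion_len_range bp range, minimum >= 1000.
#' @param hom_del_fraction fraction of deletions homozygous.
#' @param deletion_spacing minimum gap between planted deletions in bp
#'   (default one caller window, keeping at most one deletion per window).
#' @param retrocopy_count number of genes copied as intron-less retrocopies.
#' @param reads_per_retro junction reads generated per retrocopy.
#' @param n_background_reads reads drawn from the intron-containing genome.
#' @param mean_depth mean coverage depth (reads per base).
#' @param depth_dispersion negative-binomial size parameter (smaller =
#'   more overdispersed; ancient libraries are overdispersed).
#' @param read_len read length in bp (must exceed 2 x 10 + 1 so junction
#'   overhangs are attainable).
#' @param damage_rate per-base probability of a C->T (and G->A)
#'   deamination-like substitution in reads.
#' @param seed integer seed; a fixed seed yields a byte-identical corpus.
#' @param contig contig name.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(genome_length = 1e6, n_genes = 20,
                         exons_per_gene = c(3, 6), exon_len = c(120, 300),
                         intron_len = c(200, 1200), snp_rate = 2e-4,
                         het_fraction = 0.6, n_syn_snps = 40,
                         n_nonsyn_snps = 40, n_nonsense_snps = 10,
                         deletion_count = 10,
                         deletion_len_range = c(1000, 10000),
                         hom_del_fraction = 0.3, deletion_spacing = 20000,
                         retrocopy_count = 5, reads_per_retro = 8,
                         n_background_reads = 300, mean_depth = 15,
                         depth_dispersion = 5, read_len = 60,
                         damage_rate = 0.02, seed = 1, contig = "chr1") {
  cfg <- list(genome_length = as.integer(genome_length), n_genes = n_genes,
              exons_per_gene = exons_per_gene, exon_len = exon_len,
              intron_len = intron_len, snp_rate = snp_rate,
              het_fraction = het_fraction, n_syn_snps = n_syn_snps,
              n_nonsyn_snps = n_nonsyn_snps, n_nonsense_snps = n_nonsense_snps,
              deletion_count = deletion_count,
              deletion_len_range = deletion_len_range,
              hom_del_fraction = hom_del_fraction,
              deletion_spacing = deletion_spacing,
              retrocopy_count = retrocopy_count,
              reads_per_retro = reads_per_retro,
              n_background_reads = n_background_reads,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              read_len = as.integer(read_len), damage_rate = damage_rate,
              seed = as.integer(seed), contig = contig)
  with(cfg, {
    stopifnot(genome_length > 0, n_genes >= 0,
              all(exons_per_gene >= 1), all(exon_len > 0), all(intron_len > 0),
              snp_rate >= 0, snp_rate <= 1,
              het_fraction >= 0, het_fraction <= 1,
              deletion_count >= 0, hom_del_fraction >= 0, hom_del_fraction <= 1,
              retrocopy_count >= 0, read_len > 0, mean_depth > 0,
              depth_dispersion > 0, damage_rate >= 0, damage_rate <= 1)
    if (deletion_count > 0 && deletion_len_range[1] < 1000) {
      stop("deletion_len_range minimum must be >= 1000 bp")
    }
    if (retrocopy_count > 0 && read_len < 2 * 10 + 1) {
      stop("read_len too short to satisfy the 10 bp junction overhang")
    }
  })
  class(cfg) <- "synth_config"
  cfg
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# uniform integers in [lo, hi], safe when lo == hi
rint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

SENSE_CODONS <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                                        c("A","C","G","T"), paste0)),
                        c("TAA", "TAG", "TGA"))

# CDS of n_codons total: ATG + sense codons + stop; no internal stops.
rand_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  body <- sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1)), collapse = "")
}

#' Generate a synthetic reference genome and gene annotation
#'
#' Places non-overlapping intron-containing genes on both strands. Every
#' CDS (the full spliced transcript here) starts with ATG, ends with a stop
#' codon, has length divisible by 3, and translates without internal stops.
#'
#' @param config a `synth_config`.
#' @return list: `genome` (named character vector), `genes` (list of
#'   `gene_model`s).
#' @export
generate_reference_and_annotation <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  genome_chars <- sample(BASES, L, replace = TRUE)
  genes <- list()
  if (config$n_genes > 0) {
    # plan gene structures first so total footprint is known
    plans <- lapply(seq_len(config$n_genes), function(i) {
      k <- rint(1, config$exons_per_gene[1], config$exons_per_gene[2])
      ex <- rint(k, config$exon_len[1], config$exon_len[2])
      tot <- sum(ex)
      ex[k] <- ex[k] + (3 - tot %% 3) %% 3  # make CDS length divisible by 3
      intr <- if (k > 1) {
        rint(k - 1, config$intron_len[1], config$intron_len[2])
      } else integer(0)
      list(exons = ex, introns = intr, span = sum(ex) + sum(intr))
    })
    spans <- vapply(plans, `[[`, numeric(1), "span")
    gap <- 200L
    need <- sum(spans) + gap * (config$n_genes + 1)
    if (need > L) {
      stop(sprintf(
        "genome too small to place %d gene(s): need >= %d bp, have %d",
        config$n_genes, need, L))
    }
    # random non-overlapping placement: distribute the slack among gaps
    slack <- L - sum(spans) - gap * (config$n_genes + 1)
    extra <- if (slack > 0) {
      d <- stats::rmultinom(1, slack, rep(1, config$n_genes + 1))[, 1]
      as.integer(d)
    } else rep(0L, config$n_genes + 1)
    pos <- 0L
    for (i in seq_len(config$n_genes)) {
      pos <- pos + gap + extra[i]
      p <- plans[[i]]
      strand <- sample(c("+", "-"), 1)
      n_cod <- sum(p$exons) %/% 3
      cds <- rand_cds(n_cod)
      # exon sequences in transcript order
      stops <- cumsum(p$exons)
      ex_seq <- substring(cds, c(1, stops[-length(stops)] + 1), stops)
      # region in genomic orientation
      k <- length(p$exons)
      if (strand == "+") {
        ex_w <- p$exons; in_w <- p$introns
        ex_s <- ex_seq
      } else {
        ex_w <- rev(p$exons); in_w <- rev(p$introns)
        ex_s <- rev(revcomp(ex_seq))
      }
      cursor <- pos
      starts <- integer(k)
      region <- character(0)
      for (j in seq_len(k)) {
        starts[j] <- cursor
        region <- c(region, ex_s[j])
        cursor <- cursor + ex_w[j]
        if (j < k) {
          region <- c(region, rand_seq(in_w[j]))
          cursor <- cursor + in_w[j]
        }
      }
      region_seq <- paste(region, collapse = "")
      genome_chars[(pos + 1):(pos + nchar(region_seq))] <-
        strsplit(region_seq, "")[[1]]
      genes[[i]] <- gene_model(
        gene_id = sprintf("g%03d", i), contig = config$contig,
        strand = strand,
        exons = data.frame(start = starts, end = starts + ex_w))
      pos <- pos + p$span
    }
  }
  genome <- stats::setNames(paste(genome_chars, collapse = ""), config$contig)
  list(genome = genome, genes = genes)
}

#' Plant SNPs, deletions, and retrocopies; return the truth set
#'
#' Coding SNPs of each requested effect class are chosen by enumerating all
#' single-base changes over all codons and sampling sites without
#' replacement; each planted nonsense SNP verifiably creates a stop codon.
#' Background SNPs are scattered over noncoding sequence at `snp_rate`.
#' Deletions are placed outside each other with at least
#' `deletion_spacing` bp between them. Retrocopies are drawn from genes
#' with at least three exons.
#'
#' @param genome named character vector from
#'   [generate_reference_and_annotation()].
#' @param genes list of `gene_model`s.
#' @param config a `synth_config`.
#' @return list of class `truth_set`: `snps` (contig, pos, ref, alt,
#'   genotype, effect_class, damage_flag, gene_id), `deletions` (contig,
#'   start, end, zygosity), `retrocopies` (gene_id, introns_removed,
#'   insertion_site).
#' @export
plant_variant_set <- function(genome, genes, config) {
  set.seed(config$seed + 1L)
  contig <- config$contig
  seq <- contig_seq(genome, contig)
  L <- nchar(seq)

  # --- deletions -------------------------------------------------------------
  deletions <- empty_truth_deletions()
  if (config$deletion_count > 0) {
    lens <- rint(config$deletion_count, config$deletion_len_range[1],
                 config$deletion_len_range[2])
    starts <- place_spaced_intervals(L, lens, config$deletion_spacing)
    if (length(starts) < config$deletion_count) {
      stop("could not place ", config$deletion_count, " deletions with ",
           config$deletion_spacing, " bp spacing; placed ", length(starts))
    }
    n_hom <- round(config$deletion_count * config$hom_del_fraction)
    zyg <- sample(c(rep("hom", n_hom),
                    rep("het", config$deletion_count - n_hom)))
    deletions <- data.frame(contig = contig, start = starts,
                            end = starts + lens[seq_along(starts)],
                            zygosity = zyg, stringsAsFactors = FALSE)
    deletions <- deletions[order(deletions$start), , drop = FALSE]
    rownames(deletions) <- NULL
  }
  in_deletion <- function(pos) {
    if (!nrow(deletions)) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(deletions))) {
      out <- out | (pos >= deletions$start[i] & pos < deletions$end[i])
    }
    out
  }

  # --- coding SNPs -----------------------------------------------------------
  cand <- enumerate_coding_changes(genome, genes)
  cand <- cand[!in_deletion(cand$pos), , drop = FALSE]
  want <- c(synonymous = config$n_syn_snps, nonsynonymous = config$n_nonsyn_snps,
            nonsense = config$n_nonsense_snps)
  picked <- list()
  used_pos <- integer(0)
  for (cls in names(want)) {
    n <- want[[cls]]
    if (n == 0) next
    pool <- cand[cand$effect_class == cls & !(cand$pos %in% used_pos), ,
                 drop = FALSE]
    # one candidate per site to avoid planting two alts at one position
    pool <- pool[!duplicated(pool$pos), , drop = FALSE]
    if (nrow(pool) < n) {
      stop(sprintf("insufficient eligible codons for %s SNPs: requested %d, eligible %d",
                   cls, n, nrow(pool)))
    }
    take <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    used_pos <- c(used_pos, take$pos)
    picked[[cls]] <- take
  }
  coding <- do.call(rbind, picked)

  # --- background noncoding SNPs --------------------------------------------
  exonic <- rep(FALSE, L)
  for (g in genes) {
    for (i in seq_len(nrow(g$exons))) {
      exonic[(g$exons$start[i] + 1):g$exons$end[i]] <- TRUE
    }
  }
  nc_pos <- which(!exonic) - 1L
  nc_pos <- nc_pos[!in_deletion(nc_pos)]
  n_bg <- stats::rbinom(1, length(nc_pos), config$snp_rate)
  bg <- NULL
  if (n_bg > 0) {
    p <- sort(sample(nc_pos, n_bg))
    ref <- substring(seq, p + 1, p + 1)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
    bg <- data.frame(contig = contig, pos = p, ref = unname(ref),
                     alt = unname(alt), effect_class = "noncoding",
                     gene_id = NA_character_, stringsAsFactors = FALSE)
  }
  snps <- rbind(
    if (!is.null(coding)) coding[, c("contig", "pos", "ref", "alt",
                                     "effect_class", "gene_id")],
    bg)
  if (is.null(snps)) {
    snps <- data.frame(contig = character(), pos = integer(), ref = character(),
                       alt = character(), effect_class = character(),
                       gene_id = character(), stringsAsFactors = FALSE)
  }
  if (nrow(snps)) {
    snps$genotype <- ifelse(stats::runif(nrow(snps)) < config$het_fraction,
                            "het", "hom")
    snps$damage_flag <- is_damage_pair(snps$ref, snps$alt)
    snps <- snps[order(snps$pos), , drop = FALSE]
    rownames(snps) <- NULL
  } else {
    snps$genotype <- character(0)
    snps$damage_flag <- logical(0)
  }

  # --- retrocopies -----------------------------------------------------------
  retro <- data.frame(gene_id = character(), introns_removed = integer(),
                      insertion_site = integer(), stringsAsFactors = FALSE)
  if (config$retrocopy_count > 0) {
    eligible <- Filter(function(g) nrow(g$exons) >= 3, genes)
    if (length(eligible) < config$retrocopy_count) {
      stop("insufficient multi-exon genes for ", config$retrocopy_count,
           " retrocopies (have ", length(eligible), ")")
    }
    pick <- sample(eligible, config$retrocopy_count)
    retro <- data.frame(
      gene_id = vapply(pick, `[[`, "", "gene_id"),
      introns_removed = vapply(pick, function(g) nrow(g$exons) - 1L, integer(1)),
      insertion_site = sample.int(L, config$retrocopy_count) - 1L,
      stringsAsFactors = FALSE)
  }

  structure(list(snps = snps, deletions = deletions, retrocopies = retro),
            class = "truth_set")
}

empty_truth_deletions <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             zygosity = character(), stringsAsFactors = FALSE)
}

# Place intervals of the given lengths with >= spacing between any two and
# to the contig ends, by distributing free space randomly among the gaps.
place_spaced_intervals <- function(L, lens, spacing) {
  n <- length(lens)
  need <- sum(lens) + spacing * (n + 1)
  if (need > L) return(integer(0))
  slack <- L - need
  extra <- if (slack > 0) stats::rmultinom(1, slack, rep(1, n + 1))[, 1] else
    rep(0L, n + 1)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + spacing + extra[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  starts
}

# All single-base coding changes over all genes, classified.
enumerate_coding_changes <- function(genome, genes) {
  rows <- lapply(genes, function(g) {
    tx <- transcript_seq(g, genome)
    nc <- nchar(tx)
    n_cod <- nc %/% 3
    # skip the terminal stop codon; keep the start codon (changes there are
    # ordinary missense in this classification)
    codons <- codon_split(tx)[-n_cod]
    # genomic positions of each transcript position
    ex <- g$exons
    gpos_plus <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:(ex$end[i] - 1)))
    gpos <- if (g$strand == "-") rev(gpos_plus) else gpos_plus
    out <- vector("list", length(codons))
    for (ci in seq_along(codons)) {
      cd <- codons[ci]
      for (off in 0:2) {
        txp <- (ci - 1) * 3 + off
        gp <- gpos[txp + 1]
        ref_tx <- substr(cd, off + 1, off + 1)
        ref_gen <- if (g$strand == "-") comp_base(ref_tx) else ref_tx
        for (ab in setdiff(BASES, ref_gen)) {
          cls <- classify_codon_change(cd, off, ab, g$strand)
          out[[ci]] <- rbind(out[[ci]], data.frame(
            contig = g$contig, pos = gp, ref = ref_gen, alt = ab,
            effect_class = cls, gene_id = g$gene_id,
            stringsAsFactors = FALSE))
        }
      }
    }
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Render a per-base depth track with planted deletion signals
#'
#' Baseline depth is negative-binomial (`mu = mean_depth`, `size =
#' depth_dispersion`); heterozygous deletion spans are thinned binomially at
#' 0.5 (one haplotype remaining); homozygous spans have zero depth.
#'
#' @param genome named character vector (used for length and N-masking).
#' @param truth a `truth_set`.
#' @param config a `synth_config`.
#' @return a `depth_track`.
#' @export
render_depth_track <- function(genome, truth, config) {
  if (config$mean_depth <= 0) stop("mean_depth must be > 0")
  set.seed(config$seed + 2L)
  seq <- contig_seq(genome, config$contig)
  L <- nchar(seq)
  depth <- stats::rnbinom(L, mu = config$mean_depth, size = config$depth_dispersion)
  del <- truth$deletions
  for (i in seq_len(nrow(del))) {
    idx <- (del$start[i] + 1):del$end[i]
    if (del$zygosity[i] == "hom") {
      depth[idx] <- 0L
    } else {
      depth[idx] <- stats::rbinom(length(idx), depth[idx], 0.5)
    }
  }
  mask <- strsplit(seq, "")[[1]] == "N"
  depth_track(config$contig, depth, mask)
}

damage_bases <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit_c <- chars == "C" & stats::runif(length(chars)) < rate
  hit_g <- chars == "G" & stats::runif(length(chars)) < rate
  chars[hit_c] <- "T"
  chars[hit_g] <- "A"
  chars
}

#' Render junction reads and their transcript/genome alignments
#'
#' Each planted retrocopy yields `reads_per_retro` reads drawn across at
#' least two distinct exon-exon junctions of the source transcript, each
#' spanning its junction with at least 10 bp on both sides. Background
#' reads are drawn from the intron-containing genome; when one lies wholly
#' within an exon it also receives a transcript alignment with an equal
#' score, and when it crosses an exon boundary its transcript alignment is
#' soft-clipped at the junction. Deamination damage (C->T, G->A at
#' `damage_rate`) is applied to read sequences only; alignment scores are
#' `aligned_length - 5 * mismatches`.
#'
#' @param genome named character vector.
#' @param genes list of `gene_model`s.
#' @param truth a `truth_set`.
#' @param config a `synth_config`.
#' @return list: `tx_aln`, `genome_aln` (data.frames for [write_sam()] /
#'   [find_junction_reads()]), `reads` (data.frame `qname`, `seq`,
#'   `source`).
#' @export
render_junction_reads <- function(genome, genes, truth, config) {
  if (config$read_len < 21) stop("read_len too short for 10 bp overhangs")
  set.seed(config$seed + 3L)
  gene_tbl <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  rl <- config$read_len
  tx_rows <- list(); gen_rows <- list(); read_rows <- list()
  rid <- 0L

  score_of <- function(aligned_ref, read_part) {
    mm <- sum(strsplit(aligned_ref, "")[[1]] != strsplit(read_part, "")[[1]])
    nchar(read_part) - 5L * mm
  }

  for (i in seq_len(nrow(truth$retrocopies))) {
    g <- gene_tbl[[truth$retrocopies$gene_id[i]]]
    tx <- transcript_seq(g, genome)
    J <- junction_positions(g)
    n_reads <- max(3L, config$reads_per_retro)
    # guarantee >= 2 distinct junctions among the reads
    jpick <- c(sample(J, 2), sample(J, n_reads - 2, replace = TRUE))
    for (j in jpick) {
      lo <- max(0L, j - (rl - 10L))
      hi <- min(j - 10L, nchar(tx) - rl)
      if (hi < lo) next
      s <- sample(lo:hi, 1)
      raw <- substring(tx, s + 1, s + rl)
      dmg <- paste(damage_bases(strsplit(raw, "")[[1]], config$damage_rate),
                   collapse = "")
      rid <- rid + 1L
      qn <- sprintf("retro_%s_%04d", g$gene_id, rid)
      tx_rows[[length(tx_rows) + 1]] <- data.frame(
        qname = qn, flag = 0L, rname = g$gene_id, pos = s + 1L,
        cigar = sprintf("%dM", rl), seq = dmg,
        score = score_of(raw, dmg), stringsAsFactors = FALSE)
      # best genomic alignment: longest piece of the read lying in one exon
      cuts <- sort(unique(c(0, J[J > s & J < s + rl] - s, rl)))
      seg_len <- diff(cuts)
      k <- which.max(seg_len)
      a0 <- cuts[k]; a1 <- cuts[k + 1]
      part_raw <- substring(raw, a0 + 1, a1)
      part_dmg <- substring(dmg, a0 + 1, a1)
      cig <- paste0(if (a0 > 0) sprintf("%dS", a0) else "",
                    sprintf("%dM", a1 - a0),
                    if (a1 < rl) sprintf("%dS", rl - a1) else "")
      gen_rows[[length(gen_rows) + 1]] <- data.frame(
        qname = qn, flag = 0L, rname = config$contig,
        pos = genomic_pos_of_tx(g, s + a0) + 1L, cigar = cig, seq = dmg,
        score = score_of(part_raw, part_dmg), stringsAsFactors = FALSE)
      read_rows[[length(read_rows) + 1]] <- data.frame(
        qname = qn, seq = dmg, raw = raw, source = "retrocopy",
        stringsAsFactors = FALSE)
    }
  }

  # background reads from the intron-containing genome
  seq <- contig_seq(genome, config$contig)
  L <- nchar(seq)
  exon_map <- exon_lookup(genes)
  for (b in seq_len(config$n_background_reads)) {
    s <- sample.int(L - rl, 1) - 1L
    raw <- substring(seq, s + 1, s + rl)
    dmg <- paste(damage_bases(strsplit(raw, "")[[1]], config$damage_rate),
                 collapse = "")
    rid <- rid + 1L
    qn <- sprintf("bg_%05d", rid)
    gscore <- score_of(raw, dmg)
    gen_rows[[length(gen_rows) + 1]] <- data.frame(
      qname = qn, flag = 0L, rname = config$contig, pos = s + 1L,
      cigar = sprintf("%dM", rl), seq = dmg, score = gscore,
      stringsAsFactors = FALSE)
    read_rows[[length(read_rows) + 1]] <- data.frame(
      qname = qn, seq = dmg, raw = raw, source = "background",
      stringsAsFactors = FALSE)
    # transcript alignment of the exonic part, if any
    txa <- background_tx_alignment(qn, s, rl, exon_map, gene_tbl, genome, raw, dmg)
    if (!is.null(txa)) tx_rows[[length(tx_rows) + 1]] <- txa
  }

  list(tx_aln = bind_or_empty(tx_rows), genome_aln = bind_or_empty(gen_rows),
       reads = bind_or_empty(read_rows))
}

bind_or_empty <- function(rows) {
  if (!length(rows)) {
    return(data.frame(qname = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# genomic position (0-based) of a transcript position
genomic_pos_of_tx <- function(gene, txpos) {
  w <- exon_widths_tx_order(gene)
  cum <- cumsum(c(0, w))
  ei <- findInterval(txpos, cum, rightmost.closed = FALSE)  # 1-based tx exon
  off <- txpos - cum[ei]
  if (gene$strand == "+") {
    gene$exons$start[ei] + off
  } else {
    k <- nrow(gene$exons) + 1 - ei  # genomic exon index
    gene$exons$end[k] - 1 - off
  }
}

exon_lookup <- function(genes) {
  do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, start = g$exons$start, end = g$exons$end,
               stringsAsFactors = FALSE)
  }))
}

# Transcript-space alignment for a genomic background read: the part of the
# read inside a single exon aligns (soft-clipping the rest); reads entirely
# outside exons get no transcript alignment.
background_tx_alignment <- function(qn, s, rl, exon_map, gene_tbl, genome, raw, dmg) {
  if (is.null(exon_map) || !nrow(exon_map)) return(NULL)
  ov <- which(exon_map$start < s + rl & exon_map$end > s)
  if (!length(ov)) return(NULL)
  # use the exon with the largest overlap
  inter <- pmin(exon_map$end[ov], s + rl) - pmax(exon_map$start[ov], s)
  k <- ov[which.max(inter)]
  a0 <- max(exon_map$start[k], s) - s          # read-relative aligned part
  a1 <- min(exon_map$end[k], s + rl) - s
  if (a1 - a0 < 20) return(NULL)               # too short to map confidently
  g <- gene_tbl[[exon_map$gene_id[k]]]
  gstart <- s + a0
  txp <- genomic_to_tx(g, gstart:(s + a1 - 1))
  part_raw <- substring(raw, a0 + 1, a1)
  part_dmg <- substring(dmg, a0 + 1, a1)
  if (g$strand == "-") {
    txp <- rev(txp)
    part_raw <- revcomp(part_raw)
    part_dmg <- revcomp(part_dmg)
  }
  mm <- sum(strsplit(part_raw, "")[[1]] != strsplit(part_dmg, "")[[1]])
  cig <- paste0(if (a0 > 0) sprintf("%dS", a0) else "",
                sprintf("%dM", a1 - a0),
                if (a1 < rl) sprintf("%dS", rl - a1) else "")
  data.frame(qname = qn, flag = 0L, rname = g$gene_id,
             pos = min(txp) + 1L, cigar = cig, seq = dmg,
             score = (a1 - a0) - 5L * mm, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic corpus in memory
#'
#' Runs the full generator: reference + annotation, planted truth set,
#' depth track, and junction reads.
#'
#' @param config a `synth_config`.
#' @return list of class `synth_corpus`: `config`, `genome`, `genes`,
#'   `truth`, `depth`, `reads` (the [render_junction_reads()] output).
#' @export
synth_corpus <- function(config = synth_config()) {
  ra <- generate_reference_and_annotation(config)
  truth <- plant_variant_set(ra$genome, ra$genes, config)
  depth <- render_depth_track(ra$genome, truth, config)
  reads <- render_junction_reads(ra$genome, ra$genes, truth, config)
  structure(list(config = config, genome = ra$genome, genes = ra$genes,
                 truth = truth, depth = depth, reads = reads),
            class = "synth_corpus")
}

#' Write a synthetic corpus to standard-format files
#'
#' Writes FASTA, GFF3, VCF, two SAM files (alignments to transcripts and to
#' the genome), bedGraph, and truth TSV/BED, plus a checksum manifest.
#'
#' @param corpus a `synth_corpus`.
#' @param dir output directory (created if needed).
#' @return data.frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.tsv`.
#' @export
emit_truth_and_files <- function(corpus, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  p <- function(f) file.path(dir, f)
  write_genome_fasta(corpus$genome, p("reference.fasta"))
  tx <- stats::setNames(
    vapply(corpus$genes, function(g) transcript_seq(g, corpus$genome), character(1)),
    vapply(corpus$genes, `[[`, "", "gene_id"))
  if (length(tx)) write_genome_fasta(tx, p("transcripts.fasta"))
  write_gene_models_gff3(corpus$genes, p("annotation.gff3"))
  write_snp_vcf(corpus$truth$snps, p("variants.vcf"))
  write_depth_bedgraph(corpus$depth, p("depth.bedGraph"))
  tx_lens <- vapply(corpus$genes, transcript_length, numeric(1))
  names(tx_lens) <- vapply(corpus$genes, `[[`, "", "gene_id")
  write_sam(corpus$reads$tx_aln, tx_lens, p("tx_alignments.sam"))
  write_sam(corpus$reads$genome_aln,
            stats::setNames(nchar(corpus$genome), names(corpus$genome)),
            p("genome_alignments.sam"))
  del <- corpus$truth$deletions
  utils::write.table(
    data.frame(chrom = del$contig, start = del$start, end = del$end,
               name = del$zygosity),
    p("truth_deletions.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(corpus$truth$snps, p("truth_snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$truth$retrocopies, p("truth_retrocopies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("reference.fasta", "transcripts.fasta", "annotation.gff3",
             "variants.vcf", "depth.bedGraph", "tx_alignments.sam",
             "genome_alignments.sam", "truth_deletions.bed", "truth_snps.tsv",
             "truth_retrocopies.tsv")
  files <- files[file.exists(file.path(dir, files))]
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
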