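#' Construct a per-base depth track
#'
#' @param contig contig name.
#' @param depth non-negative integer vector, one value per base.
#' @param mask logical vector of positions to exclude (reference Ns,
#'   unmappable bases); masked positions carry no depth information.
#' @return object of class `depth_track`.
#' @export
depth_track <- function(contig, depth, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(depth))
  stopifnot(length(mask) == length(depth), all(depth[!mask] >= 0))
  structure(list(contig = contig, depth = as.numeric(depth), mask = mask),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track %s: %d bp, mean depth %.2f, %.1f%% masked>\n",
              x$contig, length(x$depth), mean(x$depth[!x$mask]),
              100 * mean(x$mask)))
  invisible(x)
}

# Number of candidate (start, length) tract placements on the grid for a
# window of n_bins grid bins. Used for the Bonferroni denominator.
n_tract_candidates <- function(n_bins, min_bins, max_bins) {
  lens <- min_bins:min(max_bins, n_bins - 1)
  lens <- lens[lens >= min_bins & lens <= n_bins - 1]
  if (!length(lens)) return(0L)
  sum(n_bins - lens + 1L)
}

#' Fit the best change-point tract in one window
#'
#' Piecewise-constant depth model: the window is fit with one mean (residual
#' sum of squares `RSS_1`) versus a background mean plus a distinct tract
#' mean (`RSS_2`), with tract boundaries restricted to a coarse grid. The
#' statistic `lambda = n * ln(RSS_1 / RSS_2)` for the best tract is referred
#' to a chi-squared distribution with one degree of freedom. Masked
#' positions are excluded from both RSS terms.
#'
#' @param depths numeric depth values for the window (>= 2 kb).
#' @param mask logical exclusion mask (same length); default none.
#' @param grid boundary grid step in bp (default 100).
#' @param min_len,max_len tract length bounds in bp (default 1000, 10000).
#' @return list of class `changepoint_fit`: `tract` (c(start, end), 0-based
#'   half-open, window-relative), `rss1`, `rss2`, `lambda`, `df`, `p_value`,
#'   `n_used`, `n_candidates`, `tract_mean`, `background_median`,
#'   `zero_fraction`; or `NULL` when the window is shorter than 2 kb, over
#'   half masked, or has no admissible tract.
#' @export
fit_changepoint_window <- function(depths, mask = NULL, grid = 100,
                                   min_len = 1000, max_len = 10000) {
  n <- length(depths)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (n < 2000 || mean(mask) > 0.5) return(NULL)
  d <- ifelse(mask, 0, depths)
  use <- as.numeric(!mask)

  n_bins <- n %/% grid
  if (n_bins < 2) return(NULL)
  nb_len <- n_bins * grid
  idx <- seq_len(nb_len)
  binify <- function(x) {
    cs <- c(0, cumsum(x[idx]))
    cs[seq(grid, nb_len, by = grid) + 1] - cs[seq(0, nb_len - grid, by = grid) + 1]
  }
  bsum <- binify(d)
  bsq <- binify(d * d)
  bcnt <- binify(use)
  # tail bases beyond the last full bin still inform the totals
  tail_i <- setdiff(seq_len(n), idx)
  tot_sum <- sum(bsum) + sum(d[tail_i])
  tot_sq <- sum(bsq) + sum(d[tail_i]^2)
  tot_cnt <- sum(bcnt) + sum(use[tail_i])
  if (tot_cnt < 2) return(NULL)
  rss1 <- tot_sq - tot_sum^2 / tot_cnt

  csum <- c(0, cumsum(bsum))
  csq <- c(0, cumsum(bsq))
  ccnt <- c(0, cumsum(bcnt))

  min_bins <- max(1L, ceiling(min_len / grid))
  max_bins <- min(floor(max_len / grid), n_bins - 1L)
  if (max_bins < min_bins) return(NULL)

  best <- list(lambda = -Inf)
  n_cand <- 0L
  for (L in min_bins:max_bins) {
    s <- 0:(n_bins - L)
    t_sum <- csum[s + L + 1] - csum[s + 1]
    t_cnt <- ccnt[s + L + 1] - ccnt[s + 1]
    b_sum <- tot_sum - t_sum
    b_cnt <- tot_cnt - t_cnt
    valid <- t_cnt > 0 & b_cnt > 0
    n_cand <- n_cand + sum(valid)
    if (!any(valid)) next
    rss2 <- tot_sq - ifelse(valid, t_sum^2 / pmax(t_cnt, 1) +
                              b_sum^2 / pmax(b_cnt, 1), Inf)
    rss2 <- pmax(rss2, 0)
    lam <- ifelse(valid & rss1 > 0,
                  tot_cnt * log(rss1 / pmax(rss2, .Machine$double.eps * rss1)),
                  -Inf)
    i <- which.max(lam)
    if (lam[i] > best$lambda) {
      best <- list(lambda = lam[i], start = s[i] * grid,
                   end = (s[i] + L) * grid, rss2 = rss2[i],
                   t_sum = t_sum[i], t_cnt = t_cnt[i])
    }
  }
  if (identical(best$lambda, -Inf)) return(NULL)

  tr <- best$start:(best$end - 1) + 1L
  out_tr <- setdiff(seq_len(n), tr)
  bg_vals <- depths[out_tr][!mask[out_tr]]
  tr_use <- !mask[tr]
  zero_fr <- if (any(tr_use)) mean(depths[tr][tr_use] == 0) else NA_real_
  lambda <- max(best$lambda, 0)
  structure(list(
    tract = c(best$start, best$end),
    rss1 = rss1, rss2 = best$rss2, lambda = lambda, df = 1L,
    p_value = stats::pchisq(lambda, df = 1, lower.tail = FALSE),
    n_used = tot_cnt, n_candidates = n_cand,
    tract_mean = if (best$t_cnt > 0) best$t_sum / best$t_cnt else NA_real_,
    background_median = stats::median(bg_vals),
    zero_fraction = zero_fr
  ), class = "changepoint_fit")
}

#' Genotype a deletion call from depth
#'
#' @param tract_mean mean depth over the tract.
#' @param background background depth (> 0).
#' @param zero_fraction fraction of tract positions with zero depth.
#' @return list with `zygosity` (`"hom"` iff `tract_mean < 0.10 *
#'   background`, strict, else `"het"`) and `zero_flag` (`TRUE` iff
#'   `zero_fraction >= 0.5`).
#' @export
genotype_call <- function(tract_mean, background, zero_fraction) {
  stopifnot(background > 0)
  list(zygosity = if (tract_mean < 0.10 * background) "hom" else "het",
       zero_flag = zero_fraction >= 0.5)
}

#' Scan a depth track for deletions
#'
#' Tiles the contig with non-overlapping windows, fits the best tract per
#' window ([fit_changepoint_window()]), and keeps tracts significant at a
#' Bonferroni-corrected level. The Bonferroni denominator is the total
#' number of candidate tract placements tested genome-wide, which makes the
#' family-wise error bound valid for the scan maximum (each fixed placement
#' is asymptotically chi-squared with 1 df; the per-window best is a maximum
#' over all placements). Overlapping or abutting tracts from adjacent
#' windows (within one grid step) are merged and re-genotyped from pooled
#' depth.
#'
#' @param track a `depth_track`.
#' @param alpha family-wise significance level (default 0.05).
#' @param window window size in bp (default 20000).
#' @param grid,min_len,max_len see [fit_changepoint_window()].
#' @param n_tests_total optional externally supplied Bonferroni denominator
#'   (e.g. when scanning several contigs as one family).
#' @return data.frame of calls: `contig`, `start`, `end` (0-based
#'   half-open), `length`, `zygosity`, `tract_mean`, `background`,
#'   `zero_fraction`, `zero_flag`, `lambda`, `p_value`. Attribute `n_tests`
#'   carries the denominator used.
#' @export
scan_genome <- function(track, alpha = 0.05, window = 20000, grid = 100,
                        min_len = 1000, max_len = 10000,
                        n_tests_total = NULL) {
  n <- length(track$depth)
  if (n < 2000) {
    warning("contig ", track$contig, " shorter than the minimum window; skipped")
    return(empty_calls(n_tests = 0))
  }
  starts <- seq(0, n - 1, by = window)
  fits <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    i1 <- min(i0 + window, n)
    if (i1 - i0 < 2000) next
    idx <- (i0 + 1):i1
    fits[[k]] <- fit_changepoint_window(track$depth[idx], track$mask[idx],
                                        grid = grid, min_len = min_len,
                                        max_len = max_len)
  }
  n_tests <- sum(vapply(fits, function(f) if (is.null(f)) 0L else f$n_candidates,
                        integer(1)))
  denom <- if (is.null(n_tests_total)) n_tests else n_tests_total
  thresh <- if (denom > 0) alpha / denom else 0

  kept <- list()
  for (k in seq_along(fits)) {
    f <- fits[[k]]
    if (is.null(f) || f$p_value > thresh) next
    kept[[length(kept) + 1]] <- data.frame(
      start = starts[k] + f$tract[1], end = starts[k] + f$tract[2],
      lambda = f$lambda, p_value = f$p_value)
  }
  if (!length(kept)) return(empty_calls(n_tests = n_tests))
  raw <- do.call(rbind, kept)
  raw <- raw[order(raw$start), , drop = FALSE]

  # merge tracts that overlap or abut within one grid step
  grp <- cumsum(c(1, as.integer(raw$start[-1] > raw$end[-nrow(raw)] + grid)))
  merged <- lapply(split(raw, grp), function(m) {
    s <- min(m$start); e <- max(m$end)
    tr <- (s + 1):e
    win_lo <- max(0, s - window %/% 2)
    win_hi <- min(n, e + window %/% 2)
    ctx <- setdiff((win_lo + 1):win_hi, tr)
    tr_use <- !track$mask[tr]
    bg_vals <- track$depth[ctx][!track$mask[ctx]]
    tmean <- if (any(tr_use)) mean(track$depth[tr][tr_use]) else NA_real_
    bg <- stats::median(bg_vals)
    zf <- if (any(tr_use)) mean(track$depth[tr][tr_use] == 0) else NA_real_
    gt <- genotype_call(tmean, max(bg, .Machine$double.eps), zf)
    data.frame(contig = track$contig, start = s, end = e, length = e - s,
               zygosity = gt$zygosity, tract_mean = tmean, background = bg,
               zero_fraction = zf, zero_flag = gt$zero_flag,
               lambda = max(m$lambda), p_value = min(m$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[out$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  out
}

empty_calls <- function(n_tests = 0) {
  out <- data.frame(contig = character(), start = integer(), end = integer(),
                    length = integer(), zygosity = character(),
                    tract_mean = numeric(), background = numeric(),
                    zero_fraction = numeric(), zero_flag = logical(),
                    lambda = numeric(), p_value = numeric(),
                    stringsAsFactors = FALSE)
  attr(out, "n_tests") <- n_tests
  out
}

#' Remove intervals homozygous-deleted in every sample
#'
#' An interval homozygous-deleted in all samples indicates an insertion in
#' the reference assembly rather than a deletion in the samples; such
#' intervals are removed from every sample's call set. Calls are matched
#' across samples by reciprocal overlap.
#'
#' @param call_sets named list (>= 2) of call data.frames from
#'   [scan_genome()].
#' @param reciprocal minimum reciprocal overlap to treat two calls as the
#'   same interval (default 0.5).
#' @return the list with reference-insertion intervals removed.
#' @export
filter_reference_insertions <- function(call_sets, reciprocal = 0.5) {
  if (length(call_sets) < 2) {
    warning("fewer than 2 samples: reference-insertion filter is a no-op")
    return(call_sets)
  }
  hom_sets <- lapply(call_sets, function(x) x[x$zygosity == "hom", , drop = FALSE])
  ref <- hom_sets[[1]]
  if (!nrow(ref)) return(call_sets)
  shared <- rep(TRUE, nrow(ref))
  for (j in 2:length(hom_sets)) {
    shared <- shared & has_reciprocal_partner(ref, hom_sets[[j]], reciprocal)
  }
  bad <- ref[shared, , drop = FALSE]
  if (!nrow(bad)) return(call_sets)
  lapply(call_sets, function(x) {
    drop <- has_reciprocal_partner(x, bad, reciprocal) & x$zygosity == "hom"
    x[!drop, , drop = FALSE]
  })
}

has_reciprocal_partner <- function(a, b, reciprocal) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  ga <- GenomicRanges::GRanges(a$contig, IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$contig, IRanges::IRanges(b$start + 1, b$end))
  ov <- GenomicRanges::findOverlaps(ga, gb)
  if (!length(ov)) return(rep(FALSE, nrow(a)))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  okpair <- inter >= reciprocal * (a$end - a$start)[qi] &
    inter >= reciprocal * (b$end - b$start)[si]
  res <- rep(FALSE, nrow(a))
  res[unique(qi[okpair])] <- TRUE
  res
}

#' Genes whose exons intersect deletion calls
#'
#' @param calls call data.frame from [scan_genome()].
#' @param genes list of `gene_model`s.
#' @return data.frame `gene_id`, `zygosity`: one row per (gene, zygosity)
#'   with at least one exon intersecting a call of that zygosity.
#' @export
gene_overlap <- function(calls, genes) {
  if (!nrow(calls) || !length(genes)) {
    return(data.frame(gene_id = character(), zygosity = character()))
  }
  ex <- do.call(rbind, lapply(genes, function(g) {
    data.frame(contig = g$contig, start = g$exons$start, end = g$exons$end,
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  }))
  ge <- GenomicRanges::GRanges(ex$contig, IRanges::IRanges(ex$start + 1, ex$end))
  gc <- GenomicRanges::GRanges(calls$contig, IRanges::IRanges(calls$start + 1, calls$end))
  ov <- GenomicRanges::findOverlaps(ge, gc)
  if (!length(ov)) return(data.frame(gene_id = character(), zygosity = character()))
  hit <- unique(data.frame(gene_id = ex$gene_id[S4Vectors::queryHits(ov)],
                           zygosity = calls$zygosity[S4Vectors::subjectHits(ov)],
                           stringsAsFactors = FALSE))
  rownames(hit) <- NULL
  hit[order(hit$gene_id, hit$zygosity), , drop = FALSE]
}

#' Estimate deletion-calling recall by depth downsampling
#'
#' Thins the depth track per-base binomially to a target mean depth, re-runs
#' the caller, and reports the fraction of full-depth calls recovered
#' (reciprocal overlap >= 0.5).
#'
#' @param track a `depth_track`.
#' @param target_depth target mean depth, below the track's current mean.
#' @param full_calls calls at full depth (default: computed by
#'   [scan_genome()] on `track`).
#' @param ... passed to [scan_genome()].
#' @return list with `recall`, `n_full`, `n_recovered`, `downsampled_calls`.
#' @export
estimate_recall_downsample <- function(track, target_depth, full_calls = NULL,
                                       ...) {
  cur <- mean(track$depth[!track$mask])
  if (target_depth >= cur) {
    stop("target depth (", target_depth, ") must be below the current mean (",
         round(cur, 2), ")")
  }
  if (is.null(full_calls)) full_calls <- scan_genome(track, ...)
  p <- target_depth / cur
  thin <- stats::rbinom(length(track$depth), size = round(track$depth), prob = p)
  thin_track <- depth_track(track$contig, thin, track$mask)
  down <- scan_genome(thin_track, ...)
  rec <- has_reciprocal_partner(full_calls, down, 0.5)
  list(recall = if (nrow(full_calls)) mean(rec) else NA_real_,
       n_full = nrow(full_calls), n_recovered = sum(rec),
       downsampled_calls = down)
}
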