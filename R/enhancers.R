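## Typical/super-enhancer identification in the stitched-enhancer (ROSE)
## lineage: keep distal H3K27ac peaks, stitch neighbours closer than
## 12.5 kb, rank stitched regions by total signal, and split the ranked
## curve at the point where a slope-1 line is tangent to the unit-scaled
## signal curve.

#' Filter peaks to those distal from gene TSS
#'
#' A peak is distal when its boundary lies at least `distal_boundary` bp
#' from the nearest TSS, or its center at least `distal_center` bp
#' (disjunction by default; `params$distal_rule = "and"` requires both).
#' Input order is preserved.
#'
#' @param peaks Peak `data.frame`.
#' @param genes Gene annotation (non-empty).
#' @param params A [pipeline_params()].
#' @return The distal subset of `peaks`.
#' @export
filter_distal <- function(peaks, genes, params = pipeline_params()) {
  if (is.null(genes) || nrow(genes) == 0L)
    stopf("gene annotation is empty: distality is undefined")
  keep <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    t <- sort(genes$tss[genes$chrom == ch])
    st <- peaks$start[idx]; en <- peaks$end[idx]
    edge <- .nearest_interval_dist(t, st, en)
    ctr <- .nearest_point_dist(t, floor((st + en) / 2))
    ok_edge <- edge >= params$distal_boundary
    ok_ctr <- ctr >= params$distal_center
    keep[idx] <- if (params$distal_rule == "or") ok_edge | ok_ctr
                 else ok_edge & ok_ctr
  }
  peaks[keep, , drop = FALSE]
}

#' Stitch neighbouring peaks into enhancers
#'
#' Single-linkage merge per chromosome: two peaks belong to the same
#' stitched enhancer iff the gap between them is strictly smaller than
#' `stitch_gap` (overlapping peaks have gap 0). Every input peak lands in
#' exactly one output region; output is sorted by position.
#'
#' @param peaks Peak `data.frame`.
#' @param stitch_gap Merge gap in bp (default 12500).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `n_constituents`, `total_signal` (0 until [quantify_enhancers()]),
#'   plus a list column `constituents` of row indices into `peaks`.
#' @export
stitch_peaks <- function(peaks, stitch_gap = 12500L) {
  if (nrow(peaks) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), n_constituents = integer(),
                      total_signal = numeric(), stringsAsFactors = FALSE)
    out$constituents <- list()
    return(out)
  }
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_gap,
                               with.revmap = TRUE)
  red <- GenomicRanges::sort(red)
  revmap <- lapply(S4Vectors::mcols(red)$revmap, as.integer)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = as.numeric(GenomicRanges::end(red)),
                    name = sprintf("stitched_%05d", seq_along(red)),
                    n_constituents = lengths(revmap),
                    total_signal = 0,
                    stringsAsFactors = FALSE)
  out$constituents <- revmap
  out
}

#' Quantify stitched enhancers against a signal track
#'
#' Sets `total_signal` to the area of the track intersected with each
#' region and assigns ascending ranks (rank 1 = lowest signal; ties broken
#' by genomic position for determinism).
#'
#' @param enhancers Output of [stitch_peaks()].
#' @param track A [signal_track()].
#' @return `enhancers` with `total_signal` and `rank` columns filled in.
#' @export
quantify_enhancers <- function(enhancers, track) {
  if (nrow(enhancers) == 0L) {
    enhancers$rank <- integer()
    return(enhancers)
  }
  enhancers$total_signal <- track_area(track, enhancers$chrom,
                                       enhancers$start, enhancers$end)
  ord <- order(enhancers$total_signal, enhancers$chrom, enhancers$start)
  enhancers$rank <- integer(nrow(enhancers))
  enhancers$rank[ord] <- seq_len(nrow(enhancers))
  enhancers
}

#' Slope-1 tangency cutoff on the ranked signal curve
#'
#' Signals are sorted ascending, ranks scaled to x in [0, 1] and signals to
#' y in [0, 1] (division by the maximum). The tangency point is where the
#' slope-1 line touching the scaled curve from below meets it, i.e. the
#' index minimising `y - x`; ties resolve to the higher-signal side (fewer
#' super enhancers). Enhancers with signal strictly greater than the
#' tangency signal are super.
#'
#' @param ranked_signals Non-negative signal totals (sorted internally).
#' @return A list of class `se_cutoff` with `tangency_rank` (1-based, on the
#'   ascending curve), `tangency_signal`, `n_super`, `n_typical`.
#' @export
find_se_cutoff <- function(ranked_signals) {
  s <- sort(as.numeric(ranked_signals))
  n <- length(s)
  if (n < 3L) stopf("need at least 3 enhancers to place a cutoff")
  if (any(s < 0)) stopf("signals must be non-negative")
  m <- s[n]
  if (m <= 0) stopf("degenerate curve: maximum signal is 0")
  x <- (seq_len(n) - 1) / (n - 1)
  y <- s / m
  d <- y - x
  tang <- n + 1L - which.min(rev(d))  # last minimiser: higher-signal side
  n_super <- sum(s > s[tang])
  structure(list(tangency_rank = as.integer(tang),
                 tangency_signal = s[tang],
                 n_super = as.integer(n_super),
                 n_typical = as.integer(n - n_super)),
            class = "se_cutoff")
}

#' @export
print.se_cutoff <- function(x, ...) {
  cat(sprintf(
    "Slope-1 tangency at rank %d (signal %.4g): %d super / %d typical enhancers\n",
    x$tangency_rank, x$tangency_signal, x$n_super, x$n_typical))
  invisible(x)
}

#' Call typical and super enhancers
#'
#' Composition of [filter_distal()], [stitch_peaks()],
#' [quantify_enhancers()] and [find_se_cutoff()]; enhancers above the
#' tangency point are labelled super, the rest typical. Deterministic for
#' fixed input.
#'
#' @param peaks H3K27ac peak `data.frame`.
#' @param genes Gene annotation.
#' @param track H3K27ac [signal_track()].
#' @param params A [pipeline_params()].
#' @return List of class `enhancer_calls`: `enhancers` (with `is_super`),
#'   `cutoff` (`se_cutoff` or `NULL`), `n_distal_peaks`, `status`
#'   (`"ok"`, `"no_enhancers"`, or `"no_cutoff"`).
#' @export
call_enhancers <- function(peaks, genes, track, params = pipeline_params()) {
  distal <- filter_distal(peaks, genes, params)
  enh <- stitch_peaks(distal, params$stitch_gap)
  enh <- quantify_enhancers(enh, track)
  status <- "ok"
  cutoff <- NULL
  if (nrow(enh) == 0L) {
    status <- "no_enhancers"
    enh$is_super <- logical()
  } else if (nrow(enh) < 3L || max(enh$total_signal) <= 0) {
    status <- "no_cutoff"
    enh$is_super <- rep(FALSE, nrow(enh))
  } else {
    cutoff <- find_se_cutoff(enh$total_signal)
    enh$is_super <- enh$total_signal > cutoff$tangency_signal
  }
  structure(list(enhancers = enh, cutoff = cutoff,
                 n_distal_peaks = nrow(distal), status = status),
            class = "enhancer_calls")
}

#' @export
print.enhancer_calls <- function(x, ...) {
  cat(sprintf("Enhancer calls (%s): %d stitched regions from %d distal peaks\n",
              x$status, nrow(x$enhancers), x$n_distal_peaks))
  if (!is.null(x$cutoff)) print(x$cutoff)
  invisible(x)
}

#' Average-signal profile matrix around anchors
#'
#' For each anchor (peak summit, gene TSS, or interval midpoint) the window
#' `[anchor - flank, anchor + flank)` is split into `nbins` equal bins and
#' the mean signal density per bin is recorded. Windows running past the
#' chromosome start are clipped; uncovered bases count as 0 signal. Column
#' means give the average profile curve.
#'
#' @param anchors Peak `data.frame` (summits used), gene `data.frame` (TSS
#'   used) or any `data.frame` with `chrom`, `start`, `end` (midpoint used).
#' @param track A [signal_track()].
#' @param flank Half-window in bp (> 0).
#' @param nbins Number of bins (>= 1).
#' @return List of class `profile_matrix`: `matrix` (anchors x bins),
#'   `bin_centers` (positions relative to the anchor), `mean_profile`.
#' @export
profile_matrix <- function(anchors, track, flank = 2000L, nbins = 50L) {
  if (flank <= 0) stopf("flank must be > 0")
  if (nbins < 1) stopf("nbins must be >= 1")
  pts <- if ("summit" %in% names(anchors)) anchors$summit
         else if ("tss" %in% names(anchors)) anchors$tss
         else floor((anchors$start + anchors$end) / 2)
  step <- (2 * flank) / nbins
  mat <- matrix(0, nrow = length(pts), ncol = nbins)
  for (ch in unique(anchors$chrom)) {
    runs <- track[track$chrom == ch, , drop = FALSE]
    idx <- which(anchors$chrom == ch)
    bounds <- outer(pts[idx] - flank, (0:nbins) * step, `+`)
    a <- matrix(.track_cumarea(runs, pmax(0, as.vector(bounds))),
                nrow = length(idx))
    mat[idx, ] <- (a[, -1L, drop = FALSE] - a[, -(nbins + 1L), drop = FALSE]) / step
  }
  rn <- anchors$name %||% anchors$gene_id
  if (!is.null(rn)) rownames(mat) <- rn
  structure(list(matrix = mat,
                 bin_centers = -flank + step * (seq_len(nbins) - 0.5),
                 mean_profile = colMeans(mat)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Profile matrix: %d anchors x %d bins, mean signal %.4g\n",
              nrow(x$matrix), ncol(x$matrix), mean(x$matrix)))
  invisible(x)
}
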