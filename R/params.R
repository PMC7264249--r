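#' Pipeline parameters
#'
#' Bundles every tunable distance and threshold of the analysis. Defaults are
#' the values used throughout: distal peaks are those with a boundary at
#' least 1.5 kb or a center at least 3 kb from the nearest gene TSS, peaks
#' closer than 12.5 kb are stitched into one enhancer, summit flanks are
#' 200 bp, two summits closer than 200 bp count as co-bound, and motif
#' enrichment is reported at p <= 0.05.
#'
#' @param stitch_gap Maximum gap (bp, exclusive) between neighbouring distal
#'   peaks that are merged into one stitched enhancer.
#' @param distal_boundary Minimum distance (bp) from a peak boundary to the
#'   nearest TSS for the boundary clause of the distal filter.
#' @param distal_center Minimum distance (bp) from a peak center to the
#'   nearest TSS for the center clause of the distal filter.
#' @param flank_width Width (bp) of the sequence window extracted around
#'   each peak summit for motif scoring.
#' @param cobind_max_dist Summit-to-summit distance (bp, exclusive) below
#'   which two peaks from different sets are considered overlapped.
#' @param enrich_alpha Significance level for motif enrichment calls.
#' @param distal_rule `"or"` (default) treats the boundary and center clauses
#'   as alternative sufficiency criteria; `"and"` requires both.
#' @param cobind_mode Distance used for co-binding: `"summit"` (default,
#'   summit-to-summit) or `"edge"` (interval gap).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(stitch_gap = 12500L,
                            distal_boundary = 1500L,
                            distal_center = 3000L,
                            flank_width = 200L,
                            cobind_max_dist = 200L,
                            enrich_alpha = 0.05,
                            distal_rule = c("or", "and"),
                            cobind_mode = c("summit", "edge")) {
  distal_rule <- match.arg(distal_rule)
  cobind_mode <- match.arg(cobind_mode)
  dists <- c(stitch_gap = stitch_gap, distal_boundary = distal_boundary,
             distal_center = distal_center, flank_width = flank_width,
             cobind_max_dist = cobind_max_dist)
  if (any(!is.finite(dists)) || any(dists <= 0))
    stopf("all distance parameters must be positive")
  if (!is.finite(enrich_alpha) || enrich_alpha <= 0 || enrich_alpha >= 1)
    stopf("enrich_alpha must lie in (0, 1)")
  structure(list(stitch_gap = as.integer(stitch_gap),
                 distal_boundary = as.integer(distal_boundary),
                 distal_center = as.integer(distal_center),
                 flank_width = as.integer(flank_width),
                 cobind_max_dist = as.integer(cobind_max_dist),
                 enrich_alpha = enrich_alpha,
                 distal_rule = distal_rule,
                 cobind_mode = cobind_mode),
            class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("Pipeline parameters:\n")
  cat(sprintf("  stitch gap        < %d bp\n", x$stitch_gap))
  cat(sprintf("  distal: boundary >= %d bp %s center >= %d bp\n",
              x$distal_boundary, toupper(x$distal_rule), x$distal_center))
  cat(sprintf("  flank width         %d bp\n", x$flank_width))
  cat(sprintf("  co-binding (%s)  < %d bp\n", x$cobind_mode, x$cobind_max_dist))
  cat(sprintf("  enrichment alpha    %g\n", x$enrich_alpha))
  invisible(x)
}
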