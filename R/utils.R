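`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Reverse complement of DNA strings
#'
#' Base-R reverse complement over the alphabet A, C, G, T, N (case
#' preserved). Used for the minus-strand pass of motif scanning and for
#' planting motif instances.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## distance from a point vector `x` to the nearest value in sorted vector `t`
.nearest_point_dist <- function(t, x) {
  if (length(t) == 0L) return(rep(Inf, length(x)))
  i <- findInterval(x, t)
  left <- ifelse(i >= 1L, x - t[pmax(i, 1L)], Inf)
  right <- ifelse(i < length(t), t[pmin(i + 1L, length(t))] - x, Inf)
  pmin(left, right)
}

## distance from intervals [start, end] (coordinates, half-open peaks passed
## as start/end) to the nearest point in sorted vector `t`; 0 when a point
## falls inside the interval.
.nearest_interval_dist <- function(t, start, end) {
  if (length(t) == 0L) return(rep(Inf, length(start)))
  n <- length(t)
  ## largest t <= end  -> candidate on the left/inside
  iA <- findInterval(end, t)
  tA <- ifelse(iA >= 1L, t[pmax(iA, 1L)], NA_real_)
  dA <- ifelse(is.na(tA), Inf, ifelse(tA >= start, 0, start - tA))
  ## smallest t >= start -> candidate on the right/inside
  iB <- findInterval(start - 0.5, t) + 1L
  tB <- ifelse(iB <= n, t[pmin(iB, n)], NA_real_)
  dB <- ifelse(is.na(tB), Inf, ifelse(tB <= end, 0, tB - end))
  pmin(dA, dB)
}
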