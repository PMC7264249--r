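## Domain containers. Coordinates are BED convention throughout: 0-based,
## half-open [start, end). A summit is an absolute base position with
## start <= summit < end.

#' Construct a validated peak set
#'
#' A peak set is a plain `data.frame` with columns `chrom`, `start`, `end`,
#' `name`, `summit`, `signal`. When no summit is supplied it defaults to the
#' floor of the interval midpoint.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @param name Optional peak names; generated when missing.
#' @param summit Optional absolute summit positions within `[start, end)`.
#' @param signal Optional non-negative per-peak signal/score.
#' @return `data.frame` with the six peak columns.
#' @export
peak_set <- function(chrom, start, end, name = NULL, summit = NULL,
                     signal = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  if (length(end) != n)
    stopf("start and end must have equal length")
  chrom <- rep_len(as.character(chrom), n)
  if (n && any(!nzchar(chrom))) stopf("chrom names must be non-empty")
  if (any(start < 0)) stopf("start positions must be >= 0")
  bad <- which(start >= end)
  if (length(bad))
    stopf("invalid interval (start >= end) at record %d", bad[1])
  if (is.null(name)) name <- sprintf("peak_%05d", seq_len(n))
  if (is.null(summit)) summit <- floor((start + end) / 2)
  summit <- as.numeric(summit)
  bad <- which(summit < start | summit >= end)
  if (length(bad))
    stopf("summit outside [start, end) at record %d", bad[1])
  if (is.null(signal)) signal <- rep(0, n)
  if (any(signal < 0)) stopf("peak signal must be non-negative")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = as.character(name), summit = summit,
             signal = as.numeric(signal), stringsAsFactors = FALSE)
}

#' Construct a validated gene/TSS annotation
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param tss 0-based TSS positions (width-1 anchors).
#' @param strand `"+"` or `"-"` per gene.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
gene_set <- function(gene_id, chrom, tss, strand = "+") {
  n <- length(gene_id)
  if (anyDuplicated(gene_id))
    stopf("gene_id values must be unique within an annotation")
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  if (n && !all(strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  if (any(tss < 0)) stopf("tss positions must be >= 0")
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             tss = as.numeric(tss), strand = strand, stringsAsFactors = FALSE)
}

#' Construct a piecewise-constant signal track
#'
#' Runs are per-chromosome `(start, end, value)` triples with non-negative
#' value (signal density per base). Runs are sorted and must not overlap;
#' any position not covered by a run has signal 0.
#'
#' @param chrom,start,end Run coordinates (0-based half-open).
#' @param value Non-negative signal density per base.
#' @param coalesce Merge adjacent equal-valued runs (default `TRUE`);
#'   coalescing never changes query results or total area.
#' @return `data.frame` of class `signal_track`, sorted by chrom then start.
#' @export
signal_track <- function(chrom, start, end, value, coalesce = TRUE) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0)) stopf("track run start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad)) stopf("invalid track run (start >= end) at record %d", bad[1])
  if (any(df$value < 0)) stopf("track values must be non-negative")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (nrow(df) > 1) {
    ovl <- which(same & df$start[-1] < df$end[-nrow(df)])
    if (length(ovl))
      stopf("overlapping track runs on %s near position %d",
            df$chrom[ovl[1] + 1], as.integer(df$start[ovl[1] + 1]))
  }
  if (coalesce && nrow(df) > 1) {
    join <- c(FALSE, same & df$start[-1] == df$end[-nrow(df)] &
                df$value[-1] == df$value[-nrow(df)])
    grp <- cumsum(!join)
    df <- data.frame(chrom = df$chrom[!join],
                     start = df$start[!join],
                     end = tapply(df$end, grp, max)[unique(grp)] * 1,
                     value = df$value[!join], stringsAsFactors = FALSE)
    rownames(df) <- NULL
  }
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Total area under a signal track
#'
#' @param track A `signal_track`.
#' @return Sum over runs of `value * (end - start)`.
#' @export
track_total_area <- function(track) {
  sum(track$value * (track$end - track$start))
}

## cumulative area A(pos) from chromosome origin to `pos` for one
## chromosome's runs (sorted, non-overlapping); vectorised over pos.
.track_cumarea <- function(runs, pos) {
  a <- numeric(length(pos))
  if (nrow(runs) == 0L) return(a)
  csum0 <- c(0, cumsum(runs$value * (runs$end - runs$start)))
  i <- findInterval(pos, runs$start)
  inrun <- i >= 1L
  ii <- i[inrun]
  a[inrun] <- csum0[ii] + runs$value[ii] *
    pmax(0, pmin(pos[inrun], runs$end[ii]) - runs$start[ii])
  a
}

#' Query signal area over intervals
#'
#' Area (signal density integrated over bases) of a track intersected with
#' the query intervals. Positions outside any run contribute 0.
#'
#' @param track A `signal_track`.
#' @param chrom,start,end Query intervals (0-based half-open; vectors).
#' @return Numeric vector of areas.
#' @export
track_area <- function(track, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    runs <- track[track$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    out[idx] <- .track_cumarea(runs, pmax(0, end[idx])) -
      .track_cumarea(runs, pmax(0, start[idx]))
  }
  out
}

#' Construct a position weight matrix
#'
#' @param motif_id Motif identifier.
#' @param matrix L x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; each row must sum to 1 within 1e-6.
#' @param background Length-4 background base frequencies summing to 1.
#' @return A list of class `pwm` with elements `motif_id`, `matrix`,
#'   `background`.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stopf("pwm matrix must have 4 columns (A,C,G,T)")
  if (any(matrix <= 0))
    stopf("pwm '%s': all probabilities must be > 0 (apply a pseudocount)",
          motif_id)
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stopf("pwm '%s': rows must sum to 1 within 1e-6", motif_id)
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stopf("pwm '%s': background must be positive and sum to 1", motif_id)
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), matrix = matrix,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%d positions), consensus %s\n",
              x$motif_id, nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (argmax base per position)
#'
#' @param x A `pwm`.
#' @return Single DNA string of length `nrow(x$matrix)`.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$matrix, 1L, which.max)], collapse = "")
}

#' Construct a flank-sequence set
#'
#' @param label Condition label (e.g. a drug treatment or control name).
#' @param sequences Character vector of uniform-width DNA sequences over
#'   the alphabet A, C, G, T, N.
#' @return A list of class `flank_set`.
#' @export
flank_set <- function(label, sequences) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences)) {
    w <- unique(nchar(sequences))
    if (length(w) != 1L) stopf("flank sequences must have uniform width")
    if (any(grepl("[^ACGTN]", sequences)))
      stopf("flank sequences restricted to alphabet A,C,G,T,N")
  }
  structure(list(label = as.character(label), sequences = sequences),
            class = "flank_set")
}

#' @export
print.flank_set <- function(x, ...) {
  cat(sprintf("Flank set '%s': %d sequences of width %s bp\n", x$label,
              length(x$sequences),
              if (length(x$sequences)) nchar(x$sequences[1]) else "?"))
  invisible(x)
}
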