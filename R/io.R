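## Readers/writers for the plain-text formats the pipeline consumes:
## BED (3-6+ columns, optional summit-offset column in the MACS/narrowPeak
## dialect), bedGraph, MEME minimal motif files, genome FASTA (delegated to
## Biostrings) and TSV expression/DEG tables.

.read_text_records <- function(path, min_fields, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad))
    stopf("%s parse error at line %d of %s: expected >= %d tab-separated fields, got %d",
          what, lineno[bad[1]], path, min_fields, nf[bad[1]])
  list(fields = fields, lineno = lineno)
}

.num_field <- function(fields, lineno, col, path, what) {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
  bad <- which(is.na(x))
  if (length(bad))
    stopf("%s parse error at line %d of %s: column %d is not numeric",
          what, lineno[bad[1]], path, col)
  x
}

#' Read a BED peak file
#'
#' Parses 3+ column tab-separated BED records as 0-based half-open peaks.
#' With `has_summit = TRUE` the column `summit_col` is read as the summit;
#' by default it is an offset from `start` (the MACS/narrowPeak dialect),
#' with `summit_is_offset = FALSE` it is an absolute position. Without a
#' summit column the summit defaults to the floor of the interval midpoint.
#'
#' @param path BED file path.
#' @param has_summit Does the file carry a summit column?
#' @param summit_col 1-based column index of the summit (default 6).
#' @param summit_is_offset Interpret the summit column as offset from start
#'   (default) or as an absolute coordinate.
#' @param signal_col Optional column read as peak signal (default 5 when
#'   present and numeric).
#' @return A peak `data.frame` (see [peak_set()]).
#' @export
read_bed <- function(path, has_summit = FALSE, summit_col = 6L,
                     summit_is_offset = TRUE, signal_col = 5L) {
  rec <- .read_text_records(path, if (has_summit) max(3L, summit_col) else 3L,
                            "BED")
  fields <- rec$fields; lineno <- rec$lineno
  n <- length(fields)
  if (n == 0L) return(peak_set(character(), numeric(), numeric()))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .num_field(fields, lineno, 2L, path, "BED")
  end <- .num_field(fields, lineno, 3L, path, "BED")
  bad <- which(start >= end)
  if (length(bad))
    stopf("BED validation error at line %d of %s: start >= end",
          lineno[bad[1]], path)
  name <- if (all(lengths(fields) >= 4L)) vapply(fields, `[[`, "", 4L)
          else sprintf("peak_%05d", seq_len(n))
  signal <- NULL
  if (!is.null(signal_col) && all(lengths(fields) >= signal_col)) {
    sig <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", signal_col)))
    if (!anyNA(sig) && all(sig >= 0)) signal <- sig
  }
  summit <- NULL
  if (has_summit) {
    s <- .num_field(fields, lineno, summit_col, path, "BED")
    summit <- if (summit_is_offset) start + s else s
    bad <- which(summit < start | summit >= end)
    if (length(bad))
      stopf("BED validation error at line %d of %s: summit outside [start, end)",
            lineno[bad[1]], path)
  }
  peak_set(chrom, start, end, name = name, summit = summit, signal = signal)
}

#' Write peaks as BED6+1 (name, signal, summit offset)
#'
#' Round-trips through `read_bed(path, has_summit = TRUE, summit_col = 7)`.
#'
#' @param peaks Peak `data.frame`.
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   peaks$name, format(peaks$signal, digits = 15, trim = TRUE),
                   format(peaks$summit - peaks$start, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation BED
#'
#' Expects BED with gene identifier in column 4 and strand in column 6; the
#' interval start is taken as the TSS position (width-1 anchor).
#'
#' @param path BED file path.
#' @return A gene `data.frame` (see [gene_set()]).
#' @export
read_tss_bed <- function(path) {
  rec <- .read_text_records(path, 4L, "TSS BED")
  fields <- rec$fields; lineno <- rec$lineno
  if (length(fields) == 0L)
    return(gene_set(character(), character(), numeric(), character()))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .num_field(fields, lineno, 2L, path, "TSS BED")
  gene_id <- vapply(fields, `[[`, "", 4L)
  strand <- if (all(lengths(fields) >= 6L)) vapply(fields, `[[`, "", 6L)
            else rep("+", length(fields))
  gene_set(gene_id, chrom, start, strand)
}

#' Write a TSS annotation BED
#' @param genes Gene `data.frame`.
#' @param path Output path.
#' @export
write_tss_bed <- function(genes, path) {
  df <- data.frame(genes$chrom,
                   format(genes$tss, scientific = FALSE, trim = TRUE),
                   format(genes$tss + 1, scientific = FALSE, trim = TRUE),
                   genes$gene_id, 0L, genes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Four-column chrom/start/end/value records; runs are validated as
#' non-overlapping per chromosome, values must be non-negative, and adjacent
#' equal-valued runs are coalesced (query semantics are unchanged).
#'
#' @param path bedGraph file path.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path) {
  rec <- .read_text_records(path, 4L, "bedGraph")
  fields <- rec$fields; lineno <- rec$lineno
  if (length(fields) == 0L)
    return(signal_track(character(), numeric(), numeric(), numeric()))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .num_field(fields, lineno, 2L, path, "bedGraph")
  end <- .num_field(fields, lineno, 3L, path, "bedGraph")
  value <- .num_field(fields, lineno, 4L, path, "bedGraph")
  bad <- which(value < 0)
  if (length(bad))
    stopf("bedGraph validation error at line %d of %s: negative value",
          lineno[bad[1]], path)
  signal_track(chrom, start, end, value)
}

#' Write a signal track as bedGraph
#' @param track A `signal_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   format(track$value, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' A pseudocount is added to every entry and rows are renormalised, so all
#' log-odds downstream are finite. Background frequencies come from the
#' file's `Background letter frequencies` block when present, else uniform.
#'
#' @param path MEME file path.
#' @param pseudocount Probability mass added to each matrix cell before
#'   renormalisation (default 1e-4).
#' @return List of [pwm()] objects in file order.
#' @export
read_meme_motifs <- function(path, pseudocount = 1e-4) {
  if (!file.exists(path)) stopf("MEME file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    freq <- suppressWarnings(as.numeric(toks[seq(2, length(toks), by = 2)]))
    lets <- toks[seq(1, length(toks), by = 2)]
    if (anyNA(freq) || !all(c("A", "C", "G", "T") %in% lets))
      stopf("malformed background block in %s", path)
    background <- freq[match(c("A", "C", "G", "T"), lets)]
    background <- background / sum(background)
  }
  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    id <- strsplit(trimws(lines[motif_at[k]]), "\\s+")[[1]][2]
    block_end <- if (k < length(motif_at)) motif_at[k + 1L] - 1L else length(lines)
    block <- lines[motif_at[k]:block_end]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr))
      stopf("motif '%s' in %s lacks a letter-probability matrix", id, path)
    rows <- list()
    i <- hdr[1] + 1L
    while (i <= length(block)) {
      toks <- strsplit(trimws(block[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) != 4L || anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (!length(rows))
      stopf("motif '%s' in %s has an empty probability matrix", id, path)
    m <- do.call(rbind, rows)
    bad <- which(abs(rowSums(m) - 1) > 0.1)
    if (length(bad))
      stopf("motif '%s' in %s: row %d probabilities sum to %.4f, outside [0.9, 1.1]",
            id, path, bad[1], rowSums(m)[bad[1]])
    m <- m + pseudocount
    m <- m / rowSums(m)
    motifs[[k]] <- pwm(id, m, background)
  }
  motifs
}

#' Write motifs as a MEME minimal-format file
#' @param motifs List of `pwm` objects (uniform background assumed shared;
#'   the first motif's background is written).
#' @param path Output path.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  bg <- if (length(motifs)) motifs[[1]]$background else rep(0.25, 4)
  writeLines(c("Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(m$matrix)), con)
    writeLines(apply(m$matrix, 1L, function(r)
      paste(sprintf("%.10f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector, one element per chromosome (names are
#'   the first whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  out
}

#' Write a genome FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write flank sequences as FASTA
#' @param flanks A [flank_set()].
#' @param path Output path.
#' @export
write_flank_fasta <- function(flanks, path) {
  seqs <- flanks$sequences
  nm <- names(seqs) %||% sprintf("%s_flank_%05d", flanks$label, seq_along(seqs))
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read flank sequences from FASTA
#' @param path FASTA path.
#' @param label Condition label for the resulting set.
#' @return A [flank_set()].
#' @export
read_flank_fasta <- function(path, label) {
  g <- read_genome_fasta(path)
  fs <- flank_set(label, unname(g))
  names(fs$sequences) <- names(g)
  fs
}

#' Read a DEG table
#'
#' Tab-separated with header; requires columns `gene_id` and `direction`
#' (values `up`, `down` or `none`), optionally `log2fc`.
#'
#' @param path TSV path.
#' @return `data.frame` with at least `gene_id` and `direction`.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stopf("DEG table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "direction") %in% names(df)))
    stopf("DEG table %s must have columns gene_id and direction", path)
  if (!all(df$direction %in% c("up", "down", "none")))
    stopf("DEG table %s: direction must be up/down/none", path)
  df
}

#' Write a DEG/expression table
#' @param df `data.frame` with `gene_id` and `direction` columns.
#' @param path Output path.
#' @export
write_deg_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
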