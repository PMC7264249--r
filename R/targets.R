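## Peak-to-gene annotation (nearest TSS), target-gene calling as the
## intersection of bound genes with DEGs, Venn-style set summaries, and
## summit-distance co-binding classification between two peak sets.

#' Annotate peaks with their nearest gene TSS
#'
#' Each peak is linked to the gene whose TSS is nearest its summit; ties
#' resolve to the lexicographically smaller `gene_id`. The signed distance
#' is oriented by gene strand (negative = upstream of the TSS in gene
#' orientation). Peaks on chromosomes without any annotated gene are dropped
#' with a warning.
#'
#' @param peaks Peak `data.frame`.
#' @param genes Non-empty gene annotation.
#' @return `data.frame` with columns `name`, `chrom`, `summit`, `gene_id`,
#'   `distance`.
#' @export
annotate_peaks <- function(peaks, genes) {
  if (is.null(genes) || nrow(genes) == 0L)
    stopf("gene annotation is empty")
  out <- vector("list", 0L)
  orphan <- 0L
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) { orphan <- orphan + length(idx); next }
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    u <- unique(g$tss)
    ## per unique position, the lexicographically smallest gene (g sorted)
    first <- match(u, g$tss)
    s <- peaks$summit[idx]
    i <- findInterval(s, u)
    dl <- ifelse(i >= 1L, s - u[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(u), u[pmin(i + 1L, length(u))] - s, Inf)
    pick_left <- dl < dr
    tie <- dl == dr & is.finite(dl)
    gi <- integer(length(idx))
    gi[pick_left] <- first[i[pick_left]]
    gi[!pick_left] <- first[pmin(i[!pick_left] + 1L, length(u))]
    if (any(tie)) {
      for (k in which(tie)) {
        cand <- c(first[i[k]], first[i[k] + 1L])
        gi[k] <- cand[order(g$gene_id[cand])[1L]]
      }
    }
    d <- s - g$tss[gi]
    d <- ifelse(g$strand[gi] == "-", -d, d)
    out[[length(out) + 1L]] <- data.frame(
      name = peaks$name[idx], chrom = ch, summit = s,
      gene_id = g$gene_id[gi], distance = d, stringsAsFactors = FALSE)
  }
  if (orphan > 0L)
    warning(sprintf("annotate_peaks: dropped %d peak(s) on chromosomes without genes",
                    orphan))
  if (!length(out))
    return(data.frame(name = character(), chrom = character(),
                      summit = numeric(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[match(peaks$name[peaks$chrom %in% res$chrom], res$name), , drop = FALSE] ->
    res
  rownames(res) <- NULL
  res
}

#' Call target genes as bound-and-differentially-expressed
#'
#' A gene is a target iff it is bound (adjacent to a TF peak) and
#' differentially expressed; the DE direction is carried through for
#' up/down splits.
#'
#' @param bound_gene_ids Character vector of bound gene ids.
#' @param deg Either a named character vector (`gene_id -> "up"/"down"`) or
#'   a `data.frame` with `gene_id` and `direction` columns (rows with
#'   direction `"none"` are ignored).
#' @param annotation Optional gene annotation; DEG genes missing from it
#'   trigger a warning but are retained.
#' @return `data.frame` with columns `gene_id`, `bound`, `de_status`,
#'   `is_target`, one row per gene in the union of the two inputs.
#' @export
call_targets <- function(bound_gene_ids, deg, annotation = NULL) {
  if (is.data.frame(deg)) {
    deg <- deg[deg$direction %in% c("up", "down"), , drop = FALSE]
    degv <- stats::setNames(deg$direction, deg$gene_id)
  } else degv <- deg
  bound <- unique(as.character(bound_gene_ids))
  if (!is.null(annotation)) {
    missing <- setdiff(names(degv), annotation$gene_id)
    if (length(missing))
      warning(sprintf("call_targets: %d DEG gene(s) absent from annotation (retained)",
                      length(missing)))
  }
  ids <- union(bound, names(degv))
  de_status <- ifelse(ids %in% names(degv), degv[ids], "none")
  out <- data.frame(gene_id = ids,
                    bound = ids %in% bound,
                    de_status = unname(de_status),
                    stringsAsFactors = FALSE)
  out$is_target <- out$bound & out$de_status != "none"
  out
}

#' Venn-style summary of two sets
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return List of class `set_summary` with `n_a`, `n_b`, `n_intersection`,
#'   `n_union`, `n_a_only`, `n_b_only` obeying inclusion-exclusion exactly.
#' @export
summarize_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  ni <- length(intersect(a, b))
  structure(list(n_a = length(a), n_b = length(b), n_intersection = ni,
                 n_union = length(a) + length(b) - ni,
                 n_a_only = length(a) - ni, n_b_only = length(b) - ni),
            class = "set_summary")
}

#' @export
print.set_summary <- function(x, ...) {
  cat(sprintf("Sets: |A|=%d |B|=%d intersection=%d union=%d (A only %d, B only %d)\n",
              x$n_a, x$n_b, x$n_intersection, x$n_union, x$n_a_only, x$n_b_only))
  invisible(x)
}

#' Split targets into previously reported and novel
#'
#' @param targets Character vector of called target genes.
#' @param reported Character vector of previously reported targets.
#' @return List with `n_reported` (= |targets intersect reported|) and
#'   `n_novel` (= |targets| - n_reported).
#' @export
novel_vs_reported <- function(targets, reported) {
  targets <- unique(targets)
  n_rep <- length(intersect(targets, unique(reported)))
  list(n_reported = n_rep, n_novel = length(targets) - n_rep)
}

#' Co-binding classification between two peak sets
#'
#' A pair (one peak from each set, same chromosome) is overlapped iff the
#' summit-to-summit distance is strictly below `max_dist` (or the interval
#' gap, with `mode = "edge"`). Matching is greedy nearest-first with each
#' peak used at most once; remaining peaks are unique to their set. The
#' partition is exhaustive and disjoint.
#'
#' @param peaks_a,peaks_b Peak `data.frame`s.
#' @param max_dist Distance threshold in bp (exclusive; default 200).
#' @param mode `"summit"` (default) or `"edge"`.
#' @return List of class `cobinding`: `pairs` (`name_a`, `name_b`, `chrom`,
#'   `distance`), `a_only`, `b_only` (subsets of the inputs).
#' @export
cobinding <- function(peaks_a, peaks_b, max_dist = 200L,
                      mode = c("summit", "edge")) {
  mode <- match.arg(mode)
  if (max_dist <= 0) stopf("max_dist must be > 0")
  cand <- vector("list", 0L)
  ## candidate search window around each summit; edge mode needs slack for
  ## peak widths since edges can be close while summits are far apart
  win <- max_dist + if (mode == "edge")
    max(c(peaks_a$end - peaks_a$start, 0)) +
      max(c(peaks_b$end - peaks_b$start, 0)) else 0
  for (ch in intersect(unique(peaks_a$chrom), unique(peaks_b$chrom))) {
    ia <- which(peaks_a$chrom == ch)
    ib <- which(peaks_b$chrom == ch)
    sb <- peaks_b$summit[ib]
    ord <- order(sb)
    ib <- ib[ord]; sb <- sb[ord]
    for (k in ia) {
      sa <- peaks_a$summit[k]
      lo <- findInterval(sa - win, sb) + 1L
      hi <- findInterval(sa + win, sb)
      if (lo > hi) next
      jj <- ib[lo:hi]
      d <- if (mode == "summit") abs(sb[lo:hi] - sa)
           else pmax(0, pmax(peaks_b$start[jj] - peaks_a$end[k],
                             peaks_a$start[k] - peaks_b$end[jj]))
      ok <- d < max_dist
      if (any(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          ia = k, ib = jj[ok], distance = d[ok], stringsAsFactors = FALSE)
    }
  }
  used_a <- logical(nrow(peaks_a))
  used_b <- logical(nrow(peaks_b))
  pairs <- data.frame(name_a = character(), name_b = character(),
                      chrom = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$distance, peaks_a$name[cand$ia],
                       peaks_b$name[cand$ib]), , drop = FALSE]
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_a[cand$ia[r]] && !used_b[cand$ib[r]]) {
        keep[r] <- TRUE
        used_a[cand$ia[r]] <- TRUE
        used_b[cand$ib[r]] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    pairs <- data.frame(name_a = peaks_a$name[cand$ia],
                        name_b = peaks_b$name[cand$ib],
                        chrom = peaks_a$chrom[cand$ia],
                        distance = cand$distance,
                        stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs,
                 a_only = peaks_a[!used_a, , drop = FALSE],
                 b_only = peaks_b[!used_b, , drop = FALSE]),
            class = "cobinding")
}

#' @export
print.cobinding <- function(x, ...) {
  cat(sprintf("Co-binding: %d overlapped pairs, %d A-only, %d B-only peaks\n",
              nrow(x$pairs), nrow(x$a_only), nrow(x$b_only)))
  invisible(x)
}
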