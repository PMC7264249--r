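## Seeded synthetic regulome: a toy chromosome carrying a gene annotation,
## an enhancer landscape with a small planted high-signal (super) class,
## condition-specific TF summit sets with motif instances planted in summit
## flanks, and an expression table with planted DEGs - plus a ground-truth
## record so recovery can be scored.

#' Simulation parameters
#'
#' Defaults describe the study conditions exercised throughout the package:
#' 500 typical enhancers with exponential stitched signal (mean 10 area
#' units) plus 25 planted super enhancers carrying a 50-fold signal total,
#' 200 TF summits per stimulation condition (half shared with the control
#' set), a 10-bp motif planted in 30% of condition flanks, and 60 up / 40
#' down DEGs biased toward bound genes.
#'
#' @param seed Integer seed; one stream drives every draw, so equal seeds
#'   give byte-identical bundles.
#' @param n_genes Number of genes on the toy chromosome.
#' @param n_typical_enhancers,n_super_enhancers Planted enhancer counts.
#' @param typical_signal_mean Mean total signal (area) of a typical
#'   stitched enhancer; constituents are exponential draws.
#' @param super_signal_multiplier Super total = multiplier x
#'   `typical_signal_mean` (with a modest +/-20% uniform jitter). Must be > 1.
#' @param n_peaks_per_condition TF summits per stimulation condition.
#' @param flank_width Width of summit flanks carrying planted motifs.
#' @param plant_rate Fraction of each condition's flanks receiving an exact
#'   consensus instance of the designated motif (in `[0, 1]`).
#' @param n_deg_up,n_deg_down Planted DEG counts.
#' @param chrom_length Toy chromosome length in bp.
#' @param shared_frac Fraction of each condition's summits shared (same
#'   coordinate) with the control set.
#' @param n_cobound Number of summit pairs planted < 200 bp apart between
#'   the two stimulation conditions.
#' @param n_promoter_peaks TSS-proximal H3K27ac peaks (these must be removed
#'   by the distal filter).
#' @param gene_spacing Distance between consecutive gene TSS.
#' @param n_decoy_motifs Decoy PWMs accompanying the designated motif.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_genes = 450L,
                       n_typical_enhancers = 500L,
                       n_super_enhancers = 25L,
                       typical_signal_mean = 10,
                       super_signal_multiplier = 50,
                       n_peaks_per_condition = 200L,
                       flank_width = 200L,
                       plant_rate = 0.30,
                       n_deg_up = 60L,
                       n_deg_down = 40L,
                       chrom_length = 1.8e7,
                       shared_frac = 0.5,
                       n_cobound = 30L,
                       n_promoter_peaks = 50L,
                       gene_spacing = 4000L,
                       n_decoy_motifs = 10L) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            n_typical_enhancers = as.integer(n_typical_enhancers),
            n_super_enhancers = as.integer(n_super_enhancers),
            typical_signal_mean = typical_signal_mean,
            super_signal_multiplier = super_signal_multiplier,
            n_peaks_per_condition = as.integer(n_peaks_per_condition),
            flank_width = as.integer(flank_width),
            plant_rate = plant_rate,
            n_deg_up = as.integer(n_deg_up), n_deg_down = as.integer(n_deg_down),
            chrom_length = chrom_length,
            shared_frac = shared_frac, n_cobound = as.integer(n_cobound),
            n_promoter_peaks = as.integer(n_promoter_peaks),
            gene_spacing = as.integer(gene_spacing),
            n_decoy_motifs = as.integer(n_decoy_motifs))
  counts <- c(p$n_genes, p$n_typical_enhancers, p$n_super_enhancers,
              p$n_peaks_per_condition, p$flank_width, p$gene_spacing)
  if (any(counts <= 0)) stopf("all counts must be positive")
  if (p$super_signal_multiplier <= 1)
    stopf("super_signal_multiplier must be > 1")
  if (p$plant_rate < 0 || p$plant_rate > 1)
    stopf("plant_rate must lie in [0, 1]")
  if (p$shared_frac < 0 || p$shared_frac > 1)
    stopf("shared_frac must lie in [0, 1]")
  structure(p, class = "sim_params")
}

#' Synthetic motif library
#'
#' One designated 10-bp motif (`M_TARGET`, 0.85 probability on each
#' consensus base) plus decoys of random widths 8-12 with random strong
#' consensus. Draws come from the current RNG stream.
#'
#' @param n_decoys Number of decoy motifs.
#' @param strength Probability mass on the consensus base per position.
#' @return List of [pwm()]s; the designated motif is first.
#' @export
synthetic_motif_library <- function(n_decoys = 10L, strength = 0.85) {
  make <- function(id, len) {
    cons <- sample.int(4L, len, replace = TRUE)
    m <- matrix((1 - strength) / 3, nrow = len, ncol = 4L)
    m[cbind(seq_len(len), cons)] <- strength
    pwm(id, m)
  }
  c(list(make("M_TARGET", 10L)),
    lapply(seq_len(n_decoys),
           function(i) make(sprintf("M_DECOY%02d", i), sample(8:12, 1L))))
}

#' Random null flank sequences
#'
#' I.i.d. uniform-base DNA windows; the shared null generator for both
#' foreground and background in type-I calibration checks.
#'
#' @param n Number of sequences.
#' @param width Sequence width in bp.
#' @param label Condition label.
#' @return A [flank_set()].
#' @export
random_flanks <- function(n, width = 200L, label = "null") {
  seqs <- vapply(seq_len(n), function(i)
    intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, width, replace = TRUE)]),
    character(1))
  flank_set(label, seqs)
}

#' Simulate a synthetic regulome bundle
#'
#' Emits, in one fixed draw order from a single seeded stream: (a) gene TSS
#' annotation; (b) an H3K27ac enhancer landscape (peaks + bedGraph-style
#' track) of typical and planted super enhancer slots, all > 3 kb from every
#' TSS, plus TSS-proximal decoy peaks; (c) TF summit sets for two
#' stimulation conditions (`stimA`, `stimB`) and a control (`dmso`), with
#' exact consensus instances of the designated motif planted in a
#' `plant_rate` fraction of each condition's summit flanks (only at
#' condition-unique, non-cobound summits, so control flanks stay clean);
#' (d) an expression table with planted up/down DEGs biased toward bound
#' genes; (e) an i.i.d. uniform-base genome carrying the plants; and (f) a
#' `synthetic_truth` record.
#'
#' @param params A [sim_params()].
#' @param include_genome Generate the genome sequence (default `TRUE`).
#'   Skipping it leaves every other component identical for a given seed
#'   (the genome is drawn last).
#' @return List of class `regulome_sim` with elements `params`, `genes`,
#'   `k27_peaks`, `k27_track`, `tf_peaks` (named list: `stimA`, `stimB`,
#'   `dmso`), `motifs`, `expression`, `genome` (or `NULL`), `truth`.
#' @export
simulate_regulome <- function(params = sim_params(), include_genome = TRUE) {
  p <- params
  set.seed(p$seed)
  chrom <- "chr1"
  n_cond <- p$n_peaks_per_condition
  n_shared <- round(p$shared_frac * n_cond)
  n_unique <- n_cond - n_shared
  if (p$n_cobound > n_unique)
    stopf("n_cobound exceeds the number of condition-unique summits")
  n_plant <- round(p$plant_rate * n_cond)
  if (n_plant > n_unique - p$n_cobound)
    stopf("plant_rate %.2f infeasible: needs %d plantable flanks but only %d condition-unique non-cobound summits exist",
          p$plant_rate, n_plant, n_unique - p$n_cobound)

  ## ---- layout ----------------------------------------------------------
  gene0 <- 5000
  gene_region_end <- gene0 + p$n_genes * p$gene_spacing
  enh0 <- gene_region_end + 20000
  pitch <- 30000
  n_enh <- p$n_typical_enhancers + p$n_super_enhancers
  if (enh0 + n_enh * pitch + 1000 > p$chrom_length)
    stopf("infeasible placement: %d enhancers need %g bp but chrom_length is %g",
          n_enh, enh0 + n_enh * pitch + 1000, p$chrom_length)

  ## ---- draw 1: genes ---------------------------------------------------
  tss <- gene0 + (seq_len(p$n_genes) - 1) * p$gene_spacing +
    sample(0:1500, p$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), p$n_genes, replace = TRUE)
  genes <- gene_set(sprintf("gene_%04d", seq_len(p$n_genes)), chrom, tss, strand)

  ## ---- draw 2: enhancer landscape -------------------------------------
  super_slot <- logical(n_enh)
  super_slot[sample.int(n_enh, p$n_super_enhancers)] <- TRUE
  const <- vector("list", n_enh)
  enh_meta <- data.frame(enh_id = sprintf("enh_%04d", seq_len(n_enh)),
                         start = numeric(n_enh), end = numeric(n_enh),
                         total_signal = numeric(n_enh),
                         is_super = super_slot, stringsAsFactors = FALSE)
  for (k in seq_len(n_enh)) {
    slot0 <- enh0 + (k - 1) * pitch
    if (super_slot[k]) {
      nc <- sample(5:7, 1L)
      widths <- sample(800:1200, nc, replace = TRUE)
      gaps <- sample(300:700, max(nc - 1L, 0L), replace = TRUE)
      total <- p$super_signal_multiplier * p$typical_signal_mean *
        stats::runif(1, 0.8, 1.2)
    } else {
      nc <- sample(1:2, 1L)
      widths <- sample(600:1400, nc, replace = TRUE)
      gaps <- sample(200:2000, max(nc - 1L, 0L), replace = TRUE)
      total <- stats::rexp(1, 1 / p$typical_signal_mean)
    }
    starts <- slot0 + cumsum(c(0, widths[-nc] + gaps))
    ends <- starts + widths
    sig <- total * widths / sum(widths)
    const[[k]] <- data.frame(start = starts, end = ends, signal = sig,
                             enh = k, stringsAsFactors = FALSE)
    enh_meta$start[k] <- starts[1]
    enh_meta$end[k] <- ends[nc]
    enh_meta$total_signal[k] <- total
  }
  cdf <- do.call(rbind, const)
  k27_peaks <- peak_set(chrom, cdf$start, cdf$end,
                        name = sprintf("%s_c%d", enh_meta$enh_id[cdf$enh],
                                       stats::ave(cdf$enh, cdf$enh, FUN = seq_along)),
                        signal = cdf$signal)

  ## ---- draw 3: promoter decoy peaks -----------------------------------
  prom_genes <- sample.int(p$n_genes, min(p$n_promoter_peaks, p$n_genes))
  prom <- peak_set(chrom, tss[prom_genes] - 500, tss[prom_genes] + 500,
                   name = sprintf("prom_%04d", seq_along(prom_genes)),
                   summit = tss[prom_genes],
                   signal = stats::rexp(length(prom_genes),
                                        1 / p$typical_signal_mean))
  k27_peaks <- rbind(k27_peaks, prom)
  track_rows <- rbind(
    data.frame(start = cdf$start, end = cdf$end,
               value = cdf$signal / (cdf$end - cdf$start)),
    data.frame(start = prom$start, end = prom$end,
               value = prom$signal / (prom$end - prom$start)))
  k27_track <- signal_track(chrom, track_rows$start, track_rows$end,
                            track_rows$value)

  ## ---- draw 4: TF summit roles ----------------------------------------
  need <- 2L * n_shared + 2L * n_unique - p$n_cobound
  if (need > p$n_genes)
    stopf("infeasible placement: TF roles need %d genes but only %d exist",
          need, p$n_genes)
  perm <- sample.int(p$n_genes)
  take <- function(n) { out <- perm[seq_len(n)]; perm <<- perm[-seq_len(n)]; out }
  g_sharedA <- take(n_shared)
  g_sharedB <- take(n_shared)
  g_uniqueA <- take(n_unique)            # first n_cobound also get a stimB summit
  g_cobound <- g_uniqueA[seq_len(p$n_cobound)]
  g_uniqueB <- take(n_unique - p$n_cobound)
  jitter <- function(n) sample(-100:100, n, replace = TRUE)
  pos_sharedA <- tss[g_sharedA] + 900 + jitter(n_shared)
  pos_sharedB <- tss[g_sharedB] + 900 + jitter(n_shared)
  pos_uniqueA <- tss[g_uniqueA] - 900 + jitter(n_unique)
  cobound_d <- sample(50:199, p$n_cobound, replace = TRUE)
  pos_coboundB <- pos_uniqueA[seq_len(p$n_cobound)] + cobound_d
  pos_uniqueB <- tss[g_uniqueB] - 900 + jitter(length(g_uniqueB))

  tf_peak_df <- function(cond, pos, bound_gene) {
    ord <- order(pos)
    peak_set(chrom, pos[ord] - 250, pos[ord] + 250,
             name = sprintf("%s_pk%04d", cond, seq_along(pos)),
             summit = pos[ord],
             signal = stats::rexp(length(pos), 1 / 5) + 1) ->
      pk
    attr(pk, "bound_gene") <- bound_gene[ord]
    pk
  }
  stimA <- tf_peak_df("stimA", c(pos_sharedA, pos_uniqueA),
                      genes$gene_id[c(g_sharedA, g_uniqueA)])
  stimB <- tf_peak_df("stimB", c(pos_sharedB, pos_coboundB, pos_uniqueB),
                      genes$gene_id[c(g_sharedB, g_cobound, g_uniqueB)])
  dmso <- tf_peak_df("dmso", c(pos_sharedA, pos_sharedB),
                     genes$gene_id[c(g_sharedA, g_sharedB)])
  tf_peaks <- list(stimA = stimA, stimB = stimB, dmso = dmso)

  cobound_pairs <- data.frame(
    peak_id_a = stimA$name[match(pos_uniqueA[seq_len(p$n_cobound)], stimA$summit)],
    peak_id_b = stimB$name[match(pos_coboundB, stimB$summit)],
    distance = cobound_d, stringsAsFactors = FALSE)

  ## ---- draw 5: motif library and plants -------------------------------
  motifs <- synthetic_motif_library(p$n_decoy_motifs)
  target <- motifs[[1]]
  cons <- pwm_consensus(target)
  L <- nchar(cons)
  half <- p$flank_width %/% 2L
  plan_plants <- function(pool_pos) {
    if (n_plant == 0L)
      return(data.frame(pos = numeric(), start = numeric(),
                        strand = character(), stringsAsFactors = FALSE))
    at <- sample(seq_along(pool_pos), n_plant)
    off <- sample(0:(p$flank_width - L), n_plant, replace = TRUE)
    std <- sample(c("+", "-"), n_plant, replace = TRUE)
    data.frame(pos = pool_pos[at], start = pool_pos[at] - half + off,
               strand = std, stringsAsFactors = FALSE)
  }
  plantable_A <- pos_uniqueA[-seq_len(p$n_cobound)]
  plantable_B <- pos_uniqueB
  if (p$n_cobound == 0L) plantable_A <- pos_uniqueA
  plantsA <- plan_plants(plantable_A)
  plantsB <- plan_plants(plantable_B)

  ## ---- draw 6: expression / DEGs --------------------------------------
  bound_ids <- unique(c(attr(stimA, "bound_gene"), attr(stimB, "bound_gene")))
  pick_deg <- function(n, taken) {
    from_bound <- round(0.8 * n)
    pool_b <- setdiff(bound_ids, taken)
    pool_u <- setdiff(genes$gene_id, c(bound_ids, taken))
    from_bound <- min(from_bound, length(pool_b))
    c(sample(pool_b, from_bound),
      sample(pool_u, min(n - from_bound, length(pool_u))))
  }
  deg_up <- pick_deg(p$n_deg_up, character())
  deg_down <- pick_deg(p$n_deg_down, deg_up)
  direction <- rep("none", p$n_genes)
  direction[match(deg_up, genes$gene_id)] <- "up"
  direction[match(deg_down, genes$gene_id)] <- "down"
  log2fc <- stats::rnorm(p$n_genes, 0, 0.2)
  log2fc[direction == "up"] <- stats::runif(sum(direction == "up"), 1, 3)
  log2fc[direction == "down"] <- -stats::runif(sum(direction == "down"), 1, 3)
  expression <- data.frame(gene_id = genes$gene_id,
                           log2fc = round(log2fc, 4),
                           direction = direction, stringsAsFactors = FALSE)

  ## ---- draw 7 (last): genome + plants ---------------------------------
  genome <- NULL
  if (include_genome) {
    g <- intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, p$chrom_length,
                                                    replace = TRUE)])
    plant <- function(g, plants) {
      for (r in seq_len(nrow(plants))) {
        ins <- if (plants$strand[r] == "+") cons else revcomp(cons)
        substr(g, plants$start[r] + 1L, plants$start[r] + L) <- ins
      }
      g
    }
    g <- plant(g, plantsA)
    g <- plant(g, plantsB)
    genome <- stats::setNames(g, chrom)
  }

  truth <- structure(list(
    super_enhancer_ids = enh_meta$enh_id[enh_meta$is_super],
    enhancers = enh_meta,
    motif_planted = list(
      stimA = list(motif_id = target$motif_id, plant_rate = p$plant_rate,
                   plants = plantsA),
      stimB = list(motif_id = target$motif_id, plant_rate = p$plant_rate,
                   plants = plantsB)),
    deg_truth = stats::setNames(expression$direction[direction != "none"],
                                expression$gene_id[direction != "none"]),
    cobound_pairs = cobound_pairs,
    bound_genes = list(stimA = attr(stimA, "bound_gene"),
                       stimB = attr(stimB, "bound_gene"),
                       dmso = attr(dmso, "bound_gene"))),
    class = "synthetic_truth")

  structure(list(params = p, genes = genes, k27_peaks = k27_peaks,
                 k27_track = k27_track, tf_peaks = tf_peaks, motifs = motifs,
                 expression = expression, genome = genome, truth = truth),
            class = "regulome_sim")
}

#' @export
print.regulome_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic regulome (seed %d): %d genes, %d+%d enhancers, %d TF summits x %d sets\n",
    x$params$seed, nrow(x$genes), x$params$n_typical_enhancers,
    x$params$n_super_enhancers, x$params$n_peaks_per_condition,
    length(x$tf_peaks)))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits genome FASTA (when present), TSS BED, H3K27ac peak BED + bedGraph,
#' per-condition TF summit BEDs, expression TSV, MEME motif file and a JSON
#' truth sidecar. All files are plain text and parse back through the
#' package readers.
#'
#' @param sim A [simulate_regulome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tss = file.path(dir, "tss.bed"),
             k27_peaks = file.path(dir, "h3k27ac_peaks.bed"),
             k27_track = file.path(dir, "h3k27ac.bedGraph"),
             motifs = file.path(dir, "motifs.meme"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.json"))
  write_tss_bed(sim$genes, paths[["tss"]])
  write_bed(sim$k27_peaks, paths[["k27_peaks"]])
  write_bedgraph(sim$k27_track, paths[["k27_track"]])
  write_meme_motifs(sim$motifs, paths[["motifs"]])
  write_deg_table(sim$expression, paths[["expression"]])
  for (cond in names(sim$tf_peaks)) {
    pth <- file.path(dir, sprintf("tf_%s_summits.bed", cond))
    write_bed(sim$tf_peaks[[cond]], pth)
    paths[[paste0("tf_", cond)]] <- pth
  }
  if (!is.null(sim$genome)) {
    paths[["genome"]] <- file.path(dir, "genome.fa")
    write_genome_fasta(sim$genome, paths[["genome"]])
  }
  truth <- sim$truth
  truth_json <- list(
    super_enhancer_ids = truth$super_enhancer_ids,
    enhancers = truth$enhancers,
    motif_planted = lapply(truth$motif_planted, function(mp)
      list(motif_id = mp$motif_id, plant_rate = mp$plant_rate,
           plants = mp$plants)),
    deg_truth = as.list(truth$deg_truth),
    cobound_pairs = truth$cobound_pairs,
    bound_genes = truth$bound_genes)
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' Score pipeline recovery against the planted truth
#'
#' @param truth The `synthetic_truth` from [simulate_regulome()].
#' @param enhancer_calls Optional [call_enhancers()] result; scored by
#'   matching called regions to planted regions by genomic overlap.
#' @param enrichment Optional [enrich_motifs()] result for a condition whose
#'   truth records a planted motif (`condition` selects which).
#' @param targets Optional [call_targets()] result for that condition.
#' @param condition Which planted condition to score (default `"stimA"`).
#' @return List of class `truth_metrics` with (when scorable)
#'   `se_sensitivity`, `se_specificity`, `n_super_recovered`,
#'   `motif_rank`, `motif_p`, `target_precision`, `target_recall`.
#' @export
truth_metrics <- function(truth, enhancer_calls = NULL, enrichment = NULL,
                          targets = NULL, condition = "stimA") {
  out <- list()
  if (!is.null(enhancer_calls)) {
    enh <- enhancer_calls$enhancers
    tr <- truth$enhancers
    ov <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))
    called_super <- logical(nrow(tr))
    for (k in seq_len(nrow(tr))) {
      hit <- which(ov(enh$start, enh$end, tr$start[k], tr$end[k]) > 0)
      if (!length(hit))
        stopf("truth_metrics: planted region %s matches no called enhancer",
              tr$enh_id[k])
      called_super[k] <- any(enh$is_super[hit])
    }
    tp <- sum(called_super & tr$is_super)
    out$n_super_planted <- sum(tr$is_super)
    out$n_super_recovered <- tp
    out$se_sensitivity <- tp / sum(tr$is_super)
    out$se_specificity <- sum(!called_super & !tr$is_super) / sum(!tr$is_super)
  }
  if (!is.null(enrichment)) {
    mid <- truth$motif_planted[[condition]]$motif_id
    r <- match(mid, enrichment$motif_id)
    if (is.na(r)) stopf("truth_metrics: planted motif '%s' was not tested", mid)
    out$motif_rank <- r
    out$motif_p <- enrichment$p_value[r]
  }
  if (!is.null(targets)) {
    truth_targets <- intersect(truth$bound_genes[[condition]],
                               names(truth$deg_truth))
    called <- targets$gene_id[targets$is_target]
    out$target_precision <- if (length(called))
      length(intersect(called, truth_targets)) / length(called) else NA_real_
    out$target_recall <- if (length(truth_targets))
      length(intersect(called, truth_targets)) / length(truth_targets) else NA_real_
  }
  structure(out, class = "truth_metrics")
}

#' @export
print.truth_metrics <- function(x, ...) {
  cat("Recovery against planted truth:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %.4g\n", nm, x[[nm]]))
  invisible(x)
}
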