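## End-to-end orchestration: simulate (or ingest) -> call enhancers ->
## predict co-regulators -> call targets -> co-binding and profile reports,
## with a machine-readable manifest of parameters, input digests and
## per-stage row counts.

#' Pipeline run configuration
#'
#' Either `sim` (a [sim_params()]) for a self-contained synthetic run, or
#' `inputs`, a named list of file paths: `tss`, `k27_peaks` (BED),
#' `k27_track` (bedGraph), `genome` (FASTA), `motifs` (MEME), `expression`
#' (TSV), `tf_cond`, `tf_cond2`, `tf_control` (summit BEDs).
#'
#' @param outdir Output directory.
#' @param sim Optional [sim_params()].
#' @param inputs Optional named list of input paths.
#' @param params A [pipeline_params()].
#' @param quiet Suppress stage messages.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, sim = NULL, inputs = NULL,
                       params = pipeline_params(), quiet = FALSE) {
  if (is.null(sim) && is.null(inputs))
    stopf("run_config needs either sim parameters or input paths")
  structure(list(outdir = outdir, sim = sim, inputs = inputs,
                 params = params, quiet = quiet),
            class = "run_config")
}

.stage <- function(name, quiet, outputs_so_far, expr) {
  if (!quiet) message(sprintf("[stage] %s", name))
  tryCatch(expr, error = function(e) {
    for (f in outputs_so_far) if (file.exists(f)) unlink(f)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: ingest (or simulate + write bundle), enhancer
#' calling, flank extraction + co-regulator prediction for each stimulation
#' condition versus control, peak annotation + target calling, co-binding
#' between the two stimulation sets, and an average-signal profile around
#' TF summits. Any stage failure aborts with a stage-named error and removes
#' partial outputs. Reruns on identical inputs produce identical manifests.
#'
#' @param config A [run_config()].
#' @return The run manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  counts <- list()

  inputs <- config$inputs
  if (!is.null(config$sim)) {
    sim <- .stage("simulate", config$quiet, written,
                  simulate_regulome(config$sim))
    paths <- .stage("write-bundle", config$quiet, written,
                    write_sim_bundle(sim, file.path(outdir, "inputs")))
    written <- c(written, unname(paths))
    inputs <- list(tss = paths[["tss"]], k27_peaks = paths[["k27_peaks"]],
                   k27_track = paths[["k27_track"]], genome = paths[["genome"]],
                   motifs = paths[["motifs"]], expression = paths[["expression"]],
                   tf_cond = paths[["tf_stimA"]], tf_cond2 = paths[["tf_stimB"]],
                   tf_control = paths[["tf_dmso"]])
  }
  need <- c("tss", "k27_peaks", "k27_track", "genome", "motifs",
            "expression", "tf_cond", "tf_control")
  for (nm in need) {
    if (is.null(inputs[[nm]]))
      stopf("pipeline stage 'ingest' failed: input '%s' not configured", nm)
    if (!file.exists(inputs[[nm]]))
      stopf("pipeline stage 'ingest' failed: input '%s' missing at %s",
            nm, inputs[[nm]])
  }

  dat <- .stage("ingest", config$quiet, written, {
    list(genes = read_tss_bed(inputs$tss),
         k27_peaks = read_bed(inputs$k27_peaks, has_summit = TRUE,
                              summit_col = 6L),
         k27_track = read_bedgraph(inputs$k27_track),
         genome = read_genome_fasta(inputs$genome),
         motifs = read_meme_motifs(inputs$motifs),
         expression = read_deg_table(inputs$expression),
         tf_cond = read_bed(inputs$tf_cond, has_summit = TRUE, summit_col = 6L),
         tf_cond2 = if (!is.null(inputs$tf_cond2))
           read_bed(inputs$tf_cond2, has_summit = TRUE, summit_col = 6L),
         tf_control = read_bed(inputs$tf_control, has_summit = TRUE,
                               summit_col = 6L))
  })
  counts$genes <- nrow(dat$genes)
  counts$k27_peaks <- nrow(dat$k27_peaks)

  calls <- .stage("call-enhancers", config$quiet, written, {
    ec <- call_enhancers(dat$k27_peaks, dat$genes, dat$k27_track,
                         config$params)
    enh <- ec$enhancers
    out <- data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                      name = enh$name, total_signal = enh$total_signal,
                      rank = enh$rank, n_constituents = enh$n_constituents,
                      is_super = enh$is_super)
    utils::write.table(out, note(file.path(outdir, "enhancers.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ec$cutoff))
      utils::write.table(as.data.frame(unclass(ec$cutoff)),
                         note(file.path(outdir, "se_cutoff.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    ec
  })
  counts$enhancers <- nrow(calls$enhancers)
  counts$super_enhancers <- sum(calls$enhancers$is_super)

  coreg <- .stage("predict-coregulators", config$quiet, written, {
    fl_cond <- extract_flanks(dat$tf_cond, dat$genome,
                              config$params$flank_width, "cond")
    fl_ctrl <- extract_flanks(dat$tf_control, dat$genome,
                              config$params$flank_width, "control")
    pc <- predict_coregulators(fl_cond, fl_ctrl, dat$motifs,
                               alpha = config$params$enrich_alpha)
    utils::write.table(pc, note(file.path(outdir, "coregulators.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pc
  })
  counts$coregulators_retained <- sum(coreg$retained)

  targets <- .stage("call-targets", config$quiet, written, {
    ann <- annotate_peaks(dat$tf_cond, dat$genes)
    tg <- call_targets(unique(ann$gene_id), dat$expression,
                       annotation = dat$genes)
    utils::write.table(tg, note(file.path(outdir, "targets.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tg
  })
  counts$bound_genes <- sum(targets$bound)
  counts$target_genes <- sum(targets$is_target)

  if (!is.null(dat$tf_cond2)) {
    cb <- .stage("cobind", config$quiet, written, {
      cb <- cobinding(dat$tf_cond, dat$tf_cond2,
                      config$params$cobind_max_dist,
                      mode = config$params$cobind_mode)
      utils::write.table(cb$pairs, note(file.path(outdir, "cobinding_pairs.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cb
    })
    counts$cobound_pairs <- nrow(cb$pairs)
  }

  .stage("profile", config$quiet, written, {
    pm <- profile_matrix(dat$tf_cond, dat$k27_track, flank = 2000L,
                         nbins = 50L)
    utils::write.table(
      data.frame(bin_center = pm$bin_centers, mean_signal = pm$mean_profile),
      note(file.path(outdir, "tf_summit_profile.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    NULL
  })

  manifest <- list(
    package = "enhancerkit",
    version = as.character(utils::packageVersion("enhancerkit")),
    params = unclass(config$params),
    sim_params = if (!is.null(config$sim)) unclass(config$sim),
    input_digests = {
      digs <- tools::md5sum(unlist(inputs[!vapply(inputs, is.null, TRUE)]))
      names(digs) <- basename(names(digs))
      as.list(digs)
    },
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
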