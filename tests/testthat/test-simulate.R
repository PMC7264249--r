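test_that("identical seeds give byte-identical bundles", {
  p <- small_sim_params(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_sim_bundle(simulate_regulome(p), d1)
  f2 <- write_sim_bundle(simulate_regulome(p), d2)
  expect_identical(names(f1), names(f2))
  for (nm in names(f1))
    expect_identical(unname(tools::md5sum(f1[[nm]])),
                     unname(tools::md5sum(f2[[nm]])), label = nm)
  ## a different seed changes the bundle
  f3 <- write_sim_bundle(simulate_regulome(small_sim_params(seed = 6)),
                         withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(f1[["tss"]])),
                         unname(tools::md5sum(f3[["tss"]]))))
})

test_that("emitted files parse back through the package readers", {
  sim <- simulate_regulome(small_sim_params())
  d <- withr::local_tempdir()
  paths <- write_sim_bundle(sim, d)
  genes <- read_tss_bed(paths[["tss"]])
  expect_equal(nrow(genes), nrow(sim$genes))
  pk <- read_bed(paths[["k27_peaks"]], has_summit = TRUE, summit_col = 6L)
  expect_equal(pk$start, sim$k27_peaks$start)
  tr <- read_bedgraph(paths[["k27_track"]])
  expect_equal(track_total_area(tr), track_total_area(sim$k27_track),
               tolerance = 1e-9)
  ms <- read_meme_motifs(paths[["motifs"]], pseudocount = 0)
  expect_equal(vapply(ms, `[[`, "", "motif_id"),
               vapply(sim$motifs, `[[`, "", "motif_id"))
  g <- read_genome_fasta(paths[["genome"]])
  expect_identical(nchar(g[["chr1"]]), as.integer(sim$params$chrom_length))
  ## coordinates respect chromosome bounds
  expect_true(all(sim$k27_peaks$end <= sim$params$chrom_length))
  expect_true(all(vapply(sim$tf_peaks, function(p) all(p$end <= sim$params$chrom_length), TRUE)))
})

test_that("plant_rate 0 leaves flanks consensus-free; plants hit only condition flanks", {
  p0 <- small_sim_params(seed = 2)
  p0$plant_rate <- 0
  sim0 <- simulate_regulome(p0)
  cons <- pwm_consensus(sim0$motifs[[1]])
  hits <- function(fs) sum(grepl(cons, fs$sequences) |
                             grepl(revcomp(cons), fs$sequences))
  fl0 <- extract_flanks(sim0$tf_peaks$stimA, sim0$genome, 200, "stimA")
  expect_equal(hits(fl0), 0L)

  sim <- simulate_regulome(small_sim_params(seed = 2))
  cons <- pwm_consensus(sim$motifs[[1]])
  n_plant <- round(sim$params$plant_rate * sim$params$n_peaks_per_condition)
  flA <- extract_flanks(sim$tf_peaks$stimA, sim$genome, 200, "stimA")
  flC <- extract_flanks(sim$tf_peaks$dmso, sim$genome, 200, "dmso")
  expect_gte(hits(flA), n_plant)   # >= allows chance matches elsewhere
  ## control flanks never receive plants; chance hits are ~0 for a 10-mer
  expect_equal(hits(flC), 0L)
})

test_that("planted super enhancers occupy the top signal ranks", {
  sim <- simulate_regulome(small_sim_params(seed = 3), include_genome = FALSE)
  calls <- call_enhancers(sim$k27_peaks, sim$genes, sim$k27_track)
  enh <- calls$enhancers
  n_super <- sim$params$n_super_enhancers
  truth_super <- sim$truth$enhancers[sim$truth$enhancers$is_super, ]
  ## planted regions equal stitched regions, so match by start coordinate
  m <- match(truth_super$start, enh$start)
  expect_false(anyNA(m))
  expect_true(all(rank(-enh$total_signal)[m] <= n_super))
  ## planted totals stochastically dominate typical totals
  w <- stats::wilcox.test(enh$total_signal[m], enh$total_signal[-m],
                          alternative = "greater")
  expect_lt(w$p.value, 1e-3)   # only 5 planted supers at this scale
})

test_that("cobound pairs planted in the truth are recovered exactly", {
  sim <- simulate_regulome(small_sim_params(seed = 4), include_genome = FALSE)
  cb <- cobinding(sim$tf_peaks$stimA, sim$tf_peaks$stimB, 200)
  expect_equal(nrow(cb$pairs), nrow(sim$truth$cobound_pairs))
  key <- function(a, b) paste(sort(paste(a, b)), collapse = ";")
  expect_identical(key(cb$pairs$name_a, cb$pairs$name_b),
                   key(sim$truth$cobound_pairs$peak_id_a,
                       sim$truth$cobound_pairs$peak_id_b))
})

test_that("truth metrics score perfect and shuffled results as expected", {
  sim <- simulate_regulome(small_sim_params(seed = 8), include_genome = FALSE)
  calls <- call_enhancers(sim$k27_peaks, sim$genes, sim$k27_track)
  ann <- annotate_peaks(sim$tf_peaks$stimA, sim$genes)
  tg <- call_targets(unique(ann$gene_id), sim$expression)
  tm <- truth_metrics(sim$truth, enhancer_calls = calls, targets = tg,
                      condition = "stimA")
  expect_gte(tm$se_sensitivity, 0.8)
  expect_gte(tm$target_recall, 0.8)
  expect_gte(tm$target_precision, 0.8)

  ## shuffled super labels drop sensitivity to near chance
  shuffled <- calls
  set.seed(1)
  shuffled$enhancers$is_super <- sample(shuffled$enhancers$is_super)
  tm_s <- truth_metrics(sim$truth, enhancer_calls = shuffled)
  expect_lt(tm_s$se_sensitivity, 0.6)
})

test_that("infeasible placements are rejected before anything is written", {
  p <- small_sim_params()
  p$chrom_length <- 1e5
  expect_error(simulate_regulome(p), "infeasible placement")
  p2 <- small_sim_params()
  p2$plant_rate <- 0.95
  expect_error(simulate_regulome(p2), "plant_rate")
  expect_error(sim_params(super_signal_multiplier = 0.5), "multiplier")
  expect_error(sim_params(plant_rate = 1.2), "plant_rate")
})
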