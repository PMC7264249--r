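test_that("distal filter applies the boundary-or-center disjunction", {
  genes <- gene_set("g1", "chr1", 5000)
  pk <- peak_set("chr1",
                 start = c(0, 4000, 3600),
                 end = c(1000, 6000, 3800),
                 name = c("far", "contains_tss", "near"))
  kept <- filter_distal(pk, genes)
  expect_identical(kept$name, "far")          # edge 4000 >= 1500
  ## same near peak clears via the center clause once the TSS moves
  kept2 <- filter_distal(peak_set("chr1", 3600, 3800, name = "near"),
                         gene_set("g1", "chr1", 6900))
  expect_identical(kept2$name, "near")        # center 3700 is 3200 >= 3000
  expect_error(filter_distal(pk, gene_set(character(), character(), numeric())),
               "empty")
})

test_that("conjunction mode requires both distal clauses", {
  genes <- gene_set("g1", "chr1", 5000)
  pk <- peak_set("chr1", 6600, 6700, name = "p")  # edge 1600, center 1650
  expect_equal(nrow(filter_distal(pk, genes)), 1L)
  p_and <- pipeline_params(distal_rule = "and")
  expect_equal(nrow(filter_distal(pk, genes, p_and)), 0L)
})

test_that("stitching merges below 12.5 kb with strict inequality", {
  one <- stitch_peaks(peak_set("chr1", c(0, 12599), c(100, 12700)))
  expect_equal(nrow(one), 1L)                 # gap 12499 < 12500
  expect_equal(c(one$start, one$end), c(0, 12700))
  two <- stitch_peaks(peak_set("chr1", c(0, 12600), c(100, 12700)))
  expect_equal(nrow(two), 2L)                 # gap 12500, not merged
  single <- stitch_peaks(peak_set("chr1", 50, 150))
  expect_equal(c(single$start, single$end, single$n_constituents),
               c(50, 150, 1))
})

test_that("stitching is idempotent, exhaustive and respects the gap invariant", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    start <- sort(sample(0:5e5, n))
    pk <- peak_set(sample(c("chr1", "chr2"), n, replace = TRUE),
                   start, start + sample(100:3000, n, replace = TRUE))
    st <- stitch_peaks(pk)
    expect_equal(sum(st$n_constituents), n)
    ## re-stitching the stitched regions changes nothing
    st2 <- stitch_peaks(peak_set(st$chrom, st$start, st$end))
    expect_equal(st2[c("chrom", "start", "end")], st[c("chrom", "start", "end")])
    ## pairwise gaps between neighbouring regions >= stitch gap
    for (ch in unique(st$chrom)) {
      r <- st[st$chrom == ch, ]
      if (nrow(r) > 1)
        expect_true(all(r$start[-1] - r$end[-nrow(r)] >= 12500))
    }
  }
})

test_that("quantification equals areas and the per-base oracle", {
  tr <- signal_track(c("chr1", "chr1"), c(0, 100), c(100, 200), c(1, 3))
  enh <- stitch_peaks(peak_set("chr1", 50, 150))
  q <- quantify_enhancers(enh, tr)
  expect_equal(q$total_signal, 50 * 1 + 50 * 3)  # [50,150) piecewise
  expect_equal(q$total_signal,
               oracle_track_area(tr, "chr1", 50, 150))

  uniform <- signal_track("chr1", 0, 1000, 2)
  q2 <- quantify_enhancers(stitch_peaks(peak_set("chr1", 0, 100)), uniform)
  expect_equal(q2$total_signal, 200)

  q3 <- quantify_enhancers(stitch_peaks(peak_set("chr2", 0, 100)), uniform)
  expect_equal(q3$total_signal, 0)             # no coverage
  expect_equal(q3$rank, 1L)
})

test_that("quantification matches the per-base oracle on random tracks", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    bounds <- sort(sample(0:400, 2 * n))
    tr <- signal_track("chr1", bounds[seq(1, 2 * n, 2)],
                       bounds[seq(2, 2 * n, 2)], runif(n, 0, 5))
    a <- sort(sample(0:380, 2))
    got <- track_area(tr, "chr1", a[1], a[2] + 1)
    want <- oracle_track_area(tr, "chr1", a[1], a[2] + 1)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("tangency cutoff: quadratic curve, flat curve, lone outlier", {
  n <- 1001
  co <- find_se_cutoff(((seq_len(n) - 1) / (n - 1))^2)
  expect_lte(abs(co$tangency_rank - 501L), 1L)
  expect_lte(abs(co$n_super - 500L), 1L)

  flat <- find_se_cutoff(rep(1, 100))
  expect_equal(flat$n_super, 0L)               # no elbow on a flat curve

  out <- find_se_cutoff(c(rep(1, 999), 1000))
  expect_equal(out$n_super, 1L)                # single outlier is super

  expect_error(find_se_cutoff(c(0, 0, 0)), "maximum signal is 0")
  expect_error(find_se_cutoff(c(1, 2)), "at least 3")
})

test_that("tangency cutoff agrees with the brute-force tangent-line oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(20:300, 1)
    s <- sort(switch(1 + rep %% 3,
                     rexp(n, 1 / 10),
                     runif(n, 0, 100)^2,
                     cumsum(rexp(n, 1))))
    co <- find_se_cutoff(s)
    expect_equal(co$tangency_rank, oracle_tangency_rank(s))
  }
})

test_that("cutoff labels are scale invariant and the super set is a top-k set", {
  set.seed(5)
  s <- c(rexp(200, 1 / 10), 400 + runif(10, 0, 100))
  co1 <- find_se_cutoff(s)
  co2 <- find_se_cutoff(s * 10)
  expect_equal(co1$n_super, co2$n_super)
  expect_equal(co1$tangency_rank, co2$tangency_rank)
  super <- s > co1$tangency_signal
  expect_true(min(s[super]) > max(s[!super]))  # no typical out-signals a super
})

test_that("call_enhancers composes the stages and handles empty distal sets", {
  genes <- gene_set(c("g1", "g2"), "chr1", c(5000, 9000))
  ## all peaks promoter-proximal -> nothing distal
  pk <- peak_set("chr1", c(4500, 8600), c(5500, 9300))
  tr <- signal_track("chr1", 0, 10000, 1)
  res <- call_enhancers(pk, genes, tr)
  expect_identical(res$status, "no_enhancers")
  expect_equal(nrow(res$enhancers), 0L)

  sim <- simulate_regulome(small_sim_params(), include_genome = FALSE)
  calls <- call_enhancers(sim$k27_peaks, sim$genes, sim$k27_track)
  expect_identical(calls$status, "ok")
  ## planted super regions occupy the top ranks and get labelled
  tm <- truth_metrics(sim$truth, enhancer_calls = calls)
  expect_gte(tm$se_sensitivity, 0.8)
  expect_gte(tm$se_specificity, 0.9)
  ## scaling every signal by 10 leaves labels unchanged
  tr10 <- sim$k27_track
  tr10$value <- tr10$value * 10
  calls10 <- call_enhancers(sim$k27_peaks, sim$genes, tr10)
  expect_identical(calls10$enhancers$is_super, calls$enhancers$is_super)
})

test_that("profile matrix: uniform track, locality, hand-computed means", {
  uniform <- signal_track("chr1", 0, 100000, 2.5)
  anchors <- peak_set("chr1", c(10000, 50000), c(11000, 51000))
  pm <- profile_matrix(anchors, uniform, flank = 1000, nbins = 20)
  expect_true(all(abs(pm$matrix - 2.5) < 1e-12))

  spike <- signal_track("chr1", 49990, 50010, 4)   # anchor +/- 10 bp only
  pm2 <- profile_matrix(peak_set("chr1", 49500, 50500, summit = 50000),
                        spike, flank = 1000, nbins = 100)
  nz <- which(pm2$matrix[1, ] != 0)
  expect_identical(nz, c(50L, 51L))                # the two central bins

  ## two anchors over known runs; expected column means by piecewise arithmetic
  tr <- signal_track(c("chr1", "chr1"), c(100, 140), c(120, 160), c(1, 3))
  pm3 <- profile_matrix(peak_set("chr1", c(60, 100), c(140, 180),
                                 summit = c(100, 140)),
                        tr, flank = 40, nbins = 4)
  ## bins for anchor 100: [60,80)=0, [80,100)=0, [100,120)=1, [120,140)=0
  want1 <- c(0, 0, 1, 0)
  ## bins for anchor 140: [100,120)=1, [120,140)=0, [140,160)=3, [160,180)=0
  want2 <- c(1, 0, 3, 0)
  expect_equal(unname(pm3$matrix[1, ]), want1)
  expect_equal(unname(pm3$matrix[2, ]), want2)
  expect_equal(pm3$mean_profile, (want1 + want2) / 2)

  ## window clipped at chromosome start counts missing bases as 0
  pm4 <- profile_matrix(peak_set("chr1", 0, 100, summit = 50),
                        signal_track("chr1", 0, 1000, 1),
                        flank = 100, nbins = 2)
  expect_equal(unname(pm4$matrix[1, ]), c(0.5, 1))  # [-50,50) half-covered
})
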