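test_that("nearest-TSS annotation signs distances by gene strand and breaks ties", {
  genes <- gene_set(c("gA", "gB"), "chr1", c(1500, 900), c("+", "-"))
  ann <- annotate_peaks(peak_set("chr1", 900, 1100, summit = 1000), genes)
  expect_identical(ann$gene_id, "gB")          # 100 bp beats 500 bp
  expect_equal(ann$distance, -100)             # upstream of a minus-strand gene

  ann2 <- annotate_peaks(peak_set("chr1", 500, 1500, summit = 1000),
                         gene_set(c("gA", "gB"), "chr1", c(1500, 1500),
                                  c("+", "+")))
  expect_identical(ann2$gene_id, "gA")         # same TSS: lexicographic tie rule
  expect_equal(ann2$distance, -500)            # upstream of a plus-strand gene

  ann3 <- annotate_peaks(peak_set("chr1", 2000, 4000, summit = 3000),
                         gene_set(c("gZ", "gA"), "chr1", c(1000, 5000)))
  expect_identical(ann3$gene_id, "gA")         # equidistant +/-2000 -> smaller id
})

test_that("annotation is invariant under a constant coordinate shift", {
  set.seed(13)
  genes <- gene_set(sprintf("g%02d", 1:10), "chr1", sort(sample(0:1e5, 10)),
                    sample(c("+", "-"), 10, replace = TRUE))
  pk <- peak_set("chr1", seq(1000, 91000, 10000), seq(1000, 91000, 10000) + 500)
  a1 <- annotate_peaks(pk, genes)
  shift <- 12345
  genes2 <- genes; genes2$tss <- genes2$tss + shift
  pk2 <- pk; pk2$start <- pk2$start + shift
  pk2$end <- pk2$end + shift; pk2$summit <- pk2$summit + shift
  a2 <- annotate_peaks(pk2, genes2)
  expect_identical(a2$gene_id, a1$gene_id)
  expect_identical(a2$distance, a1$distance)
})

test_that("target calling intersects bound genes with DEGs and carries direction", {
  deg <- c(g2 = "up", g3 = "down")
  tg <- call_targets(c("g1", "g2"), deg)
  expect_identical(tg$gene_id[tg$is_target], "g2")
  expect_identical(tg$de_status[tg$gene_id == "g2"], "up")
  expect_identical(tg$de_status[tg$gene_id == "g1"], "none")

  expect_equal(sum(call_targets(c("a", "b"), c(c = "up"))$is_target), 0L)
  all_t <- call_targets(c("a", "b"), c(a = "up", b = "down"))
  expect_true(all(all_t$is_target))

  ann <- gene_set(c("g1", "g2"), "chr1", c(1, 2))
  expect_warning(tg2 <- call_targets("g1", c(gX = "up"), annotation = ann),
                 "absent from annotation")
  expect_true("gX" %in% tg2$gene_id)           # retained despite the warning

  ## monotone: enlarging the bound set never removes a target
  t1 <- call_targets("g2", deg)
  t2 <- call_targets(c("g2", "g3"), deg)
  expect_true(all(t1$gene_id[t1$is_target] %in% t2$gene_id[t2$is_target]))
})

test_that("set summaries obey inclusion-exclusion exactly", {
  su <- summarize_sets(paste0("g", 1:475), paste0("g", 406:523))
  expect_equal(su$n_intersection, 70)
  expect_equal(su$n_union, 523)

  same <- summarize_sets(letters, letters)
  expect_equal(same$n_union, same$n_a)
  expect_equal(same$n_a_only, 0L)

  set.seed(77)
  for (rep in 1:50) {
    a <- sample(1:60, sample(0:40, 1))
    b <- sample(1:60, sample(0:40, 1))
    su <- summarize_sets(a, b)
    expect_equal(su$n_union, length(unique(c(a, b))))       # brute force
    expect_equal(su$n_intersection, sum(unique(a) %in% b))
    expect_equal(su$n_union, su$n_a + su$n_b - su$n_intersection)
    expect_equal(su$n_a_only, su$n_a - su$n_intersection)
    expect_gte(min(unlist(unclass(su))), 0)
  }
})

test_that("novel/reported split counts are exact", {
  nv <- novel_vs_reported(paste0("g", 1:523), paste0("g", 1:237))
  expect_equal(nv$n_reported, 237)
  expect_equal(nv$n_novel, 286)
  expect_equal(novel_vs_reported(letters[1:5], letters)$n_novel, 0)
  expect_equal(novel_vs_reported(letters[1:5], LETTERS)$n_novel, 5)
})

test_that("co-binding uses a strict distance threshold at the 200 bp boundary", {
  a <- peak_set("chr1", 900, 1200, name = "a1", summit = 1000)
  b199 <- peak_set("chr1", 1100, 1400, name = "b1", summit = 1199)
  b200 <- peak_set("chr1", 1100, 1400, name = "b1", summit = 1200)
  expect_equal(nrow(cobinding(a, b199, 200)$pairs), 1L)   # 199 < 200
  expect_equal(nrow(cobinding(a, b200, 200)$pairs), 0L)   # 200 is not < 200
  empty <- cobinding(a, peak_set(character(), numeric(), numeric()), 200)
  expect_equal(nrow(empty$pairs), 0L)
  expect_equal(nrow(empty$a_only), 1L)
})

test_that("co-binding partition is exhaustive and disjoint", {
  set.seed(55)
  for (rep in 1:15) {
    na <- sample(5:30, 1); nb <- sample(5:30, 1)
    sa <- sample(0:20000, na); sb <- sample(0:20000, nb)
    a <- peak_set("chr1", sa, sa + 100, name = sprintf("a%02d", seq_len(na)),
                  summit = sa + 50)
    b <- peak_set("chr1", sb, sb + 100, name = sprintf("b%02d", seq_len(nb)),
                  summit = sb + 50)
    cb <- cobinding(a, b, 200)
    expect_equal(nrow(cb$a_only) + nrow(cb$pairs), na)
    expect_equal(nrow(cb$b_only) + nrow(cb$pairs), nb)
    expect_true(all(cb$pairs$distance < 200))
    expect_false(any(duplicated(cb$pairs$name_a)))
    expect_false(any(duplicated(cb$pairs$name_b)))
  }
})

test_that("edge mode measures interval gaps instead of summit distance", {
  a <- peak_set("chr1", 1000, 2000, name = "a1", summit = 1100)
  b <- peak_set("chr1", 2100, 3000, name = "b1", summit = 2900)
  expect_equal(nrow(cobinding(a, b, 200)$pairs), 0L)              # summits 1800
  expect_equal(nrow(cobinding(a, b, 200, mode = "edge")$pairs), 1L)  # gap 100
})
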