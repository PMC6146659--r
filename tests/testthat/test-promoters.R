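test_that("scanning windows enumerate step-offset windows with correct counts", {
  expect_equal(nrow(scan_windows(data.frame(chrom = character(0),
                                            position = integer(0),
                                            strand = character(0),
                                            count = integer(0)))), 0L)

  # 10 reads on one base of a 100-bp toy: checked against exhaustive window
  # enumeration
  reads <- data.frame(chrom = "c1", position = 50L, strand = "+", count = 10L)
  hits <- scan_windows(reads, sizes = c(1L, 10L), steps = c(1L, 1L))
  h1 <- hits[hits$window_size == 1, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$start, 50L)
  expect_equal(h1$read_count, 10L)
  h10 <- hits[hits$window_size == 10, ]
  # exhaustive: windows [k, k+10) containing base 50 are k in 41..50
  expect_equal(sort(h10$start), 41:50)
  expect_true(all(h10$read_count == 10L))

  # strand separation
  expect_equal(nrow(hits[hits$strand == "-", ]), 0L)

  # multi-read toy vs exhaustive enumeration at all default scales
  set.seed(3)
  toy <- data.frame(chrom = "c1", position = sample.int(100, 20) - 1L,
                    strand = sample(c("+", "-"), 20, replace = TRUE),
                    count = sample(1:5, 20, replace = TRUE))
  hits <- scan_windows(toy)
  for (k in sample(nrow(hits), 25)) {
    h <- hits[k, ]
    expected <- sum(toy$count[toy$strand == h$strand &
                                toy$position >= h$start &
                                toy$position < h$end])
    expect_equal(h$read_count, expected)
  }
})

test_that("the randomized null matches the alignment count and binomial occupancy", {
  set.seed(5)
  reads <- data.frame(chrom = "c1",
                      position = sample.int(1e5, 3000, replace = TRUE) - 1L,
                      strand = "+", count = sample(1:3, 3000, replace = TRUE))
  null1 <- build_null(reads, 1e5, seed = 9)
  expect_equal(sum(null1$reads$count), sum(reads$count))
  null2 <- build_null(reads, 1e5, seed = 9)
  expect_identical(null1, null2)

  # occupancy of disjoint size-1000 windows (+ strand) follows
  # Binomial(N_plus, w/L)
  n_total <- sum(null1$reads$count[null1$reads$strand == "+"])
  h <- null1$hits[null1$hits$window_size == 1000 &
                    null1$hits$start %% 1000 == 0 &
                    null1$hits$strand == "+", ]
  occ <- rep(0L, 100)
  occ[h$start / 1000 + 1] <- h$read_count
  p <- 1000 / 1e5
  breaks <- c(-Inf, qbinom(c(0.2, 0.4, 0.6, 0.8), n_total, p), Inf)
  obs <- table(cut(occ, breaks))
  expected_p <- diff(pbinom(c(-Inf, qbinom(c(0.2, 0.4, 0.6, 0.8),
                                           n_total, p), Inf), n_total, p))
  chi <- suppressWarnings(chisq.test(obs, p = expected_p / sum(expected_p)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("significant-window calling is calibrated and resolves multi-scale overlaps", {
  set.seed(6)
  reads <- data.frame(chrom = "c1",
                      position = sample.int(5e5, 4000, replace = TRUE) - 1L,
                      strand = sample(c("+", "-"), 4000, replace = TRUE),
                      count = 1L)
  real <- scan_windows(reads)

  # exchangeability: scanning the data against itself yields nothing at
  # FDR 0.001
  expect_equal(nrow(call_significant_windows(real, real, fdr = 0.001)), 0L)

  # a 500-read spike over the background is called and resolved to a single
  # region containing the spike
  spike <- rbind(reads, data.frame(chrom = "c1", position = 250000L,
                                   strand = "+", count = 500L))
  real_spike <- scan_windows(spike)
  null <- build_null(reads, 5e5, seed = 4)
  sig <- call_significant_windows(real_spike, null$hits, fdr = 0.001)
  expect_gte(nrow(sig), 1L)
  covering <- sig$start <= 250000 & sig$end > 250000 & sig$strand == "+"
  expect_true(any(covering))
  # per-strand disjointness after resolution
  for (s in c("+", "-")) {
    ss <- sig[sig$strand == s, ]
    if (nrow(ss) > 1) {
      ss <- ss[order(ss$start), ]
      expect_true(all(ss$start[-1] >= ss$end[-nrow(ss)]))
    }
  }

  # monotonicity: a stricter FDR never adds regions
  sig_loose <- call_significant_windows(real_spike, null$hits, fdr = 0.01)
  expect_true(all(sig$read_count %in% sig_loose$read_count))
  expect_lte(nrow(sig), nrow(sig_loose))
})

test_that("TSS filters remove 3'-UTR and distal-orphan candidates only", {
  ann <- list(
    genes = data.frame(chrom = "c1", start = 100000L, end = 110000L,
                       strand = "+", gene_id = "g1"),
    utr3 = data.frame(chrom = "c1", start = 109500L, end = 110000L,
                      strand = "+", gene_id = "g1")
  )
  cands <- data.frame(
    chrom = "c1",
    start = c(109600L, 49999L, 50001L, 105000L, 99000L),
    end = c(109610L, 50009L, 50011L, 105010L, 99010L),
    strand = "+"
  )
  # upstream gaps: gene start 100000 - candidate end
  # cand2 end 50009 -> gap 49991 (kept), cand3 end 50011 -> gap 49989 (kept)
  cands$end[2] <- 49999L  # gap 50001 -> removed
  cands$start[2] <- 49989L
  cands$end[3] <- 50001L  # gap 49999 -> kept
  cands$start[3] <- 49991L
  out <- filter_tss(cands, ann, max_upstream = 50000L)
  expect_false(109600 %in% out$start)      # inside 3' UTR
  expect_false(49989 %in% out$start)       # 50001 bp upstream
  expect_true(49991 %in% out$start)        # 49999 bp upstream
  expect_true(105000 %in% out$start)       # gene body, non-UTR: kept
  expect_true(99000 %in% out$start)        # just upstream: kept

  # a candidate on the opposite strand of the only gene is an orphan
  minus <- data.frame(chrom = "c1", start = 99000L, end = 99010L,
                      strand = "-")
  expect_equal(nrow(filter_tss(minus, ann)), 0L)
})

test_that("representative-TSS selection picks the strongest supported base per gene", {
  gene_tss <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                         pos = c(10000L, 50000L), strand = "+",
                         stringsAsFactors = FALSE)
  cands <- data.frame(chrom = "c1",
                      start = c(9990L, 10200L, 49990L),
                      end = c(10010L, 10220L, 50010L),
                      strand = "+")
  reads <- data.frame(
    chrom = "c1",
    position = c(10000L, 10001L, 10210L, 50000L),
    strand = "+",
    count = c(100L, 40L, 60L, 30L)
  )
  evidence <- data.frame(chrom = "c1", start = c(9000L, 49000L),
                         end = c(11000L, 51000L), value = c(5, 5))
  prom <- select_representative(cands, reads, gene_tss, pol2 = evidence)
  expect_equal(nrow(prom), 2L)
  g1 <- prom[prom$gene_id == "g1", ]
  # candidate with count 100+40 beats candidate with 60; representative base
  # is the maximal base, not the sum
  expect_equal(g1$tss, 10000L)
  expect_equal(g1$tss_count, 140)

  # no Pol2/H3K4me3 evidence within +/- 1 kb: candidate discarded
  far_evidence <- data.frame(chrom = "c1", start = 9000L, end = 11000L,
                             value = 5)
  prom2 <- select_representative(cands, reads, gene_tss, pol2 = far_evidence)
  expect_false("g2" %in% prom2$gene_id)

  # tie on the representative base goes to the 5'-most base on the strand
  tie_reads <- data.frame(chrom = "c1", position = c(10000L, 10005L),
                          strand = "+", count = c(50L, 50L))
  prom3 <- select_representative(cands[1, , drop = FALSE], tie_reads,
                                 gene_tss, pol2 = evidence)
  expect_equal(prom3$tss, 10000L)
})

test_that("annotation supplementation adds non-overlapping promoters, one per gene", {
  ann <- generate_annotation(100, 8e6, seed = 21)
  # 60 genes carry a TSS-seq-based promoter at their annotated TSS
  with_signal <- ann$tss[1:60, ]
  prom <- data.frame(
    gene_id = with_signal$gene_id, chrom = with_signal$chrom,
    tss = with_signal$pos, strand = with_signal$strand, source = "tss_seq",
    window_start = with_signal$pos - 1000L,
    window_end = with_signal$pos + 1000L, tss_count = 10,
    stringsAsFactors = FALSE
  )
  final <- supplement_refseq(prom, ann$tss)
  # one promoter per gene
  expect_equal(anyDuplicated(final$gene_id), 0L)
  # already-represented genes are untouched
  expect_true(all(with_signal$gene_id %in% final$gene_id))

  # brute-force sequential enumeration with the same ordering convention
  expected <- nrow(prom)
  windows <- prom[, c("chrom", "window_start", "window_end")]
  for (g in sort(setdiff(ann$tss$gene_id, prom$gene_id))) {
    row <- ann$tss[ann$tss$gene_id == g, ]
    ws <- row$pos - 1000L
    we <- row$pos + 1000L
    if (!any(windows$chrom == row$chrom & windows$window_start < we &
               windows$window_end > ws)) {
      expected <- expected + 1L
      windows <- rbind(windows, data.frame(chrom = row$chrom,
                                           window_start = ws,
                                           window_end = we))
    }
  }
  expect_equal(nrow(final), expected)

  # empty TSS-seq set: the final set is the full annotation set (toy genomes
  # here have no overlapping promoter windows closer than the gene gap)
  empty <- prom[0, ]
  all_ann <- supplement_refseq(empty, ann$tss)
  expect_true(all(all_ann$source == "annotation"))
})

test_that("CpG classification equals brute-force interval intersection", {
  set.seed(31)
  prom <- data.frame(chrom = "c1", tss = sample.int(1e6, 200))
  islands <- data.frame(chrom = "c1", start = sample.int(1e6, 50))
  islands$end <- islands$start + sample(100:1000, 50, replace = TRUE)
  flags <- classify_cpg(prom, islands)
  brute <- vapply(seq_len(nrow(prom)), function(i) {
    any(islands$start < prom$tss[i] + 1000 & islands$end > prom$tss[i] - 1000)
  }, logical(1))
  expect_equal(flags, brute)

  # 1-bp overlap at the window edge counts; no islands means FALSE
  edge <- data.frame(chrom = "c1", start = 1999L, end = 2500L)
  expect_true(classify_cpg(data.frame(chrom = "c1", tss = 1000L), edge))
  expect_false(classify_cpg(data.frame(chrom = "c1", tss = 1000L),
                            data.frame(chrom = "c1", start = 2000L,
                                       end = 2500L)))
  expect_equal(classify_cpg(prom, islands[0, ]), rep(FALSE, 200))
})

test_that("promoter strand symmetry: mirrored input yields the mirrored promoter set", {
  L <- 500000L
  reads <- data.frame(chrom = "c1",
                      position = c(rep(100000L, 50), rep(300000L, 40)),
                      strand = c(rep("+", 50), rep("-", 40)), count = 1L)
  ann <- list(
    genes = data.frame(chrom = "c1", start = c(100000L, 250000L),
                       end = c(120000L, 300001L), strand = c("+", "-"),
                       gene_id = c("g1", "g2")),
    utr3 = data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0)),
    tss = data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                     pos = c(100000L, 300000L), strand = c("+", "-")),
    cpg_islands = data.frame(chrom = character(0), start = integer(0),
                             end = integer(0)),
    chrom = "c1", chrom_length = L
  )
  mirror_pos <- function(p) L - 1L - p
  reads_m <- data.frame(chrom = "c1", position = mirror_pos(reads$position),
                        strand = ifelse(reads$strand == "+", "-", "+"),
                        count = reads$count)
  ann_m <- ann
  ann_m$genes <- data.frame(chrom = "c1",
                            start = mirror_pos(ann$genes$end - 1L),
                            end = mirror_pos(ann$genes$start) + 1L,
                            strand = ifelse(ann$genes$strand == "+", "-", "+"),
                            gene_id = ann$genes$gene_id)
  ann_m$tss <- data.frame(gene_id = ann$tss$gene_id, chrom = "c1",
                          pos = mirror_pos(ann$tss$pos),
                          strand = ifelse(ann$tss$strand == "+", "-", "+"))
  p1 <- call_promoters(reads, ann, seed = 2)
  p2 <- call_promoters(reads_m, ann_m, seed = 2)
  p2_back <- p2[order(p2$gene_id), ]
  p1 <- p1[order(p1$gene_id), ]
  expect_equal(p1$gene_id, p2_back$gene_id)
  expect_equal(mirror_pos(p2_back$tss), p1$tss)
  expect_equal(ifelse(p2_back$strand == "+", "-", "+"), p1$strand)
})
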