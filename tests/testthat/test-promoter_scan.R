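test_that("scanner equals the brute-force all-windows oracle", {
  set.seed(21)
  for (rep in 1:5) {
    p <- random_pfm(6, tss_offset = 2L)
    g <- list(c1 = random_seq(400), c2 = random_seq(150))
    hits <- scan_genome(p, g, threshold_fraction = 0.75)
    orc <- oracle_scan(p, g, 0.75)
    expect_equal(nrow(hits), nrow(orc))
    key <- function(d) paste(d$contig, d$start, d$strand)
    o <- order(key(orc))
    h <- order(key(hits))
    expect_equal(key(hits)[h], key(orc)[o])
    expect_equal(hits$score[h], orc$score[o], tolerance = 1e-12)
  }
})

test_that("planted consensus site is recovered exactly; background is not", {
  p <- build_pfm(c("TTGCAC", "TTGCAC", "TTGCAT"), tss_offset = 4L)
  bg <- paste(rep("A", 300), collapse = "")
  planted <- paste0(substr(bg, 1, 100), "TTGCAC", substr(bg, 107, 300))
  hits <- scan_genome(p, list(chr = planted), 0.85)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 100L)
  expect_equal(plus$end, 106L)
  expect_equal(plus$score, max_score(p))
  expect_equal(plus$minus11_pos, 104L)   # start + tss_offset
})

test_that("threshold 1.0 with an absent argmax string yields no hits", {
  p <- build_pfm("GGGG", tss_offset = 0L)
  hits <- scan_genome(p, list(c1 = paste(rep("AT", 100), collapse = "")),
                      1.0)
  expect_equal(nrow(hits), 0L)
})

test_that("palindromic motifs hit both strands at the same span", {
  p <- build_pfm("ACGT", tss_offset = 0L)   # reverse complement of itself
  g <- list(c1 = "TTTTACGTTTTT")
  hits <- scan_genome(p, g, 0.99)
  expect_equal(nrow(hits), 2L)
  expect_equal(sort(hits$strand), c("+", "-"))
  expect_equal(unique(hits$start), 4L)
})

test_that("reverse-complementing the genome mirrors the hit set", {
  set.seed(22)
  p <- random_pfm(8, tss_offset = 3L)
  s <- random_seq(600)
  h1 <- scan_genome(p, list(c1 = s), 0.75)
  h2 <- scan_genome(p, list(c1 = oracle_revcomp(s)), 0.75)
  expect_equal(nrow(h1), nrow(h2))
  # a + hit at start p maps to a - hit at L - p - i, and vice versa
  L <- nchar(s)
  mirrored <- data.frame(start = L - h1$start - p$i,
                         strand = ifelse(h1$strand == "+", "-", "+"),
                         score = h1$score)
  o1 <- order(mirrored$start, mirrored$strand)
  o2 <- order(h2$start, h2$strand)
  expect_equal(mirrored$start[o1], h2$start[o2])
  expect_equal(mirrored$strand[o1], h2$strand[o2])
  expect_equal(mirrored$score[o1], h2$score[o2], tolerance = 1e-12)
})

test_that("short contigs are skipped with a warning", {
  p <- build_pfm("ACGTACGT", tss_offset = 0L)
  expect_warning(h <- scan_genome(p, list(tiny = "ACG", ok = random_seq(50)),
                                  0.5), "skipped")
})

test_that("rank_hits sorts by score with positional tie-break", {
  h <- data.table::data.table(
    contig = "c", start = c(10L, 50L, 30L), end = c(16L, 56L, 36L),
    strand = "+", score = c(0.9, 0.95, 0.9), minus11_pos = c(12L, 52L, 32L))
  r <- rank_hits(h)
  expect_equal(r[r$start == 50]$rank, 1L)
  expect_equal(r[r$start == 10]$rank, 2L)
  expect_equal(r[r$start == 30]$rank, 3L)
  expect_equal(nrow(rank_hits(h[0])), 0L)
  # all-equal scores rank in positional order
  h2 <- data.table::copy(h)[, score := 0.9]
  r2 <- rank_hits(h2)
  expect_equal(r2$start, c(10L, 30L, 50L))
  expect_equal(r2$rank, 1:3)
})

test_that("gene linkage reproduces the signed-distance conventions", {
  fx <- distance_fixture()
  links <- link_hits_to_genes(fx$hits, fx$genes)
  expect_equal(nrow(links), 7L)
  lk <- function(m11, gid) links[links$minus11_pos == m11 &
                                   links$gene_id == gid, ]
  # upstream inline promoter: -11 at 1000, + gene starts 1100
  expect_equal(lk(1000, "gA")$distance, 100L)
  expect_equal(lk(1000, "gA")$orientation, "inline")
  # element inside gB (2000..3200): negative distance
  expect_equal(lk(2295, "gB")$distance, -295L)
  expect_equal(lk(2295, "gB")$orientation, "inline")
  # - strand hit upstream of - gene gC (tls 4199)
  expect_equal(lk(4490, "gC")$distance, 291L)
  expect_equal(lk(4490, "gC")$orientation, "inline")
  # opposing neighbors
  expect_equal(lk(4490, "gD")$distance, -510L)
  expect_equal(lk(4490, "gD")$orientation, "opposing")
  expect_equal(lk(2295, "gC")$distance, 1904L)
  expect_equal(lk(2295, "gC")$orientation, "opposing")
  expect_equal(lk(5290, "gD")$distance, -290L)
  expect_equal(lk(5290, "gE")$distance, 2109L)
  expect_equal(lk(5290, "gE")$orientation, "opposing")
})

test_that("filter_promoters applies window, orientation and rank rules", {
  fx <- distance_fixture()
  links <- link_hits_to_genes(rank_hits(fx$hits), fx$genes)
  kept <- filter_promoters(links)
  expect_setequal(paste(kept$minus11_pos, kept$gene_id),
                  c("1000 gA", "4490 gC"))
  # rank cut: scores 0.99 > 0.95 > 0.90 > 0.88, so the 4490 hit has rank 4
  kept3 <- filter_promoters(links, top_rank = 3)
  expect_equal(paste(kept3$minus11_pos, kept3$gene_id), "1000 gA")
  # subset of input and idempotent
  expect_true(nrow(kept) <= nrow(links))
  expect_equal(filter_promoters(kept), kept)
})

test_that("distance histogram bins half-open and normalizes over both series", {
  links <- data.table::data.table(
    distance = c(10, 20, 150, 250), orientation = "inline")
  h <- distance_histogram(links)
  expect_equal(h$fraction[h$bin_start == 0], 0.5)
  expect_equal(h$fraction[h$bin_start == 100], 0.25)
  expect_equal(h$fraction[h$bin_start == 200], 0.25)

  expect_equal(nrow(distance_histogram(links[0])), 0L)

  h2 <- distance_histogram(data.table::data.table(
    distance = c(-30, 30), orientation = "inline"))
  expect_equal(h2$bin_start, c(-100, 0))
  expect_equal(h2$fraction, c(0.5, 0.5))

  # two-series normalization: grand total is 1
  fx <- distance_fixture()
  links3 <- link_hits_to_genes(fx$hits, fx$genes)
  h3 <- distance_histogram(links3)
  expect_equal(sum(h3$fraction), 1)
  expect_equal(sum(h3$count), 7L)
  expect_equal(h3[h3$bin_start == -300 & h3$orientation == "inline",
                  ]$fraction, 2 / 7)
})
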