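mk_genes <- function(starts, ends, strands, contig = "c1") {
  data.frame(gene_id = sprintf("%s_g%02d", contig, seq_along(starts)),
             contig = contig, start = starts, end = ends, strand = strands)
}

test_that("operon building honors the 300-nt gap criterion exactly", {
  # gap 200 joins
  g <- mk_genes(c(0, 700), c(500, 1200), c("+", "+"))
  u <- build_units(g)
  expect_equal(nrow(u$operons), 1L)
  expect_equal(u$operons$gene_ids[[1]], g$gene_id)
  # gap 400 splits
  g2 <- mk_genes(c(0, 900), c(500, 1400), c("+", "+"))
  expect_equal(nrow(build_units(g2)$operons), 2L)
  # boundary: gap of exactly 300 joins, 301 splits
  g3 <- mk_genes(c(0, 800), c(500, 1300), c("+", "+"))
  expect_equal(nrow(build_units(g3)$operons), 1L)
  g4 <- mk_genes(c(0, 801), c(500, 1300), c("+", "+"))
  expect_equal(nrow(build_units(g4)$operons), 2L)
  # strand change always splits
  g5 <- mk_genes(c(0, 700), c(500, 1200), c("+", "-"))
  expect_equal(nrow(build_units(g5)$operons), 2L)
  # singleton
  expect_equal(nrow(build_units(mk_genes(10, 400, "+"))$operons), 1L)
})

test_that("operon grouping equals the brute-force oracle on random layouts", {
  set.seed(51)
  for (rep in 1:60) {
    g <- random_gene_layout(sample(2:12, 1))
    got <- build_units(g)$operons$gene_ids
    want <- oracle_operons(g)
    expect_equal(length(got), length(want))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # every gene in exactly one operon
    all_ids <- unlist(got)
    expect_setequal(all_ids, g$gene_id)
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("divergons pair adjacent units transcribed away from each other", {
  # <-- unit1 | 250 nt | unit2 -->
  g <- mk_genes(c(0, 1250), c(1000, 2200), c("-", "+"))
  u <- build_units(g)
  expect_equal(nrow(u$divergons), 1L)
  expect_equal(u$divergons$gap, 250L)
  # convergent orientation (+ then -) is not a divergon
  g2 <- mk_genes(c(0, 1250), c(1000, 2200), c("+", "-"))
  expect_equal(nrow(build_units(g2)$divergons), 0L)
  # gap beyond 300 is not a divergon
  g3 <- mk_genes(c(0, 1350), c(1000, 2200), c("-", "+"))
  expect_equal(nrow(build_units(g3)$divergons), 0L)
})

test_that("context windows truncate at contig edges", {
  g <- mk_genes(seq(0, 14000, by = 1000), seq(600, 14600, by = 1000),
                rep("+", 15))
  w <- context_window(g, "c1_g08", 10, 10)
  expect_equal(length(w$gene_ids), 14L)       # 7 up + 7 down available
  w2 <- context_window(g, "c1_g03", 10, 10)
  expect_equal(w2$gene_ids,
               c("c1_g01", "c1_g02",
                 sprintf("c1_g%02d", 4:13)))  # 2 up + 10 down
  single <- mk_genes(0, 500, "+", contig = "solo")
  w3 <- context_window(single, "solo_g01")
  expect_equal(length(w3$gene_ids), 0L)
  expect_error(context_window(g, "nope"), "not found")
})

test_that("promoter context takes the downstream unit plus one upstream gene", {
  # 4-gene + operon at 2000.., upstream gene ends at 1500
  g <- mk_genes(c(0, 2000, 2600, 3200, 3800),
                c(1500, 2500, 3100, 3700, 4300),
                c("+", "+", "+", "+", "+"))
  units <- build_units(g)
  link <- data.frame(contig = "c1", strand = "+", minus11_pos = 1900,
                     gene_id = "c1_g02")
  w <- promoter_context(link, g, units)
  expect_setequal(w$gene_ids, g$gene_id)      # 4 operon genes + 1 upstream
  # 12-gene operon: capped at 10 downstream
  g2 <- mk_genes(seq(1000, 12000, by = 1000), seq(1800, 12800, by = 1000),
                 rep("+", 12))
  u2 <- build_units(g2)
  expect_equal(nrow(u2$operons), 1L)
  link2 <- data.frame(contig = "c1", strand = "+", minus11_pos = 900,
                      gene_id = "c1_g01")
  w2 <- promoter_context(link2, g2, u2)
  expect_equal(w2$gene_ids, sprintf("c1_g%02d", 1:10))  # no upstream gene
})

test_that("annotation collection counts per window occurrence and coverage", {
  g <- mk_genes(c(0, 1000, 2000, 3000), c(600, 1600, 2600, 3600),
                rep("+", 4))
  ann <- data.frame(
    gene_id = c("c1_g01", "c1_g02", "c1_g02", "c1_g03"),
    type = c("COG", "COG", "PFAM", "COG"),
    term = c("COG0642", "COG0642", "PF00158", "COG0001"))
  md <- data.frame(genome_id = "c1", phylum = "Alpha")
  w1 <- list(anchor = "c1_g04", gene_ids = c("c1_g01", "c1_g02", "c1_g03"),
             genome_id = "c1")
  prof <- collect_annotations(list(w1), ann, md)
  expect_equal(prof$counts[prof$counts$term == "COG0642", ]$count, 2L)
  # COG coverage: 3 of 3 context genes have a COG term
  expect_equal(prof$coverage[prof$coverage$type == "COG", ]$coverage, 1)
  # PFAM coverage: 1 of 3
  expect_equal(prof$coverage[prof$coverage$type == "PFAM", ]$coverage,
               1 / 3)
  # a gene in two windows counts once per occurrence
  prof2 <- collect_annotations(list(w1, w1), ann, md)
  expect_equal(prof2$counts[prof2$counts$term == "COG0642", ]$count, 4L)
  expect_equal(prof2$n_context_genes, 6L)
  # empty windows
  empty <- collect_annotations(list(), ann, md)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("conserved tendencies require >= 2 phyla and keep boundary ties", {
  counts <- data.table::rbindlist(list(
    data.table::data.table(phylum = "A", type = "COG",
                           term = sprintf("t%02d", 1:12),
                           count = c(50, 40:30)),
    data.table::data.table(phylum = "B", type = "COG",
                           term = c("t01", sprintf("u%02d", 1:10)),
                           count = c(60, 30:21))))
  gpp <- c(A = 3L, B = 3L)
  tend <- extract_conserved_tendencies(counts, gpp, k_small = 10,
                                       min_phyla = 2)
  expect_equal(tend$term, "t01")            # only t01 is top-10 in both
  expect_equal(tend$n_phyla, 2L)
  # t12 (rank 12 in A) never appears even with min_phyla = 1
  t1 <- extract_conserved_tendencies(counts, gpp, k_small = 10,
                                     min_phyla = 1)
  expect_false("t12" %in% t1$term)
  # boundary tie: two terms share the 10th-largest count -> both kept
  cc <- data.table::data.table(phylum = "A", type = "COG",
                               term = sprintf("t%02d", 1:11),
                               count = c(20:11, 11))
  tt <- extract_conserved_tendencies(cc, c(A = 1L), min_phyla = 1)
  expect_true(all(c("t10", "t11") %in% tt$term))
  # monotone in min_phyla
  t2 <- extract_conserved_tendencies(counts, gpp, min_phyla = 2)
  expect_true(all(t2$term %in% t1$term))
  # k switches to k_large for phyla with many genomes
  gpp_big <- c(A = 12L, B = 3L)
  tbig <- extract_conserved_tendencies(counts, gpp_big, k_small = 10,
                                       k_large = 20, large_threshold = 10,
                                       min_phyla = 1)
  expect_true("t12" %in% tbig$term)         # now inside A's top-20
})

test_that("COG category representation flags enrichment via binomial test", {
  ann <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    type = "COG_category",
                    term = c(rep("M", 60), rep("C", 20), rep("T", 120)))
  w <- list(anchor = "x", gene_ids = sprintf("g%03d", 1:200),
            genome_id = "G")
  bg <- data.frame(category = c("M", "C", "T"),
                   fraction = c(0.10, 0.10, 0.60))
  rep_tbl <- cog_category_representation(list(w), ann, bg)
  expect_equal(rep_tbl[rep_tbl$category == "M", ]$flag, "+")  # 0.30 vs 0.10
  expect_equal(rep_tbl[rep_tbl$category == "C", ]$flag, "-")  # 0.10 vs 0.10
  expect_equal(rep_tbl[rep_tbl$category == "T", ]$flag, "-")  # equal
  # no annotated genes -> blank flags
  blank <- cog_category_representation(
    list(list(anchor = "x", gene_ids = character(), genome_id = "G")),
    ann, bg)
  expect_true(all(blank$flag == ""))
})
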