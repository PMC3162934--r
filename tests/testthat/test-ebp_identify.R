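test_that("sigma54 detection applies the 1e-20 cutoff per best hit", {
  rows <- data.table::rbindlist(list(
    data.table::data.table(qseqid = "sigma54_Ec", sseqid = "p1",
                           evalue = 1e-25),
    data.table::data.table(qseqid = "sigma54_Bs", sseqid = "p1",
                           evalue = 1e-10),
    data.table::data.table(qseqid = "sigma54_Ec", sseqid = "p2",
                           evalue = 1e-15),
    data.table::data.table(qseqid = "sigma54_Ec", sseqid = "p3",
                           evalue = 1e-30),
    data.table::data.table(qseqid = "sigma54_Bs", sseqid = "p4",
                           evalue = 1e-21)), fill = TRUE)
  gm <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                   genome_id = c("gA", "gA", "gB", "gB"))
  res <- detect_sigma54(rows, gm)
  expect_true("p1" %in% res$proteins$protein_id)    # best 1e-25 <= cutoff
  expect_false("p2" %in% res$proteins$protein_id)   # 1e-15 > cutoff
  gB <- res$genomes[res$genomes$genome_id == "gB", ]
  expect_true(gB$present)
  expect_equal(gB$n_copies, 2L)                     # multi-copy genome
})

test_that("e-value profiles impute missing hits and floor zeros", {
  seeds <- sprintf("s%02d", 1:34)
  rows <- data.table::data.table(
    qseqid = seeds[1:30], sseqid = "prot1",
    evalue = c(0, rep(1e-40, 29)))
  prof <- build_evalue_profiles(rows, seeds)
  expect_equal(dim(prof), c(1L, 34L))
  expect_equal(sum(prof["prot1", ] == 10), 4L)       # 4 missing -> 10
  expect_equal(prof["prot1", "s01"], 1e-200)         # zero floored
  # duplicate hits keep the minimum
  rows2 <- data.table::data.table(qseqid = c("s01", "s01"), sseqid = "p",
                                  evalue = c(1e-5, 1e-9))
  expect_equal(build_evalue_profiles(rows2, seeds)["p", "s01"], 1e-9)
  expect_error(build_evalue_profiles(
    data.table::data.table(qseqid = "zz", sseqid = "p", evalue = 1),
    seeds), "unknown seed")
})

test_that("product/sum filter matches hand arithmetic", {
  seeds <- sprintf("s%02d", 1:34)
  mk <- function(e) matrix(e, 1, 34, dimnames = list("p", seeds))
  # all 1e-3: product 1e-102 passes, sum 0.034 passes
  expect_true(filter_candidates(mk(1e-3))$pass)
  # 33 x 1e-10 plus one 10: product passes, sum 10 fails
  expect_false(filter_candidates(mk(c(rep(1e-10, 33), 10)))$pass)
  # all 1: product 1 fails
  expect_false(filter_candidates(mk(1))$pass)
})

test_that("log-space filter equals brute force across extreme profiles", {
  set.seed(31)
  seeds <- sprintf("s%02d", 1:34)
  for (rep in 1:300) {
    e <- 10^stats::runif(34, -300, 1)
    prof <- matrix(e, 1, 34, dimnames = list("p", seeds))
    expect_equal(filter_candidates(prof)$pass, oracle_filter(e))
  }
  # profiles that underflow a naive double product
  e <- rep(1e-300, 34)
  expect_identical(prod(e), 0)                      # naive product dies
  prof <- matrix(e, 1, 34, dimnames = list("p", seeds))
  expect_true(filter_candidates(prof)$pass)
  expect_true(oracle_filter(e))
})

test_that("locate_gaftga finds exact, substituted and gapped windows", {
  g <- locate_gaftga("MKLGAFTGAKPL")
  expect_equal(g$window, "GAFTGA")
  expect_equal(g$window_start, 3L)
  expect_false(g$gapped)
  expect_equal(g$score, 1.0)

  g2 <- locate_gaftga("MKLGAFPGAKPL")
  expect_equal(g2$window, "GAFPGA")
  expect_equal(g2$score, 5 / 6, tolerance = 1e-12)
  expect_false(g2$gapped)

  # one-residue deletion: GA-TGA
  g3 <- locate_gaftga("MKWWGATGAKPL")
  expect_true(g3$gapped)
  expect_equal(g3$window, "GATGA")
  expect_equal(g3$score, 5 / 6, tolerance = 1e-12)

  expect_error(locate_gaftga("MKW"), "too short")
})

test_that("locate_gaftga is translation invariant", {
  set.seed(32)
  base <- paste(sample(setdiff(PROTEIN_ALPHABET, "F"), 60, replace = TRUE),
                collapse = "")
  prot <- paste0(substr(base, 1, 25), "GAFTGA", substr(base, 26, 60))
  g0 <- locate_gaftga(prot)
  for (k in c(1, 5, 17)) {
    pre <- paste(rep("K", k), collapse = "")
    gk <- locate_gaftga(paste0(pre, prot))
    expect_equal(gk$window_start, g0$window_start + k)
    expect_equal(gk$window, g0$window)
  }
})

test_that("classify_gaftga reproduces the substitution-rule table", {
  cls <- function(w, gapped = FALSE) {
    classify_gaftga(list(window = w, gapped = gapped))$overall
  }
  expect_equal(cls("GAFTGA"), "functional")
  expect_equal(cls("GSFTGA"), "functional")     # A2 -> S (LevR)
  expect_equal(cls("NAFTGA"), "functional")     # G1 -> N
  expect_equal(cls("GAYTGA"), "functional")     # F3 -> Y (TouR)
  expect_equal(cls("GAFEGA"), "functional")     # T4 -> E (PhhR)
  expect_equal(cls("GAFTDA"), "functional")     # G5 -> D (FlgR)
  expect_equal(cls("GAFPGA"), "inactive")       # T4 -> P
  expect_equal(cls("GAFTGT"), "putative")       # A6 -> T
  expect_equal(cls("DAFTGA"), "putative")       # G1 -> D
  expect_equal(cls("GDFTGA"), "inactive")       # A2 -> D explicitly inactive
  expect_equal(cls("GATGA", gapped = TRUE), "inactive")
})

test_that("classifier matches the rule-table oracle on all 121 windows", {
  canon <- c("G", "A", "F", "T", "G", "A")
  windows <- "GAFTGA"
  for (p in 1:6) for (aa in setdiff(PROTEIN_ALPHABET, canon[p])) {
    w <- canon; w[p] <- aa
    windows <- c(windows, paste(w, collapse = ""))
  }
  expect_length(windows, 1 + 6 * 19)
  for (w in windows) {
    got <- classify_gaftga(list(window = w, gapped = FALSE))$overall
    expect_equal(got, oracle_gaftga(w), info = w)
  }
  for (p in 1:6) {
    w <- paste(canon[-p], collapse = "")
    got <- classify_gaftga(list(window = w, gapped = TRUE))$overall
    expect_equal(got, "inactive", info = w)
  }
})

test_that("architecture typing follows the precedence rules", {
  expect_equal(classify_architecture(c("receiver", "activator", "HTH_8"),
                                     480), "Ia")
  expect_equal(classify_architecture(c("PAS", "activator", "HTH_8"), 520),
               "Ib")
  expect_equal(classify_architecture(c("HTH_8", "activator", "PRD",
                                       "PTS-EII", "PRD", "PTS-EII"), 900),
               "II")
  expect_equal(classify_architecture("activator", 320), "Ic")
  # missing DNA-binding domain -> Ic even when long
  expect_equal(classify_architecture(c("receiver", "activator"), 500), "Ic")
  # receiver AFTER activator is not Ia, but still a signal domain + HTH_8
  expect_equal(classify_architecture(c("activator", "receiver", "HTH_8"),
                                     500), "Ib")
  expect_equal(classify_architecture(character(0), 450), "Ic")
})

test_that("coarse annotation picks the argmin seed with ties and cutoff", {
  sg <- c(AtoC = "AtoC-like", NtrC = "NtrC-like", ZraR = "ZraR-like")
  prof <- c(AtoC = 1e-40, NtrC = 1e-22, ZraR = 1e-21)
  expect_equal(annotate_by_seed(prof, sg), "AtoC-like")
  tied <- c(NtrC = 1e-40, AtoC = 1e-40, ZraR = 1)
  expect_equal(annotate_by_seed(tied, sg), "AtoC-like")  # lexicographic
  weak <- c(AtoC = 1e-5, NtrC = 1e-4, ZraR = 1)
  expect_true(is.na(annotate_by_seed(weak, sg)))
})

test_that("identify_ebps separates synthetic true EBPs from decoys", {
  spec <- synthetic_spec(seed = 33, n_genomes = 2L)
  prot <- generate_proteins(spec)
  tbl <- identify_ebps(prot$blast_rows, prot$seeds, prot$proteins,
                       prot$domains, prot$genome_map)
  kinds <- vapply(prot$manifest, function(m) m$kind, character(1))
  true_ids <- names(kinds)[kinds == "true_ebp"]
  decoy_ids <- names(kinds)[kinds == "decoy"]
  expect_true(all(tbl[tbl$protein_id %in% true_ids, ]$pass_filter))
  expect_false(any(tbl[tbl$protein_id %in% decoy_ids, ]$pass_filter))
  expect_true(all(tbl[tbl$protein_id %in% true_ids, ]$status == "true_ebp"))
  expect_true(all(tbl[tbl$protein_id %in% decoy_ids, ]$status ==
                    "rejected"))
  expect_setequal(unique(tbl[tbl$protein_id %in% true_ids, ]$architecture),
                  c("Ia", "Ib", "Ic", "II"))
})
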