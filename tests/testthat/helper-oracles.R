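# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-implementations (character loops, brute force) that
# never share code with the package internals they check.

# direct evaluation of the frequency-sum score: (1/i) * sum_j f[seq[j], j]
oracle_sms_score <- function(f, alphabet, seq) {
  cc <- strsplit(seq, "")[[1]]
  total <- 0
  for (j in seq_along(cc)) {
    row <- match(cc[j], alphabet)
    if (!is.na(row)) total <- total + unname(f[row, j])
  }
  unname(total) / ncol(f)
}

# random PFM: Dirichlet-ish columns via normalized uniforms
random_pfm <- function(i, alphabet = c("A", "C", "G", "T"),
                       tss_offset = NULL) {
  f <- matrix(stats::runif(length(alphabet) * i), nrow = length(alphabet))
  f <- sweep(f, 2, colSums(f), "/")
  rownames(f) <- alphabet
  new_pfm(name = "rand", alphabet = alphabet, f = f, tss_offset = tss_offset)
}

random_seq <- function(i, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, i, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# brute-force scanner: every window on both strands, no vectorization
oracle_scan <- function(pfm, contigs, threshold_fraction) {
  cutoff <- threshold_fraction * max_score(pfm)
  out <- list()
  for (ct in names(contigs)) {
    s <- contigs[[ct]]
    L <- nchar(s)
    if (L < pfm$i) next
    for (p in 0:(L - pfm$i)) {
      win <- substr(s, p + 1, p + pfm$i)
      sc <- oracle_sms_score(pfm$f, pfm$alphabet, win)
      if (sc >= cutoff - 1e-12)
        out[[length(out) + 1]] <- data.frame(contig = ct, start = p,
                                             strand = "+", score = sc)
      scm <- oracle_sms_score(pfm$f, pfm$alphabet, oracle_revcomp(win))
      if (scm >= cutoff - 1e-12)
        out[[length(out) + 1]] <- data.frame(contig = ct, start = p,
                                             strand = "-", score = scm)
    }
  }
  if (!length(out)) return(data.frame(contig = character(),
                                      start = integer(),
                                      strand = character(),
                                      score = numeric()))
  do.call(rbind, out)
}

# rule-table oracle for GAFTGA windows, coded straight off the table text
oracle_gaftga <- function(window) {
  if (nchar(window) != 6) return("inactive")      # any deletion
  aa <- strsplit(window, "")[[1]]
  fun <- list(c("G", "N"), c("A", "S"), c("F", "Y"), c("T", "S", "E"),
              c("G", "D"), c("A", "S"))
  put <- list(c("A", "D", "E", "H", "S"), c("T", "G", "I", "V", "M", "C"),
              character(0), "D", c("E", "A", "H", "N", "S"),
              c("T", "G", "I", "V", "M", "C"))
  st <- character(6)
  for (p in 1:6) {
    st[p] <- if (aa[p] %in% fun[[p]]) "functional"
    else if (aa[p] %in% put[[p]]) "putative" else "inactive"
  }
  if (all(st == "functional")) "functional"
  else if (!any(st == "inactive")) "putative"
  else "inactive"
}

# brute-force product/sum filter in plain arithmetic (log for the product)
oracle_filter <- function(evalues, product_cut = 1e-5, sum_cut = 1) {
  sum(log10(evalues)) < log10(product_cut) && sum(evalues) < sum_cut
}

# brute-force operon grouping: repeatedly merge adjacent same-strand genes
# with gap <= max_gap
oracle_operons <- function(genes, max_gap = 300) {
  genes <- genes[order(genes$contig, genes$start, genes$end), ]
  groups <- list()
  for (ct in unique(genes$contig)) {
    g <- genes[genes$contig == ct, ]
    grp <- 1
    ids <- list(g$gene_id[1])
    if (nrow(g) > 1) for (r in 2:nrow(g)) {
      joined <- g$strand[r] == g$strand[r - 1] &&
        (g$start[r] - g$end[r - 1]) <= max_gap
      if (joined) ids[[grp]] <- c(ids[[grp]], g$gene_id[r])
      else { grp <- grp + 1; ids[[grp]] <- g$gene_id[r] }
    }
    groups <- c(groups, ids)
  }
  groups
}

# random gene layout on one contig for property tests
random_gene_layout <- function(n_genes, contig = "c1") {
  pos <- 0
  rows <- list()
  for (k in seq_len(n_genes)) {
    len <- sample(50:500, 1)
    gap <- sample(c(0:350, 250:400), 1)   # oversample the 300-nt boundary
    pos <- pos + gap
    rows[[k]] <- data.frame(gene_id = sprintf("%s_g%03d", contig, k),
                            contig = contig, start = pos, end = pos + len,
                            strand = sample(c("+", "-"), 1))
    pos <- pos + len
  }
  do.call(rbind, rows)
}

# six-gene fixture used for the distance-convention tests: two contigs
# worth of geometry on one contig, plus four hand-placed hits
distance_fixture <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
    contig = "chr",
    start = c(1100, 2000, 3300, 5000, 6500, 8000),
    end = c(1900, 3200, 4200, 6000, 7400, 9000),
    strand = c("+", "+", "-", "+", "-", "+"))
  hits <- data.frame(
    contig = "chr",
    start = c(984, 2284, 4484, 5284),
    end = c(1000, 2300, 4500, 5300),
    strand = c("+", "+", "-", "+"),
    score = c(0.95, 0.90, 0.88, 0.99),
    minus11_pos = c(1000, 2295, 4490, 5290))
  list(genes = genes, hits = hits)
}
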