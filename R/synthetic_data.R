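# Deterministic synthetic inputs with planted ground truth: genomes with
# operon structure and planted promoter sites, EBP/decoy proteins with
# seed e-value profiles, and per-phylum annotation tables with planted
# enriched terms.  E-values are modeled directly (log-uniform regimes), not
# computed from alignments.

#' Default synthetic -24/-12 promoter motif
#'
#' A 16-column DNA PFM with two conserved blocks separated by a degenerate
#' spacer, mimicking the bipartite Sigma-54 element; `tss_offset` anchors
#' the -11 position inside the downstream block (column 14 of 16, 0-based
#' offset 13).  The published matrix is not printed anywhere, so this is a
#' synthetic stand-in with comparable information content.
#'
#' @param conserved frequency of the dominant base in conserved columns
#'   (default 0.94).
#' @return a pfm object.
#' @export
default_promoter_pfm <- function(conserved = 0.94) {
  consensus <- c("T","G","G","C","A","C","G",      # -24 block
                 "N","N","N","N",                  # spacer
                 "T","T","G","C","A")              # -12 block (-11 = col 14)
  f <- matrix(NA_real_, nrow = 4, ncol = 16,
              dimnames = list(DNA_ALPHABET, NULL))
  minor <- (1 - conserved) / 3
  for (j in seq_along(consensus)) {
    if (consensus[j] == "N") {
      f[, j] <- c(0.30, 0.22, 0.22, 0.26)  # mildly AT-rich spacer
    } else {
      f[, j] <- minor
      f[consensus[j], j] <- conserved
    }
  }
  new_pfm(name = "syn_sigma54_promoter", alphabet = DNA_ALPHABET, f = f,
          m = 0L, tss_offset = 13L)
}

#' Specification of a synthetic data bundle
#'
#' Collects every knob of the generator with defaults chosen to emulate the
#' statistical structure the pipeline assumes: ~200-kb genomes, operon gaps
#' below / between-operon gaps above the 300-nt criterion, planted inline
#' promoters at -50..300 nt from a unit-leading translation start, true-EBP
#' e-value profiles log-uniform in [1e-150, 1e-25] versus sparse weak decoy
#' profiles, and per-phylum annotation tables with planted enriched terms.
#'
#' @param seed integer master seed; every generator stream derives from it.
#' @param n_genomes number of genomes (default 6, two per phylum).
#' @param genome_length genome length in bp (default 2e5).
#' @param gc background G+C fraction (default 0.5).
#' @param n_genes genes per genome (default 60).
#' @param gene_length_range gene length range in bp.
#' @param operon_gap_range within-operon intergenic gap range (<= 300).
#' @param interoperon_gap_range between-operon gap range (> 300).
#' @param pfm promoter motif, default [default_promoter_pfm()].
#' @param n_planted_promoters argmax-string promoter plants per genome.
#' @param planted_distance_range signed -11 -> start distances for plants.
#' @param n_decoy_sites opposing/deep-intergenic motif placements.
#' @param n_true_ebps,n_decoy_proteins protein counts per genome.
#' @param gaftga_variants character vector of windows sampled for true EBPs.
#' @param n_seeds number of verified seed activators (default 34).
#' @param phyla phylum labels cycled over genomes.
#' @param enriched_terms named list: term -> character vector of phyla where
#'   it is planted as context-enriched.
#' @param sigma54_positive logical vector per genome (recycled).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genomes = 6L,
                           genome_length = 2e5,
                           gc = 0.5,
                           n_genes = 60L,
                           gene_length_range = c(600L, 1800L),
                           operon_gap_range = c(20L, 200L),
                           interoperon_gap_range = c(400L, 900L),
                           pfm = default_promoter_pfm(),
                           n_planted_promoters = 5L,
                           planted_distance_range = c(-50L, 300L),
                           n_decoy_sites = 3L,
                           n_true_ebps = 4L,
                           n_decoy_proteins = 4L,
                           gaftga_variants = c("GAFTGA", "GAFTGA", "GSFTGA",
                                               "GAFSGA"),
                           n_seeds = 34L,
                           phyla = c("PhylumA", "PhylumB", "PhylumC"),
                           enriched_terms = list(
                             COG9001 = c("PhylumA", "PhylumB", "PhylumC"),
                             COG9002 = "PhylumA"),
                           sigma54_positive = TRUE) {
  spec <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
               genome_length = genome_length, gc = gc,
               n_genes = as.integer(n_genes),
               gene_length_range = gene_length_range,
               operon_gap_range = operon_gap_range,
               interoperon_gap_range = interoperon_gap_range,
               pfm = pfm,
               n_planted_promoters = as.integer(n_planted_promoters),
               planted_distance_range = planted_distance_range,
               n_decoy_sites = as.integer(n_decoy_sites),
               n_true_ebps = as.integer(n_true_ebps),
               n_decoy_proteins = as.integer(n_decoy_proteins),
               gaftga_variants = gaftga_variants,
               n_seeds = as.integer(n_seeds),
               phyla = phyla,
               enriched_terms = enriched_terms,
               sigma54_positive = rep_len(sigma54_positive, n_genomes))
  stopifnot(spec$operon_gap_range[2L] <= 300,
            spec$interoperon_gap_range[1L] > 300,
            diff(spec$gene_length_range) >= 0)
  class(spec) <- "synthetic_spec"
  spec
}

# derived substream seed, kept inside 32-bit integer range
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate synthetic genomes with planted promoter sites
#'
#' Lays out genes left to right with a mixture of within-operon (<= 300 nt)
#' and between-operon (> 300 nt) gaps and per-operon random strands, then
#' overwrites background sequence with the motif's argmax string upstream of
#' randomly chosen unit-leading genes, inline and at a known signed
#' distance; decoy sites are placed in opposing orientation relative to
#' their nearest unit-leading gene.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `genomes` (named list of contig vectors), `genes`
#'   (data.table), `metadata` (data.table), `manifest` (list; per-genome
#'   planted promoter coordinates, strands, distances and decoys).
#' @export
generate_genomes <- function(spec) {
  set.seed(.substream(spec$seed, 1L))
  pfm <- spec$pfm
  plant_str <- consensus_string(pfm)
  plant_chars <- .chars(plant_str)
  rc_chars <- .chars(.revcomp(plant_str))
  genomes <- list(); gene_rows <- list(); meta <- list(); manifest <- list()
  for (gi in seq_len(spec$n_genomes)) {
    gid <- sprintf("g%02d", gi)
    L <- spec$genome_length
    seqv <- .random_dna(L, spec$gc)
    # gene layout
    pos <- 1200L   # leave room for upstream plants of the first gene
    rows <- list(); leading <- logical(spec$n_genes)
    strand <- sample(c("+", "-"), 1L)
    new_unit <- TRUE
    for (k in seq_len(spec$n_genes)) {
      len <- sample(spec$gene_length_range[1L]:spec$gene_length_range[2L],
                    1L)
      if (pos + len + 1200L > L) break
      rows[[k]] <- data.table::data.table(
        gene_id = sprintf("%s_gene%03d", gid, k), contig = gid,
        start = pos, end = pos + len, strand = strand)
      leading[k] <- new_unit
      within <- stats::runif(1) < 0.6
      gap <- if (within)
        sample(spec$operon_gap_range[1L]:spec$operon_gap_range[2L], 1L)
      else
        sample(spec$interoperon_gap_range[1L]:
                 spec$interoperon_gap_range[2L], 1L)
      pos <- pos + len + gap
      new_unit <- !within
      if (!within) strand <- sample(c("+", "-"), 1L)
    }
    genes <- data.table::rbindlist(rows)
    leading <- leading[seq_len(nrow(genes))]
    # unit-leading gene in reading order: first of a '+' run is its leftmost
    # member; first of a '-' run is its rightmost member
    lead_idx <- .reading_order_leaders(genes)
    planted <- list(); used <- integer()
    n_plant <- if (spec$sigma54_positive[gi]) spec$n_planted_promoters
               else 0L
    cand <- sample(lead_idx, min(n_plant, length(lead_idx)))
    for (ci in cand) {
      gene <- genes[ci]
      d <- sample(spec$planted_distance_range[1L]:
                    spec$planted_distance_range[2L], 1L)
      if (gene$strand == "+") {
        minus11 <- gene$start - d
        mstart <- minus11 - pfm$tss_offset          # 0-based
        if (mstart < 0L || mstart + pfm$i > L) next
        seqv[(mstart + 1L):(mstart + pfm$i)] <- plant_chars
      } else {
        tls <- gene$end - 1L
        minus11 <- tls + d
        mstart <- minus11 - (pfm$i - 1L - pfm$tss_offset)
        if (mstart < 0L || mstart + pfm$i > L) next
        seqv[(mstart + 1L):(mstart + pfm$i)] <- rc_chars
      }
      planted[[length(planted) + 1L]] <- list(
        contig = gid, start = mstart, end = mstart + pfm$i,
        strand = gene$strand, minus11_pos = as.integer(minus11),
        gene_id = gene$gene_id, distance = as.integer(d))
    }
    # decoys: motif string planted in the gene-free leading margin, > 300 nt
    # from the first translation start, alternating strands
    decoys <- list()
    first_start <- min(genes$start)
    for (k in seq_len(spec$n_decoy_sites)) {
      mstart <- 16L + (k - 1L) * 250L
      if (mstart + pfm$i + 350L > first_start) break
      dstrand <- if (k %% 2L == 1L) "+" else "-"
      seqv[(mstart + 1L):(mstart + pfm$i)] <-
        if (dstrand == "+") plant_chars else rc_chars
      decoys[[length(decoys) + 1L]] <- list(contig = gid, start = mstart,
                                            strand = dstrand)
    }
    genomes[[gid]] <- paste(seqv, collapse = "")
    gene_rows[[gi]] <- genes
    meta[[gi]] <- data.table::data.table(
      genome_id = gid,
      phylum = spec$phyla[((gi - 1L) %% length(spec$phyla)) + 1L],
      size_bp = L,
      motile = if (spec$sigma54_positive[gi]) stats::runif(1) < 0.8
               else stats::runif(1) < 0.3,
      membrane = sample(c("monoderm", "diderm"), 1L),
      lps = sample(c("present", "absent", "atypical"), 1L))
    manifest[[gid]] <- list(planted_promoters = planted, decoys = decoys)
  }
  list(genomes = genomes, genes = data.table::rbindlist(gene_rows),
       metadata = data.table::rbindlist(meta), manifest = manifest)
}

# indices of genes that lead their transcriptional unit in reading order
.reading_order_leaders <- function(genes) {
  units <- build_units(genes, max_gap = 300)$operons
  leaders <- character()
  for (r in seq_len(nrow(units))) {
    ids <- units$gene_ids[[r]]
    leaders <- c(leaders,
                 if (units$strand[r] == "+") ids[1L] else ids[length(ids)])
  }
  which(genes$gene_id %in% leaders)
}

#' Generate synthetic EBP and decoy proteins with e-value profiles
#'
#' True EBPs carry a chosen GAFTGA variant inside a random scaffold and one
#' of the four canonical architectures; their 34-seed e-value profiles are
#' log-uniform in [1e-150, 1e-25] so they pass both filters.  Decoys
#' (chelatase/protease-like) carry a scrambled motif and sparse weak hits in
#' [1e-6, 1] to a few seeds, so they fail the sum filter through the
#' missing-hit imputation.
#'
#' When a gene table is supplied, the proteins are attached to real genes
#' (protein id = gene id): the Sigma-54 ortholog sits on each genome's
#' middle gene and EBPs/decoys on genes spread across the chromosome, so
#' genomic-context windows around them are well defined downstream.
#'
#' @param spec a [synthetic_spec()].
#' @param genes optional gene table from [generate_genomes()]; when given,
#'   protein ids are gene ids.
#' @param genome_ids genomes to attach proteins to (default from spec).
#' @return list: `proteins` (named character), `blast_rows` (data.table in
#'   outfmt-6 column layout), `domains` (data.table), `seeds` (data.table:
#'   seed_id, group), `genome_map`, `sigma54_rows` (homology rows for the
#'   two Sigma-54 seeds), `manifest`.
#' @export
generate_proteins <- function(spec, genes = NULL, genome_ids = NULL) {
  set.seed(.substream(spec$seed, 2L))
  if (is.null(genome_ids))
    genome_ids <- sprintf("g%02d", seq_len(spec$n_genomes))
  gene_slots <- NULL
  if (!is.null(genes)) {
    genes <- data.table::as.data.table(genes)
    gene_slots <- lapply(genome_ids, function(gid) {
      gg <- genes[contig == gid]$gene_id
      need <- 1L + spec$n_true_ebps + spec$n_decoy_proteins
      if (length(gg) < need)
        stop("genome ", gid, " has too few genes to host all proteins")
      mid <- ceiling(length(gg) / 2)
      pool <- setdiff(seq_along(gg), mid)
      picks <- pool[round(seq(1, length(pool),
                              length.out = need - 1L))]
      list(rpoN = gg[mid],
           ebps = gg[picks[seq_len(spec$n_true_ebps)]],
           decoys = gg[picks[spec$n_true_ebps +
                               seq_len(spec$n_decoy_proteins)]])
    })
    names(gene_slots) <- genome_ids
  }
  seed_ids <- sprintf("seed%02d", seq_len(spec$n_seeds))
  groups <- c("AtoC-like", "NtrC-like", "DctD-like", "AcoR-like",
              "FleQ-like", "LevR-like", "PspF-like", "NorR-like")
  seeds <- data.table::data.table(
    seed_id = seed_ids,
    group = groups[((seq_len(spec$n_seeds) - 1L) %% length(groups)) + 1L])
  archs <- list(
    Ia = list(domains = c("receiver", "activator", "HTH_8"), len = 480L),
    Ib = list(domains = c("PAS", "activator", "HTH_8"), len = 520L),
    Ic = list(domains = c("activator"), len = 330L),
    II = list(domains = c("HTH_8", "activator", "PRD", "PTS-EII", "PRD",
                          "PTS-EII"), len = 900L))
  proteins <- character(); blast <- list(); domains <- list()
  gmap <- list(); s54 <- list(); manifest <- list()
  bi <- 0L
  for (gid in genome_ids) {
    gix <- match(gid, genome_ids)
    # Sigma-54 ortholog(s) for positive genomes
    if (spec$sigma54_positive[gix]) {
      pid <- if (!is.null(gene_slots)) gene_slots[[gid]]$rpoN
             else sprintf("%s_rpoN", gid)
      proteins[pid] <- paste(sample(PROTEIN_ALPHABET, 470L, replace = TRUE),
                             collapse = "")
      gmap[[length(gmap) + 1L]] <- data.table::data.table(
        protein_id = pid, genome_id = gid)
      for (sid in c("sigma54_Ec", "sigma54_Bs")) {
        bi <- bi + 1L
        s54[[bi]] <- .blast_row(sid, pid, 10^stats::runif(1, -80, -30))
      }
    }
    for (k in seq_len(spec$n_true_ebps)) {
      pid <- if (!is.null(gene_slots)) gene_slots[[gid]]$ebps[k]
             else sprintf("%s_ebp%02d", gid, k)
      arch_name <- names(archs)[((k - 1L) %% length(archs)) + 1L]
      arch <- archs[[arch_name]]
      variant <- spec$gaftga_variants[((k - 1L) %%
                                         length(spec$gaftga_variants)) + 1L]
      scaffold <- sample(setdiff(PROTEIN_ALPHABET, c("F")), arch$len,
                         replace = TRUE)
      at <- 150L
      scaffold[at:(at + nchar(variant) - 1L)] <- .chars(variant)
      proteins[pid] <- paste(scaffold, collapse = "")
      evs <- 10^stats::runif(spec$n_seeds, -150, -25)
      for (si in seq_len(spec$n_seeds))
        blast[[length(blast) + 1L]] <- .blast_row(seed_ids[si], pid, evs[si])
      domains[[length(domains) + 1L]] <- data.table::data.table(
        protein_id = pid, term = arch$domains,
        start = seq_along(arch$domains) * 100L,
        end = seq_along(arch$domains) * 100L + 90L)
      gmap[[length(gmap) + 1L]] <- data.table::data.table(
        protein_id = pid, genome_id = gid)
      manifest[[pid]] <- list(kind = "true_ebp", gaftga = variant,
                              gaftga_at = at - 1L,
                              architecture = arch_name,
                              intended_filter = "pass")
    }
    for (k in seq_len(spec$n_decoy_proteins)) {
      pid <- if (!is.null(gene_slots)) gene_slots[[gid]]$decoys[k]
             else sprintf("%s_decoy%02d", gid, k)
      scaffold <- sample(setdiff(PROTEIN_ALPHABET, c("F", "G")), 400L,
                         replace = TRUE)
      proteins[pid] <- paste(scaffold, collapse = "")
      n_hits <- sample(1:3, 1L)
      for (si in sample(seq_len(spec$n_seeds), n_hits))
        blast[[length(blast) + 1L]] <-
          .blast_row(seed_ids[si], pid, 10^stats::runif(1, -6, 0))
      domains[[length(domains) + 1L]] <- data.table::data.table(
        protein_id = pid, term = "chelatase", start = 10L, end = 380L)
      gmap[[length(gmap) + 1L]] <- data.table::data.table(
        protein_id = pid, genome_id = gid)
      manifest[[pid]] <- list(kind = "decoy", intended_filter = "fail")
    }
  }
  list(proteins = proteins,
       blast_rows = data.table::rbindlist(blast),
       domains = data.table::rbindlist(domains),
       seeds = seeds,
       genome_map = data.table::rbindlist(gmap),
       sigma54_rows = if (bi) data.table::rbindlist(s54[seq_len(bi)])
                      else .empty_blast(),
       manifest = manifest)
}

.blast_row <- function(q, s, evalue) {
  data.table::data.table(qseqid = q, sseqid = s, pident = 35.0,
                         length = 200L, mismatch = 120L, gapopen = 3L,
                         qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
                         evalue = evalue, bitscore = 150.0)
}

.empty_blast <- function() {
  data.table::data.table(qseqid = character(), sseqid = character(),
                         pident = numeric(), length = integer(),
                         mismatch = integer(), gapopen = integer(),
                         qstart = integer(), qend = integer(),
                         sstart = integer(), send = integer(),
                         evalue = numeric(), bitscore = numeric())
}

#' Generate per-phylum annotation tables with planted enriched terms
#'
#' Baseline terms are drawn from a shared vocabulary for every gene;
#' designated enriched terms are over-sampled on the genes inside context
#' windows of designated anchor genes in their designated phyla (>= 2 phyla
#' for conserved terms, exactly 1 for the control term).  Also emits a
#' COG-category layer and a flat background-category table.
#'
#' @param spec a [synthetic_spec()].
#' @param genes gene table from [generate_genomes()].
#' @param metadata metadata table from [generate_genomes()].
#' @param anchors named character vector: genome_id -> anchor gene id
#'   (defaults to each genome's middle gene).
#' @return list: `annotations` (data.table: gene_id, type, term),
#'   `background` (data.table: category, fraction), `anchors`, `manifest`.
#' @export
generate_annotations <- function(spec, genes, metadata, anchors = NULL) {
  set.seed(.substream(spec$seed, 3L))
  genes <- data.table::as.data.table(genes)
  md <- data.table::as.data.table(metadata)
  if (length(spec$phyla) < 2L)
    stop("conservation tests need at least 2 phyla")
  if (is.null(anchors)) {
    anchors <- vapply(unique(genes$contig), function(ct) {
      ids <- genes[contig == ct]$gene_id
      ids[ceiling(length(ids) / 2)]
    }, character(1))
  }
  base_vocab <- sprintf("COG%04d", 1:40)
  cats <- c("C", "E", "G", "M", "N", "O", "T", "U")
  ann <- list()
  for (r in seq_len(nrow(genes))) {
    gid <- genes$gene_id[r]
    ann[[length(ann) + 1L]] <- data.table::data.table(
      gene_id = gid, type = "COG",
      term = sample(base_vocab, 1L))
    ann[[length(ann) + 1L]] <- data.table::data.table(
      gene_id = gid, type = "COG_category",
      term = sample(cats, 1L, prob = c(2, 1, 1, 3, 2, 1, 3, 1)))
  }
  # plant enriched terms on the context genes of the anchors
  planted <- list()
  for (term in names(spec$enriched_terms)) {
    target_phyla <- spec$enriched_terms[[term]]
    gids <- md[phylum %in% target_phyla]$genome_id
    for (g in gids) {
      w <- context_window(genes, anchors[[g]], 10, 10)
      take <- w$gene_ids
      if (length(take) == 0L) next
      ann[[length(ann) + 1L]] <- data.table::data.table(
        gene_id = take, type = "COG", term = term)
    }
    planted[[term]] <- target_phyla
  }
  background <- data.table::data.table(
    category = cats, fraction = rep(1 / length(cats), length(cats)))
  list(annotations = data.table::rbindlist(ann),
       background = background, anchors = anchors, manifest = planted)
}

#' Write a complete synthetic bundle to disk
#'
#' Emits the exact formats the pipeline consumes: genome FASTA, GFF3,
#' protein FASTA, BLAST outfmt-6 TSVs (EBP seeds and Sigma-54 seeds),
#' domain/annotation/metadata/seed/background TSVs, the promoter PFM TSV,
#' and a ground-truth manifest JSON.  Byte-identical across runs for a
#' fixed spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if absent).
#' @return invisibly, the list of generated in-memory objects.
#' @export
write_synthetic_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genomes(spec)
  prot <- generate_proteins(spec, genes = gen$genes)
  ann <- generate_annotations(spec, gen$genes, gen$metadata)
  write_fasta(gen$genomes, file.path(dir, "genomes.fna"))
  write_gff3(gen$genes, file.path(dir, "genes.gff3"))
  write_fasta(as.list(prot$proteins), file.path(dir, "proteins.faa"))
  .write_tsv(gen$metadata, file.path(dir, "metadata.tsv"))
  .write_tsv(prot$blast_rows, file.path(dir, "ebp_blast.tsv"),
             col.names = FALSE)
  .write_tsv(prot$sigma54_rows, file.path(dir, "sigma54_blast.tsv"),
             col.names = FALSE)
  .write_tsv(prot$domains, file.path(dir, "domains.tsv"))
  .write_tsv(prot$seeds, file.path(dir, "seeds.tsv"))
  .write_tsv(prot$genome_map, file.path(dir, "genome_map.tsv"))
  .write_tsv(ann$annotations, file.path(dir, "annotations.tsv"))
  .write_tsv(ann$background, file.path(dir, "cog_background.tsv"))
  write_pfm(spec$pfm, file.path(dir, "promoter_pfm.tsv"))
  manifest <- list(seed = spec$seed,
                   genomes = gen$manifest,
                   proteins = prot$manifest,
                   enriched_terms = ann$manifest,
                   anchors = as.list(ann$anchors))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genomes = gen, proteins = prot, annotations = ann,
                 manifest = manifest))
}
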