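# Pipeline configuration and the run-all driver tying the stages together
# in the published order: EBP identification -> promoter scan/filter ->
# taxonomic survey -> genomic context and conserved tendencies.

#' Build a validated pipeline configuration
#'
#' Houses the analysis constants: the 85%-of-maximum score threshold, the
#' -50..300 promoter window, the top-15 rank cut used at the context stage,
#' the 300-nt operon gap, the 10/10 (gene context) and 1-up/10-down
#' (promoter context) window sizes, the 1e-20 Sigma-54 and coarse-annotation
#' cutoffs, and the log-product/sum e-value filters.  Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(threshold_fraction = 0.85,
              promoter_window = c(-50, 300),
              top_rank = 15L,
              max_gap = 300L,
              context_up = 10L, context_down = 10L,
              promoter_context_down = 10L,
              sigma54_cutoff = 1e-20,
              log10_product_max = -5,
              evalue_sum_max = 1,
              annotation_cutoff = 1e-20,
              k_small = 10L, k_large = 20L, large_threshold = 10L,
              min_phyla = 2L,
              hist_bin_width = 100L,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (!(cfg$threshold_fraction > 0 && cfg$threshold_fraction <= 1))
    stop("threshold_fraction must lie in (0, 1]")
  if (cfg$max_gap < 0) stop("max_gap must be >= 0")
  if (cfg$promoter_window[1L] > cfg$promoter_window[2L])
    stop("promoter_window must be ordered")
  if (cfg$top_rank < 1) stop("top_rank must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full comparative pipeline on a file bundle
#'
#' Consumes the file layout written by [write_synthetic_bundle()] (or
#' equivalent real inputs) and writes result TSVs plus a machine-readable
#' run-summary JSON to `out_dir`.  Any stage failure aborts with a
#' stage-named error and removes partial outputs.  Reruns on the same
#' inputs produce byte-identical results.
#'
#' @param input_dir directory holding genomes.fna, genes.gff3,
#'   proteins.faa, metadata.tsv, ebp_blast.tsv, sigma54_blast.tsv,
#'   domains.tsv, seeds.tsv, genome_map.tsv, annotations.tsv,
#'   cog_background.tsv and promoter_pfm.tsv.
#' @param out_dir output directory (created; cleared of pipeline outputs on
#'   failure).
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    .write_tsv(x, p)
    written <<- c(written, p)
    p
  }
  stage <- "load"
  res <- tryCatch({
    stage <- "load-inputs"
    pfm <- read_pfm(file.path(input_dir, "promoter_pfm.tsv"))
    genome <- read_fasta(file.path(input_dir, "genomes.fna"))
    genes <- read_gff3(file.path(input_dir, "genes.gff3"))
    proteins <- read_fasta(file.path(input_dir, "proteins.faa"))
    metadata <- read_tsv(file.path(input_dir, "metadata.tsv"))
    ebp_blast <- read_blast_tab(file.path(input_dir, "ebp_blast.tsv"))
    s54_blast <- read_blast_tab(file.path(input_dir, "sigma54_blast.tsv"))
    domains <- read_tsv(file.path(input_dir, "domains.tsv"))
    seeds <- read_tsv(file.path(input_dir, "seeds.tsv"))
    genome_map <- read_tsv(file.path(input_dir, "genome_map.tsv"))
    annotations <- read_tsv(file.path(input_dir, "annotations.tsv"))
    background <- read_tsv(file.path(input_dir, "cog_background.tsv"))

    stage <- "ebp-identification"
    s54 <- detect_sigma54(s54_blast, genome_map,
                          cutoff = config$sigma54_cutoff)
    ebps <- identify_ebps(ebp_blast, seeds, proteins, domains, genome_map,
                          annotation_cutoff = config$annotation_cutoff)
    emit(s54$genomes, "sigma54_presence.tsv")
    emit(ebps, "ebp_table.tsv")

    stage <- "promoter-scan"
    contig_genome <- .contig_to_genome(names(genome), genes)
    all_links <- list(); all_hits <- list()
    for (gid in unique(contig_genome$genome_id)) {
      contigs <- contig_genome[genome_id == gid]$contig
      hits <- scan_genome(pfm, genome[contigs],
                          threshold_fraction = config$threshold_fraction)
      hits <- rank_hits(hits)
      links <- link_hits_to_genes(hits, genes[genes$contig %in% contigs])
      links[, genome_id := gid]
      hits[, genome_id := gid]
      all_hits[[gid]] <- hits
      all_links[[gid]] <- links
    }
    links <- data.table::rbindlist(all_links)
    promoters <- filter_promoters(links, window = config$promoter_window)
    promoter_tbl <- data.table::copy(links)
    promoter_tbl[, passes_window := as.integer(
      orientation == "inline" & distance >= config$promoter_window[1L] &
        distance <= config$promoter_window[2L])]
    out_tbl <- promoter_tbl[, .(genome_id, contig, start = start + 1L,
                                end, strand, score, rank, gene_id,
                                distance, orientation, passes_window)]
    emit(out_tbl, "promoter_table.tsv")
    hist <- distance_histogram(links, bin_width = config$hist_bin_width)
    emit(hist, "distance_histogram.tsv")

    stage <- "taxonomic-survey"
    presence <- s54$genomes[, .(genome_id, present)]
    ebp_counts <- ebps[status == "true_ebp",
                       .(n_ebp = .N), by = genome_id]
    ebp_counts <- merge(presence[, .(genome_id)], ebp_counts,
                        by = "genome_id", all.x = TRUE)
    ebp_counts[is.na(n_ebp), n_ebp := 0L]
    phyl <- summarize_phylum(metadata, presence, ebp_counts)
    emit(phyl$summary, "phylum_summary.tsv")
    emit(bin_by_genome_size(metadata, presence), "size_bins.tsv")
    mot <- motility_and_ebp_fractions(metadata, presence, ebp_counts)
    emit(mot$motility, "motility_fractions.tsv")
    emit(mot$ebp_surface, "ebp_surface.tsv")

    stage <- "context-analysis"
    units <- build_units(genes, max_gap = config$max_gap)
    top_promoters <- filter_promoters(links,
                                      window = config$promoter_window,
                                      top_rank = config$top_rank)
    windows <- list()
    # context of Sigma-54 genes and EBP genes: +/- 10 genes
    anchor_prots <- c(s54$proteins$protein_id,
                      ebps[status == "true_ebp"]$protein_id)
    anchor_genes <- intersect(anchor_prots, genes$gene_id)
    for (ag in anchor_genes) {
      w <- context_window(genes, ag, config$context_up,
                          config$context_down)
      w$genome_id <- genes$contig[match(ag, genes$gene_id)]
      w$genome_id <- contig_genome$genome_id[
        match(w$genome_id, contig_genome$contig)]
      windows[[length(windows) + 1L]] <- w
    }
    for (r in seq_len(nrow(top_promoters))) {
      w <- promoter_context(top_promoters[r], genes, units,
                            n_down = config$promoter_context_down)
      w$genome_id <- top_promoters$genome_id[r]
      windows[[length(windows) + 1L]] <- w
    }
    profile <- collect_annotations(windows, annotations, metadata)
    gpp <- .genomes_per_phylum(windows, metadata)
    tendencies <- extract_conserved_tendencies(
      profile, gpp, k_small = config$k_small, k_large = config$k_large,
      large_threshold = config$large_threshold,
      min_phyla = config$min_phyla)
    emit(profile$counts, "context_counts.tsv")
    emit(profile$coverage, "annotation_coverage.tsv")
    emit(tendencies, "conserved_tendencies.tsv")
    rep_tbl <- cog_category_representation(windows, annotations,
                                           background)
    emit(rep_tbl, "cog_representation.tsv")

    summary <- list(package_version =
                      as.character(utils::packageVersion("sms54")),
                    seed = config$seed,
                    thresholds = config[setdiff(names(unclass(config)),
                                                "seed")],
                    n_genomes = length(unique(metadata$genome_id)),
                    n_hits = nrow(links),
                    n_promoters = nrow(promoters),
                    n_true_ebps = nrow(ebps[status == "true_ebp"]),
                    n_tendencies = nrow(tendencies),
                    outputs = basename(written))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(sigma54 = s54, ebps = ebps, links = links, promoters = promoters,
         histogram = hist, phylum_summary = phyl, units = units,
         profile = profile, tendencies = tendencies,
         representation = rep_tbl)
  }, error = function(e) {
    unlink(c(written, file.path(out_dir, "run_summary.json")))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# contigs are named after their genome in the synthetic bundle; fall back
# to identity for single-contig-per-genome layouts
.contig_to_genome <- function(contigs, genes) {
  data.table::data.table(contig = contigs, genome_id = contigs)
}

.genomes_per_phylum <- function(windows, metadata) {
  md <- data.table::as.data.table(metadata)
  gids <- unique(vapply(windows, function(w)
    as.character(w$genome_id), character(1)))
  ph <- md$phylum[match(gids, md$genome_id)]
  tab <- table(ph)
  stats::setNames(as.integer(tab), names(tab))
}
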