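# Transcriptional units (operons, divergons), genomic-context windows, and
# extraction of cross-phylum conserved function tendencies.

#' Group genes into operons and pair divergons
#'
#' Operons are maximal runs of same-strand adjacent genes with intergenic
#' gaps of at most `max_gap` nucleotides (a gap of exactly `max_gap` still
#' joins); every gene belongs to exactly one operon.  Divergons are pairs of
#' adjacent, oppositely oriented units transcribed away from each other
#' (left unit on '-', right unit on '+') whose shared upstream region — the
#' stretch between the two translation starts — is at most `max_gap` nt.
#' Same-strand overlapping genes are merged into one unit.
#'
#' @param genes data.table: `gene_id`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param max_gap maximum intergenic distance inside a unit (default 300).
#' @return list with `operons` (data.table: unit_id, contig, strand,
#'   gene_ids (list-column, genomic order), first_start, last_end) and
#'   `divergons` (data.table: divergon_id, contig, left_unit, right_unit,
#'   gap).
#' @export
build_units <- function(genes, max_gap = 300) {
  g <- data.table::as.data.table(genes)
  data.table::setorder(g, contig, start, end, gene_id)
  ops <- list(); k <- 0L
  for (ct in unique(g$contig)) {
    gc <- g[contig == ct]
    run_start <- 1L
    n <- nrow(gc)
    breaks <- integer()
    if (n > 1L) for (r in 2:n) {
      gap <- gc$start[r] - gc$end[r - 1L]
      if (gc$strand[r] != gc$strand[r - 1L] || gap > max_gap)
        breaks <- c(breaks, r)
    }
    bounds <- c(1L, breaks, n + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      rows <- bounds[b]:(bounds[b + 1L] - 1L)
      k <- k + 1L
      ops[[k]] <- data.table::data.table(
        unit_id = NA_character_, contig = ct,
        strand = gc$strand[rows[1L]],
        gene_ids = list(gc$gene_id[rows]),
        first_start = gc$start[rows[1L]],
        last_end = gc$end[rows[length(rows)]])
    }
  }
  operons <- data.table::rbindlist(ops)
  if (nrow(operons)) {
    data.table::setorder(operons, contig, first_start)
    operons[, unit_id := sprintf("op%04d", seq_len(.N))]
  } else {
    operons <- data.table::data.table(unit_id = character(),
                                      contig = character(),
                                      strand = character(),
                                      gene_ids = list(),
                                      first_start = integer(),
                                      last_end = integer())
  }
  divs <- list(); k <- 0L
  if (nrow(operons) > 1L) for (ct in unique(operons$contig)) {
    oc <- operons[contig == ct]
    if (nrow(oc) < 2L) next
    for (r in seq_len(nrow(oc) - 1L)) {
      # left unit read right-to-left ('-'), right unit left-to-right ('+'):
      # the region between their translation starts is shared upstream DNA
      if (oc$strand[r] == "-" && oc$strand[r + 1L] == "+") {
        gap <- oc$first_start[r + 1L] - oc$last_end[r]
        if (gap <= max_gap && gap >= 0L) {
          k <- k + 1L
          divs[[k]] <- data.table::data.table(
            divergon_id = NA_character_, contig = ct,
            left_unit = oc$unit_id[r], right_unit = oc$unit_id[r + 1L],
            gap = gap)
        }
      }
    }
  }
  divergons <- if (k) data.table::rbindlist(divs)
  else data.table::data.table(divergon_id = character(),
                              contig = character(),
                              left_unit = character(),
                              right_unit = character(), gap = integer())
  if (nrow(divergons))
    divergons[, divergon_id := sprintf("dv%04d", seq_len(.N))]
  list(operons = operons[], divergons = divergons[])
}

#' Genomic-context window around an anchor gene
#'
#' Up to `n_up` genes before and `n_down` genes after the anchor in genomic
#' order on the anchor's contig, truncated at contig edges.  The anchor
#' itself is not part of the window.
#'
#' @param genes gene table as in [build_units()].
#' @param anchor_gene gene id of the anchor.
#' @param n_up,n_down neighbor counts on each side (default 10).
#' @return list: `anchor`, `gene_ids` (character, genomic order).
#' @export
context_window <- function(genes, anchor_gene, n_up = 10, n_down = 10) {
  g <- data.table::as.data.table(genes)
  a <- g[gene_id == anchor_gene]
  if (nrow(a) == 0L) stop("anchor gene '", anchor_gene, "' not found")
  gc <- g[contig == a$contig[1L]]
  data.table::setorder(gc, start, end, gene_id)
  pos <- which(gc$gene_id == anchor_gene)[1L]
  up <- if (pos > 1L) gc$gene_id[max(1L, pos - n_up):(pos - 1L)]
        else character()
  dn <- if (pos < nrow(gc))
    gc$gene_id[(pos + 1L):min(nrow(gc), pos + n_down)] else character()
  list(anchor = anchor_gene, gene_ids = c(up, dn))
}

#' Context window of a putative promoter
#'
#' The genes of the transcriptional unit downstream of (and inline with)
#' the promoter, in reading order, capped at `n_down`, plus one gene
#' upstream of the promoter on the chromosome.
#'
#' @param link one row of a filtered promoter-link table (rank-cut applied
#'   by the caller).
#' @param genes gene table.
#' @param units result of [build_units()].
#' @param n_down cap on downstream unit genes (default 10).
#' @return list: `anchor` (the linked gene id), `gene_ids`.
#' @export
promoter_context <- function(link, genes, units, n_down = 10) {
  link <- data.table::as.data.table(link)
  stopifnot(nrow(link) == 1L)
  g <- data.table::as.data.table(genes)
  ops <- units$operons
  target <- link$gene_id
  hit_unit <- NULL
  for (r in seq_len(nrow(ops)))
    if (target %in% ops$gene_ids[[r]]) { hit_unit <- ops[r]; break }
  down <- if (is.null(hit_unit)) target else {
    ids <- hit_unit$gene_ids[[1L]]
    if (hit_unit$strand[1L] == "-") ids <- rev(ids)   # reading order
    from <- match(target, ids)
    ids <- ids[from:length(ids)]
    utils::head(ids, n_down)
  }
  # one upstream gene: chromosomal neighbor of the promoter on the side
  # opposite the reading direction
  gc <- g[contig == link$contig]
  data.table::setorder(gc, start, end, gene_id)
  pos11 <- link$minus11_pos
  up <- if (link$strand == "+") {
    cand <- gc[end <= pos11]
    if (nrow(cand)) cand$gene_id[nrow(cand)] else character()
  } else {
    cand <- gc[start > pos11]
    if (nrow(cand)) cand$gene_id[1L] else character()
  }
  list(anchor = target, gene_ids = unique(c(up, setdiff(down, NA))))
}

#' Lump annotations of context windows per phylum
#'
#' Counts, per phylum and annotation term, the number of context-gene
#' occurrences carrying the term (a gene appearing in several windows
#' counts once per window), and computes per-annotation-type coverage: the
#' fraction of context-gene occurrences carrying at least one term of that
#' type.
#'
#' @param windows list of context windows, each carrying `gene_ids` and a
#'   `genome_id` attribute/field.
#' @param annotations data.table: `gene_id`, `type`, `term`.
#' @param metadata data.table with `genome_id`, `phylum`.
#' @return list with `counts` (data.table: phylum, type, term, count),
#'   `coverage` (data.table: type, coverage), `n_context_genes`.
#' @export
collect_annotations <- function(windows, annotations, metadata) {
  ann <- data.table::as.data.table(annotations)
  md <- data.table::as.data.table(metadata)
  occ <- data.table::rbindlist(lapply(windows, function(w) {
    if (length(w$gene_ids) == 0L) return(NULL)
    data.table::data.table(gene_id = w$gene_ids, genome_id = w$genome_id)
  }))
  if (is.null(occ) || nrow(occ) == 0L)
    return(list(counts = data.table::data.table(phylum = character(),
                                                type = character(),
                                                term = character(),
                                                count = integer()),
                coverage = data.table::data.table(type = character(),
                                                  coverage = numeric()),
                n_context_genes = 0L))
  occ[, phylum := md$phylum[match(genome_id, md$genome_id)]]
  if (anyNA(occ$phylum)) stop("context window genome lacks a phylum label")
  occ[, occ_id := seq_len(.N)]
  hits <- merge(occ, ann, by = "gene_id", allow.cartesian = TRUE)
  counts <- hits[, .(count = .N), by = .(phylum, type, term)]
  data.table::setorder(counts, phylum, type, -count, term)
  n_occ <- nrow(occ)
  coverage <- hits[, .(coverage = length(unique(occ_id)) / n_occ),
                   by = type]
  data.table::setorder(coverage, type)
  list(counts = counts[], coverage = coverage[], n_context_genes = n_occ)
}

#' Extract cross-phylum conserved function tendencies
#'
#' Within each phylum the terms are ranked by context count; the top-K terms
#' are taken (K = `k_large` when the phylum contributed at least
#' `large_threshold` genomes, else `k_small`; ties at the boundary are all
#' included).  Terms that are top-K in at least `min_phyla` phyla are the
#' conserved tendencies.
#'
#' @param profile result of [collect_annotations()] (its `counts` is used),
#'   or a counts data.table directly.
#' @param genomes_per_phylum named integer vector: phylum -> number of
#'   genomes contributing windows.
#' @param k_small,k_large top-K sizes (defaults 10 / 20).
#' @param large_threshold genome count at/above which `k_large` applies
#'   (default 10).
#' @param min_phyla minimum number of supporting phyla (default 2).
#' @param types annotation types to consider (default all).
#' @return data.table: `term`, `type`, `n_phyla`, `phyla`
#'   (comma-separated), `ranks` (comma-separated per-phylum ranks).
#' @export
extract_conserved_tendencies <- function(profile, genomes_per_phylum,
                                         k_small = 10, k_large = 20,
                                         large_threshold = 10,
                                         min_phyla = 2, types = NULL) {
  counts <- if (is.data.frame(profile)) data.table::as.data.table(profile)
            else data.table::as.data.table(profile$counts)
  if (!is.null(types)) counts <- counts[type %in% types]
  if (nrow(counts) == 0L)
    return(data.table::data.table(term = character(), type = character(),
                                  n_phyla = integer(), phyla = character(),
                                  ranks = character()))
  topk <- counts[, {
    kk <- if (!is.na(genomes_per_phylum[phylum[1L]]) &&
              genomes_per_phylum[phylum[1L]] >= large_threshold) k_large
          else k_small
    o <- order(-count, term)
    rnk <- seq_along(o)
    sel <- o[seq_len(min(kk, length(o)))]
    # boundary ties: include every term with count >= the K-th count
    if (length(o) > kk) {
      cut_count <- count[o[kk]]
      sel <- o[count[o] >= cut_count]
    }
    .(term = term[sel], rank = match(sel, o))
  }, by = .(phylum, type)]
  tend <- topk[, .(n_phyla = length(unique(phylum)),
                   phyla = paste(phylum, collapse = ","),
                   ranks = paste(rank, collapse = ",")),
               by = .(term, type)]
  tend <- tend[n_phyla >= min_phyla]
  data.table::setorder(tend, -n_phyla, type, term)
  tend[, .(term, type, n_phyla, phyla, ranks)][]
}

#' COG functional-category representation vs a background
#'
#' Compares the fraction of context-gene category assignments in each COG
#' functional category with the background fraction (e.g. the whole COG
#' database); a category is over-represented ("+") when the observed
#' fraction exceeds background and a one-sided binomial test is significant
#' at `alpha`.
#'
#' @param windows context windows (as in [collect_annotations()]).
#' @param annotations annotation table; rows with `type == "COG_category"`
#'   are used, `term` being the one-letter category code.
#' @param background data.table: `category`, `fraction` (sums to <= 1).
#' @param alpha significance level (default 0.05).
#' @return data.table: `category`, `observed`, `expected_fraction`, `n`,
#'   `p_value`, `flag` ("+", "-", or "" when nothing is annotated).
#' @export
cog_category_representation <- function(windows, annotations, background,
                                        alpha = 0.05) {
  ann <- data.table::as.data.table(annotations)
  bg <- data.table::as.data.table(background)
  stopifnot(sum(bg$fraction) <= 1 + 1e-9)
  occ <- data.table::rbindlist(lapply(windows, function(w) {
    if (length(w$gene_ids) == 0L) return(NULL)
    data.table::data.table(gene_id = w$gene_ids)
  }))
  cats <- if (!is.null(occ) && nrow(occ))
    merge(occ, ann[type == "COG_category"], by = "gene_id",
          allow.cartesian = TRUE)
  else data.table::data.table(term = character())
  n <- nrow(cats)
  out <- lapply(seq_len(nrow(bg)), function(r) {
    cat_ <- bg$category[r]; p0 <- bg$fraction[r]
    if (n == 0L)
      return(data.table::data.table(category = cat_, observed = 0L,
                                    expected_fraction = p0, n = 0L,
                                    p_value = NA_real_, flag = ""))
    x <- sum(cats$term == cat_)
    pv <- stats::binom.test(x, n, p = p0,
                            alternative = "greater")$p.value
    flag <- if (x / n > p0 && pv < alpha) "+" else "-"
    data.table::data.table(category = cat_, observed = x,
                           expected_fraction = p0, n = n, p_value = pv,
                           flag = flag)
  })
  data.table::rbindlist(out)[]
}
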