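# Genome scanning with a promoter PFM, hit ranking, gene linkage with the
# signed -11 -> translation-start distance convention, and the distance
# histogram used to separate genuine promoters from chance matches.
#
# Coordinates are 0-based half-open on the forward strand throughout; file
# I/O converts from/to the 1-based inclusive GFF3 convention.

#' Scan a genome for motif matches on both strands
#'
#' Every window of motif width on both strands is scored with the SMS score;
#' windows scoring at least `threshold_fraction * max_score(pfm)` are
#' returned.  Overlapping hits and both-strand hits at the same span are all
#' kept.  The minus strand is scored on the reverse complement; windows
#' containing N score those positions as 0.
#'
#' @param pfm a promoter pfm with a `tss_offset` anchor.
#' @param genome named character vector of contig sequences (A,C,G,T,N), or
#'   a `Biostrings::DNAStringSet`.
#' @param threshold_fraction fraction of the maximum obtainable score, in
#'   (0, 1]; default 0.85.
#' @return data.table of hits: `contig`, `start`, `end` (0-based half-open,
#'   forward strand), `strand`, `score`, `minus11_pos` (forward-strand
#'   coordinate of the motif's -11 column).
#' @export
scan_genome <- function(pfm, genome, threshold_fraction = 0.85) {
  if (is.null(pfm$tss_offset))
    stop("promoter scanning requires a pfm with a tss_offset anchor")
  if (!(threshold_fraction > 0 && threshold_fraction <= 1))
    stop("threshold_fraction must lie in (0, 1]")
  genome <- .as_contig_vector(genome)
  cutoff <- threshold_fraction * max_score(pfm)
  out <- vector("list", 2L * length(genome))
  k <- 0L
  for (contig in names(genome)) {
    seq <- toupper(genome[[contig]])
    if (nchar(seq) < pfm$i) {
      warning("contig '", contig, "' shorter than motif width; skipped")
      next
    }
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else .revcomp(seq)
      scores <- .scan_scores(pfm, s)
      hit0 <- which(scores >= cutoff - 1e-12) - 1L  # 0-based window starts
      if (!length(hit0)) next
      if (strand == "+") {
        start <- hit0
        minus11 <- hit0 + pfm$tss_offset
      } else {
        # window at position p on the reverse complement spans forward
        # coordinates [L - p - i, L - p); its -11 column sits tss_offset
        # bases into the reading direction, i.e. at forward L - p - 1 - tss
        L <- nchar(seq)
        start <- L - hit0 - pfm$i
        minus11 <- L - hit0 - 1L - pfm$tss_offset
      }
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        contig = contig, start = start, end = start + pfm$i,
        strand = strand, score = scores[hit0 + 1L], minus11_pos = minus11)
    }
  }
  if (k == 0L)
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  score = numeric(), minus11_pos = integer()))
  res <- data.table::rbindlist(out[seq_len(k)])
  data.table::setorder(res, contig, start, strand)
  res[]
}

# vectorized sliding-window SMS scores over one oriented sequence
.scan_scores <- function(pfm, seq) {
  n <- nchar(seq)
  code <- match(.chars(seq), pfm$alphabet)      # NA for N etc.
  nwin <- n - pfm$i + 1L
  acc <- numeric(nwin)
  for (j in seq_len(pfm$i)) {
    idx <- code[j:(j + nwin - 1L)]
    contrib <- pfm$f[cbind(idx, j)]
    contrib[is.na(contrib)] <- 0
    acc <- acc + contrib
  }
  acc / pfm$i
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.as_contig_vector <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome contigs must carry unique names")
  if (any(nchar(genome) == 0L)) stop("empty contig sequence")
  as.list(genome)
}

#' Rank hits within one genome
#'
#' Descending score, ties broken by (contig, start, strand) so ranks are
#' deterministic; rank is 1-based and dense in the sense of consecutive
#' integers 1..n.
#'
#' @param hits data.table from [scan_genome()].
#' @return the hits with a `rank` column, ordered by rank.
#' @export
rank_hits <- function(hits) {
  hits <- data.table::as.data.table(hits)
  if (nrow(hits) == 0L) {
    hits[, rank := integer()]
    return(hits[])
  }
  data.table::setorder(hits, -score, contig, start, strand)
  hits[, rank := seq_len(.N)]
  hits[]
}

# forward-strand coordinate of a gene's translation start
.tls <- function(start, end, strand) ifelse(strand == "+", start, end - 1L)

#' Link motif hits to their flanking genes
#'
#' Each hit is linked to the nearest gene on each chromosomal side, located
#' by translation start.  The signed distance runs from the hit's -11
#' position to the gene's translation start, measured along the hit's
#' reading direction: positive when the start lies downstream of the
#' promoter, negative when the element sits within/downstream of the gene
#' start.  Orientation is `inline` when gene and hit share a strand,
#' `opposing` otherwise.
#'
#' @param hits (ranked) hits from [scan_genome()] / [rank_hits()].
#' @param genes data.table of gene records: `gene_id`, `contig`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @return data.table of links: all hit columns plus `gene_id`, `distance`,
#'   `orientation`.
#' @export
link_hits_to_genes <- function(hits, genes) {
  hits <- data.table::as.data.table(hits)
  genes <- data.table::as.data.table(genes)
  empty <- data.table::data.table(
    contig = character(), start = integer(), end = integer(),
    strand = character(), score = numeric(), minus11_pos = integer(),
    rank = integer(), gene_id = character(), distance = integer(),
    orientation = character())
  if (nrow(hits) == 0L) return(empty)
  if (!"rank" %in% names(hits)) hits[, rank := NA_integer_]
  out <- vector("list", nrow(hits))
  genes[, .tls_pos := .tls(start, end, strand)]
  for (h in seq_len(nrow(hits))) {
    hit <- hits[h]
    g <- genes[contig == hit$contig]
    if (nrow(g) == 0L) next
    pos <- hit$minus11_pos
    gl <- g[.tls_pos <= pos]
    gr <- g[.tls_pos > pos]
    picks <- data.table::rbindlist(list(
      if (nrow(gl)) gl[.tls_pos == max(.tls_pos)][1L] else NULL,
      if (nrow(gr)) gr[.tls_pos == min(.tls_pos)][1L] else NULL))
    if (nrow(picks) == 0L) next
    sgn <- if (hit$strand == "+") 1L else -1L
    out[[h]] <- data.table::data.table(
      hit[, .(contig, start, end, strand, score, minus11_pos, rank)],
      gene_id = picks$gene_id,
      distance = sgn * (picks$.tls_pos - pos),
      orientation = ifelse(picks$strand == hit$strand, "inline", "opposing"))
  }
  genes[, .tls_pos := NULL]
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  res[]
}

#' Filter links down to putative promoters
#'
#' Keeps inline links whose signed distance lies inside `window`
#' (default -50..300 nucleotides upstream of the translation start) and,
#' when `top_rank` is given, whose hit rank does not exceed it.  The
#' genome-wide promoter list uses the window alone; the context stage adds
#' the rank cut.
#'
#' @param links from [link_hits_to_genes()].
#' @param window length-2 numeric, inclusive distance bounds.
#' @param top_rank maximum hit rank to keep, or NULL for no rank cut.
#' @export
filter_promoters <- function(links, window = c(-50, 300), top_rank = NULL) {
  links <- data.table::as.data.table(links)
  keep <- links$orientation == "inline" &
    links$distance >= window[1L] & links$distance <= window[2L]
  if (!is.null(top_rank)) keep <- keep & !is.na(links$rank) &
      links$rank <= top_rank
  links[keep][]
}

#' Distance histogram of promoter-gene links
#'
#' Counts link distances in half-open bins `[k*w, (k+1)*w)`, split by
#' orientation; the grand total over both series is normalized to 1.
#'
#' @param links from [link_hits_to_genes()].
#' @param bin_width bin width in nucleotides (default 100).
#' @return data.table: `bin_start`, `bin_end`, `orientation`, `count`,
#'   `fraction` (fractions over both series sum to 1).
#' @export
distance_histogram <- function(links, bin_width = 100) {
  stopifnot(bin_width > 0)
  links <- data.table::as.data.table(links)
  if (nrow(links) == 0L)
    return(data.table::data.table(bin_start = numeric(), bin_end = numeric(),
                                  orientation = character(),
                                  count = integer(), fraction = numeric()))
  b <- floor(links$distance / bin_width)
  tab <- data.table::data.table(bin_start = b * bin_width,
                                orientation = links$orientation)
  h <- tab[, .(count = .N), by = .(bin_start, orientation)]
  h[, bin_end := bin_start + bin_width]
  h[, fraction := count / sum(count)]
  data.table::setorder(h, bin_start, orientation)
  h[, .(bin_start, bin_end, orientation, count, fraction)][]
}
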