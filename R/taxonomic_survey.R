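# Presence/absence summaries of Sigma-54 and activator counts across
# genomes, by phylum/class, 1-Mb genome-size bin and motility.

#' Per-phylum Sigma-54 presence and activator-count summary
#'
#' For each phylum/class: number of Sigma-54-positive genomes over the
#' total, and the mean number of EBP activators with a "discrete" standard
#' deviation — sample SD and mean both rounded to the nearest integer —
#' computed over the Sigma-54-positive genomes only.
#'
#' @param metadata data.table: `genome_id`, `phylum`, `size_bp`, `motile`
#'   (TRUE/FALSE/NA), plus free columns.
#' @param presence data.table: `genome_id`, `present` (logical).
#' @param ebp_counts data.table: `genome_id`, `n_ebp`.
#' @return list with `summary` (data.table: phylum, n_with_sigma54, n_total,
#'   mean_ebp, sd_ebp) and `excluded` (genome ids present in `presence` but
#'   lacking metadata).
#' @export
summarize_phylum <- function(metadata, presence, ebp_counts) {
  md <- data.table::as.data.table(metadata)
  pr <- data.table::as.data.table(presence)
  ec <- data.table::as.data.table(ebp_counts)
  excluded <- setdiff(pr$genome_id, md$genome_id)
  d <- merge(md, pr, by = "genome_id", all.x = TRUE)
  d <- merge(d, ec, by = "genome_id", all.x = TRUE)
  d[is.na(present), present := FALSE]
  s <- d[, {
    pos <- n_ebp[present & !is.na(n_ebp)]
    .(n_with_sigma54 = sum(present), n_total = .N,
      mean_ebp = if (length(pos)) as.integer(round(mean(pos)))
                 else NA_integer_,
      sd_ebp = if (length(pos) >= 2L) as.integer(round(stats::sd(pos)))
               else if (length(pos) == 1L) 0L else NA_integer_)
  }, by = phylum]
  data.table::setorder(s, phylum)
  list(summary = s[], excluded = excluded)
}

#' Bin genomes by size into 1-Mb half-open bins
#'
#' Bin k covers sizes `[k*bin, (k+1)*bin)`; a genome of exactly 2,000,000 bp
#' with the default bin falls in bin 2.
#'
#' @param metadata as in [summarize_phylum()].
#' @param presence as in [summarize_phylum()].
#' @param bin bin width in bp (default 1e6).
#' @return data.table: `bin` (index), `bin_start_bp`, `n_with_sigma54`,
#'   `n_without_sigma54`.
#' @export
bin_by_genome_size <- function(metadata, presence, bin = 1e6) {
  stopifnot(bin > 0)
  md <- data.table::as.data.table(metadata)
  pr <- data.table::as.data.table(presence)
  d <- merge(md, pr, by = "genome_id", all.x = TRUE)
  d[is.na(present), present := FALSE]
  if (nrow(d) == 0L)
    return(data.table::data.table(bin = integer(), bin_start_bp = numeric(),
                                  n_with_sigma54 = integer(),
                                  n_without_sigma54 = integer()))
  d[, bin_idx := floor(size_bp / bin)]
  out <- d[, .(n_with_sigma54 = sum(present),
               n_without_sigma54 = sum(!present)), by = .(bin = bin_idx)]
  out[, bin_start_bp := bin * ..bin]
  data.table::setorder(out, bin)
  out[, .(bin, bin_start_bp, n_with_sigma54, n_without_sigma54)][]
}

#' Per-bin motile fractions and EBP-count fraction surface
#'
#' For each genome-size bin and presence group, the fraction of motile
#' genomes among those whose motility is known (unknowns are excluded from
#' the denominator; a bin with no known motility reports NA).  For
#' Sigma-54-positive genomes, additionally the fraction of genomes carrying
#' each particular EBP count ("height plot" surface); fractions within a bin
#' sum to 1.
#'
#' @param metadata,presence,ebp_counts as in [summarize_phylum()].
#' @param bin bin width in bp (default 1e6).
#' @return list with `motility` (data.table: bin, group, n_known, motile_fraction)
#'   and `ebp_surface` (data.table: bin, n_ebp, fraction).
#' @export
motility_and_ebp_fractions <- function(metadata, presence, ebp_counts,
                                       bin = 1e6) {
  md <- data.table::as.data.table(metadata)
  pr <- data.table::as.data.table(presence)
  ec <- data.table::as.data.table(ebp_counts)
  d <- merge(md, pr, by = "genome_id", all.x = TRUE)
  d <- merge(d, ec, by = "genome_id", all.x = TRUE)
  d[is.na(present), present := FALSE]
  d[, bin_idx := floor(size_bp / bin)]
  motility <- d[, {
    known <- !is.na(motile)
    .(n_known = sum(known),
      motile_fraction = if (any(known)) mean(motile[known]) else NA_real_)
  }, by = .(bin = bin_idx, group = ifelse(present, "with_sigma54",
                                          "without_sigma54"))]
  data.table::setorder(motility, bin, group)
  pos <- d[present == TRUE & !is.na(n_ebp)]
  surface <- if (nrow(pos)) {
    s <- pos[, .(n = .N), by = .(bin = bin_idx, n_ebp)]
    s[, fraction := n / sum(n), by = bin]
    data.table::setorder(s, bin, n_ebp)
    s[, .(bin, n_ebp, fraction)]
  } else data.table::data.table(bin = integer(), n_ebp = integer(),
                                fraction = numeric())
  list(motility = motility[], ebp_surface = surface[])
}
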