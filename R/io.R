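# Readers and writers for the standard formats the pipeline consumes and
# emits.  Internal coordinates are 0-based half-open; GFF3 and the result
# TSVs use 1-based inclusive coordinates.

#' Read a FASTA file into a named list of sequences
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.list(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named list/vector of sequence strings.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read gene records from GFF3
#'
#' Keeps features of the configured types, converts 1-based inclusive to
#' 0-based half-open coordinates, requires a strand, and returns records
#' sorted per contig.  The gene id is taken from the `ID=` attribute (or
#' `locus_tag=` as fallback).
#'
#' @param path GFF3 file.
#' @param feature_types feature types to keep (default CDS and gene).
#' @return data.table: `gene_id`, `contig`, `start`, `end`, `strand`.
#' @export
read_gff3 <- function(path, feature_types = c("CDS", "gene")) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lnum <- which(keep)
  if (!length(lnum))
    return(data.table::data.table(gene_id = character(),
                                  contig = character(), start = integer(),
                                  end = integer(), strand = character()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop("GFF3 parse error at line ", lnum[bad[1L]],
         ": expected 9 tab-separated columns")
  m <- do.call(rbind, parts)
  skipped <- 0L
  rows <- list()
  for (r in seq_len(nrow(m))) {
    if (!(m[r, 3L] %in% feature_types)) { skipped <- skipped + 1L; next }
    s <- suppressWarnings(as.integer(m[r, 4L]))
    e <- suppressWarnings(as.integer(m[r, 5L]))
    strand <- m[r, 7L]
    if (is.na(s) || is.na(e) || e < s)
      stop("GFF3 parse error at line ", lnum[r], ": bad coordinates")
    if (!strand %in% c("+", "-"))
      stop("GFF3 parse error at line ", lnum[r], ": missing strand")
    attrs <- m[r, 9L]
    id <- sub(".*ID=([^;]+).*", "\\1", attrs)
    if (identical(id, attrs))
      id <- sub(".*locus_tag=([^;]+).*", "\\1", attrs)
    if (identical(id, attrs)) id <- sprintf("feature_%d", lnum[r])
    rows[[length(rows) + 1L]] <- data.table::data.table(
      gene_id = id, contig = m[r, 1L], start = s - 1L, end = e,
      strand = strand)
  }
  if (skipped) message(skipped, " GFF3 feature(s) of other types skipped")
  g <- data.table::rbindlist(rows)
  if (nrow(g)) data.table::setorder(g, contig, start, end, gene_id)
  g[]
}

#' Write gene records to GFF3
#' @param genes data.table with `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param path output file.
#' @param feature_type emitted feature type (default "gene").
#' @export
write_gff3 <- function(genes, path, feature_type = "gene") {
  g <- data.table::as.data.table(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(g)) {
    data.table::setorder(g, contig, start, end, gene_id)
    writeLines(sprintf("%s\tsms54\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, feature_type, g$start + 1L, g$end,
                       g$strand, g$gene_id), con)
  }
  invisible(path)
}

#' Read a 12-column BLAST tabular file (-outfmt 6)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore.  E-values in scientific notation are parsed as
#' reals; reported zeros are kept (downstream flooring handles them).
#'
#' @param path tabular file (no header).
#' @return typed data.table with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(lines)) {
    out <- .empty_blast()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("BLAST tabular parse error at line ", bad[1L],
         ": expected 12 columns, got ", lengths(parts)[bad[1L]])
  m <- do.call(rbind, parts)
  out <- data.table::data.table(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]))
  if (anyNA(out$evalue)) {
    bad <- which(is.na(out$evalue))[1L]
    stop("BLAST tabular parse error at line ", bad, ": bad e-value")
  }
  out[]
}

#' Write a PFM to its TSV exchange format
#'
#' Header lines `#name`, `#alphabet`, optionally `#tss_offset_minus11`;
#' then one row per column: 1-based column index and tab-separated
#' frequencies in alphabet order at 10 decimal digits.
#'
#' @param pfm a pfm object.
#' @param path output file.
#' @export
write_pfm <- function(pfm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#name ", pfm$name),
               paste0("#alphabet ", paste(pfm$alphabet, collapse = ""))),
             con)
  if (!is.null(pfm$tss_offset))
    writeLines(paste0("#tss_offset_minus11 ", pfm$tss_offset), con)
  for (j in seq_len(pfm$i))
    writeLines(paste(c(j, sprintf("%.10f", pfm$f[, j])), collapse = "\t"),
               con)
  invisible(path)
}

#' Read a PFM from its TSV exchange format
#'
#' Rejects rows whose frequencies deviate from sum 1 by more than 1e-6 and
#' offsets violating `0 <= tss_offset < i`.
#'
#' @param path PFM TSV file.
#' @return a pfm object (`m = 0`, externally supplied).
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, " "))]
    if (!length(h)) return(NULL)
    sub(paste0("^#", key, " +"), "", h[1L])
  }
  name <- get_hdr("name")
  alpha <- get_hdr("alphabet")
  if (is.null(alpha)) stop("PFM format error: missing #alphabet header")
  if (is.null(name)) name <- "pfm"
  alphabet <- .chars(alpha)
  tss <- get_hdr("tss_offset_minus11")
  rows <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(rows) != length(alphabet) + 1L))
    stop("PFM format error: rows must carry index + ", length(alphabet),
         " frequencies")
  f <- vapply(rows, function(r) as.numeric(r[-1L]),
              numeric(length(alphabet)))
  f <- matrix(f, nrow = length(alphabet), dimnames = list(alphabet, NULL))
  sums <- colSums(f)
  if (any(abs(sums - 1) > 1e-6))
    stop("PFM format error: column ", which(abs(sums - 1) > 1e-6)[1L],
         " frequencies sum to ", format(sums[abs(sums - 1) > 1e-6][1L]))
  new_pfm(name = name, alphabet = alphabet, f = f, m = 0L,
          tss_offset = if (is.null(tss)) NULL else as.integer(tss))
}

#' Read a simple TSV with header into a data.table
#' @param path TSV file.
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

.write_tsv <- function(x, path, col.names = TRUE) {
  data.table::fwrite(x, path, sep = "\t", col.names = col.names,
                     quote = FALSE)
  invisible(path)
}
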