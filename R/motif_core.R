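# Position-frequency matrices and the frequency-sum similarity (SMS) score.
#
# An SMS score of a length-i sequence against a PFM is the mean, over
# positions, of the input-set frequency of the observed symbol.  It ranges
# from 0 to 1, needs no pseudocounts, and its maximum over all sequences is
# the mean of the column maxima.

#' DNA alphabet used throughout the package
#' @export
DNA_ALPHABET <- c("A", "C", "G", "T")

#' The 20 standard amino acids
#' @export
PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a position frequency matrix from aligned sites
#'
#' Column frequencies are raw fractions of the input set: no pseudocounts are
#' ever added, so fully conserved or absent symbols keep frequencies of
#' exactly 1 and 0.
#'
#' @param sites character vector of equal-length strings over `alphabet`.
#' @param alphabet ordered symbol set; defaults to [DNA_ALPHABET].
#' @param name motif label.
#' @param tss_offset optional 0-based column index of the position that maps
#'   to genomic -11 relative to the transcription start (promoter motifs).
#' @return an object of class `pfm`: a list with elements `name`, `alphabet`,
#'   `i` (motif width), `f` (|alphabet| x i frequency matrix, rows named by
#'   symbol), `m` (number of source sites) and `tss_offset`.
#' @examples
#' p <- build_pfm(c("ACGT", "ACGA"))
#' score_sequence(p, "ACGA")   # (1 + 1 + 1 + 0.5) / 4
#' @export
build_pfm <- function(sites, alphabet = DNA_ALPHABET, name = "motif",
                      tss_offset = NULL) {
  if (length(sites) < 1L) stop("need at least one site")
  if (any(is.na(sites))) stop("NA site")
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L)
    stop("aligned sites must all have the same length")
  i <- widths[1L]
  if (i < 1L) stop("sites must be non-empty")
  chars <- matrix(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(sites), ncol = i, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), alphabet)
  if (length(bad))
    stop("symbol(s) outside alphabet: ", paste(bad, collapse = ", "))
  f <- vapply(seq_len(i), function(j) {
    tab <- table(factor(chars[, j], levels = alphabet))
    as.numeric(tab) / length(sites)
  }, numeric(length(alphabet)))
  f <- matrix(f, nrow = length(alphabet), ncol = i,
              dimnames = list(alphabet, NULL))
  new_pfm(name = name, alphabet = alphabet, f = f, m = length(sites),
          tss_offset = tss_offset)
}

#' Construct a pfm object from a frequency matrix
#'
#' @param name motif label
#' @param alphabet ordered symbol set
#' @param f |alphabet| x i matrix of column frequencies (each column sums
#'   to 1)
#' @param m number of source sites (0 when supplied externally)
#' @param tss_offset 0-based column index of the -11 position, or NULL
#' @export
new_pfm <- function(name, alphabet, f, m = 0L, tss_offset = NULL) {
  stopifnot(is.matrix(f), nrow(f) == length(alphabet))
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("frequencies must lie in [0, 1]")
  sums <- colSums(f)
  if (any(abs(sums - 1) > 1e-6))
    stop("pfm column frequencies must each sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  if (!is.null(tss_offset)) {
    tss_offset <- as.integer(tss_offset)
    if (tss_offset < 0L || tss_offset >= ncol(f))
      stop("tss_offset must satisfy 0 <= tss_offset < motif width")
  }
  rownames(f) <- alphabet
  structure(list(name = name, alphabet = alphabet, i = ncol(f), f = f,
                 m = as.integer(m), tss_offset = tss_offset),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm '%s': %d columns over {%s}, m = %d%s\n", x$name, x$i,
              paste(x$alphabet, collapse = ""), x$m,
              if (is.null(x$tss_offset)) ""
              else sprintf(", tss_offset = %d", x$tss_offset)))
  print(round(x$f, 3))
  invisible(x)
}

# split a string into single characters
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Score one sequence against a PFM (SMS score)
#'
#' The score is `(1/i) * sum_j f[seq[j], j]`.  Symbols outside the motif
#' alphabet (N, ambiguity codes, X, U, O) contribute frequency 0, keeping the
#' score inside `[0, 1]`.
#'
#' @param pfm a [build_pfm()] object.
#' @param seq a string of length `pfm$i`.
#' @return numeric score in `[0, 1]`.
#' @export
score_sequence <- function(pfm, seq) {
  cc <- .chars(seq)
  if (length(cc) != pfm$i)
    stop("sequence length ", length(cc), " != motif width ", pfm$i)
  idx <- match(cc, pfm$alphabet)
  keep <- !is.na(idx)
  if (!any(keep)) return(0)
  sum(pfm$f[cbind(idx[keep], which(keep))]) / pfm$i
}

#' Maximum obtainable SMS score of a PFM
#'
#' Mean of the per-column maxima; the supremum of [score_sequence()] over all
#' length-`i` strings.  Promoter scans threshold at a fraction of this value.
#'
#' @param pfm a pfm object.
#' @export
max_score <- function(pfm) {
  mean(apply(pfm$f, 2L, max))
}

#' Consensus (argmax) string of a PFM
#'
#' Ties resolved toward the earliest symbol in the alphabet.
#' @param pfm a pfm object
#' @export
consensus_string <- function(pfm) {
  paste(pfm$alphabet[apply(pfm$f, 2L, which.max)], collapse = "")
}

#' Degeneracy read-out of a motif's own build set
#'
#' Scores every build site against the PFM; the deviation of each score from
#' 1 measures how degenerate the motif is at that site.  The mean site score
#' has the closed form `(1/i) * sum_j sum_N f_N(j)^2`.
#'
#' @param pfm a pfm object built from `sites`.
#' @param sites the aligned build set (same length as `pfm$i`).
#' @return data.frame with columns `site`, `score`, `deviation`.
#' @export
degeneracy_report <- function(pfm, sites) {
  scores <- vapply(sites, function(s) score_sequence(pfm, s), numeric(1),
                   USE.NAMES = FALSE)
  data.frame(site = sites, score = scores, deviation = 1 - scores,
             stringsAsFactors = FALSE)
}

#' Per-column information content of a PFM
#'
#' `sum_N f_N log2(f_N / bg_N)` with the convention `0 * log(0) = 0`.
#'
#' @param pfm a pfm object.
#' @param background per-symbol background frequencies (default uniform).
#' @return numeric vector, one value (bits) per column.
#' @export
column_information <- function(pfm, background = NULL) {
  bg <- .check_background(background, pfm$alphabet)
  apply(pfm$f, 2L, function(col) {
    nz <- col > 0
    sum(col[nz] * log2(col[nz] / bg[nz]))
  })
}

.check_background <- function(background, alphabet) {
  if (is.null(background))
    background <- rep(1 / length(alphabet), length(alphabet))
  if (!is.null(names(background))) background <- background[alphabet]
  if (length(background) != length(alphabet) || any(is.na(background)))
    stop("background must give one frequency per alphabet symbol")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  background
}

#' Smooth uninformative columns and trim uninformative motif ends
#'
#' Columns whose information content (relative to `background`) falls below
#' `info_threshold` are replaced by the background distribution; maximal runs
#' of such columns at either end of the motif are then removed and the
#' `tss_offset` anchor is re-indexed.  This reproduces the usual motif
#' reduction step applied to a raw promoter alignment before genome
#' scanning.
#'
#' @param pfm a pfm object.
#' @param info_threshold minimum information (bits) for a column to be kept
#'   as-is; default 0.2.
#' @param background per-symbol background frequencies (default uniform).
#' @return a new pfm object, possibly narrower.
#' @export
smooth_and_trim_pfm <- function(pfm, info_threshold = 0.2,
                                background = NULL) {
  bg <- .check_background(background, pfm$alphabet)
  info <- column_information(pfm, bg)
  low <- info < info_threshold
  f <- pfm$f
  f[, low] <- bg
  keep <- which(!low)
  if (length(keep) == 0L)
    stop("smoothing removed every informative column: degenerate motif")
  first <- min(keep); last <- max(keep)
  f <- f[, first:last, drop = FALSE]
  tss <- pfm$tss_offset
  if (!is.null(tss)) {
    tss <- tss - (first - 1L)
    if (tss < 0L || tss >= ncol(f)) {
      warning("tss_offset column was trimmed; dropping the anchor")
      tss <- NULL
    }
  }
  new_pfm(name = pfm$name, alphabet = pfm$alphabet, f = f, m = pfm$m,
          tss_offset = tss)
}
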