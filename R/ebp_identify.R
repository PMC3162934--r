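# Identification and classification of Sigma-54 and its enhancer-binding
# proteins (EBPs) from homology-search tables.
#
# Candidate EBPs are filtered on their e-value profile against the 34
# experimentally verified seed activators (product < 1e-5 evaluated in
# log-space, then sum < 1), then screened for the integrity of the GAFTGA
# loop that contacts Sigma-54, and finally typed by domain architecture.

#' Detect Sigma-54 orthologs per genome
#'
#' A protein is called a Sigma-54 ortholog when its best e-value against any
#' of the (typically two: E. coli and B. subtilis) seed sequences is at or
#' below `cutoff`.  Multi-copy genomes are reported with their copy count.
#'
#' @param rows homology rows from [read_blast_tab()] (`qseqid` = seed id,
#'   `sseqid` = subject protein id).
#' @param genome_map data.frame mapping `protein_id` to `genome_id`.
#' @param cutoff e-value cutoff, default 1e-20.
#' @return list with `proteins` (data.table: protein_id, genome_id,
#'   best_evalue) and `genomes` (data.table: genome_id, present, n_copies).
#' @export
detect_sigma54 <- function(rows, genome_map, cutoff = 1e-20) {
  rows <- data.table::as.data.table(rows)
  gm <- data.table::as.data.table(genome_map)
  best <- rows[, .(best_evalue = min(evalue)), by = .(protein_id = sseqid)]
  hits <- best[best_evalue <= cutoff]
  hits <- merge(hits, gm, by = "protein_id", all.x = TRUE)
  per_genome <- hits[, .(n_copies = .N), by = genome_id]
  genomes <- merge(gm[, .(genome_id = unique(genome_id))], per_genome,
                   by = "genome_id", all.x = TRUE)
  genomes[is.na(n_copies), n_copies := 0L]
  genomes[, present := n_copies > 0L]
  list(proteins = hits[], genomes = genomes[, .(genome_id, present,
                                                n_copies)][])
}

#' Build per-protein e-value profiles against a seed set
#'
#' One row per subject protein, one column per seed.  Seeds with no reported
#' hit are imputed with `missing_value` (default 10, the classic BLAST
#' reporting ceiling); duplicate hits keep the minimum e-value; reported
#' zeros are floored at `floor_value` so log-space arithmetic stays finite.
#'
#' @param rows homology rows (`qseqid` = seed id, `sseqid` = protein id).
#' @param seed_ids character vector of expected seed ids (length 34 for the
#'   EBP screen).
#' @param missing_value imputed e-value for seeds without a hit.
#' @param floor_value lower floor applied to reported e-values.
#' @return numeric matrix, rows = proteins, columns = seeds.
#' @export
build_evalue_profiles <- function(rows, seed_ids, missing_value = 10,
                                  floor_value = 1e-200) {
  rows <- data.table::as.data.table(rows)
  unknown <- setdiff(unique(rows$qseqid), seed_ids)
  if (length(unknown))
    stop("homology rows reference unknown seed id(s): ",
         paste(unknown, collapse = ", "))
  prots <- sort(unique(rows$sseqid))
  prof <- matrix(missing_value, nrow = length(prots),
                 ncol = length(seed_ids),
                 dimnames = list(prots, seed_ids))
  best <- rows[, .(e = min(evalue)), by = .(qseqid, sseqid)]
  prof[cbind(match(best$sseqid, prots), match(best$qseqid, seed_ids))] <-
    best$e
  prof[prof < floor_value] <- floor_value
  prof
}

#' Filter candidate EBPs on their seed e-value profile
#'
#' A profile passes when the product of all seed e-values is below
#' `10^log10_product_max` AND their sum is below `sum_max`.  The product is
#' evaluated as a sum of log10 e-values: real profiles underflow a naive
#' double-precision product.
#'
#' @param profiles matrix from [build_evalue_profiles()].
#' @param log10_product_max log10 of the product cutoff (default -5).
#' @param sum_max sum cutoff (default 1).
#' @return data.table: `protein_id`, `log10_product`, `evalue_sum`, `pass`.
#' @export
filter_candidates <- function(profiles, log10_product_max = -5,
                              sum_max = 1) {
  stopifnot(is.matrix(profiles), all(profiles > 0))
  lp <- rowSums(log10(profiles))
  es <- rowSums(profiles)
  data.table::data.table(protein_id = rownames(profiles),
                         log10_product = lp, evalue_sum = es,
                         pass = lp < log10_product_max & es < sum_max)
}

#' Default GAFTGA substitution-rule table
#'
#' Per loop position, the residue sets treated as functional and as
#' putatively functional; everything else (and any deletion) abolishes the
#' Sigma-54 contact.  The canonical residue is always functional.  The sets
#' compile reported natural variants: G1->N (Paracoccus/Ruegeria), A2->S
#' (LevR), F3->Y (TouR), T4->S (BkdR) / ->E (PhhR), G5->D (FlgR), A6->S
#' (PrpR).
#'
#' @return list of six elements, each `list(functional =, putative =)`.
#' @export
default_gaftga_rules <- function() {
  list(
    list(functional = c("G", "N"), putative = c("A", "D", "E", "H", "S")),
    list(functional = c("A", "S"),
         putative = c("T", "G", "I", "V", "M", "C")),
    list(functional = c("F", "Y"), putative = character()),
    list(functional = c("T", "S", "E"), putative = "D"),
    list(functional = c("G", "D"),
         putative = c("E", "A", "H", "N", "S")),
    list(functional = c("A", "S"),
         putative = c("T", "G", "I", "V", "M", "C")))
}

#' Locate the GAFTGA window in a protein sequence
#'
#' Finds the hexamer window maximizing the protein SMS score against
#' `motif` (default: the strict GAFTGA consensus with frequency 1 per
#' column); ties go to the leftmost window.  Single-residue deletions are
#' detected by also scanning length-5 windows against the 6-column motif
#' with one column skipped (scored over the 5 matched columns, still
#' divided by 6); a gapped call is made only when it strictly beats the
#' best full-length window.
#'
#' @param protein amino-acid string, length >= 5.
#' @param motif optional protein pfm with 6 columns.
#' @return list: `window` (string), `window_start` (0-based), `gapped`
#'   (logical), `skipped_col` (1-based motif column skipped, NA if not
#'   gapped), `score`.
#' @export
locate_gaftga <- function(protein, motif = NULL) {
  if (is.null(motif)) motif <- .gaftga_consensus_pfm()
  stopifnot(motif$i == 6L)
  n <- nchar(protein)
  if (n < 5L) stop("protein too short to carry a GAFTGA window")
  aa <- .chars(toupper(protein))
  code <- match(aa, motif$alphabet)
  best6 <- -Inf; best6_at <- NA_integer_
  if (n >= 6L) {
    nwin <- n - 5L
    acc <- numeric(nwin)
    for (j in 1:6) {
      contrib <- motif$f[cbind(code[j:(j + nwin - 1L)], j)]
      contrib[is.na(contrib)] <- 0
      acc <- acc + contrib
    }
    acc <- acc / 6
    best6_at <- which.max(acc)          # leftmost maximum
    best6 <- acc[best6_at]
  }
  # gapped scan: skip one motif column, align the remaining 5
  best5 <- -Inf; best5_at <- NA_integer_; best5_skip <- NA_integer_
  nwin5 <- n - 4L
  for (skip in 1:6) {
    cols <- setdiff(1:6, skip)
    acc <- numeric(nwin5)
    for (k in seq_along(cols)) {
      contrib <- motif$f[cbind(code[k:(k + nwin5 - 1L)], cols[k])]
      contrib[is.na(contrib)] <- 0
      acc <- acc + contrib
    }
    acc <- acc / 6
    w <- which.max(acc)
    if (acc[w] > best5 + 1e-12) {
      best5 <- acc[w]; best5_at <- w; best5_skip <- skip
    }
  }
  if (is.finite(best6) && best6 >= best5 - 1e-12) {
    list(window = paste(aa[best6_at:(best6_at + 5L)], collapse = ""),
         window_start = best6_at - 1L, gapped = FALSE,
         skipped_col = NA_integer_, score = best6)
  } else {
    list(window = paste(aa[best5_at:(best5_at + 4L)], collapse = ""),
         window_start = best5_at - 1L, gapped = TRUE,
         skipped_col = best5_skip, score = best5)
  }
}

.gaftga_consensus_pfm <- function() {
  f <- matrix(0, nrow = length(PROTEIN_ALPHABET), ncol = 6,
              dimnames = list(PROTEIN_ALPHABET, NULL))
  canon <- c("G", "A", "F", "T", "G", "A")
  f[cbind(match(canon, PROTEIN_ALPHABET), 1:6)] <- 1
  new_pfm(name = "GAFTGA", alphabet = PROTEIN_ALPHABET, f = f, m = 0L)
}

#' Classify a located GAFTGA window
#'
#' Assigns each of the six positions a status (functional / putative /
#' inactive) from the substitution-rule table, then combines them: the
#' window is functional only when all six positions are, putative when none
#' is inactive and at least one is merely putative, inactive otherwise.
#' Gapped (deletion-carrying) windows are inactive outright.
#'
#' @param call result of [locate_gaftga()].
#' @param rules rule table, default [default_gaftga_rules()].
#' @return the call, augmented with `per_position_status` (character(6)) and
#'   `overall`.
#' @export
classify_gaftga <- function(call, rules = default_gaftga_rules()) {
  if (isTRUE(call$gapped)) {
    call$per_position_status <- rep("inactive", 6L)
    call$overall <- "inactive"
    return(call)
  }
  aa <- .chars(call$window)
  stopifnot(length(aa) == 6L)
  status <- vapply(1:6, function(p) {
    if (aa[p] %in% rules[[p]]$functional) "functional"
    else if (aa[p] %in% rules[[p]]$putative) "putative"
    else "inactive"
  }, character(1))
  call$per_position_status <- status
  call$overall <- if (all(status == "functional")) "functional"
  else if (!any(status == "inactive")) "putative"
  else "inactive"
  call
}

#' Type the domain architecture of a candidate EBP
#'
#' Four basic architectures of functional Sigma-54 activators, resolved with
#' precedence II > Ia > Ib > Ic: type II carries PTS-related
#' phosphorylatable domains (PRD / PTS-EII); Ia has a response-regulator
#' receiver domain preceding the central activator domain plus an HTH_8
#' DNA-binding domain; Ib has some other signal-recognition domain plus
#' HTH_8; Ic lacks the signal and/or DNA-binding domain — proteins shorter
#' than 400 residues are taken as Ic even without domain annotation.
#'
#' @param domains character vector of domain terms in N->C order; recognized
#'   vocabulary: "receiver", "HTH_8", "PAS", "GAF", "HPr", "PRD", "PTS-EII",
#'   "activator" (the central Sigma-54 interaction domain); other terms are
#'   ignored.
#' @param length protein length in residues.
#' @param signal_domains terms counting as signal-recognition domains.
#' @return one of "Ia", "Ib", "Ic", "II", "unclassified".
#' @export
classify_architecture <- function(domains, length,
                                  signal_domains = c("receiver", "PAS",
                                                     "GAF", "HPr")) {
  domains <- as.character(domains)
  if (any(domains %in% c("PRD", "PTS-EII"))) return("II")
  has_hth <- "HTH_8" %in% domains
  act_at <- match("activator", domains)
  rec_at <- match("receiver", domains)
  if (has_hth && !is.na(act_at) && !is.na(rec_at) && rec_at < act_at)
    return("Ia")
  if (has_hth && any(domains %in% signal_domains)) return("Ib")
  has_signal <- any(domains %in% signal_domains)
  if (length < 400 || !has_signal || !has_hth) return("Ic")
  "unclassified"
}

#' Coarse annotation by most similar verified seed
#'
#' The annotation group is the label of the seed with the minimum e-value in
#' the profile (ties: lexicographically first seed id); no group is assigned
#' when even the best e-value exceeds `cutoff`.
#'
#' @param profile named numeric vector of per-seed e-values (names = seed
#'   ids).
#' @param seed_groups named character vector mapping seed id to group label.
#' @param cutoff coarse-annotation e-value cutoff, default 1e-20.
#' @return group label, or `NA_character_` when unannotated.
#' @export
annotate_by_seed <- function(profile, seed_groups, cutoff = 1e-20) {
  stopifnot(!is.null(names(profile)))
  ord <- order(profile, names(profile))
  best <- ord[1L]
  if (profile[best] > cutoff) return(NA_character_)
  unname(seed_groups[names(profile)[best]])
}

#' Run the full EBP identification and classification stage
#'
#' Combines profile filtering, GAFTGA localization/classification,
#' architecture typing and coarse annotation into the published EBP table.
#'
#' @param blast_rows homology rows of seeds vs proteins.
#' @param seeds data.table: `seed_id`, `group` (and optionally `sequence`).
#' @param proteins named character vector of protein sequences.
#' @param domain_table data.table: `protein_id`, `term`, `start`, `end`.
#' @param genome_map data.frame `protein_id`, `genome_id`.
#' @param rules GAFTGA substitution-rule table.
#' @param annotation_cutoff coarse-annotation e-value cutoff.
#' @return data.table, one row per profiled protein: `protein_id`,
#'   `genome_id`, `pass_filter`, `gaftga_window`, `gaftga_status`, `status`
#'   (true_ebp / putative_ebp / rejected), `architecture`,
#'   `annotation_group`, `min_evalue_seed`.
#' @export
identify_ebps <- function(blast_rows, seeds, proteins, domain_table,
                          genome_map, rules = default_gaftga_rules(),
                          annotation_cutoff = 1e-20) {
  seeds <- data.table::as.data.table(seeds)
  domain_table <- data.table::as.data.table(domain_table)
  gm <- data.table::as.data.table(genome_map)
  prof <- build_evalue_profiles(blast_rows, seeds$seed_id)
  filt <- filter_candidates(prof)
  seed_groups <- stats::setNames(seeds$group, seeds$seed_id)
  rows <- lapply(seq_len(nrow(filt)), function(r) {
    pid <- filt$protein_id[r]
    pass <- filt$pass[r]
    pseq <- proteins[[pid]]
    gaftga <- if (!is.null(pseq) && nchar(pseq) >= 5L)
      classify_gaftga(locate_gaftga(pseq), rules)
    else list(window = NA_character_, overall = "inactive")
    doms <- domain_table[protein_id == pid]
    data.table::setorder(doms, start)
    arch <- classify_architecture(doms$term,
                                  if (!is.null(pseq)) nchar(pseq) else 0L)
    status <- if (!pass) "rejected"
    else if (gaftga$overall == "functional") "true_ebp"
    else if (gaftga$overall == "putative") "putative_ebp"
    else "rejected"
    pvec <- prof[pid, ]
    data.table::data.table(
      protein_id = pid,
      genome_id = gm$genome_id[match(pid, gm$protein_id)],
      pass_filter = pass,
      gaftga_window = gaftga$window,
      gaftga_status = gaftga$overall,
      status = status,
      architecture = arch,
      annotation_group = if (pass)
        annotate_by_seed(pvec, seed_groups, annotation_cutoff)
      else NA_character_,
      min_evalue_seed = names(pvec)[order(pvec, names(pvec))[1L]])
  })
  data.table::rbindlist(rows)[]
}
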