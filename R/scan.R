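#' Scan a genome for protein fossils
#'
#' Runs the frameshift-aware aligner over sliding windows of each genome
#' sequence (both strands), merges duplicate hits recovered from overlapping
#' windows, and culls alignments contained in higher-scoring ones.  Windowing
#' is lossless for any hit shorter than `overlap_bp`.  Simple repeats are
#' soft-masked once, genome-wide, before scanning.
#'
#' @param genome named character vector of DNA sequences (or a FASTA path)
#' @param protein query protein string (or a FASTA path with one record)
#' @param params an [alignment_params()] object
#' @param window_bp,overlap_bp window size and inter-window overlap;
#'   `window_bp` must exceed `overlap_bp`, and `overlap_bp` should exceed the
#'   longest expected hit
#' @param min_score score cutoff; by default calibrated with
#'   [score_threshold()]
#' @param expected_hits tolerated expected chance hits in the searched space;
#'   the default NULL uses one chance hit per 1e9 bp (the usual fossil-search
#'   stringency), i.e. `genome bp / 1e9`
#' @param seed passed to [score_threshold()] when `min_score` is NULL
#' @param mask whether to soft-mask simple repeats first
#' @return list of `dna_protein_alignment` objects (each carrying a `seqname`
#'   field), sorted by (score desc, start asc), with the used cutoff as
#'   attribute `min_score`
#' @export
scan_genome <- function(genome, protein, params, window_bp = 10000L,
                        overlap_bp = 2000L, min_score = NULL,
                        expected_hits = NULL, seed = 1L, mask = TRUE) {
  if (length(genome) == 1 && !grepl("[ACGTacgt]{10}", genome) &&
      file.exists(genome))
    genome <- read_fasta(genome)
  if (length(protein) == 1 && file.exists(protein))
    protein <- read_fasta(protein)[[1]]
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  if (window_bp < 3) stop("window_bp must be at least one codon (3 bp)")
  if (window_bp <= overlap_bp) stop("window_bp must exceed overlap_bp")
  if (is.null(min_score)) {
    space <- sum(nchar(genome))
    if (is.null(expected_hits)) expected_hits <- space / 1e9
    min_score <- score_threshold(params, space,
                                 expected_hits = expected_hits, seed = seed)
  }
  hits <- list()
  for (sq in names(genome)) {
    dna <- genome[[sq]]
    if (mask) dna <- mask_simple_repeats(dna)
    L <- nchar(dna)
    starts <- seq(0L, max(0L, L - 1L), by = window_bp - overlap_bp)
    starts <- starts[starts == 0L | starts + overlap_bp < L]
    for (ws in starts) {
      wseq <- substr(dna, ws + 1, min(ws + window_bp, L))
      if (nchar(wseq) < 3) next
      als <- align_local(wseq, protein, params, min_score = min_score)
      for (al in als) {
        al$dna_interval <- al$dna_interval + ws
        al$seqname <- sq
        hits[[length(hits) + 1]] <- al
      }
    }
  }
  # merge duplicates found in overlapping windows
  if (length(hits) > 0) {
    key <- vapply(hits, function(h)
      paste(h$seqname, h$dna_interval[1], h$dna_interval[2], h$strand,
            h$score, sep = ":"), "")
    hits <- hits[!duplicated(key)]
    bysq <- split(hits, vapply(hits, `[[`, "", "seqname"))
    hits <- unlist(lapply(bysq, cull_overlaps), recursive = FALSE,
                   use.names = FALSE)
    ord <- order(-vapply(hits, `[[`, 0, "score"),
                 vapply(hits, function(h) h$dna_interval[1], 0))
    hits <- hits[ord]
  }
  attr(hits, "min_score") <- as.integer(min_score)
  hits
}

hit_ids <- function(hits) {
  vapply(seq_along(hits), function(i)
    sprintf("hit%03d", i), "")
}

overlap_bp_1based <- function(s0, e0, qb, qe) {
  # s0,e0: 0-based half-open; qb,qe: 1-based inclusive
  as.integer(max(0, min(e0, qe) - max(s0, qb - 1)))
}

#' Assign fossil hits to repeat families
#'
#' Each hit is assigned to the repeat family (annotation `repeat_name`) with
#' maximal base-pair overlap; ties go to the lexicographically first family.
#' A hit overlapping two or more same-family annotations separated by an
#' unannotated gap of at least 1 bp, with a consensus-coordinate discontinuity
#' of at most `gap_slack` bp, has relation `spans_gap`; hits with no overlap
#' are `unannotated`; everything else is `inside`.
#'
#' @param hits list of alignments from [scan_genome()]
#' @param annotations data.frame from [parse_rm_out()]
#' @param other_below families with fewer hits than this are pooled into an
#'   `Other` row of the count table
#' @param gap_slack maximum consensus-coordinate discontinuity for a spanned
#'   gap to count as the same element
#' @return list with `summaries` (data.frame: hit_id, family, overlap_bp,
#'   relation) and `family_table` (data.frame: family, count)
#' @export
assign_families <- function(hits, annotations, other_below = 2L,
                            gap_slack = 5000L) {
  ids <- hit_ids(hits)
  summaries <- do.call(rbind, lapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    sq <- if (!is.null(h$seqname)) h$seqname else annotations$query_name[1]
    s0 <- h$dna_interval[1]; e0 <- h$dna_interval[2]
    ann <- annotations[annotations$query_name == sq, , drop = FALSE]
    if (nrow(ann) > 0) {
      ov <- vapply(seq_len(nrow(ann)), function(k)
        overlap_bp_1based(s0, e0, ann$query_begin[k], ann$query_end[k]), 0L)
    } else ov <- integer(0)
    touched <- which(ov > 0)
    if (length(touched) == 0)
      return(data.frame(hit_id = ids[i], family = NA_character_,
                        overlap_bp = 0L, relation = "unannotated",
                        stringsAsFactors = FALSE))
    fam_ov <- tapply(ov[touched], ann$repeat_name[touched], sum)
    fam <- sort(names(fam_ov)[fam_ov == max(fam_ov)])[1]
    rel <- "inside"
    same <- touched[ann$repeat_name[touched] == fam]
    if (length(same) >= 2) {
      a2 <- ann[same, , drop = FALSE]
      a2 <- a2[order(a2$query_begin), , drop = FALSE]
      for (k in seq_len(nrow(a2) - 1)) {
        genomic_gap <- a2$query_begin[k + 1] - a2$query_end[k] - 1
        cons_jump <- abs(a2$consensus_begin[k + 1] - a2$consensus_end[k])
        if (genomic_gap >= 1 && cons_jump <= gap_slack) rel <- "spans_gap"
      }
    }
    data.frame(hit_id = ids[i], family = fam,
               overlap_bp = as.integer(max(fam_ov)), relation = rel,
               stringsAsFactors = FALSE)
  }))
  counts <- table(summaries$family[!is.na(summaries$family)])
  tab <- data.frame(family = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$family), ]
  small <- tab$count < other_below
  if (any(small)) {
    tab <- rbind(tab[!small, ],
                 data.frame(family = "Other", count = sum(tab$count[small])))
  }
  rownames(tab) <- NULL
  list(summaries = summaries, family_table = tab)
}

#' Project a hit onto repeat-consensus coordinates
#'
#' The genomic offsets of the hit within each overlapped annotation are mapped
#' linearly onto the annotation's consensus interval, respecting strand
#' (`C`-strand annotations map reversed).  Offsets are rounded down
#' (`floor`) onto consensus positions.
#'
#' @param hit one alignment
#' @param annotations data.frame from [parse_rm_out()]
#' @return data.frame (family, cons_start, cons_end, 1-based inclusive),
#'   sorted by cons_start
#' @export
project_to_consensus <- function(hit, annotations) {
  sq <- if (!is.null(hit$seqname)) hit$seqname else annotations$query_name[1]
  s0 <- hit$dna_interval[1]; e0 <- hit$dna_interval[2]
  ann <- annotations[annotations$query_name == sq, , drop = FALSE]
  out <- data.frame()
  for (k in seq_len(nrow(ann))) {
    qb <- ann$query_begin[k]; qe <- ann$query_end[k]
    if (overlap_bp_1based(s0, e0, qb, qe) == 0) next
    if (is.na(ann$consensus_begin[k]) || ann$consensus_begin[k] <= 0) {
      warning("annotation ", ann$annot_id[k],
              " lacks consensus coordinates; skipped")
      next
    }
    glen <- qe - qb + 1
    cb <- ann$consensus_begin[k]; ce <- ann$consensus_end[k]
    clen <- ce - cb + 1
    # overlap in 1-based genomic coordinates
    g1 <- max(s0 + 1, qb); g2 <- min(e0, qe)
    map <- function(g) floor((g - qb) * clen / glen)
    if (ann$strand[k] == "+") {
      ival <- c(cb + map(g1), cb + map(g2))
    } else {
      ival <- c(ce - map(g2), ce - map(g1))
    }
    out <- rbind(out, data.frame(family = ann$repeat_name[k],
                                 cons_start = min(ival),
                                 cons_end = max(ival),
                                 stringsAsFactors = FALSE))
  }
  if (nrow(out) > 0) out <- out[order(out$cons_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hits suitable for ancestral reconstruction
#'
#' A hit qualifies when its protein coverage misses fewer than
#' `max_missing_start` residues at the protein start and fewer than
#' `max_missing_end` at the end.  Qualifying hits are returned as DNA
#' segments extended by `flank` bp on both sides (clipped at sequence
#' bounds) and reverse-complemented where needed so every segment reads in
#' the protein-forward orientation.
#'
#' @param hits list of alignments from [scan_genome()]
#' @param genome named character vector of sequences the hits refer to
#' @param protein_length query protein length in residues
#' @param max_missing_start,max_missing_end tolerated missing residues
#' @param flank bp added on each side
#' @return data.frame: hit_id, seqname, start, end (flanked, 0-based
#'   half-open), strand, seq (oriented segment)
#' @export
select_for_reconstruction <- function(hits, genome, protein_length,
                                      max_missing_start = 10L,
                                      max_missing_end = 30L, flank = 200L) {
  stopifnot(protein_length > max_missing_start + max_missing_end)
  ids <- hit_ids(hits)
  rows <- list()
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    ok <- h$protein_interval[1] < max_missing_start &&
      h$protein_interval[2] > protein_length - max_missing_end
    if (!ok) next
    sq <- if (!is.null(h$seqname)) h$seqname else names(genome)[1]
    L <- nchar(genome[[sq]])
    s <- max(0L, h$dna_interval[1] - flank)
    e <- min(L, h$dna_interval[2] + flank)
    seg <- substr(genome[[sq]], s + 1, e)
    if (h$strand == "-") seg <- revcomp(seg)
    rows[[length(rows) + 1]] <- data.frame(
      hit_id = ids[i], seqname = sq, start = s, end = e, strand = h$strand,
      seq = toupper(seg), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(hit_id = character(0), seqname = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0)))
  do.call(rbind, rows)
}
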