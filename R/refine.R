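dna_submat <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

# Align one segment to the consensus (ends-free affine DNA-DNA alignment) and
# return its letters laid out on consensus coordinates plus the insertions.
stack_one <- function(segment, consensus, submat, gap_open, gap_extend) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(segment), Biostrings::DNAString(consensus),
    type = "overlap", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  L <- nchar(consensus)
  row <- rep("", L)                       # "" = not covered by this segment
  ins <- list()
  pos <- Biostrings::start(Biostrings::subject(al)) - 1L  # consensus 0-based
  if (pos > 0) row[seq_len(pos)] <- ""
  for (k in seq_along(sub)) {
    if (sub[k] == "-") {                  # insertion relative to consensus
      key <- as.character(pos)
      ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]],
                           pat[k])
    } else {
      pos <- pos + 1L
      row[pos] <- if (pat[k] == "-") "-" else pat[k]
    }
  }
  # left-align insertions (indel normalization): equivalent placements inside
  # tandem context otherwise split the votes across adjacent slots
  if (length(ins)) {
    cons_chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
    shifted <- list()
    for (key in names(ins)) {
      c0 <- as.integer(key); s <- ins[[key]]
      while (c0 > 0 && substr(s, nchar(s), nchar(s)) == cons_chars[c0]) {
        s <- paste0(cons_chars[c0], substr(s, 1, nchar(s) - 1))
        c0 <- c0 - 1L
      }
      k2 <- as.character(c0)
      shifted[[k2]] <- paste0(s,
                              if (is.null(shifted[[k2]])) "" else shifted[[k2]])
    }
    ins <- shifted
  }
  list(row = row, ins = ins, score = Biostrings::score(al))
}

call_column <- function(letters, n_seg, min_support) {
  cnt <- c(A = sum(letters == "A"), C = sum(letters == "C"),
           G = sum(letters == "G"), T = sum(letters == "T"))
  non_gap <- sum(cnt)
  gap <- n_seg - non_gap
  if (non_gap < min_support) return(NULL)
  best <- max(cnt)
  if (gap > best) return(NULL)            # gap wins only strictly
  names(cnt)[cnt == best][1]              # alphabetic tie-break A<C<G<T
}

#' Iteratively refine an ancestral consensus from decayed copies
#'
#' A Refiner-style fixpoint scheme: the starting consensus is the medoid
#' segment (maximum summed pairwise alignment score); each round aligns every
#' segment to the current consensus with an ends-free affine DNA-DNA
#' alignment, stacks segment letters on consensus columns, and calls a new
#' consensus by per-column plurality (ties broken alphabetically A<C<G<T).
#' Columns whose non-gap support falls below `min_support`, or where gaps
#' strictly outnumber the best letter, are dropped; new columns are created
#' where a strict majority of segments insert the same position relative to
#' the consensus.  Iteration stops when the consensus is unchanged or after
#' `max_iters` rounds.
#'
#' @param segments character vector of >= 2 DNA segments, all oriented the
#'   same way
#' @param max_iters maximum refinement rounds
#' @param min_support minimum non-gap support to keep a column (trims ragged
#'   flank-derived ends)
#' @param match,mismatch,gap_open,gap_extend DNA-DNA alignment scores
#' @return a `consensus_model`: `consensus` (DNA string), `column_support`
#'   (5 x L counts of A,C,G,T,gap per column), `n_iterations`, `converged`,
#'   `mean_identity` (per-round mean segment-to-consensus identity)
#' @export
refine <- function(segments, max_iters = 10L, min_support = 3L,
                   match = 1, mismatch = -1, gap_open = 5, gap_extend = 1) {
  segments <- toupper(as.character(segments))
  if (length(segments) < 2) stop("need at least 2 segments")
  if (any(nchar(segments) == 0)) stop("empty segment supplied")
  n_seg <- length(segments)
  submat <- dna_submat(match, mismatch)
  # medoid seed: segment with maximum summed alignment score to the others
  sc <- matrix(0, n_seg, n_seg)
  for (i in seq_len(n_seg - 1)) for (j in (i + 1):n_seg) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(segments[i]), Biostrings::DNAString(segments[j]),
      type = "overlap", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    sc[i, j] <- sc[j, i] <- s
  }
  consensus <- segments[which.max(rowSums(sc))]
  converged <- FALSE
  mean_identity <- numeric(0)
  stacks <- NULL
  for (iter in seq_len(max_iters)) {
    stacks <- lapply(segments, stack_one, consensus = consensus,
                     submat = submat, gap_open = gap_open,
                     gap_extend = gap_extend)
    rows <- do.call(rbind, lapply(stacks, `[[`, "row"))
    cons_chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
    ident <- vapply(seq_len(n_seg), function(i) {
      covered <- rows[i, ] != "" & rows[i, ] != "-"
      if (!any(covered)) return(0)
      sum(rows[i, covered] == cons_chars[covered]) / sum(covered)
    }, 0)
    mean_identity <- c(mean_identity, mean(ident))
    L <- nchar(consensus)
    # insertion calling: pool votes over a 3-slot window (equivalent indel
    # placements scatter over adjacent slots in repeat context), require a
    # strict majority of the segments covering the site, and insert the
    # plurality string (ties broken lexicographically)
    ins_by_slot <- lapply(stacks, function(st) {
      v <- unlist(st$ins)
      if (is.null(v)) return(integer(0))
      stats::setNames(as.integer(names(st$ins)), NULL)
    })
    coverage_at <- function(slot) {
      left <- max(slot, 1L); right <- min(slot + 1L, L)
      sum(rows[, left] != "" | rows[, right] != "")
    }
    ins_plan <- rep(NA_character_, L + 1)   # planned insert after slot 0..L
    c0 <- 0L
    while (c0 <= L) {
      window <- c0:min(c0 + 2L, L)
      votes <- vapply(seq_len(n_seg), function(i) {
        slots <- ins_by_slot[[i]]
        w <- slots[slots %in% window]
        if (length(w) == 0) return(NA_character_)
        stacks[[i]]$ins[[as.character(min(w))]]
      }, "")
      have <- !is.na(votes)
      if (sum(have) >= min_support && sum(have) > coverage_at(c0) / 2) {
        tab <- sort(table(votes[have]), decreasing = TRUE)
        best <- names(tab)[tab == max(tab)]
        ins_plan[c0 + 1] <- sort(best)[1]
        c0 <- c0 + 3L
      } else c0 <- c0 + 1L
    }
    new_parts <- character(0)
    if (!is.na(ins_plan[1])) new_parts <- ins_plan[1]
    for (c0 in seq_len(L)) {
      cal <- call_column(rows[, c0], n_seg, min_support)
      if (!is.null(cal)) new_parts <- c(new_parts, cal)
      if (!is.na(ins_plan[c0 + 1])) new_parts <- c(new_parts, ins_plan[c0 + 1])
    }
    new_consensus <- paste(new_parts, collapse = "")
    if (identical(new_consensus, consensus)) { converged <- TRUE; break }
    consensus <- new_consensus
  }
  rows <- do.call(rbind, lapply(stacks, `[[`, "row"))
  support <- apply(rows, 2, function(col) {
    c(A = sum(col == "A"), C = sum(col == "C"), G = sum(col == "G"),
      T = sum(col == "T"),
      gap = sum(col == "-" | col == ""))
  })
  structure(list(consensus = consensus, column_support = support,
                 n_iterations = iter, converged = converged,
                 mean_identity = mean_identity),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model: %d bp, %d iteration(s), converged: %s\n",
              nchar(x$consensus), x$n_iterations, x$converged))
  invisible(x)
}

#' Find open reading frames in all six frames
#'
#' An ORF is a maximal run of non-stop codons in one reading frame
#' (stop-to-stop; no start codon required).  The interval excludes the
#' terminating stop codon, so an ORF of length `3n` encodes `n` residues.
#' Coordinates are 0-based half-open on the forward strand of the input.
#'
#' @param consensus DNA string
#' @param min_len_bp minimum ORF length (>= 30)
#' @return data.frame sorted by length descending: start, end, strand, frame,
#'   length_bp, protein
#' @export
find_orfs <- function(consensus, min_len_bp = 300L) {
  stopifnot(min_len_bp >= 30)
  L <- nchar(consensus)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(consensus) else revcomp(toupper(consensus))
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3
      if (n_cod < 1) next
      codons <- substring(s, frame + 1 + 3 * (0:(n_cod - 1)),
                          frame + 3 * (1:n_cod))
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      r <- rle(!is_stop)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values & r$lengths * 3 >= min_len_bp)) {
        cs <- frame + 3 * (starts[k] - 1)        # 0-based on strand s
        ce <- frame + 3 * ends[k]
        iv <- if (strand == "+") c(cs, ce) else c(L - ce, L - cs)
        out[[length(out) + 1]] <- data.frame(
          start = iv[1], end = iv[2], strand = strand, frame = frame,
          length_bp = ce - cs,
          protein = translate_dna(substr(s, cs + 1, ce)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_bp = integer(0), protein = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(-res$length_bp, res$start), ]
  rownames(res) <- NULL
  res
}

#' Does an ORF encompass a homology interval?
#'
#' TRUE iff the ORF interval covers `homology_interval` within `slack_bp` at
#' each end.  A degenerate empty homology interval is covered by convention.
#'
#' @param orf one row of [find_orfs()] output (or a list with start/end)
#' @param homology_interval c(start, end), 0-based half-open, same consensus
#' @param slack_bp tolerated overhang per end
#' @return logical
#' @export
check_encompasses <- function(orf, homology_interval, slack_bp = 0L) {
  hs <- homology_interval[1]; he <- homology_interval[2]
  if (he <= hs) {
    message("empty homology interval: encompassed by convention")
    return(TRUE)
  }
  orf$start <= hs + slack_bp && orf$end >= he - slack_bp
}
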