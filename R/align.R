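OP_NT <- c(3L, 2L, 4L, 0L, 3L)   # nt consumed per op code 1..5
OP_AA <- c(1L, 1L, 1L, 1L, 0L)   # aa consumed per op code
OP_NAME <- c("match", "fs_minus", "fs_plus", "deletion", "insertion")

sanitize_dna <- function(dna) {
  if (grepl("[^ACGTNacgtn]", dna)) {
    warning("non-ACGTN letters treated as N")
    dna <- gsub("[^ACGTNacgtn]", "N", dna)
  }
  dna
}

# Build the per-column description of one alignment from the C++ op string.
# Coordinates in `dna` are 0-based on the strand that was aligned.
build_columns <- function(ops, dna, protein, dna_start, prot_start, params) {
  n <- length(ops)
  codon <- character(n); aa <- character(n)
  dlen <- OP_NT[ops]; masked <- logical(n); score <- integer(n)
  i <- dna_start; j <- prot_start
  up <- toupper(dna)
  prot_chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  for (k in seq_len(n)) {
    op <- ops[k]
    if (op %in% c(1L, 2L, 3L)) {           # codon column (maybe frameshift)
      i <- i + dlen[k]
      codon[k] <- substr(up, i - 2, i)
      aa[k] <- prot_chars[j + 1]
      j <- j + 1
      masked[k] <- grepl("[acgtn]", substr(dna, i - 2, i))
      score[k] <- subst_score_of(params, codon[k], aa[k], masked[k])
    } else if (op == 4L) {                 # unaligned protein letter
      codon[k] <- "-"
      aa[k] <- prot_chars[j + 1]
      j <- j + 1
    } else {                               # unaligned codon
      i <- i + 3
      codon[k] <- substr(up, i - 2, i)
      aa[k] <- "-"
      masked[k] <- grepl("[acgtn]", substr(dna, i - 2, i))
    }
  }
  data.frame(op = OP_NAME[ops], codon = codon, aa = aa,
             frameshift = ops %in% c(2L, 3L), subst = score,
             masked = masked, stringsAsFactors = FALSE)
}

subst_score_of <- function(params, codon, aa, masked = FALSE) {
  ci <- match(codon, CODONS); ai <- match(aa, AA21)
  if (is.na(ci) || is.na(ai)) return(0L)
  s <- params$subst_score[ci, ai]
  if (masked) s <- min(s, 0L)
  s
}

alignment_identity <- function(columns) {
  cc <- columns[columns$op %in% c("match", "fs_minus", "fs_plus"), , drop = FALSE]
  if (nrow(cc) == 0) return(0)
  tr <- CODON_AA[match(cc$codon, CODONS)]
  100 * sum(!is.na(tr) & tr == cc$aa) / nrow(cc)
}

#' Frameshift-tolerant local alignment of DNA against a protein
#'
#' Dynamic programming over DNA position x protein position with a codon match
#' state (3 nt / 1 aa), frameshift transitions consuming 2 or 4 nt charged
#' `frameshift_penalty`, and affine gap states for unaligned protein letters
#' and unaligned codons.  Both strands of the DNA are searched.  Soft-masked
#' (lowercase) positions have substitution scores capped at 0; codons
#' containing N score 0 against everything.
#'
#' @param dna DNA string (soft-masking lowercase honoured)
#' @param protein protein string (letters outside the 21-letter alphabet,
#'   e.g. X, score 0 against every codon)
#' @param params an [alignment_params()] object
#' @param min_score minimum reported score
#' @param strands which strands to search
#' @return a list of `dna_protein_alignment` objects sorted by
#'   (score desc, DNA start asc); each has `dna_interval` (0-based half-open,
#'   forward-strand coordinates), `strand`, `protein_interval`, `score`,
#'   `identity` (percent of codon columns translating exactly to the aligned
#'   residue) and a per-column table
#' @export
align_local <- function(dna, protein, params, min_score = 1L,
                        strands = c("+", "-")) {
  stopifnot(inherits(params, "alignment_params"))
  if (nchar(dna) == 0 || nchar(protein) == 0)
    stop("sequences must be non-empty")
  dna <- sanitize_dna(dna)
  pidx <- protein_indices(protein)
  L <- nchar(dna)
  hits <- list()
  for (strand in strands) {
    s_dna <- if (strand == "+") dna else revcomp(dna)
    raw <- fs_align_cpp(s_dna, pidx, params$subst_score,
                        params$gap_open_del, params$gap_extend_del,
                        params$gap_open_ins, params$gap_extend_ins,
                        params$frameshift_penalty,
                        as.integer(min_score), FALSE)
    for (r in raw) {
      cols <- build_columns(r$ops, s_dna, protein, r$dna_start, r$prot_start,
                            params)
      iv <- if (strand == "+") c(r$dna_start, r$dna_end)
            else c(L - r$dna_end, L - r$dna_start)
      al <- structure(list(
        dna_interval = iv, strand = strand,
        protein_interval = c(r$prot_start, r$prot_end),
        score = r$score, identity = alignment_identity(cols),
        columns = cols, masked_flags = cols$masked),
        class = "dna_protein_alignment")
      hits[[length(hits) + 1]] <- al
    }
  }
  ord <- order(-vapply(hits, `[[`, 0, "score"),
               vapply(hits, function(h) h$dna_interval[1], 0))
  hits[ord]
}

#' @export
print.dna_protein_alignment <- function(x, ...) {
  cat(sprintf("DNA-protein alignment: dna [%d,%d) %s, protein [%d,%d), score %d, identity %.1f%%\n",
              x$dna_interval[1], x$dna_interval[2], x$strand,
              x$protein_interval[1], x$protein_interval[2],
              x$score, x$identity))
  invisible(x)
}

#' Soft-mask simple tandem repeats
#'
#' For each period p in 1..`period_max`, positions matching the letter p
#' before them score +1 and mismatches -3 in a running sum that resets at 0
#' (a Kadane-style scan).  Runs whose score reaches `threshold` are
#' lowercased, including the p leading positions of the repeat unit.
#' Masking is idempotent and case-insensitive; existing lowercase is kept.
#'
#' @param dna DNA string
#' @param period_max largest repeat period considered
#' @param threshold run score required to call a repeat (each matching
#'   position beyond the expected background contributes +1)
#' @return the DNA with simple repeats lowercased
#' @export
mask_simple_repeats <- function(dna, period_max = 6L, threshold = 10) {
  stopifnot(period_max >= 1)
  n <- nchar(dna)
  if (n == 0) return(dna)
  chars <- strsplit(toupper(dna), "", fixed = TRUE)[[1]]
  mask <- grepl("[acgtn]", strsplit(dna, "", fixed = TRUE)[[1]])
  for (p in seq_len(min(period_max, n - 1))) {
    v <- ifelse(chars[(p + 1):n] == chars[1:(n - p)], 1, -3)
    r <- 0; run_start <- 1L; best <- 0; best_k <- 0L
    for (k in seq_along(v)) {
      if (r + v[k] <= 0) {                     # run ends: flush if it qualified
        if (best >= threshold) mask[run_start:(best_k + p)] <- TRUE
        r <- 0; run_start <- k + 1L; best <- 0
      } else {
        r <- r + v[k]
        if (r >= best) { best <- r; best_k <- k }
      }
    }
    if (best >= threshold) mask[run_start:(best_k + p)] <- TRUE
  }
  out <- chars
  out[mask] <- tolower(out[mask])
  paste(out, collapse = "")
}

#' Calibrate a score threshold by shuffling
#'
#' Aligns i.i.d. DNA (at the background nucleotide composition implied by
#' `params$codon_freq`) against i.i.d. protein (at `params$aa_freq`, stops
#' excluded) `n_shuffles` times, fits a Gumbel distribution to the maximum
#' local scores by moment matching, and returns the smallest integer score S
#' whose expected number of chance hits in `search_space_bp` is at most
#' `expected_hits`.
#'
#' @param params an [alignment_params()] object
#' @param search_space_bp size of the DNA search space in bp
#' @param expected_hits tolerated expected chance alignments in the space
#' @param n_shuffles number of shuffles (>= 100)
#' @param seed RNG seed; the calibration is exactly reproducible
#' @param shuffle_dna_bp,protein_len size of each shuffled instance
#' @return integer score cutoff, with attributes `gumbel_loc`, `gumbel_scale`
#' @export
score_threshold <- function(params, search_space_bp, expected_hits = 1,
                            n_shuffles = 200L, seed = 1L,
                            shuffle_dna_bp = 3000L, protein_len = 300L) {
  stopifnot(inherits(params, "alignment_params"))
  if (n_shuffles < 100)
    stop("n_shuffles must be at least 100 for the tail fit")
  if (max(params$subst_score) <= 0)
    stop("degenerate matrix: no positive substitution score, no finite cutoff")
  nt_freq <- nt_background(params$codon_freq)
  aa_p <- params$aa_freq
  aa_p["*"] <- 0
  aa_p <- aa_p / sum(aa_p)
  maxes <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    d <- paste(sample(NT, shuffle_dna_bp, replace = TRUE, prob = nt_freq),
               collapse = "")
    p <- paste(sample(AA21, protein_len, replace = TRUE, prob = aa_p),
               collapse = "")
    fs_align_cpp(d, protein_indices(p), params$subst_score,
                 params$gap_open_del, params$gap_extend_del,
                 params$gap_open_ins, params$gap_extend_ins,
                 params$frameshift_penalty, 1L, TRUE)$best
  }, 0L))
  if (stats::sd(maxes) == 0)
    stop("degenerate score distribution: all shuffle maxima identical")
  g_scale <- stats::sd(maxes) * sqrt(6) / pi
  g_loc <- mean(maxes) - 0.5772156649 * g_scale
  # chance-hit rate scales linearly with searched bp (extreme-value tail)
  ratio <- (2 * search_space_bp) / shuffle_dna_bp  # both strands searched
  cutoff <- as.integer(ceiling(g_loc + g_scale * log(ratio / expected_hits)))
  cutoff <- max(cutoff, 1L)
  structure(cutoff, gumbel_loc = g_loc, gumbel_scale = g_scale)
}

nt_background <- function(codon_freq) {
  f <- numeric(4); names(f) <- NT
  for (k in seq_len(64)) {
    nts <- strsplit(CODONS[k], "", fixed = TRUE)[[1]]
    for (b in nts) f[b] <- f[b] + codon_freq[k] / 3
  }
  f / sum(f)
}

#' Remove alignments contained in higher-scoring ones
#'
#' An alignment is dropped iff its DNA interval is fully contained in the DNA
#' interval of a strictly higher-scoring retained alignment (any strand).
#' Output is ordered by (score desc, DNA start asc).
#'
#' @param alignments list of `dna_protein_alignment` objects
#' @return the retained list
#' @export
cull_overlaps <- function(alignments) {
  if (length(alignments) <= 1) return(alignments)
  sc <- vapply(alignments, `[[`, 0, "score")
  st <- vapply(alignments, function(a) a$dna_interval[1], 0)
  ord <- order(-sc, st)
  kept <- list()
  for (k in ord) {
    a <- alignments[[k]]
    contained <- any(vapply(kept, function(b)
      b$score > a$score &&
        a$dna_interval[1] >= b$dna_interval[1] &&
        a$dna_interval[2] <= b$dna_interval[2], TRUE))
    if (!contained) kept[[length(kept) + 1]] <- a
  }
  kept
}

#' Render an alignment as text
#'
#' Four-line blocks: the DNA's translation, the DNA, a match line and the
#' protein, wrapped at `width` characters.  Each codon column occupies as many
#' characters as nucleotides it consumed (3, or 2/4 at frameshifts); the match
#' glyph is `|` for an exact translation match, `:` for a positive
#' substitution score, `.` for a zero score and a space otherwise.
#' Soft-masked DNA stays lowercase.
#'
#' @param alignment a `dna_protein_alignment`
#' @param width characters per block
#' @return a single text string
#' @export
render <- function(alignment, width = 60L) {
  cols <- alignment$columns
  tln <- dna <- mat <- prt <- character(nrow(cols))
  pad_center <- function(ch, w) {
    left <- (w - 1) %/% 2
    paste0(strrep(" ", left), ch, strrep(" ", w - 1 - left))
  }
  for (k in seq_len(nrow(cols))) {
    op <- cols$op[k]
    if (op == "deletion") {
      w <- 1L; d <- "-"
    } else {
      w <- if (op == "fs_minus") 2L else if (op == "fs_plus") 4L else 3L
      d <- cols$codon[k]
      if (op == "fs_minus") d <- substr(d, 2, 3)          # shows consumed nt
      if (op == "fs_plus") d <- paste0("\\", d)           # 4th char marks skip
      if (cols$masked[k]) d <- tolower(d) else d <- toupper(d)
    }
    aa_tr <- if (op %in% c("match", "fs_minus", "fs_plus"))
      { t <- CODON_AA[match(toupper(cols$codon[k]), CODONS)]
        if (is.na(t)) "X" else t } else ""
    glyph <- if (op %in% c("match", "fs_minus", "fs_plus")) {
      if (!is.na(aa_tr) && nzchar(aa_tr) && aa_tr == cols$aa[k]) "|"
      else if (cols$subst[k] > 0) ":"
      else if (cols$subst[k] == 0) "."
      else " "
    } else " "
    tln[k] <- if (op == "insertion" || op == "deletion") strrep(" ", w)
              else pad_center(aa_tr, w)
    dna[k] <- formatC(d, width = w)
    mat[k] <- strrep(glyph, w)
    prt[k] <- if (op == "insertion") strrep("-", w)
              else if (op == "deletion") cols$aa[k]
              else pad_center(cols$aa[k], w)
  }
  lines <- vapply(list(tln, dna, mat, prt), paste, "", collapse = "")
  total <- nchar(lines[1])
  out <- character(0)
  for (off in seq(1, max(total, 1), by = width)) {
    chunk <- vapply(lines, substr, "", off, min(off + width - 1, total))
    out <- c(out, chunk, "")
  }
  paste(out, collapse = "\n")
}
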