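# Independent oracles used by the tests.  These enumerate explicitly rather
# than reusing the package's dynamic programming / greedy code paths.

# Best local DNA-protein alignment score by exhaustive enumeration of all
# monotone column sequences (start anywhere; first and last column must be a
# regular codon column; frameshift columns consume 2 or 4 nt and score the
# last 3 nt ending at the new position).
bf_best_score <- function(dna, protein, params) {
  n <- nchar(dna); m <- nchar(protein)
  up <- toupper(dna)
  maxcell <- max(params$subst_score)
  sc <- function(i) {   # substitution score for codon ending at nt i vs aa j
    codon <- substr(up, i - 2, i)
    masked <- grepl("[a-z]", substr(dna, i - 2, i))
    function(j) {
      ci <- match(codon, ervfossils::CODONS)
      ai <- match(substr(protein, j, j), ervfossils::AA21)
      if (is.na(ci) || is.na(ai)) return(0L)
      s <- params$subst_score[ci, ai]
      if (masked) min(s, 0L) else s
    }
  }
  scache <- lapply(seq_len(n), function(i) if (i >= 3) sc(i) else NULL)
  best <- 0
  go_d <- params$gap_open_del; ge_d <- params$gap_extend_del
  go_i <- params$gap_open_ins; ge_i <- params$gap_extend_ins
  fs <- params$frameshift_penalty
  rec <- function(i, j, score, last) {
    if (last == "M" && score > best) best <<- score
    # bound: even all-max codon columns cannot beat best
    if (score + maxcell * min(m - j, (n - i + 2) %/% 2) <= best) return()
    if (j < m) {
      if (i + 3 <= n) rec(i + 3, j + 1, score + scache[[i + 3]](j + 1), "M")
      if (i + 2 <= n && i >= 1)
        rec(i + 2, j + 1, score - fs + scache[[i + 2]](j + 1), "M")
      if (i + 4 <= n)
        rec(i + 4, j + 1, score - fs + scache[[i + 4]](j + 1), "M")
      rec(i, j + 1, score - (if (last == "D") ge_d else go_d), "D")
    }
    if (i + 3 <= n)
      rec(i + 3, j, score - (if (last == "I") ge_i else go_i), "I")
  }
  for (i0 in 0:max(n - 3, 0)) for (j0 in 0:max(m - 1, 0)) {
    if (i0 + 3 <= n && j0 + 1 <= m)
      rec(i0 + 3, j0 + 1, scache[[i0 + 3]](j0 + 1), "M")
  }
  best
}

# brute-force longest-ORF scanner (independent of find_orfs)
bf_longest_orf <- function(dna, min_len_bp = 30L) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(toupper(dna), revcomp(toupper(dna)))) {
    for (f in 0:2) {
      run <- 0L
      i <- f + 1
      while (i + 2 <= nchar(s)) {
        if (substr(s, i, i + 2) %in% stops) {
          if (run * 3 >= min_len_bp) best <- max(best, run * 3L)
          run <- 0L
        } else run <- run + 1L
        i <- i + 3
      }
      if (run * 3 >= min_len_bp) best <- max(best, run * 3L)
    }
  }
  best
}

# O(n^2) containment-culling oracle
bf_cull <- function(alignments) {
  keep <- rep(TRUE, length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    for (j in seq_along(alignments)) {
      b <- alignments[[j]]
      if (b$score > a$score &&
          a$dna_interval[1] >= b$dna_interval[1] &&
          a$dna_interval[2] <= b$dna_interval[2]) keep[i] <- FALSE
    }
  }
  alignments[keep]
}

# exhaustive MaxAlign oracle: best area over all subsets keeping >= 3 rows
bf_best_area <- function(rows) {
  n <- length(rows)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  best <- 0
  for (mask in 0:(2^n - 1)) {
    keep <- which(bitwAnd(bitwShiftL(1, 0:(n - 1)), mask) > 0)
    if (length(keep) < 3) next
    sub <- m[keep, , drop = FALSE]
    area <- length(keep) * sum(colSums(sub == "-") == 0)
    if (area > best) best <- area
  }
  best
}

# random alignment parameters for property tests (seed matrix + noise)
random_params <- function() {
  p <- seed_params()
  s <- p$subst_score + matrix(sample(-2:2, 64 * 21, replace = TRUE), 64, 21)
  alignment_params(s, scale = p$scale,
                   gap_open_del = sample(3:12, 1), gap_extend_del = sample(1:3, 1),
                   gap_open_ins = sample(3:12, 1), gap_extend_ins = sample(1:3, 1),
                   frameshift_penalty = sample(2:12, 1),
                   codon_freq = p$codon_freq, aa_freq = p$aa_freq)
}

toy_params <- function(match = 5L, penalty = 10L, fs = 10L) {
  alignment_params(
    {
      s <- matrix(-1L, 64, 21)
      for (k in seq_len(64)) {
        a <- match(ervfossils:::CODON_AA[k], AA21)
        if (!is.na(a)) s[k, a] <- match
      }
      s
    },
    scale = 1 / 3,
    gap_open_del = penalty, gap_extend_del = penalty,
    gap_open_ins = penalty, gap_extend_ins = penalty,
    frameshift_penalty = fs,
    codon_freq = rep(1 / 64, 64), aa_freq = rep(1 / 21, 21))
}

# simple exact back-translation (first codon of each amino acid)
back_translate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  vapply(aa, function(a) CODONS[ervfossils:::CODON_AA == a][1], "") |>
    paste(collapse = "")
}
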