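#' Alignment parameters for DNA-versus-protein alignment
#'
#' Bundles the trained 64x21 integer log-odds substitution matrix (codon rows
#' in lexicographic order AAA..TTT, protein columns in [AA21] order), the
#' affine gap penalties for unaligned protein letters (deletions) and
#' unaligned codons (insertions), the frameshift penalty charged for a
#' +/- 1-nucleotide frame change, the score scale (bits per score unit) and
#' the background codon and amino-acid frequencies.
#'
#' @param subst_score 64x21 integer matrix of substitution scores
#' @param scale bits per score unit (> 0)
#' @param gap_open_del,gap_extend_del penalties for unaligned protein letters
#' @param gap_open_ins,gap_extend_ins penalties for unaligned codons
#' @param frameshift_penalty penalty for a +/- 1 nt frame change
#' @param codon_freq 64 background codon probabilities (sum 1)
#' @param aa_freq 21 background protein-letter probabilities (sum 1)
#' @return an object of class `alignment_params`
#' @export
alignment_params <- function(subst_score, scale,
                             gap_open_del, gap_extend_del,
                             gap_open_ins, gap_extend_ins,
                             frameshift_penalty,
                             codon_freq, aa_freq) {
  subst_score <- as.matrix(subst_score)
  storage.mode(subst_score) <- "integer"
  if (!identical(dim(subst_score), c(64L, 21L)))
    stop("subst_score must be a 64x21 matrix")
  dimnames(subst_score) <- list(CODONS, AA21)
  codon_freq <- as.numeric(codon_freq)
  aa_freq <- as.numeric(aa_freq)
  if (length(codon_freq) != 64 || abs(sum(codon_freq) - 1) > 1e-9)
    stop("codon_freq must be 64 probabilities summing to 1")
  if (length(aa_freq) != 21 || abs(sum(aa_freq) - 1) > 1e-9)
    stop("aa_freq must be 21 probabilities summing to 1")
  pens <- c(gap_open_del, gap_extend_del, gap_open_ins, gap_extend_ins,
            frameshift_penalty)
  if (any(pens < 0)) stop("all penalties must be >= 0")
  if (scale <= 0) stop("scale must be > 0")
  expected <- sum(outer(codon_freq, aa_freq) * subst_score)
  if (expected >= 0)
    stop("expected substitution score under background must be negative (got ",
         format(expected), ")")
  structure(list(subst_score = subst_score, scale = scale,
                 gap_open_del = as.integer(gap_open_del),
                 gap_extend_del = as.integer(gap_extend_del),
                 gap_open_ins = as.integer(gap_open_ins),
                 gap_extend_ins = as.integer(gap_extend_ins),
                 frameshift_penalty = as.integer(frameshift_penalty),
                 codon_freq = stats::setNames(codon_freq, CODONS),
                 aa_freq = stats::setNames(aa_freq, AA21)),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat("alignment_params: 64x21 substitution matrix\n")
  cat(sprintf("  scale %.4g bits/unit; gap del %d/%d, ins %d/%d; frameshift %d\n",
              x$scale, x$gap_open_del, x$gap_extend_del,
              x$gap_open_ins, x$gap_extend_ins, x$frameshift_penalty))
  cat(sprintf("  score range [%d, %d]\n", min(x$subst_score), max(x$subst_score)))
  invisible(x)
}

#' Fixed seed parameters used to start training
#'
#' An identity-codon bonus matrix: +5 when the codon translates exactly to the
#' protein letter (including stop codons against `*`), -1 otherwise, with
#' uniform backgrounds.  This is the documented initial condition of [train()].
#'
#' @param match,mismatch scores for translating/non-translating codon cells
#' @return an `alignment_params` object
#' @export
seed_params <- function(match = 5L, mismatch = -1L) {
  s <- matrix(as.integer(mismatch), 64, 21, dimnames = list(CODONS, AA21))
  for (k in seq_len(64)) {
    a <- match(CODON_AA[k], AA21)
    if (!is.na(a)) s[k, a] <- as.integer(match)
  }
  alignment_params(s, scale = 1 / 3,
                   gap_open_del = 12L, gap_extend_del = 2L,
                   gap_open_ins = 12L, gap_extend_ins = 2L,
                   frameshift_penalty = 12L,
                   codon_freq = rep(1 / 64, 64), aa_freq = rep(1 / 21, 21))
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write alignment parameters to a plain-text file
#'
#' Header lines carry the scale, penalties and background frequencies; the
#' body is 64 rows (lexicographic codons AAA..TTT) by 21 columns
#' (ARNDCQEGHILKMFPSTWYV*) of integer scores.  [read_params()] inverts this
#' exactly: `read_params(write_params(p, f))` equals `p`.
#'
#' @param params an `alignment_params` object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "alignment_params"))
  con <- file(path, "wb")  # binary mode: byte-stable newlines across platforms
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w("# ervfossils DNA-protein alignment parameters")
  w("scale ", fmt_num(params$scale))
  w("gap_open_del ", params$gap_open_del)
  w("gap_extend_del ", params$gap_extend_del)
  w("gap_open_ins ", params$gap_open_ins)
  w("gap_extend_ins ", params$gap_extend_ins)
  w("frameshift_penalty ", params$frameshift_penalty)
  w("codon_freq ", paste(fmt_num(params$codon_freq), collapse = " "))
  w("aa_freq ", paste(fmt_num(params$aa_freq), collapse = " "))
  w("# subst_score: rows AAA..TTT, columns ", paste(AA21, collapse = ""))
  for (k in seq_len(64))
    w(CODONS[k], " ", paste(params$subst_score[k, ], collapse = " "))
  invisible(path)
}

#' Read alignment parameters written by [write_params()]
#'
#' @param path file path
#' @return an `alignment_params` object
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(trimws(lines), "\\s+")
  kv <- list()
  rows <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    key <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals))
      stop("non-numeric entry at line ", lineno[i], " of ", path)
    if (key %in% CODONS) {
      if (length(vals) != 21)
        stop("codon row ", key, " at line ", lineno[i],
             " has ", length(vals), " scores (need 21)")
      rows[[key]] <- vals
    } else {
      kv[[key]] <- vals
    }
  }
  missing_codon <- setdiff(CODONS, names(rows))
  if (length(missing_codon))
    stop("missing codon row(s), first: ", missing_codon[1])
  need <- c("scale", "gap_open_del", "gap_extend_del", "gap_open_ins",
            "gap_extend_ins", "frameshift_penalty", "codon_freq", "aa_freq")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("missing header line(s): ", paste(miss, collapse = ", "))
  s <- do.call(rbind, rows[CODONS])
  alignment_params(s, scale = kv$scale,
                   gap_open_del = kv$gap_open_del,
                   gap_extend_del = kv$gap_extend_del,
                   gap_open_ins = kv$gap_open_ins,
                   gap_extend_ins = kv$gap_extend_ins,
                   frameshift_penalty = kv$frameshift_penalty,
                   codon_freq = kv$codon_freq, aa_freq = kv$aa_freq)
}
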