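#' @useDynLib ervfossils, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Nucleotide and codon alphabets.  Codon order is lexicographic AAA..TTT and
# is the row order of every 64x21 substitution matrix in this package.
NT <- c("A", "C", "G", "T")

#' The 64 codons in lexicographic order (AAA..TTT)
#' @export
CODONS <- paste0(rep(NT, each = 16), rep(rep(NT, each = 4), 4), rep(NT, 16))

#' The 21-letter protein alphabet used by the substitution matrix
#'
#' The 20 amino acids in the conventional order ARNDCQEGHILKMFPSTWYV plus the
#' translation-stop symbol `*`, which is what translated protein fossils
#' contain.  `X` is not part of the matrix; it scores 0 against every codon.
#' @export
AA21 <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "*")

# codon -> amino-acid letter (standard genetic code), in CODONS order
codon_aa_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[CODONS])
}

CODON_AA <- NULL  # filled at load time

.onLoad <- function(libname, pkgname) {
  CODON_AA <<- codon_aa_table()
}

#' Translate DNA in frame 0 using the standard genetic code
#'
#' Codons containing any letter other than ACGT translate to `X`; stop codons
#' translate to `*`.  Case is ignored.
#'
#' @param dna a DNA string whose length is a multiple of 3
#' @return a protein string of `nchar(dna)/3` letters
#' @examples
#' translate_dna("ATGAAAGTG")  # "MKV"
#' @export
translate_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1)
  n <- nchar(dna)
  if (n %% 3 != 0)
    stop("DNA length (", n, ") is not a multiple of 3")
  if (n == 0) return("")
  up <- toupper(dna)
  codons <- substring(up, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  aa <- CODON_AA[match(codons, CODONS)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse-complement a DNA string, preserving case
#' @param dna a DNA string (may contain N and soft-masking lowercase)
#' @return the reverse complement
#' @export
revcomp <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1)
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", dna)
  paste(rev(strsplit(flipped, "", fixed = TRUE)[[1]]), collapse = "")
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  force(expr)
}

# random DNA string at a given GC content
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(NT, n, replace = TRUE, prob = p), collapse = "")
}

# protein letter indices (0-based) for the C++ core: AA21 -> 0..20, X/other -> -1
protein_indices <- function(protein) {
  letters <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  idx <- match(letters, AA21)
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}
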