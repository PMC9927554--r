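#' Create a table of DNA/protein training pairs
#'
#' @param dna,protein character vectors of equal length
#' @param weight non-negative per-pair weights
#' @return a data.frame with class `train_pairs`
#' @export
train_pairs <- function(dna, protein, weight = 1) {
  stopifnot(length(dna) == length(protein), all(nchar(dna) > 0),
            all(nchar(protein) > 0), all(weight >= 0))
  structure(data.frame(dna = dna, protein = protein,
                       weight = rep_len(weight, length(dna)),
                       stringsAsFactors = FALSE),
            class = c("train_pairs", "data.frame"))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Train DNA-versus-protein alignment parameters
#'
#' Iterates: (i) locally align every pair under the current parameters;
#' (ii) discard alignments with identity above `max_pid` percent; (iii)
#' accumulate codon/amino-acid, gap-run and frameshift counts with a +1
#' pseudocount per cell; (iv) rebuild integer log-odds scores
#' `s(c,a) = round(log2(P(c,a) / (pi(c) rho(a))) / scale)` with the scale set
#' so the best translating-codon score is about 15, and re-derive gap and
#' frameshift penalties from observed event frequencies.  Stops when the
#' largest score change is below `tol` or after `max_iters` rounds.  The
#' initial condition is the fixed [seed_params()] identity-codon matrix.
#'
#' @param pairs a [train_pairs()] data.frame (columns dna, protein, weight)
#' @param max_pid maximum percent identity a training alignment may have;
#'   more-identical alignments carry little information about divergence and
#'   are discarded
#' @param max_iters maximum training iterations
#' @param tol convergence tolerance in score units
#' @param params0 initial parameters
#' @param target_max_score the scale is set so the best translating-codon
#'   log-odds maps to about this integer score
#' @return an `alignment_params` object with attributes `iterations`,
#'   `converged` and `counts` (the final 64x21 raw count matrix)
#' @export
train <- function(pairs, max_pid = 50, max_iters = 10L, tol = 1,
                  params0 = seed_params(), target_max_score = 15) {
  stopifnot(nrow(pairs) >= 1, max_pid > 0, max_pid <= 100)
  params <- params0
  converged <- FALSE
  counts <- NULL
  for (iter in seq_len(max_iters)) {
    counts <- matrix(0, 64, 21, dimnames = list(CODONS, AA21))
    n_fs <- 0; n_cols <- 0
    n_del_open <- 0; n_del_ext <- 0; n_ins_open <- 0; n_ins_ext <- 0
    n_survivors <- 0; n_mismatch <- 0; n_matchcol <- 0
    for (r in seq_len(nrow(pairs))) {
      als <- align_local(pairs$dna[r], pairs$protein[r], params,
                         strands = "+")
      if (length(als) == 0) next
      al <- als[[1]]
      if (al$identity > max_pid) next
      n_survivors <- n_survivors + 1
      w <- pairs$weight[r]
      cols <- al$columns
      prev_op <- ""
      for (k in seq_len(nrow(cols))) {
        op <- cols$op[k]
        if (op %in% c("match", "fs_minus", "fs_plus")) {
          ci <- match(cols$codon[k], CODONS); ai <- match(cols$aa[k], AA21)
          if (!is.na(ci) && !is.na(ai)) {
            counts[ci, ai] <- counts[ci, ai] + w
            tr <- CODON_AA[ci]
            n_matchcol <- n_matchcol + 1
            if (tr != cols$aa[k]) n_mismatch <- n_mismatch + 1
          }
          n_cols <- n_cols + w
          if (op != "match") n_fs <- n_fs + w
        } else if (op == "deletion") {
          if (prev_op == "deletion") n_del_ext <- n_del_ext + w
          else n_del_open <- n_del_open + w
          n_cols <- n_cols + w
        } else {
          if (prev_op == "insertion") n_ins_ext <- n_ins_ext + w
          else n_ins_open <- n_ins_open + w
          n_cols <- n_cols + w
        }
        prev_op <- op
      }
    }
    if (n_survivors == 0)
      stop("no training alignment passed the identity filter (max_pid = ",
           max_pid, ")")
    if (n_matchcol > 0 && n_mismatch == 0)
      warning("zero-divergence training data: all aligned codons translate ",
              "exactly; the matrix only reflects pseudocounts")

    cp <- counts + 1                       # +1 pseudocount per cell
    P <- cp / sum(cp)
    pi_c <- rowSums(P); rho_a <- colSums(P)
    L <- log2(P / outer(pi_c, rho_a))
    diag_cells <- cbind(seq_len(64), match(CODON_AA, AA21))
    scale <- max(L[diag_cells]) / target_max_score
    if (!is.finite(scale) || scale <= 0) scale <- params$scale
    s_new <- matrix(as.integer(round_half_away(L / scale)), 64, 21,
                    dimnames = list(CODONS, AA21))

    pen <- function(n_event, n_total) {
      f <- (n_event + 1) / (n_total + 2)
      max(1L, as.integer(round_half_away(-log2(f) / scale)))
    }
    new_params <- alignment_params(
      s_new, scale = scale,
      gap_open_del = pen(n_del_open, n_cols),
      gap_extend_del = pen(n_del_ext, n_del_open + n_del_ext),
      gap_open_ins = pen(n_ins_open, n_cols),
      gap_extend_ins = pen(n_ins_ext, n_ins_open + n_ins_ext),
      frameshift_penalty = pen(n_fs, n_cols),
      codon_freq = pi_c, aa_freq = rho_a)

    delta <- max(abs(new_params$subst_score - params$subst_score))
    params <- new_params
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(params, "iterations") <- iter
  attr(params, "converged") <- converged
  attr(params, "counts") <- counts
  params
}

#' Simulate DNA/protein training pairs from a coding-decay model
#'
#' Each pair is generated by drawing ancestral codons uniformly from the 61
#' non-stop codons, translating them to obtain the protein, and mutating the
#' DNA per site with the Jukes-Cantor equal-rates kernel at the given
#' divergence, optionally adding short indels.  The analytic joint
#' codon/amino-acid distribution of this process gives the ground-truth
#' log-odds matrix returned alongside the pairs.
#'
#' @param n_codons total codons across all pairs
#' @param divergence substitutions/site
#' @param n_pairs number of pairs the codons are split into
#' @param indel_rate indel events per codon
#' @param frameshift_fraction fraction of indel events that are 1 nt
#'   (frame-disrupting) instead of 3 nt
#' @param seed RNG seed
#' @param target_max_score passed to the truth-score rounding
#' @return list with `pairs` (a [train_pairs()] table), `true_scores`
#'   (64x21 integer matrix), `true_scale`
#' @export
simulate_train_pairs <- function(n_codons = 2000L, divergence = 0.3,
                                 n_pairs = 20L, indel_rate = 0,
                                 frameshift_fraction = 0, seed = 1L,
                                 target_max_score = 15) {
  sense <- CODONS[CODON_AA != "*"]
  p_sub <- 0.75 * (1 - exp(-4 * divergence / 3))
  out <- with_seed(seed, {
    per <- rep(n_codons %/% n_pairs, n_pairs)
    per[seq_len(n_codons %% n_pairs)] <- per[seq_len(n_codons %% n_pairs)] + 1
    dna <- character(n_pairs); prot <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      anc <- sample(sense, per[i], replace = TRUE)
      prot[i] <- paste(CODON_AA[match(anc, CODONS)], collapse = "")
      nts <- strsplit(paste(anc, collapse = ""), "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(nts)) < p_sub)
      for (h in hit) nts[h] <- sample(setdiff(NT, nts[h]), 1)
      d <- paste(nts, collapse = "")
      if (indel_rate > 0) {
        n_ev <- stats::rbinom(1, per[i], indel_rate)
        for (e in seq_len(n_ev)) {
          pos <- sample.int(nchar(d) - 4, 1)
          len <- if (stats::runif(1) < frameshift_fraction) 1L else 3L
          if (stats::runif(1) < 0.5)
            d <- paste0(substr(d, 1, pos), random_dna(len),
                        substr(d, pos + 1, nchar(d)))
          else
            d <- paste0(substr(d, 1, pos), substr(d, pos + len + 1, nchar(d)))
        }
      }
      dna[i] <- d
    }
    train_pairs(dna, prot)
  })
  # analytic joint: P(c, a) = sum_{c0 translating to a} u(c0) K(c0 -> c)
  K1 <- matrix(p_sub / 3, 4, 4); diag(K1) <- 1 - p_sub
  P <- matrix(0, 64, 21, dimnames = list(CODONS, AA21))
  idx <- function(codon) match(strsplit(codon, "", fixed = TRUE)[[1]], NT)
  for (c0 in sense) {
    a <- match(CODON_AA[match(c0, CODONS)], AA21)
    i0 <- idx(c0)
    for (k in seq_len(64)) {
      i1 <- idx(CODONS[k])
      P[k, a] <- P[k, a] +
        (1 / length(sense)) * K1[i0[1], i1[1]] * K1[i0[2], i1[2]] * K1[i0[3], i1[3]]
    }
  }
  pi_c <- rowSums(P); rho_a <- colSums(P)
  L <- log2(P / outer(pi_c, rho_a))
  L[P == 0] <- NA
  diag_cells <- cbind(seq_len(64), match(CODON_AA, AA21))
  true_scale <- max(L[diag_cells], na.rm = TRUE) / target_max_score
  list(pairs = out,
       true_scores = round_half_away(L / true_scale),
       true_scale = true_scale)
}
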