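#' Construct a random ancestral retroviral element
#'
#' The element mirrors a proviral layout with a protein-coding ORF upstream of
#' the gag-like internal region: 5' LTR, ORF, spacer standing in for
#' gag-pol-env, 3' LTR.  The two LTRs are identical at generation time.  The
#' ORF is built from uniformly sampled non-stop codons, so its translation is
#' stop-free, and it is bounded by in-frame stop codons (the 5' LTR ends with
#' TAA in the ORF's frame and the spacer begins with TAA), making its
#' stop-to-stop length exactly `orf_length_bp`.
#'
#' @param orf_length_bp ORF length in bp; must be a multiple of 3 and >= 30
#' @param seed RNG seed; fixed seed gives an identical element
#' @param ltr_bp,spacer_bp lengths of the LTRs and of the gag-pol-env spacer
#' @param gc GC content of the non-ORF parts
#' @return an `ancestral_element` with fields `ltr5`, `orf`,
#'   `spacer_gag_pol_env`, `ltr3`, plus `protein` and the ORF interval
#'   (0-based half-open) on the full sequence
#' @export
make_ancestor <- function(orf_length_bp = 879L, seed = 7L,
                          ltr_bp = 400L, spacer_bp = 1200L, gc = 0.5) {
  if (orf_length_bp %% 3 != 0)
    stop("orf_length_bp must be divisible by 3 (got ", orf_length_bp, ")")
  if (orf_length_bp < 30) stop("orf_length_bp must be >= 30")
  stopifnot(ltr_bp >= 3, spacer_bp >= 3)
  sense <- CODONS[CODON_AA != "*"]
  el <- with_seed(seed, {
    ltr <- random_dna(ltr_bp, gc)
    # in-frame stop immediately before the ORF lives at the LTR's 3' end
    substr(ltr, ltr_bp - 2, ltr_bp) <- "TAA"
    orf <- paste(sample(sense, orf_length_bp / 3, replace = TRUE),
                 collapse = "")
    spacer <- random_dna(spacer_bp, gc)
    substr(spacer, 1, 3) <- "TAA"          # terminating stop
    list(ltr5 = ltr, orf = orf, spacer_gag_pol_env = spacer, ltr3 = ltr)
  })
  el$protein <- translate_dna(el$orf)
  stopifnot(!grepl("*", el$protein, fixed = TRUE))
  el$orf_interval <- c(nchar(el$ltr5), nchar(el$ltr5) + orf_length_bp)
  structure(el, class = "ancestral_element")
}

#' @export
print.ancestral_element <- function(x, ...) {
  cat(sprintf("ancestral_element: LTR %d bp | ORF %d bp (%d aa) | spacer %d bp | LTR %d bp\n",
              nchar(x$ltr5), nchar(x$orf), nchar(x$protein),
              nchar(x$spacer_gag_pol_env), nchar(x$ltr3)))
  invisible(x)
}

#' Full DNA sequence of an ancestral element
#' @param ancestor an `ancestral_element`
#' @return one DNA string
#' @export
ancestor_sequence <- function(ancestor) {
  paste0(ancestor$ltr5, ancestor$orf, ancestor$spacer_gag_pol_env,
         ancestor$ltr3)
}

#' Simulation configuration for ERV proliferation and decay
#'
#' @param n_copies_per_clade copies planted per clade
#' @param n_clades number of independent proliferations (deep branches)
#' @param divergence substitutions/site on each deep branch (Jukes-Cantor);
#'   within-clade branches use `divergence / 5`
#' @param indel_rate indel events per site per branch
#' @param frameshift_fraction fraction of indel events whose length is not a
#'   multiple of 3
#' @param truncation_prob probability a copy loses a uniform-random prefix or
#'   suffix (up to 40 percent of its length)
#' @param host_length host genome length in bp
#' @param gc_content host background GC
#' @param flank minimum unplanted bp between/around copies
#' @param seed master RNG seed; fixed seed gives byte-identical outputs
#' @return a validated `simulation_config` list
#' @export
simulation_config <- function(n_copies_per_clade = 5L, n_clades = 3L,
                              divergence = 0.15, indel_rate = 0.01,
                              frameshift_fraction = 2 / 3,
                              truncation_prob = 0.3,
                              host_length = 120000L, gc_content = 0.5,
                              flank = 500L, seed = 1L) {
  rates <- c(indel_rate = indel_rate,
             frameshift_fraction = frameshift_fraction,
             truncation_prob = truncation_prob, gc_content = gc_content)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (divergence < 0) stop("divergence must be >= 0")
  stopifnot(n_copies_per_clade >= 1, n_clades >= 1, host_length > 0,
            flank >= 0)
  structure(list(n_copies_per_clade = as.integer(n_copies_per_clade),
                 n_clades = as.integer(n_clades), divergence = divergence,
                 indel_rate = indel_rate,
                 frameshift_fraction = frameshift_fraction,
                 truncation_prob = truncation_prob,
                 host_length = as.integer(host_length),
                 gc_content = gc_content, flank = as.integer(flank),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# one indel length: geometric(p = 0.5) capped at 30, conditioned on frame
# disruption (length %% 3 != 0) or preservation
indel_length <- function(frameshifting) {
  for (try in 1:100) {
    len <- min(stats::rgeom(1, 0.5) + 1, 30)
    if ((len %% 3 != 0) == frameshifting) return(len)
  }
  if (frameshifting) 1L else 3L
}

# Jukes-Cantor substitutions plus indels on one sequence.  Returns the evolved
# sequence and whether any frame-disrupting indel occurred.
mutate_seq <- function(seq, branch_length, indel_rate, frameshift_fraction,
                       gc) {
  nts <- strsplit(seq, "", fixed = TRUE)[[1]]
  p_sub <- 0.75 * (1 - exp(-4 * branch_length / 3))
  hit <- which(stats::runif(length(nts)) < p_sub)
  for (h in hit) nts[h] <- sample(setdiff(NT, toupper(nts[h])), 1)
  frameshifted <- FALSE
  n_ev <- stats::rbinom(1, length(nts), indel_rate)
  if (n_ev > 0) {
    pos <- sort(sample.int(length(nts), n_ev), decreasing = TRUE)
    for (p in pos) {
      fs <- stats::runif(1) < frameshift_fraction
      len <- indel_length(fs)
      if (fs) frameshifted <- TRUE
      if (stats::runif(1) < 0.5) {   # insertion after p
        ins <- sample(NT, len, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
        nts <- append(nts, ins, after = p)
      } else {                       # deletion starting at p
        drop <- p:min(p + len - 1, length(nts))
        nts <- nts[-drop]
      }
    }
  }
  list(seq = paste(nts, collapse = ""), frameshifted = frameshifted)
}

#' Evolve one copy of an ancestral element
#'
#' Applies per-site Jukes-Cantor substitutions at the given branch length and
#' short indels (geometric lengths, p = 0.5, capped at 30 bp;
#' `frameshift_fraction` of events have length not divisible by 3) to each
#' part of the element independently, then optionally truncates a random
#' prefix or suffix.  Uses the current RNG state; seed the caller.
#'
#' @param ancestor an [make_ancestor()] element (or an evolved copy of one)
#' @param branch_length substitutions/site (>= 0)
#' @param config a [simulation_config()]; only the mutation-rate fields are
#'   used
#' @param truncate whether truncation may be applied
#' @return list with `seq` (the full evolved copy), `parts` (evolved element,
#'   reusable as an ancestor), `orf_intact` (TRUE iff the ORF region kept its
#'   reading frame end to end, stayed stop-free and was not truncated) and
#'   `orf_interval` (0-based half-open on `seq`, or NULL if truncated away)
#' @export
evolve_copy <- function(ancestor, branch_length, config, truncate = FALSE) {
  if (branch_length < 0) stop("branch_length must be >= 0")
  parts <- lapply(ancestor[c("ltr5", "orf", "spacer_gag_pol_env", "ltr3")],
                  mutate_seq, branch_length = branch_length,
                  indel_rate = config$indel_rate,
                  frameshift_fraction = config$frameshift_fraction,
                  gc = config$gc_content)
  evolved <- lapply(parts, `[[`, "seq")
  orf_fs <- parts$orf$frameshifted
  prior_intact <- !isFALSE(attr(ancestor, "orf_intact"))
  # stop-free in frame 0 of the (possibly 3n-indel-shifted) ORF part
  orf_seq <- evolved$orf
  trimmed <- substr(orf_seq, 1, 3 * (nchar(orf_seq) %/% 3))
  stop_free <- nchar(trimmed) == 0 ||
    !grepl("*", translate_dna(trimmed), fixed = TRUE)
  orf_intact <- prior_intact && !orf_fs && stop_free
  seq <- paste(unlist(evolved), collapse = "")
  orf_iv <- c(nchar(evolved$ltr5), nchar(evolved$ltr5) + nchar(evolved$orf))
  if (truncate && stats::runif(1) < config$truncation_prob) {
    cut <- floor(stats::runif(1, 0, 0.4) * nchar(seq))
    if (stats::runif(1) < 0.5) {   # prefix
      seq <- substr(seq, cut + 1, nchar(seq))
      if (cut > orf_iv[1]) orf_intact <- FALSE
      orf_iv <- pmax(orf_iv - cut, 0)
    } else {                       # suffix
      seq <- substr(seq, 1, nchar(seq) - cut)
      if (nchar(seq) < orf_iv[2]) orf_intact <- FALSE
      orf_iv <- pmin(orf_iv, nchar(seq))
    }
    if (orf_iv[1] >= orf_iv[2]) orf_iv <- NULL
  }
  out <- evolved
  attr(out, "orf_intact") <- orf_intact
  list(seq = seq, parts = out, orf_intact = orf_intact, orf_interval = orf_iv)
}

#' Plant decayed element copies in a synthetic host genome
#'
#' Copies are evolved along a three-level tree: the ancestor splits into
#' `n_clades` clade founders (deep branches of length `divergence`), and each
#' founder spawns `n_copies_per_clade` copies along shallow branches of
#' `divergence / 5` (star-like within clades).  Copies are placed on random
#' strands at random non-overlapping positions separated by at least `flank`
#' bp of i.i.d. host background.
#'
#' @param config a [simulation_config()]
#' @param ancestor optionally a pre-built [make_ancestor()] element; by
#'   default one is generated from the configuration seed
#' @return an `erv_simulation` list: `genome` (named DNA string), `truth`
#'   (BED-like data.frame: copy_id, start, end, strand, clade,
#'   true_divergence, orf_intact), `tree` (ape phylo), `ancestor`
#' @export
plant_copies <- function(config, ancestor = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(ancestor))
    ancestor <- make_ancestor(seed = config$seed + 104729L,
                              gc = config$gc_content)
  shallow <- config$divergence / 5
  n_total <- config$n_clades * config$n_copies_per_clade
  sim <- with_seed(config$seed, {
    copies <- list()
    for (cl in seq_len(config$n_clades)) {
      founder <- evolve_copy(ancestor, config$divergence, config,
                             truncate = FALSE)
      for (cp in seq_len(config$n_copies_per_clade)) {
        cc <- evolve_copy(founder$parts, shallow, config, truncate = TRUE)
        copies[[paste0("c", cl, "_", cp)]] <-
          c(cc, list(clade = paste0("clade", cl),
                     true_divergence = config$divergence + shallow))
      }
    }
    lens <- vapply(copies, function(x) nchar(x$seq), 0)
    spare <- config$host_length - sum(lens) - (n_total + 1) * config$flank
    if (spare < 0)
      stop("host overflow: ", n_total, " copies totalling ", sum(lens),
           " bp plus flanks do not fit in ", config$host_length, " bp")
    # random gap sizes >= flank via a uniform stick-breaking of the spare bp
    cuts <- sort(stats::runif(n_total))
    gaps <- config$flank + floor(diff(c(0, cuts, 1)) * spare)
    order_idx <- sample(n_total)
    strands <- sample(c("+", "-"), n_total, replace = TRUE)
    pieces <- character(0)
    truth <- data.frame()
    pos <- 0L
    for (k in seq_len(n_total)) {
      g <- random_dna(gaps[k], config$gc_content)
      pieces <- c(pieces, g)
      pos <- pos + nchar(g)
      id <- names(copies)[order_idx[k]]
      cpy <- copies[[order_idx[k]]]
      s <- if (strands[k] == "+") cpy$seq else revcomp(cpy$seq)
      pieces <- c(pieces, s)
      truth <- rbind(truth, data.frame(
        copy_id = id, start = pos, end = pos + nchar(s),
        strand = strands[k], clade = cpy$clade,
        true_divergence = cpy$true_divergence,
        orf_intact = cpy$orf_intact, stringsAsFactors = FALSE))
      pos <- pos + nchar(s)
    }
    tail_len <- config$host_length - pos
    if (tail_len > 0) pieces <- c(pieces, random_dna(tail_len,
                                                     config$gc_content))
    genome <- paste(pieces, collapse = "")
    truth <- truth[order(truth$start), ]
    rownames(truth) <- NULL
    list(genome = genome, truth = truth)
  })
  nwk <- paste0("(", paste(vapply(seq_len(config$n_clades), function(cl) {
    paste0("(", paste(sprintf("c%d_%d:%g", cl,
                              seq_len(config$n_copies_per_clade), shallow),
                      collapse = ","), "):", config$divergence)
  }, ""), collapse = ","), ");")
  structure(list(genome = stats::setNames(sim$genome, "host"),
                 truth = sim$truth, tree = ape::read.tree(text = nwk),
                 tree_newick = nwk, ancestor = ancestor, config = config),
            class = "erv_simulation")
}

#' @export
print.erv_simulation <- function(x, ...) {
  cat(sprintf("erv_simulation: %d bp host, %d planted copies in %d clades\n",
              nchar(x$genome), nrow(x$truth), x$config$n_clades))
  invisible(x)
}

#' Write a simulation to FASTA, BED6 and Newick files
#'
#' Outputs `<prefix>_genome.fa`, `<prefix>_ancestor.fa`, `<prefix>_truth.bed`
#' (0-based half-open, strand in column 6) and `<prefix>_tree.nwk`.  A fixed
#' configuration seed gives byte-identical files.
#'
#' @param sim an `erv_simulation`
#' @param prefix output path prefix
#' @return the four paths, invisibly
#' @export
write_simulation <- function(sim, prefix) {
  paths <- paste0(prefix, c("_genome.fa", "_ancestor.fa", "_truth.bed",
                            "_tree.nwk"))
  write_fasta(sim$genome, paths[1])
  anc <- ancestor_sequence(sim$ancestor)
  write_fasta(stats::setNames(c(anc, sim$ancestor$orf),
                              c("ancestor", "ancestor_orf")), paths[2])
  bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", "host", sim$truth$start,
                 sim$truth$end, sim$truth$copy_id,
                 as.integer(round(1000 * sim$truth$true_divergence)),
                 sim$truth$strand)
  con <- file(paths[3], "wb"); writeLines(bed, con, sep = "\n"); close(con)
  con <- file(paths[4], "wb"); writeLines(sim$tree_newick, con, sep = "\n")
  close(con)
  invisible(paths)
}

#' Read/write FASTA (thin wrappers over Biostrings)
#' @param x named character vector of sequences
#' @param path file path
#' @return `read_fasta` returns a named character vector
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(x)   # BStringSet preserves soft-mask case
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
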