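#' Keep segments longer than a minimum length
#' @param segments character vector of DNA segments
#' @param min_len_bp strict lower bound: segments of exactly this length are
#'   dropped
#' @return the surviving segments
#' @export
filter_segments <- function(segments, min_len_bp = 300L) {
  segments[nchar(segments) > min_len_bp]
}

#' Align segments onto fixed reference coordinates
#'
#' Each segment is pairwise-aligned to the reference with the same ends-free
#' affine DNA-DNA scoring as [refine()]; its letters are placed at reference
#' columns, and segment insertions relative to the reference are discarded,
#' so every row has exactly the reference length (keeplength semantics).
#'
#' @param segments named character vector of DNA segments (names become row
#'   labels; unnamed input is labelled seg1, seg2, ...)
#' @param reference DNA string defining the column space (typically the
#'   refined consensus)
#' @param min_score segments alignment-scoring at or below this are excluded
#'   with a warning
#' @param match,mismatch,gap_open,gap_extend DNA-DNA alignment scores
#' @return a `reference_alignment`: `reference`, `rows` (named character
#'   vector, every string of reference length, gaps as `-`), `coverage`
#'   (non-gap fraction per row)
#' @export
align_to_reference <- function(segments, reference, min_score = 1,
                               match = 1, mismatch = -1, gap_open = 5,
                               gap_extend = 1) {
  stopifnot(nchar(reference) > 0)
  nms <- names(segments)
  segments <- stats::setNames(toupper(as.character(segments)), nms)
  if (is.null(names(segments)) || any(!nzchar(names(segments))))
    names(segments) <- paste0("seg", seq_along(segments))
  submat <- dna_submat(match, mismatch)
  rows <- character(0)
  for (lab in names(segments)) {
    st <- stack_one(segments[[lab]], reference, submat, gap_open, gap_extend)
    if (st$score < min_score) {
      warning("segment ", lab, " aligns below score ", min_score,
              "; excluded")
      next
    }
    row <- st$row
    row[row == ""] <- "-"
    rows[lab] <- paste(row, collapse = "")
  }
  structure(list(reference = toupper(reference), rows = rows,
                 coverage = 1 - vapply(strsplit(rows, ""), function(ch)
                   mean(ch == "-"), 0)),
            class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat(sprintf("reference_alignment: %d rows x %d columns, mean coverage %.2f\n",
              length(x$rows), nchar(x$reference), mean(x$coverage)))
  invisible(x)
}

ra_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

ra_area <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0) return(0)
  nrow(m) * sum(colSums(m == "-") == 0)
}

#' Prune rows to maximize alignment area
#'
#' Greedily removes the row whose removal most increases
#' area = rows x gap-free columns, stopping when no single removal helps or
#' when only 3 rows remain (with a warning).  Ties are broken by label order.
#'
#' @param aln a [align_to_reference()] result
#' @return the pruned `reference_alignment`
#' @export
maxalign_prune <- function(aln) {
  stopifnot(inherits(aln, "reference_alignment"), length(aln$rows) >= 3)
  rows <- aln$rows
  repeat {
    if (length(rows) <= 3) {
      warning("pruning stopped at 3 rows")
      break
    }
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    base <- ra_area(m)
    gains <- vapply(seq_along(rows), function(i)
      ra_area(m[-i, , drop = FALSE]) - base, 0)
    ord <- order(-gains, names(rows))
    if (gains[ord[1]] <= 0) break
    rows <- rows[-ord[1]]
  }
  structure(list(reference = aln$reference, rows = rows,
                 coverage = aln$coverage[names(rows)]),
            class = "reference_alignment")
}

#' Jukes-Cantor distance between two aligned rows
#'
#' Pairwise deletion: only columns where both rows have a non-gap letter are
#' compared.  `d = -(3/4) log(1 - (4/3) p)` with p the mismatch fraction.
#'
#' @param row_i,row_j aligned strings of equal length (gaps as `-`)
#' @return distance in substitutions/site
#' @export
jc_distance <- function(row_i, row_j) {
  a <- strsplit(row_i, "", fixed = TRUE)[[1]]
  b <- strsplit(row_j, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b))
  shared <- a != "-" & b != "-"
  if (!any(shared)) stop("no shared non-gap columns")
  p <- mean(a[shared] != b[shared])
  if (p >= 0.75)
    stop(structure(class = c("jc_saturation", "error", "condition"),
                   list(message = sprintf(
                     "saturated pair: mismatch fraction %.3f >= 0.75", p),
                     call = sys.call())))
  -0.75 * log(1 - 4 * p / 3)
}

# distance matrix from a character matrix of aligned rows; saturated or
# shared-column-free pairs become NA
jc_dist_matrix <- function(m, labels) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(shared)) { D[i, j] <- D[j, i] <- NA; next }
    p <- mean(m[i, shared] != m[j, shared])
    D[i, j] <- D[j, i] <- if (p >= 0.75) NA else -0.75 * log(1 - 4 * p / 3)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (Q-criterion join selection with the usual
#' branch-length formulas); exact on additive matrices.  Ties in Q are broken
#' by joining the pair whose (sorted) representative leaf labels are
#' lexicographically smallest.  Negative branch lengths are clamped to 0.
#'
#' @param D symmetric distance matrix with zero diagonal and >= 3 labelled
#'   taxa
#' @return an unrooted `ape::phylo` tree (root trifurcation)
#' @export
nj_build <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(nrow(D)))
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (any(is.na(D))) stop("distance matrix contains NA")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  nwk <- labels          # newick fragment per active cluster
  rep_lab <- labels      # lexicographic representative for tie-breaks
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(nwk) > 3) {
    N <- nrow(D)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij)
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r"))
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- dij - li
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj),
                      ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    rownames(D) <- colnames(D) <- rep_lab
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  txt <- paste0("(", nwk[1], ":", fmt(l1), ",", nwk[2], ":", fmt(l2), ",",
                nwk[3], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

# canonical bipartition keys of all internal (non-root) nodes of a phylo tree
tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  anchor <- min(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- vapply(seq_along(parts), function(k) {
    tips <- tree$tip.label[parts[[k]]]
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) == 0 || length(tips) == n_tip - 1) return(NA_character_)
    paste(sort(tips), collapse = "\r")
  }, "")
  names(keys) <- seq_along(parts) + n_tip  # node numbers
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the point-estimate NJ tree from all columns, then resamples columns
#' with replacement `n_reps` times (replicate i uses an RNG substream derived
#' from `seed` and i, making supports invariant to input row order), rebuilds
#' the tree, and reports for every internal branch the percentage of
#' replicates containing the same bipartition.  Replicates in which some pair
#' of rows is saturated (mismatch fraction >= 3/4) or shares no columns are
#' skipped and counted.
#'
#' @param aln a [align_to_reference()] result (possibly pruned)
#' @param n_reps bootstrap replicates (>= 1)
#' @param seed master seed
#' @return the point tree (`ape::phylo`) with `node.label` carrying percent
#'   supports and attributes `n_effective` (used replicates) and `n_skipped`
#' @export
bootstrap <- function(aln, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(aln, "reference_alignment"), n_reps >= 1)
  m <- ra_char_matrix(aln)
  rownames(m) <- names(aln$rows)
  D <- jc_dist_matrix(m, rownames(m))
  if (any(is.na(D))) stop("saturated pair in the point distance matrix")
  point <- nj_build(D)
  point_keys <- tree_splits(point)
  valid_keys <- unique(point_keys[!is.na(point_keys)])
  counts <- stats::setNames(numeric(length(valid_keys)), valid_keys)
  n_used <- 0L; n_skipped <- 0L
  L <- ncol(m)
  for (i in seq_len(n_reps)) {
    idx <- with_seed((seed + i * 1000003) %% 2147483647,
                     sample.int(L, L, replace = TRUE))
    Di <- jc_dist_matrix(m[, idx, drop = FALSE], rownames(m))
    if (any(is.na(Di))) { n_skipped <- n_skipped + 1L; next }
    n_used <- n_used + 1L
    ki <- tree_splits(nj_build(Di))
    hit <- intersect(valid_keys, ki[!is.na(ki)])
    counts[hit] <- counts[hit] + 1
  }
  if (n_skipped > 0)
    warning(n_skipped, " replicate(s) skipped due to saturated pairs")
  supports <- if (n_used > 0) 100 * counts / n_used else counts * NA
  lab <- rep("", point$Nnode)
  for (k in seq_along(point_keys)) {
    key <- point_keys[k]
    node <- as.integer(names(point_keys)[k])
    lab[node - length(point$tip.label)] <-
      if (is.na(key)) "" else sprintf("%.5g", supports[[key]])
  }
  point$node.label <- lab
  attr(point, "n_effective") <- n_used
  attr(point, "n_skipped") <- n_skipped
  point
}

#' Percent support of each clade of labels in a supported tree
#'
#' Convenience accessor: for each requested set of tip labels, returns the
#' bootstrap support if that set forms a bipartition of the tree, else NA.
#'
#' @param tree a tree from [bootstrap()]
#' @param clades list of character vectors of tip labels
#' @return numeric vector of supports (percent), NA when not monophyletic
#' @export
clade_supports <- function(tree, clades) {
  keys <- tree_splits(tree)
  anchor <- min(tree$tip.label)
  vapply(clades, function(tips) {
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    key <- paste(sort(tips), collapse = "\r")
    k <- which(!is.na(keys) & keys == key)
    if (length(k) == 0) return(NA_real_)
    node <- as.integer(names(keys)[k[1]])
    as.numeric(tree$node.label[node - length(tree$tip.label)])
  }, 0)
}

#' Write a tree as Newick text
#'
#' Branch lengths are included; internal node labels (bootstrap supports) are
#' written after the closing parenthesis.  Labels containing spaces or Newick
#' metacharacters are single-quoted.
#'
#' @param tree an `ape::phylo` tree
#' @param path optional output file
#' @return the Newick string (invisibly when `path` is given)
#' @export
write_newick <- function(tree, path = NULL) {
  if (any(duplicated(tree$tip.label))) stop("duplicate tip labels")
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  elen <- tree$edge.length
  qlab <- function(x) {
    if (grepl("[][ ():;,']", x))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  rec <- function(node, edge_idx) {
    txt <- if (node <= n_tip) {
      qlab(tree$tip.label[node])
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], function(e)
        rec(tree$edge[e, 2], e), ""), collapse = ",")
      nl <- if (!is.null(tree$node.label)) tree$node.label[node - n_tip]
            else ""
      paste0("(", inner, ")", if (is.null(nl) || is.na(nl)) "" else qlab(nl))
    }
    if (!is.null(edge_idx) && !is.null(elen))
      txt <- paste0(txt, ":", sprintf("%.10g", elen[edge_idx]))
    txt
  }
  out <- paste0(rec(n_tip + 1L, NULL), ";")
  if (!is.null(path)) {
    con <- file(path, "wb"); writeLines(out, con, sep = "\n"); close(con)
    return(invisible(out))
  }
  out
}
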