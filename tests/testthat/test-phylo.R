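test_that("length filtering is strict", {
  segs <- c(strrep("A", 300), strrep("C", 301), strrep("G", 1000))
  expect_equal(nchar(filter_segments(segs, 300)), c(301, 1000))
  expect_length(filter_segments(character(0), 300), 0)
  expect_equal(filter_segments(segs, 0), segs)
})

test_that("reference-anchored alignment keeps reference coordinates", {
  set.seed(101)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  aln <- align_to_reference(c(x = ref), ref)
  expect_identical(aln$rows[["x"]], ref)
  expect_equal(aln$coverage[["x"]], 1)
  # internal insertion in the segment is dropped (keeplength)
  seg_ins <- paste0(substr(ref, 1, 150), "ACGTACGTAC", substr(ref, 151, 300))
  aln2 <- align_to_reference(c(y = seg_ins), ref)
  expect_identical(aln2$rows[["y"]], ref)
  # internal deletion appears as exactly 10 gap columns
  seg_del <- paste0(substr(ref, 1, 100), substr(ref, 111, 300))
  aln3 <- align_to_reference(c(z = seg_del), ref)
  ch <- strsplit(aln3$rows[["z"]], "")[[1]]
  expect_equal(sum(ch == "-"), 10)
  expect_identical(paste(ch[ch != "-"], collapse = ""), seg_del)
  # hopeless segments are excluded with a warning
  expect_warning(
    aln4 <- align_to_reference(c(w = strrep("A", 50), x = ref), ref,
                               min_score = 40),
    "excluded")
  expect_equal(names(aln4$rows), "x")
})

test_that("area pruning matches the exhaustive subset oracle", {
  clean <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  aln <- structure(list(reference = "ACGTACGT", rows = clean,
                        coverage = rep(1, 3)),
                   class = "reference_alignment")
  expect_warning(pruned <- maxalign_prune(aln), "3 rows")
  expect_equal(names(pruned$rows), names(clean))
  gappy <- c(clean, d = "AC--AC--", e = "A-------")
  aln2 <- structure(list(reference = "ACGTACGT", rows = gappy,
                         coverage = c(rep(1, 3), 0.5, 0.125)),
                    class = "reference_alignment")
  pruned2 <- suppressWarnings(maxalign_prune(aln2))
  expect_false("e" %in% names(pruned2$rows))
  set.seed(31)
  for (rep in 1:10) {
    rows <- vapply(1:8, function(i)
      paste(ifelse(stats::runif(40) < 0.25, "-",
                   sample(c("A", "C", "G", "T"), 40, replace = TRUE)),
            collapse = ""), "")
    names(rows) <- letters[1:8]
    aln3 <- structure(list(reference = strrep("A", 40), rows = rows,
                           coverage = rep(1, 8)),
                      class = "reference_alignment")
    got <- suppressWarnings(maxalign_prune(aln3))
    m <- do.call(rbind, strsplit(got$rows, ""))
    got_area <- nrow(m) * sum(colSums(m == "-") == 0)
    base <- do.call(rbind, strsplit(rows, ""))
    expect_gte(got_area, nrow(base) * sum(colSums(base == "-") == 0))
    # greedy never beats, and here should match, the exhaustive optimum
    expect_lte(got_area, bf_best_area(rows))
  }
})

test_that("Jukes-Cantor distances follow the closed form and its domain", {
  expect_equal(jc_distance("ACGT", "ACGT"), 0)
  expect_equal(jc_distance("ACGT", "ACGA"), -0.75 * log(2 / 3),
               tolerance = 1e-12)
  expect_equal(jc_distance("AC-GT", "ACTGT"), 0)  # pairwise deletion
  expect_equal(jc_distance("ACGT", "ACGA"), jc_distance("ACGA", "ACGT"))
  expect_error(jc_distance("ACGT", "AAAA"), "saturated")
  expect_error(jc_distance("A---", "-CGT"), "shared")
})

test_that("estimated JC distance inverts the substitution simulator", {
  cfg <- simulation_config(indel_rate = 0, truncation_prob = 0)
  anc <- list(ltr5 = "AAA", orf = with_seed(51, ervfossils:::random_dna(99999)),
              spacer_gag_pol_env = "AAA", ltr3 = "AAA")
  for (d in c(0.05, 0.2, 0.5)) {
    set.seed(61)
    cp <- evolve_copy(anc, d, cfg)
    dd <- jc_distance(anc$orf, cp$parts$orf)
    p <- 0.75 * (1 - exp(-4 * d / 3))
    se_d <- sqrt(p * (1 - p) / 99999) / (1 - 4 * p / 3)
    expect_lt(abs(dd - d), 3 * se_d)
  }
})

test_that("neighbor-joining solves 3 taxa in closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_build(D)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  len <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(len[["A"]], 1)  # (3+4-5)/2
  expect_equal(len[["B"]], 2)
  expect_equal(len[["C"]], 3)
})

test_that("neighbor-joining is exact on additive matrices", {
  tr4 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D4 <- ape::cophenetic.phylo(tr4)
  nj4 <- nj_build(D4)
  expect_equal(ape::dist.topo(ape::unroot(tr4), nj4), 0,
               ignore_attr = TRUE)
  set.seed(71)
  for (n in 4:6) {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5))
    D <- ape::cophenetic.phylo(tr)
    nj <- nj_build(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
    back <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
    expect_lt(max(abs(back - D)), 1e-9)
    # independent cross-check against the reference NJ implementation
    expect_equal(ape::dist.topo(ape::nj(D), nj), 0, ignore_attr = TRUE)
  }
  Dbad <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3)
  expect_error(nj_build(Dbad), "symmetric")
})

make_ra <- function(rows) {
  structure(list(reference = strrep("A", nchar(rows[1])), rows = rows,
                 coverage = rep(1, length(rows))),
            class = "reference_alignment")
}

test_that("bootstrap supports behave at the degenerate ends", {
  # duplicated identical-information columns: every branch at 100
  block <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC",
             c = "GGGAAAAAAA", d = "GGGAAAAAAC")
  rows <- vapply(block, strrep, "", times = 50)
  bt <- bootstrap(make_ra(rows), n_reps = 25, seed = 1)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  bt1 <- bootstrap(make_ra(rows), n_reps = 1, seed = 1)
  sup1 <- suppressWarnings(as.numeric(bt1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to row order", {
  set.seed(81)
  rows <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1)), collapse = ""), "")
  base <- strsplit(rows[1], "")[[1]]
  for (i in 2:8) {   # two clades of four
    ch <- strsplit(rows[i], "")[[1]]
    src <- if (i <= 4) base else strsplit(rows[5], "")[[1]]
    keep <- stats::runif(500) < 0.95
    ch[keep] <- src[keep]
    rows[i] <- paste(ch, collapse = "")
  }
  names(rows) <- paste0("t", 1:8)
  bt_a <- bootstrap(make_ra(rows), n_reps = 30, seed = 4)
  bt_b <- bootstrap(make_ra(rev(rows)), n_reps = 30, seed = 4)
  clade <- list(paste0("t", 1:4), paste0("t", 5:8))
  expect_equal(clade_supports(bt_a, clade), clade_supports(bt_b, clade))
})

test_that("three simulated clades are recovered with strong support", {
  cfg <- simulation_config(n_copies_per_clade = 5, n_clades = 3,
                           divergence = 0.15, indel_rate = 0.01,
                           host_length = 80000, seed = 77)
  sim <- plant_copies(cfg)
  segs <- vapply(seq_len(nrow(sim$truth)), function(i) {
    s <- substr(sim$genome[[1]], sim$truth$start[i] + 1, sim$truth$end[i])
    if (sim$truth$strand[i] == "-") s <- revcomp(s)
    s
  }, "")
  names(segs) <- sim$truth$copy_id
  segs <- filter_segments(segs, 300)
  aln <- align_to_reference(segs, ancestor_sequence(sim$ancestor))
  pruned <- maxalign_prune(aln)
  bt <- bootstrap(pruned, n_reps = 100, seed = 10)
  clades <- lapply(1:3, function(cl)
    intersect(sim$truth$copy_id[sim$truth$clade == paste0("clade", cl)],
              names(pruned$rows)))
  sup <- clade_supports(bt, clades)
  expect_true(all(!is.na(sup)))   # all three clades monophyletic
  expect_true(all(sup > 70))
})

test_that("Newick output round-trips and quotes awkward labels", {
  tr <- nj_build(matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                        dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  txt <- write_newick(tr)
  expect_match(txt, ";$")
  back <- ape::read.tree(text = txt)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  # supports survive the round trip
  rows <- c(a = strrep("AAAAAAAAAA", 30), b = strrep("AAAAAAAAAC", 30),
            c = strrep("GGGAAAAAAA", 30), d = strrep("GGGAAAAAAC", 30))
  bt <- bootstrap(make_ra(rows), n_reps = 10, seed = 2)
  back2 <- ape::read.tree(text = write_newick(bt))
  expect_setequal(setdiff(back2$node.label, ""),
                  setdiff(bt$node.label, ""))
  # labels with spaces are quoted
  tr$tip.label[1] <- "taxon one"
  expect_match(write_newick(tr), "'taxon one'", fixed = TRUE)
  tr$tip.label[2] <- "taxon one"
  expect_error(write_newick(tr), "duplicate")
})
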