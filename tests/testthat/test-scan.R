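# shared study-condition fixtures for the scanning tests
sim20 <- plant_copies(simulation_config(
  n_copies_per_clade = 5, n_clades = 3, divergence = 0.2, indel_rate = 0.01,
  host_length = 80000, seed = 21))
params20 <- train(simulate_train_pairs(n_codons = 2000, divergence = 0.3,
                                       n_pairs = 20, indel_rate = 0.02,
                                       frameshift_fraction = 0.5,
                                       seed = 2)$pairs, max_pid = 100)

test_that("a genome scan recovers planted fossils with no off-truth hits", {
  hits <- scan_genome(sim20$genome, sim20$ancestor$protein, params20,
                      seed = 5)
  tr <- sim20$truth
  recalled <- vapply(seq_len(nrow(tr)), function(i)
    any(vapply(hits, function(h)
      h$dna_interval[1] < tr$end[i] && h$dna_interval[2] > tr$start[i],
      TRUE)), TRUE)
  expect_gte(sum(recalled), 14)
  off_truth <- vapply(hits, function(h)
    !any(h$dna_interval[1] < tr$end + 100 & h$dna_interval[2] > tr$start - 100),
    TRUE)
  expect_equal(sum(off_truth), 0)
})

test_that("a fossil-free genome yields no hits at the calibrated threshold", {
  null_genome <- c(host = with_seed(33, ervfossils:::random_dna(20000)))
  hits <- scan_genome(null_genome, sim20$ancestor$protein, params20,
                      seed = 5)
  expect_length(hits, 0)
})

test_that("windowed scanning equals the whole-sequence scan", {
  cfg <- simulation_config(n_copies_per_clade = 2, n_clades = 2,
                           divergence = 0.15, indel_rate = 0.01,
                           host_length = 30000, flank = 300, seed = 31)
  sim <- plant_copies(cfg)
  key <- function(h) paste(h$dna_interval[1], h$dna_interval[2], h$strand,
                           h$score)
  whole <- scan_genome(sim$genome, sim$ancestor$protein, params20,
                       window_bp = 40000, min_score = 150)
  windowed <- scan_genome(sim$genome, sim$ancestor$protein, params20,
                          window_bp = 8000, overlap_bp = 4000,
                          min_score = 150)
  expect_setequal(vapply(windowed, key, ""), vapply(whole, key, ""))
  expect_error(scan_genome(sim$genome, "MKV", params20, window_bp = 2),
               "codon")
  expect_error(scan_genome(sim$genome, "MKV", params20, window_bp = 100,
                           overlap_bp = 100), "exceed")
})

mk_hit2 <- function(start, end, score = 100, seqname = "host", strand = "+",
                    prot = c(0, 100)) {
  structure(list(dna_interval = c(start, end), strand = strand,
                 protein_interval = prot, score = score, identity = 50,
                 columns = data.frame(), seqname = seqname),
            class = "dna_protein_alignment")
}

ann_fix <- parse_rm_out(system.file("extdata", "example_annotations.out",
                                    package = "ervfossils"))

test_that("hits are assigned to families by maximal overlap", {
  hits <- list(
    mk_hit2(1100, 1600),            # fully inside HERV17 annotation 1
    mk_hit2(4600, 6300),            # HERV9 200 bp vs MER41B 300 bp
    mk_hit2(2000, 2700),            # spans the HERV17 annotation gap
    mk_hit2(50000, 50500))          # annotation-free
  res <- assign_families(hits, ann_fix, other_below = 1)
  s <- res$summaries
  expect_equal(s$family, c("HERV17", "MER41B", "HERV17", NA))
  expect_equal(s$relation, c("inside", "inside", "spans_gap", "unannotated"))
  expect_equal(s$overlap_bp[1], 500)   # hit length: fully annotated
  # conservation: table counts sum to the number of annotated hits
  expect_equal(sum(res$family_table$count), sum(!is.na(s$family)))
})

test_that("gap spanning requires consensus-coordinate continuity", {
  hit <- list(mk_hit2(2000, 2700))
  res <- assign_families(hit, ann_fix, gap_slack = 100)
  expect_equal(res$summaries$relation, "inside")  # jump of 301 > slack 100
})

test_that("projection to consensus coordinates is linear and strand-aware", {
  # exact annotation span maps to the full consensus interval
  p <- project_to_consensus(mk_hit2(6000, 6900), ann_fix)
  p <- p[p$family == "MER41B", ]
  expect_equal(c(p$cons_start, p$cons_end), c(11, 910))
  # left half of a +-strand annotation -> left half of consensus interval
  p2 <- project_to_consensus(mk_hit2(6000, 6450), ann_fix)
  p2 <- p2[p2$family == "MER41B", ]
  expect_equal(c(p2$cons_start, p2$cons_end), c(11, 460))
  # C-strand annotation projects reversed
  p3 <- project_to_consensus(mk_hit2(4000, 4400), ann_fix)
  p3 <- p3[p3$family == "HERV9", ]
  expect_equal(c(p3$cons_start, p3$cons_end), c(601, 1000))
  # monotone within one +-strand annotation
  starts <- vapply(seq(6000, 6800, by = 200), function(s) {
    pr <- project_to_consensus(mk_hit2(s, s + 100), ann_fix)
    pr$cons_start[pr$family == "MER41B"]
  }, 0)
  expect_true(all(diff(starts) > 0))
})

test_that("segment selection applies the protein-coverage rule and flanks", {
  genome <- c(host = strrep("ACGT", 2000))
  hits <- list(
    mk_hit2(1000, 1600, prot = c(5, 283)),    # qualifies (defaults 10 / 30)
    mk_hit2(2000, 2600, prot = c(20, 293)),   # start coverage fails
    mk_hit2(3000, 3600, prot = c(0, 250)),    # end coverage fails
    mk_hit2(50, 500, prot = c(2, 290)),       # qualifies; 5' flank clipped
    mk_hit2(4000, 4600, prot = c(3, 290), strand = "-"))
  seg <- select_for_reconstruction(hits, genome, protein_length = 293)
  expect_equal(seg$hit_id, c("hit001", "hit004", "hit005"))
  expect_equal(seg$start[2], 0)               # clipped at sequence bound
  expect_equal(seg$end[1] - seg$start[1], 600 + 400)
  expect_equal(seg$seq[3],
               revcomp(toupper(substr(genome[[1]], 3801, 4800))))
  none <- select_for_reconstruction(hits[2], genome, protein_length = 293)
  expect_equal(nrow(none), 0)
})
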