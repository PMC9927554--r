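test_that("perfect back-translation aligns at full score and identity", {
  p <- toy_params()
  dna <- back_translate("MKV")
  als <- align_local(dna, "MKV", p, strands = "+")
  expect_length(als, 1)
  expect_equal(als[[1]]$score, 15)
  expect_equal(als[[1]]$identity, 100)
  expect_equal(als[[1]]$dna_interval, c(0, 9))
  expect_equal(als[[1]]$protein_interval, c(0, 3))
})

test_that("a 1-nt insertion costs exactly one frameshift penalty", {
  p <- toy_params(fs = 4L)
  dna <- back_translate("MKV")
  dna_ins <- paste0(substr(dna, 1, 3), "C", substr(dna, 4, 9))
  als <- align_local(dna_ins, "MKV", p, strands = "+")
  expect_equal(als[[1]]$score, 15 - 4)
  expect_equal(sum(als[[1]]$columns$frameshift), 1)
  # matches brute-force enumeration over all monotone alignments
  expect_equal(als[[1]]$score, bf_best_score(dna_ins, "MKV", p))
})

test_that("alignment is strand-symmetric", {
  p <- toy_params()
  dna <- back_translate("MKVLW")
  fwd <- align_local(dna, "MKVLW", p)[[1]]
  rev <- align_local(revcomp(dna), "MKVLW", p)[[1]]
  expect_equal(rev$score, fwd$score)
  expect_equal(rev$identity, fwd$identity)
  expect_equal(rev$strand, "-")
  expect_equal(rev$dna_interval, fwd$dna_interval)
})

test_that("DP optimum equals brute-force enumeration on random instances", {
  set.seed(42)
  n_bad <- 0
  for (rep in 1:200) {
    p <- random_params()
    n <- sample(6:15, 1); m <- sample(2:5, 1)
    dna <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    prot <- paste(sample(setdiff(AA21, "*"), m, replace = TRUE),
                  collapse = "")
    bf <- bf_best_score(dna, prot, p)
    als <- align_local(dna, prot, p, strands = "+")
    dp <- if (length(als)) max(vapply(als, `[[`, 0, "score")) else 0
    if (bf >= 1) {
      if (dp != bf) n_bad <- n_bad + 1
    } else if (dp > 0) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("non-ACGTN letters are warned about and score as N", {
  p <- toy_params()
  dna <- paste0(back_translate("MKV"), "RYK")
  expect_warning(als <- align_local(dna, "MKV", p, strands = "+"),
                 "treated as N")
  expect_equal(als[[1]]$score, 15)
})

test_that("empty sequences are rejected", {
  expect_error(align_local("", "MKV", toy_params()), "non-empty")
})

test_that("simple tandem repeats are masked fully and idempotently", {
  x <- "ACACACACACACACAC"
  expect_equal(mask_simple_repeats(x, period_max = 2),
               tolower(x))
  r <- with_seed <- NULL
  set.seed(1)
  rnd <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  masked <- mask_simple_repeats(rnd)
  frac <- mean(grepl("[a-z]", strsplit(masked, "")[[1]]))
  expect_lt(frac, 0.05)
  expect_equal(mask_simple_repeats(masked), masked)
  expect_equal(mask_simple_repeats(""), "")
})

test_that("masking caps positive substitution scores during alignment", {
  p <- toy_params()
  dna <- tolower(back_translate("MKV"))
  als <- align_local(dna, "MKV", p, strands = "+")
  expect_length(als, 0)   # all columns capped at 0: nothing above threshold
})

test_that("score threshold calibration is monotone, reproducible and guarded", {
  p <- seed_params()
  c1 <- score_threshold(p, 1e5, n_shuffles = 100, seed = 3,
                        shuffle_dna_bp = 500, protein_len = 60)
  c2 <- score_threshold(p, 2e5, n_shuffles = 100, seed = 3,
                        shuffle_dna_bp = 500, protein_len = 60)
  expect_gte(c2, c1)
  c1b <- score_threshold(p, 1e5, n_shuffles = 100, seed = 3,
                         shuffle_dna_bp = 500, protein_len = 60)
  expect_identical(as.integer(c1), as.integer(c1b))
  expect_error(score_threshold(p, 1e5, n_shuffles = 50), "at least 100")
  neg <- alignment_params(matrix(-1L, 64, 21), scale = 1 / 3,
                          gap_open_del = 5, gap_extend_del = 1,
                          gap_open_ins = 5, gap_extend_ins = 1,
                          frameshift_penalty = 5,
                          codon_freq = rep(1 / 64, 64),
                          aa_freq = rep(1 / 21, 21))
  expect_error(score_threshold(neg, 1e5, n_shuffles = 100), "degenerate")
})

mk_hit <- function(start, end, score) {
  structure(list(dna_interval = c(start, end), strand = "+",
                 protein_interval = c(0, 1), score = score, identity = 50,
                 columns = data.frame()), class = "dna_protein_alignment")
}

test_that("containment culling keeps only top-scoring containers", {
  two <- list(mk_hit(0, 100, 50), mk_hit(0, 100, 40))
  expect_length(cull_overlaps(two), 1)
  expect_equal(cull_overlaps(two)[[1]]$score, 50)
  disjoint <- list(mk_hit(0, 100, 50), mk_hit(200, 300, 40))
  expect_length(cull_overlaps(disjoint), 2)
  # inward-increasing nested chain: no hit is contained in a higher scorer
  nested <- list(mk_hit(0, 300, 30), mk_hit(50, 250, 40), mk_hit(100, 200, 50))
  expect_length(cull_overlaps(nested), 3)
  # outward-increasing chain: only the outermost survives
  nested2 <- list(mk_hit(0, 300, 50), mk_hit(50, 250, 40), mk_hit(100, 200, 30))
  expect_length(cull_overlaps(nested2), 1)
  expect_equal(cull_overlaps(nested2)[[1]]$score, 50)
})

test_that("culling agrees with the quadratic containment oracle", {
  set.seed(7)
  for (rep in 1:25) {
    hits <- lapply(1:12, function(i) {
      s <- sample(0:200, 1); mk_hit(s, s + sample(10:120, 1),
                                    sample(10:60, 1))
    })
    got <- cull_overlaps(hits)
    want <- bf_cull(hits)
    key <- function(h) paste(h$dna_interval[1], h$dna_interval[2], h$score)
    expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  }
})

test_that("rendering shows matches, substitutions and gaps", {
  p <- toy_params()
  dna <- back_translate("MKVLW")
  al <- align_local(dna, "MKVLW", p)[[1]]
  txt <- render(al)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[3], strrep("|", 15))     # all-match line
  expect_equal(lines[2], dna)
  # gap column renders as space in the match line
  dna_del <- paste0(substr(dna, 1, 6), substr(dna, 10, 15))  # drop codon 3
  al2 <- align_local(dna_del, "MKVLW", toy_params(penalty = 2L))[[1]]
  txt2 <- render(al2)
  expect_match(strsplit(txt2, "\n")[[1]][3], " ")
})
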