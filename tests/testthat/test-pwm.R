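test_that("log-odds scanning recovers consensus and uniform limits", {
  bm <- builtin_motifs()
  p <- bm$SDTF_GASlike
  cons <- pwm_consensus(p)
  seq <- paste0("AATT", cons, "GGCC")
  expect_equal(best_motif_score(seq, p), pwm_max_score(p), tolerance = 1e-10)

  uni <- pwm(matrix(1, 4, 6), name = "uniform")
  expect_equal(best_motif_score("ACGTACGTAC", uni), 0, tolerance = 1e-12)
})

test_that("best score equals an exhaustive two-strand scan on random sequences", {
  p <- builtin_motifs()$LDTF_ETSlike
  lods <- log2(p$matrix / p$background)
  oracle <- function(seq) {
    rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                            collapse = "")
    best <- -Inf
    for (s in c(seq, rc(seq))) {
      ch <- strsplit(s, "")[[1]]
      for (o in 1:(length(ch) - ncol(lods) + 1)) {
        sc <- sum(lods[cbind(match(ch[o:(o + ncol(lods) - 1)], c("A", "C", "G", "T")),
                             seq_len(ncol(lods)))])
        best <- max(best, sc)
      }
    }
    best
  }
  set.seed(11)
  for (i in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    expect_equal(best_motif_score(seq, p), oracle(seq), tolerance = 1e-10)
  }
})

test_that("short sequences score at the floor instead of erroring", {
  p <- builtin_motifs()$LDTF_ETSlike
  floor_score <- sum(apply(log2(p$matrix / p$background), 2, min))
  expect_equal(best_motif_score("ACG", p), floor_score)
})

test_that("reverse complementation leaves best scores unchanged", {
  p <- builtin_motifs()$SDTF_GASlike
  set.seed(4)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
    expect_equal(best_motif_score(seq, p), best_motif_score(rc, p))
  }
})

test_that("decoy generation is seeded and can exclude planted-motif lookalikes", {
  d1 <- make_decoy_pwms(5, seed = 3)
  d2 <- make_decoy_pwms(5, seed = 3)
  expect_identical(lapply(d1, `[[`, "matrix"), lapply(d2, `[[`, "matrix"))

  avoid <- builtin_motifs()
  d3 <- make_decoy_pwms(30, seed = 3, avoid = avoid)
  sims <- vapply(d3, function(q)
    max(vapply(avoid, function(a)
      strainwise:::.pwm_cross_score(pwm_consensus(q), a), 0)), 0)
  expect_true(all(sims < 5))
})
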