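rand_seq <- function(n, len = 60) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

test_that("identical pairs carry no signal and label swaps negate the statistic", {
  set.seed(41)
  p <- builtin_motifs()$SDTF_GASlike
  seqs <- rand_seq(15)
  pairs <- data.frame(id = as.character(1:15), positive_seq = seqs,
                      negative_seq = seqs)
  r <- motif_mutation_test(pairs, p)
  expect_equal(r$signed_logp, 0)
  expect_equal(r$n_nonzero, 0L)

  cons <- pwm_consensus(p)
  mut <- sub("TTC", "GGC", cons)
  pos <- paste0(substr(rand_seq(50, 40), 1, 40), cons)
  neg <- paste0(substr(pos, 1, 40), mut)
  pairs2 <- data.frame(id = as.character(1:50), positive_seq = pos,
                       negative_seq = neg)
  r2 <- motif_mutation_test(pairs2, p)
  expect_gt(r2$signed_logp, 5)
  swapped <- data.frame(id = pairs2$id, positive_seq = pairs2$negative_seq,
                        negative_seq = pairs2$positive_seq)
  r3 <- motif_mutation_test(swapped, p)
  expect_equal(r3$signed_logp, -r2$signed_logp)
  expect_error(motif_mutation_test(pairs2[1:5, ], p), "at least 10")
})

test_that("small-sample p-values agree with exhaustive signed-rank enumeration", {
  # random sequences without planted sites give continuous best-score
  # differences (chance matches move by fractional bits), exercising the
  # exact tie-free signed-rank path
  p <- builtin_motifs()$SDTF_GASlike
  set.seed(17)
  n_checked <- 0L
  for (rep in 1:8) {
    n_pairs <- 12
    pos <- rand_seq(n_pairs, 60)
    neg <- vapply(pos, function(s) {
      ch <- strsplit(s, "")[[1]]
      j <- sample(60, 8)
      ch[j] <- vapply(ch[j], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
    pairs <- data.frame(id = as.character(1:n_pairs), positive_seq = pos,
                        negative_seq = neg)
    r <- motif_mutation_test(pairs, p)
    d <- r$score_diffs[r$score_diffs != 0]
    if (length(d) >= 2 && length(d) <= 15 && !anyDuplicated(abs(d))) {
      expect_equal(r$p.value, oracle_signed_rank_p(d), tolerance = 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 3L)
})

test_that("motif clustering groups correlated score profiles by single linkage", {
  mk <- function(name, diffs, slp) structure(
    list(motif = name, score_diffs = diffs, n_nonzero = sum(diffs != 0),
         p.value = 10^-abs(slp), signed_logp = slp),
    class = "strainwise_motif_result")
  set.seed(5)
  base <- rnorm(40)
  res <- list(mk("m1", base, 6), mk("m2", base + rnorm(40, 0, 0.1), 4),
              mk("m3", rnorm(40), 1), mk("m4", rep(0, 40), 0))
  cl <- cluster_motifs(res)
  m12 <- cl[grepl("m1", cl$members), ]
  expect_true(grepl("m2", m12$members))
  expect_equal(m12$mean_signed_logp, 5)
  expect_equal(m12$representative, "m1")
  expect_true(any(cl$members == "m3"))
  expect_true(any(cl$members == "m4")) # constant profile stays a singleton
})

test_that("expression filtering keeps clusters with an expressed member", {
  clusters <- data.frame(cluster = 1:3,
                         members = c("m1,m2", "m3", "m4"),
                         representative = c("m1", "m3", "m4"),
                         mean_signed_logp = c(5, 2, 1),
                         n_members = c(2L, 1L, 1L))
  expr <- data.frame(gene_id = c("g1", "g2", "g3"), strain = "s1",
                     condition = "basal", replicate = 1L,
                     tpm = c(5, 0.1, 2.0), count = 10L, q = NA_real_)
  map <- c(m1 = "g1", m2 = "g2", m3 = "g2", m4 = "g3")
  kept <- expression_filter(clusters, expr, map)
  expect_equal(kept$cluster, 1L) # g3 at exactly 2.0 TPM is not "larger than 2"
  expect_warning(expression_filter(clusters, expr, map[-4]), "without gene mapping")
})

test_that("the planted signal motif outranks decoys on strain pairs", {
  ds <- simulate_dataset(tiny_params(
    seed = 23, n_elements = 100, frac_promoter = 0, frac_wired = 0,
    frac_silent_variants = 0.8,
    mechanism_mix = c(low_basal = 0, equal_basal = 0.6, high_basal = 0,
                      conserved = 0.2, background = 0.2)))
  pairs <- strain_sequence_pairs(ds, "equal_basal")
  pwms <- c(builtin_motifs()["SDTF_GASlike"],
            make_decoy_pwms(10, seed = 23, avoid = builtin_motifs()))
  res <- motif_mutation_scan(pairs, pwms)
  expect_equal(res$motif[which.max(abs(res$signed_logp))], "SDTF_GASlike")
  expect_gt(res$signed_logp[res$motif == "SDTF_GASlike"], 0)
})
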