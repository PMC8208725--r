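mk_elements <- function() {
  data.frame(chrom = "chrS",
             start = c(10000L, 30000L, 60000L, 90000L),
             end = c(10300L, 30300L, 60300L, 90300L),
             id = c("p1", "e1", "e2", "e3"),
             kind = c("promoter", "enhancer", "enhancer", "enhancer"),
             stringsAsFactors = FALSE)
}

mk_interaction <- function(s1, e1, s2, e2) {
  data.frame(chrom1 = "chrS", start1 = s1, end1 = e1,
             chrom2 = "chrS", start2 = s2, end2 = e2, strength = 10)
}

test_that("anchors match elements within the merge distance with promoter precedence", {
  cfg <- pipeline_config()
  el <- mk_elements()
  ia <- rbind(
    mk_interaction(9000L, 11500L, 29500L, 31000L),   # promoter x enhancer
    mk_interaction(9800L, 10500L, 9900L, 10400L),    # promoter x promoter
    mk_interaction(30000L, 30300L, 60000L, 60300L),  # enhancer x enhancer
    mk_interaction(150000L, 151000L, 30000L, 30300L))# nothing within 2.5 kb
  cl <- classify_interactions(ia, el, cfg)
  expect_equal(cl$class, c("enhancer-promoter", "promoter-promoter",
                           "enhancer-enhancer", "unassigned"))
  # gap slightly beyond merge_dist does not match: anchor ends 3 kb from e1
  ia2 <- mk_interaction(24000L, 27199L, 60000L, 60300L)
  expect_equal(classify_interactions(ia2, el, cfg)$class, "unassigned")
  ia3 <- mk_interaction(24000L, 27500L, 60000L, 60300L)
  expect_equal(classify_interactions(ia3, el, cfg)$class, "enhancer-enhancer")
})

test_that("contingency Fisher tests match closed forms", {
  cfg <- pipeline_config()
  el <- data.frame(chrom = "chrS",
                   start = seq(10000L, by = 30000L, length.out = 40L),
                   end = seq(10300L, by = 30000L, length.out = 40L),
                   id = sprintf("x%02d", 1:40),
                   kind = rep(c("promoter", "enhancer"), each = 20L),
                   stringsAsFactors = FALSE)
  states <- stats::setNames(rep(c("induced", "repressed"), times = 20L), el$id)
  # wire promoter i to enhancer i: state matches perfectly (10 ind-ind,
  # 10 rep-rep)
  ia <- do.call(rbind, lapply(1:20, function(i)
    mk_interaction(el$start[i], el$end[i], el$start[20 + i], el$end[20 + i])))
  cl <- classify_interactions(ia, el, cfg)
  ct <- promoter_enhancer_contingency(cl, states)
  expect_equal(unname(ct$table["induced", "induced"]), 10)
  expect_equal(unname(ct$table["repressed", "repressed"]), 10)
  # collapsed [[10,0],[0,10]] has the hypergeometric two-sided p
  expect_equal(ct$tests$induced_vs_noninduced$p.value, 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_equal(ct$tests$induced_vs_repressed$p.value, 2 / choose(20, 10),
               tolerance = 1e-9)

  # independent wiring (balanced 2x2, [[5,5],[5,5]]): p = 1
  states2 <- stats::setNames(c(rep(c("induced", "neutral"), each = 10L),
                               rep(c("induced", "neutral"), 10L)), el$id)
  ct2 <- promoter_enhancer_contingency(cl, states2)
  expect_equal(ct2$tests$induced_vs_noninduced$p.value, 1)
})

test_that("induced promoters wired to induced enhancers give an induced-induced excess", {
  ds <- simulate_dataset(tiny_params(seed = 37, n_elements = 700))
  cfg <- pipeline_config()
  el <- ds$elements
  cl <- classify_interactions(ds$interactions, el, cfg)
  calls <- rbind(classify_elements(ds$signals, "strainA", cfg))
  states <- stats::setNames(ifelse(calls$state == "neutral", "neutral",
                                   calls$state), calls$element_id)
  ct <- promoter_enhancer_contingency(cl, states)
  expect_gt(ct$table["induced", "induced"],
            sum(ct$table["induced", ]) * sum(ct$table[, "induced"]) / sum(ct$table))
  expect_lt(ct$tests$induced_vs_noninduced$p.value, 0.01)
})

test_that("connected enhancers correlate more than nulls when sharing a latent factor", {
  set.seed(19)
  n <- 120
  el <- data.frame(chrom = "chrS", start = seq(0L, by = 20000L, length.out = n),
                   end = seq(300L, by = 20000L, length.out = n),
                   id = sprintf("e%03d", 1:n), kind = "enhancer",
                   stringsAsFactors = FALSE)
  # 5 strains; connected pairs share a per-pair latent activity profile
  pairs <- data.frame(id1 = el$id[seq(1, 60, by = 2)],
                      id2 = el$id[seq(2, 60, by = 2)])
  sig <- matrix(2^rnorm(n * 5, 5, 1.5), n, 5,
                dimnames = list(el$id, paste0("s", 1:5)))
  for (k in seq_len(nrow(pairs))) {
    shared <- 2^rnorm(5, 5, 1.5)
    sig[pairs$id1[k], ] <- shared * 2^rnorm(5, 0, 0.2)
    sig[pairs$id2[k], ] <- shared * 2^rnorm(5, 0, 0.2)
  }
  r <- connected_correlation_comparison(pairs, sig, el, fc_filter = 2, seed = 7)
  expect_gte(length(r$connected), 3L)
  expect_gt(median(r$connected), median(r$random))
  expect_lt(r$test_vs_random$p.value, 0.01)
  expect_gt(r$cohens_d_random, 0)
  # identical and anti-proportional vectors give the correlation limits
  m2 <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10), c = c(5, 4, 3, 2, 1))
  expect_equal(suppressWarnings(cor(m2["a", ], m2["b", ])), 1)
  expect_equal(suppressWarnings(cor(m2["a", ], m2["c", ])), -1)
  expect_error(connected_correlation_comparison(pairs, sig[, 1:2], el),
               "at least 3 strains")
})

test_that("attribution assigns exactly one category per differential enhancer", {
  cfg <- pipeline_config()
  el <- mk_elements()
  # e1 carries a flagged local variant; e3 is variant-free but wired to e1;
  # e2 is variant-free and unconnected
  fv <- data.frame(chrom = "chrS", pos = c(30100L, 90100L), ref = "A",
                   alt = "G", strain = "s2",
                   predicted_functional = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  ia <- mk_interaction(90000L, 90300L, 30000L, 30300L)
  cl <- classify_interactions(ia, el, cfg)
  att <- attribute_differential_enhancers(c("e1", "e2", "e3"), fv, cl, el, cfg)
  expect_equal(att$attribution[att$element_id == "e1"], "local_only")
  expect_equal(att$attribution[att$element_id == "e2"], "neither")
  expect_equal(att$attribution[att$element_id == "e3"], "connected_only")
  expect_equal(sum(attr(att, "percentages")), 100)
  # a flagged local variant plus the connected one makes both_ends
  fv2 <- fv; fv2$predicted_functional <- c(TRUE, TRUE)
  att2 <- attribute_differential_enhancers(c("e3"), fv2, cl, el, cfg)
  expect_equal(att2$attribution, "both_ends")
})

test_that("Fisher p-values agree with hypergeometric enumeration on random tables", {
  set.seed(44)
  for (i in 1:200) {
    N <- sample(4:40, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c <- sample(0:(N - a - b), 1); d <- N - a - b - c
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    p <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-10)
  }
})
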