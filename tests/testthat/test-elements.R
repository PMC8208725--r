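test_that("state calls follow the two-marker fold-change rules", {
  sig <- make_signals(c("a", "b", "c", "d"), "s1",
                      h_b = c(20, 10, 20, 20), h_s = c(60, 10, 26, 60),
                      p_b = c(10, 20, 10, 20), p_s = c(30, 20, 13, 30))
  calls <- classify_elements(sig, "s1")
  expect_equal(calls$state[calls$element_id == "a"], "induced")
  expect_equal(calls$state[calls$element_id == "b"], "below_minimum")
  expect_equal(calls$state[calls$element_id == "c"], "neutral")
  expect_equal(calls$state[calls$element_id == "d"], "ambiguous")
  # repressed mirror
  sig2 <- make_signals("r", "s1", h_b = 90, h_s = 25, p_b = 60, p_s = 15)
  expect_equal(classify_elements(sig2, "s1")$state, "repressed")
  # missing assay errors with the element named
  expect_error(classify_elements(sig[-1, ], "s1"), "'a'")
})

test_that("classification matches the brute-force oracle and partitions states", {
  set.seed(21)
  n <- 2000
  h_b <- round(runif(n, 0, 80), 2); h_s <- round(runif(n, 0, 80), 2)
  p_b <- round(runif(n, 0, 40), 2); p_s <- round(runif(n, 0, 40), 2)
  sig <- make_signals(sprintf("e%04d", 1:n), "s1", h_b, h_s, p_b, p_s)
  calls <- classify_elements(sig, "s1")
  expect_identical(calls$state, oracle_classify(h_b, h_s, p_b, p_s))
  expect_true(all(table(calls$element_id) == 1))
  expect_true(all(calls$state %in% c("induced", "repressed", "neutral",
                                     "ambiguous", "below_minimum")))
})

test_that("TSS proximity annotation uses an inclusive window", {
  cfg <- pipeline_config()
  el <- data.frame(chrom = "c", start = c(800, 49900, 1000) * 10L,
                   end = c(800, 49900, 1000) * 10L + 200L,
                   id = c("near", "far", "edge"), kind = "unassigned")
  ctr <- (el$start + el$end) %/% 2L
  tss <- data.frame(chrom = "c", pos = c(ctr[1] + 200L, ctr[3] + 1000L))
  out <- annotate_context(el, tss, cfg)
  expect_equal(out$kind, c("promoter", "enhancer", "promoter"))
})

test_that("super-enhancer calling separates a high-signal tail and stitches", {
  cfg <- pipeline_config()
  set.seed(2)
  n <- 100
  el <- data.frame(chrom = "c", start = seq(0, by = 50000, length.out = n),
                   end = seq(0, by = 50000, length.out = n) + 500L,
                   id = sprintf("e%03d", 1:n), kind = "enhancer")
  sig <- stats::setNames(c(runif(95, 0.9, 1.1), runif(5, 95, 105)), el$id)
  se <- call_super_enhancers(el, sig, cfg = cfg)
  expect_equal(sum(se$is_super), 5L)
  expect_setequal(unlist(strsplit(se$members[se$is_super], ",")),
                  el$id[96:100])

  # invariant to input ordering
  perm <- sample(n)
  se2 <- call_super_enhancers(el[perm, ], sig, cfg = cfg)
  expect_equal(se2$total, se$total)
  expect_equal(se2$is_super, se$is_super)

  # all-equal signals: degenerate line, no supers
  expect_equal(sum(call_super_enhancers(el, stats::setNames(rep(5, n), el$id),
                                        cfg = cfg)$is_super), 0L)

  # two enhancers 5 kb apart stitch into one region
  el2 <- data.frame(chrom = "c", start = c(0L, 5500L, 100000L, 200000L),
                    end = c(500L, 6000L, 100500L, 200500L),
                    id = c("a", "b", "c", "d"), kind = "enhancer")
  se3 <- call_super_enhancers(el2, stats::setNames(c(1, 1, 1, 1), el2$id), cfg = cfg)
  expect_equal(nrow(se3), 3L)
  expect_true("a,b" %in% se3$members)

  expect_error(call_super_enhancers(el2[1:2, ], sig, cfg = cfg), "at least 3")
})

test_that("TSS exclusion removes signal from promoter-proximal members", {
  cfg <- pipeline_config()
  el <- data.frame(chrom = "c", start = c(0L, 50000L, 100000L),
                   end = c(500L, 50500L, 100500L),
                   id = c("a", "b", "c"), kind = "enhancer")
  sig <- stats::setNames(c(10, 10, 10), el$id)
  tss <- data.frame(chrom = "c", pos = 50250L)
  se <- call_super_enhancers(el, sig, tss = tss, cfg = cfg)
  expect_equal(sort(se$total), c(0, 10, 10))
})

test_that("response variance comparison behaves as Levene's test", {
  set.seed(31)
  fc_sup <- 2^rnorm(200, 1, 1)
  fc_conv <- 2^rnorm(200, 1, 5)
  r <- response_variance_test(fc_sup, fc_conv)
  expect_lt(r$p.value, 1e-6)
  r2 <- response_variance_test(fc_conv, fc_sup)
  expect_equal(r$p.value, r2$p.value)

  # permuted halves of one sample: null, not significant
  x <- 2^rnorm(300, 0, 2)
  r3 <- response_variance_test(x[1:150], x[151:300])
  expect_gt(r3$p.value, 0.05)

  expect_warning(r4 <- response_variance_test(c(2, 2, 2), c(4, 4)), "constant")
  expect_equal(r4$p.value, 1)
})
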