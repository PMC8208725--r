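test_that("gene induction calls require both the fold-change and q-value gates", {
  expr <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    strain = "s1",
    condition = rep(c("basal", "il4"), 3),
    replicate = 1L,
    tpm = c(10, 50, 10, 50, 10, 15),
    count = 100L,
    q = rep(c(0.001, 0.2, 0.001), each = 2))
  calls <- call_induced_genes(expr, "s1")
  expect_equal(calls$induced, c(TRUE, FALSE, FALSE))
  expect_false(any(calls$repressed))
  expect_error(call_induced_genes(expr[expr$condition == "basal", ], "s1"),
               "missing condition")
})

test_that("basal categories split at the documented ratios with pseudocounts", {
  cfg <- pipeline_config()
  expect_equal(categorize_gene(10, 20, cfg), "high_basal")
  expect_equal(categorize_gene(10, 10, cfg), "equal_basal")
  expect_equal(categorize_gene(15, 9, cfg), "low_basal") # (16)/(10) = 1.6
  expect_equal(categorize_enhancer(15, 40, cfg), "high_basal")
  expect_equal(categorize_enhancer(20, 18, cfg), "equal_basal")
  expect_equal(categorize_enhancer(30, 8, cfg), "low_basal")
  expect_error(categorize_gene(-1, 5, cfg), "non-negative")
})

test_that("every basal ratio receives exactly one category (grid property)", {
  cfg <- pipeline_config()
  b_ind <- rep(seq(0, 60, by = 0.5), times = 121)
  b_non <- rep(seq(0, 60, by = 0.5), each = 121)
  cat <- categorize_gene(b_ind, b_non, cfg)
  expect_true(all(cat %in% c("low_basal", "equal_basal", "high_basal")))
  r <- (b_non + 1) / (b_ind + 1)
  expect_true(all((cat == "high_basal") == (r >= cfg$gene_basal_fc)))
  expect_true(all((cat == "low_basal") == (1 / r >= cfg$gene_basal_fc)))
})

test_that("differential tiers are cumulative with strict boundaries", {
  cfg <- pipeline_config()
  t1 <- differential_tiers(11, 9, cfg)     # ratio 1.2
  expect_true(t1$similar)
  expect_false(t1$`tier_gt_1.5`)
  t2 <- differential_tiers(899, 199, cfg)  # ratio 4.5
  expect_false(t2$similar)
  expect_true(all(unlist(t2[paste0("tier_gt_", c(1.5, 2, 3, 4))])))
  t3 <- differential_tiers(29, 19, cfg)    # ratio exactly 1.5
  expect_false(t3$similar)
  expect_false(t3$`tier_gt_1.5`)
})

test_that("variant overlap uses the inclusive centered window", {
  cfg <- pipeline_config()
  el <- data.frame(chrom = "chrS", start = 1000L, end = 1200L, id = "e1",
                   kind = "enhancer")
  v <- function(pos) data.frame(chrom = "chrS", pos = pos, ref = "A",
                                alt = "G", strain = "s2")
  expect_true(element_has_variant(el, v(1095L), 150L))  # window [950, 1250]
  expect_true(element_has_variant(el, v(1250L), 150L))
  expect_false(element_has_variant(el, v(1251L), 150L))

  el4 <- data.frame(chrom = "chrS", start = c(0, 3000, 6000, 9000),
                    end = c(300, 3300, 6300, 9300),
                    id = paste0("e", 1:4), kind = "enhancer")
  vs <- v(c(150L, 3100L, 6200L))
  expect_equal(unname(variant_overlap_fraction(el4, vs, rep("g", 4), cfg)), 0.75)
  expect_true(is.na(variant_overlap_fraction(el4[0, ], vs, character(0), cfg)["g"]) ||
                length(variant_overlap_fraction(el4[0, ], vs, character(0), cfg)) == 0)

  # monotone non-decreasing in window size
  set.seed(8)
  vr <- v(sort(sample.int(10000, 40)))
  fr <- vapply(c(50L, 150L, 300L, 600L), function(w)
    mean(element_has_variant(el4, vr, w)), 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("cis/trans classification follows the log2 window and attenuation gates", {
  cfg <- pipeline_config()
  expect_equal(cis_trans_classify(8, 6, cfg), "cis")
  expect_equal(cis_trans_classify(8, 1, cfg), "trans")
  expect_equal(cis_trans_classify(1.5, 0.5, cfg), "unclassified")
  # repressed-direction symmetry
  expect_equal(cis_trans_classify(1 / 8, 1.05, cfg), "trans")
  expect_error(cis_trans_classify(0, 1, cfg), "positive")
})

test_that("F1 allelic assignment is proportional and filters uninformative alleles", {
  r <- assign_f1_allelic_counts(100, 15, 5)
  expect_equal(r$count_a, 75)
  expect_equal(r$count_b, 25)
  expect_false(r$filtered)
  r2 <- assign_f1_allelic_counts(100, 10, 0)
  expect_true(r2$filtered)
  expect_true(is.na(r2$count_a))
  r3 <- assign_f1_allelic_counts(80, 7, 7)
  expect_equal(r3$count_a, r3$count_b)
})

test_that("strain comparison recovers planted mechanisms on a small dataset", {
  ds <- simulate_dataset(tiny_params(seed = 13, n_elements = 200))
  mr <- mechanism_recovery(ds)
  expect_gt(mr$recovery, 0.9)
  # zero-noise limit is exact
  ds0 <- simulate_dataset(tiny_params(seed = 13, n_elements = 200,
                                      noise_dispersion = 0))
  expect_equal(mechanism_recovery(ds0)$recovery, 1)
})
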