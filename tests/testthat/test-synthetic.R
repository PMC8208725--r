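test_that("generation is deterministic given the seed", {
  a <- simulate_dataset(tiny_params(seed = 5))
  b <- simulate_dataset(tiny_params(seed = 5))
  expect_identical(a, b)
  c <- simulate_dataset(tiny_params(seed = 6))
  expect_false(identical(a$genomes, c$genomes))
})

test_that("invalid mechanism mixes are rejected", {
  expect_error(generator_params(mechanism_mix = c(low_basal = 0.5, equal_basal = 0.2,
                                                  high_basal = 0.2, conserved = 0.2,
                                                  background = 0.2)), "sum to 1")
  expect_error(generator_params(mechanism_mix = c(a = 1)), "must be named")
  expect_error(generator_params(n_elements = 5), "n_elements")
})

test_that("pure conserved datasets show no strain differences at zero noise", {
  ds <- simulate_dataset(tiny_params(
    seed = 3, n_elements = 40, noise_dispersion = 0,
    mechanism_mix = c(low_basal = 0, equal_basal = 0, high_basal = 0,
                      conserved = 1, background = 0)))
  sA <- subset(ds$signals, strain == "strainA" & assay == "H3K27ac" & condition == "il4")
  sB <- subset(ds$signals, strain == "strainB" & assay == "H3K27ac" & condition == "il4")
  r <- sA$value[match(sB$element_id, sA$element_id)] / sB$value
  expect_true(all(r < 1.5 & r > 1 / 1.5))
})

test_that("pure equal-basal datasets meet the planted activity contract at zero noise", {
  cfg <- pipeline_config()
  ds <- simulate_dataset(tiny_params(
    seed = 3, n_elements = 40, noise_dispersion = 0,
    frac_promoter = 0, frac_wired = 0,
    mechanism_mix = c(low_basal = 0, equal_basal = 1, high_basal = 0,
                      conserved = 0, background = 0)))
  g <- function(str, cond) {
    sel <- ds$signals$strain == str & ds$signals$assay == "H3K27ac" &
      ds$signals$condition == cond
    stats::setNames(ds$signals$value[sel], ds$signals$element_id[sel])
  }
  ids <- ds$elements$id
  bA <- g("strainA", "basal")[ids]; iA <- g("strainA", "il4")[ids]
  bB <- g("strainB", "basal")[ids]; iB <- g("strainB", "il4")[ids]
  expect_true(all(abs(bA / bB - 1) < 1e-12))
  expect_true(all((iA + 1) / (bA + 1) >= cfg$induce_fc))
  expect_true(all((iB + 1) / (bB + 1) < cfg$neutral_fc))
})

test_that("variants applied to the strain-A genome reproduce strain B exactly", {
  ds <- simulate_dataset(tiny_params(seed = 9))
  gA <- strsplit(ds$genomes[["strainA"]], "")[[1]]
  gB <- strsplit(ds$genomes[["strainB"]], "")[[1]]
  edited <- gA
  expect_true(all(nchar(ds$variants$ref) == 1L))
  edited[ds$variants$pos + 1L] <- ds$variants$alt
  expect_identical(paste(edited, collapse = ""), paste(gB, collapse = ""))
  # and the variant table is exactly the set of differing positions
  expect_identical(sort(which(gA != gB) - 1L), sort(ds$variants$pos))
})

test_that("causal flags sit in responsive elements; silent flags never mutate motifs", {
  ds <- simulate_dataset(tiny_params(seed = 9))
  tv <- ds$truth$variants
  te <- ds$truth$elements
  mech <- te$mechanism[match(tv$element_id, te$element_id)]
  expect_true(all(mech[tv$causal] %in% c("low_basal", "equal_basal", "high_basal")))
  # causal edits change the planted-site occupancy of their strain-B element
  ca <- te[te$mechanism %in% c("low_basal", "equal_basal", "high_basal"), ]
  expect_true(all(ca$occL_B < ca$occL_A | ca$occL_B > ca$occL_A |
                    ca$occS_B < ca$occS_A))
  # silent variants leave both occupancies untouched
  sil_el <- unique(tv$element_id[!tv$causal])
  sil_only <- setdiff(sil_el, tv$element_id[tv$causal])
  se <- te[te$element_id %in% sil_only & te$mechanism %in% c("conserved", "background"), ]
  expect_true(all(se$occL_A == se$occL_B & se$occS_A == se$occS_B))
})

test_that("datasets survive a write/read round-trip and truth covers all elements", {
  ds <- simulate_dataset(tiny_params(seed = 2))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$genomes, ds$genomes)
  expect_equal(back$elements, ds$elements)
  expect_equal(back$variants, ds$variants)
  expect_equal(back$signals, ds$signals, tolerance = 1e-9)
  expect_equal(nrow(back$truth$elements), ds$params$n_elements)
  expect_equal(back$interactions[, 1:6], ds$interactions[, 1:6])
  expect_setequal(back$truth$genes$gene_id, ds$truth$genes$gene_id)
})
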