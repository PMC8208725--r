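rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

tiny_model <- function(seed = 1, seq_len = 40L) {
  arch <- list(filters = c(4L, 4L, 4L), kernels = c(8L, 5L, 3L),
               pools = c(2L, 2L), fc_units = 8L, seq_len = seq_len)
  set.seed(seed)
  structure(list(params = strainwise:::.init_net(arch), arch = arch,
                 log = data.frame(), auroc = NA_real_, split = NULL,
                 seq_len = seq_len, seed = seed),
            class = "strainwise_cnn")
}

test_that("one-hot encoding produces indicator columns with zeroed ambiguity", {
  X <- encode_sequences(c("ACGT", "ANNT"))
  expect_equal(dim(X), c(4L, 2L, 4L))
  expect_equal(apply(X[, 1, ], 1, sum), rep(1, 4))
  expect_equal(unname(apply(X[, 2, ], 1, sum)), c(1, 0, 0, 1))
  expect_error(encode_sequences(c("ACGT", "ACG")), "equal length")
})

test_that("network gradients match finite differences", {
  m <- tiny_model(seed = 7)
  seqs <- rand_dna(5, 40)
  X <- encode_sequences(seqs)
  y <- c(1, 0, 1, 0, 1)
  fw <- strainwise:::.net_forward(m$params, X, m$arch)
  dz <- (stats::plogis(fw$z) - y) / length(y)
  gr <- strainwise:::.net_backward(m$params, X, m$arch, fw, dz)
  lossfn <- function(par) {
    f <- strainwise:::.net_forward(par, X, m$arch)
    strainwise:::.bce_loss(f$z, y)
  }
  eps <- 1e-6
  set.seed(3)
  for (nm in c("Wc1", "Wc3", "W1", "W2")) {
    i <- sample(length(m$params[[nm]]), 1)
    par2 <- m$params
    par2[[nm]][i] <- par2[[nm]][i] + eps
    expect_equal(gr[[nm]][i], (lossfn(par2) - lossfn(m$params)) / eps,
                 tolerance = 1e-4)
  }
})

test_that("functional-position selection takes the exact top quantile with left ties", {
  cfg <- pipeline_config()
  expect_length(predicted_functional_positions(runif(300), cfg), 60L)
  expect_equal(predicted_functional_positions(rep(1, 300), cfg), 1:60)
  # sort oracle on random tracks
  set.seed(12)
  for (i in 1:50) {
    sc <- rnorm(300)
    got <- predicted_functional_positions(sc, cfg)
    expect_equal(got, sort(sort.list(-sc)[1:60]))
  }
})

test_that("GC-matched backgrounds respect tolerance, distance and non-overlap", {
  ds <- simulate_dataset(tiny_params(seed = 31, n_elements = 60))
  el <- ds$elements[1:30, ]
  bg <- sample_gc_matched_background(ds$genomes[["strainA"]], el, seed = 4)
  bg2 <- sample_gc_matched_background(ds$genomes[["strainA"]], el, seed = 4)
  expect_identical(bg, bg2)
  gc <- function(iv) vapply(seq_len(nrow(iv)), function(r)
    strainwise:::.gc_content(substr(ds$genomes[["strainA"]], iv$start[r] + 1,
                                    iv$end[r])), 0)
  expect_true(all(abs(gc(bg) - gc(el)) <= 0.02 + 1e-12))
  expect_true(all(bg$end - bg$start == el$end - el$start))
  # no overlap with any foreground interval
  for (r in seq_len(nrow(bg)))
    expect_false(any(bg$start[r] < el$end & bg$end[r] > el$start))
})

test_that("importance tracks are reverse-complement symmetric by construction", {
  m <- tiny_model(seed = 9)
  seqs <- rand_dna(6, 40)
  tr <- importance_scores(m, seqs)
  rc <- strainwise:::.revcomp(seqs)
  tr_rc <- importance_scores(m, rc)
  expect_equal(unname(tr_rc), unname(tr[, rev(seq_len(ncol(tr))), drop = FALSE]),
               tolerance = 1e-12)
  expect_true(all(tr >= 0))
  expect_error(importance_scores(m, rand_dna(1, 39)), "input length")
})

test_that("a constant-output model attributes zero importance everywhere", {
  m <- tiny_model(seed = 2)
  m$params <- lapply(m$params, function(p) p * 0)
  tr <- importance_scores(m, "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  expect_true(all(tr == 0))
})

test_that("variant flags follow top positions of covering windows", {
  cfg <- pipeline_config(seq_len_bp = 40L, top_frac = 0.25) # top 10 of 40
  el <- data.frame(chrom = "chrS", start = 100L, end = 140L, id = "e1",
                   kind = "enhancer")
  sc <- matrix(0, 1, 40, dimnames = list("e1", NULL))
  sc[1, 1:10] <- 10:1 # positions 1..10 are the top-10 block
  v <- data.frame(chrom = "chrS",
                  pos = c(100L, 115L, 108L, 500L),
                  ref = c("A", "C", "AGCT", "G"),
                  alt = c("G", "T", "A", "C"),
                  strain = "s2", stringsAsFactors = FALSE)
  out <- prioritize_variants(v, sc, el, cfg)
  expect_equal(out$predicted_functional, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(out, "n_outside"), 1L)
})

test_that("category enrichment is the log2 ratio of group to global percentage", {
  flags <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 0), rep(FALSE, 10))
  groups <- rep(c("hot", "cold"), each = 10)
  enr <- category_enrichment(flags, groups)
  expect_equal(enr$log2_enrichment[enr$group == "hot"], 1)
  same <- category_enrichment(flags, rep("all", 20))
  expect_equal(same$log2_enrichment, 0)
})

test_that("k-mer scoring finds a planted high-importance k-mer", {
  set.seed(6)
  cfg <- pipeline_config(seq_len_bp = 50L)
  n <- 120
  seqs <- rand_dna(n, 50)
  substr(seqs, 21, 25) <- "TTCGA"
  tracks <- matrix(runif(n * 50, 0, 0.2), n, 50)
  tracks[, 21:25] <- tracks[, 21:25] + 1
  km <- kmer_interpretation(tracks, seqs, cfg)
  planted <- km[km$kmer == "TTCGA", ]
  expect_gt(planted$odds_ratio, 1)
  expect_lt(planted$p.value, 1e-4)
  expect_true("TTCGA" %in% km$kmer[1:5])

  # null: uniform scores, no k-mer survives Bonferroni
  tracks0 <- matrix(runif(n * 50), n, 50)
  km0 <- kmer_interpretation(tracks0, rand_dna(n, 50), cfg)
  expect_gt(min(km0$p.value) * nrow(km0), 0.05)
})

test_that("training rejects degenerate inputs", {
  cfg <- pipeline_config()
  few <- rand_dna(10, 300)
  expect_error(train_classifier(few, few, NULL, cfg), "at least")
  expect_error(train_classifier(rand_dna(2500, 300), rand_dna(220, 300),
                                NULL, cfg), "imbalance")
})

test_that("rank-based auROC agrees with an independent implementation", {
  set.seed(14)
  sc <- rnorm(200)
  y <- runif(200) < stats::plogis(sc)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, sc, quiet = TRUE))))
    expect_equal(auroc(sc, y), ref, tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
})
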