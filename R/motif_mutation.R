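# Motif-mutation association testing: do motif-score losses between
# homologous strain sequences track activity losses? Pairs are supplied
# pre-aligned by element id; positive sequences come from the responsive
# strain, negative sequences from the unresponsive strain.

#' Build homologous sequence pairs from a synthetic dataset
#'
#' For each element of the requested mechanisms, the strain-A (responsive)
#' window is the positive sequence and the strain-B window the negative
#' sequence.
#'
#' @param ds a `strainwise_dataset`.
#' @param mechanisms truth mechanisms to include (default `equal_basal`).
#' @param seq_len window length.
#' @return data.frame with `id`, `positive_seq`, `negative_seq`.
#' @export
strain_sequence_pairs <- function(ds, mechanisms = "equal_basal",
                                  seq_len = 300L) {
  ids <- ds$truth$elements$element_id[ds$truth$elements$mechanism %in% mechanisms]
  el <- ds$elements[match(ids, ds$elements$id), , drop = FALSE]
  data.frame(id = ids,
             positive_seq = unname(element_sequences(ds$genomes[["strainA"]], el, seq_len)),
             negative_seq = unname(element_sequences(ds$genomes[["strainB"]], el, seq_len)),
             stringsAsFactors = FALSE)
}

.pair_score_diffs <- function(pairs, p) {
  pos <- pairs$positive_seq; neg <- pairs$negative_seq
  same_len <- length(unique(nchar(c(pos, neg)))) == 1L
  if (same_len) {
    enc <- function(ss) {
      m <- matrix(match(unlist(strsplit(ss, "", fixed = TRUE)), .BASES),
                  nrow = length(ss), byrow = TRUE)
      m[is.na(m)] <- 5L
      m
    }
    .scan_best_scores(enc(pos), p) - .scan_best_scores(enc(neg), p)
  } else {
    best_motif_scores(pos, p) - best_motif_scores(neg, p)
  }
}

#' Motif-mutation association test
#'
#' For every pair, computes the difference of best motif log-odds scores
#' (positive minus negative sequence). Pairs with zero difference carry no
#' information about this motif and are dropped; the remaining differences
#' are tested against a zero median with a Wilcoxon signed-rank test (exact
#' null for fewer than 26 tie-free nonzero differences, normal approximation
#' with continuity correction otherwise). The summary statistic is
#' `sign(median difference) x -log10(p)`.
#'
#' @param pairs data.frame with `positive_seq`, `negative_seq` (and
#'   optionally `id`).
#' @param p a [pwm()].
#' @param min_pairs minimum number of pairs required (default 10).
#' @return a `strainwise_motif_result`: list with `motif`, `score_diffs`,
#'   `n_nonzero`, `p.value`, `signed_logp`.
#' @export
motif_mutation_test <- function(pairs, p, min_pairs = 10L) {
  if (nrow(pairs) < min_pairs)
    stop("need at least ", min_pairs, " sequence pairs", call. = FALSE)
  d <- .pair_score_diffs(pairs, p)
  nz <- d[d != 0]
  if (!length(nz)) {
    res <- list(motif = p$name, score_diffs = d, n_nonzero = 0L,
                p.value = 1, signed_logp = 0)
    class(res) <- "strainwise_motif_result"
    return(res)
  }
  exact <- length(nz) < 26L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(wilcox.test(nz, mu = 0, exact = exact,
                                     correct = TRUE))
  pv <- max(wt$p.value, .Machine$double.xmin)
  res <- list(motif = p$name, score_diffs = d, n_nonzero = length(nz),
              p.value = pv,
              signed_logp = sign(median(nz)) * -log10(pv))
  class(res) <- "strainwise_motif_result"
  res
}

#' @export
print.strainwise_motif_result <- function(x, ...) {
  cat(sprintf("motif %s: signed -log10 p = %.3f (n nonzero = %d)\n",
              x$motif, x$signed_logp, x$n_nonzero))
  invisible(x)
}

#' Run the motif-mutation test for a set of motifs
#'
#' @param pairs sequence pair data.frame.
#' @param pwms list of [pwm()] objects.
#' @param min_pairs minimum pairs per test.
#' @return data.frame with one row per motif (`motif`, `n_nonzero`,
#'   `p.value`, `signed_logp`, `padj` by Benjamini-Hochberg) and an attribute
#'   `"results"` holding the full result objects (including score-difference
#'   vectors used for clustering).
#' @export
motif_mutation_scan <- function(pairs, pwms, min_pairs = 10L) {
  results <- lapply(pwms, function(p) motif_mutation_test(pairs, p, min_pairs))
  out <- data.frame(
    motif = vapply(results, `[[`, "", "motif"),
    n_nonzero = vapply(results, `[[`, 0L, "n_nonzero"),
    p.value = vapply(results, `[[`, 0, "p.value"),
    signed_logp = vapply(results, `[[`, 0, "signed_logp"),
    stringsAsFactors = FALSE)
  out$padj <- p.adjust(out$p.value, "BH")
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Cluster motifs by correlation of their score-difference vectors
#'
#' Pearson correlation between per-pair score differences; motifs linked at
#' correlation above the threshold are grouped by single linkage. Motifs with
#' constant score differences have undefined correlation and form
#' singletons. Each cluster reports the mean signed statistic and the member
#' with the largest absolute statistic as representative.
#'
#' @param results list of `strainwise_motif_result` (all computed on the same
#'   pair set), or the output of [motif_mutation_scan()].
#' @param cfg a [pipeline_config()] supplying `motif_cluster_corr`.
#' @return data.frame with `cluster`, `members` (comma-separated),
#'   `representative`, `mean_signed_logp`.
#' @export
cluster_motifs <- function(results, cfg = pipeline_config()) {
  validate_config(cfg)
  if (is.data.frame(results)) results <- attr(results, "results")
  nm <- vapply(results, `[[`, "", "motif")
  D <- do.call(cbind, lapply(results, `[[`, "score_diffs"))
  colnames(D) <- nm
  k <- ncol(D)
  constant <- apply(D, 2, function(v) stats::sd(v) == 0)
  # union-find single linkage over pairs correlated above threshold
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1L) {
    suppressWarnings(C <- cor(D))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (constant[i] || constant[j]) next
      if (!is.na(C[i, j]) && C[i, j] > cfg$motif_cluster_corr) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(k), find, 0L)
  slp <- vapply(results, `[[`, 0, "signed_logp")
  out <- do.call(rbind, lapply(unique(root), function(r) {
    idx <- which(root == r)
    data.frame(members = paste(nm[idx], collapse = ","),
               representative = nm[idx][which.max(abs(slp[idx]))],
               mean_signed_logp = mean(slp[idx]),
               n_members = length(idx),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-abs(out$mean_signed_logp)), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("cluster", "members", "representative", "mean_signed_logp", "n_members")]
}

#' Filter motif clusters by factor gene expression
#'
#' Keeps a cluster when any member motif maps to a gene with TPM above
#' `expr_filter_tpm` in any strain/condition. Unmapped motifs are treated as
#' non-expressed with a warning.
#'
#' @param clusters output of [cluster_motifs()].
#' @param expr expression table.
#' @param motif_gene named character vector mapping motif name to gene id.
#' @param cfg a [pipeline_config()].
#' @return the kept rows of `clusters`.
#' @export
expression_filter <- function(clusters, expr, motif_gene,
                              cfg = pipeline_config()) {
  validate_config(cfg)
  max_tpm <- tapply(expr$tpm, expr$gene_id, max)
  keep <- vapply(clusters$members, function(ms) {
    members <- strsplit(ms, ",", fixed = TRUE)[[1L]]
    genes <- motif_gene[members]
    if (any(is.na(genes)))
      warning("motif(s) without gene mapping treated as non-expressed: ",
              paste(members[is.na(genes)], collapse = ", "), call. = FALSE)
    genes <- genes[!is.na(genes)]
    any(max_tpm[genes] > cfg$expr_filter_tpm, na.rm = TRUE)
  }, TRUE)
  clusters[keep, , drop = FALSE]
}
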