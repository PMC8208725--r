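# Interaction classification (E-E / E-P / P-P), promoter-enhancer state
# contingency, connected-enhancer correlation comparison, and attribution of
# variant-free differential enhancers to variants at connected enhancers.

.element_gr <- function(elements) {
  GenomicRanges::GRanges(elements$chrom,
                         IRanges::IRanges(elements$start + 1L, elements$end))
}

#' Classify interactions as enhancer-enhancer, enhancer-promoter or
#' promoter-promoter
#'
#' An anchor matches an element when their intervals overlap or are separated
#' by at most `merge_dist_bp`. Anchors matching both a promoter and an
#' enhancer take promoter precedence (conservative E-P counting). The
#' interaction class is determined by the two anchor kinds; anchors matching
#' no element leave the interaction `unassigned`.
#'
#' @param interactions interaction data.frame (see [read_bedpe()]).
#' @param elements element interval data.frame with `kind` annotated.
#' @param cfg a [pipeline_config()].
#' @return `interactions` with added columns `anchor1_elements`,
#'   `anchor2_elements` (comma-separated ids), `anchor1_kind`,
#'   `anchor2_kind`, `anchor1_best`, `anchor2_best` (nearest matched element
#'   of the anchor kind) and `class`.
#' @export
classify_interactions <- function(interactions, elements,
                                  cfg = pipeline_config()) {
  validate_config(cfg)
  el_gr <- .element_gr(elements)
  annotate_anchor <- function(chrom, start, end) {
    agr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    hits <- GenomicRanges::findOverlaps(agr, el_gr, maxgap = cfg$merge_dist_bp)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::distance(agr[q], el_gr[s])
    ids <- rep("", length(agr)); kind <- rep("unassigned", length(agr))
    best <- rep(NA_character_, length(agr))
    for (i in unique(q)) {
      sel <- q == i
      eids <- elements$id[s[sel]]
      ekind <- elements$kind[s[sel]]
      ids[i] <- paste(eids, collapse = ",")
      k <- if (any(ekind == "promoter")) "promoter"
      else if (any(ekind == "enhancer")) "enhancer" else "unassigned"
      kind[i] <- k
      if (k != "unassigned") {
        cand <- which(ekind == k)
        best[i] <- eids[cand[which.min(d[sel][cand])]]
      }
    }
    list(ids = ids, kind = kind, best = best)
  }
  a1 <- annotate_anchor(interactions$chrom1, interactions$start1, interactions$end1)
  a2 <- annotate_anchor(interactions$chrom2, interactions$start2, interactions$end2)
  cls <- rep("unassigned", nrow(interactions))
  k1 <- a1$kind; k2 <- a2$kind
  cls[k1 == "promoter" & k2 == "promoter"] <- "promoter-promoter"
  cls[(k1 == "promoter" & k2 == "enhancer") |
        (k1 == "enhancer" & k2 == "promoter")] <- "enhancer-promoter"
  cls[k1 == "enhancer" & k2 == "enhancer"] <- "enhancer-enhancer"
  interactions$anchor1_elements <- a1$ids
  interactions$anchor2_elements <- a2$ids
  interactions$anchor1_kind <- k1
  interactions$anchor2_kind <- k2
  interactions$anchor1_best <- a1$best
  interactions$anchor2_best <- a2$best
  interactions$class <- cls
  interactions
}

#' Promoter-enhancer state contingency table with Fisher tests
#'
#' Counts enhancer-promoter interactions by (promoter state x enhancer
#' state) over induced/neutral/repressed, then tests three collapsed 2x2
#' comparisons two-sided: induced-induced versus the rest of both margins,
#' repressed-repressed likewise, and induced versus repressed restricted to
#' those two states.
#'
#' @param classified output of [classify_interactions()].
#' @param states named character vector (element id -> state from
#'   [classify_elements()]).
#' @return list with `table` (3x3 matrix) and `tests` (named list of
#'   `fisher.test` results).
#' @export
promoter_enhancer_contingency <- function(classified, states) {
  ep <- classified[classified$class == "enhancer-promoter", , drop = FALSE]
  if (!nrow(ep)) stop("no enhancer-promoter interactions", call. = FALSE)
  p_el <- ifelse(ep$anchor1_kind == "promoter", ep$anchor1_best, ep$anchor2_best)
  e_el <- ifelse(ep$anchor1_kind == "promoter", ep$anchor2_best, ep$anchor1_best)
  ps <- states[p_el]; es <- states[e_el]
  lev <- c("induced", "neutral", "repressed")
  keep <- ps %in% lev & es %in% lev
  if (!any(keep)) stop("no interactions with classified states", call. = FALSE)
  tab <- table(factor(ps[keep], lev), factor(es[keep], lev))
  names(dimnames(tab)) <- c("promoter", "enhancer")
  collapse <- function(pstate, estate) {
    m <- matrix(c(tab[pstate, estate],
                  sum(tab[pstate, ]) - tab[pstate, estate],
                  sum(tab[, estate]) - tab[pstate, estate],
                  sum(tab) - sum(tab[pstate, ]) - sum(tab[, estate]) +
                    tab[pstate, estate]), 2L)
    fisher.test(m)
  }
  ind_rep <- tab[c("induced", "repressed"), c("induced", "repressed")]
  tests <- list(
    induced_vs_noninduced = collapse("induced", "induced"),
    repressed_vs_nonrepressed = collapse("repressed", "repressed"),
    induced_vs_repressed = if (all(rowSums(ind_rep) > 0) && all(colSums(ind_rep) > 0))
      fisher.test(ind_rep) else NULL)
  list(table = unclass(tab), tests = tests)
}

.cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

#' Compare activity correlations of connected versus unconnected enhancers
#'
#' For strongly strain-differential enhancers (between-strain fold difference
#' of at least `fc_filter`), computes the Pearson correlation of H3K27ac
#' across strains for every connected (interactive) pair, and for two null
#' constructions: random pairs of preselected enhancers on the same
#' chromosome, and distance-matched unconnected pairs. Connected
#' correlations are compared to each null with a Mann-Whitney U test;
#' Cohen's d is reported as effect size.
#'
#' @param ee_pairs data.frame with columns `id1`, `id2` of connected
#'   enhancer pairs.
#' @param signal_matrix numeric matrix (elements x strains) of H3K27ac, at
#'   least 3 strains.
#' @param elements interval data.frame (for chromosome and distance).
#' @param cfg a [pipeline_config()].
#' @param fc_filter between-strain fold-difference preselection (default 4).
#' @param dist_tol_bp distance-matching tolerance (default 1e5).
#' @param n_random number of random null pairs (default: number of connected
#'   pairs).
#' @param seed integer seed for the null draws.
#' @return list with correlation vectors (`connected`, `random`,
#'   `dist_matched`) and test summaries.
#' @export
connected_correlation_comparison <- function(ee_pairs, signal_matrix, elements,
                                             cfg = pipeline_config(),
                                             fc_filter = 4, dist_tol_bp = 1e5,
                                             n_random = NULL, seed = 1L) {
  validate_config(cfg)
  if (ncol(signal_matrix) < 3L)
    stop("correlation across strains needs at least 3 strains", call. = FALSE)
  set.seed(seed)
  rng <- (apply(signal_matrix, 1, max) + 1) / (apply(signal_matrix, 1, min) + 1)
  pre <- rownames(signal_matrix)[rng >= fc_filter]
  keep <- ee_pairs$id1 %in% pre & ee_pairs$id2 %in% pre &
    ee_pairs$id1 != ee_pairs$id2
  pairs <- ee_pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3L)
    stop("fewer than 3 connected pairs pass the fold-change preselection",
         call. = FALSE)
  pair_r <- function(i1, i2)
    vapply(seq_along(i1), function(j)
      cor(signal_matrix[i1[j], ], signal_matrix[i2[j], ]), 0)
  r_conn <- pair_r(pairs$id1, pairs$id2)
  center <- stats::setNames((elements$start + elements$end) %/% 2L, elements$id)
  chrom <- stats::setNames(elements$chrom, elements$id)
  if (is.null(n_random)) n_random <- nrow(pairs)
  # same-chromosome random pairs among preselected enhancers
  rnd1 <- character(0); rnd2 <- character(0)
  guard <- 0L
  while (length(rnd1) < n_random && guard < 50L * n_random) {
    guard <- guard + 1L
    c1 <- sample(pre, 1L)
    cand <- pre[chrom[pre] == chrom[c1] & pre != c1]
    if (!length(cand)) next
    rnd1 <- c(rnd1, c1); rnd2 <- c(rnd2, sample(cand, 1L))
  }
  r_rand <- pair_r(rnd1, rnd2)
  # distance-matched unconnected pairs
  conn_key <- c(paste(pairs$id1, pairs$id2), paste(pairs$id2, pairs$id1))
  dm1 <- character(0); dm2 <- character(0)
  d_conn <- abs(center[pairs$id1] - center[pairs$id2])
  for (j in seq_len(nrow(pairs))) {
    found <- FALSE
    for (t in seq_len(100L)) {
      c1 <- sample(pre, 1L)
      cand <- pre[chrom[pre] == chrom[c1] & pre != c1 &
                    abs(abs(center[pre] - center[c1]) - d_conn[j]) <= dist_tol_bp]
      cand <- setdiff(cand, c1)
      if (!length(cand)) next
      c2 <- sample(cand, 1L)
      if (paste(c1, c2) %in% conn_key) next
      dm1 <- c(dm1, c1); dm2 <- c(dm2, c2); found <- TRUE; break
    }
  }
  r_dist <- if (length(dm1)) pair_r(dm1, dm2) else numeric(0)
  mw <- function(a, b) if (length(a) >= 2L && length(b) >= 2L)
    suppressWarnings(wilcox.test(a, b)) else NULL
  list(connected = r_conn, random = r_rand, dist_matched = r_dist,
       test_vs_random = mw(r_conn, r_rand),
       test_vs_dist_matched = mw(r_conn, r_dist),
       cohens_d_random = if (length(r_rand) >= 2L) .cohens_d(r_conn, r_rand) else NA_real_,
       cohens_d_dist = if (length(r_dist) >= 2L) .cohens_d(r_conn, r_dist) else NA_real_)
}

#' Attribute differential enhancers to local versus connected functional
#' variants
#'
#' Each differential enhancer is assigned exactly one label: `local_only`
#' when it carries a predicted-functional variant within
#' `variant_window_bp` of its center and none of its connected enhancers do;
#' `both_ends` when both; `connected_only` when only a connected enhancer
#' carries one; `neither` otherwise. Enhancers without interactions can only
#' be `local_only` or `neither`.
#'
#' @param diff_ids character vector of differential enhancer element ids.
#' @param flagged_variants variant table with `predicted_functional` column
#'   (see [prioritize_variants()]).
#' @param classified classified interactions ([classify_interactions()]).
#' @param elements element interval data.frame.
#' @param cfg a [pipeline_config()].
#' @return data.frame with `element_id`, `attribution`, plus attribute
#'   `"percentages"` (named percentage vector over the four categories).
#' @export
attribute_differential_enhancers <- function(diff_ids, flagged_variants,
                                             classified, elements,
                                             cfg = pipeline_config()) {
  validate_config(cfg)
  fv <- flagged_variants[flagged_variants$predicted_functional, , drop = FALSE]
  has_local <- stats::setNames(
    element_has_variant(elements, fv, cfg$variant_window_bp), elements$id)
  ee <- classified[classified$class == "enhancer-enhancer", , drop = FALSE]
  split_ids <- function(x) strsplit(x, ",", fixed = TRUE)
  a1 <- split_ids(ee$anchor1_elements)
  a2 <- split_ids(ee$anchor2_elements)
  partners <- stats::setNames(vector("list", length(diff_ids)), diff_ids)
  for (j in seq_len(nrow(ee))) {
    in1 <- intersect(a1[[j]], diff_ids)
    in2 <- intersect(a2[[j]], diff_ids)
    for (e in in1)
      partners[[e]] <- union(partners[[e]], setdiff(a2[[j]], e))
    for (e in in2)
      partners[[e]] <- union(partners[[e]], setdiff(a1[[j]], e))
  }
  enh_ids <- elements$id[elements$kind != "promoter"]
  attribution <- vapply(diff_ids, function(e) {
    loc <- isTRUE(has_local[[e]])
    conn_els <- intersect(partners[[e]], enh_ids)
    conn <- length(conn_els) > 0L && any(has_local[conn_els], na.rm = TRUE)
    if (loc && conn) "both_ends"
    else if (loc) "local_only"
    else if (conn) "connected_only"
    else "neither"
  }, "")
  out <- data.frame(element_id = diff_ids, attribution = attribution,
                    stringsAsFactors = FALSE)
  lev <- c("local_only", "both_ends", "connected_only", "neither")
  pct <- 100 * table(factor(attribution, lev)) / length(attribution)
  attr(out, "percentages") <- stats::setNames(as.numeric(pct), lev)
  out
}
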