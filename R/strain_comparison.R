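# Pairwise strain categorization of induced genes and enhancers
# (low/equal/high basal), strain-similar/differential tiers, variant overlap
# fractions and F1-based cis/trans decomposition.

#' Call stimulus-induced and -repressed genes
#'
#' A gene is induced when its pseudocounted mean TPM fold change
#' `(stim + 1)/(basal + 1)` exceeds `gene_induce_fc` and its differential
#' q-value is below 0.05; repressed reciprocally.
#'
#' @param expr expression table (see [read_expression_table()]).
#' @param strain strain to analyse.
#' @param cfg a [pipeline_config()].
#' @param conditions basal and stimulated condition labels.
#' @return data.frame with `gene_id`, `fc`, `q`, `induced`, `repressed`.
#' @export
call_induced_genes <- function(expr, strain, cfg = pipeline_config(),
                               conditions = c("basal", "il4")) {
  validate_config(cfg)
  e <- expr[expr$strain == strain, , drop = FALSE]
  genes <- unique(expr$gene_id)
  agg <- function(cond) {
    sel <- e$condition == cond
    out <- tapply(e$tpm[sel], e$gene_id[sel], mean)
    miss <- setdiff(genes, names(out))
    if (length(miss))
      stop("gene '", miss[1L], "' is missing condition '", cond,
           "' for strain ", strain, call. = FALSE)
    out[genes]
  }
  basal <- agg(conditions[1L]); stim <- agg(conditions[2L])
  q <- tapply(e$q, e$gene_id, function(v) v[1L])[genes]
  fc <- (stim + 1) / (basal + 1)
  data.frame(gene_id = genes, fc = unname(fc), q = unname(q),
             induced = unname(fc > cfg$gene_induce_fc & !is.na(q) & q < 0.05),
             repressed = unname(fc < 1 / cfg$gene_induce_fc & !is.na(q) & q < 0.05),
             stringsAsFactors = FALSE)
}

.basal_category <- function(basal_induced, basal_noninduced, fc_threshold) {
  r_high <- (basal_noninduced + 1) / (basal_induced + 1)
  ifelse(r_high >= fc_threshold, "high_basal",
         ifelse(1 / r_high >= fc_threshold, "low_basal", "equal_basal"))
}

#' Categorize a strain-differential induced gene by basal expression
#'
#' For a gene induced in exactly one strain of a pair, compares basal
#' expression (pseudocount 1): `high_basal` when the noninduced strain has at
#' least `gene_basal_fc`-fold more basal expression, `low_basal` when the
#' induced strain does, `equal_basal` in between.
#'
#' @param basal_induced_strain,basal_noninduced_strain basal TPM in the
#'   induced and noninduced strain.
#' @param cfg a [pipeline_config()].
#' @return character vector of categories.
#' @export
categorize_gene <- function(basal_induced_strain, basal_noninduced_strain,
                            cfg = pipeline_config()) {
  validate_config(cfg)
  if (any(basal_induced_strain < 0) || any(basal_noninduced_strain < 0))
    stop("basal TPM must be non-negative", call. = FALSE)
  .basal_category(basal_induced_strain, basal_noninduced_strain, cfg$gene_basal_fc)
}

#' Categorize a strain-differential induced enhancer by basal H3K27ac
#'
#' Same three-way split as [categorize_gene()] at the `enhancer_basal_fc`
#' threshold (default twofold).
#'
#' @param basal_induced_strain,basal_noninduced_strain basal H3K27ac in the
#'   induced and noninduced strain.
#' @param cfg a [pipeline_config()].
#' @return character vector of categories.
#' @export
categorize_enhancer <- function(basal_induced_strain, basal_noninduced_strain,
                                cfg = pipeline_config()) {
  validate_config(cfg)
  if (any(basal_induced_strain < 0) || any(basal_noninduced_strain < 0))
    stop("basal signal must be non-negative", call. = FALSE)
  .basal_category(basal_induced_strain, basal_noninduced_strain,
                  cfg$enhancer_basal_fc)
}

#' Pairwise strain comparison of stimulus-induced enhancers
#'
#' Classifies both strains with [classify_elements()], keeps elements induced
#' in exactly one strain whose H3K27ac induction fold changes differ more
#' than `gene_induce_fc`-fold between the strains, and assigns each a
#' low/equal/high basal category from the basal H3K27ac ratio.
#'
#' @param signals signal table covering both strains.
#' @param strains length-2 character vector of strain names.
#' @param cfg a [pipeline_config()].
#' @param conditions basal and stimulated condition labels.
#' @return data.frame with `element_id`, `induced_strain`,
#'   `noninduced_strain`, `basal_ratio` (noninduced/induced, pseudocounted),
#'   `category`.
#' @export
compare_strain_enhancers <- function(signals, strains = c("strainA", "strainB"),
                                     cfg = pipeline_config(),
                                     conditions = c("basal", "il4")) {
  validate_config(cfg)
  c1 <- classify_elements(signals, strains[1L], cfg, conditions)
  c2 <- classify_elements(signals, strains[2L], cfg, conditions)
  m <- merge(c1, c2, by = "element_id", suffixes = c("_1", "_2"))
  one_ind <- xor(m$state_1 == "induced", m$state_2 == "induced")
  fc_gap <- pmax(m$fc_h3k27ac_1, m$fc_h3k27ac_2) /
    pmin(m$fc_h3k27ac_1, m$fc_h3k27ac_2)
  m <- m[one_ind & fc_gap > cfg$gene_induce_fc, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(element_id = character(), induced_strain = character(),
                      noninduced_strain = character(), basal_ratio = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  ind1 <- m$state_1 == "induced"
  ind_strain <- ifelse(ind1, strains[1L], strains[2L])
  non_strain <- ifelse(ind1, strains[2L], strains[1L])
  b1 <- .signal_lookup(signals, strains[1L], "H3K27ac", conditions[1L])[m$element_id]
  b2 <- .signal_lookup(signals, strains[2L], "H3K27ac", conditions[1L])[m$element_id]
  b_ind <- ifelse(ind1, b1, b2)
  b_non <- ifelse(ind1, b2, b1)
  data.frame(element_id = m$element_id, induced_strain = ind_strain,
             noninduced_strain = non_strain,
             basal_ratio = (b_non + 1) / (b_ind + 1),
             category = categorize_enhancer(b_ind, b_non, cfg),
             stringsAsFactors = FALSE)
}

#' Assign strain-difference tiers to enhancers
#'
#' Uses stimulated-condition H3K27ac of the two strains (pseudocount 1,
#' either direction). Elements with ratio below `similar_fc` are
#' strain-similar; tiers are cumulative, so an element belongs to every tier
#' whose threshold its ratio strictly exceeds. Comparisons at exactly a
#' threshold are neither similar nor in that tier (strict inequalities).
#'
#' @param h3k27ac_1,h3k27ac_2 stimulated H3K27ac per element in each strain.
#' @param cfg a [pipeline_config()].
#' @return data.frame with `ratio` (max direction), `similar` (logical), and
#'   one logical column `tier_gt_<t>` per configured tier.
#' @export
differential_tiers <- function(h3k27ac_1, h3k27ac_2, cfg = pipeline_config()) {
  validate_config(cfg)
  r <- pmax((h3k27ac_1 + 1) / (h3k27ac_2 + 1), (h3k27ac_2 + 1) / (h3k27ac_1 + 1))
  out <- data.frame(ratio = r, similar = r < cfg$similar_fc)
  for (t in cfg$differential_tiers)
    out[[paste0("tier_gt_", t)]] <- r > t
  out
}

#' Fraction of elements containing at least one variant near their center
#'
#' Searches `variant_window_bp` to either side of the element center
#' (both ends inclusive) and reports, per group, the fraction of elements
#' with one or more variants. Empty groups give `NA`.
#'
#' @param elements interval data.frame.
#' @param variants variant table (0-based positions).
#' @param groups factor/character of group labels, one per element.
#' @param cfg a [pipeline_config()].
#' @return named numeric vector of fractions per group level.
#' @export
variant_overlap_fraction <- function(elements, variants, groups,
                                     cfg = pipeline_config()) {
  validate_config(cfg)
  if (length(groups) != nrow(elements))
    stop("groups must have one label per element", call. = FALSE)
  has <- element_has_variant(elements, variants, cfg$variant_window_bp)
  groups <- as.factor(groups)
  vapply(levels(groups), function(g) {
    sel <- groups == g
    if (!any(sel)) NA_real_ else mean(has[sel])
  }, 0)
}

#' Which elements contain a variant within a centered window
#' @param elements interval data.frame.
#' @param variants variant table (0-based positions).
#' @param window_bp half-width of the window around each element center.
#' @return logical vector, one per element.
#' @export
element_has_variant <- function(elements, variants, window_bp = 150L) {
  center <- (elements$start + elements$end) %/% 2L
  out <- logical(nrow(elements))
  for (chr in unique(elements$chrom)) {
    vsel <- variants$chrom == chr
    esel <- elements$chrom == chr
    if (!any(vsel)) next
    vp <- sort(variants$pos[vsel])
    lo <- center[esel] - window_bp
    hi <- center[esel] + window_bp
    # count of variants <= hi minus count < lo
    out[esel] <- (findInterval(hi, vp) - findInterval(lo - 1L, vp)) > 0L
  }
  out
}

#' Classify a gene as cis, trans or unclassified from parental and F1 fold
#' changes
#'
#' A gene is `cis` when the parental strain ratio is preserved between the F1
#' alleles (`|log2(parental) - log2(F1)| < cis_window_log2`); otherwise
#' `trans` when the parental ratio reaches `parental_fc_min` in either
#' direction and the F1 ratio is attenuated toward 1 relative to the parental
#' ratio; otherwise `unclassified`.
#'
#' @param parental_fc strain-1/strain-2 expression ratio in the parents.
#' @param f1_fc allele-1/allele-2 ratio in the F1 hybrid.
#' @param cfg a [pipeline_config()].
#' @return character vector in `c("cis", "trans", "unclassified")`.
#' @export
cis_trans_classify <- function(parental_fc, f1_fc, cfg = pipeline_config()) {
  validate_config(cfg)
  if (any(parental_fc <= 0) || any(f1_fc <= 0))
    stop("fold changes must be positive", call. = FALSE)
  lp <- log2(parental_fc); lf <- log2(f1_fc)
  ifelse(abs(lp - lf) < cfg$cis_window_log2, "cis",
         ifelse(abs(lp) >= log2(cfg$parental_fc_min) & abs(lf) < abs(lp),
                "trans", "unclassified"))
}

#' Assign total transcript counts to F1 alleles
#'
#' Distributes each transcript's total count proportionally to the
#' variant-overlapping (informative) reads observed per allele. Transcripts
#' with zero informative reads for either allele are flagged `filtered` and
#' receive no counts.
#'
#' @param total_count total read count per transcript.
#' @param informative_a,informative_b informative read counts per allele.
#' @return data.frame with `count_a`, `count_b`, `filtered`.
#' @export
assign_f1_allelic_counts <- function(total_count, informative_a, informative_b) {
  if (any(total_count < 0) || any(informative_a < 0) || any(informative_b < 0))
    stop("counts must be non-negative", call. = FALSE)
  tot <- informative_a + informative_b
  filtered <- informative_a == 0 | informative_b == 0
  frac <- ifelse(tot > 0, informative_a / tot, NA_real_)
  data.frame(count_a = ifelse(filtered, NA_real_, total_count * frac),
             count_b = ifelse(filtered, NA_real_, total_count * (1 - frac)),
             filtered = filtered)
}

#' Recover planted mechanism categories on a synthetic dataset
#'
#' Convenience wrapper used in validation: runs [compare_strain_enhancers()]
#' and scores the assignments against the generator's truth labels for
#' low/equal/high-basal elements.
#'
#' @param ds a `strainwise_dataset`.
#' @param cfg a [pipeline_config()].
#' @return list with the comparison table (`calls`), the per-element truth
#'   join (`joined`), and the overall `recovery` fraction.
#' @export
mechanism_recovery <- function(ds, cfg = pipeline_config()) {
  calls <- compare_strain_enhancers(ds$signals, c("strainA", "strainB"), cfg)
  truth <- ds$truth$elements
  planted <- truth[truth$mechanism %in% c("low_basal", "equal_basal",
                                          "high_basal"), , drop = FALSE]
  j <- merge(planted, calls, by = "element_id", all.x = TRUE)
  correct <- !is.na(j$category) & j$category == j$mechanism &
    j$induced_strain == "strainA"
  list(calls = calls, joined = j, recovery = mean(correct))
}

#' Recover planted cis/trans labels on a synthetic dataset
#'
#' Computes parental fold changes from stimulated-condition mean TPM and F1
#' fold changes from the allelic counts (both pseudocounted), classifies with
#' [cis_trans_classify()] and scores against truth.
#'
#' @param ds a `strainwise_dataset`.
#' @param cfg a [pipeline_config()].
#' @param condition condition used for the parental contrast.
#' @return list with the classification table and recovery fractions for
#'   planted cis and trans genes.
#' @export
cis_trans_recovery <- function(ds, cfg = pipeline_config(), condition = "il4") {
  e <- ds$expression[ds$expression$condition == condition, , drop = FALSE]
  mA <- tapply(e$tpm[e$strain == "strainA"], e$gene_id[e$strain == "strainA"], mean)
  mB <- tapply(e$tpm[e$strain == "strainB"], e$gene_id[e$strain == "strainB"], mean)
  genes <- ds$f1_counts$gene_id
  parental_fc <- (mA[genes] + 1) / (mB[genes] + 1)
  f1_fc <- (ds$f1_counts$count_A + 1) / (ds$f1_counts$count_B + 1)
  lab <- cis_trans_classify(unname(parental_fc), f1_fc, cfg)
  truth <- ds$truth$genes$label[match(genes, ds$truth$genes$gene_id)]
  tab <- data.frame(gene_id = genes, parental_fc = unname(parental_fc),
                    f1_fc = f1_fc, label = lab, truth = truth,
                    stringsAsFactors = FALSE)
  list(table = tab,
       cis_recovery = mean(lab[truth == "cis"] == "cis"),
       trans_recovery = mean(lab[truth == "trans"] == "trans"))
}
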