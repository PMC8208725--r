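# Synthetic strain-pair generator. Emulates the three mechanisms by which
# strain genetic variation alters stimulus-induced enhancer activity
# (low/equal/high basal), plus conserved, non-responsive and trans-regulated
# ("wired") elements, with ground-truth labels for every element, variant and
# gene.

#' Generator parameters
#'
#' Defaults define the study conditions for all synthetic experiments:
#' element activity follows an occupancy model in which a lineage factor
#' (LDTF) site licenses basal activity and the product of LDTF and
#' signal-dependent factor (SDTF) occupancies drives stimulus induction,
#' saturating at `act_max`. Motif occupancy is a logistic function of the
#' best log-odds site score. The defaults are calibrated so that conserved
#' elements induce ~4-fold, high-basal edits give >2-fold basal gain with
#' saturated (<1.4-fold) induction, and equal-basal edits abolish induction
#' while leaving basal signal untouched.
#'
#' @param n_elements total number of elements (promoter and trans-regulated
#'   elements are carved out of this total; the rest follow `mechanism_mix`).
#' @param n_genes number of genes.
#' @param chrom_len chromosome length; `NULL` = sized automatically.
#' @param ldtf_pwms,sdtf_pwms lists of [pwm()] objects; `NULL` = packaged
#'   ETS-like / GAS-like consensus matrices.
#' @param mechanism_mix named proportions over `low_basal`, `equal_basal`,
#'   `high_basal`, `conserved`, `background`; must sum to 1.
#' @param frac_promoter,frac_wired fractions of `n_elements` set aside as
#'   promoter elements and as variant-free trans-regulated ("wired")
#'   differential enhancers, each wired to a causal-variant low-basal
#'   partner. Wired elements require low-basal partners and are dropped when
#'   the mix contains none.
#' @param occupancy_slope logistic steepness (per bit) mapping best site
#'   log-odds to occupancy; `occ_max` is the consensus-site occupancy.
#' @param act_base,act_basal_coef,act_induced_coef,act_max H3K27ac activity
#'   model: `mu = min(base + basal_coef*occL + induced_coef*occL*occS*stim,
#'   act_max)`, in normalized tags per 1e7.
#' @param polii_scale RNA Pol II signal as a fraction of H3K27ac.
#' @param atac_base,atac_coef,tf_base,tf_coef accessory assay coefficients.
#' @param noise_dispersion negative-binomial overdispersion of simulated tag
#'   counts (variance `mu + phi mu^2`); 0 gives the deterministic mean.
#' @param n_replicates replicates per condition (signal tables carry the
#'   replicate average).
#' @param frac_silent_variants fraction of all planted variants that are
#'   silent (outside motifs).
#' @param gene_mix named proportions over `cis`, `trans`, `none`.
#' @param gene_fc_log2_range range of |log2 parental ratio| for cis/trans
#'   genes.
#' @param gene_induce_fc expression induction fold of induced genes.
#' @param gene_tpm_meanlog,gene_tpm_sdlog log-normal basal TPM distribution.
#' @param tpm_rep_sd replicate log-normal noise sd on TPM.
#' @param count_scale raw counts per TPM unit.
#' @param f1_informative informative (variant-overlapping) reads per gene in
#'   the F1 hybrid.
#' @param wired_fc_log2_base,wired_fc_log2_span,wired_fc_decay strain
#'   fold-difference of wired elements: log2 ratio = base + truncated
#'   exponential(decay) on [0, span].
#' @param element_spacing_bp spacing between element centers.
#' @param n_random_interactions number of random element-element interaction
#'   pairs (`NULL` = `n_elements`).
#' @param anchor_halfwidth_bp interaction anchor half-width (5-kb resolution).
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the parameters.
#' @return a `strainwise_genparams` object.
#' @export
generator_params <- function(n_elements = 1500L,
                             n_genes = 300L,
                             chrom_len = NULL,
                             ldtf_pwms = NULL,
                             sdtf_pwms = NULL,
                             mechanism_mix = c(low_basal = 0.15,
                                               equal_basal = 0.15,
                                               high_basal = 0.10,
                                               conserved = 0.35,
                                               background = 0.25),
                             frac_promoter = 0.12,
                             frac_wired = 0.10,
                             occupancy_slope = 0.68,
                             occ_max = 0.95,
                             act_base = 12,
                             act_basal_coef = 120,
                             act_induced_coef = 530,
                             act_max = 175,
                             polii_scale = 0.5,
                             atac_base = 10,
                             atac_coef = 150,
                             tf_base = 5,
                             tf_coef = 200,
                             noise_dispersion = 0.005,
                             n_replicates = 3L,
                             frac_silent_variants = 0.5,
                             gene_mix = c(cis = 0.3, trans = 0.2, none = 0.5),
                             gene_fc_log2_range = c(1.8, 3),
                             gene_induce_fc = 4,
                             gene_tpm_meanlog = log(50),
                             gene_tpm_sdlog = 0.8,
                             tpm_rep_sd = 0.15,
                             count_scale = 30,
                             f1_informative = 200L,
                             wired_fc_log2_base = 0.585,
                             wired_fc_log2_span = 1.415,
                             wired_fc_decay = 1,
                             element_spacing_bp = 3000L,
                             n_random_interactions = NULL,
                             anchor_halfwidth_bp = 2500L,
                             seed = 1L) {
  p <- as.list(environment())
  need <- c("low_basal", "equal_basal", "high_basal", "conserved", "background")
  if (!setequal(names(p$mechanism_mix), need))
    stop("mechanism_mix must be named: ", paste(need, collapse = ", "),
         call. = FALSE)
  p$mechanism_mix <- p$mechanism_mix[need]
  if (abs(sum(p$mechanism_mix) - 1) > 1e-8)
    stop("mechanism_mix must sum to 1", call. = FALSE)
  if (any(p$mechanism_mix < 0)) stop("mechanism_mix must be non-negative", call. = FALSE)
  if (p$n_elements < 10L) stop("n_elements must be >= 10", call. = FALSE)
  if (abs(sum(p$gene_mix) - 1) > 1e-8) stop("gene_mix must sum to 1", call. = FALSE)
  for (f in c("act_basal_coef", "act_induced_coef", "atac_coef", "tf_coef"))
    if (p[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  if (p$frac_silent_variants < 0 || p$frac_silent_variants >= 1)
    stop("frac_silent_variants must lie in [0, 1)", call. = FALSE)
  structure(p, class = "strainwise_genparams")
}

# fast best-score scan of many equal-length sequences against one PWM
.scan_best_scores <- function(codes, p) {
  # codes: integer matrix (n sequences x window length), values 1..5
  L <- ncol(p$matrix)
  lods <- .pwm_lods(p)
  W <- ncol(codes)
  n <- nrow(codes)
  scan1 <- function(cod) {
    best <- rep(-Inf, n)
    for (off in seq_len(W - L + 1L)) {
      s <- lods[cbind(as.vector(cod[, off]), 1L)]
      for (k in 2:L) s <- s + lods[cbind(as.vector(cod[, off + k - 1L]), k)]
      best <- pmax(best, s)
    }
    best
  }
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rc <- matrix(comp[codes[, rev(seq_len(W)), drop = FALSE]], nrow = n)
  pmax(scan1(codes), scan1(rc))
}

.encode_windows <- function(genome_chars, starts, width) {
  # starts are 0-based; returns integer code matrix (length(starts) x width)
  idx <- outer(starts, seq_len(width), `+`) # 1-based genome index
  m <- matrix(match(genome_chars[idx], .BASES), nrow = length(starts))
  m[is.na(m)] <- 5L
  m
}

.nb_sample <- function(n, mu, phi) {
  if (phi <= 0) return(rep(mu, n))
  rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a strain-pair dataset with ground truth
#'
#' Generates two haplotype genomes differing by planted SNPs, per-element
#' activity signals for both strains under basal and stimulated conditions,
#' gene expression with q-values, F1 allelic counts, and enhancer interaction
#' pairs, together with truth labels for every element mechanism, variant
#' causality and gene cis/trans status. See [generator_params()] for the
#' generative model.
#'
#' @param params a `strainwise_genparams` object.
#' @return a `strainwise_dataset`: list with components `genomes` (named
#'   character vector, strains `strainA`/`strainB`), `elements` (interval
#'   data.frame with `kind`), `variants`, `signals`, `expression`,
#'   `interactions`, `f1_counts`, `tss`, `truth` (list of `elements`,
#'   `variants`, `genes` data.frames) and `params`.
#' @export
simulate_dataset <- function(params = generator_params()) {
  stopifnot(inherits(params, "strainwise_genparams"))
  p <- params
  set.seed(p$seed)
  win <- 300L
  half <- win %/% 2L

  ldtf_list <- p$ldtf_pwms
  sdtf_list <- p$sdtf_pwms
  if (is.null(ldtf_list) || is.null(sdtf_list)) {
    bm <- builtin_motifs()
    if (is.null(ldtf_list)) ldtf_list <- bm[grep("^LDTF", names(bm))[1L]]
    if (is.null(sdtf_list)) sdtf_list <- bm[grep("^SDTF", names(bm))[1L]]
  }

  n <- as.integer(p$n_elements)
  n_prom <- round(p$frac_promoter * n)
  n_wired <- round(p$frac_wired * n)

  # ---- element layout on one synthetic chromosome --------------------------
  spacing <- as.integer(p$element_spacing_bp)
  centers <- 5000L + (seq_len(n) - 1L) * spacing +
    as.integer(round(runif(n, -spacing / 10, spacing / 10)))
  gene_tail_start <- max(centers) + 10000L
  n_other_genes <- max(0L, p$n_genes - n_prom)
  chrom_len <- p$chrom_len
  if (is.null(chrom_len))
    chrom_len <- gene_tail_start + 2000L * (n_other_genes + 2L)
  chrom_len <- as.integer(chrom_len)
  if (chrom_len < max(centers) + half)
    stop("chrom_len too small for n_elements", call. = FALSE)

  # ---- role assignment -----------------------------------------------------
  role <- rep(NA_character_, n)
  if (n_prom > 0L) {
    step <- max(2L, n %/% n_prom)
    ip <- seq(2L, n - 1L, by = step)[seq_len(min(n_prom, length(seq(2L, n - 1L, by = step))))]
    role[ip] <- "promoter"
    n_prom <- length(ip)
  }
  free <- which(is.na(role))
  # wired elements and their low-basal partners must not sit next to a
  # promoter: a 5-kb interaction anchor also matches immediate neighbours and
  # promoter precedence would reclassify the pair as enhancer-promoter
  prom_idx <- which(role == "promoter")
  no_prom_nbr <- free[!((free - 1L) %in% prom_idx | (free + 1L) %in% prom_idx)]
  n_rest <- length(free)
  if (p$mechanism_mix[["low_basal"]] == 0) n_wired <- 0L
  mech_n <- round(p$mechanism_mix * (n_rest - n_wired))
  while (sum(mech_n) > n_rest - n_wired) mech_n[which.max(mech_n)] <- mech_n[which.max(mech_n)] - 1L
  while (sum(mech_n) < n_rest - n_wired) mech_n[which.max(p$mechanism_mix)] <- mech_n[which.max(p$mechanism_mix)] + 1L
  if (n_wired > 0L && mech_n[["low_basal"]] < n_wired)
    stop("frac_wired requires at least as many low_basal elements as wired ",
         "elements; increase mechanism_mix['low_basal']", call. = FALSE)
  wired_idx <- integer()
  low_idx <- integer()
  if (n_wired > 0L) {
    if (length(no_prom_nbr) < n_wired + mech_n[["low_basal"]])
      stop("not enough promoter-free positions for wired elements", call. = FALSE)
    pick <- sample(no_prom_nbr, n_wired + mech_n[["low_basal"]])
    wired_idx <- pick[seq_len(n_wired)]
    low_idx <- pick[n_wired + seq_len(mech_n[["low_basal"]])]
    role[wired_idx] <- "wired"
    role[low_idx] <- "low_basal"
  } else if (mech_n[["low_basal"]] > 0L) {
    low_idx <- sample(free, mech_n[["low_basal"]])
    role[low_idx] <- "low_basal"
  }
  remaining <- which(is.na(role))
  labs <- rep(names(mech_n), times = mech_n)
  labs <- labs[labs != "low_basal"]
  role[remaining] <- sample(labs, length(remaining))

  # equal-basal severity: 2 or 3 SDTF core/flank mismatches
  severity <- integer(n)
  eq_idx <- which(role == "equal_basal")
  severity[eq_idx] <- 2L + (seq_along(eq_idx) %% 2L)

  # promoter genes: half induced, half neutral
  prom_idx <- which(role == "promoter")
  prom_induced <- rep(c(TRUE, FALSE), length.out = length(prom_idx))

  # ---- genome A and motif planting -----------------------------------------
  # local GC composition varies along the chromosome in isochore-like 20-kb
  # blocks so that GC-matched backgrounds exist near every element
  n_blocks <- chrom_len %/% 20000L + 1L
  block_gc <- pmin(pmax(rnorm(n_blocks, 0.5, 0.04), 0.35), 0.65)
  gc_at <- rep(block_gc, each = 20000L)[seq_len(chrom_len)]
  is_gc <- runif(chrom_len) < gc_at
  pick2 <- runif(chrom_len) < 0.5
  genomeA <- ifelse(is_gc, ifelse(pick2, "G", "C"), ifelse(pick2, "A", "T"))
  ldtf_pick <- sample(length(ldtf_list), n, replace = TRUE)
  sdtf_pick <- sample(length(sdtf_list), n, replace = TRUE)
  ldtf_len <- vapply(ldtf_list, function(q) ncol(q$matrix), 0L)
  sdtf_len <- vapply(sdtf_list, function(q) ncol(q$matrix), 0L)

  # every element carries an LDTF site; background elements (and neutral
  # promoters) lack the SDTF site and therefore cannot respond to stimulation
  has_sdtf <- !(role %in% "background")
  has_sdtf[prom_idx] <- prom_induced

  ldtf_off <- as.integer(round(runif(n, 40, 120)))
  sdtf_off <- as.integer(round(runif(n, 160, 240)))

  win_start <- centers - half # 0-based window starts
  edits <- vector("list", n)  # per-element strain-B edits: window offsets + bases
  footprint <- vector("list", n)
  # planted site strings per strain; occupancy is the logistic of the
  # cognate site's log-odds score (the TF binds its licensed site, so truth
  # occupancies are exact functions of the planted edits)
  siteL_A <- siteL_B <- siteS_A <- siteS_B <- vector("list", n)

  for (i in seq_len(n)) {
    lp <- ldtf_list[[ldtf_pick[i]]]
    sp <- sdtf_list[[sdtf_pick[i]]]
    fp <- integer()
    ed_off <- integer(); ed_base <- character()
    # LDTF: planted one sharp mismatch below consensus so that improvement
    # (high_basal) has headroom
    lv <- .motif_variant(lp, "weak")
    lsite <- strsplit(lv$site, "", fixed = TRUE)[[1L]]
    gpos <- win_start[i] + ldtf_off[i] # 0-based genome pos of site start
    genomeA[(gpos + 1L):(gpos + length(lsite))] <- lsite
    fp <- c(fp, ldtf_off[i] + seq_along(lsite) - 1L)
    siteL_A[[i]] <- siteL_B[[i]] <- lsite
    if (has_sdtf[i]) {
      ssite <- strsplit(pwm_consensus(sp), "", fixed = TRUE)[[1L]]
      gpos2 <- win_start[i] + sdtf_off[i]
      genomeA[(gpos2 + 1L):(gpos2 + length(ssite))] <- ssite
      fp <- c(fp, sdtf_off[i] + seq_along(ssite) - 1L)
      siteS_A[[i]] <- siteS_B[[i]] <- ssite
    }
    if (role[i] == "low_basal") {
      mv <- .motif_variant(lp, "weak", n_sharp_mm = 3L)
      sb <- lsite
      for (m in mv$mismatches) {
        ed_off <- c(ed_off, ldtf_off[i] + m$pos - 1L)
        ed_base <- c(ed_base, m$base)
        sb[m$pos] <- m$base
      }
      siteL_B[[i]] <- sb
    } else if (role[i] == "equal_basal") {
      mv <- .motif_variant(sp, "consensus", n_sharp_mm = 1L,
                           n_soft_mm = severity[i] - 1L)
      sb <- siteS_A[[i]]
      for (m in mv$mismatches) {
        ed_off <- c(ed_off, sdtf_off[i] + m$pos - 1L)
        ed_base <- c(ed_base, m$base)
        sb[m$pos] <- m$base
      }
      siteS_B[[i]] <- sb
    } else if (role[i] == "high_basal") {
      # improvement: revert the weak LDTF position to consensus
      cons <- strsplit(pwm_consensus(lp), "", fixed = TRUE)[[1L]]
      j <- lv$weak_pos
      ed_off <- ldtf_off[i] + j - 1L
      ed_base <- cons[j]
      sb <- lsite; sb[j] <- cons[j]
      siteL_B[[i]] <- sb
    }
    edits[[i]] <- list(off = ed_off, base = ed_base)
    footprint[[i]] <- fp
  }

  # ---- strain-B genome, causal + silent variants ---------------------------
  genomeB <- genomeA
  var_pos <- integer(); var_ref <- character(); var_alt <- character()
  var_causal <- logical(); var_elem <- character()
  elem_id <- sprintf("el%05d", seq_len(n))
  for (i in seq_len(n)) {
    ed <- edits[[i]]
    if (!length(ed$off)) next
    gpos <- win_start[i] + ed$off # 0-based
    ref <- genomeA[gpos + 1L]
    keep <- ref != ed$base
    gpos <- gpos[keep]; alt <- ed$base[keep]; ref <- ref[keep]
    genomeB[gpos + 1L] <- alt
    var_pos <- c(var_pos, gpos); var_ref <- c(var_ref, ref)
    var_alt <- c(var_alt, alt); var_causal <- c(var_causal, rep(TRUE, length(gpos)))
    var_elem <- c(var_elem, rep(elem_id[i], length(gpos)))
  }
  n_causal <- length(var_pos)
  fs <- p$frac_silent_variants
  n_silent <- round(fs / (1 - fs) * n_causal)
  if (n_silent > 0L) {
    host_pool <- which(role != "wired")
    hosts <- sample(host_pool, n_silent, replace = TRUE)
    for (i in hosts) {
      avoid <- c(footprint[[i]], edits[[i]]$off,
                 var_pos[var_elem == elem_id[i]] - win_start[i])
      off <- sample(setdiff(0:(win - 1L), avoid), 1L)
      gpos <- win_start[i] + off
      ref <- genomeA[gpos + 1L]
      alt <- sample(setdiff(.BASES, ref), 1L)
      genomeB[gpos + 1L] <- alt
      var_pos <- c(var_pos, gpos); var_ref <- c(var_ref, ref)
      var_alt <- c(var_alt, alt); var_causal <- c(var_causal, FALSE)
      var_elem <- c(var_elem, elem_id[i])
    }
  }
  ord <- order(var_pos)
  variants <- data.frame(chrom = rep("chrS", length(var_pos)),
                         pos = var_pos[ord], ref = var_ref[ord],
                         alt = var_alt[ord],
                         strain = rep("strainB", length(var_pos)),
                         stringsAsFactors = FALSE)
  truth_variants <- data.frame(chrom = rep("chrS", length(var_pos)),
                               pos = var_pos[ord],
                               strain = rep("strainB", length(var_pos)),
                               causal = var_causal[ord],
                               element_id = var_elem[ord],
                               stringsAsFactors = FALSE)

  # ---- occupancies of the planted sites ------------------------------------
  site_occ <- function(site, pw) {
    if (is.null(site)) return(0)
    lods <- log2(pw$matrix / pw$background)
    s <- sum(lods[cbind(match(site, .BASES), seq_along(site))])
    .occupancy(s, pw, p$occupancy_slope, p$occ_max)
  }
  occL_A <- occL_B <- occS_A <- occS_B <- numeric(n)
  for (i in seq_len(n)) {
    lp <- ldtf_list[[ldtf_pick[i]]]
    sp <- sdtf_list[[sdtf_pick[i]]]
    occL_A[i] <- site_occ(siteL_A[[i]], lp)
    occL_B[i] <- site_occ(siteL_B[[i]], lp)
    occS_A[i] <- site_occ(siteS_A[[i]], sp)
    occS_B[i] <- site_occ(siteS_B[[i]], sp)
  }

  # ---- activity means and sampled signals ----------------------------------
  mu_k27 <- function(occL, occS, stim)
    pmin(p$act_base + p$act_basal_coef * occL +
           p$act_induced_coef * occL * occS * as.numeric(stim), p$act_max)
  muA_b <- mu_k27(occL_A, occS_A, FALSE); muA_s <- mu_k27(occL_A, occS_A, TRUE)
  muB_b <- mu_k27(occL_B, occS_B, FALSE); muB_s <- mu_k27(occL_B, occS_B, TRUE)

  # wired elements: strain-B stimulated activity attenuated by a connected
  # (trans) effect, with no local sequence difference
  wired_r <- rep(NA_real_, n)
  if (length(wired_idx)) {
    u <- runif(length(wired_idx))
    lam <- p$wired_fc_decay
    delta <- -log(1 - u * (1 - exp(-lam * p$wired_fc_log2_span))) / lam
    wired_r[wired_idx] <- 2^(p$wired_fc_log2_base + delta)
    muB_s[wired_idx] <- muA_s[wired_idx] / wired_r[wired_idx]
    muB_b[wired_idx] <- muA_b[wired_idx]
  }

  muS_stim_A <- occS_A; muS_stim_B <- occS_B
  assay_mu <- list(
    H3K27ac = list(A = cbind(muA_b, muA_s), B = cbind(muB_b, muB_s)),
    PolII = list(A = p$polii_scale * cbind(muA_b, muA_s),
                 B = p$polii_scale * cbind(muB_b, muB_s)),
    ATAC = list(A = cbind(p$atac_base + p$atac_coef * occL_A,
                          p$atac_base + p$atac_coef * occL_A +
                            0.2 * p$atac_coef * occL_A * occS_A),
                B = cbind(p$atac_base + p$atac_coef * occL_B,
                          p$atac_base + p$atac_coef * occL_B +
                            0.2 * p$atac_coef * occL_B * occS_B)),
    LDTF = list(A = cbind(p$tf_base + p$tf_coef * occL_A,
                          p$tf_base + p$tf_coef * occL_A),
                B = cbind(p$tf_base + p$tf_coef * occL_B,
                          p$tf_base + p$tf_coef * occL_B)),
    SDTF = list(A = cbind(rep(2, n), 2 + p$tf_coef * muS_stim_A),
                B = cbind(rep(2, n), 2 + p$tf_coef * muS_stim_B))
  )
  conds <- c("basal", "il4")
  sig <- vector("list", length(assay_mu) * 4L)
  si <- 0L
  for (assay in names(assay_mu)) {
    for (strain in c("strainA", "strainB")) {
      mus <- assay_mu[[assay]][[substr(strain, 7L, 7L)]]
      for (ci in 1:2) {
        vals <- rowMeans(matrix(.nb_sample(n * p$n_replicates,
                                           rep(mus[, ci], p$n_replicates),
                                           p$noise_dispersion),
                                nrow = n))
        si <- si + 1L
        sig[[si]] <- data.frame(element_id = elem_id, strain = strain,
                                condition = conds[ci], assay = assay,
                                value = vals, stringsAsFactors = FALSE)
      }
    }
  }
  signals <- do.call(rbind, sig)

  elements <- data.frame(chrom = "chrS", start = centers - half,
                         end = centers + half, id = elem_id,
                         kind = ifelse(role == "promoter", "promoter", "enhancer"),
                         stringsAsFactors = FALSE)

  # ---- genes, expression, q-values, F1 allelic counts ----------------------
  ng <- as.integer(p$n_genes)
  gene_id <- sprintf("gene%04d", seq_len(ng))
  gene_label <- sample(names(p$gene_mix), ng, replace = TRUE, prob = p$gene_mix)
  lr <- numeric(ng) # log2 strain ratio A/B
  ct <- gene_label %in% c("cis", "trans")
  lr[ct] <- sample(c(-1, 1), sum(ct), replace = TRUE) *
    runif(sum(ct), p$gene_fc_log2_range[1L], p$gene_fc_log2_range[2L])
  # induction structure: promoter-linked genes follow their element; of the
  # remaining "none" genes some are induced in both strains or in A only
  induced_A <- induced_B <- rep(FALSE, ng)
  basal_ratio_target <- rep(1, ng) # B/A basal multiplier for A-only genes
  gene_tss <- rep(NA_integer_, ng)
  if (length(prom_idx)) {
    gp <- seq_len(min(length(prom_idx), ng))
    gene_tss[gp] <- centers[prom_idx[gp]]
    induced_A[gp] <- induced_B[gp] <- prom_induced[gp]
  }
  rest <- which(is.na(gene_tss))
  gene_tss[rest] <- gene_tail_start + 2000L * seq_along(rest)
  pool <- intersect(rest, which(gene_label == "none"))
  if (length(pool) >= 5L) {
    both <- pool[seq_len(floor(length(pool) * 0.35))]
    aonly <- setdiff(pool, both)[seq_len(floor(length(pool) * 0.25))]
    induced_A[both] <- induced_B[both] <- TRUE
    induced_A[aonly] <- TRUE
    basal_ratio_target[aonly] <- sample(c(0.4, 1, 2.5), length(aonly), replace = TRUE)
  } else {
    aonly <- integer()
  }
  gene_cat <- rep(NA_character_, ng)
  gene_cat[aonly] <- c("0.4" = "low_basal", "1" = "equal_basal",
                       "2.5" = "high_basal")[as.character(basal_ratio_target[aonly])]

  basalA <- exp(rnorm(ng, p$gene_tpm_meanlog, p$gene_tpm_sdlog))
  basalB <- basalA / 2^lr * basal_ratio_target
  stimA <- basalA * ifelse(induced_A, p$gene_induce_fc, 1)
  stimB <- basalB * ifelse(induced_B, p$gene_induce_fc, 1)

  reps <- seq_len(p$n_replicates)
  expr_rows <- vector("list", 4L)
  mus <- list(strainA = cbind(basalA, stimA), strainB = cbind(basalB, stimB))
  ei <- 0L
  for (strain in c("strainA", "strainB")) for (ci in 1:2) {
    mu <- mus[[strain]][, ci]
    tpm <- matrix(mu, ng, p$n_replicates) *
      exp(matrix(rnorm(ng * p$n_replicates, 0, p$tpm_rep_sd), ng))
    cnt <- matrix(.nb_sample(ng * p$n_replicates, as.vector(tpm) * p$count_scale,
                             p$noise_dispersion), ng)
    ei <- ei + 1L
    expr_rows[[ei]] <- data.frame(
      gene_id = rep(gene_id, p$n_replicates),
      strain = strain, condition = conds[ci],
      replicate = rep(reps, each = ng),
      tpm = as.vector(tpm), count = round(as.vector(cnt)),
      stringsAsFactors = FALSE)
  }
  expression <- do.call(rbind, expr_rows)
  expression$q <- NA_real_
  # q-values for the induction contrast from a Welch t-test on
  # log2(count + 1) across replicates, BH-adjusted per strain
  for (strain in c("strainA", "strainB")) {
    sel <- expression$strain == strain
    blk <- function(cond)
      matrix(log2(expression$count[sel & expression$condition == cond] + 1), ng)
    x <- blk("basal"); y <- blk("il4")
    nr <- ncol(x)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nr - 1); vy <- rowSums((y - my)^2) / (nr - 1)
    se2 <- vx / nr + vy / nr
    tt <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nr)^2 / (nr - 1) + (vy / nr)^2 / (nr - 1))
    pv <- 2 * stats::pt(-abs(tt), df)
    pv[!is.finite(pv)] <- ifelse(mx[!is.finite(pv)] == my[!is.finite(pv)], 1, 0)
    qv <- p.adjust(pv, "BH")
    expression$q[sel] <- qv[match(expression$gene_id[sel], gene_id)]
  }

  # F1 allelic counts: cis genes keep the parental allelic ratio, trans genes
  # draw both alleles from the mid-parent mean
  pA <- ifelse(gene_label == "cis", 2^lr / (1 + 2^lr), 0.5)
  infA <- rbinom(ng, p$f1_informative, pA)
  f1_counts <- data.frame(gene_id = gene_id, count_A = infA,
                          count_B = p$f1_informative - infA,
                          stringsAsFactors = FALSE)

  tss <- data.frame(gene_id = gene_id, chrom = "chrS", pos = gene_tss,
                    stringsAsFactors = FALSE)

  # ---- interactions --------------------------------------------------------
  aw <- as.integer(p$anchor_halfwidth_bp)
  anchor <- function(idx) data.frame(chrom = "chrS", start = centers[idx] - aw,
                                     end = centers[idx] + aw)
  ia <- list()
  if (length(wired_idx)) {
    partner <- sample(low_idx, length(wired_idx))
    ia[[length(ia) + 1L]] <- cbind(anchor(wired_idx),
                                   stats::setNames(anchor(partner),
                                                   c("chrom2", "start2", "end2")),
                                   wired = TRUE)
    wired_partner <- stats::setNames(elem_id[partner], elem_id[wired_idx])
  } else wired_partner <- character()
  n_rand <- if (is.null(p$n_random_interactions)) n else as.integer(p$n_random_interactions)
  enh_idx <- which(role != "promoter")
  if (n_rand > 0L && length(enh_idx) >= 2L) {
    i1 <- sample(enh_idx, n_rand, replace = TRUE)
    i2 <- sample(enh_idx, n_rand, replace = TRUE)
    keep <- abs(i1 - i2) >= 3L # avoid self/adjacent pairs
    ia[[length(ia) + 1L]] <- cbind(anchor(i1[keep]),
                                   stats::setNames(anchor(i2[keep]),
                                                   c("chrom2", "start2", "end2")),
                                   wired = FALSE)
  }
  # promoter wiring: induced promoters preferentially contact induced
  # (conserved) enhancers
  if (length(prom_idx)) {
    cons_idx <- which(role == "conserved")
    bg_idx <- which(role == "background")
    tgt <- integer(0); src <- integer(0)
    for (k in seq_along(prom_idx)) {
      for (rep2 in 1:2) {
        if (prom_induced[k] && length(cons_idx) && runif(1) < 0.7)
          t1 <- sample(cons_idx, 1L)
        else if (!prom_induced[k] && length(bg_idx) && runif(1) < 0.7)
          t1 <- sample(bg_idx, 1L)
        else t1 <- sample(enh_idx, 1L)
        src <- c(src, prom_idx[k]); tgt <- c(tgt, t1)
      }
    }
    keep <- abs(src - tgt) >= 3L
    ia[[length(ia) + 1L]] <- cbind(anchor(src[keep]),
                                   stats::setNames(anchor(tgt[keep]),
                                                   c("chrom2", "start2", "end2")),
                                   wired = FALSE)
  }
  interactions <- do.call(rbind, ia)
  names(interactions)[1:3] <- c("chrom1", "start1", "end1")
  interactions$strength <- rpois(nrow(interactions), 20) + 1L
  interactions$wired <- NULL
  rownames(interactions) <- NULL

  truth_elements <- data.frame(
    element_id = elem_id, mechanism = role, severity = severity,
    wired_partner = NA_character_,
    wired_fc = wired_r,
    occL_A = occL_A, occL_B = occL_B, occS_A = occS_A, occS_B = occS_B,
    stringsAsFactors = FALSE)
  if (length(wired_partner))
    truth_elements$wired_partner[match(names(wired_partner),
                                       truth_elements$element_id)] <- wired_partner
  truth_genes <- data.frame(gene_id = gene_id, label = gene_label,
                            log2_parental = lr,
                            induced_A = induced_A, induced_B = induced_B,
                            category = gene_cat, stringsAsFactors = FALSE)

  structure(list(
    genomes = c(strainA = paste(genomeA, collapse = ""),
                strainB = paste(genomeB, collapse = "")),
    elements = elements, variants = variants, signals = signals,
    expression = expression, interactions = interactions,
    f1_counts = f1_counts, tss = tss,
    truth = list(elements = truth_elements, variants = truth_variants,
                 genes = truth_genes),
    params = p), class = "strainwise_dataset")
}

#' @export
print.strainwise_dataset <- function(x, ...) {
  cat("strainwise synthetic dataset:",
      nrow(x$elements), "elements,",
      nrow(x$variants), "variants,",
      nrow(x$truth$genes), "genes,",
      nrow(x$interactions), "interactions\n")
  cat("mechanisms:\n")
  print(table(x$truth$elements$mechanism))
  invisible(x)
}

#' Extract element window sequences from a genome
#'
#' @param genome single genome sequence (character string).
#' @param elements interval data.frame.
#' @param seq_len window length; windows are centered on the element center.
#' @return named character vector of sequences (names = element ids).
#' @export
element_sequences <- function(genome, elements, seq_len = 300L) {
  center <- (elements$start + elements$end) %/% 2L
  start <- center - seq_len %/% 2L # 0-based
  out <- substring(genome, start + 1L, start + seq_len)
  names(out) <- elements$id
  out
}

#' Write a synthetic dataset to a directory
#'
#' Emits the pipeline's on-disk formats (FASTA, BED, VCF-like TSV, signal and
#' expression TSV, BEDPE) plus truth tables; [read_dataset()] reproduces the
#' dataset (minus generator parameters).
#'
#' @param ds a `strainwise_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- function(f) file.path(dir, f)
  write_fasta(ds$genomes, pt("genomes.fa"))
  write_bed(ds$elements, pt("elements.bed"))
  write_vcf_like(ds$variants, pt("variants.tsv"))
  write_signal_table(ds$signals, pt("signals.tsv"))
  write_expression_table(ds$expression, pt("expression.tsv"))
  write_bedpe(ds$interactions, pt("interactions.bedpe"))
  wt <- function(x, f) {
    con <- file(pt(f), "w"); on.exit(close(con))
    writeLines(.sw_header(NULL), con)
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(ds$f1_counts, "f1_counts.tsv")
  wt(ds$tss, "tss.tsv")
  wt(ds$truth$elements, "truth_elements.tsv")
  wt(ds$truth$variants, "truth_variants.tsv")
  wt(ds$truth$genes, "truth_genes.tsv")
  invisible(dir)
}

#' Read a synthetic dataset back from a directory
#' @param dir directory written by [write_dataset()].
#' @return a `strainwise_dataset` (with `params = NULL`).
#' @export
read_dataset <- function(dir) {
  pt <- function(f) file.path(dir, f)
  rt <- function(f) {
    lines <- readLines(pt(f))
    read.delim(text = lines[!grepl("^#", lines)], header = TRUE,
               stringsAsFactors = FALSE)
  }
  structure(list(
    genomes = read_fasta(pt("genomes.fa")),
    elements = read_bed(pt("elements.bed")),
    variants = read_vcf_like(pt("variants.tsv")),
    signals = read_signal_table(pt("signals.tsv")),
    expression = read_expression_table(pt("expression.tsv")),
    interactions = read_bedpe(pt("interactions.bedpe")),
    f1_counts = rt("f1_counts.tsv"),
    tss = rt("tss.tsv"),
    truth = list(elements = rt("truth_elements.tsv"),
                 variants = rt("truth_variants.tsv"),
                 genes = rt("truth_genes.tsv")),
    params = NULL), class = "strainwise_dataset")
}
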