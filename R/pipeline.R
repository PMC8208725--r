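# End-to-end pipeline on a synthetic dataset plus the summary report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes every stage in order — simulate (unless a dataset is supplied),
#' element calling, strain comparison, cis/trans decomposition, motif-mutation
#' scan, sequence-model training, variant prioritization, connectivity
#' attribution — writing stage outputs and a run manifest to `out_dir`.
#' All randomness derives from `cfg$seed`; reruns with the same seed are
#' identical up to timestamps.
#'
#' @param cfg a [pipeline_config()].
#' @param params a [generator_params()] (its `seed` is overridden by
#'   `cfg$seed`).
#' @param out_dir output directory.
#' @param ds optionally, an existing `strainwise_dataset` to analyse instead
#'   of simulating a fresh one.
#' @param n_decoys decoy motifs added to the motif-mutation scan.
#' @param train_max_epochs cap on training epochs.
#' @param verbose print stage progress.
#' @return (invisibly) a list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         params = generator_params(),
                         out_dir = tempfile("strainwise_run_"),
                         ds = NULL,
                         n_decoys = 20L,
                         train_max_epochs = 120L,
                         verbose = FALSE) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()

  if (is.null(ds)) {
    params$seed <- cfg$seed
    say("stage simulate")
    ds <- .stage("simulate", simulate_dataset(params))
    .stage("simulate", write_dataset(ds, file.path(out_dir, "dataset")))
  }

  say("stage call-elements")
  calls <- .stage("call-elements", list(
    strainA = classify_elements(ds$signals, "strainA", cfg),
    strainB = classify_elements(ds$signals, "strainB", cfg)))
  for (s in names(calls))
    write.table(calls[[s]], file.path(out_dir, paste0("element_calls_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage compare-strains")
  comparison <- .stage("compare-strains", compare_strain_enhancers(ds$signals, cfg = cfg))
  write.table(comparison, file.path(out_dir, "strain_categories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage cis-trans")
  ct <- .stage("cis-trans", cis_trans_recovery(ds, cfg))
  write.table(ct$table, file.path(out_dir, "cis_trans.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage motif-test")
  pairs <- .stage("motif-test", strain_sequence_pairs(ds, c("equal_basal", "low_basal")))
  motif_res <- NULL
  if (nrow(pairs) >= 10L) {
    pwms <- c(builtin_motifs(),
              make_decoy_pwms(n_decoys, seed = cfg$seed,
                              avoid = builtin_motifs()))
    motif_res <- .stage("motif-test", motif_mutation_scan(pairs, pwms))
    write.table(motif_res, file.path(out_dir, "motif_mutation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("stage train-model")
  truth <- ds$truth$elements
  # positives: every active (above-minimum) enhancer in the reference
  # strain, whatever its response state; negatives: GC-matched backgrounds
  active_a <- calls$strainA$element_id[calls$strainA$state != "below_minimum"]
  enh <- ds$elements$id[ds$elements$kind != "promoter"]
  active <- intersect(active_a, enh)
  el_active <- ds$elements[match(active, ds$elements$id), , drop = FALSE]
  pos_seqs <- element_sequences(ds$genomes[["strainA"]], el_active, cfg$seq_len_bp)
  bg <- .stage("train-model",
               sample_gc_matched_background(ds$genomes[["strainA"]], el_active,
                                            seed = cfg$seed))
  neg_seqs <- element_sequences(ds$genomes[["strainA"]], bg, cfg$seq_len_bp)
  split <- c(split_by_thirds(el_active$start, props = c(8, 1, 1)),
             split_by_thirds(bg$start, props = c(8, 1, 1)))
  model <- .stage("train-model",
                  train_classifier(pos_seqs, neg_seqs, split, cfg,
                                   seed = cfg$seed,
                                   max_epochs = train_max_epochs))

  say("stage score-variants")
  tracks <- .stage("score-variants", importance_scores(model, pos_seqs))
  rownames(tracks) <- el_active$id
  flagged <- .stage("score-variants",
                    prioritize_variants(ds$variants, tracks, el_active, cfg))
  write.table(flagged, file.path(out_dir, "variants_flagged.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage connectivity")
  elements_annot <- ds$elements
  classified <- .stage("connectivity",
                       classify_interactions(ds$interactions, elements_annot, cfg))
  write.table(classified, file.path(out_dir, "interactions_classified.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  wired_ids <- truth$element_id[truth$mechanism == "wired"]
  attribution <- NULL
  if (length(wired_ids)) {
    diff_ids <- union(comparison$element_id, wired_ids)
    attribution <- .stage("connectivity",
                          attribute_differential_enhancers(diff_ids, flagged,
                                                           classified,
                                                           elements_annot, cfg))
    write.table(attribution, file.path(out_dir, "attribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  res <- list(dataset = ds, calls = calls, comparison = comparison,
              cis_trans = ct, motifs = motif_res, model = model,
              tracks = tracks, flagged_variants = flagged,
              classified_interactions = classified,
              attribution = attribution, cfg = cfg, out_dir = out_dir)

  say("stage report")
  report <- .stage("report", pipeline_report(res))
  writeLines(report, file.path(out_dir, "report.txt"))

  manifest <- list(
    version = as.character(utils::packageVersion("strainwise")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    rows = list(elements = nrow(ds$elements), variants = nrow(ds$variants),
                signals = nrow(ds$signals), genes = nrow(ds$truth$genes),
                interactions = nrow(ds$interactions),
                categories = nrow(comparison),
                flagged = sum(flagged$predicted_functional)),
    file_digests = as.list(tools::md5sum(sort(list.files(out_dir, "\\.tsv$",
                                                         full.names = TRUE,
                                                         recursive = TRUE)))),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}

#' Text summary report of a pipeline run
#'
#' Tables mirroring the analysis surfaces: element state counts per strain,
#' low/equal/high basal category counts, tiered variant fractions, the
#' enrichment curve over tiers, attribution percentages, the top motif
#' clusters, and — when generator truth is available — mechanism and
#' cis/trans confusion matrices.
#'
#' @param res result list from [run_pipeline()].
#' @return character vector of report lines.
#' @export
pipeline_report <- function(res) {
  out <- character()
  add <- function(...) out <<- c(out, paste0(...))
  fmt_table <- function(t) utils::capture.output(print(t))
  add("strainwise pipeline report")
  add("==========================")
  for (s in names(res$calls)) {
    add("", paste0("element states (", s, "):"))
    add(fmt_table(table(factor(res$calls[[s]]$state,
                               c("induced", "repressed", "neutral",
                                 "ambiguous", "below_minimum")))))
  }
  add("", "strain-differential categories:")
  cat_tab <- table(factor(res$comparison$category,
                          c("low_basal", "equal_basal", "high_basal")))
  add(fmt_table(cat_tab))

  ds <- res$dataset
  cfg <- res$cfg
  truth <- ds$truth$elements
  # tiers over elements induced in at least one strain
  ind_any <- unique(c(
    res$calls$strainA$element_id[res$calls$strainA$state == "induced"],
    res$calls$strainB$element_id[res$calls$strainB$state == "induced"]))
  hA <- .signal_lookup(ds$signals, "strainA", "H3K27ac", "il4")[ind_any]
  hB <- .signal_lookup(ds$signals, "strainB", "H3K27ac", "il4")[ind_any]
  tiers <- differential_tiers(hA, hB, cfg)
  el_ind <- ds$elements[match(ind_any, ds$elements$id), , drop = FALSE]
  grp <- ifelse(tiers$similar, "similar", "differential")
  add("", "variant-containing fraction by tier:")
  vf <- c(variant_overlap_fraction(el_ind[tiers$similar, , drop = FALSE],
                                   ds$variants,
                                   rep("similar", sum(tiers$similar)), cfg))
  for (t in cfg$differential_tiers) {
    sel <- tiers[[paste0("tier_gt_", t)]]
    vf[paste0(">", t)] <- if (any(sel))
      mean(element_has_variant(el_ind[sel, , drop = FALSE], ds$variants,
                               cfg$variant_window_bp)) else NA
  }
  add(fmt_table(round(vf, 3)))

  if (!is.null(res$flagged_variants)) {
    fv <- res$flagged_variants[res$flagged_variants$predicted_functional, ,
                               drop = FALSE]
    flags <- element_has_variant(el_ind, fv, cfg$variant_window_bp)
    groups <- rep("similar", nrow(el_ind))
    for (t in cfg$differential_tiers)
      groups[tiers[[paste0("tier_gt_", t)]]] <- paste0(">", t)
    add("", "top-variant enrichment by tier (log2):")
    enr <- category_enrichment(flags, groups)
    add(fmt_table(enr))
  }

  if (!is.null(res$attribution)) {
    add("", "attribution of differential enhancers (%):")
    add(fmt_table(round(attr(res$attribution, "percentages"), 1)))
  }
  if (!is.null(res$motifs)) {
    add("", "top motif-mutation hits:")
    top <- head(res$motifs[order(-abs(res$motifs$signed_logp)), ], 5L)
    add(fmt_table(top))
  }
  if (!is.null(res$model))
    add("", sprintf("sequence model: test auROC = %.3f (%d epochs)",
                    res$model$auroc, nrow(res$model$log)))

  if (!is.null(truth)) {
    add("", "mechanism confusion (planted vs called):")
    j <- merge(truth[truth$mechanism %in% c("low_basal", "equal_basal",
                                            "high_basal"), ],
               res$comparison, by = "element_id", all.x = TRUE)
    j$category[is.na(j$category)] <- "uncalled"
    add(fmt_table(table(planted = j$mechanism, called = j$category)))
    ct <- res$cis_trans$table
    tr <- ct$truth %in% c("cis", "trans")
    add("", "cis/trans confusion (planted vs called):")
    add(fmt_table(table(planted = ct$truth[tr], called = ct$label[tr])))
  }
  out
}
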