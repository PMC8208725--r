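#' Pipeline configuration
#'
#' Builds the validated configuration object consumed by every stage of the
#' pipeline. Each numeric threshold used anywhere downstream lives here; stage
#' code contains no analysis literals, so overriding a field changes the
#' corresponding behaviour everywhere.
#'
#' @param ... named overrides of the default fields, e.g. `induce_fc = 3`.
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{induce_fc (2.5)}{fold-change threshold calling an element
#'     stimulus-induced (or, reciprocally, repressed) on both activity
#'     markers.}
#'   \item{neutral_fc (1.4)}{upper bound of fold change for a neutral call.}
#'   \item{min_h3k27ac (16), min_polii (8)}{minimum normalized tag counts
#'     (tags per 1e7); elements below either on both conditions are filtered
#'     as `below_minimum`.}
#'   \item{gene_basal_fc (1.5)}{basal-expression ratio splitting
#'     low/equal/high basal gene categories.}
#'   \item{enhancer_basal_fc (2)}{basal H3K27ac ratio splitting enhancer
#'     categories.}
#'   \item{gene_induce_fc (2)}{gene induction fold-change threshold; also the
#'     required difference in H3K27ac induction between strains for an
#'     enhancer to be considered strain-differentially induced.}
#'   \item{similar_fc (1.5)}{strain-similar enhancer bound.}
#'   \item{differential_tiers (1.5, 2, 3, 4)}{cumulative strain-difference
#'     tier thresholds.}
#'   \item{variant_window_bp (150)}{half-width around the element center used
#'     when searching for variants.}
#'   \item{signal_window_bp (500), tf_window_bp (150)}{half-widths used to
#'     quantify histone/Pol II and TF binding signal.}
#'   \item{merge_dist_bp (2500)}{maximal gap matching an interaction anchor to
#'     an element.}
#'   \item{tss_exclusion_bp (2500), stitch_dist_bp (12500)}{super-enhancer TSS
#'     exclusion and stitching distances.}
#'   \item{promoter_window_bp (1000)}{half-width around a TSS within which an
#'     element is annotated as a promoter.}
#'   \item{seq_len_bp (300)}{sequence-model input length.}
#'   \item{top_frac (0.2)}{quantile of positions per element called predicted
#'     functional.}
#'   \item{kmer_k (5), kmer_top_frac (0.1)}{k-mer size and score quantile for
#'     model interpretation.}
#'   \item{motif_cluster_corr (0.6)}{correlation threshold grouping motifs.}
#'   \item{expr_filter_tpm (2)}{minimum TPM for a motif cluster to be kept.}
#'   \item{lr_init (1e-3), lr_factor (0.9), patience_epochs (20)}{training
#'     schedule: initial learning rate, reduction factor on stagnation, and
#'     early-stopping patience. The 1e-3 default suits training from random
#'     initialization; fine-tuning an already-trained model warrants a
#'     smaller rate (e.g. 1e-4).}
#'   \item{cis_window_log2 (1)}{half-width of the cis classification window on
#'     log2 fold-change differences.}
#'   \item{parental_fc_min (2)}{minimum parental fold change for trans
#'     eligibility.}
#'   \item{seed (1)}{integer random seed.}
#' }
#'
#' @return a `strainwise_config` object (named list).
#' @seealso [load_config()], [write_config()]
#' @export
#' @examples
#' cfg <- pipeline_config(induce_fc = 3)
#' cfg$induce_fc
pipeline_config <- function(...) {
  cfg <- list(
    induce_fc          = 2.5,
    neutral_fc         = 1.4,
    min_h3k27ac        = 16,
    min_polii          = 8,
    gene_basal_fc      = 1.5,
    enhancer_basal_fc  = 2.0,
    gene_induce_fc     = 2.0,
    similar_fc         = 1.5,
    differential_tiers = c(1.5, 2, 3, 4),
    variant_window_bp  = 150L,
    signal_window_bp   = 500L,
    tf_window_bp       = 150L,
    merge_dist_bp      = 2500L,
    tss_exclusion_bp   = 2500L,
    stitch_dist_bp     = 12500L,
    promoter_window_bp = 1000L,
    seq_len_bp         = 300L,
    top_frac           = 0.20,
    kmer_k             = 5L,
    kmer_top_frac      = 0.10,
    motif_cluster_corr = 0.6,
    expr_filter_tpm    = 2.0,
    lr_init            = 1e-3,
    lr_factor          = 0.9,
    patience_epochs    = 20L,
    cis_window_log2    = 1.0,
    parental_fc_min    = 2.0,
    seed               = 1L
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  class(cfg) <- "strainwise_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks all configuration invariants (fold thresholds above 1, fractions in
#' (0, 1), windows/distances positive, `neutral_fc < induce_fc`, ...).
#'
#' @param cfg a `strainwise_config` object.
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, why)
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)
  num1 <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      fail(field, "must be a single number")
    x
  }
  for (f in c("induce_fc", "neutral_fc", "gene_basal_fc", "enhancer_basal_fc",
              "gene_induce_fc", "similar_fc", "parental_fc_min"))
    if (num1(f) <= 1) fail(f, "fold threshold must be > 1")
  if (!is.numeric(cfg$differential_tiers) || length(cfg$differential_tiers) < 1L ||
      any(cfg$differential_tiers <= 1) || is.unsorted(cfg$differential_tiers, strictly = TRUE))
    fail("differential_tiers", "must be strictly increasing fold thresholds > 1")
  for (f in c("top_frac", "kmer_top_frac")) {
    x <- num1(f)
    if (x <= 0 || x >= 1) fail(f, "must lie strictly between 0 and 1")
  }
  for (f in c("variant_window_bp", "signal_window_bp", "tf_window_bp",
              "merge_dist_bp", "tss_exclusion_bp", "stitch_dist_bp",
              "promoter_window_bp", "seq_len_bp", "kmer_k", "patience_epochs")) {
    x <- num1(f)
    if (x < 1 || x != round(x)) fail(f, "must be a positive integer")
  }
  for (f in c("min_h3k27ac", "min_polii"))
    if (num1(f) < 0) fail(f, "must be non-negative")
  if (num1("neutral_fc") >= cfg$induce_fc)
    fail("neutral_fc", "must be smaller than induce_fc")
  if (num1("motif_cluster_corr") <= 0 || cfg$motif_cluster_corr >= 1)
    fail("motif_cluster_corr", "must lie strictly between 0 and 1")
  if (num1("lr_init") <= 0) fail("lr_init", "must be positive")
  if (num1("lr_factor") <= 0 || cfg$lr_factor >= 1)
    fail("lr_factor", "must lie strictly between 0 and 1")
  if (num1("expr_filter_tpm") < 0) fail("expr_filter_tpm", "must be non-negative")
  if (num1("cis_window_log2") <= 0) fail("cis_window_log2", "must be positive")
  x <- num1("seed"); if (x != round(x)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML key-value file and overlays it on the defaults of
#' [pipeline_config()]. Unknown keys are rejected and the merged configuration
#' is re-validated, so a file can never produce an inconsistent configuration.
#'
#' @param path path to a YAML config file, or `NULL` for all defaults.
#' @return a validated `strainwise_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed config file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("malformed config file '", path,
                           "': expected a key-value mapping", call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to a YAML file
#'
#' The written file round-trips: [load_config()] on the result reproduces the
#' identical configuration.
#'
#' @param cfg a `strainwise_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.strainwise_config <- function(x, ...) {
  cat("strainwise pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Hash of a configuration (for provenance stamps)
#' @param cfg a `strainwise_config`.
#' @return character md5 digest of the canonical serialized fields.
#' @keywords internal
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}
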