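# Stimulus-response classification of regulatory elements and ROSE-style
# super-enhancer calling.

.signal_lookup <- function(signals, strain, assay, condition) {
  sel <- signals$strain == strain & signals$assay == assay &
    signals$condition == condition
  stats::setNames(signals$value[sel], signals$element_id[sel])
}

#' Classify elements as induced / repressed / neutral from paired-condition
#' signals
#'
#' Elements whose maximum-over-conditions H3K27ac falls below `min_h3k27ac`
#' or RNA Pol II below `min_polii` are filtered as `below_minimum`. For the
#' rest, fold changes are computed with a +1 pseudocount on normalized tags,
#' `(stim + 1) / (basal + 1)`, for both markers. An element is `induced` when
#' both fold changes are at least `induce_fc`, `repressed` when both are at
#' most `1/induce_fc`, `neutral` when both lie strictly inside
#' `(1/neutral_fc, neutral_fc)`, and `ambiguous` otherwise (intermediate or
#' discordant markers).
#'
#' @param signals signal table (see [read_signal_table()]) containing assays
#'   `H3K27ac` and `PolII` for `strain` under both conditions.
#' @param strain strain name to classify.
#' @param cfg a [pipeline_config()].
#' @param conditions length-2 character: basal then stimulated condition
#'   labels.
#' @return data.frame with columns `element_id`, `strain`, `state`,
#'   `fc_h3k27ac`, `fc_polii`.
#' @export
classify_elements <- function(signals, strain, cfg = pipeline_config(),
                              conditions = c("basal", "il4")) {
  validate_config(cfg)
  h_b <- .signal_lookup(signals, strain, "H3K27ac", conditions[1L])
  h_s <- .signal_lookup(signals, strain, "H3K27ac", conditions[2L])
  p_b <- .signal_lookup(signals, strain, "PolII", conditions[1L])
  p_s <- .signal_lookup(signals, strain, "PolII", conditions[2L])
  ids <- unique(signals$element_id)
  for (nm in ids) {
    if (is.na(h_b[nm]) || is.na(h_s[nm]) || is.na(p_b[nm]) || is.na(p_s[nm]))
      stop("element '", nm, "' is missing H3K27ac/PolII values for strain ",
           strain, " in both conditions", call. = FALSE)
  }
  h_b <- h_b[ids]; h_s <- h_s[ids]; p_b <- p_b[ids]; p_s <- p_s[ids]
  fc_h <- (h_s + 1) / (h_b + 1)
  fc_p <- (p_s + 1) / (p_b + 1)
  below <- pmax(h_b, h_s) < cfg$min_h3k27ac | pmax(p_b, p_s) < cfg$min_polii
  state <- rep("ambiguous", length(ids))
  state[fc_h >= cfg$induce_fc & fc_p >= cfg$induce_fc] <- "induced"
  state[fc_h <= 1 / cfg$induce_fc & fc_p <= 1 / cfg$induce_fc] <- "repressed"
  neutral <- fc_h < cfg$neutral_fc & fc_h > 1 / cfg$neutral_fc &
    fc_p < cfg$neutral_fc & fc_p > 1 / cfg$neutral_fc
  state[neutral] <- "neutral"
  state[below] <- "below_minimum"
  data.frame(element_id = ids, strain = strain, state = state,
             fc_h3k27ac = unname(fc_h), fc_polii = unname(fc_p),
             stringsAsFactors = FALSE)
}

#' Annotate elements as promoters or enhancers by TSS proximity
#'
#' An element whose center lies within `promoter_window_bp` of any TSS
#' (boundary inclusive) is a promoter; all others are enhancers.
#'
#' @param intervals element interval data.frame.
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS positions).
#' @param cfg a [pipeline_config()] supplying `promoter_window_bp`.
#' @return `intervals` with the `kind` column filled in.
#' @export
annotate_context <- function(intervals, tss, cfg = pipeline_config()) {
  validate_config(cfg)
  center <- (intervals$start + intervals$end) %/% 2L
  kind <- rep("enhancer", nrow(intervals))
  for (chr in unique(intervals$chrom)) {
    tpos <- sort(tss$pos[tss$chrom == chr])
    sel <- intervals$chrom == chr
    if (!length(tpos)) next
    i <- findInterval(center[sel], tpos)
    lo <- ifelse(i >= 1L, tpos[pmax(i, 1L)], -Inf)
    hi <- ifelse(i < length(tpos), tpos[pmin(i + 1L, length(tpos))], Inf)
    d <- pmin(abs(center[sel] - lo), abs(hi - center[sel]))
    kind[sel][d <= cfg$promoter_window_bp] <- "promoter"
  }
  intervals$kind <- kind
  intervals
}

#' Call super enhancers by ranked-signal tangent cutoff
#'
#' Enhancers within `stitch_dist_bp` of each other are stitched into regions;
#' the signal of member elements overlapping a TSS exclusion zone
#' (+/- `tss_exclusion_bp`) is excluded. Regions are ranked by total H3K27ac
#' signal; with both axes scaled to `[0, 1]`, the cutoff is the point of the
#' ranked curve minimizing the number of points below the slope-one line
#' through it (the tangent-slope-1 geometry), and all regions with signal
#' strictly above the cutoff are super enhancers. When all totals are equal
#' the curve is a degenerate line and no region is called super.
#'
#' @param intervals enhancer interval data.frame.
#' @param signal named numeric vector of H3K27ac signal per element id
#'   (single strain and condition).
#' @param tss optional TSS data.frame (`chrom`, `pos`) for signal exclusion.
#' @param cfg a [pipeline_config()].
#' @return data.frame of stitched regions: `chrom`, `start`, `end`,
#'   `members` (comma-separated element ids), `total`, `rank` (1 = strongest),
#'   `is_super`.
#' @export
call_super_enhancers <- function(intervals, signal, tss = NULL,
                                 cfg = pipeline_config()) {
  validate_config(cfg)
  if (nrow(intervals) < 3L)
    stop("super-enhancer calling needs at least 3 regions", call. = FALSE)
  if (is.null(names(signal)) || !all(intervals$id %in% names(signal)))
    stop("signal must be named by element id and cover all intervals",
         call. = FALSE)
  ord <- order(intervals$chrom, intervals$start)
  intervals <- intervals[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end))
  stitched <- GenomicRanges::reduce(gr, min.gapwidth = cfg$stitch_dist_bp + 1L)
  hit <- GenomicRanges::findOverlaps(gr, stitched)
  member_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  sig <- signal[intervals$id]
  if (!is.null(tss) && nrow(tss)) {
    tgr <- GenomicRanges::GRanges(tss$chrom,
                                  IRanges::IRanges(pmax(tss$pos - cfg$tss_exclusion_bp + 1L, 1L),
                                                   tss$pos + cfg$tss_exclusion_bp))
    excl <- IRanges::overlapsAny(gr, tgr)
    sig[excl] <- 0
  }
  nreg <- length(stitched)
  total <- vapply(seq_len(nreg), function(r) sum(sig[member_of == r]), 0)
  members <- vapply(seq_len(nreg), function(r)
    paste(intervals$id[member_of == r], collapse = ","), "")
  if (nreg < 3L)
    stop("super-enhancer calling needs at least 3 stitched regions", call. = FALSE)
  # ROSE geometry: sort ascending, slope of the scaled diagonal, pick the
  # point whose slope-1 tangent leaves the fewest points below it
  v <- sort(total)
  if (max(v) == min(v)) {
    is_super <- rep(FALSE, nreg)
  } else {
    slope <- (max(v) - min(v)) / length(v)
    xs <- seq_along(v)
    below_count <- vapply(xs, function(x) {
      b <- v[x] - slope * x
      sum(v <= slope * xs + b)
    }, 0L)
    cutoff <- v[which.min(below_count)]
    is_super <- total > cutoff
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(stitched)),
                    start = GenomicRanges::start(stitched) - 1L,
                    end = GenomicRanges::end(stitched),
                    members = members, total = total,
                    rank = rank(-total, ties.method = "first"),
                    is_super = is_super, stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}

#' Compare response variance between super and conventional enhancers
#'
#' Levene's test (median-centered) on the log2 fold-change distributions of
#' the two groups, asking whether stimulus responses are more variable in one
#' class of enhancer than the other.
#'
#' @param fc_super,fc_conventional fold changes (>0) of the two groups; at
#'   least 2 values each.
#' @return list with `statistic`, `p.value`, `df`, and the group sizes.
#' @export
response_variance_test <- function(fc_super, fc_conventional) {
  if (length(fc_super) < 2L || length(fc_conventional) < 2L)
    stop("need at least 2 fold changes per group", call. = FALSE)
  if (any(c(fc_super, fc_conventional) <= 0))
    stop("fold changes must be positive", call. = FALSE)
  x <- log2(c(fc_super, fc_conventional))
  g <- factor(rep(c("super", "conventional"), c(length(fc_super),
                                                length(fc_conventional))))
  if (stats::var(x[g == "super"]) == 0 && stats::var(x[g == "conventional"]) == 0) {
    warning("both groups constant; Levene's test undefined, returning p = 1")
    return(list(statistic = 0, p.value = 1, df = c(1L, length(x) - 2L),
                n = table(g)))
  }
  lt <- car::leveneTest(x ~ g, center = median)
  list(statistic = lt[1, "F value"], p.value = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]), n = table(g))
}
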