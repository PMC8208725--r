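# Sequence classifier (active vs background), per-nucleotide importance
# scores, predicted-functional positions/variants, category enrichment and
# 5-mer interpretation.

.gc_content <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(v %in% c("G", "C"))
}

#' Sample GC-matched background intervals
#'
#' Draws one background window per foreground interval: equal length, GC
#' content within `gc_tol` (absolute difference in fraction), center within
#' `max_dist` of the foreground center, and no overlap with any foreground
#' interval. Deterministic given the seed. When no eligible window is found
#' within the search range the range is widened once (doubled); if that also
#' fails an error is raised.
#'
#' @param genome genome sequence (single string).
#' @param intervals foreground interval data.frame (single chromosome).
#' @param seed integer seed.
#' @param max_dist maximal center distance (bp, default 1e5).
#' @param gc_tol GC tolerance (default 0.02 = 2 percentage points).
#' @param stride spacing of candidate window starts scanned within the
#'   search range (default 25 bp); all candidates are evaluated and one
#'   eligible window is drawn at random.
#' @return data.frame of background intervals (ids `bg_<foreground id>`).
#' @export
sample_gc_matched_background <- function(genome, intervals, seed = 1L,
                                         max_dist = 1e5, gc_tol = 0.02,
                                         stride = 25L) {
  set.seed(seed)
  glen <- nchar(genome)
  is_gc <- strsplit(genome, "", fixed = TRUE)[[1L]] %in% c("G", "C")
  gcc <- c(0, cumsum(is_gc))
  ord <- order(intervals$start)
  fs <- intervals$start[ord]
  fe <- intervals$end[ord]
  out <- intervals
  out$id <- paste0("bg_", intervals$id)
  for (r in seq_len(nrow(intervals))) {
    L <- intervals$end[r] - intervals$start[r]
    ctr <- (intervals$start[r] + intervals$end[r]) %/% 2L
    gc_f <- (gcc[intervals$end[r] + 1L] - gcc[intervals$start[r] + 1L]) / L
    found <- FALSE
    for (stage in 1:2) {
      range_bp <- max_dist * stage
      lo <- max(0L, ctr - as.integer(range_bp))
      hi <- min(glen - L, ctr + as.integer(range_bp))
      s <- seq.int(lo, hi, by = stride)
      # overlap with any foreground: last interval starting before the
      # candidate end must end at or before the candidate start
      i <- findInterval(s + L - 1L, fs)
      clear <- ifelse(i > 0L, fe[pmax(i, 1L)] <= s, TRUE)
      gc_b <- (gcc[s + L + 1L] - gcc[s + 1L]) / L
      ok <- which(clear & abs(gc_b - gc_f) <= gc_tol)
      if (length(ok)) {
        pick <- ok[sample.int(length(ok), 1L)]
        out$start[r] <- s[pick]; out$end[r] <- s[pick] + L
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("no GC-matched background found for interval ", intervals$id[r],
           call. = FALSE)
  }
  out$kind <- "background"
  out
}

#' Partition sequences into train/validation/test by coordinate
#'
#' On a single synthetic chromosome, coordinate blocks stand in for
#' chromosome holdouts: an initial block of positions trains the model, the
#' next is validation, the last is the test partition. The default gives
#' equal thirds; `props` reweights the blocks (the chromosome-holdout
#' protocol this emulates trains on most of the genome and holds out one
#' chromosome each for validation and testing, i.e. roughly 9:0.5:0.5).
#'
#' @param starts interval start coordinates.
#' @param props length-3 positive weights for train/val/test blocks.
#' @return character vector of `"train"`, `"val"`, `"test"`.
#' @export
split_by_thirds <- function(starts, props = c(1, 1, 1)) {
  stopifnot(length(props) == 3L, all(props > 0))
  props <- props / sum(props)
  q <- quantile(starts, c(props[1L], props[1L] + props[2L]))
  ifelse(starts <= q[1L], "train", ifelse(starts <= q[2L], "val", "test"))
}

#' Train the enhancer sequence classifier
#'
#' Three convolutional layers (ReLU, max pooling) followed by a global max
#' pool and two fully connected layers, trained with binary cross-entropy and
#' Adam. The learning rate starts at `cfg$lr_init` and is multiplied by
#' `cfg$lr_factor` whenever the validation loss has not improved for
#' `lr_patience` consecutive epochs; training stops once the validation loss
#' has not improved for `cfg$patience_epochs` epochs (or at `max_epochs`).
#' The weights of the best validation epoch are kept and the held-out test
#' partition is scored by auROC.
#'
#' @param pos_seqs,neg_seqs character vectors of positive / negative
#'   sequences, all of length `cfg$seq_len_bp`.
#' @param split character vector over `c("train","val","test")`, one entry
#'   per sequence (positives first, then negatives); `NULL` = seeded random
#'   thirds.
#' @param cfg a [pipeline_config()].
#' @param seed integer seed controlling initialization and batch order.
#' @param filters,kernels,pools,fc_units architecture sizes.
#' @param batch_size minibatch size; `NULL` (default) sizes batches so that
#'   an epoch makes about 300 optimizer steps regardless of training-set
#'   size, keeping the epoch count to convergence stable across scales.
#' @param max_epochs hard cap on epochs.
#' @param min_per_class minimum sequences per class.
#' @param augment_rc also train on the reverse complement of every training
#'   sequence (strand symmetry; validation and test sets untouched).
#' @param weight_decay L2 penalty on the weight matrices.
#' @param verbose print per-epoch progress.
#' @return a `strainwise_cnn`: list with `params`, `arch`, `log`
#'   (per-epoch data.frame: epoch, train_loss, val_loss, lr), `auroc`
#'   (held-out test), `split`, `seq_len`, `seed`.
#' @export
train_classifier <- function(pos_seqs, neg_seqs, split = NULL,
                             cfg = pipeline_config(), seed = cfg$seed,
                             filters = c(12L, 16L, 16L),
                             kernels = c(10L, 5L, 3L),
                             pools = c(4L, 4L),
                             fc_units = 32L,
                             batch_size = NULL,
                             max_epochs = 300L,
                             min_per_class = 200L,
                             lr_patience = 5L,
                             augment_rc = TRUE,
                             weight_decay = 1e-4,
                             verbose = FALSE) {
  validate_config(cfg)
  n1 <- length(pos_seqs); n0 <- length(neg_seqs)
  if (n1 < min_per_class || n0 < min_per_class)
    stop("need at least ", min_per_class, " sequences per class", call. = FALSE)
  if (max(n1, n0) / min(n1, n0) > 10)
    stop("class imbalance exceeds 10:1; resample the larger class", call. = FALSE)
  seqs <- c(pos_seqs, neg_seqs)
  if (any(nchar(seqs) != cfg$seq_len_bp))
    stop("all sequences must have length seq_len_bp = ", cfg$seq_len_bp,
         call. = FALSE)
  y <- c(rep(1, n1), rep(0, n0))
  set.seed(seed)
  if (is.null(split))
    split <- sample(c("train", "val", "test"), n1 + n0, replace = TRUE,
                    prob = c(1, 1, 1) / 3)
  if (length(split) != n1 + n0)
    stop("split must have one entry per sequence", call. = FALSE)
  idx_train0 <- which(split == "train")
  if (augment_rc) {
    seqs <- c(seqs, .revcomp(seqs[idx_train0]))
    y <- c(y, y[idx_train0])
    split <- c(split, rep("train", length(idx_train0)))
  }
  X <- encode_sequences(seqs)
  arch <- list(filters = filters, kernels = kernels, pools = pools,
               fc_units = fc_units, seq_len = cfg$seq_len_bp)
  params <- .init_net(arch)
  adam <- list(t = 0L,
               m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0))
  idx_train <- which(split == "train")
  idx_val <- which(split == "val")
  idx_test <- which(split == "test")
  if (!length(idx_train) || !length(idx_val) || !length(idx_test))
    stop("split must populate train, val and test partitions", call. = FALSE)
  if (is.null(batch_size))
    batch_size <- max(4L, as.integer(round(length(idx_train) / 300)))

  eval_loss <- function(par, idx) {
    tot <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / 512L))) {
      fw <- .net_forward(par, X[, chunk, , drop = FALSE], arch)
      tot <- tot + .bce_loss(fw$z, y[chunk]) * length(chunk)
    }
    tot / length(idx)
  }

  lr <- cfg$lr_init
  best_val <- Inf; best_params <- params; since_best <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), lr = numeric())
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(idx_train)
    tr_loss <- 0
    for (chunk in split(ord, ceiling(seq_along(ord) / batch_size))) {
      Xb <- X[, chunk, , drop = FALSE]
      fw <- .net_forward(params, Xb, arch)
      yb <- y[chunk]
      tr_loss <- tr_loss + .bce_loss(fw$z, yb) * length(chunk)
      dz <- (stats::plogis(fw$z) - yb) / length(chunk)
      gr <- .net_backward(params, Xb, arch, fw, dz)
      if (weight_decay > 0)
        for (nm in grep("^W", names(params), value = TRUE))
          gr[[nm]] <- gr[[nm]] + weight_decay * params[[nm]]
      st <- .adam_step(adam, params, gr, lr)
      adam <- st$state; params <- st$params
    }
    tr_loss <- tr_loss / length(idx_train)
    val_loss <- eval_loss(params, idx_val)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                 val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, tr_loss, val_loss, lr))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_params <- params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best %% lr_patience == 0L) lr <- lr * cfg$lr_factor
      if (since_best >= cfg$patience_epochs) break
    }
  }
  test_scores <- numeric(0)
  for (chunk in split(idx_test, ceiling(seq_along(idx_test) / 512L))) {
    fw <- .net_forward(best_params, X[, chunk, , drop = FALSE], arch)
    test_scores <- c(test_scores, fw$z)
  }
  model <- list(params = best_params, arch = arch, log = log,
                auroc = auroc(test_scores, y[idx_test]),
                split = split, seq_len = cfg$seq_len_bp, seed = seed)
  class(model) <- "strainwise_cnn"
  model
}

#' @export
print.strainwise_cnn <- function(x, ...) {
  cat(sprintf("strainwise_cnn: %d conv layers, %d epochs trained, test auROC %.3f\n",
              length(x$arch$filters), nrow(x$log), x$auroc))
  invisible(x)
}

#' Predict with a trained sequence classifier
#' @param object a `strainwise_cnn`.
#' @param seqs character vector of sequences of the model's input length.
#' @param type `"prob"` (default) or `"logit"`.
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.strainwise_cnn <- function(object, seqs, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  X <- encode_sequences(seqs)
  z <- numeric(0)
  for (chunk in split(seq_along(seqs), ceiling(seq_along(seqs) / 512L))) {
    fw <- .net_forward(object$params, X[, chunk, , drop = FALSE], object$arch)
    z <- c(z, fw$z)
  }
  if (type == "prob") stats::plogis(z) else z
}

# gradient of the positive-class logit with respect to the input, times
# (input - uniform reference); per-position contribution summed over channels
.attribution_raw <- function(model, seqs) {
  X <- encode_sequences(seqs)
  W <- dim(X)[1L]; n <- dim(X)[2L]
  out <- matrix(0, n, W)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 256L))) {
    Xb <- X[, chunk, , drop = FALSE]
    fw <- .net_forward(model$params, Xb, model$arch)
    gr <- .net_backward(model$params, Xb, model$arch, fw, rep(1, length(chunk)))
    contrib <- gr$input * (Xb - 0.25)
    out[chunk, ] <- t(contrib[, , 1L] + contrib[, , 2L] +
                        contrib[, , 3L] + contrib[, , 4L])
  }
  out
}

#' Per-nucleotide importance scores
#'
#' Attribution of the classifier's positive-class logit to each input
#' position against a uniform-base reference (gradient x (input - 0.25),
#' summed over the four channels). Scores are computed for the sequence and
#' its reverse complement; the reverse-complement track is reversed to align
#' positions and the final non-negative score per position is
#' `max(|forward|, |reverse-complement|)`.
#'
#' @param model a `strainwise_cnn`.
#' @param seqs character vector of sequences (model input length).
#' @return numeric matrix (sequences x positions) of importance scores; a
#'   single sequence gives a 1-row matrix.
#' @export
importance_scores <- function(model, seqs) {
  if (any(nchar(seqs) != model$seq_len))
    stop("sequences must have the model input length ", model$seq_len,
         call. = FALSE)
  fwd <- abs(.attribution_raw(model, seqs))
  rc <- abs(.attribution_raw(model, .revcomp(seqs)))
  rc <- rc[, rev(seq_len(ncol(rc))), drop = FALSE]
  out <- pmax(fwd, rc)
  rownames(out) <- names(seqs)
  out
}

#' Predicted functional positions of an importance track
#'
#' Exactly `round(top_frac * length)` positions with the highest scores; ties
#' at the cutoff are broken toward the leftmost position.
#'
#' @param scores numeric importance track (one sequence).
#' @param cfg a [pipeline_config()].
#' @return sorted integer vector of 1-based positions.
#' @export
predicted_functional_positions <- function(scores, cfg = pipeline_config()) {
  validate_config(cfg)
  k <- round(cfg$top_frac * length(scores))
  sort(order(-scores, seq_along(scores))[seq_len(k)])
}

#' Flag predicted-functional variants
#'
#' A variant is flagged when its position (any base of the left-aligned ref
#' allele) falls on a predicted functional position of any element window
#' covering it. Variants outside all windows are reported unflagged and
#' counted in the returned summary attribute.
#'
#' @param variants variant table (0-based positions).
#' @param tracks importance score matrix from [importance_scores()], rows
#'   named by element id.
#' @param elements interval data.frame for the scored elements.
#' @param cfg a [pipeline_config()].
#' @return `variants` with added logical column `predicted_functional` and
#'   attribute `"n_outside"` (variants covered by no scored window).
#' @export
prioritize_variants <- function(variants, tracks, elements,
                                cfg = pipeline_config()) {
  validate_config(cfg)
  ids <- intersect(rownames(tracks), elements$id)
  el <- elements[match(ids, elements$id), , drop = FALSE]
  W <- ncol(tracks)
  center <- (el$start + el$end) %/% 2L
  wstart <- center - W %/% 2L # 0-based window starts
  top <- lapply(ids, function(i)
    predicted_functional_positions(tracks[i, ], cfg))
  names(top) <- ids
  flag <- logical(nrow(variants))
  covered <- logical(nrow(variants))
  vlen <- nchar(variants$ref)
  for (j in seq_len(nrow(variants))) {
    vp <- variants$pos[j]:(variants$pos[j] + vlen[j] - 1L)
    hit <- which(el$chrom == variants$chrom[j] &
                   wstart <= max(vp) & wstart + W > min(vp))
    if (!length(hit)) next
    covered[j] <- TRUE
    for (h in hit) {
      off <- vp - wstart[h] + 1L
      off <- off[off >= 1L & off <= W]
      if (any(off %in% top[[ids[h]]])) { flag[j] <- TRUE; break }
    }
  }
  variants$predicted_functional <- flag
  attr(variants, "n_outside") <- sum(!covered)
  variants
}

#' Per-group enrichment of elements carrying top-scoring variants
#'
#' log2 of (percent of elements in the group with a predicted-functional
#' variant) over (percent among all elements). Groups with zero global
#' percentage are undefined and reported `NA`.
#'
#' @param flags named logical vector: element has >= 1 flagged variant.
#' @param groups factor/character of group labels, one per element.
#' @return data.frame with `group`, `n`, `pct`, `global_pct`,
#'   `log2_enrichment`.
#' @export
category_enrichment <- function(flags, groups) {
  if (length(flags) != length(groups))
    stop("flags and groups must have equal length", call. = FALSE)
  groups <- as.factor(groups)
  global_pct <- mean(flags)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    sel <- groups == g
    pct <- if (any(sel)) mean(flags[sel]) else NA_real_
    data.frame(group = g, n = sum(sel), pct = pct, global_pct = global_pct,
               log2_enrichment = if (global_pct > 0) log2(pct / global_pct)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' k-mer interpretation of importance tracks
#'
#' Every k-mer occurrence is scored by its mean per-position importance;
#' occurrences in the global top `kmer_top_frac` by score are cross-tabulated
#' against the rest per k-mer identity, giving a Haldane-corrected odds ratio
#' and a two-sided Fisher exact p-value per k-mer.
#'
#' @param tracks importance matrix (sequences x positions).
#' @param seqs the scored sequences.
#' @param cfg a [pipeline_config()] (`kmer_k`, `kmer_top_frac`).
#' @param min_count drop k-mers with fewer occurrences (default 5).
#' @return data.frame with `kmer`, `n`, `n_top`, `odds_ratio`, `p.value`,
#'   `padj`, ordered by decreasing odds ratio.
#' @export
kmer_interpretation <- function(tracks, seqs, cfg = pipeline_config(),
                                min_count = 5L) {
  validate_config(cfg)
  k <- cfg$kmer_k
  W <- ncol(tracks)
  if (k > W) stop("kmer_k exceeds the track length", call. = FALSE)
  n_off <- W - k + 1L
  km <- matrix("", length(seqs), n_off)
  sc <- matrix(0, length(seqs), n_off)
  cum <- cbind(0, t(apply(tracks, 1, cumsum)))
  for (off in seq_len(n_off)) {
    km[, off] <- substr(seqs, off, off + k - 1L)
    sc[, off] <- (cum[, off + k] - cum[, off]) / k
  }
  kmer <- as.vector(km); score <- as.vector(sc)
  keep <- !grepl("[^ACGT]", kmer)
  kmer <- kmer[keep]; score <- score[keep]
  N <- length(score)
  n_top <- round(cfg$kmer_top_frac * N)
  in_top <- rank(-score, ties.method = "first") <= n_top
  tab <- table(kmer, in_top)
  if (!"TRUE" %in% colnames(tab)) tab <- cbind(tab, "TRUE" = 0L)
  cnt <- tab[, "FALSE"] + tab[, "TRUE"]
  sel <- cnt >= min_count
  kmers <- rownames(tab)[sel]
  a <- tab[sel, "TRUE"]; b <- n_top - a
  c2 <- tab[sel, "FALSE"]; d <- (N - n_top) - c2
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c2 + 0.5))
  pv <- vapply(seq_along(kmers), function(i)
    fisher.test(matrix(c(a[i], b[i], c2[i], d[i]), 2L))$p.value, 0)
  out <- data.frame(kmer = kmers, n = as.integer(cnt[sel]),
                    n_top = as.integer(a), odds_ratio = unname(or),
                    p.value = pv, padj = p.adjust(pv, "BH"),
                    stringsAsFactors = FALSE)
  out[order(-out$odds_ratio), ]
}
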