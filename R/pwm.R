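# Position weight matrices and log-odds scanning. Matrices are stored as
# 4 x L probability matrices (rows A,C,G,T); scanning always considers both
# strands since elements are strandless.

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param matrix 4 x L numeric matrix of counts or probabilities, rows in
#'   A, C, G, T order (rownames, when present, are honoured).
#' @param name motif name.
#' @param pseudocount added to every cell before column normalization
#'   (default 0.25).
#' @param background nucleotide background frequencies (default uniform).
#' @return a `strainwise_pwm` object.
#' @export
pwm <- function(matrix, name = "motif", pseudocount = 0.25,
                background = rep(0.25, 4)) {
  if (!is.matrix(matrix) || nrow(matrix) != 4L)
    stop("PWM matrix must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(matrix) < 4L)
    stop("PWM '", name, "' must have length >= 4", call. = FALSE)
  if (any(is.na(matrix)) || any(matrix < 0))
    stop("PWM matrix must be non-negative", call. = FALSE)
  if (!is.null(rownames(matrix))) {
    if (!setequal(toupper(rownames(matrix)), .BASES))
      stop("PWM rownames must be A, C, G, T", call. = FALSE)
    matrix <- matrix[match(.BASES, toupper(rownames(matrix))), , drop = FALSE]
  }
  m <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  rownames(m) <- .BASES
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive frequencies", call. = FALSE)
  background <- background / sum(background)
  structure(list(name = name, matrix = m, pseudocount = pseudocount,
                 background = background),
            class = "strainwise_pwm")
}

#' @export
print.strainwise_pwm <- function(x, ...) {
  cat("PWM", x$name, "- length", ncol(x$matrix),
      "- consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per column)
#' @param p a `strainwise_pwm`.
#' @return character consensus string.
#' @export
pwm_consensus <- function(p) {
  paste(.BASES[apply(p$matrix, 2, which.max)], collapse = "")
}

#' Maximum attainable log-odds score of a PWM
#' @param p a `strainwise_pwm`.
#' @return numeric score in bits.
#' @export
pwm_max_score <- function(p) {
  sum(apply(log2(p$matrix / p$background), 2, max))
}

# log-odds score matrix with a 5th row for ambiguous bases; the pseudo-floor
# probability caps the penalty a non-ACGT base can contribute.
.pwm_lods <- function(p, ambig_floor = 1e-3) {
  lo <- log2(p$matrix / p$background)
  rbind(lo, N = log2(ambig_floor / mean(p$background)))
}

.encode_bases <- function(seq) {
  # integer codes 1..4 for A,C,G,T; 5 for anything else
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]], .BASES)
  code[is.na(code)] <- 5L
  code
}

.revcomp <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "",
                       fixed = TRUE)[[1L]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

# score floor: every column at its minimum log-odds (used when the sequence
# is shorter than the motif)
.pwm_score_floor <- function(p) sum(apply(log2(p$matrix / p$background), 2, min))

#' Best motif score of a sequence
#'
#' Maximum log2 odds score of the PWM over all offsets of both strands.
#' Bases outside A/C/G/T contribute a fixed pseudo-floor log-odds. A sequence
#' shorter than the motif scores at the floor (every column at its minimum
#' log-odds) rather than raising an error, so score differences over
#' indel-carrying pairs remain defined.
#'
#' @param seq character DNA sequence (a single string).
#' @param p a `strainwise_pwm`.
#' @return numeric best score in bits.
#' @export
best_motif_score <- function(seq, p) {
  L <- ncol(p$matrix)
  lods <- .pwm_lods(p)
  sc <- function(code) {
    n <- length(code)
    if (n < L) return(-Inf)
    # rows = offsets, cols = motif positions
    idx <- outer(seq_len(n - L + 1L) - 1L, seq_len(L), `+`)
    max(rowSums(matrix(lods[cbind(as.vector(code[idx]), rep(seq_len(L), each = nrow(idx)))],
                       nrow = nrow(idx))))
  }
  fwd <- sc(.encode_bases(seq))
  rev <- sc(.encode_bases(.revcomp(seq)))
  out <- max(fwd, rev)
  if (!is.finite(out)) out <- .pwm_score_floor(p)
  out
}

#' Best motif scores for many sequences
#' @param seqs character vector of sequences.
#' @param p a `strainwise_pwm`.
#' @return numeric vector of best scores.
#' @export
best_motif_scores <- function(seqs, p) {
  vapply(seqs, best_motif_score, 0, p = p, USE.NAMES = FALSE)
}

#' Read PWMs from a JASPAR-style PFM file
#'
#' Accepts count or probability matrices in the JASPAR text layout: a `>`
#' header line followed by four rows (optionally prefixed by the base letter
#' and wrapped in brackets). Counts are converted to probabilities with the
#' pseudocount; probability input is idempotent up to re-normalization.
#'
#' @param path PFM file path.
#' @param pseudocount per-cell pseudocount (default 0.25).
#' @param background background frequencies (default uniform).
#' @return list of `strainwise_pwm` objects, named by motif.
#' @export
read_pfm <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') found in ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    nm <- strsplit(header, "\\s+")[[1L]]
    nm <- if (length(nm) >= 2L) nm[[2L]] else nm[[1L]]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L)
      stop("motif '", nm, "': expected 4 matrix rows, got ", length(body),
           call. = FALSE)
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
      if (any(is.na(vals)))
        stop("motif '", nm, "': non-numeric matrix entry", call. = FALSE)
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif '", nm, "': ragged matrix", call. = FALSE)
    m <- do.call(rbind, rows)
    rownames(m) <- .BASES
    out[[nm]] <- pwm(m, name = nm, pseudocount = pseudocount,
                     background = background)
  }
  out
}

#' Write PWMs to a JASPAR-style PFM file
#' @param pwms list of `strainwise_pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name, " ", p$name), con)
    for (b in .BASES)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(formatC(p$matrix[b, ], format = "f", digits = 6),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Packaged synthetic consensus-like motifs
#'
#' Returns the PWMs shipped with the package: consensus-like matrices
#' emulating a lineage-determining factor class (ETS/PU.1-like, C/EBP-like)
#' and a signal-dependent factor class (STAT6-like GAS element, EGR-like).
#' These are synthetic stand-ins constructed for simulation, not database
#' matrices.
#'
#' @return named list of `strainwise_pwm` objects.
#' @export
builtin_motifs <- function() {
  read_pfm(system.file("extdata", "motifs", "synthetic_motifs.pfm",
                       package = "strainwise", mustWork = TRUE))
}

# best partial-overlap alignment score (bits) of a consensus string against
# a PWM: slides the string across the matrix on both strands, scoring
# overlapping columns only (minimum overlap min_ov)
.pwm_cross_score <- function(site, p, min_ov = 5L) {
  lods <- log2(p$matrix / p$background)
  L <- ncol(lods)
  score_one <- function(code) {
    n <- length(code)
    best <- -Inf
    for (s in seq(-(n - min_ov), L - min_ov)) {
      cols <- seq_len(L)
      pos <- cols - s
      ok <- pos >= 1L & pos <= n
      if (sum(ok) < min_ov) next
      best <- max(best, sum(lods[cbind(code[pos[ok]], cols[ok])]))
    }
    best
  }
  code <- .encode_bases(site)
  code_rc <- rev(c(4L, 3L, 2L, 1L, 5L)[code])
  max(score_one(code), score_one(code_rc))
}

#' Random decoy PWMs
#'
#' Generates sharp random motifs (one dominant base per column) used as decoy
#' competitors in motif-mutation recovery experiments. When `avoid` is given,
#' candidates resembling any of those motifs (best partial-overlap alignment
#' of the decoy consensus at or above `max_cross` bits) are rejected and
#' redrawn, so the decoys form a genuine null set relative to the planted
#' motifs.
#'
#' @param n number of decoys.
#' @param length motif length.
#' @param seed integer seed.
#' @param avoid optional list of [pwm()] objects the decoys must not
#'   resemble.
#' @param max_cross similarity rejection threshold in bits (default 5).
#' @return named list of `strainwise_pwm` objects `decoy01..`.
#' @export
make_decoy_pwms <- function(n, length = 10L, seed = 1L, avoid = NULL,
                            max_cross = 5) {
  withr_seed <- function(code) { # local seed without disturbing global RNG
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    out <- list()
    i <- 0L
    guard <- 0L
    while (i < n && guard < 100L * n) {
      guard <- guard + 1L
      cons <- sample(4L, length, replace = TRUE)
      m <- matrix(0.05, 4L, length)
      m[cbind(cons, seq_len(length))] <- 0.85
      cand <- pwm(m, name = sprintf("decoy%02d", i + 1L))
      if (!is.null(avoid)) {
        sims <- vapply(avoid, function(a)
          .pwm_cross_score(pwm_consensus(cand), a), 0)
        if (any(sims >= max_cross)) next
      }
      i <- i + 1L
      out[[cand$name]] <- cand
    }
    if (i < n) stop("could not generate enough dissimilar decoys", call. = FALSE)
    out
  })
}

# --- motif editing helpers used by the synthetic generator ------------------

# column sharpness = information content (bits)
.pwm_col_ic <- function(p) {
  apply(p$matrix, 2, function(col) 2 + sum(col * log2(col)))
}

# Plant/edit machinery: positions are 1-based within the motif. An edit
# substitutes the consensus base by the lowest-probability base (sharp
# columns: large log-odds penalty) or, for "soft" mismatches, any
# non-consensus base of a low-information column.
.pwm_worst_base <- function(p, j) .BASES[which.min(p$matrix[, j])]

# Returns motif instance strings for the generator:
#   consensus              -- full-strength site
#   weak                   -- consensus with one sharp-column mismatch
#   mutations of a site    -- list(pos, base) edits relative to the given site
# Column informativeness splits positions into a sharp (core) and a soft
# (flank) class; mutated positions are drawn at random within their class so
# that repeated edits across elements are not stereotyped, while the
# log-odds penalty (hence occupancy) depends only on the class. The
# substituted base is always the column's lowest-probability base.
.motif_variant <- function(p, kind = c("consensus", "weak"),
                           n_sharp_mm = 0L, n_soft_mm = 0L) {
  kind <- match.arg(kind)
  cons <- strsplit(pwm_consensus(p), "", fixed = TRUE)[[1L]]
  ic <- .pwm_col_ic(p)
  is_sharp <- ic >= stats::median(ic)
  sharp <- which(is_sharp)
  soft  <- which(!is_sharp)
  site <- cons
  used <- integer()
  if (kind == "weak") {
    j <- if (length(sharp) > 1L) sample(sharp, 1L) else sharp[1L]
    site[j] <- .pwm_worst_base(p, j)
    used <- j
  }
  mm <- list()
  pick <- function(pool, k) if (length(pool) == 1L) pool else sample(pool, k)
  sharp_pool <- setdiff(sharp, used)
  for (j in pick(sharp_pool, min(n_sharp_mm, length(sharp_pool)))[seq_len(n_sharp_mm)])
    mm[[length(mm) + 1L]] <- list(pos = j, base = .pwm_worst_base(p, j))
  soft_pool <- setdiff(soft, c(used, vapply(mm, `[[`, 0L, "pos")))
  for (j in pick(soft_pool, min(n_soft_mm, length(soft_pool)))[seq_len(n_soft_mm)])
    mm[[length(mm) + 1L]] <- list(pos = j, base = .pwm_worst_base(p, j))
  list(site = paste(site, collapse = ""), weak_pos = used, mismatches = mm)
}

# logistic occupancy given a best log-odds score; anchored so that a
# consensus site occupies at occ_max
.occupancy <- function(score, p, slope, occ_max = 0.95) {
  stats::plogis(slope * (score - pwm_max_score(p)) + stats::qlogis(occ_max))
}
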