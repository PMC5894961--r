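#' Batch depth-correlation precondition
#'
#' The z-score CNV statistic is only meaningful when per-exon depths
#' are highly correlated across the samples of a batch (the shared
#' capture-efficiency profile dominates). This check computes all
#' pairwise Pearson correlations of per-exon depths and passes only if
#' every pair exceeds `r_min` (default 0.7). A constant (zero
#' variance) sample makes its pairs undefined; such pairs are reported
#' with `r = NA` and treated as failing.
#'
#' @param depth samples-by-exons depth matrix.
#' @param r_min minimum pairwise Pearson correlation (default 0.7).
#' @return List with `pass` (logical), `r` (pairwise correlation
#'   matrix) and `failing` (data frame of pairs at or below `r_min`).
#' @export
check_batch_correlation <- function(depth, r_min = 0.7) {
  stopifnot(is.matrix(depth), nrow(depth) >= 3)
  r <- suppressWarnings(stats::cor(t(depth)))
  fail <- which(upper.tri(r) & (is.na(r) | r <= r_min), arr.ind = TRUE)
  failing <- data.frame(
    sample_a = rownames(depth)[fail[, 1]],
    sample_b = rownames(depth)[fail[, 2]],
    r = r[fail], stringsAsFactors = FALSE)
  list(pass = nrow(failing) == 0, r = r, failing = failing)
}

#' Normalize exon depths within each sample
#'
#' Divides every exon's mean depth by the sample's mean depth over the
#' whole target, removing library-size differences. The sample mean is
#' weighted by exon base length, i.e. it is the per-base mean depth
#' over the target ("mean depth of all target region"); an unweighted
#' mean over exons is available via `weighted = FALSE`. By
#' construction the length-weighted mean of the normalized values is 1
#' in every sample.
#'
#' @param depth samples-by-exons depth matrix (column order = panel
#'   order).
#' @param panel the [target_panel()] supplying exon lengths.
#' @param weighted use exon-length weights for the sample mean
#'   (default TRUE).
#' @return Matrix of normalized depths (dimensionless), same dimnames.
#' @export
normalize_depth <- function(depth, panel, weighted = TRUE) {
  stopifnot(is.matrix(depth), ncol(depth) == nrow(panel))
  if (any(depth < 0)) stop("negative depths")
  w <- if (weighted) panel$length else rep(1, nrow(panel))
  sample_mean <- as.vector(depth %*% w) / sum(w)
  zero <- sample_mean <= 0
  if (any(zero))
    stop("zero mean target depth for sample(s): ",
         paste(rownames(depth)[zero], collapse = ", "))
  sweep(depth, 1, sample_mean, `/`)
}

#' Per-exon batch statistics of normalized depth
#'
#' For each exon, the mean and standard deviation of the normalized
#' depth over all samples of the batch. The SD uses the n-1 sample
#' denominator, appropriate for the small batches (20-30 samples)
#' pooled per capture.
#'
#' @param nom normalized depth matrix from [normalize_depth()].
#' @return List with `mu`, `sigma` (per-exon vectors) and `n`.
#' @export
batch_stats <- function(nom) {
  stopifnot(is.matrix(nom))
  if (nrow(nom) < 3)
    stop("batch statistics need at least 3 samples (SD unstable)")
  list(mu = colMeans(nom), sigma = apply(nom, 2, stats::sd), n = nrow(nom))
}

#' Exon z-scores of normalized depth
#'
#' z = (nom - mu) / sigma per (sample, exon). Exons with sigma = 0
#' carry no information about copy number in this batch; they get
#' z = 0 and are listed in the `uninformative` attribute rather than
#' raising an error.
#'
#' Three estimators for mu/sigma are offered. `"all"` uses every batch
#' sample including the one under test (the literal reading of the
#' batch formula). `"loo"` computes leave-one-out statistics per
#' sample, so a sample's own CNV cannot inflate the SD it is tested
#' against. `"masked"` estimates mu/sigma per exon from the
#' copy-neutral samples only: an initial median/MAD screen flags
#' gross outliers, then mean/SD are iteratively refined excluding
#' samples at `|z| > cutoff`. This recovers the reference
#' distribution even when several relatives in the batch share the
#' same CNV (where the literal all-sample SD would swallow the
#' carriers).
#'
#' @param nom normalized depth matrix.
#' @param stats_ precomputed [batch_stats()] (only for
#'   `method = "all"`; computed when NULL).
#' @param method "all", "loo" or "masked".
#' @param cutoff exclusion threshold for the masked estimator.
#' @return Matrix of z-scores with an `uninformative` attribute naming
#'   zero-variance exons.
#' @export
zscores <- function(nom, stats_ = NULL, method = c("all", "loo", "masked"),
                    cutoff = 2.58) {
  method <- match.arg(method)
  n <- nrow(nom)
  if (method == "all") {
    if (is.null(stats_)) stats_ <- batch_stats(nom)
    if (length(stats_$mu) != ncol(nom))
      stop("batch statistics do not match the matrix shape")
    z <- sweep(sweep(nom, 2, stats_$mu), 2, stats_$sigma, `/`)
    zero <- stats_$sigma == 0
  } else if (method == "loo") {
    z <- nom * 0
    zero <- rep(FALSE, ncol(nom))
    for (i in seq_len(n)) {
      st <- batch_stats(nom[-i, , drop = FALSE])
      zi <- (nom[i, ] - st$mu) / st$sigma
      zi[st$sigma == 0] <- 0
      zero <- zero | st$sigma == 0
      z[i, ] <- zi
    }
  } else {
    z <- nom * 0
    zero <- rep(FALSE, ncol(nom))
    for (e in seq_len(ncol(nom))) {
      # robust initialization: median/MAD flags gross outliers (shared
      # family CNVs included) before the mean/SD refinement, which on
      # its own can stall with contaminated statistics
      # screening at 2 robust SDs only seeds the exclusion set; the
      # refinement below re-admits anything within the cutoff, so the
      # converged reference set is governed by `cutoff` alone
      med <- stats::median(nom[, e])
      madv <- stats::mad(nom[, e])
      use <- if (madv > 0) abs(nom[, e] - med) / madv <= 2
             else rep(TRUE, n)
      if (sum(use) < 3) use <- rep(TRUE, n)
      for (iter in 1:10) {
        if (sum(use) < 3) break
        mu <- mean(nom[use, e]); sg <- stats::sd(nom[use, e])
        if (sg == 0) break
        ze <- (nom[, e] - mu) / sg
        new_use <- abs(ze) <= cutoff
        if (all(new_use == use)) break
        use <- new_use
      }
      mu <- mean(nom[use, e]); sg <- stats::sd(nom[use, e])
      if (is.na(sg) || sg == 0) { z[, e] <- 0; zero[e] <- TRUE }
      else z[, e] <- (nom[, e] - mu) / sg
    }
  }
  z[, which(zero)] <- 0
  attr(z, "uninformative") <- colnames(nom)[zero]
  z
}

#' Call exon-level CNVs from batch z-scores
#'
#' Flags (sample, exon) cells with z below -`cutoff` as deletion
#' evidence and above +`cutoff` as duplication evidence (default
#' 2.58, the two-sided standard-normal point leaving about 1% in the
#' tails, so over 99% of copy-neutral cells are filtered out). Within
#' each sample and gene, maximal runs of consecutive panel exons with
#' the same direction are merged into one call; `max_gap_exons`
#' consecutive non-flagged exons (default 0) may be bridged inside a
#' run. Deletion zygosity comes from the mean normalized depth over
#' the spanned exons: below `hom_max` homozygous, between `hom_max`
#' and `het_max` heterozygous; duplications get `NA`.
#'
#' @param z z-score matrix from [zscores()].
#' @param nom the matching normalized depth matrix.
#' @param panel the [target_panel()] (column order must match).
#' @param cutoff bilateral z threshold (default 2.58).
#' @param max_gap_exons non-flagged exons tolerated inside a run.
#' @param hom_max,het_max zygosity thresholds on mean normalized depth
#'   (defaults 0.25 and 0.75).
#' @return Data frame of calls: sample, gene, chrom, span_start,
#'   span_end, exon_start, exon_end, n_exons, call_type, zygosity,
#'   min_abs_z, mean_nom.
#' @export
call_cnvs <- function(z, nom, panel, cutoff = 2.58, max_gap_exons = 0L,
                      hom_max = 0.25, het_max = 0.75) {
  stopifnot(identical(dim(z), dim(nom)), ncol(z) == nrow(panel))
  calls <- list()
  for (s in seq_len(nrow(z))) {
    for (g in unique(panel$gene)) {
      idx <- which(panel$gene == g)
      idx <- idx[order(panel$exon_index[idx])]
      dir <- integer(length(idx))
      dir[z[s, idx] > cutoff] <- 1L
      dir[z[s, idx] < -cutoff] <- -1L
      runs <- merge_runs(dir, max_gap_exons)
      for (r in runs) {
        span <- idx[r$from:r$to]
        flagged <- span[dir[r$from:r$to] == r$dir]
        mean_nom <- mean(nom[s, span])
        type <- if (r$dir < 0) "deletion" else "duplication"
        zyg <- if (type == "duplication") NA_character_
               else if (mean_nom < hom_max) "homozygous"
               else if (mean_nom < het_max) "heterozygous"
               else NA_character_
        calls[[length(calls) + 1L]] <- data.frame(
          sample = rownames(z)[s], gene = g, chrom = panel$chrom[span[1]],
          span_start = min(panel$start[span]), span_end = max(panel$end[span]),
          exon_start = panel$exon_index[span[1]],
          exon_end = panel$exon_index[span[length(span)]],
          n_exons = length(span), call_type = type, zygosity = zyg,
          min_abs_z = min(abs(z[s, flagged])),
          mean_nom = mean_nom, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0)
    return(data.frame(sample = character(), gene = character(),
                      chrom = character(), span_start = numeric(),
                      span_end = numeric(), exon_start = integer(),
                      exon_end = integer(), n_exons = integer(),
                      call_type = character(), zygosity = character(),
                      min_abs_z = numeric(), mean_nom = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# maximal same-direction runs over a +1/0/-1 vector, bridging up to
# max_gap zeros strictly inside a run
merge_runs <- function(dir, max_gap = 0L) {
  runs <- list()
  i <- 1L
  n <- length(dir)
  while (i <= n) {
    if (dir[i] == 0L) { i <- i + 1L; next }
    d <- dir[i]
    last_hit <- i
    j <- i + 1L
    while (j <= n) {
      if (dir[j] == d) { last_hit <- j; j <- j + 1L }
      else if (dir[j] == 0L && (j - last_hit) <= max_gap) j <- j + 1L
      else break
    }
    runs[[length(runs) + 1L]] <- list(from = i, to = last_hit, dir = d)
    i <- last_hit + 1L
  }
  runs
}

#' Run the full depth-based CNV detection on one batch
#'
#' Convenience pipeline: correlation precondition, per-sample
#' normalization, batch statistics, z-scores and segmentation into
#' calls. When the r > `r_min` precondition fails, calling aborts
#' unless `force = TRUE` (then it proceeds with a warning).
#'
#' @param depth samples-by-exons depth matrix.
#' @param panel the matching [target_panel()].
#' @param cutoff bilateral z threshold (default 2.58).
#' @param r_min correlation precondition (default 0.7).
#' @param method mu/sigma estimator passed to [zscores()].
#' @param force proceed despite a failed precondition.
#' @param max_gap_exons passed to [call_cnvs()].
#' @param weighted passed to [normalize_depth()].
#' @return List with `calls`, `z`, `nom`, `stats`, `correlation`.
#' @export
detect_cnvs <- function(depth, panel, cutoff = 2.58, r_min = 0.7,
                        method = c("all", "loo", "masked"), force = FALSE,
                        max_gap_exons = 0L, weighted = TRUE) {
  method <- match.arg(method)
  cc <- check_batch_correlation(depth, r_min)
  if (!cc$pass) {
    if (!force)
      stop("batch depth correlation precondition failed (",
           nrow(cc$failing), " pair(s) with r <= ", r_min,
           "); use force = TRUE to override")
    warning("proceeding despite failed depth-correlation precondition")
  }
  nom <- normalize_depth(depth, panel, weighted = weighted)
  st <- batch_stats(nom)
  z <- zscores(nom, stats_ = st, method = method, cutoff = cutoff)
  calls <- call_cnvs(z, nom, panel, cutoff = cutoff,
                     max_gap_exons = max_gap_exons)
  list(calls = calls, z = z, nom = nom, stats = st, correlation = cc)
}
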