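#' Coverage-threshold fractions over target and flank
#'
#' Computes, from a per-base depth track, the mean depth of the target
#' and flank regions and the fraction of bases covered at or above
#' each threshold (default 1x/4x/20x, the panel's standard QC
#' thresholds). Flank bases are those within `flank_bp` of an exon
#' but outside every target interval; they are reported separately
#' because off-probe capture is systematically shallower. Also
#' returns, per exon, the fraction of its bases covered at >= 1x,
#' which feeds poor-exon flagging.
#'
#' @param track data frame with columns `region` ("target"/"flank"),
#'   `gene`, `exon_index` and `depth` (see [simulate_base_depths()];
#'   missing bases count as depth 0 only if present as rows).
#' @param thresholds integer coverage thresholds (default c(1, 4, 20)).
#' @return List of class `coverage_report`: `mean_depth_target`,
#'   `mean_depth_flank`, `frac_ge`, `frac_ge_flank` (named by
#'   threshold), `per_exon_frac_ge1` (named `GENE_exon<k>`).
#' @export
coverage_fractions <- function(track, thresholds = c(1, 4, 20)) {
  stopifnot(all(c("region", "depth") %in% names(track)),
            length(thresholds) > 0)
  if (any(track$depth < 0)) stop("negative depth in track")
  tgt <- track[track$region == "target", , drop = FALSE]
  flk <- track[track$region == "flank", , drop = FALSE]
  frac_at <- function(d, t) if (length(d)) mean(d >= t) else NA_real_
  frac_ge <- vapply(thresholds, frac_at, numeric(1), d = tgt$depth)
  frac_ge_flank <- vapply(thresholds, frac_at, numeric(1), d = flk$depth)
  names(frac_ge) <- names(frac_ge_flank) <- as.character(thresholds)
  per_exon <- tapply(tgt$depth >= 1,
                     paste0(tgt$gene, "_exon", tgt$exon_index), mean)
  out <- list(
    mean_depth_target = if (nrow(tgt)) mean(tgt$depth) else NA_real_,
    mean_depth_flank = if (nrow(flk)) mean(flk$depth) else NA_real_,
    frac_ge = frac_ge, frac_ge_flank = frac_ge_flank,
    per_exon_frac_ge1 = per_exon[!is.na(per_exon)])
  class(out) <- "coverage_report"
  out
}

#' Flag poorly covered exons
#'
#' An exon is poorly covered when strictly less than `min_frac` of its
#' bases are covered at >= 1x (default 50%): such exons cannot be
#' reliably screened by capture sequencing and are candidates for
#' Sanger complementation.
#'
#' @param report a [coverage_fractions()] report.
#' @param panel the [target_panel()].
#' @param min_frac strict lower bound on the covered fraction.
#' @return The flagged subset of panel rows with a `frac_ge1` column.
#' @export
flag_poor_exons <- function(report, panel, min_frac = 0.5) {
  stopifnot(inherits(report, "coverage_report"))
  ids <- exon_ids(panel)
  frac <- report$per_exon_frac_ge1[ids]
  flagged <- which(!is.na(frac) & frac < min_frac)
  out <- panel[flagged, , drop = FALSE]
  out$frac_ge1 <- unname(frac[flagged])
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Minimal depth-gated variant detector
#'
#' Used only by saturation curves: a planted variant site is callable
#' at a given read subset iff the thinned depth at its position is at
#' least `min_depth` reads (default 4). This is a deliberately simple
#' detectability gate, not a genotype caller.
#'
#' @param track per-base depth track.
#' @param sites data frame with columns `chrom`, `pos`, `type`
#'   ("snv"/"indel").
#' @param min_depth minimum reads for a callable site.
#' @return `sites` with a logical `callable` column.
#' @export
variant_caller_stub <- function(track, sites, min_depth = 4L) {
  key <- paste(track$chrom, track$pos)
  d <- track$depth[match(paste(sites$chrom, sites$pos), key)]
  d[is.na(d)] <- 0
  sites$callable <- d >= min_depth
  sites
}

#' Downsampling saturation analysis
#'
#' Emulates randomly extracting subsets of reads at a range of mean
#' depths: for each retained fraction, the track is binomially
#' thinned, target coverage fractions are recomputed at the given
#' thresholds (default 1x/20x/40x) and the planted variant sites
#' still callable by the depth-gated detector are counted. The curve
#' locates the depth beyond which coverage and variant yield stop
#' improving.
#'
#' @param track full-depth per-base track.
#' @param fractions retained read fractions in (0, 1].
#' @param thresholds coverage thresholds (default c(1, 20, 40)).
#' @param sites optional planted variant sites (chrom, pos, type).
#' @param min_depth callable-site threshold (default 4).
#' @param seed RNG seed; thinning at fraction i uses `seed + i`.
#' @return Data frame, one row per fraction: fraction, mean_depth,
#'   `frac_ge_<t>` columns, n_snv, n_indel.
#' @export
saturation_analysis <- function(track, fractions, thresholds = c(1, 20, 40),
                                sites = NULL, min_depth = 4L, seed = 1L) {
  if (length(fractions) == 0) stop("no fractions given")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  rows <- lapply(seq_along(fractions), function(i) {
    thin <- downsample_track(track, fractions[i], seed = seed + i)
    rep_ <- coverage_fractions(thin, thresholds)
    row <- data.frame(fraction = fractions[i],
                      mean_depth = rep_$mean_depth_target)
    for (t in thresholds)
      row[[paste0("frac_ge_", t)]] <- rep_$frac_ge[[as.character(t)]]
    if (!is.null(sites)) {
      called <- variant_caller_stub(thin, sites, min_depth)
      row$n_snv <- sum(called$callable & called$type == "snv")
      row$n_indel <- sum(called$callable & called$type == "indel")
    } else {
      row$n_snv <- NA_integer_; row$n_indel <- NA_integer_
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$fraction), , drop = FALSE]
}

#' Pairwise reproducibility correlations between samples
#'
#' Pearson correlations over the consensus exon set: `depth_r` from
#' per-exon mean depths, and `coverage_r` from per-exon coverage rates
#' (fraction of exon bases covered at >= 1x) when supplied. High
#' pairwise correlation (r > 0.7) both within and between capture
#' batches indicates a reproducible capture, and is the precondition
#' of the batch z-score CNV statistic.
#'
#' @param depth samples-by-exons mean-depth matrix (may pool batches).
#' @param coverage optional samples-by-exons coverage-rate matrix.
#' @param batch optional per-sample batch labels for the intra/inter
#'   summary.
#' @return List of class `correlation_report`: `labels`, `depth_r`,
#'   `coverage_r`, and `summary` (min/max off-diagonal r, split by
#'   intra-/inter-batch when labels are given).
#' @export
reproducibility_correlations <- function(depth, coverage = NULL,
                                         batch = NULL) {
  stopifnot(is.matrix(depth))
  if (nrow(depth) < 2) stop("need at least 2 samples")
  if (!is.null(coverage))
    stopifnot(identical(dim(coverage), dim(depth)))
  depth_r <- suppressWarnings(stats::cor(t(depth)))
  coverage_r <- if (is.null(coverage)) NULL
                else suppressWarnings(stats::cor(t(coverage)))
  summarize <- function(r) {
    if (is.null(r)) return(NULL)
    ut <- upper.tri(r)
    if (is.null(batch))
      return(data.frame(scope = "all", min_r = min(r[ut]),
                        max_r = max(r[ut])))
    same <- outer(batch, batch, `==`)
    rbind(
      data.frame(scope = "intra", min_r = min(r[ut & same]),
                 max_r = max(r[ut & same])),
      if (any(ut & !same))
        data.frame(scope = "inter", min_r = min(r[ut & !same]),
                   max_r = max(r[ut & !same])))
  }
  out <- list(labels = rownames(depth), depth_r = depth_r,
              coverage_r = coverage_r,
              summary = list(depth = summarize(depth_r),
                             coverage = summarize(coverage_r)))
  class(out) <- "correlation_report"
  out
}
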