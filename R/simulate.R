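#' Configuration for batch depth simulation
#'
#' The simulated batch mimics a pooled capture experiment: every exon
#' has a capture efficiency shared by all samples in the batch (drawn
#' lognormal with log-sd `efficiency_sd_log`, mean 1), and each
#' (sample, exon) depth is drawn negative-binomially around
#' `mean_depth * efficiency * copy_ratio`. The dispersion parameter is
#' the negative-binomial overdispersion alpha (variance
#' `mu + alpha * mu^2`); `dispersion = 0` is the exact noise-free
#' limit. Defaults describe a standard batch: 20 samples pooled per
#' capture at 400-fold mean target depth.
#'
#' @param n_samples number of samples in the batch (>= 3).
#' @param mean_depth mean fold coverage over the target (default 400).
#' @param efficiency_sd_log log-sd of per-exon capture efficiency
#'   (default 0.3).
#' @param dispersion negative-binomial overdispersion alpha; 0.01
#'   gives a coefficient of variation of normalized depth near 10% at
#'   400-fold.
#' @param seed RNG seed.
#' @return List of validated settings.
#' @export
depth_sim_config <- function(n_samples = 20L, mean_depth = 400,
                             efficiency_sd_log = 0.3, dispersion = 0.01,
                             seed = 1L) {
  stopifnot(n_samples >= 3, mean_depth > 0, efficiency_sd_log >= 0,
            dispersion >= 0)
  list(n_samples = as.integer(n_samples), mean_depth = mean_depth,
       efficiency_sd_log = efficiency_sd_log, dispersion = dispersion,
       seed = as.integer(seed))
}

#' Declare an injected copy-number truth
#'
#' @param sample sample index (1-based) within the simulated batch.
#' @param gene gene symbol present in the panel.
#' @param exon_start,exon_end inclusive range of exon ordinals hit.
#' @param copy_ratio expected depth ratio: 0 homozygous deletion, 0.5
#'   heterozygous deletion, 1.5 heterozygous duplication.
#' @return One-row data frame.
#' @export
cnv_truth <- function(sample, gene, exon_start, exon_end, copy_ratio) {
  stopifnot(copy_ratio >= 0, exon_start <= exon_end)
  data.frame(sample = as.integer(sample), gene = as.character(gene),
             exon_start = as.integer(exon_start),
             exon_end = as.integer(exon_end),
             copy_ratio = copy_ratio, stringsAsFactors = FALSE)
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion == 0) return(mu)
  out <- numeric(n)
  pos <- mu > 0
  out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
  out
}

#' Simulate a per-batch exon depth matrix with known CNV truth
#'
#' @param panel a [target_panel()].
#' @param cfg a [depth_sim_config()].
#' @param truths data frame of [cnv_truth()] rows (may be empty/NULL).
#' @param efficiency optional per-exon capture-efficiency vector. The
#'   profile belongs to the probe design, so pass the same vector to
#'   several calls to emulate repeated capture experiments of one
#'   panel; when NULL a profile is drawn from the seed.
#' @return A list with `depth` (samples x exons matrix, batch_id
#'   attribute set), `truths` (echoed), and `efficiency` (the per-exon
#'   profile used).
#' @export
simulate_depth_matrix <- function(panel, cfg, truths = NULL,
                                  efficiency = NULL) {
  stopifnot(nrow(panel) > 0)
  if (is.null(truths))
    truths <- cnv_truth(integer(), character(), integer(), integer(),
                        numeric())[0, ]
  if (nrow(truths) > 0) {
    if (any(truths$sample < 1 | truths$sample > cfg$n_samples))
      stop("truth sample index outside the batch")
    for (i in seq_len(nrow(truths))) {
      idx <- panel$exon_index[panel$gene == truths$gene[i]]
      if (length(idx) == 0 || truths$exon_start[i] < min(idx) ||
          truths$exon_end[i] > max(idx))
        stop("truth exon span outside gene '", truths$gene[i], "'")
    }
  }
  set.seed(cfg$seed)
  E <- nrow(panel)
  eff <- if (!is.null(efficiency)) {
    stopifnot(length(efficiency) == E, all(efficiency > 0))
    efficiency
  } else if (cfg$efficiency_sd_log == 0) rep(1, E)
  else stats::rlnorm(E, meanlog = -cfg$efficiency_sd_log^2 / 2,
                     sdlog = cfg$efficiency_sd_log)
  ratio <- matrix(1, cfg$n_samples, E)
  for (i in seq_len(nrow(truths))) {
    hit <- which(panel$gene == truths$gene[i] &
                 panel$exon_index >= truths$exon_start[i] &
                 panel$exon_index <= truths$exon_end[i])
    ratio[truths$sample[i], hit] <- truths$copy_ratio[i]
  }
  mu <- sweep(ratio, 2, cfg$mean_depth * eff, `*`)
  depth <- matrix(nb_draw(length(mu), as.vector(mu), cfg$dispersion),
                  cfg$n_samples, E)
  rownames(depth) <- sprintf("S%02d", seq_len(cfg$n_samples))
  colnames(depth) <- exon_ids(panel)
  attr(depth, "batch_id") <- paste0("simbatch", cfg$seed)
  list(depth = depth, truths = truths, efficiency = eff)
}

#' Simulate a per-base depth track over a panel
#'
#' Emits one row per base of the target and its flanks. Flank bases
#' (`flank_bp` each side of each exon, target bases excluded) are
#' captured off-probe and get a reduced efficiency,
#' `flank_efficiency` times the exon's. Depths are integer read counts
#' so that the track supports binomial read thinning.
#'
#' @param panel a [target_panel()].
#' @param cfg a [depth_sim_config()].
#' @param flank_efficiency depth ratio of flank to target (default
#'   0.74, i.e. roughly 295 vs 400-fold).
#' @return Data frame with columns chrom, pos (0-based), region
#'   ("target"/"flank"), gene, exon_index, depth.
#' @export
simulate_base_depths <- function(panel, cfg, flank_efficiency = 0.74) {
  stopifnot(nrow(panel) > 0)
  set.seed(cfg$seed + 1L)
  flank <- attr(panel, "flank_bp")
  if (is.null(flank)) flank <- 200L
  E <- nrow(panel)
  eff <- if (cfg$efficiency_sd_log == 0) rep(1, E)
         else stats::rlnorm(E, meanlog = -cfg$efficiency_sd_log^2 / 2,
                            sdlog = cfg$efficiency_sd_log)
  rows <- vector("list", E)
  target_pos <- split(
    unlist(lapply(seq_len(E), function(i) seq(panel$start[i], panel$end[i] - 1))),
    rep(panel$chrom, panel$length))
  for (i in seq_len(E)) {
    tpos <- seq(panel$start[i], panel$end[i] - 1)
    fpos <- c(seq(panel$start[i] - flank, panel$start[i] - 1),
              seq(panel$end[i], panel$end[i] + flank - 1))
    fpos <- fpos[fpos >= 0 & !(fpos %in% target_pos[[panel$chrom[i]]])]
    mu_t <- cfg$mean_depth * eff[i]
    rows[[i]] <- data.frame(
      chrom = panel$chrom[i],
      pos = c(tpos, fpos),
      region = rep(c("target", "flank"), c(length(tpos), length(fpos))),
      gene = panel$gene[i], exon_index = panel$exon_index[i],
      depth = c(round(nb_draw(length(tpos), rep(mu_t, length(tpos)),
                              cfg$dispersion)),
                round(nb_draw(length(fpos),
                              rep(mu_t * flank_efficiency, length(fpos)),
                              cfg$dispersion))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Thin a depth track to a fraction of the reads
#'
#' Binomial thinning per base: each of the `depth` reads covering a
#' base survives independently with probability `fraction`, so the
#' expected depth scales exactly by `fraction`. This emulates randomly
#' extracting a subset of reads without modelling individual reads.
#'
#' @param track a per-base depth track (see [simulate_base_depths()]).
#' @param fraction retained read fraction in (0, 1].
#' @param seed RNG seed.
#' @return The track with thinned depths; `fraction = 1` returns the
#'   input unchanged.
#' @export
downsample_track <- function(track, fraction, seed = 1L) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(track)
  set.seed(seed)
  track$depth <- stats::rbinom(nrow(track), track$depth, fraction)
  track
}

#' Configuration for variant-table simulation
#'
#' Background (non-causal) variants are drawn across the panel genes
#' with the given consequence-class mix; each is constructed to fail
#' at least one interpretation-cascade rule, so that on a simulated
#' cohort the cascade's survivors are exactly the planted diagnoses.
#' Depending on class, a background variant is non-protein-changing,
#' common in a public database (allele frequency above `common_af_lo`),
#' common in the internal control database, or a novel missense called
#' damaging by fewer than two predictors.
#'
#' @param n_background number of background variants.
#' @param class_weights named proportions over the eight consequence
#'   classes (normalized to sum to 1).
#' @param common_af_lo,common_af_hi range of the "common" allele
#'   frequencies given to frequency-violating background variants.
#' @param seed RNG seed.
#' @return List of validated settings.
#' @export
variant_sim_config <- function(n_background = 200L,
                               class_weights = c(
                                 nonsense = 0.02, missense = 0.35,
                                 frameshift_indel = 0.03, inframe_indel = 0.02,
                                 splice_region = 0.08, synonymous = 0.25,
                                 intronic = 0.15, UTR = 0.10),
                               common_af_lo = 0.02, common_af_hi = 0.30,
                               seed = 1L) {
  stopifnot(setequal(names(class_weights), consequence_levels),
            all(class_weights >= 0), sum(class_weights) > 0,
            common_af_lo > 0.01, common_af_hi >= common_af_lo)
  list(n_background = as.integer(n_background),
       class_weights = class_weights / sum(class_weights),
       common_af_lo = common_af_lo, common_af_hi = common_af_hi,
       seed = as.integer(seed))
}

planted_variant <- function(id, sample, gene, class, zygosity, reported,
                            pos) {
  variant_record(
    id = id, sample = sample, gene = gene, consequence = class,
    zygosity = zygosity, pos = pos,
    splice_offset = if (class %in% c("splice_region", "intronic")) 5 else NA,
    af_kg1000 = if (reported) 0.001 else NA,
    reported_pathogenic = reported, novel = !reported,
    sift = if (class == "missense") "damage" else NA,
    polyphen2 = if (class == "missense") "damage" else NA,
    phylop = if (class == "missense") 2.5 else NA)
}

#' Simulate an annotated variant table with a known diagnosis truth set
#'
#' The pathogenic plan lists the diagnoses to plant, one row per
#' patient-gene diagnosis: columns `sample`, `gene`, `mode`
#' (ad/ar/xl), `v1_class`, `v1_zygosity`, `v1_reported` and optional
#' `v2_*` for a second allele (NA when absent). Planted variants are
#' constructed to satisfy every cascade step for their mode: protein
#' changing (splice records within 10 bp of an exon), rare in all
#' databases, and damaging by at least two predictors when novel
#' missense. An `ar` plan needs either one hom variant or two het
#' variants.
#'
#' @param cfg a [variant_sim_config()].
#' @param panel a [target_panel()] providing the gene universe.
#' @param plan data frame of planted diagnoses (may be empty/NULL).
#' @return List with `variants` (full annotated table) and `truth`
#'   (per planted diagnosis: sample, gene, mode, variant ids, and the
#'   confidence group its construction dictates).
#' @export
simulate_variants <- function(cfg, panel, plan = NULL) {
  genes <- unique(panel$gene)
  if (is.null(plan))
    plan <- data.frame(sample = character(), gene = character(),
                       mode = character(), v1_class = character(),
                       v1_zygosity = character(), v1_reported = logical(),
                       v2_class = character(), v2_zygosity = character(),
                       v2_reported = logical(), stringsAsFactors = FALSE)
  if (nrow(plan) > 0) {
    if (!all(plan$gene %in% genes))
      stop("plan gene(s) not in panel: ",
           paste(setdiff(plan$gene, genes), collapse = ", "))
    if (!all(plan$mode %in% c("ad", "ar", "xl")))
      stop("plan mode must be ad, ar or xl")
  }
  set.seed(cfg$seed)
  planted <- list(); truth <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    two <- !is.na(p$v2_class)
    if (p$mode == "ar" && !two && p$v1_zygosity != "hom")
      stop("ar plan with a single allele requires a hom variant (row ", i, ")")
    if (p$mode == "xl" && p$v1_zygosity == "het")
      stop("xl plan requires hemizygous (or hom) genotype (row ", i, ")")
    v1 <- planted_variant(sprintf("plant%d_1", i), p$sample, p$gene,
                          p$v1_class, p$v1_zygosity, isTRUE(p$v1_reported),
                          pos = 1000L * i)
    vs <- v1
    if (two) {
      v2 <- planted_variant(sprintf("plant%d_2", i), p$sample, p$gene,
                            p$v2_class, p$v2_zygosity, isTRUE(p$v2_reported),
                            pos = 1000L * i + 500L)
      vs <- rbind(v1, v2)
    }
    planted[[i]] <- vs
    reported <- vs$reported_pathogenic
    truncating <- vs$consequence %in% c("frameshift_indel", "nonsense",
                                        "inframe_indel")
    group <- if (all(reported)) 1L
             else if (any(!reported & truncating)) 2L else 3L
    truth[[i]] <- data.frame(
      sample = p$sample, gene = p$gene, mode = p$mode,
      variant_ids = paste(vs$id, collapse = ","), group = group,
      stringsAsFactors = FALSE)
  }
  bg <- list()
  if (cfg$n_background > 0) {
    classes <- sample(names(cfg$class_weights), cfg$n_background,
                      replace = TRUE, prob = cfg$class_weights)
    bg_samples <- if (nrow(plan) > 0)
      sample(unique(plan$sample), cfg$n_background, replace = TRUE)
    else rep("S1", cfg$n_background)
    for (j in seq_len(cfg$n_background)) {
      cls <- classes[j]
      common <- stats::runif(1, cfg$common_af_lo, cfg$common_af_hi)
      viol <- if (cls %in% c("synonymous", "UTR", "intronic")) "class"
              else if (cls == "missense") sample(c("af", "benign"), 1)
              else sample(c("af", "internal"), 1)
      bg[[j]] <- variant_record(
        id = sprintf("bg%04d", j), sample = bg_samples[j],
        gene = sample(genes, 1), consequence = cls,
        zygosity = sample(c("het", "hom"), 1, prob = c(0.9, 0.1)),
        pos = 10000L + j,
        splice_offset = switch(cls, intronic = sample(11:50, 1),
                               splice_region = sample(1:10, 1), NA),
        af_kg1000 = if (viol == "af") common else NA,
        af_dbsnp = if (viol == "class") stats::runif(1, 0, 1) else NA,
        internal_af = if (viol == "internal")
          stats::runif(1, 0.05, 0.5) else NA,
        sift = if (cls == "missense" && viol == "benign") "tolerated" else
          if (cls == "missense") "damage" else NA,
        polyphen2 = if (cls == "missense" && viol == "benign")
          "tolerated" else if (cls == "missense") "damage" else NA,
        phylop = if (cls == "missense" && viol == "benign") -0.8 else
          if (cls == "missense") 1.5 else NA,
        reported_pathogenic = FALSE, novel = viol != "af")
      # a common (af-violating) variant is a known polymorphism, not novel;
      # splice_region backgrounds sit within 10 bp so the AF rule must drop them
      if (viol == "af") bg[[j]]$novel <- FALSE
    }
  }
  variants <- do.call(rbind, c(planted, bg))
  if (is.null(variants)) variants <- variant_record("x", genes[1],
    "missense", "het")[0, ]
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(sample = character(), gene = character(),
                           mode = character(), variant_ids = character(),
                           group = integer(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(variants = variants, truth = truth)
}

#' Simulate family genotypes segregating with a diagnosis
#'
#' Produces a Mendelian-consistent nuclear family (father, mother,
#' affected proband, unaffected sib) for the given inheritance mode.
#' For `ar` with two candidate variants, the parents carry one variant
#' each (trans configuration); the unaffected sib never carries the
#' full causal configuration.
#'
#' @param candidates data frame with columns `id` and `zygosity` of
#'   the 1-2 causal variants (proband genotypes).
#' @param mode inheritance mode: "ad", "ar" or "xl".
#' @param seed RNG seed.
#' @return Long data frame: member, relation, sex, affected,
#'   variant_id, copies.
#' @export
simulate_family <- function(candidates, mode = c("ad", "ar", "xl"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(candidates), nrow(candidates) %in% 1:2,
            all(c("id", "zygosity") %in% names(candidates)))
  set.seed(seed)
  ids <- candidates$id
  member <- c("F1", "M1", "P1", "U1")
  relation <- c("father", "mother", "proband", "sib")
  sex <- c("male", "female", "male", sample(c("male", "female"), 1))
  affected <- c(FALSE, FALSE, TRUE, FALSE)
  geno <- matrix(0L, 4, length(ids), dimnames = list(member, ids))
  if (mode == "ar" && length(ids) == 2) {
    geno["F1", 1] <- 1L; geno["M1", 2] <- 1L
    geno["P1", ] <- 1L
    sib_opts <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L))
    geno["U1", ] <- sib_opts[[sample(3, 1)]]
  } else if (mode == "ar") {
    stopifnot(candidates$zygosity[1] == "hom")
    geno[c("F1", "M1"), 1] <- 1L
    geno["P1", 1] <- 2L
    geno["U1", 1] <- sample(0:1, 1)
  } else if (mode == "ad") {
    carrier <- sample(c("F1", "M1"), 1)
    affected[match(carrier, member)] <- TRUE
    geno[carrier, 1] <- 1L
    geno["P1", 1] <- 1L
  } else { # xl: carrier mother, affected hemizygous son
    geno["M1", 1] <- 1L
    geno["P1", 1] <- 1L
    sex[3] <- "male"
    if (sex[4] == "female") geno["U1", 1] <- sample(0:1, 1)
  }
  out <- expand.grid(member = member, variant_id = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$relation <- relation[match(out$member, member)]
  out$sex <- sex[match(out$member, member)]
  out$affected <- affected[match(out$member, member)]
  out$copies <- geno[cbind(out$member, out$variant_id)]
  out[, c("member", "relation", "sex", "affected", "variant_id", "copies")]
}

#' A small synthetic example panel
#'
#' Builds a deterministic multi-gene capture design with synthetic
#' coordinates, covering the gene/exon structure the examples and
#' tests exercise (including a 26-exon CACNA2D4-like gene and a
#' 15-exon TULP1-like gene). Not real genome coordinates.
#'
#' @param genes named integer vector: exon count per gene.
#' @param exon_len exon length in bases (constant).
#' @param gap intergenic/intron spacing in bases.
#' @return A [target_panel()].
#' @export
example_panel <- function(genes = c(CACNA2D4 = 26L, CRX = 4L, TULP1 = 15L,
                                    RDH5 = 5L, NMNAT1 = 5L, USH2A = 20L,
                                    BBS2 = 17L, RPGR = 19L),
                          exon_len = 150L, gap = 1000L) {
  rows <- list()
  pos <- 10000L
  chroms <- paste0("chr", seq_along(genes))
  for (g in seq_along(genes)) {
    n <- genes[g]
    start <- pos + gap * seq_len(n) + exon_len * (seq_len(n) - 1L)
    rows[[g]] <- data.frame(gene = names(genes)[g], exon_index = seq_len(n),
                            chrom = chroms[g], start = start,
                            end = start + exon_len,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  target_panel(df$gene, df$exon_index, df$chrom, df$start, df$end)
}

#' Example gene-to-inheritance-mode table
#'
#' Modes follow the genes' real disease associations: e.g. CRX
#' supports dominant disease, RPGR is X-linked, USH2A/TULP1/RDH5 are
#' recessive.
#'
#' @return Data frame with columns gene and modes (pipe-separated
#'   subset of ad/ar/xl).
#' @export
example_gene_modes <- function() {
  data.frame(
    gene = c("CACNA2D4", "CRX", "TULP1", "RDH5", "NMNAT1", "USH2A",
             "BBS2", "RPGR"),
    modes = c("ar", "ad|ar", "ar", "ar", "ar", "ar", "ar", "xl"),
    stringsAsFactors = FALSE)
}
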