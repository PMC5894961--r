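#' Interpretation cascade, step 1: protein-affecting consequences
#'
#' Keeps the variants that can change the protein or its splicing:
#' nonsense, missense, frameshift and inframe coding indels, plus
#' splice-region/intronic records within 10 bp of an exon boundary
#' (potential canonical splice sites). Synonymous, UTR and deeper
#' intronic variants are dropped.
#'
#' @param variants annotated variant table (see [variant_record()]).
#' @return The surviving subset.
#' @export
step1_consequence <- function(variants) {
  v <- validate_variants(variants)
  coding <- v$consequence %in% c("nonsense", "missense", "frameshift_indel",
                                 "inframe_indel")
  splice <- v$consequence %in% c("splice_region", "intronic") &
    !is.na(v$splice_offset) & abs(v$splice_offset) <= 10
  v[coding | splice, , drop = FALSE]
}

#' Step 2: population allele-frequency filter
#'
#' Drops any variant with an allele frequency strictly greater than
#' `max_af` (default 0.01) in at least one population database (1000
#' Genomes, dbSNP, HapMap): the target diseases are too rare for a
#' causal allele to be that common. An absent frequency means the
#' variant is unobserved in that database and passes.
#'
#' @param variants annotated variant table.
#' @param max_af strict upper bound (default 0.01).
#' @return The surviving subset.
#' @export
step2_population_af <- function(variants, max_af = 0.01) {
  v <- validate_variants(variants)
  af <- cbind(v$af_kg1000, v$af_dbsnp, v$af_hapmap)
  common <- apply(af > max_af, 1, any, na.rm = TRUE)
  v[!common, , drop = FALSE]
}

#' Step 2b: internal control-database filter
#'
#' Drops variants at or above `max_af` (default 0.05) in the internal
#' control database of sequenced normal individuals, removing
#' population-specific polymorphisms the public databases
#' under-represent. Variants absent from the internal database are
#' kept.
#'
#' @param variants annotated variant table.
#' @param max_af frequency at or above which a variant is dropped.
#' @return The surviving subset.
#' @export
step2b_internal_control <- function(variants, max_af = 0.05) {
  v <- validate_variants(variants)
  common <- !is.na(v$internal_af) & v$internal_af >= max_af
  v[!common, , drop = FALSE]
}

predictor_damage_count <- function(v) {
  verdicts <- cbind(v$sift == "damage", v$polyphen2 == "damage",
                    v$mutation_taster == "damage", v$fathmm == "damage",
                    !is.na(v$phylop) & v$phylop > 0)
  verdicts[is.na(verdicts)] <- FALSE
  rowSums(verdicts)
}

#' Step 3: predictor consensus on novel missense variants
#'
#' A novel missense variant is kept only when at least two of the five
#' predictors (SIFT, PolyPhen2, MutationTaster, FATHMM, PhyloP) call
#' it damaging; a PhyloP score strictly greater than 0 counts as
#' damage. All other survivors (truncating, splice, reported variants)
#' pass through untouched. A missing predictor output counts as
#' non-damage.
#'
#' @param variants annotated variant table.
#' @param min_damage consensus threshold (default 2).
#' @return The surviving subset.
#' @export
step3_prediction_consensus <- function(variants, min_damage = 2L) {
  v <- validate_variants(variants)
  applies <- v$novel & v$consequence == "missense"
  keep <- !applies | predictor_damage_count(v) >= min_damage
  v[keep, , drop = FALSE]
}

#' Run the filtering cascade (steps 1, 2, 2b, 3)
#'
#' @param variants annotated variant table.
#' @param max_af public-database threshold (default 0.01).
#' @param internal_max_af internal-database threshold (default 0.05).
#' @return Surviving variants with a `cascade_counts` attribute giving
#'   the count after each step.
#' @export
run_cascade <- function(variants, max_af = 0.01, internal_max_af = 0.05) {
  s1 <- step1_consequence(variants)
  s2 <- step2_population_af(s1, max_af)
  s2b <- step2b_internal_control(s2, internal_max_af)
  s3 <- step3_prediction_consensus(s2b)
  attr(s3, "cascade_counts") <- c(input = nrow(variants), step1 = nrow(s1),
                                  step2 = nrow(s2), step2b = nrow(s2b),
                                  step3 = nrow(s3))
  s3
}

parse_modes <- function(gene_modes) {
  stopifnot(all(c("gene", "modes") %in% names(gene_modes)))
  stats::setNames(strsplit(gene_modes$modes, "|", fixed = TRUE),
                  gene_modes$gene)
}

#' Assign a confidence group to a solved diagnosis
#'
#' Group 1 (highest): every causal variant previously reported
#' pathogenic. Group 2 (middle): at least one novel truncating allele
#' (frameshift, nonsense, or novel coding indel). Group 3 (lower):
#' only novel missense/splice alleles (and any mixed
#' reported-plus-novel-missense configuration the first two
#' definitions do not cover).
#'
#' @param causal data frame of the diagnosis's causal variant records.
#' @return Integer group 1, 2 or 3.
#' @export
assign_confidence_group <- function(causal) {
  if (nrow(causal) == 0) stop("cannot group an unsolved diagnosis")
  truncating <- causal$consequence %in% c("frameshift_indel", "nonsense",
                                          "inframe_indel")
  if (all(causal$reported_pathogenic)) return(1L)
  if (any(!causal$reported_pathogenic & truncating)) return(2L)
  3L
}

diagnosis_row <- function(sample, gene, mode, causal, assumption = "",
                          cnv = FALSE) {
  group <- assign_confidence_group(causal)
  data.frame(sample = sample, gene = gene, mode = mode,
             variant_ids = paste(causal$id, collapse = ","),
             group = group, solved = TRUE, uses_cnv = cnv,
             n_reported = sum(causal$reported_pathogenic),
             assumption = assumption, stringsAsFactors = FALSE)
}

#' Match cascade survivors against gene inheritance modes
#'
#' Per sample and gene: autosomal recessive disease is solved by a
#' homozygous variant or by two heterozygous variants (assumed in
#' trans when no family genotypes resolve the phase; the assumption
#' is recorded); autosomal dominant by at least one variant in a gene
#' with a dominant mode; X-linked by a hemizygous (or homozygous
#' female) variant in an X-linked gene. A single heterozygous variant
#' in a recessive-only gene does not solve the case. When several
#' genes qualify for one sample, all are reported, ranked by
#' confidence group and then by the number of reported-pathogenic
#' alleles.
#'
#' @param variants cascade survivors (any number of samples).
#' @param gene_modes data frame with columns `gene` and `modes`
#'   (pipe-separated subset of ad/ar/xl).
#' @return Data frame of solved diagnoses (possibly empty): sample,
#'   gene, mode, variant_ids, group, solved, uses_cnv, n_reported,
#'   assumption.
#' @export
match_inheritance <- function(variants, gene_modes) {
  v <- validate_variants(variants)
  modes <- parse_modes(gene_modes)
  out <- list()
  for (s in unique(v$sample)) {
    for (g in unique(v$gene[v$sample == s])) {
      vg <- v[v$sample == s & v$gene == g, , drop = FALSE]
      gm <- modes[[g]]
      if (is.null(gm)) next
      hom <- vg[vg$zygosity == "hom", , drop = FALSE]
      het <- vg[vg$zygosity == "het", , drop = FALSE]
      hemi <- vg[vg$zygosity == "hemizygous", , drop = FALSE]
      if ("ar" %in% gm) {
        if (nrow(hom) > 0) {
          out[[length(out) + 1L]] <- diagnosis_row(s, g, "ar", hom[1, ])
        } else if (nrow(het) >= 2) {
          out[[length(out) + 1L]] <- diagnosis_row(
            s, g, "ar", het[1:2, ],
            assumption = "compound het assumed in trans (no family data)")
        }
      }
      if ("ad" %in% gm && nrow(vg[vg$zygosity != "hemizygous", ]) >= 1) {
        cand <- vg[vg$zygosity != "hemizygous", , drop = FALSE]
        out[[length(out) + 1L]] <- diagnosis_row(s, g, "ad", cand[1, ])
      }
      if ("xl" %in% gm && (nrow(hemi) > 0 || nrow(hom) > 0)) {
        cand <- if (nrow(hemi) > 0) hemi[1, ] else hom[1, ]
        out[[length(out) + 1L]] <- diagnosis_row(s, g, "xl", cand)
      }
    }
  }
  if (length(out) == 0)
    return(empty_diagnoses())
  d <- do.call(rbind, out)
  mixed <- d$group == 3 & d$n_reported > 0
  d$assumption[mixed] <- paste0(d$assumption[mixed],
    "; mixed reported + novel missense/splice evidence (group by rule)")
  d <- d[order(d$sample, d$group, -d$n_reported), , drop = FALSE]
  rownames(d) <- NULL
  d
}

empty_diagnoses <- function() {
  data.frame(sample = character(), gene = character(), mode = character(),
             variant_ids = character(), group = integer(), solved = logical(),
             uses_cnv = logical(), n_reported = integer(),
             assumption = character(), stringsAsFactors = FALSE)
}

#' Step 4: copy-number fallback for unsolved samples
#'
#' When the first three stages leave a sample unsolved, its CNV calls
#' over candidate disease genes are consulted. A homozygous deletion
#' in a recessive gene solves the case on its own; a heterozygous
#' deletion can serve as the second allele beside a surviving
#' heterozygous variant in the same recessive gene (compound
#' configuration), or as the single allele of a dominant gene. A
#' deletion allele counts as novel truncating evidence for confidence
#' grouping.
#'
#' @param sample sample identifier.
#' @param variants cascade survivors for that sample.
#' @param cnv_calls CNV call table from [call_cnvs()] (same sample).
#' @param gene_modes gene inheritance-mode table.
#' @return Data frame of solved diagnoses (possibly empty).
#' @export
step4_cnv_fallback <- function(sample, variants, cnv_calls, gene_modes) {
  modes <- parse_modes(gene_modes)
  out <- list()
  calls <- cnv_calls[cnv_calls$sample == sample &
                     cnv_calls$call_type == "deletion", , drop = FALSE]
  v <- validate_variants(variants)
  v <- v[v$sample == sample, , drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    gm <- modes[[cl$gene]]
    if (is.null(gm)) next
    del_id <- sprintf("cnv:%s:del_ex%d_%d", cl$gene, cl$exon_start,
                      cl$exon_end)
    if ("ar" %in% gm && identical(cl$zygosity, "homozygous")) {
      out[[length(out) + 1L]] <- data.frame(
        sample = sample, gene = cl$gene, mode = "ar", variant_ids = del_id,
        group = 2L, solved = TRUE, uses_cnv = TRUE, n_reported = 0L,
        assumption = "homozygous deletion as both alleles",
        stringsAsFactors = FALSE)
    } else if (identical(cl$zygosity, "heterozygous")) {
      het <- v[v$gene == cl$gene & v$zygosity == "het", , drop = FALSE]
      if ("ar" %in% gm && nrow(het) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          sample = sample, gene = cl$gene, mode = "ar",
          variant_ids = paste(het$id[1], del_id, sep = ","),
          group = 2L, solved = TRUE, uses_cnv = TRUE,
          n_reported = sum(het$reported_pathogenic[1]),
          assumption = "het SNV + het deletion assumed in trans",
          stringsAsFactors = FALSE)
      } else if ("ad" %in% gm) {
        out[[length(out) + 1L]] <- data.frame(
          sample = sample, gene = cl$gene, mode = "ad", variant_ids = del_id,
          group = 2L, solved = TRUE, uses_cnv = TRUE, n_reported = 0L,
          assumption = "het deletion in dominant gene",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_diagnoses())
  do.call(rbind, out)
}

#' Interpret a cohort end-to-end
#'
#' Runs the filtering cascade, matches inheritance modes, and for
#' samples left unsolved consults CNV calls (step 4). Returns one row
#' per solved sample-gene diagnosis plus an `unsolved` attribute
#' listing samples with no diagnosis.
#'
#' @param variants full annotated variant table (all samples).
#' @param gene_modes gene inheritance-mode table.
#' @param cnv_calls optional CNV call table.
#' @param max_af,internal_max_af cascade thresholds.
#' @return Diagnoses data frame; attributes `unsolved` (sample ids)
#'   and `cascade_counts`.
#' @export
interpret_cohort <- function(variants, gene_modes, cnv_calls = NULL,
                             max_af = 0.01, internal_max_af = 0.05) {
  surv <- run_cascade(variants, max_af, internal_max_af)
  diag <- match_inheritance(surv, gene_modes)
  samples <- unique(variants$sample)
  if (!is.null(cnv_calls))
    samples <- unique(c(samples, cnv_calls$sample))
  unsolved <- setdiff(samples, diag$sample)
  if (!is.null(cnv_calls) && length(unsolved) > 0) {
    for (s in unsolved) {
      d4 <- step4_cnv_fallback(s, surv, cnv_calls, gene_modes)
      if (nrow(d4) > 0) diag <- rbind(diag, d4)
    }
  }
  rownames(diag) <- NULL
  attr(diag, "unsolved") <- setdiff(samples, diag$sample)
  attr(diag, "cascade_counts") <- attr(surv, "cascade_counts")
  diag
}

#' Check family segregation of a diagnosis
#'
#' Autosomal dominant: every affected member carries at least one
#' causal allele and no unaffected member carries any. Autosomal
#' recessive: affected members carry the full causal configuration
#' (both copies of a homozygous allele, or one copy of each of two
#' variants); unaffected members never do, and with two variants the
#' parental origins must be compatible with a trans configuration
#' (each parent of an affected compound heterozygote carries at least
#' one of the two). X-linked: affected males are hemizygous carriers;
#' unaffected males carry nothing.
#'
#' @param mode inheritance mode ("ad", "ar", "xl").
#' @param causal_ids character vector of 1-2 causal variant ids.
#' @param family long genotype table from [simulate_family()] or the
#'   same schema: member, relation, sex, affected, variant_id, copies.
#' @return TRUE when the family genotypes are consistent with the
#'   diagnosis.
#' @export
check_segregation <- function(mode, causal_ids, family) {
  stopifnot(mode %in% c("ad", "ar", "xl"),
            all(causal_ids %in% family$variant_id))
  fam <- family[family$variant_id %in% causal_ids, , drop = FALSE]
  g <- stats::xtabs(copies ~ member + variant_id, data = fam)
  aff <- tapply(fam$affected, fam$member, `[`, 1)
  sex <- tapply(fam$sex, fam$member, `[`, 1)
  rel <- tapply(fam$relation, fam$member, `[`, 1)
  members <- rownames(g)
  carries_config <- function(m) {
    if (mode == "ar" && length(causal_ids) == 1)
      g[m, causal_ids] >= 2
    else if (mode == "ar")
      all(g[m, causal_ids] >= 1)
    else g[m, causal_ids[1]] >= 1
  }
  for (m in members) {
    if (aff[m] && !carries_config(m)) return(FALSE)
    if (!aff[m]) {
      if (mode == "ad" && any(g[m, causal_ids] > 0)) return(FALSE)
      if (mode == "ar" && carries_config(m)) return(FALSE)
      if (mode == "xl" && sex[m] == "male" && g[m, causal_ids[1]] > 0)
        return(FALSE)
    }
  }
  if (mode == "ar" && length(causal_ids) == 2) {
    parents <- members[rel[members] %in% c("father", "mother")]
    probands <- members[aff[members] & rel[members] == "proband"]
    if (length(parents) == 2 && length(probands) > 0) {
      # trans requires each parent to supply one allele
      for (vid in causal_ids)
        if (all(g[parents, vid] == 0)) return(FALSE)
    }
  }
  TRUE
}
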