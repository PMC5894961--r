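test_that("step 1 keeps protein-changing classes and near-exon splice", {
  v <- rbind(
    variant_record("syn", "G1", "synonymous", "het"),
    variant_record("mis", "G1", "missense", "het"),
    variant_record("non", "G1", "nonsense", "het"),
    variant_record("fs", "G1", "frameshift_indel", "het"),
    variant_record("inf", "G1", "inframe_indel", "het"),
    variant_record("utr", "G1", "UTR", "het"),
    variant_record("spl10", "G1", "splice_region", "het", splice_offset = 10),
    variant_record("int11", "G1", "intronic", "het", splice_offset = 11),
    variant_record("intm10", "G1", "intronic", "het", splice_offset = -10),
    variant_record("int40", "G1", "intronic", "het", splice_offset = 40))
  kept <- step1_consequence(v)
  # rule-by-rule enumeration oracle
  oracle <- v$id[v$consequence %in% c("nonsense", "missense",
                                      "frameshift_indel", "inframe_indel") |
                   (v$consequence %in% c("splice_region", "intronic") &
                      abs(v$splice_offset) <= 10)]
  expect_setequal(kept$id, oracle)
  expect_true(all(c("mis", "non", "fs", "inf", "spl10", "intm10") %in% kept$id))
  expect_false(any(c("syn", "utr", "int11", "int40") %in% kept$id))
})

test_that("step 2 drops variants common in any one public database", {
  v <- rbind(
    variant_record("a", "G", "missense", "het", af_dbsnp = 0.02,
                   novel = FALSE),
    variant_record("b", "G", "missense", "het", af_kg1000 = 0.005,
                   af_dbsnp = 0.005, af_hapmap = 0.005),
    variant_record("c", "G", "missense", "het", af_hapmap = 0.01),
    variant_record("d", "G", "missense", "het"))
  kept <- step2_population_af(v)
  expect_setequal(kept$id, c("b", "c", "d"))  # 0.01 exactly is kept
})

test_that("step 2b applies the internal control threshold at 0.05", {
  v <- rbind(
    variant_record("hi", "G", "missense", "het", internal_af = 0.10),
    variant_record("edge", "G", "missense", "het", internal_af = 0.05),
    variant_record("lo", "G", "missense", "het", internal_af = 0.049),
    variant_record("abs", "G", "missense", "het"))
  expect_setequal(step2b_internal_control(v)$id, c("lo", "abs"))
})

test_that("step 3 needs two damaging predictors on novel missense only", {
  two <- variant_record("two", "G", "missense", "het", sift = "damage",
                        polyphen2 = "damage", phylop = -1)
  one <- variant_record("one", "G", "missense", "het", sift = "damage",
                        phylop = -0.5)
  phy_only <- variant_record("phy", "G", "missense", "het", phylop = 0.3)
  phy_zero <- variant_record("pz", "G", "missense", "het", phylop = 0)
  reported <- variant_record("rep", "G", "missense", "het", novel = FALSE,
                             reported_pathogenic = TRUE)
  truncating <- variant_record("tr", "G", "nonsense", "het")
  v <- rbind(two, one, phy_only, phy_zero, reported, truncating)
  kept <- step3_prediction_consensus(v)
  # PhyloP > 0 counts as one damaging verdict; 0 does not
  expect_setequal(kept$id, c("two", "rep", "tr"))
  expect_false("phy" %in% kept$id)   # 1 damaging predictor only
  # "possibly damaging" vocabulary normalizes to damage at ingest
  poss <- variant_record("poss", "G", "missense", "het",
                         sift = "possibly_damaging",
                         polyphen2 = "probably_damaging")
  expect_equal(nrow(step3_prediction_consensus(poss)), 1)
})

test_that("each cascade step returns a subset of its input", {
  p <- study_panel(3)
  plan <- data.frame(sample = "P1", gene = "USH2A", mode = "ar",
                     v1_class = "nonsense", v1_zygosity = "hom",
                     v1_reported = TRUE, v2_class = NA, v2_zygosity = NA,
                     v2_reported = NA, stringsAsFactors = FALSE)
  sim <- simulate_variants(variant_sim_config(n_background = 300, seed = 5),
                           p, plan)
  s1 <- step1_consequence(sim$variants)
  s2 <- step2_population_af(s1)
  s2b <- step2b_internal_control(s2)
  s3 <- step3_prediction_consensus(s2b)
  expect_true(all(s1$id %in% sim$variants$id))
  expect_true(all(s2$id %in% s1$id))
  expect_true(all(s2b$id %in% s2$id))
  expect_true(all(s3$id %in% s2b$id))
  counts <- attr(run_cascade(sim$variants), "cascade_counts")
  expect_true(all(diff(counts) <= 0))
})

test_that("inheritance matching solves hom, compound het, and xl cases", {
  gm <- example_gene_modes()
  hom <- variant_record("h1", "USH2A", "missense", "hom", sample = "P1",
                        novel = FALSE, reported_pathogenic = TRUE)
  d <- match_inheritance(hom, gm)
  expect_equal(nrow(d), 1)
  expect_equal(d$mode, "ar")
  expect_equal(d$group, 1L)
  # two hets in one ar gene -> compound het, assumption recorded
  ch <- rbind(
    variant_record("c1", "BBS2", "nonsense", "het", sample = "P2",
                   novel = FALSE, reported_pathogenic = TRUE),
    variant_record("c2", "BBS2", "missense", "het", sample = "P2",
                   sift = "damage", polyphen2 = "damage"))
  d2 <- match_inheritance(ch, gm)
  expect_equal(d2$mode, "ar")
  expect_equal(d2$variant_ids, "c1,c2")
  expect_match(d2$assumption, "trans")
  # hemizygous variant in an xl gene
  xl <- variant_record("x1", "RPGR", "frameshift_indel", "hemizygous",
                       sample = "P3")
  d3 <- match_inheritance(xl, gm)
  expect_equal(d3$mode, "xl")
  expect_equal(d3$group, 2L)
})

test_that("a single het in a recessive-only gene stays unsolved", {
  gm <- example_gene_modes()
  v <- variant_record("v1", "USH2A", "nonsense", "het", sample = "P9")
  expect_equal(nrow(match_inheritance(v, gm)), 0)
  # the same variant in a gene with a dominant mode solves as ad
  v2 <- variant_record("v1", "CRX", "nonsense", "het", sample = "P9")
  expect_equal(match_inheritance(v2, gm)$mode, c("ar", "ad")[2])
})

test_that("confidence groups follow the reported/novel-truncating rules", {
  # all reported -> Group 1
  rep2 <- rbind(
    variant_record("r1", "BBS1", "nonsense", "het", novel = FALSE,
                   reported_pathogenic = TRUE),
    variant_record("r2", "BBS1", "missense", "het", novel = FALSE,
                   reported_pathogenic = TRUE))
  expect_equal(assign_confidence_group(rep2), 1L)
  # homozygous novel coding indel (RDH5-type case) -> Group 2
  indel <- variant_record("i1", "RDH5", "inframe_indel", "hom")
  expect_equal(assign_confidence_group(indel), 2L)
  # novel splice + novel missense (NMNAT1-type case) -> Group 3
  g3 <- rbind(
    variant_record("s1", "NMNAT1", "splice_region", "het",
                   splice_offset = 7),
    variant_record("m1", "NMNAT1", "missense", "het", sift = "damage",
                   polyphen2 = "damage"))
  expect_equal(assign_confidence_group(g3), 3L)
  # mixed reported + novel missense falls to Group 3 by the stated rules
  mixed <- rbind(
    variant_record("r1", "BBS2", "nonsense", "het", novel = FALSE,
                   reported_pathogenic = TRUE),
    variant_record("m2", "BBS2", "missense", "het", sift = "damage",
                   polyphen2 = "damage"))
  expect_equal(assign_confidence_group(mixed), 3L)
  expect_error(assign_confidence_group(mixed[0, ]), "unsolved")
})

test_that("every solved diagnosis gets exactly one group", {
  p <- study_panel(3)
  plan <- data.frame(
    sample = paste0("P", 1:4),
    gene = c("USH2A", "BBS2", "RDH5", "NMNAT1"),
    mode = "ar",
    v1_class = c("nonsense", "nonsense", "inframe_indel", "splice_region"),
    v1_zygosity = c("hom", "het", "hom", "het"),
    v1_reported = c(TRUE, TRUE, FALSE, FALSE),
    v2_class = c(NA, "missense", NA, "missense"),
    v2_zygosity = c(NA, "het", NA, "het"),
    v2_reported = c(NA, TRUE, NA, FALSE),
    stringsAsFactors = FALSE)
  sim <- simulate_variants(variant_sim_config(n_background = 100, seed = 3),
                           p, plan)
  d <- interpret_cohort(sim$variants, example_gene_modes())
  expect_true(all(d$group %in% 1:3))
  expect_true(all(table(d$sample) >= 1))
})

test_that("CNV fallback solves deletion-driven cases", {
  gm <- example_gene_modes()
  empty <- variant_record("x", "USH2A", "missense", "het")[0, ]
  hom_del <- data.frame(sample = "P1", gene = "CACNA2D4", chrom = "chr1",
                        span_start = 0, span_end = 1, exon_start = 17L,
                        exon_end = 26L, n_exons = 10L,
                        call_type = "deletion", zygosity = "homozygous",
                        min_abs_z = 4.2, mean_nom = 0.01,
                        stringsAsFactors = FALSE)
  d <- step4_cnv_fallback("P1", empty, hom_del, gm)
  expect_equal(nrow(d), 1)
  expect_equal(d$mode, "ar")
  expect_true(d$uses_cnv)
  expect_equal(d$group, 2L)
  # het deletion + surviving het variant in the same recessive gene
  het_del <- hom_del
  het_del$gene <- "TULP1"; het_del$zygosity <- "heterozygous"
  het_del$exon_start <- 9L; het_del$exon_end <- 13L
  snv <- variant_record("t1", "TULP1", "missense", "het", sample = "P1",
                        sift = "damage", polyphen2 = "damage")
  d2 <- step4_cnv_fallback("P1", snv, het_del, gm)
  expect_equal(nrow(d2), 1)
  expect_match(d2$variant_ids, "t1,cnv:TULP1")
  # het deletion alone in a dominant-capable gene (whole-CRX case)
  crx_del <- hom_del
  crx_del$gene <- "CRX"; crx_del$zygosity <- "heterozygous"
  crx_del$exon_start <- 1L; crx_del$exon_end <- 4L
  d3 <- step4_cnv_fallback("P1", empty, crx_del, gm)
  expect_equal(d3$mode, "ad")
  # nothing at all stays unsolved
  expect_equal(nrow(step4_cnv_fallback("P1", empty, hom_del[0, ], gm)), 0)
})

test_that("interpret_cohort falls back to CNVs only for unsolved samples", {
  p <- study_panel(3)
  plan <- data.frame(sample = "P1", gene = "USH2A", mode = "ar",
                     v1_class = "nonsense", v1_zygosity = "hom",
                     v1_reported = TRUE, v2_class = NA, v2_zygosity = NA,
                     v2_reported = NA, stringsAsFactors = FALSE)
  sim <- simulate_variants(variant_sim_config(n_background = 50, seed = 9),
                           p, plan)
  calls <- data.frame(sample = "P2", gene = "CACNA2D4", chrom = "chr1",
                      span_start = 0, span_end = 1, exon_start = 17L,
                      exon_end = 26L, n_exons = 10L, call_type = "deletion",
                      zygosity = "homozygous", min_abs_z = 4.0,
                      mean_nom = 0.02, stringsAsFactors = FALSE)
  d <- interpret_cohort(sim$variants, example_gene_modes(), cnv_calls = calls)
  expect_setequal(d$sample, c("P1", "P2"))
  expect_false(d$uses_cnv[d$sample == "P1"])
  expect_true(d$uses_cnv[d$sample == "P2"])
  expect_equal(length(attr(d, "unsolved")), 0)
})

test_that("segregation checks accept consistent and reject broken families", {
  fam <- simulate_family(data.frame(id = c("vA", "vB"),
                                    zygosity = c("het", "het")),
                         "ar", seed = 2)
  expect_true(check_segregation("ar", c("vA", "vB"), fam))
  # an unaffected member carrying both candidate hets is inconsistent
  bad <- fam
  bad$copies[bad$member == "U1"] <- 1L
  expect_false(check_segregation("ar", c("vA", "vB"), bad))
  # ad: unaffected carrier breaks segregation
  fam_ad <- simulate_family(data.frame(id = "vC", zygosity = "het"),
                            "ad", seed = 2)
  expect_true(check_segregation("ad", "vC", fam_ad))
  bad_ad <- fam_ad
  bad_ad$copies[bad_ad$member == "U1"] <- 1L
  expect_false(check_segregation("ad", "vC", bad_ad))
  # ar trans check: both alleles from one parent is inconsistent
  cis <- fam
  cis$copies[cis$member == "F1"] <- 1L
  cis$copies[cis$member == "M1"] <- 0L
  expect_false(check_segregation("ar", c("vA", "vB"), cis))
})
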