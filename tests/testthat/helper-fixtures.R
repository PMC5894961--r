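# Fixtures shared across test files; all generated in code.

# tiny 3-gene panel for unit tests
tiny_panel <- function() {
  target_panel(
    gene = c("GENEA", "GENEA", "GENEA", "GENEB", "GENEB", "GENEC"),
    exon_index = c(1L, 2L, 3L, 1L, 2L, 1L),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr3"),
    start = c(100, 400, 900, 100, 500, 100),
    end = c(200, 600, 1000, 300, 650, 220))
}

# study-sized panel: the clinically structured genes plus background
# genes, ~1100 exons so a 10-exon CNV is a realistically small
# fraction of the design
study_panel <- function(n_bg_genes = 50L) {
  core <- c(CACNA2D4 = 26L, CRX = 4L, TULP1 = 15L, RDH5 = 5L,
            NMNAT1 = 5L, USH2A = 20L, BBS2 = 17L, RPGR = 19L)
  if (n_bg_genes > 0)
    core <- c(core, stats::setNames(rep(20L, n_bg_genes),
                                    paste0("BG", seq_len(n_bg_genes))))
  example_panel(genes = core)
}

# brute-force position-by-position mismatch count (N never matches),
# used as the index-filter oracle
hamming_oracle <- function(index, barcode) {
  si <- strsplit(index, "")[[1]]; sb <- strsplit(barcode, "")[[1]]
  sum(si != sb | si == "N")
}

# a valid, cascade-passing variant with overridable fields
passing_variant <- function(id = "v1", gene = "USH2A", zygosity = "het",
                            consequence = "missense", ...) {
  variant_record(id = id, gene = gene, consequence = consequence,
                 zygosity = zygosity,
                 sift = if (consequence == "missense") "damage" else NA,
                 polyphen2 = if (consequence == "missense") "damage" else NA,
                 splice_offset = if (consequence %in%
                   c("splice_region", "intronic")) 5 else NA, ...)
}
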