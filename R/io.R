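#' Filter reads by barcode index
#'
#' Keeps the reads whose fixed-length sample index matches the expected
#' barcode with at most `max_mismatch` mismatching positions (Hamming
#' distance). An `N` in the index never matches and counts as a
#' mismatch. The default of 3 mismatches is the validity threshold
#' applied during demultiplexing surveillance of indexed libraries.
#'
#' @param reads data frame with columns `read_id` and `index_seq`
#'   (equal-length strings over A/C/G/T/N).
#' @param barcode expected index sequence; must match the index length.
#' @param max_mismatch maximum tolerated mismatches (default 3).
#' @return The subset of `reads` identified as valid.
#' @export
filter_reads_by_index <- function(reads, barcode, max_mismatch = 3L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "index_seq") %in% names(reads)))
  if (nrow(reads) == 0) return(reads)
  lens <- nchar(reads$index_seq)
  if (length(unique(lens)) > 1)
    stop("index length is not constant across reads")
  if (nchar(barcode) != lens[1])
    stop("barcode length (", nchar(barcode),
         ") does not equal index length (", lens[1], ")")
  bc <- strsplit(toupper(barcode), "")[[1]]
  dist <- vapply(strsplit(toupper(reads$index_seq), ""), function(s) {
    sum(s != bc | s == "N")
  }, integer(1))
  reads[dist <= max_mismatch, , drop = FALSE]
}

#' Read and write per-batch depth matrices
#'
#' A depth matrix holds the mean sequencing depth (fold coverage) of
#' every sample over every panel exon for one capture batch: rows are
#' samples, columns are exons named `GENE_exon<k>`. The TSV dialect has
#' a `sample` first column and one column per exon; numbers round-trip
#' bit-exactly. Depth matrices are strictly per-batch files: the batch
#' z statistic is only defined among samples captured and sequenced
#' together, so no merge operation across batches is provided.
#'
#' @param path file path.
#' @param panel optional [target_panel()]; when given, the file must
#'   contain a column for every panel exon and columns are returned in
#'   panel order.
#' @return `read_depth_matrix`: a numeric matrix with sample rownames
#'   and exon colnames, plus a `batch_id` attribute when present in the
#'   file's `# batch:` header comment.
#' @export
read_depth_matrix <- function(path, panel = NULL) {
  first <- readLines(path, n = 1L)
  batch_id <- NULL
  if (grepl("^# *batch:", first))
    batch_id <- sub("^# *batch: *", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sample")
    stop("depth matrix must have 'sample' as its first column")
  samples <- as.character(df$sample)
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col) || anyNA(col)) {
      i <- which(is.na(suppressWarnings(as.numeric(col))) | is.na(col))[1]
      stop("non-numeric or missing depth for sample '", samples[i],
           "', exon '", names(body)[j], "'")
    }
  }
  m <- as.matrix(body)
  rownames(m) <- samples
  if (any(m < 0))
    stop("negative depth values in ", path)
  if (!is.null(panel)) {
    ids <- exon_ids(panel)
    missing <- setdiff(ids, colnames(m))
    if (length(missing))
      stop("depth matrix is missing exon column(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    m <- m[, ids, drop = FALSE]
  }
  attr(m, "batch_id") <- batch_id
  m
}

#' @rdname read_depth_matrix
#' @param m numeric samples-by-exons matrix with dimnames.
#' @param batch_id optional batch identifier written as a header comment.
#' @export
write_depth_matrix <- function(m, path, batch_id = attr(m, "batch_id")) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(batch_id))
    writeLines(paste0("# batch: ", batch_id), con)
  writeLines(paste(c("sample", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Map a VCF genotype string to zygosity
#'
#' `0/1`-style heterozygous genotypes map to `"het"`, `1/1`-style to
#' `"hom"`, and a single non-reference allele (haploid GT, as on male X
#' chromosomes) to `"hemizygous"`.
#'
#' @param gt character vector of GT strings (`/` or `|` separated).
#' @return Character vector in `c("het", "hom", "hemizygous")`.
#' @export
zygosity_from_gt <- function(gt) {
  vapply(gt, function(g) {
    alleles <- strsplit(g, "[/|]")[[1]]
    alt <- alleles != "0" & alleles != "."
    if (length(alleles) == 1 && alt) return("hemizygous")
    if (all(alt)) return("hom")
    if (any(alt)) return("het")
    stop("genotype '", g, "' carries no alternate allele")
  }, character(1), USE.NAMES = FALSE)
}

variant_columns <- c(
  "id", "sample", "gene", "chrom", "pos", "ref", "alt", "consequence",
  "splice_offset", "zygosity", "af_kg1000", "af_dbsnp", "af_hapmap",
  "internal_af", "sift", "polyphen2", "mutation_taster", "fathmm",
  "phylop", "reported_pathogenic", "novel")

consequence_levels <- c(
  "nonsense", "missense", "frameshift_indel", "inframe_indel",
  "splice_region", "synonymous", "intronic", "UTR")

normalize_verdict <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("damage", "damaging", "possibly_damaging", "probably_damaging",
             "possible_damage", "deleterious", "disease_causing", "d")] <- "damage"
  x[x %in% c("tolerated", "benign", "neutral", "polymorphism", "t", "n")] <- "tolerated"
  x[!(x %in% c("damage", "tolerated"))] <- NA
  x
}

#' Construct a single annotated variant record
#'
#' Convenience constructor for one row of the annotated variant table
#' that the interpretation cascade consumes. Allele frequencies absent
#' from a database are `NA` (unobserved). Predictor verdicts are
#' normalized to damage/tolerated; PhyloP is kept as a raw score.
#'
#' @param id variant identifier.
#' @param gene gene symbol.
#' @param consequence one of nonsense, missense, frameshift_indel,
#'   inframe_indel, splice_region, synonymous, intronic, UTR.
#' @param zygosity one of het, hom, hemizygous.
#' @param sample sample identifier.
#' @param chrom,pos,ref,alt site coordinates and alleles.
#' @param splice_offset signed distance in bases from the nearest exon
#'   boundary (positive into the intron); required for splice_region
#'   and intronic records.
#' @param af_kg1000,af_dbsnp,af_hapmap population database allele
#'   frequencies, `NA` when unobserved.
#' @param internal_af internal control-database frequency, `NA` when
#'   unobserved.
#' @param sift,polyphen2,mutation_taster,fathmm predictor verdicts.
#' @param phylop PhyloP conservation score.
#' @param reported_pathogenic TRUE when previously reported pathogenic.
#' @param novel TRUE when never reported (implies not
#'   reported_pathogenic).
#' @return One-row data frame with the canonical variant columns.
#' @export
variant_record <- function(id, gene, consequence, zygosity,
                           sample = "S1", chrom = "chr1", pos = 1L,
                           ref = "A", alt = "T", splice_offset = NA_real_,
                           af_kg1000 = NA_real_, af_dbsnp = NA_real_,
                           af_hapmap = NA_real_, internal_af = NA_real_,
                           sift = NA, polyphen2 = NA, mutation_taster = NA,
                           fathmm = NA, phylop = NA_real_,
                           reported_pathogenic = FALSE, novel = TRUE) {
  consequence <- match.arg(consequence, consequence_levels)
  zygosity <- match.arg(zygosity, c("het", "hom", "hemizygous"))
  if (novel && reported_pathogenic)
    stop("a novel variant cannot be reported_pathogenic")
  if (consequence %in% c("splice_region", "intronic") && is.na(splice_offset))
    stop("splice_region/intronic records need a splice_offset")
  df <- data.frame(
    id = id, sample = sample, gene = gene, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, consequence = consequence,
    splice_offset = as.numeric(splice_offset), zygosity = zygosity,
    af_kg1000 = af_kg1000, af_dbsnp = af_dbsnp, af_hapmap = af_hapmap,
    internal_af = internal_af,
    sift = normalize_verdict(sift), polyphen2 = normalize_verdict(polyphen2),
    mutation_taster = normalize_verdict(mutation_taster),
    fathmm = normalize_verdict(fathmm), phylop = as.numeric(phylop),
    reported_pathogenic = reported_pathogenic, novel = novel,
    stringsAsFactors = FALSE)
  validate_variants(df)
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v))
  missing <- setdiff(variant_columns, names(v))
  if (length(missing))
    stop("variant table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(v$consequence), consequence_levels)
  if (length(bad))
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  afs <- c(v$af_kg1000, v$af_dbsnp, v$af_hapmap, v$internal_af)
  if (any(afs < 0 | afs > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  if (any(v$novel & v$reported_pathogenic))
    stop("novel variants cannot be reported_pathogenic")
  v[, variant_columns]
}

#' Read and write annotated variant tables
#'
#' The documented TSV schema has one row per variant call with the
#' columns produced by [variant_record()]. A `gt` column (VCF-style GT
#' string) may stand in for `zygosity` and is mapped via
#' [zygosity_from_gt()]. Verdict vocabulary is normalized at ingest
#' ("possibly_damaging" counts as damage).
#'
#' @param path TSV file path.
#' @return Data frame of validated variant records.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!("zygosity" %in% names(df)) && "gt" %in% names(df))
    df$zygosity <- zygosity_from_gt(df$gt)
  for (col in c("sift", "polyphen2", "mutation_taster", "fathmm"))
    if (col %in% names(df)) df[[col]] <- normalize_verdict(df[[col]])
  for (col in setdiff(variant_columns, names(df))) {
    df[[col]] <- switch(col,
      reported_pathogenic = , novel = NA,
      sample = "S1", chrom = "chr1", ref = "N", alt = "N",
      pos = NA_integer_, NA_real_)
  }
  df$reported_pathogenic <- as.logical(df$reported_pathogenic)
  df$novel <- as.logical(df$novel)
  validate_variants(df)
}

#' @rdname read_variants
#' @param v data frame of variant records.
#' @export
write_variants <- function(v, path) {
  v <- validate_variants(v)
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNV calls to TSV
#'
#' @param calls data frame of calls as returned by [call_cnvs()].
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML keys mirror function arguments (e.g. `flank_bp`, `cutoff`,
#' `r_min`, `max_af`, `internal_max_af`); unknown keys are kept so that
#' callers can namespace their own settings.
#'
#' @param path YAML file.
#' @return Named list of settings merged over the defaults.
#' @export
read_config <- function(path) {
  defaults <- list(flank_bp = 200L, probe_flank_bp = 30L, cutoff = 2.58,
                   r_min = 0.7, max_af = 0.01, internal_max_af = 0.05,
                   max_mismatch = 3L)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  utils::modifyList(defaults, cfg)
}
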