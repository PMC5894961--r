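#' Target capture panel
#'
#' A `target_panel` is a data frame of exon capture regions, one row per
#' exon, ordered by (chrom, start), with columns `gene`, `exon_index`
#' (1-based ordinal within its gene), `chrom`, `start`, `end` and
#' `length`. Coordinates are 0-based half-open (BED convention), so
#' `length == end - start`. The flank width used for off-target QC is
#' carried as the `flank_bp` attribute (default 200 bp each side).
#'
#' @param gene character vector of gene symbols.
#' @param exon_index integer exon ordinal within each gene.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds.
#' @param flank_bp flank width in bases used by QC statistics.
#' @return A `target_panel` data frame sorted by (chrom, start).
#' @export
target_panel <- function(gene, exon_index, chrom, start, end, flank_bp = 200L) {
  df <- data.frame(
    gene = as.character(gene),
    exon_index = as.integer(exon_index),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    bad <- which(df$start >= df$end)
    if (length(bad))
      stop("invalid exon interval (start >= end) at row(s): ",
           paste(bad, collapse = ", "))
    dup <- duplicated(df[, c("gene", "exon_index")])
    if (any(dup))
      stop("duplicate exon_index within gene: ",
           paste(unique(df$gene[dup]), collapse = ", "))
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$length <- df$end - df$start
  attr(df, "flank_bp") <- as.integer(flank_bp)
  class(df) <- c("target_panel", "data.frame")
  df
}

#' Read a target panel from a BED-like file
#'
#' Expects >= 4 whitespace-delimited columns: chrom, start, end, name,
#' where the name encodes the gene and exon ordinal as
#' `GENE_exon<k>` (e.g. `CACNA2D4_exon17`). Coordinates are taken as
#' 0-based half-open. Overlapping exons within a gene are kept as given
#' but reported with a message.
#'
#' @param path path to a BED-like file. Lines starting with `#` or
#'   `track` are skipped.
#' @param flank_bp flank width stored on the panel (default 200).
#' @return A [target_panel()].
#' @export
read_panel <- function(path, flank_bp = 200L) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    return(target_panel(character(), integer(), character(),
                        numeric(), numeric(), flank_bp = flank_bp))
  fields <- strsplit(lines, "[ \t]+")
  n <- vapply(fields, length, integer(1))
  if (any(n < 4))
    stop("malformed BED line (fewer than 4 columns) at line ",
         lineno[which(n < 4)[1]])
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  name <- vapply(fields, `[`, "", 4)
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinate at line ",
         lineno[which(is.na(start) | is.na(end))[1]])
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", lineno[bad[1]])
  m <- regmatches(name, regexec("^(.*)_exon([0-9]+)$", name))
  ok <- vapply(m, length, integer(1)) == 3
  if (any(!ok))
    stop("panel name not of the form GENE_exon<k> at line ",
         lineno[which(!ok)[1]], ": '", name[which(!ok)[1]], "'")
  gene <- vapply(m, `[`, "", 2)
  exon_index <- as.integer(vapply(m, `[`, "", 3))
  panel <- target_panel(gene, exon_index, chrom, start, end,
                        flank_bp = flank_bp)
  ov <- overlapping_exons(panel)
  if (nrow(ov) > 0)
    message("read_panel: ", nrow(ov),
            " overlapping exon pair(s) within a gene kept as given")
  panel
}

overlapping_exons <- function(panel) {
  out <- list()
  for (g in unique(panel$gene)) {
    p <- panel[panel$gene == g, , drop = FALSE]
    if (nrow(p) < 2) next
    for (ch in unique(p$chrom)) {
      q <- p[p$chrom == ch, , drop = FALSE]
      if (nrow(q) < 2) next
      ir <- IRanges::IRanges(start = q$start + 1, end = q$end)
      hits <- IRanges::findOverlaps(ir, ir)
      i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
      sel <- i < j
      if (any(sel))
        out[[length(out) + 1L]] <- data.frame(
          gene = g, exon_a = q$exon_index[i[sel]],
          exon_b = q$exon_index[j[sel]])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(gene = character(), exon_a = integer(), exon_b = integer())
}

#' Total target length after merging overlaps
#'
#' Sum of region lengths with overlapping and duplicate intervals
#' counted once, i.e. the number of distinct genomic bases covered by
#' the panel. Used as the region length `L` in base-resolution
#' confusion matrices.
#'
#' @param panel a [target_panel()].
#' @return Integer number of bases.
#' @export
target_length <- function(panel) {
  if (nrow(panel) == 0) return(0L)
  total <- 0L
  for (ch in unique(panel$chrom)) {
    p <- panel[panel$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1, end = p$end))
    total <- total + sum(IRanges::width(ir))
  }
  as.integer(total)
}

#' Unique exon identifiers for a panel
#'
#' `GENE_exon<k>` labels in panel order; these are the column names of
#' depth matrices tied to the panel.
#'
#' @param panel a [target_panel()].
#' @return Character vector.
#' @export
exon_ids <- function(panel) {
  if (nrow(panel) == 0) return(character())
  paste0(panel$gene, "_exon", panel$exon_index)
}
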