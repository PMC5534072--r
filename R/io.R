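#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Read a gene x sample count matrix from TSV
#'
#' First column holds gene identifiers, header row the sample identifiers.
#' Cells must be non-negative integers; duplicate gene or sample ids are
#' rejected.
#'
#' @param path TSV file path.
#' @return integer matrix with gene row names and sample column names.
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) fail("malformed count table: need gene id column plus samples")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) fail("duplicate gene id in count table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) fail("duplicate sample id in count table")
  storage.mode(m) <- "double"
  if (any(is.na(m))) fail("non-numeric cell in count table")
  if (any(m < 0)) fail("negative count in count table")
  if (any(m != round(m))) fail("non-integer count in count table")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count or abundance matrix as TSV
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param idColumn header of the identifier column.
#' @export
writeCounts <- function(m, path, idColumn = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a metabolite abundance matrix from TSV
#'
#' Same layout as [readCounts()] but cells are non-negative reals.
#'
#' @param path TSV file path.
#' @return numeric matrix, metabolites x samples.
#' @export
readMetabolites <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) fail("duplicate metabolite id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) fail("non-numeric abundance")
  if (any(m < 0)) fail("negative abundance")
  rownames(m) <- ids
  m
}

# generic numeric matrix reader (no sign/integrality constraint); used
# for normalized expression written by the pipeline stages
readNumericMatrix <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) fail("non-numeric cell in matrix")
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated members.
#' Duplicate members within a line are collapsed; an empty file yields an
#' empty list.
#'
#' @param path GMT file path.
#' @return named list of character vectors, in file order.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      fail("GMT line with fewer than 3 fields: ", substr(ln, 1, 40))
    out[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (default the
#'   set name).
#' @export
writeGmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read BED3+/narrowPeak intervals
#'
#' Coordinates on disk are 0-based half-open; the returned `GRanges` uses
#' the usual 1-based closed convention (`start0 + 1`, `end0`), so widths
#' are preserved. Columns beyond the first three are kept as metadata
#' columns `V4`, `V5`, ... (narrowPeak payload).
#'
#' @param path BED/narrowPeak file path.
#' @return `GRanges`, one range per input line.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) fail("BED requires at least 3 columns")
  start0 <- as.numeric(df[[2L]]); end0 <- as.numeric(df[[3L]])
  if (any(is.na(start0)) || any(is.na(end0)))
    fail("non-numeric BED coordinate")
  if (any(start0 < 0)) fail("negative BED coordinate")
  if (any(start0 >= end0)) fail("BED interval with start >= end")
  gr <- GRanges(df[[1L]], IRanges(start0 + 1, end0))
  if (ncol(df) > 3L)
    mcols(gr) <- df[, -(1:3), drop = FALSE]
  gr
}

#' Write intervals as BED (0-based half-open)
#' @param gr a `GRanges`; metadata columns are appended after the first
#'   three BED columns.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  extra <- as.data.frame(mcols(gr))
  if (ncol(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-gene transcription start sites
#'
#' Two dialects. `"tsv"`: columns `gene_id`, `chrom`, `tss`, `strand`
#' with `tss` already a 0-based position. `"gtf-lite"`: GTF gene feature
#' lines (1-based closed coordinates, `gene_id` attribute); the TSS is
#' the 5' end of the gene — `start - 1` (0-based) on the `+` strand and
#' `end - 1` on the `-` strand. Duplicate gene ids keep the first
#' occurrence with a warning.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"gtf-lite"`.
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @export
readTss <- function(path, dialect = c("tsv", "gtf-lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fail("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% colnames(df)))
      fail("TSS TSV requires columns: ", paste(need, collapse = ", "))
    out <- df[, need]
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(parts, function(p) length(p) >= 9L && p[3L] == "gene",
                   logical(1L))
    parts <- parts[keep]
    if (!length(parts)) fail("no gene feature lines in GTF")
    gid <- vapply(parts, function(p) {
      m <- regmatches(p[9L], regexec('gene_id "?([^";]+)"?', p[9L]))[[1L]]
      if (length(m) < 2L) fail("gene feature without gene_id attribute")
      m[2L]
    }, character(1L))
    strand <- vapply(parts, `[[`, character(1L), 7L)
    if (!all(strand %in% c("+", "-")))
      fail("gene feature with missing or invalid strand")
    s <- as.integer(vapply(parts, `[[`, character(1L), 4L))
    e <- as.integer(vapply(parts, `[[`, character(1L), 5L))
    out <- data.frame(gene_id = gid,
                      chrom = vapply(parts, `[[`, character(1L), 1L),
                      tss = ifelse(strand == "+", s - 1L, e - 1L),
                      strand = strand, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene_id)) {
    warning("duplicate gene ids in TSS table; keeping first occurrence")
    out <- out[!duplicated(out$gene_id), ]
  }
  if (!all(out$strand %in% c("+", "-"))) fail("invalid strand in TSS table")
  rownames(out) <- NULL
  out
}

#' Write a TSS table as TSV (0-based positions)
#' @param tss data.frame as returned by [readTss()].
#' @param path output path.
#' @export
writeTss <- function(tss, path) {
  utils::write.table(tss[, c("gene_id", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# TSS table -> width-1 GRanges at the TSS base (1-based internally)
tssAsGRanges <- function(tss) {
  gr <- GRanges(tss$chrom, IRanges(tss$tss + 1L, width = 1L),
                strand = tss$strand)
  names(gr) <- tss$gene_id
  gr
}

#' Read integrated pathway definitions (extended GMT)
#'
#' Two record types share the standard GMT layout, joined on the pathway
#' id in the first field: lines whose second field is `"genes"` list gene
#' members, lines whose second field is `"metabolites"` list metabolite
#' members. A pathway may appear in either or both layers.
#'
#' @param path file path.
#' @return named list; each element a list with `genes` and `metabolites`
#'   character vectors (possibly empty).
#' @export
readPathwayGmt <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) fail("pathway GMT line with fewer than 3 fields")
    id <- parts[1L]; layer <- parts[2L]
    if (!layer %in% c("genes", "metabolites"))
      fail("pathway GMT description field must be 'genes' or 'metabolites'")
    if (is.null(out[[id]]))
      out[[id]] <- list(genes = character(), metabolites = character())
    out[[id]][[layer]] <- unique(c(out[[id]][[layer]], parts[-(1:2)]))
  }
  out
}

#' Write integrated pathway definitions (extended GMT)
#' @param pathways named list as returned by [readPathwayGmt()].
#' @param path output path.
#' @export
writePathwayGmt <- function(pathways, path) {
  lines <- character()
  for (id in names(pathways)) {
    pw <- pathways[[id]]
    if (length(pw$genes))
      lines <- c(lines, paste(c(id, "genes", pw$genes), collapse = "\t"))
    if (length(pw$metabolites))
      lines <- c(lines, paste(c(id, "metabolites", pw$metabolites),
                              collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires columns `sample_id`, `diagnosis` (CTL/SZ/BPD/MDD), `region`
#' (AnCg/DLPFC/nAcc), `age`, `pH`, `PMI`, `PRUA` with `PRUA` in \[0, 1\].
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readSampleTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validateSampleTable(df)
}

validateSampleTable <- function(df) {
  need <- c("sample_id", "diagnosis", "region", "age", "pH", "PMI", "PRUA")
  if (!all(need %in% colnames(df)))
    fail("sample table requires columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) fail("duplicate sample_id")
  if (!all(df$diagnosis %in% c("CTL", "SZ", "BPD", "MDD")))
    fail("diagnosis must be one of CTL, SZ, BPD, MDD")
  if (!all(df$region %in% c("AnCg", "DLPFC", "nAcc")))
    fail("region must be one of AnCg, DLPFC, nAcc")
  if (any(df$PRUA < 0 | df$PRUA > 1)) fail("PRUA must lie in [0, 1]")
  df
}
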