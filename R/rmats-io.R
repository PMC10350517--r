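#' Read an rMATS-style junction-count table
#'
#' Parses the tab-separated junction-count format with columns `ID`,
#' `GeneID`, `IJC_SAMPLE_1`, `SJC_SAMPLE_1`, `IJC_SAMPLE_2`, `SJC_SAMPLE_2`,
#' `IncFormLen`, `SkipFormLen`, where replicate counts are comma-separated
#' within a field.  Extra columns are ignored.  Rows whose count fields are
#' empty, non-numeric, or have inconsistent replicate numbers are skipped
#' with a warning naming the line.
#'
#' @param path path to the TSV.
#' @param conditions labels for the two sample groups (defaults
#'   `"SAMPLE_1"`, `"SAMPLE_2"`).
#' @return a [SpliceEventCounts-class]; samples are named
#'   `<condition>_rep<i>`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c(paste("ID", "GeneID", "IJC_SAMPLE_1", "SJC_SAMPLE_1",
#'                    "IJC_SAMPLE_2", "SJC_SAMPLE_2", "IncFormLen",
#'                    "SkipFormLen", sep = "\t"),
#'              paste("1", "GeneX", "10,20", "5,5", "30,10", "2,3",
#'                    "150", "75", sep = "\t")), f)
#' readRmatsTable(f)
#' @export
readRmatsTable <- function(path, conditions = c("SAMPLE_1", "SAMPLE_2")) {
  stopIf(!file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("ID", "GeneID", "IJC_SAMPLE_1", "SJC_SAMPLE_1",
            "IJC_SAMPLE_2", "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen")
  missing <- setdiff(need, colnames(raw))
  stopIf(length(missing) > 0, "missing required column(s): %s",
         paste(missing, collapse = ", "))
  parseCounts <- function(field) {
    parts <- strsplit(field, ",", fixed = TRUE)
    lapply(parts, function(p) suppressWarnings(as.integer(trimws(p))))
  }
  i1 <- parseCounts(raw$IJC_SAMPLE_1); s1 <- parseCounts(raw$SJC_SAMPLE_1)
  i2 <- parseCounts(raw$IJC_SAMPLE_2); s2 <- parseCounts(raw$SJC_SAMPLE_2)
  lI <- suppressWarnings(as.numeric(raw$IncFormLen))
  lS <- suppressWarnings(as.numeric(raw$SkipFormLen))
  bad <- vapply(seq_len(nrow(raw)), function(k) {
    anyNA(i1[[k]]) || anyNA(s1[[k]]) || anyNA(i2[[k]]) || anyNA(s2[[k]]) ||
      !length(i1[[k]]) || !length(i2[[k]]) ||
      length(i1[[k]]) != length(s1[[k]]) ||
      length(i2[[k]]) != length(s2[[k]]) ||
      is.na(lI[k]) || is.na(lS[k])
  }, logical(1))
  if (any(bad))
    warning(sprintf("skipped %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
  keep <- which(!bad)
  stopIf(!length(keep), "no well-formed rows in %s", path)
  n1 <- length(i1[[keep[1]]]); n2 <- length(i2[[keep[1]]])
  consistent <- vapply(keep, function(k)
    length(i1[[k]]) == n1 && length(i2[[k]]) == n2, logical(1))
  if (!all(consistent)) {
    warning(sprintf("skipped %d row(s) with inconsistent replicate counts",
                    sum(!consistent)))
    keep <- keep[consistent]
  }
  inc <- t(vapply(keep, function(k) c(i1[[k]], i2[[k]]), integer(n1 + n2)))
  skp <- t(vapply(keep, function(k) c(s1[[k]], s2[[k]]), integer(n1 + n2)))
  rownames(inc) <- rownames(skp) <- raw$ID[keep]
  colnames(inc) <- colnames(skp) <-
    c(sprintf("%s_rep%d", conditions[1], seq_len(n1)),
      sprintf("%s_rep%d", conditions[2], seq_len(n2)))
  SpliceEventCounts(inc, skp, geneId = raw$GeneID[keep],
                    incFormLen = lI[keep], skipFormLen = lS[keep],
                    condition = rep(conditions, c(n1, n2)))
}

#' Write a SpliceEventCounts object as an rMATS-style table
#'
#' Inverse of [readRmatsTable()]: the first condition's samples become
#' `*_SAMPLE_1` fields and the second's `*_SAMPLE_2`, replicate counts
#' comma-separated.  A round trip preserves counts exactly.
#'
#' @param counts a [SpliceEventCounts-class] with exactly two conditions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRmatsTable <- function(counts, path) {
  conds <- as.character(colData(counts)$condition)
  u <- unique(conds)
  stopIf(length(u) != 2L, "rMATS layout needs exactly two conditions")
  inc <- inclusionCounts(counts); skp <- skippingCounts(counts)
  join <- function(m, idx) apply(m[, idx, drop = FALSE], 1, paste,
                                 collapse = ",")
  g1 <- which(conds == u[1]); g2 <- which(conds == u[2])
  rd <- rowData(counts)
  out <- data.frame(
    ID = rownames(counts), GeneID = rd$GeneID,
    IJC_SAMPLE_1 = join(inc, g1), SJC_SAMPLE_1 = join(skp, g1),
    IJC_SAMPLE_2 = join(inc, g2), SJC_SAMPLE_2 = join(skp, g2),
    IncFormLen = rd$IncFormLen, SkipFormLen = rd$SkipFormLen,
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a gene x sample expression TSV
#'
#' The layout is one `gene_id` column followed by one numeric column per
#' sample.
#'
#' @param path TSV path.
#' @param mat numeric gene x sample matrix with dimnames.
#' @return `readExprTable` returns the matrix; `writeExprTable` returns
#'   `path` invisibly.
#' @export
readExprTable <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  stopIf(colnames(tab)[1] != "gene_id", "first column must be gene_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  stopIf(!is.numeric(m) || anyNA(m), "expression values must be numeric")
  m
}

#' @rdname readExprTable
#' @export
writeExprTable <- function(mat, path) {
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
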