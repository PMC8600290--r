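# Readers and writers for every table the pipeline touches. All files are
# plain text: TSV for matrices and result tables, CSV for genotypes, maps,
# metadata and weather. Readers validate the type invariants and name the
# offending row/column in error messages; reader/writer pairs are exact
# inverses on valid data.

.schemaStop <- function(file, what) {
  stop(sprintf("schema error in '%s': %s", file, what), call. = FALSE)
}

#' Read / write a gene-level count matrix
#'
#' TSV with a header row of sample ids and gene ids in the first column
#' (named \code{gene_id}). Counts must be non-negative integers.
#'
#' @param path file path.
#' @return integer matrix genes x samples with dimnames.
#' @export
readCounts <- function(path) {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character"),
    error = function(e) .schemaStop(path, conditionMessage(e)))
  if (ncol(df) < 1) .schemaStop(path, "no columns")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    .schemaStop(path, paste("duplicate gene id:", genes[duplicated(genes)][1]))
  if (anyDuplicated(colnames(df)[-1]))
    .schemaStop(path, "duplicate sample id in header")
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    .schemaStop(path, sprintf("malformed number at row %d (gene %s), column %s",
                              bad[1, 1], genes[bad[1, 1]],
                              colnames(mat)[bad[1, 2]]))
  if (anyNA(num)) .schemaStop(path, "missing value in count matrix")
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    .schemaStop(path, sprintf("negative count at gene %s, sample %s",
                              genes[bad[1]], colnames(mat)[bad[2]]))
  }
  if (any(num != round(num))) {
    bad <- which(num != round(num), arr.ind = TRUE)[1, ]
    .schemaStop(path, sprintf("non-integer count at gene %s, sample %s",
                              genes[bad[1]], colnames(mat)[bad[2]]))
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(genes, colnames(mat))
  num
}

#' @rdname readCounts
#' @param counts integer matrix genes x samples.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' CSV with columns \code{sample_id}, \code{line_id}, \code{transplant_set},
#' \code{sowing_date} (ISO date), \code{sampling_time} (ISO-8601 timestamp)
#' and optionally \code{site_id}.
#'
#' @param path file path.
#' @return data.frame with parsed POSIXct time columns.
#' @export
readSampleMeta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "line_id", "transplant_set", "sowing_date",
            "sampling_time")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .schemaStop(path, paste("missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    .schemaStop(path, "duplicate sample_id")
  df$sowing_date <- .parseTime(df$sowing_date)
  df$sampling_time <- .parseTime(df$sampling_time)
  if (any(df$sampling_time <= df$sowing_date))
    .schemaStop(path, sprintf("sampling_time not after sowing_date for sample %s",
                              df$sample_id[df$sampling_time <= df$sowing_date][1]))
  if (!"site_id" %in% names(df)) df$site_id <- "site1"
  df
}

#' @rdname readSampleMeta
#' @param meta data.frame as returned by \code{readSampleMeta}.
#' @export
writeSampleMeta <- function(meta, path) {
  out <- meta
  out$sowing_date <- .formatTime(out$sowing_date)
  out$sampling_time <- .formatTime(out$sampling_time)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genotype panel
#'
#' The allele table is a CSV of lines x markers with cells "P1"/"P2" and a
#' first column \code{line_id}; the marker map is a CSV with columns
#' \code{marker}, \code{chrom}, \code{pos_bp}. Markers are sorted by
#' (chrom, pos_bp) on reading; the background of every line is inferred as
#' its majority allele, its type as parent (uniform), cssl (single contiguous
#' donor run) or bil (several runs).
#'
#' @param pathAlleles allele CSV path.
#' @param pathMap marker map CSV path.
#' @param pathHeading optional CSV with columns line_id, transplant_set,
#'   heading_days.
#' @return a \linkS4class{GenotypePanel}.
#' @export
readGenotypes <- function(pathAlleles, pathMap, pathHeading = NULL) {
  al <- read.csv(pathAlleles, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(al)[1] != "line_id")
    .schemaStop(pathAlleles, "first column must be line_id")
  lines <- al$line_id
  if (anyDuplicated(lines)) .schemaStop(pathAlleles, "duplicate line_id")
  mat <- as.matrix(al[, -1, drop = FALSE])
  bad <- which(!mat %in% c("P1", "P2"))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(mat))
    .schemaStop(pathAlleles,
                sprintf("allele '%s' outside {P1,P2} at line %s, marker %s",
                        mat[bad[1]], lines[idx[1]], colnames(mat)[idx[2]]))
  }
  rownames(mat) <- lines
  mp <- read.csv(pathMap, stringsAsFactors = FALSE)
  if (!all(c("marker", "chrom", "pos_bp") %in% names(mp)))
    .schemaStop(pathMap, "need columns marker, chrom, pos_bp")
  miss <- setdiff(colnames(mat), mp$marker)
  if (length(miss))
    .schemaStop(pathMap, paste("marker(s) in alleles missing from map:",
                               paste(miss, collapse = ", ")))
  mp <- mp[mp$marker %in% colnames(mat), , drop = FALSE]
  mp <- mp[order(mp$chrom, mp$pos_bp), , drop = FALSE]
  rownames(mp) <- NULL
  mat <- mat[, mp$marker, drop = FALSE]
  heading <- if (is.null(pathHeading)) {
    data.frame(line_id = character(0), transplant_set = integer(0),
               heading_days = numeric(0))
  } else {
    hd <- read.csv(pathHeading, stringsAsFactors = FALSE)
    if (any(hd$heading_days <= 0))
      .schemaStop(pathHeading, "heading_days must be positive")
    hd
  }
  GenotypePanel(mat, mp, headingDays = heading)
}

#' Construct a GenotypePanel from in-memory tables
#'
#' @param alleles character matrix lines x markers with entries "P1"/"P2".
#' @param markerMap data.frame(marker, chrom, pos_bp); reordered internally.
#' @param headingDays data.frame(line_id, transplant_set, heading_days).
#' @return a validated \linkS4class{GenotypePanel}.
#' @export
GenotypePanel <- function(alleles, markerMap,
                          headingDays = data.frame(line_id = character(0),
                                                   transplant_set = integer(0),
                                                   heading_days = numeric(0))) {
  markerMap <- markerMap[order(markerMap$chrom, markerMap$pos_bp), , drop = FALSE]
  rownames(markerMap) <- NULL
  alleles <- alleles[, markerMap$marker, drop = FALSE]
  bg <- apply(alleles, 1, function(a) {
    if (sum(a == "P1") >= sum(a == "P2")) "P1" else "P2"
  })
  nRuns <- apply(alleles, 1, function(a) {
    r <- rle(a)
    sum(r$values != names(which.max(table(a))))
  })
  type <- ifelse(apply(alleles, 1, function(a) length(unique(a)) == 1L),
                 "parent", ifelse(nRuns <= 1L, "cssl", "bil"))
  new("GenotypePanel", alleles = alleles, markerMap = markerMap,
      background = bg, lineType = setNames(type, rownames(alleles)),
      headingDays = headingDays)
}

#' @rdname readGenotypes
#' @param panel a GenotypePanel.
#' @param dir output directory; writes alleles.csv, marker_map.csv,
#'   heading_days.csv.
#' @export
writeGenotypes <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  al <- data.frame(line_id = lineIds(panel), alleles(panel),
                   check.names = FALSE)
  write.table(al, file.path(dir, "alleles.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(markerMap(panel), file.path(dir, "marker_map.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(headingDays(panel), file.path(dir, "heading_days.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read / write a weather series
#'
#' CSV with columns \code{time} (ISO-8601), \code{temperature} (degC) and
#' \code{radiation} (kJ m-2 min-1).
#'
#' @param path file path.
#' @return a \linkS4class{MeteoSeries}.
#' @export
readMeteo <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "temperature", "radiation")
  if (!all(need %in% names(df)))
    .schemaStop(path, "need columns time, temperature, radiation")
  MeteoSeries(.parseTime(df$time), df$temperature, df$radiation)
}

#' @rdname readMeteo
#' @param meteo a MeteoSeries.
#' @export
writeMeteo <- function(meteo, path) {
  df <- data.frame(time = .formatTime(timestamps(meteo)),
                   temperature = temperature(meteo),
                   radiation = radiation(meteo))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a MeteoSeries
#' @param time POSIXct timestamps, strictly increasing.
#' @param temperature,radiation numeric series of matching length.
#' @export
MeteoSeries <- function(time, temperature, radiation) {
  new("MeteoSeries", time = time, temperature = as.numeric(temperature),
      radiation = as.numeric(radiation))
}

#' Read / write gene positions
#'
#' CSV with columns \code{gene_id}, \code{chrom}, \code{pos_bp}.
#' @param path file path.
#' @return data.frame(gene_id, chrom, pos_bp).
#' @export
readGenePositions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "pos_bp") %in% names(df)))
    .schemaStop(path, "need columns gene_id, chrom, pos_bp")
  if (any(df$pos_bp <= 0)) .schemaStop(path, "positions must be positive")
  if (anyDuplicated(df$gene_id)) .schemaStop(path, "duplicate gene_id")
  df
}

#' @rdname readGenePositions
#' @param positions data.frame(gene_id, chrom, pos_bp).
#' @export
writeGenePositions <- function(positions, path) {
  write.table(positions, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an eQTL call table
#'
#' TSV with columns gene, marker_block, representative_marker, chrom,
#' pos_span, statistic, p, q, cis_trans, n_markers_in_block, selected.
#' Rows are ordered deterministically by gene id, then chrom and position.
#'
#' @param calls data.frame as returned by \code{\link{callEqtls}}.
#' @param path output path.
#' @export
writeEqtlCalls <- function(calls, path) {
  cols <- c("gene", "marker_block", "representative_marker", "chrom",
            "pos_span", "statistic", "p", "q", "cis_trans",
            "n_markers_in_block", "selected")
  if (nrow(calls) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    out <- calls[order(calls$gene, calls$chrom, calls$pos_start), cols]
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to '", path, "': ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEqtlCalls
#' @export
readEqtlCalls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    span <- do.call(rbind, strsplit(as.character(df$pos_span), "-", fixed = TRUE))
    df$pos_start <- as.numeric(span[, 1])
    df$pos_end <- as.numeric(span[, 2])
  } else {
    df$pos_start <- numeric(0); df$pos_end <- numeric(0)
  }
  df
}
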