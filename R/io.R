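#' @include AllClasses.R
NULL

## MatrixMarket indices are 1-based on disk (per the standard); everything
## in memory is addressed by identifier, never by raw index.

#' Read a 10x-style MatrixMarket count matrix with sidecar tables
#'
#' @param matrixPath path to the .mtx triplet file.
#' @param featuresPath path to the features table (1--3 tab-separated
#'   columns; the first is the gene identifier).
#' @param barcodesPath path to the barcodes file (one cell id per line).
#' @return A sparse \code{dgCMatrix} of non-negative integer counts with
#'   gene rownames and cell colnames.
#' @examples
#' \dontrun{counts <- readMtxTriplet("matrix.mtx", "features.tsv",
#'                                   "barcodes.tsv")}
#' @export
readMtxTriplet <- function(matrixPath, featuresPath, barcodesPath) {
  for (p in c(matrixPath, featuresPath, barcodesPath))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrixPath)
  feats <- utils::read.delim(featuresPath, header = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(feats) < 1L || ncol(feats) > 3L)
    stop("features file must have 1-3 columns, got ", ncol(feats))
  genes <- as.character(feats[[1L]])
  cells <- readLines(barcodesPath)
  cells <- cells[nzchar(cells)]
  if (length(genes) != nrow(m))
    stop("dimension mismatch: ", nrow(m), " matrix rows but ",
         length(genes), " features")
  if (length(cells) != ncol(m))
    stop("dimension mismatch: ", ncol(m), " matrix columns but ",
         length(cells), " barcodes")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in features")
  if (anyDuplicated(cells)) stop("duplicate cell identifiers in barcodes")
  v <- m@x
  if (any(v < 0)) stop("negative entries are not valid counts")
  if (any(v != round(v))) stop("non-integer entries are not valid counts")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a count matrix as MatrixMarket triplet plus sidecars
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} (gene ids) and
#' \code{barcodes.tsv} (cell ids) into \code{dir}. Round-trips losslessly
#' through [readMtxTriplet()].
#'
#' @param counts genes x cells matrix of non-negative integer counts with
#'   dimnames.
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
writeMtxTriplet <- function(counts, dir) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"), paths[1L])
  writeLines(rownames(counts), paths[2L])
  writeLines(colnames(counts), paths[3L])
  invisible(paths)
}

#' Write a simulated experiment to disk
#'
#' Emits one 10x-style directory per sample (matrix.mtx + features.tsv +
#' barcodes.tsv), a \code{truth.tsv} ground-truth table and a
#' \code{genes.tsv} annotation table.
#'
#' @param sce a \linkS4class{SingleCellExperiment} from
#'   [simulateExperiment()].
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
writeSimulation <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- assay(sce, "counts")
  for (s in unique(sce$sample_id))
    writeMtxTriplet(counts[, sce$sample_id == s, drop = FALSE],
                    file.path(dir, s))
  utils::write.table(simTruth(sce), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeGeneAnnotation(geneAnnotation(sce), file.path(dir, "genes.tsv"))
  invisible(dir)
}

## ---------------------------------------------------------------------------
## GMT
## ---------------------------------------------------------------------------

#' Read gene signatures from a GMT file
#'
#' Each non-empty line is \code{name<TAB>description<TAB>gene1<TAB>...}.
#' Duplicate genes within a line are removed with a warning.
#'
#' @param path path to a GMT file.
#' @return A named list of [GeneSignature-class] objects (possibly empty).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  sigs <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    sigs[[fields[1L]]] <- geneSignature(fields[1L], fields[-(1:2)],
                                        description = fields[2L])
  }
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures a list of [GeneSignature-class] objects.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    stopifnot(is(s, "GeneSignature"))
    paste(c(s@name, s@description, s@genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## TSV tables
## ---------------------------------------------------------------------------

.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

#' Read a gene-annotation table
#'
#' Expects a TSV with header columns \code{gene_id}, \code{chromosome},
#' \code{start} (0-based or any coordinate system; only relative order per
#' chromosome matters downstream).
#'
#' @param path path to the TSV.
#' @return data.frame with one validated row per gene.
#' @export
readGeneAnnotation <- function(path) {
  df <- .readTsv(path, c("gene_id", "chromosome", "start"))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
  if (any(df$start < 0)) stop("negative start coordinates in ", path)
  df
}

#' Write a gene-annotation table
#' @param annotation data.frame with \code{gene_id}, \code{chromosome},
#'   \code{start}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a centroid model table
#'
#' Expects a TSV whose first column (\code{gene_id}) holds gene ids and
#' whose remaining columns are one subtype each.
#'
#' @param path path to the TSV.
#' @return A [CentroidModel-class].
#' @export
readCentroidModel <- function(path) {
  df <- .readTsv(path, "gene_id")
  if (ncol(df) < 3L) stop("a centroid table needs >= 2 subtype columns")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  centroidModel(m)
}

#' Write a centroid model table
#' @param model a [CentroidModel-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeCentroidModel <- function(model, path) {
  m <- centroidMatrix(model)
  utils::write.table(
    data.frame(gene_id = rownames(m), m, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mouse-to-human ortholog table
#'
#' Expects a TSV with columns \code{source_symbol} and \code{target_symbol}
#' (one row per ortholog pair). A \code{mapping_class} column
#' (one-to-one / one-to-many / many-to-one) is derived from the pair
#' structure if absent.
#'
#' @param path path to the TSV.
#' @return data.frame with \code{source_symbol}, \code{target_symbol},
#'   \code{mapping_class}.
#' @export
readOrthologTable <- function(path) {
  df <- .readTsv(path, c("source_symbol", "target_symbol"))
  if (anyDuplicated(df[, c("source_symbol", "target_symbol")]))
    stop("duplicate (source, target) ortholog pairs in ", path)
  if (!"mapping_class" %in% colnames(df)) {
    srcN <- unname(table(df$source_symbol)[df$source_symbol])
    tgtN <- unname(table(df$target_symbol)[df$target_symbol])
    df$mapping_class <- as.character(
      ifelse(srcN > 1L, "one-to-many",
             ifelse(tgtN > 1L, "many-to-one", "one-to-one")))
  }
  df
}

#' Read a bulk expression count table
#'
#' Expects a TSV whose first column (\code{gene_id}) holds gene ids and
#' whose remaining columns are one sample each, with non-negative integer
#' counts.
#'
#' @param path path to the TSV.
#' @return genes x samples integer matrix with dimnames.
#' @export
readBulkCounts <- function(path) {
  df <- .readTsv(path, "gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (any(m < 0) || any(m != round(m)))
    stop("bulk counts must be non-negative integers")
  rownames(m) <- df$gene_id
  m
}

#' Write a bulk expression count table
#' @param counts genes x samples matrix with dimnames.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBulkCounts <- function(counts, path) {
  utils::write.table(
    data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
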