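#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d (need name, description, >=1 gene)", i)
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character gene vectors.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stopf("sets must be named")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a spot dataset (plus optional ground truth) as a fixture directory
#'
#' Emits MatrixMarket counts, spot/gene TSV metadata, GMT signatures and JSON
#' ground truth, plus a manifest with md5 checksums. Round-trips losslessly
#' through [read_fixture()].
#'
#' @param dataset a `spot_dataset`.
#' @param directory destination directory (created if needed).
#' @param truth optional `ground_truth` to serialize alongside.
#' @param config optional configuration list to serialize.
#' @return data.frame manifest (file, md5), invisibly written to manifest.json.
#' @export
write_fixture <- function(dataset, directory, truth = NULL, config = NULL) {
  stopifnot(inherits(dataset, "spot_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory %s", directory)
  mtx <- file.path(directory, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE), mtx)
  ids <- rownames(dataset$counts) %||% character(0)
  spots <- data.frame(spot_id = ids,
                      x = dataset$coords$x, y = dataset$coords$y,
                      patient_id = unname(dataset$patient_id[ids]) %||% character(0),
                      stringsAsFactors = FALSE)
  write.table(spots, file.path(directory, "spots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(dataset$genes, file.path(directory, "genes.tsv"))
  files <- c("counts.mtx", "spots.tsv", "genes.tsv")
  if (!is.null(truth)) {
    sigs <- truth$planted_signatures
    if (!is.null(sigs) && length(sigs))
      write_gmt(sigs, file.path(directory, "signatures.gmt"))
    tr <- truth; class(tr) <- NULL
    tr$spot_mixture <- as.data.frame(tr$spot_mixture)
    jsonlite::write_json(tr, file.path(directory, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, if (!is.null(sigs) && length(sigs)) "signatures.gmt", "truth.json")
  }
  if (!is.null(config)) {
    cf <- config; class(cf) <- NULL
    jsonlite::write_json(cf, file.path(directory, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "config.json")
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(directory, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a spot-dataset fixture directory written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return a `spot_dataset`.
#' @export
read_fixture <- function(directory) {
  need <- file.path(directory, c("counts.mtx", "spots.tsv", "genes.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stopf("fixture incomplete, missing: %s",
                          paste(basename(miss), collapse = ", "))
  counts <- as.matrix(Matrix::readMM(need[1]))
  spots <- read.delim(need[2], stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("spot_id", "x", "y", "patient_id"))
    if (!col %in% names(spots)) stopf("spots.tsv lacks column '%s'", col)
  genes <- readLines(need[3], warn = FALSE)
  if (nrow(counts) != nrow(spots))
    stopf("counts.mtx has %d rows but spots.tsv %d", nrow(counts), nrow(spots))
  if (ncol(counts) != length(genes))
    stopf("counts.mtx has %d columns but genes.tsv %d", ncol(counts), length(genes))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(spots$spot_id, genes)
  structure(list(
    counts = counts,
    coords = data.frame(spot_id = spots$spot_id, x = spots$x, y = spots$y,
                        stringsAsFactors = FALSE),
    patient_id = setNames(spots$patient_id, spots$spot_id),
    genes = genes,
    qc_flags = data.frame(spot_id = spots$spot_id,
                          pass = rep(TRUE, nrow(spots)),
                          reason = rep("", nrow(spots)),
                          stringsAsFactors = FALSE)
  ), class = "spot_dataset")
}

#' Read a segmented-cell intensity table (cells.csv schema)
#' @param path CSV with columns cell_id, marker columns, region_grade, patient_id.
#' @return a `cell_table` data.frame.
#' @export
read_cell_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("cell_id", "region_grade", "patient_id"))
    if (!col %in% names(x)) stopf("cell table lacks column '%s'", col)
  class(x) <- c("cell_table", "data.frame")
  x
}

#' Write a data.frame as TSV with string identifiers
#' @param x data.frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
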