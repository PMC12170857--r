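# Readers and writers for the supported on-disk formats: MTX triplets with
# gene/barcode sidecars, dense CSV/TSV (genes in rows), an HDF5 single-cell
# container dialect (matrix + obs/var tables + spatial coordinates), and
# the slice manifest tying them together.

#' Read one slice from MTX + sidecar tables
#'
#' Expects `matrix.mtx` (genes x spots), `genes.tsv`, `barcodes.tsv` and
#' `coords.csv` (columns x,y) in `dir`.
#'
#' @param dir Directory holding the four files.
#' @param slice_id Slice identifier (default: the directory name).
#' @return A [raw_slice()].
#' @export
read_slice_mtx <- function(dir, slice_id = basename(dir)) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- read.table(file.path(dir, "genes.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)[, 1L]
  barcodes <- read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                         stringsAsFactors = FALSE)[, 1L]
  coords <- unname(as.matrix(read.table(file.path(dir, "coords.csv"),
                                        sep = ",",
                                        header = TRUE)[, c("x", "y")]))
  colnames(m) <- barcodes
  raw_slice(m, genes, coords, slice_id)
}

#' Write one slice as MTX + sidecar tables
#' @param slice A [raw_slice()].
#' @param dir Output directory (created).
#' @export
write_slice_mtx <- function(slice, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(slice$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(slice$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(colnames(slice$counts) %||%
               sprintf("spot%05d", seq_len(ncol(slice$counts))),
             file.path(dir, "barcodes.tsv"))
  write.table(data.frame(x = slice$coords[, 1L], y = slice$coords[, 2L]),
              file.path(dir, "coords.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(dir)
}

#' Read one slice from a dense CSV/TSV (genes in rows) plus coordinates
#' @param matrix_path Dense matrix file; first column = gene ids, header =
#'   spot ids; separator inferred from the extension.
#' @param coords_path CSV with columns x,y.
#' @param slice_id Slice identifier.
#' @return A [raw_slice()].
#' @export
read_slice_csv <- function(matrix_path, coords_path, slice_id) {
  sep <- if (grepl("\\.tsv$", matrix_path)) "\t" else ","
  df <- read.table(matrix_path, sep = sep, header = TRUE,
                   check.names = FALSE, row.names = 1L)
  coords <- unname(as.matrix(read.table(coords_path, sep = ",",
                                        header = TRUE)[, c("x", "y")]))
  raw_slice(as.matrix(df), rownames(df), coords, slice_id)
}

#' Write one slice as dense CSV plus coordinates
#' @param slice A [raw_slice()].
#' @param matrix_path,coords_path Output files.
#' @export
write_slice_csv <- function(slice, matrix_path, coords_path) {
  df <- data.frame(gene = slice$gene_ids, slice$counts,
                   check.names = FALSE)
  write.table(df, matrix_path, sep = ",", row.names = FALSE, quote = FALSE)
  write.table(data.frame(x = slice$coords[, 1L], y = slice$coords[, 2L]),
              coords_path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(matrix_path)
}

h5_available <- function() requireNamespace("rhdf5", quietly = TRUE)

#' Read a slice or assembled dataset from the HDF5 container dialect
#'
#' Layout: `X` (genes x spots), `var/gene_ids`, `obs/slice_of` (optional),
#' `obsm/spatial` (spots x 2), written by [write_h5()].
#'
#' @param path HDF5 file.
#' @return A `multislice_dataset` when `obs/slice_of` is present, otherwise
#'   a [raw_slice()].
#' @export
read_h5 <- function(path) {
  if (!h5_available()) stop("rhdf5 not installed", call. = FALSE)
  X <- rhdf5::h5read(path, "X")
  genes <- as.character(rhdf5::h5read(path, "var/gene_ids"))
  S <- t(rhdf5::h5read(path, "obsm/spatial"))
  if (nrow(S) != ncol(X)) S <- t(S)
  cont <- rhdf5::h5ls(path)$name
  if ("slice_of" %in% cont) {
    slice_of <- as.integer(rhdf5::h5read(path, "obs/slice_of"))
    slice_ids <- as.character(rhdf5::h5read(path, "obs/slice_ids"))
    rownames(X) <- genes
    structure(list(X = X, slice_of = slice_of, S = S,
                   L = length(unique(slice_of)), gene_ids = genes,
                   slice_ids = slice_ids, Y = NULL,
                   target_sums = rep(NA_real_, length(unique(slice_of)))),
              class = "multislice_dataset")
  } else {
    sid <- as.character(rhdf5::h5read(path, "obs/slice_id"))[1L]
    raw_slice(X, genes, S, sid)
  }
}

#' Write a slice or assembled dataset to the HDF5 container dialect
#' @param x A [raw_slice()] or `multislice_dataset`.
#' @param path Output HDF5 file (overwritten).
#' @export
write_h5 <- function(x, path) {
  if (!h5_available()) stop("rhdf5 not installed", call. = FALSE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (g in c("obs", "var", "obsm")) rhdf5::h5createGroup(path, g)
  if (inherits(x, "multislice_dataset")) {
    rhdf5::h5write(unname(x$X), path, "X")
    rhdf5::h5write(x$gene_ids, path, "var/gene_ids")
    rhdf5::h5write(as.integer(x$slice_of), path, "obs/slice_of")
    rhdf5::h5write(x$slice_ids, path, "obs/slice_ids")
    rhdf5::h5write(t(unname(x$S)), path, "obsm/spatial")
  } else {
    rhdf5::h5write(unname(x$counts), path, "X")
    rhdf5::h5write(x$gene_ids, path, "var/gene_ids")
    rhdf5::h5write(x$slice_id, path, "obs/slice_id")
    rhdf5::h5write(t(unname(x$coords)), path, "obsm/spatial")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Write simulated slices, manifest, and ground truth to a directory
#'
#' Exercises the reader formats: slices rotate through MTX, CSV and (when
#' rhdf5 is available) the HDF5 dialect; a `manifest.tsv` lists them and
#' `truth.json` records the planted structure.
#'
#' @param sim Result of [simulate_slices()].
#' @param dir Output directory.
#' @param format `"mtx"`, `"csv"`, `"h5"`, or `"mixed"` (rotate).
#' @return The manifest path.
#' @export
write_sim_dir <- function(sim, dir, format = c("mixed", "mtx", "csv", "h5")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmts <- c("mtx", "csv", if (h5_available()) "h5")
  rows <- lapply(seq_along(sim$slices), function(i) {
    s <- sim$slices[[i]]
    f <- if (format == "mixed") fmts[(i - 1L) %% length(fmts) + 1L] else format
    path <- switch(f,
      mtx = { write_slice_mtx(s, file.path(dir, s$slice_id))
              file.path(dir, s$slice_id) },
      csv = { mp <- file.path(dir, paste0(s$slice_id, ".csv"))
              write_slice_csv(s, mp,
                              file.path(dir, paste0(s$slice_id, "_coords.csv")))
              mp },
      h5 = { hp <- file.path(dir, paste0(s$slice_id, ".h5"))
             write_h5(s, hp); hp })
    data.frame(slice_id = s$slice_id, format = f, path = path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(domains = truth$domains, composition = truth$composition,
         marker_block = truth$marker_block,
         config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read slices listed in a manifest
#' @param manifest_path TSV with columns slice_id, format, path.
#' @return List of [raw_slice()] objects.
#' @export
read_manifest <- function(manifest_path) {
  man <- read.table(manifest_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    with(man[i, ], switch(format,
      mtx = read_slice_mtx(path, slice_id),
      csv = read_slice_csv(path, sub("\\.csv$", "_coords.csv", path),
                           slice_id),
      h5 = read_h5(path),
      stop(sprintf("unknown format '%s'", format), call. = FALSE)))
  })
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding all parameter arrays plus a config echo and
#' a schema version.
#'
#' @param fit A `fit_result` (or any list of parameter arrays).
#' @param path Checkpoint file.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(schema = 1L, fit = fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$schema)) stop("not a checkpoint file", call. = FALSE)
  ck$fit
}
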