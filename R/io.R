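#' Write a spike raster to disk
#'
#' Two interchangeable on-disk forms: `"text"` writes a plain two-column
#' table `time_ms neuron_id` with `#`-prefixed metadata header lines
#' (lossless, diff-able); `"rds"` writes the full object as a compressed R
#' container. The format is inferred from the file extension when not given
#' (`.txt`/`.tsv` vs `.rds`).
#'
#' @param raster a `spike_raster`.
#' @param path output file path.
#' @param format `"text"` or `"rds"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, format = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(format))
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "text"
  if (format == "rds") {
    saveRDS(raster, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# n_neurons %d", raster$n_neurons),
      sprintf("# t_total %.10g", raster$t_total),
      sprintf("# t_transient %.10g", raster$t_transient),
      sprintf("# seed %s", if (is.null(raster$config$seed)) "NA" else raster$config$seed),
      "# time_ms neuron_id"), con)
    utils::write.table(data.frame(time = raster$times, id = raster$ids),
                       con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a spike raster written by [write_raster()]
#'
#' @param path file path (`.rds` or text).
#' @return A `spike_raster`.
#' @export
read_raster <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    r <- readRDS(path)
    stopifnot(inherits(r, "spike_raster"))
    return(r)
  }
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(ln) == 0) return(NA)
    strsplit(ln[1], " ")[[1]][3]
  }
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("time", "id"))
  seed <- get_meta("seed")
  structure(
    list(times = tab$time, ids = as.integer(tab$id),
         n_neurons = as.integer(get_meta("n_neurons")),
         t_total = as.numeric(get_meta("t_total")),
         t_transient = as.numeric(get_meta("t_transient")),
         config = list(seed = if (is.na(seed) || seed == "NA") NULL else as.integer(seed)),
         stsd = NULL),
    class = "spike_raster"
  )
}

#' Write a weight matrix to disk
#'
#' `"rds"` stores the sparse matrix with its survivor-count attributes;
#' `"edgelist"` writes a plain text table `i j J_ij` (one surviving directed
#' connection per line) for inspection with standard tools.
#'
#' @param W weight matrix (dense or sparse).
#' @param path output path.
#' @param format `"rds"` or `"edgelist"`; default inferred from extension.
#' @return `path`, invisibly.
#' @export
write_weights <- function(W, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "edgelist"
  if (format == "rds") {
    saveRDS(W, path)
  } else {
    Wt <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                      "TsparseMatrix")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# N %d", nrow(W)), con)
    writeLines("# i j J_ij", con)
    utils::write.table(
      data.frame(i = Wt@i + 1L, j = Wt@j + 1L, J = Wt@x),
      con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a weight matrix written by [write_weights()]
#'
#' @param path file path (`.rds` or edge-list text).
#' @return A sparse `Matrix::dgCMatrix`.
#' @export
read_weights <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) return(readRDS(path))
  hdr <- readLines(path, n = 2)
  N <- as.integer(strsplit(grep("^# N", hdr, value = TRUE)[1], " ")[[1]][3])
  tab <- utils::read.table(path, comment.char = "#", col.names = c("i", "j", "J"))
  Matrix::sparseMatrix(i = tab$i, j = tab$j, x = tab$J, dims = c(N, N))
}
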