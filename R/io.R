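# Plain-text interchange: FreeSurfer-style .label files, an annot-like TSV
# parcellation table, TSV matrix containers and JSON provenance sidecars.

#' Write a parcellation as FreeSurfer-style label files
#'
#' One `.label` file per parcel: a comment header, a vertex count line, then
#' `vertex_index x y z value` rows (0-based vertex indices, coordinates in
#' mm).
#'
#' @param parc A `ctf_parcellation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_labels <- function(parc, dir) {
  stopifnot(inherits(parc, "ctf_parcellation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(parc$n_parcels)
  for (p in seq_len(parc$n_parcels)) {
    path <- file.path(dir, paste0(parc$labels[p], ".label"))
    v <- parc$vertices[[p]]
    con <- file(path, "w")
    writeLines(c(sprintf("#!ascii label %s", parc$labels[p]),
                 as.character(length(v))), con)
    utils::write.table(
      data.frame(v - 1L, parc$space$coords[v, , drop = FALSE], 0),
      con, row.names = FALSE, col.names = FALSE, sep = " ")
    close(con)
    paths[p] <- path
  }
  invisible(paths)
}

#' Write / read the annot-like parcellation table
#'
#' TSV with columns `vertex_id` (1-based), `parcel_id`, `parcel_name`,
#' `hemisphere`; uncovered vertices are omitted.
#'
#' @param parc A `ctf_parcellation`.
#' @param path Output TSV path.
#' @return `write_parcellation_tsv` invisibly returns `path`;
#'   `read_parcellation_tsv` returns a `ctf_parcellation`.
#' @export
write_parcellation_tsv <- function(parc, path) {
  stopifnot(inherits(parc, "ctf_parcellation"))
  rows <- do.call(rbind, lapply(seq_len(parc$n_parcels), function(p) {
    data.frame(vertex_id = parc$vertices[[p]], parcel_id = p,
               parcel_name = parc$labels[p],
               hemisphere = parc$hemisphere[p])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation_tsv
#' @param space The `ctf_source_space` the table refers to.
#' @export
read_parcellation_tsv <- function(path, space) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- sort(unique(tab$parcel_id))
  verts <- lapply(ids, function(i) tab$vertex_id[tab$parcel_id == i])
  name <- vapply(ids, function(i) tab$parcel_name[tab$parcel_id == i][1L],
                 character(1))
  hemi <- vapply(ids, function(i) tab$hemisphere[tab$parcel_id == i][1L],
                 character(1))
  base <- sub(paste0("-", "(lh|rh)$"), "", name)
  parcellation(verts, base, hemi, space)
}

#' TSV matrix container
#'
#' Writes a numeric matrix as a tab-separated table with a one-line `#`
#' header recording the container name and dimensions, and reads it back.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @param name Dataset name stored in the header.
#' @return `write_matrix_tsv` invisibly returns `path`; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(m, path, name = "matrix") {
  con <- file(path, "w")
  writeLines(sprintf("# %s %d %d", name, nrow(m), ncol(m)), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), " ")[[1L]]
  m <- as.matrix(utils::read.delim(path, header = FALSE, skip = 1L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == as.integer(hdr[3L]), ncol(m) == as.integer(hdr[4L]))
  m
}

#' Write a JSON provenance sidecar
#'
#' Records configuration, seeds and stage logs next to an output artifact.
#'
#' @param x Named list of provenance fields.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
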