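#' Read a FASTA alignment into a core alignment
#'
#' Records must be equal length. Sequences are uppercased, `U` mapped to `T`,
#' and any character outside `A C G T N -` mapped to `N` with a counted
#' warning. Duplicate ids or ragged lengths are errors (the offending record
#' is named).
#'
#' @param path FASTA file path.
#' @return A [core_alignment()].
#' @export
read_alignment <- function(path) {
  # read as plain characters (no nucleotide bit-packing) so that stray
  # symbols survive to be counted and normalised here
  x <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
  if (length(x) == 0) abort("Empty FASTA file.")
  ids <- names(x)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  lens <- lengths(x)
  if (length(unique(lens)) > 1) {
    bad <- ids[lens != lens[1]][1]
    abort(sprintf("Ragged alignment: record '%s' has %d bp, expected %d.",
                  bad, lens[ids == bad][1], lens[1]))
  }
  m <- toupper(do.call(rbind, x))
  rownames(m) <- ids
  m[m == "U"] <- "T"
  bad <- !(m %in% c(DNA_BASES, "N", "-"))
  if (any(bad)) {
    warn(sprintf("%d character(s) outside {A,C,G,T,N,-} mapped to N.",
                 sum(bad)))
    m[bad] <- "N"
  }
  core_alignment(m)
}

#' Write a core alignment as FASTA
#'
#' @param aln A [core_alignment()] or character matrix with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2 * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cladeflow_tables
#' @export
write_gene_matrix <- function(m, path) {
  m <- as_gene_matrix(m)
  df <- cbind(tibble(gene = rownames(m)), as_tibble(as.data.frame(m)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname cladeflow_tables
#' @export
read_gene_matrix <- function(path) {
  as_gene_matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' Tabular readers and writers
#'
#' All tabular artifacts are single-header TSV files: the gene copy-number
#' matrix (`gene` column + one column per sample), sample metadata
#' (`sample`, `habitat`, `lat`, `lon`), recombination events (`recipient`,
#' `start`, `end`, 0-based half-open, plus optional annotation columns),
#' growth readings (`sample`, `condition`, `replicate`, `time_h`, `abs450`),
#' window tracks (BED-like: `chrom`, `start`, `end`, `value`,
#' `n_valid_sites`) and labelled square distance matrices.
#'
#' @param m,meta,events,growth,track,d Object to write.
#' @param path File path.
#' @name cladeflow_tables
NULL

#' @rdname cladeflow_tables
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' @rdname cladeflow_tables
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", habitat = "c", .default = "d"))
}

#' @rdname cladeflow_tables
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname cladeflow_tables
#' @export
read_events <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    recipient = "c", start = "i", end = "i", .default = "?"))
}

#' @rdname cladeflow_tables
#' @export
write_growth <- function(growth, path) {
  readr::write_tsv(growth, path)
  invisible(path)
}

#' @rdname cladeflow_tables
#' @export
read_growth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", condition = "c", replicate = "i",
    time_h = "d", abs450 = "d"))
}

#' @rdname cladeflow_tables
#' @param chrom Placeholder chromosome name for the BED-like track.
#' @export
write_window_track <- function(track, path, chrom = "core") {
  df <- tibble(chrom = chrom, start = track$start, end = track$end,
               value = track$value,
               n_valid_sites = track$n_valid_sites %||% NA_integer_)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname cladeflow_tables
#' @export
read_window_track <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", value = "d", n_valid_sites = "i"))
  out <- select(x, -"chrom")
  class(out) <- c("cf_track", class(out))
  out
}

#' @rdname cladeflow_tables
#' @export
write_distance_matrix <- function(d, path) {
  d <- as.matrix(d)
  df <- cbind(tibble(sample = rownames(d)), as_tibble(as.data.frame(d)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname cladeflow_tables
#' @export
read_distance_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(x[, -1])
  rownames(m) <- x[[1]]
  m
}

#' Write a JSON run manifest
#'
#' Records package version, seed, parameters and input-file checksums so any
#' output can be regenerated byte-identically.
#'
#' @param path Output path.
#' @param seed Integer seed governing all randomness of the run.
#' @param params Named list of parameters.
#' @param inputs Character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, params = list(), inputs = character()) {
  hashes <- vapply(inputs, function(f) {
    as.character(tools::md5sum(f))
  }, character(1))
  manifest <- list(
    package = "cladeflow",
    version = as.character(utils::packageVersion("cladeflow")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed, params = params,
    input_md5 = as.list(hashes))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
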