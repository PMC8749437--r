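#' Construct and validate a core-genome alignment
#'
#' A core alignment is a character matrix with one row per sample and one
#' column per alignment position, over the alphabet `A C G T N -`. Row names
#' are the sample identifiers. All coordinates in this package are 0-based
#' half-open.
#'
#' @param x Character matrix (rows = samples, columns = sites) with unique,
#'   non-empty row names.
#' @return The validated matrix, with class `"core_alignment"` prepended.
#' @export
core_alignment <- function(x) {
  if (!is.matrix(x) || !is.character(x)) {
    abort("`x` must be a character matrix (samples x sites).")
  }
  if (nrow(x) < 2) abort("An alignment needs at least 2 samples.")
  if (ncol(x) < 1) abort("An alignment needs at least 1 column.")
  ids <- rownames(x)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    abort("All rows must be named with sample identifiers.")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  bad <- !(x %in% c(DNA_BASES, "N", "-"))
  if (any(bad)) {
    abort(sprintf("%d alignment cells outside {A,C,G,T,N,-}.", sum(bad)))
  }
  class(x) <- c("core_alignment", class(x))
  x
}

#' @export
print.core_alignment <- function(x, ...) {
  cat(sprintf("<core_alignment> %d samples x %d sites\n", nrow(x), ncol(x)))
  cat("samples:", paste(head(rownames(x), 8), collapse = ", "),
      if (nrow(x) > 8) "..." else "", "\n")
  invisible(x)
}

# Normalise the many ways callers can hand us a two-clade assignment:
# a named character vector (sample -> label) or a metadata data frame with
# `sample` and `habitat` columns. Returns a named character vector covering
# `samples`, erroring on gaps or (unless allowed) >2 labels.
as_clades <- function(clades, samples, max_labels = 2) {
  if (is.data.frame(clades)) {
    if (!all(c("sample", "habitat") %in% names(clades))) {
      abort("Metadata must have `sample` and `habitat` columns.")
    }
    clades <- setNames(as.character(clades$habitat), clades$sample)
  }
  if (is.null(names(clades))) {
    abort("Clade assignment must be named by sample id.")
  }
  missing <- setdiff(samples, names(clades))
  if (length(missing) > 0) {
    abort(paste0("Samples without a clade label: ",
                 paste(missing, collapse = ", ")))
  }
  out <- clades[samples]
  labs <- unique(out)
  if (!is.na(max_labels) && length(labs) > max_labels) {
    abort(sprintf("Expected at most %d clade labels, got %d (%s).",
                  max_labels, length(labs), paste(labs, collapse = ", ")))
  }
  out
}

# Split sample ids into a list of two character vectors keyed by clade label.
clade_split <- function(clades, samples) {
  cl <- as_clades(clades, samples)
  split(samples, cl)
}
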