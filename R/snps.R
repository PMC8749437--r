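#' Extract single-nucleotide polymorphisms from a core alignment
#'
#' A column is polymorphic when at least two distinct bases among `A C G T`
#' occur in it; gaps and `N` are ignored. Invariant columns (after excluding
#' missing data) are omitted.
#'
#' @param aln A [core_alignment()] (or plain character matrix with row names).
#' @return A tibble of class `"snp_tbl"` with one row per SNP: `pos` (0-based
#'   bp), `alleles` (e.g. `"A/T"`), `n_alleles`, `dimorphic`. The per-sample
#'   allele columns are kept in `attr(, "allele_matrix")` (samples x SNPs) for
#'   downstream clade logic; `attr(, "genome_length")` records the alignment
#'   length.
#' @export
extract_snps <- function(aln) {
  aln <- if (inherits(aln, "core_alignment")) aln else core_alignment(aln)
  base_counts <- vapply(DNA_BASES, function(b) colSums(aln == b),
                        numeric(ncol(aln)))
  if (ncol(aln) == 1) base_counts <- matrix(base_counts, nrow = 1,
                                            dimnames = list(NULL, DNA_BASES))
  n_alleles <- rowSums(base_counts > 0)
  poly <- which(n_alleles >= 2)
  alleles <- vapply(poly, function(j) {
    paste(DNA_BASES[base_counts[j, ] > 0], collapse = "/")
  }, character(1))
  n_all <- as.integer(n_alleles[poly])
  out <- tibble(pos = poly - 1L, alleles = alleles,
                n_alleles = n_all, dimorphic = n_all == 2L)
  attr(out, "allele_matrix") <- unclass(aln)[, poly, drop = FALSE]
  attr(out, "genome_length") <- ncol(aln)
  class(out) <- c("snp_tbl", class(out))
  out
}

#' Detect clade-specific SNPs
#'
#' A SNP is clade-specific when the allele sets observed in the two clades
#' (gaps and `N` excluded) are disjoint; with exactly two alleles overall this
#' is a fixed difference ("clade-specific dimorphic SNP"). Sites where one
#' clade has only missing data cannot be classified and are skipped with a
#' message. Swapping the clade labels leaves the result unchanged.
#'
#' @param snps A `"snp_tbl"` from [extract_snps()].
#' @param clades Named character vector (sample -> clade label) or a metadata
#'   data frame with `sample`/`habitat` columns; exactly two labels.
#' @return The subset of `snps` that is clade-specific, with added columns
#'   `alleles_<label>` for each clade. The `allele_matrix` attribute is
#'   subset accordingly.
#' @export
clade_specific_snps <- function(snps, clades) {
  if (!inherits(snps, "snp_tbl")) abort("`snps` must come from extract_snps().")
  am <- attr(snps, "allele_matrix")
  cl <- as_clades(clades, rownames(am))
  labs <- unique(cl)
  if (length(labs) != 2) abort("Exactly 2 clade labels are required.")
  rows <- split(seq_len(nrow(am)), cl)

  present <- function(idx) {
    # base x SNP presence within one clade
    vapply(DNA_BASES, function(b) {
      colSums(am[idx, , drop = FALSE] == b) > 0
    }, logical(ncol(am)))
  }
  p1 <- present(rows[[labs[1]]]); p2 <- present(rows[[labs[2]]])
  if (ncol(am) == 1) { p1 <- matrix(p1, 1); p2 <- matrix(p2, 1) }
  any1 <- rowSums(p1) > 0; any2 <- rowSums(p2) > 0
  skipped <- !(any1 & any2)
  if (any(skipped)) {
    inform(sprintf(
      "%d site(s) skipped: one clade has only missing data there.",
      sum(skipped)))
  }
  specific <- any1 & any2 & rowSums(p1 & p2) == 0
  idx <- which(specific)
  out <- snps[idx, ]
  allele_str <- function(p) apply(p, 1, function(z)
    paste(DNA_BASES[z], collapse = "/"))
  out[[paste0("alleles_", labs[1])]] <- allele_str(p1[idx, , drop = FALSE])
  out[[paste0("alleles_", labs[2])]] <- allele_str(p2[idx, , drop = FALSE])
  attr(out, "allele_matrix") <- am[, idx, drop = FALSE]
  attr(out, "genome_length") <- attr(snps, "genome_length")
  attr(out, "clades") <- cl
  class(out) <- c("snp_tbl", class(tibble()))
  out
}

# Sliding-window layout: 0-based half-open windows of `window` bp every
# `step` bp; a final partial window is emitted only if at least `step` long.
window_layout <- function(genome_length, window, step) {
  if (!(window >= step && step > 0)) abort("Require window >= step > 0.")
  if (genome_length < window) {
    warn(sprintf(
      "Genome (%d bp) shorter than window (%d bp): single truncated window.",
      genome_length, window))
    return(tibble(start = 0L, end = as.integer(genome_length)))
  }
  starts <- seq(0L, as.integer(genome_length - step), by = as.integer(step))
  ends <- pmin(starts + as.integer(window), as.integer(genome_length))
  keep <- (ends - starts) >= step
  tibble(start = starts[keep], end = ends[keep])
}

#' Sliding-window SNP counts
#'
#' Counts each SNP in every window whose half-open interval contains its
#' position (overlapping windows count a SNP more than once).
#'
#' @param snps A `"snp_tbl"` (typically the clade-specific subset).
#' @param genome_length Alignment length in bp; defaults to the length
#'   recorded in `snps`.
#' @param window,step Window size and step in bp (defaults 5000 / 2500).
#' @return A tibble of class `"cf_track"` with `start`, `end`, `value`
#'   (SNP count) and `n_valid_sites` (window width); the genome-wide mean
#'   count per window is stored in `attr(, "mean_value")`.
#' @export
window_counts <- function(snps, genome_length = attr(snps, "genome_length"),
                          window = 5000, step = 2500) {
  if (is.null(genome_length)) abort("`genome_length` is required.")
  lay <- window_layout(genome_length, window, step)
  pos <- snps$pos
  value <- vapply(seq_len(nrow(lay)), function(w) {
    sum(pos >= lay$start[w] & pos < lay$end[w])
  }, numeric(1))
  out <- mutate(lay, value = value, n_valid_sites = .data$end - .data$start)
  attr(out, "mean_value") <- mean(value)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "stat") <- "snp_count"
  class(out) <- c("cf_track", class(out))
  out
}

#' Call peaks on a window track
#'
#' Selects windows whose value reaches `fold` times the genome-wide mean and
#' merges selected windows that overlap or abut into maximal intervals
#' (overlapping windows would otherwise double-report one locus).
#'
#' @param track A `"cf_track"` tibble.
#' @param fold Fold-over-mean threshold (default 4).
#' @return Tibble with one row per peak: `start`, `end`, `max_value`,
#'   `n_windows`; `attr(, "mean_value")` carries the mean used.
#' @export
call_peaks <- function(track, fold = 4.0) {
  if (nrow(track) == 0) abort("`track` is empty.")
  m <- mean(track$value, na.rm = TRUE)
  empty <- tibble(start = integer(), end = integer(),
                  max_value = numeric(), n_windows = integer())
  attr(empty, "mean_value") <- m
  if (!is.finite(m) || m == 0) {
    warn("Track mean is 0: no peaks can be called.")
    return(empty)
  }
  sel <- track[!is.na(track$value) & track$value >= fold * m, ]
  if (nrow(sel) == 0) return(empty)
  sel <- arrange(sel, .data$start)
  grp <- cumsum(c(TRUE, sel$start[-1] > sel$end[-nrow(sel)]))
  out <- sel |>
    mutate(grp = grp) |>
    group_by(grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              max_value = max(.data$value), n_windows = n(),
              .groups = "drop") |>
    select(-"grp")
  attr(out, "mean_value") <- m
  out
}
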