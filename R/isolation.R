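#' Great-circle geographic distance matrix
#'
#' Haversine distances on a sphere of radius 6,378,137 m (the equatorial
#' radius used by common geospatial defaults), via
#' \code{\link[geosphere]{distHaversine}}. Samples lacking coordinates are
#' excluded before matrix construction (listwise, never pairwise) and listed
#' in `attr(, "excluded")` and a message.
#'
#' @param meta Tibble with `sample`, `lat`, `lon` (decimal degrees).
#' @return Symmetric matrix of distances in meters with sample dimnames.
#' @export
geo_distance_matrix <- function(meta) {
  stopifnot(all(c("sample", "lat", "lon") %in% names(meta)))
  miss <- is.na(meta$lat) | is.na(meta$lon)
  excluded <- meta$sample[miss]
  if (length(excluded) > 0) {
    inform(paste0("Excluding sample(s) without coordinates: ",
                  paste(excluded, collapse = ", ")))
    meta <- meta[!miss, ]
  }
  if (any(meta$lat < -90 | meta$lat > 90 | meta$lon < -180 | meta$lon > 180)) {
    abort("Coordinates out of range: lat in [-90,90], lon in [-180,180].")
  }
  d <- geosphere::distm(cbind(meta$lon, meta$lat),
                        fun = geosphere::distHaversine)
  dimnames(d) <- list(meta$sample, meta$sample)
  attr(d, "excluded") <- excluded
  d
}

#' Habitat difference matrix
#'
#' 0 for pairs from the same habitat type, 1 for pairs from different types.
#' With the default binary design more than two habitat labels is an error;
#' set `allow_multiclass = TRUE` to accept any number of labels with the same
#' 0 = same / 1 = different coding.
#'
#' @param meta Tibble with `sample` and `habitat` columns.
#' @param allow_multiclass Permit more than two habitat labels.
#' @return Symmetric 0/1 matrix with sample dimnames.
#' @export
habitat_matrix <- function(meta, allow_multiclass = FALSE) {
  stopifnot(all(c("sample", "habitat") %in% names(meta)))
  labs <- unique(meta$habitat)
  if (length(labs) > 2 && !allow_multiclass) {
    abort(sprintf("Found %d habitat types; the design is binary (use allow_multiclass = TRUE to override).",
                  length(labs)))
  }
  d <- outer(meta$habitat, meta$habitat, FUN = "!=") * 1
  dimnames(d) <- list(meta$sample, meta$sample)
  d
}

#' Phylogenetic distance matrix from a tree or an alignment
#'
#' From a tree: patristic distances (sum of branch lengths along the path).
#' From an alignment: p-distances with pairwise deletion of gaps/`N`
#' (via \code{\link[ape]{dist.dna}} with `model = "raw"`). The mode used is
#' recorded in `attr(, "mode")`.
#'
#' @param aln A [core_alignment()] (used when `tree` is NULL).
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param samples Optional sample set the matrix must cover (error otherwise).
#' @return Symmetric distance matrix with sample dimnames.
#' @export
phylo_distance_matrix <- function(aln = NULL, tree = NULL, samples = NULL) {
  if (is.null(aln) == is.null(tree)) {
    abort("Provide exactly one of `aln` or `tree`.")
  }
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object.")
    d <- cophenetic(tree)
    mode <- "patristic"
  } else {
    aln <- if (inherits(aln, "core_alignment")) aln else core_alignment(aln)
    dna <- ape::as.DNAbin(matrix(tolower(unclass(aln)), nrow(aln),
                                 dimnames = dimnames(aln)))
    d <- as.matrix(ape::dist.dna(dna, model = "raw",
                                 pairwise.deletion = TRUE))
    mode <- "p_distance"
  }
  if (!is.null(samples)) {
    if (!setequal(rownames(d), samples)) {
      abort("Tree/alignment labels do not match the sample set.")
    }
    d <- d[samples, samples]
  }
  attr(d, "mode") <- mode
  d
}

# upper-triangle utilities ----------------------------------------------------

check_aligned <- function(...) {
  ms <- list(...)
  ref <- rownames(ms[[1]])
  for (m in ms) {
    if (nrow(m) != ncol(m)) abort("Distance matrices must be square.")
    if (!is.null(ref) && !is.null(rownames(m)) &&
        !identical(rownames(m), ref)) {
      abort("Distance matrices must share the same samples in the same order.")
    }
  }
  invisible(TRUE)
}

ut_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = ut[, 1], j = ut[, 2])
}

# all permutations of 1..n (n small), for exhaustive relabelling tests
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the upper-triangle vectors; the null distribution
#' is generated by jointly permuting rows and columns of `a`. The one-sided
#' (greater) p-value is `(1 + #permutations with r >= r_obs) / (n_perm + 1)`.
#' With `exhaustive = TRUE` all `n!` relabellings are enumerated instead and
#' the p-value is the exact proportion (identity included).
#'
#' @param a,b Aligned symmetric distance matrices (same samples, same order).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Optional integer seed for the permutation draw.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param exhaustive Enumerate all permutations (feasible for n <= ~8).
#' @return A list of class `"cf_mantel"`: `statistic` (observed r),
#'   `p.value`, `n_perm`, `alternative`, `method`.
#' @export
mantel_test <- function(a, b, n_perm = 10000, seed = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  a <- as.matrix(a); b <- as.matrix(b)
  check_aligned(a, b)
  n <- nrow(a)
  if (n < 3) abort("Need at least 3 samples.")
  idx <- ut_index(n)
  va <- a[cbind(idx$i, idx$j)]
  vb <- b[cbind(idx$i, idx$j)]
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("A distance matrix has zero variance in its upper triangle.")
  }
  r_obs <- cor(va, vb)
  if (!is.null(seed)) set.seed(seed)
  perm_r <- function(p) cor(a[cbind(p[idx$i], p[idx$j])], vb)
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p <- switch(alternative,
                greater = mean(rs >= r_obs - 1e-12),
                less = mean(rs <= r_obs + 1e-12),
                two.sided = mean(abs(rs) >= abs(r_obs) - 1e-12))
    n_perm <- length(perms)
    method <- "Mantel test (exhaustive enumeration)"
  } else {
    rs <- vapply(seq_len(n_perm), function(k) perm_r(sample.int(n)),
                 numeric(1))
    p <- switch(alternative,
                greater = (1 + sum(rs >= r_obs)) / (n_perm + 1),
                less = (1 + sum(rs <= r_obs)) / (n_perm + 1),
                two.sided = (1 + sum(abs(rs) >= abs(r_obs))) / (n_perm + 1))
    method <- "Mantel test (permutation)"
  }
  structure(list(statistic = r_obs, p.value = p, n_perm = n_perm,
                 alternative = alternative, method = method),
            class = "cf_mantel")
}

#' Partial Mantel test controlling for a third distance matrix
#'
#' The partial correlation
#' `r_ab.c = (r_ab - r_ac r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2))` is tested
#' by permuting matrix `a` only and recomputing the full partial statistic
#' for every permutation (`r_bc` is unaffected by the permutation). One-sided
#' (greater) p-value as in [mantel_test()].
#'
#' @inheritParams mantel_test
#' @param control The distance matrix to control for.
#' @return A `"cf_mantel"` result.
#' @export
partial_mantel_test <- function(a, b, control, n_perm = 10000, seed = NULL,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as.matrix(a); b <- as.matrix(b); control <- as.matrix(control)
  check_aligned(a, b, control)
  n <- nrow(a)
  if (n < 4) abort("Need at least 4 samples.")
  idx <- ut_index(n)
  va <- a[cbind(idx$i, idx$j)]
  vb <- b[cbind(idx$i, idx$j)]
  vc <- control[cbind(idx$i, idx$j)]
  if (sd(va) == 0 || sd(vb) == 0 || sd(vc) == 0) {
    abort("A distance matrix has zero variance in its upper triangle.")
  }
  r_bc <- cor(vb, vc)
  partial <- function(r_ab, r_ac) {
    den <- sqrt((1 - r_ac^2) * (1 - r_bc^2))
    if (!is.finite(den) || den == 0) {
      abort("Partial correlation undefined: a marginal correlation is +/-1.")
    }
    (r_ab - r_ac * r_bc) / den
  }
  r_obs <- partial(cor(va, vb), cor(va, vc))
  if (!is.null(seed)) set.seed(seed)
  rs <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    vap <- a[cbind(p[idx$i], p[idx$j])]
    partial(cor(vap, vb), cor(vap, vc))
  }, numeric(1))
  p <- switch(alternative,
              greater = (1 + sum(rs >= r_obs)) / (n_perm + 1),
              less = (1 + sum(rs <= r_obs)) / (n_perm + 1),
              two.sided = (1 + sum(abs(rs) >= abs(r_obs))) / (n_perm + 1))
  structure(list(statistic = r_obs, p.value = p, n_perm = n_perm,
                 alternative = alternative,
                 method = "Partial Mantel test (permute first matrix)"),
            class = "cf_mantel")
}

#' @export
print.cf_mantel <- function(x, ...) {
  cat(sprintf("%s\nr = %.4f, p = %.4g (%s, %d permutations)\n",
              x$method, x$statistic, x$p.value, x$alternative, x$n_perm))
  invisible(x)
}

#' @export
tidy.cf_mantel <- function(x, ...) {
  tibble(estimate = x$statistic, p.value = x$p.value,
         n_perm = x$n_perm, alternative = x$alternative, method = x$method)
}

#' @export
glance.cf_mantel <- function(x, ...) tidy(x)
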