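# Coerce gene input (integer copy-number matrix with gene rownames and sample
# colnames, or a tibble whose first column is the gene id) to a matrix.
as_gene_matrix <- function(m) {
  if (is.data.frame(m)) {
    genes <- as.character(m[[1]])
    m <- as.matrix(m[, -1, drop = FALSE])
    rownames(m) <- genes
  }
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    abort("Gene matrix needs gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("Gene and sample ids must be unique.")
  }
  storage.mode(m) <- "integer"
  if (any(m < 0)) abort("Copy numbers must be nonnegative.")
  m
}

#' Partition a pan-genome into core, accessory and strain-specific genes
#'
#' Core genes are present (copy number >= 1) in every sample; accessory is
#' the rest of the pan-genome; strain-specific genes occur in exactly one
#' sample; single-copy core genes have exactly one copy in every sample.
#' Genes absent from all samples are not pan-genome members and are dropped
#' with a warning.
#'
#' @param m Gene x sample copy-number matrix (or tibble with a gene id column).
#' @return A list of class `"pan_partition"` with character-vector elements
#'   `core`, `accessory`, `strain_specific`, `single_copy_core` and the
#'   filtered presence matrix in `$presence`.
#' @export
partition_pangenome <- function(m) {
  m <- as_gene_matrix(m)
  if (ncol(m) < 1) abort("At least one sample is required.")
  absent <- rowSums(m >= 1) == 0
  if (any(absent)) {
    warn(sprintf("%d gene(s) absent from all samples dropped (not pan-genome members).",
                 sum(absent)))
    m <- m[!absent, , drop = FALSE]
  }
  pres <- m >= 1
  n_with <- rowSums(pres)
  core <- rownames(m)[n_with == ncol(m)]
  accessory <- rownames(m)[n_with < ncol(m)]
  strain_specific <- rownames(m)[n_with == 1 & ncol(m) > 1]
  single_copy_core <- rownames(m)[rowSums(m == 1) == ncol(m)]
  structure(list(core = core, accessory = accessory,
                 strain_specific = strain_specific,
                 single_copy_core = single_copy_core,
                 presence = pres, copy_number = m),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf(
    "<pan_partition> pan %d = core %d (+%d single-copy) + accessory %d (%d strain-specific)\n",
    nrow(x$presence), length(x$core), length(x$single_copy_core),
    length(x$accessory), length(x$strain_specific)))
  invisible(x)
}

#' @export
tidy.pan_partition <- function(x, ...) {
  tibble(gene = rownames(x$presence),
         class = ifelse(rownames(x$presence) %in% x$core, "core", "accessory"),
         strain_specific = rownames(x$presence) %in% x$strain_specific,
         single_copy_core = rownames(x$presence) %in% x$single_copy_core,
         n_samples = rowSums(x$presence))
}

#' @export
glance.pan_partition <- function(x, ...) {
  tibble(pan = nrow(x$presence), core = length(x$core),
         accessory = length(x$accessory),
         strain_specific = length(x$strain_specific),
         single_copy_core = length(x$single_copy_core),
         n_genomes = ncol(x$presence))
}

#' Genes universal in one clade and absent from the other
#'
#' @param m Gene x sample copy-number matrix (or tibble).
#' @param clades Two-label clade assignment covering all samples.
#' @return Tibble with columns `gene` and `clade` (the clade in which the
#'   gene is universal).
#' @export
clade_specific_genes <- function(m, clades) {
  m <- as_gene_matrix(m)
  cl <- as_clades(clades, colnames(m))
  labs <- unique(cl)
  if (length(labs) != 2) abort("Exactly 2 clade labels are required.")
  pres <- m >= 1
  res <- purrr::map(labs, function(lab) {
    own <- pres[, cl == lab, drop = FALSE]
    oth <- pres[, cl != lab, drop = FALSE]
    rownames(m)[rowSums(own) == ncol(own) & rowSums(oth) == 0]
  })
  tibble(gene = unlist(res),
         clade = rep(labs, lengths(res)))
}

#' Jaccard distances between accessory-gene repertoires
#'
#' `d(i, j) = 1 - |G_i intersect G_j| / |G_i union G_j|` over the accessory
#' (dispensable) gene sets of each pair of samples. A pair with two empty
#' repertoires gets distance 0 with a warning. Set `accessory_only = FALSE`
#' to compute the distance on the whole pan-genome instead (useful for a
#' presence/absence clustering of all genes).
#'
#' @param m Gene x sample copy-number matrix (or tibble).
#' @param partition Optional precomputed [partition_pangenome()] result.
#' @param accessory_only Restrict to accessory genes (default TRUE).
#' @return Symmetric distance matrix with sample dimnames and zero diagonal;
#'   `attr(, "similarity")` holds `1 - d`.
#' @export
jaccard_distances <- function(m, partition = NULL, accessory_only = TRUE) {
  m <- as_gene_matrix(m)
  if (ncol(m) < 2) abort("At least two samples are required.")
  if (is.null(partition)) {
    partition <- suppressWarnings(partition_pangenome(m))
  }
  genes <- if (accessory_only) partition$accessory else
    rownames(partition$presence)
  p <- partition$presence[genes, , drop = FALSE]
  inter <- crossprod(p)             # |G_i intersect G_j|
  size <- diag(inter)
  uni <- outer(size, size, "+") - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    n_empty_pairs <- sum(uni[upper.tri(uni)] == 0)
    if (n_empty_pairs > 0) {
      warn(sprintf("%d pair(s) with two empty gene sets: distance set to 0.",
                   n_empty_pairs))
    }
    d[uni == 0] <- 0
  }
  diag(d) <- 0
  attr(d, "similarity") <- 1 - d
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (Q-criterion join selection and the
#' usual branch-length formulas, negative branch lengths not adjusted),
#' delegated to \code{\link[ape]{nj}}. The leaf set is preserved.
#'
#' @param d Symmetric distance matrix with sample dimnames (>= 3 samples).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("Neighbor joining needs at least 3 samples.")
  if (any(!is.finite(d))) abort("Distance matrix has non-finite entries.")
  ape::nj(as.dist(d))
}

#' Average-linkage clustering of gene presence/absence
#'
#' Hierarchical clustering (UPGMA/average linkage) of samples on Jaccard
#' distances over the pan-genome presence/absence matrix — an approximation
#' to presence/absence-profile clustering when the original linkage is
#' unknown.
#'
#' @inheritParams jaccard_distances
#' @return An `hclust` object.
#' @export
pangenome_clustering <- function(m, accessory_only = FALSE) {
  d <- jaccard_distances(m, accessory_only = accessory_only)
  hclust(as.dist(d), method = "average")
}
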