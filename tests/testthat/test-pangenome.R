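gene_mat <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                     samples = sprintf("s%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

test_that("pan-genome partition follows the presence definitions", {
  m <- gene_mat(rbind(rep(1, 5),                 # single-copy core
                      c(2, 1, 1, 1, 1),          # core, not single-copy
                      c(1, 0, 0, 0, 0),          # strain-specific
                      c(1, 1, 0, 0, 0)))         # plain accessory
  p <- partition_pangenome(m)
  expect_setequal(p$core, c("g01", "g02"))
  expect_setequal(p$single_copy_core, "g01")
  expect_setequal(p$strain_specific, "g03")
  expect_setequal(p$accessory, c("g03", "g04"))
  g <- glance(p)
  expect_equal(g$pan, g$core + g$accessory)
})

test_that("genes absent everywhere are dropped with a warning", {
  m <- gene_mat(rbind(c(1, 1), c(0, 0)))
  expect_warning(p <- partition_pangenome(m), "absent")
  expect_equal(nrow(p$presence), 1)
})

test_that("partition agrees with a set-comprehension oracle on random input", {
  set.seed(99)
  m <- gene_mat(matrix(rpois(200 * 10, 0.8), 200, 10))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  p <- partition_pangenome(m)
  core_o <- rownames(m)[apply(m >= 1, 1, all)]
  ss_o <- rownames(m)[apply(m >= 1, 1, sum) == 1]
  scc_o <- rownames(m)[apply(m == 1, 1, all)]
  expect_setequal(p$core, core_o)
  expect_setequal(p$strain_specific, ss_o)
  expect_setequal(p$single_copy_core, scc_o)
  expect_setequal(c(p$core, p$accessory), rownames(m))
  expect_length(intersect(p$core, p$accessory), 0)
  expect_true(all(p$strain_specific %in% p$accessory))
  expect_true(all(p$single_copy_core %in% p$core))
})

test_that("clade-specific genes are universal in one clade, absent in the other", {
  m <- gene_mat(rbind(c(1, 1, 0, 0, 0),
                      c(1, 1, 1, 0, 0),          # leaks into other clade
                      c(0, 0, 1, 1, 1),
                      c(1, 1, 1, 1, 1)))
  cl <- toy_clades(colnames(m), 2)
  cg <- clade_specific_genes(m, cl)
  expect_equal(cg$gene[cg$clade == "IA"], "g01")
  expect_equal(cg$gene[cg$clade == "FL"], "g03")
})

test_that("the simulator's planted habitat genes are recovered exactly", {
  cfg <- sim_config(n_clade_a = 4, n_clade_b = 5, core_length = 5000,
                    n_habitat_genes_a = 7, n_habitat_genes_b = 11,
                    n_shared_core_genes = 30, n_random_accessory = 200,
                    gene_noise = 0, growth_replicates = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  cg <- clade_specific_genes(sim$genes, sim$truth$clade_assignment)
  lab <- cfg$clade_labels
  got_a <- cg$gene[cg$clade == lab[["a"]]]
  got_b <- cg$gene[cg$clade == lab[["b"]]]
  # random accessory genes can mimic clade specificity by chance, so planted
  # sets must be contained and any extras must genuinely satisfy the pattern
  expect_true(all(sim$truth$planted_genes$a %in% got_a))
  expect_true(all(sim$truth$planted_genes$b %in% got_b))
  pres <- sim$genes >= 1
  in_a <- sim$truth$clade_assignment[colnames(sim$genes)] == lab[["a"]]
  for (g in setdiff(got_a, sim$truth$planted_genes$a)) {
    expect_true(all(pres[g, in_a]) && !any(pres[g, !in_a]))
  }
})

test_that("Jaccard distances follow the set formula", {
  m <- gene_mat(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 1, 1),
                      c(1, 1, 1)))
  # accessory = g01..g04 (g05 core): s1 {g01,g02,g04*0...}
  d <- jaccard_distances(m)
  sets <- apply(m[paste0("g0", 1:4), ] >= 1, 2, which, simplify = FALSE)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- sets[[i]]; b <- sets[[j]]
    expect_equal(d[i, j], 1 - length(intersect(a, b)) / length(union(a, b)))
  }
  # identical accessory repertoires
  m2 <- gene_mat(rbind(c(1, 1, 0), c(1, 1, 1)))
  expect_equal(unname(jaccard_distances(m2)[1, 2]), 0)
  # disjoint nonempty repertoires
  m3 <- gene_mat(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(jaccard_distances(m3)[1, 2]), 1)
})

test_that("a pair of empty accessory repertoires gets distance 0, flagged", {
  m <- gene_mat(rbind(c(1, 1, 1), c(1, 1, 0)))
  # s3 lacks g02; s1 and s2 share identical (and s3-empty) sets
  expect_silent(d <- jaccard_distances(m))
  m4 <- gene_mat(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_warning(d4 <- jaccard_distances(m4), "empty")
  expect_equal(unname(d4[3, 4]), 0)
})

test_that("Jaccard matches vegan and satisfies the triangle inequality", {
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- gene_mat(matrix(rbinom(40 * 6, 1, 0.5), 40, 6))
  m <- m[rowSums(m) > 0 & rowSums(m) < 6, , drop = FALSE]  # accessory only
  d <- jaccard_distances(m)
  dv <- as.matrix(vegan::vegdist(t(m), method = "jaccard", binary = TRUE))
  expect_equal(unclass(d), unclass(dv), tolerance = 1e-12,
               ignore_attr = TRUE)
  n <- ncol(m)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("neighbor joining solves the three-point formulas exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 2)
})

test_that("neighbor joining recovers additive trees and their path lengths", {
  # ((A:1,B:2):1,(C:3,D:4)) -> AB|CD with internal branch 1
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 1, B = 2, C = 3, D = 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      same <- (i <= 2) == (j <= 2)
      d4[i, j] <- bl[i] + bl[j] + if (same) 0 else 1
    }
  }
  tr <- neighbor_joining(d4)
  expect_equal(cophenetic(tr)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-9)
  # 5-taxon caterpillar
  tr5 <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,(D:2,E:1):0.7):0.3);")
  d5 <- cophenetic(tr5)
  rec <- neighbor_joining(d5)
  expect_equal(cophenetic(rec)[rownames(d5), colnames(d5)], d5,
               tolerance = 1e-9)
  # ultrametric star: all internal branch lengths collapse to 0
  ds <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(ds) <- 0
  st <- neighbor_joining(ds)
  internal <- st$edge[, 2] > length(st$tip.label)
  expect_equal(st$edge.length[internal], rep(0, sum(internal)),
               tolerance = 1e-12)
  expect_error(neighbor_joining(ds[1:2, 1:2]), "at least 3")
})

test_that("sample order permutation permutes outputs consistently", {
  set.seed(31)
  m <- gene_mat(matrix(rbinom(60 * 6, 1, 0.5), 60, 6))
  m <- m[rowSums(m) > 0, ]
  d <- jaccard_distances(m)
  perm <- c(4, 2, 6, 1, 3, 5)
  dp <- jaccard_distances(m[, perm])
  expect_equal(unclass(dp), unclass(d[perm, perm]), ignore_attr = TRUE)
  t1 <- neighbor_joining(d); t2 <- neighbor_joining(dp)
  expect_equal(cophenetic(t2)[rownames(d), rownames(d)],
               cophenetic(t1)[rownames(d), rownames(d)], tolerance = 1e-9)
})

test_that("planted habitat genes pull clades apart in accessory Jaccard space", {
  cfg <- sim_config(n_clade_a = 5, n_clade_b = 6, core_length = 5000,
                    n_habitat_genes_a = 40, n_habitat_genes_b = 60,
                    n_shared_core_genes = 50, n_random_accessory = 100,
                    growth_replicates = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  d <- jaccard_distances(sim$genes)
  cl <- sim$truth$clade_assignment[rownames(d)]
  same <- outer(cl, cl, "==") & upper.tri(d)
  diff <- outer(cl, cl, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})
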