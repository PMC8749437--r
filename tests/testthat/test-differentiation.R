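aln_from <- function(strings, ids = paste0("s", seq_along(strings))) {
  core_alignment(matrix(unlist(strsplit(strings, "")), length(strings),
                        byrow = TRUE, dimnames = list(ids, NULL)))
}

test_that("extract_snps finds exactly the polymorphic ACGT columns", {
  expect_equal(nrow(extract_snps(aln_from(c("ACGT", "ACGT")))), 0)
  s <- extract_snps(aln_from(c("AAT", "AAT", "AAA")))
  expect_equal(s$pos, 2L)
  expect_equal(s$alleles, "A/T")
  expect_true(s$dimorphic)
  # gaps and N do not create polymorphism
  expect_equal(nrow(extract_snps(aln_from(c("AN-T", "AA-T", "AAGT")))), 0)
  s2 <- extract_snps(aln_from(c("ANGT", "AAGT", "AACT")))
  expect_equal(s2$pos, 2L)
})

test_that("extract_snps agrees with a brute-force column scan", {
  m <- rand_aln(6, 100, miss = 0.08, seed = 42)
  # make most columns invariant so the scan is non-trivial
  m[, 1:60] <- rep(m[1, 1:60], each = 6)
  expect_identical(extract_snps(core_alignment(m))$pos, snp_scan_oracle(m))
})

test_that("clade-specific SNPs require disjoint clade allele sets", {
  aln <- aln_from(c("AT", "AT", "TA", "TA"))
  cl <- toy_clades(rownames(aln), 2)
  cs <- clade_specific_snps(extract_snps(aln), cl)
  expect_equal(cs$pos, c(0L, 1L))
  # shared allele disqualifies: FL {A,T}, IA {A}
  aln2 <- aln_from(c("A", "A", "A", "T"))
  expect_equal(nrow(clade_specific_snps(extract_snps(aln2),
                                        toy_clades(rownames(aln2), 2))), 0)
  # swapping labels leaves the result unchanged
  swapped <- setNames(ifelse(cl == "IA", "FL", "IA"), names(cl))
  expect_equal(clade_specific_snps(extract_snps(aln), swapped)$pos, cs$pos)
})

test_that("sites where a clade is all-missing are skipped with a message", {
  aln <- aln_from(c("A-", "A-", "TT", "TA"))
  expect_message(
    cs <- clade_specific_snps(extract_snps(aln),
                              toy_clades(rownames(aln), 2)),
    "missing")
  expect_equal(cs$pos, 0L)
})

test_that("window_counts places SNPs in all covering windows", {
  fake_snps <- function(pos, len) {
    s <- tibble::tibble(pos = as.integer(pos))
    attr(s, "genome_length") <- len
    s
  }
  t1 <- window_counts(fake_snps(0, 10000))
  expect_equal(t1$value[t1$start == 0], 1)
  expect_equal(sum(t1$value), 1)
  t2 <- window_counts(fake_snps(2600, 10000))
  expect_equal(t2$value[t2$start %in% c(0, 2500)], c(1, 1))
  expect_equal(sum(t2$value), 2)
  # conservation: total count equals sum over SNPs of windows containing them
  pos <- seq(0, 99999, by = 100)
  tr <- window_counts(fake_snps(pos, 100000))
  per_snp <- vapply(pos, function(p) {
    sum(tr$start <= p & p < tr$end)
  }, numeric(1))
  expect_equal(sum(tr$value), sum(per_snp))
  # uniform density: every full window holds window/100 SNPs
  expect_equal(unique(tr$value[tr$end - tr$start == 5000]), 50)
  expect_warning(window_counts(fake_snps(10, 3000)), "truncated")
})

test_that("call_peaks thresholds at fold x mean and merges touching windows", {
  flat <- tibble::tibble(start = seq(0, 7500, 2500),
                         end = seq(5000, 12500, 2500), value = rep(5, 4))
  expect_equal(nrow(call_peaks(flat, fold = 4)), 0)
  spike <- tibble::tibble(start = seq(0, 47500, 2500),
                          end = seq(5000, 52500, 2500), value = rep(5, 20))
  spike$value[8] <- 50  # 50 >= 4 x mean (7.25); neighbours stay below
  pk <- call_peaks(spike, fold = 4)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(spike$start[8], spike$end[8]))
  # two separated bumps merge into exactly two peaks (hand-merged oracle)
  tr <- tibble::tibble(start = seq(0, 97500, 2500),
                       end = seq(5000, 102500, 2500), value = rep(1, 40))
  tr$value[3:5] <- 10; tr$value[25:26] <- 10
  mean_v <- mean(tr$value)  # 2.125, so threshold 8.5 < 10
  pk2 <- call_peaks(tr, fold = 4)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$start, tr$start[c(3, 25)])
  expect_equal(pk2$end, tr$end[c(5, 26)])
  expect_true(all(pk2$max_value >= 4 * mean_v))
  zero <- flat; zero$value <- 0
  expect_warning(call_peaks(zero), "mean")
})

test_that("F_ST is 1 for fixed differences and matches the all-pairs oracle", {
  aln <- aln_from(c("AAAA", "AAAA", "TTTT", "TTTT"))
  fst <- suppressWarnings(window_fst(aln, toy_clades(rownames(aln), 2),
                                     window = 4, step = 4))
  expect_equal(fst$value, 1)
  m <- rand_aln(12, 5000, miss = 0.05, seed = 7)
  cl <- toy_clades(rownames(m), 6)
  got <- window_fst(core_alignment(m), cl)
  want <- fst_oracle(m, cl)
  expect_equal(got$value, want$value, tolerance = 1e-12)
  expect_true(all(got$value <= 1 + 1e-12, na.rm = TRUE))
})

test_that("the estimator can be negative and is not clamped", {
  aln <- aln_from(c("AAAA", "TTTT", "AAAA", "TTTT"))
  fst <- suppressWarnings(window_fst(aln, toy_clades(rownames(aln), 2),
                                     window = 4, step = 4))
  expect_equal(fst$value, -1)  # pi_within = 1, pi_between = 0.5
})

test_that("panmictic clades show no differentiation on average", {
  means <- vapply(1:10, function(s) {
    set.seed(s)
    anc <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
    m <- t(vapply(1:8, function(i) {
      mut <- runif(4000) < 0.01
      x <- anc
      x[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
      x
    }, character(4000)))
    rownames(m) <- paste0("s", 1:8)
    tr <- window_fst(core_alignment(m), toy_clades(rownames(m), 4),
                     window = 4000, step = 4000)
    mean(tr$value, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("diverged clades beat their panmictic counterparts (paired seeds)", {
  diff_fst <- function(seed) {
    base <- list(n_clade_a = 4, n_clade_b = 4, core_length = 10000,
                 theta = 0.002, rho_rel = 0, n_habitat_genes_a = 0,
                 n_habitat_genes_b = 0, n_shared_core_genes = 1,
                 n_random_accessory = 0, growth_replicates = 0, seed = seed)
    div <- do.call(sim_config, c(base, split_depth = 0.02))
    pan <- do.call(sim_config, c(base, split_depth = 0))
    f <- function(cfg) {
      s <- simulate_dataset(cfg)
      mean(window_fst(s$alignment, s$truth$clade_assignment)$value,
           na.rm = TRUE)
    }
    f(div) - f(pan)
  }
  expect_true(all(vapply(1:10, diff_fst, numeric(1)) > 0))
})

test_that("genome-wide mean F_ST is nondecreasing in the clade split depth", {
  depths <- c(0.001, 0.005, 0.02, 0.05)
  mean_fst <- function(depth) {
    mean(vapply(1:10, function(s) {
      cfg <- sim_config(n_clade_a = 4, n_clade_b = 4, core_length = 10000,
                        theta = 0.002, rho_rel = 0, split_depth = depth,
                        n_habitat_genes_a = 0, n_habitat_genes_b = 0,
                        n_shared_core_genes = 1, n_random_accessory = 0,
                        growth_replicates = 0, seed = s)
      sim <- simulate_dataset(cfg)
      mean(window_fst(sim$alignment, sim$truth$clade_assignment)$value,
           na.rm = TRUE)
    }, numeric(1)))
  }
  curve <- vapply(depths, mean_fst, numeric(1))
  expect_true(all(diff(curve) >= 0))
})

test_that("pairwise identity matches a direct Hamming computation", {
  expect_equal(unname(pairwise_identity(aln_from(c("ACGT", "ACGT")))[1, 2]),
               100)
  m100 <- rand_aln(2, 100, seed = 1)
  m100[2, ] <- m100[1, ]; m100[2, 50] <- setdiff(c("A", "C", "G", "T"),
                                                 m100[1, 50])[1]
  expect_equal(unname(pairwise_identity(core_alignment(m100))[1, 2]), 99)
  m <- rand_aln(5, 1000, miss = 0.05, seed = 3)
  expect_equal(pairwise_identity(core_alignment(m)), identity_oracle(m),
               ignore_attr = TRUE)
})
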