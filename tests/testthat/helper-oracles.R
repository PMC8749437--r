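# Independent brute-force oracles used across the suite. These deliberately
# recompute everything with plain loops and direct slicing, sharing no code
# path with the package implementations they check.

# random alignment with optional missing data
rand_aln <- function(n, L, miss = 0, seed = NULL, prefix = "s") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L,
              dimnames = list(paste0(prefix, seq_len(n)), NULL))
  if (miss > 0) {
    hit <- runif(n * L) < miss
    m[hit] <- sample(c("N", "-"), sum(hit), replace = TRUE)
  }
  m
}

# per-column SNP scan: list of 0-based positions with >= 2 bases among ACGT
snp_scan_oracle <- function(m) {
  bases <- c("A", "C", "G", "T")
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    seen <- unique(m[, j])
    if (length(intersect(seen, bases)) >= 2) out <- c(out, j - 1L)
  }
  out
}

# Hudson F_ST per window by direct pair enumeration and column slicing
fst_oracle <- function(m, clades, window = 5000, step = 2500) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(m)
  starts <- seq(0, L - step, by = step)
  ends <- pmin(starts + window, L)
  keep <- ends - starts >= step
  starts <- starts[keep]; ends <- ends[keep]
  labs <- unique(clades[rownames(m)])
  vals <- rep(NA_real_, length(starts))
  for (w in seq_along(starts)) {
    cols <- (starts[w] + 1):ends[w]
    rate_pairs <- function(rows_i, rows_j = NULL) {
      rates <- numeric(0)
      same <- is.null(rows_j)
      if (same) rows_j <- rows_i
      for (i in rows_i) for (j in rows_j) {
        if (same && j <= i) next
        a <- m[i, cols]; b <- m[j, cols]
        ok <- a %in% bases & b %in% bases
        if (sum(ok) > 0) rates <- c(rates, sum(a[ok] != b[ok]) / sum(ok))
      }
      rates
    }
    g1 <- which(clades[rownames(m)] == labs[1])
    g2 <- which(clades[rownames(m)] == labs[2])
    w1 <- rate_pairs(g1); w2 <- rate_pairs(g2)
    bt <- rate_pairs(g1, g2)
    pw <- mean(c(if (length(g1) < 2) 0 else mean(w1),
                 if (length(g2) < 2) 0 else mean(w2)))
    pb <- if (length(bt) == 0) NA_real_ else mean(bt)
    if (!is.na(pb) && pb > 0 && !is.na(pw)) vals[w] <- 1 - pw / pb
  }
  list(start = starts, end = ends, value = vals)
}

# percent identity by direct comparison
identity_oracle <- function(m) {
  bases <- c("A", "C", "G", "T")
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% bases & m[j, ] %in% bases
    out[i, j] <- out[j, i] <- 100 * sum(m[i, ok] == m[j, ok]) / sum(ok)
  }
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mwu_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(combn(n, na), 2, u_of)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive Mantel p: all n! relabellings, correlation by explicit loops
mantel_enum_oracle <- function(a, b) {
  n <- nrow(a)
  vec <- function(m) {
    v <- numeric(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) v <- c(v, m[i, j])
    v
  }
  r_obs <- cor(vec(a), vec(b))
  perms <- gtools_perms(n)
  rs <- apply(perms, 1, function(p) cor(vec(a[p, p]), vec(b)))
  mean(rs >= r_obs - 1e-12)
}

# all permutations of 1..n as a matrix (rows), written independently
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- gtools_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in 1:n) {
    block <- cbind(k, matrix(setdiff(1:n, k)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# two-clade metadata helper
toy_clades <- function(samples, n_a) {
  setNames(rep(c("IA", "FL"), c(n_a, length(samples) - n_a)), samples)
}
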