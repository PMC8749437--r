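#' Sliding-window Hudson-type F_ST between two clades
#'
#' For each window the statistic is `1 - pi_within / pi_between`, where
#' `pi_within` is the unweighted mean of the two within-clade mean pairwise
#' difference rates and `pi_between` is the mean pairwise difference rate
#' across clades. Each pair's rate is mismatches over pairwise-valid sites
#' (sites where both sequences have a base in `A C G T`); pairs with no valid
#' site in a window drop out of that window's mean. Windows with
#' `pi_between = 0` (or no surviving between-clade comparison) are undefined
#' (`NA`) and excluded from the summary. The estimator is not clamped: it can
#' be negative when within-clade diversity exceeds between-clade divergence,
#' and equals 1 exactly when clades are internally invariant but differ.
#'
#' A clade represented by a single sample contributes a within-clade
#' diversity of 0 by convention (reported via a message).
#'
#' @param aln A [core_alignment()].
#' @param clades Two-label clade assignment (named vector or metadata frame).
#' @param window,step Window and step sizes in bp (defaults 5000 / 2500).
#' @return A `"cf_track"` tibble (`start`, `end`, `value`, `n_valid_sites`)
#'   with `attr(, "summary")`: a list with `mean`, `sd` and `n_defined`
#'   over defined windows.
#' @export
window_fst <- function(aln, clades, window = 5000, step = 2500) {
  aln <- if (inherits(aln, "core_alignment")) aln else core_alignment(aln)
  cl <- as_clades(clades, rownames(aln))
  labs <- unique(cl)
  if (length(labs) != 2) abort("Exactly 2 clades are required.")
  sizes <- table(cl)
  if (any(sizes == 1)) {
    inform(paste0("Singleton clade(s): ",
                  paste(names(sizes)[sizes == 1], collapse = ", "),
                  "; within-clade diversity taken as 0 there."))
  }
  L <- ncol(aln)
  lay <- window_layout(L, window, step)
  W <- nrow(lay)
  ij <- combn(nrow(aln), 2)
  npair <- ncol(ij)
  kind <- character(npair)
  nd <- nv <- matrix(0, npair, W)
  # per-site counts of surviving within/between comparisons (for n_valid_sites)
  wv <- bv <- integer(L)
  valid_base <- matrix(unclass(aln) %in% DNA_BASES, nrow(aln))
  s0 <- lay$start; s1 <- lay$end
  for (p in seq_len(npair)) {
    i <- ij[1, p]; j <- ij[2, p]
    kind[p] <- if (cl[i] != cl[j]) "between"
               else if (cl[i] == labs[1]) "within_1" else "within_2"
    valid <- valid_base[i, ] & valid_base[j, ]
    diff <- valid & (aln[i, ] != aln[j, ])
    if (kind[p] == "between") bv <- bv + valid else wv <- wv + valid
    cv <- c(0, cumsum(valid)); cd <- c(0, cumsum(diff))
    nv[p, ] <- cv[s1 + 1] - cv[s0 + 1]
    nd[p, ] <- cd[s1 + 1] - cd[s0 + 1]
  }
  rate <- nd / nv  # NaN where a pair has no valid site in a window
  grp_mean <- function(k) {
    r <- rate[kind == k, , drop = FALSE]
    if (nrow(r) == 0) return(rep(0, W))  # singleton clade convention
    out <- colMeans(r, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  pw <- (grp_mean("within_1") + grp_mean("within_2")) / 2
  pb <- grp_mean("between")
  fst <- ifelse(is.na(pb) | pb == 0, NA_real_, 1 - pw / pb)

  both <- (wv > 0 | all(kind == "between")) & bv > 0
  # with two singleton clades there is no within pair at all; every site with
  # a between comparison is then valid
  cboth <- c(0, cumsum(both))
  out <- mutate(lay, value = fst,
                n_valid_sites = as.integer(cboth[s1 + 1] - cboth[s0 + 1]))
  defined <- !is.na(fst)
  attr(out, "summary") <- list(mean = mean(fst[defined]),
                               sd = sd(fst[defined]),
                               n_defined = sum(defined))
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "stat") <- "fst"
  class(out) <- c("cf_track", class(out))
  out
}

#' Pairwise percent identity of aligned sequences
#'
#' Percent identical sites over pairwise-valid sites (both bases in
#' `A C G T`), an alignment-based analogue of an ANI summary. The diagonal is
#' 100. Pairs with no valid site are `NA` and flagged with a warning.
#'
#' @param aln A [core_alignment()].
#' @return Symmetric numeric matrix (percent) with sample dimnames.
#' @export
pairwise_identity <- function(aln) {
  aln <- if (inherits(aln, "core_alignment")) aln else core_alignment(aln)
  n <- nrow(aln)
  out <- matrix(100, n, n, dimnames = list(rownames(aln), rownames(aln)))
  valid_base <- matrix(unclass(aln) %in% DNA_BASES, n)
  undef <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      valid <- valid_base[i, ] & valid_base[j, ]
      nvalid <- sum(valid)
      if (nvalid == 0) {
        out[i, j] <- out[j, i] <- NA_real_
        undef <- undef + 1L
      } else {
        idn <- 100 * sum(valid & (aln[i, ] == aln[j, ])) / nvalid
        out[i, j] <- out[j, i] <- idn
      }
    }
  }
  if (undef > 0) {
    warn(sprintf("%d pair(s) had no pairwise-valid site; identity is NA.",
                 undef))
  }
  out
}

#' Summary row for a window track
#'
#' @param track A `"cf_track"` tibble.
#' @return One-row tibble with the statistic name, mean, sd and window counts.
#' @export
track_summary <- function(track) {
  s <- attr(track, "summary")
  if (is.null(s)) {
    v <- track$value[!is.na(track$value)]
    s <- list(mean = mean(v), sd = sd(v), n_defined = length(v))
  }
  tibble(stat = attr(track, "stat") %||% "value",
         mean = s$mean, sd = s$sd,
         n_windows = nrow(track), n_defined = s$n_defined,
         window = attr(track, "window") %||% NA_real_,
         step = attr(track, "step") %||% NA_real_)
}
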