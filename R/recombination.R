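#' Recombination-to-mutation substitution ratio from ClonalFrameML parameters
#'
#' `r/m = (R/theta) * delta * nu`: the relative impact of recombination
#' versus mutation on the per-site substitution rate, from the per-site
#' recombination initiation rate relative to mutation (`R/theta`), the mean
#' imported tract length (`delta`, bp) and the per-site divergence of
#' imported DNA (`nu`).
#'
#' @param r_over_theta,delta,nu Nonnegative finite parameters (vectorised).
#' @return `r_over_theta * delta * nu`.
#' @export
rm_from_params <- function(r_over_theta, delta, nu) {
  x <- c(r_over_theta, delta, nu)
  if (any(!is.finite(x))) abort("Parameters must be finite.")
  if (any(x < 0)) abort("Parameters must be nonnegative.")
  r_over_theta * delta * nu
}

#' r/m table from per-clade parameter rows
#'
#' @param params Tibble/data frame with columns `clade`, `n_events`,
#'   `r_over_theta`, `delta`, `nu`.
#' @return The input with an `r_m` column appended.
#' @export
rm_table <- function(params) {
  stopifnot(all(c("r_over_theta", "delta", "nu") %in% names(params)))
  mutate(as_tibble(params),
         r_m = rm_from_params(.data$r_over_theta, .data$delta, .data$nu))
}

#' Assign likely donor origins to recombination tracts
#'
#' For each event the recipient's imported tract is compared to the
#' homologous stretch of every panel sequence (leaves and internal nodes,
#' excluding the recipient itself) by p-distance with pairwise exclusion of
#' gaps/`N`. With `m` the minimum distance over the panel:
#' * `external` if `m > tau` — no sampled source is close enough;
#' * otherwise classification uses the clade-labelled sources only (nodes
#'   labelled `"ancestral"`/unassigned support the external test but carry
#'   no clade vote): with `m_c` their minimum distance, the clades of all
#'   labelled sources within `(1 + epsilon) * m_c` are collected — a single
#'   clade gives `within-clade` or `other-clade` (relative to the
#'   recipient's clade), both clades (or no labelled source) give
#'   `internal-ambiguous`. The band always contains its own argmin, so
#'   shrinking `epsilon` can only resolve ambiguity, never create it.
#' Tracts with fewer than `min_sites` pairwise-valid sites receive no call
#' (`NA`) and are flagged.
#'
#' @param events Tibble with `recipient`, `start`, `end` (0-based half-open).
#' @param aln The recipient alignment ([core_alignment()]).
#' @param panel List with `seqs` (matrix of panel sequences, rows named) and
#'   `clades` (named labels per row; clade labels or `"ancestral"`), e.g.
#'   from [source_panel()].
#' @param clades Clade assignment of the recipients (named vector or
#'   metadata frame).
#' @param epsilon Relative width of the ambiguity band (default 0.1).
#' @param tau Absolute p-distance cap beyond which the origin is external
#'   (default 0.045).
#' @param min_sites Minimum pairwise-valid tract sites for a call.
#' @return `events` with columns `origin_call`, `min_dist`,
#'   `min_dist_within`, `min_dist_other`, `n_valid_sites`, `low_sites`.
#' @export
assign_origins <- function(events, aln, panel, clades,
                           epsilon = 0.1, tau = 0.045, min_sites = 10) {
  aln <- if (inherits(aln, "core_alignment")) aln else core_alignment(aln)
  cl <- as_clades(clades, rownames(aln))
  labs <- unique(cl)
  if (length(labs) != 2) abort("Exactly 2 recipient clades are required.")
  seqs <- panel$seqs
  pcl <- panel$clades[rownames(seqs)]
  if (is.null(rownames(seqs)) || anyNA(pcl)) {
    abort("Panel rows must be named and labelled via panel$clades.")
  }
  L <- ncol(aln)
  if (ncol(seqs) != L) abort("Panel sequences must span the full alignment.")
  n_ev <- nrow(events)
  call <- rep(NA_character_, n_ev)
  m_all <- m_w <- m_o <- rep(NA_real_, n_ev)
  nvs <- integer(n_ev)
  for (e in seq_len(n_ev)) {
    rec <- events$recipient[e]
    s <- events$start[e]; t <- events$end[e]
    if (is.na(s) || is.na(t) || s < 0 || s >= t || t > L) {
      abort(sprintf("Event %d has an invalid tract [%s, %s).", e, s, t))
    }
    idx <- (s + 1L):t
    frag <- aln[rec, idx]
    keep <- rownames(seqs) != rec
    sub <- seqs[keep, idx, drop = FALSE]
    fv <- is_base(frag)
    valid <- sweep(matrix(sub %in% DNA_BASES, nrow(sub)), 2, fv, "&")
    diffs <- valid & sweep(sub, 2, frag, "!=")
    nv <- rowSums(valid)
    d <- ifelse(nv > 0, rowSums(diffs) / nv, NA_real_)
    nvs[e] <- max(nv, 0)
    usable <- !is.na(d)
    if (nvs[e] < min_sites || !any(usable)) next   # no call, flagged below
    d <- d[usable]
    src_clade <- pcl[keep][usable]
    own <- cl[[rec]]
    other <- setdiff(labs, own)
    m <- min(d)
    m_all[e] <- m
    if (any(src_clade == own)) m_w[e] <- min(d[src_clade == own])
    if (any(src_clade == other)) m_o[e] <- min(d[src_clade == other])
    if (m > tau) {
      call[e] <- "external"
    } else {
      labelled <- src_clade %in% labs
      if (!any(labelled)) {
        call[e] <- "internal-ambiguous"
      } else {
        m_c <- min(d[labelled])
        band <- labelled & d <= (1 + epsilon) * m_c
        in_clades <- unique(src_clade[band])
        call[e] <- if (length(in_clades) != 1) "internal-ambiguous"
                   else if (in_clades == own) "within-clade" else "other-clade"
      }
    }
  }
  mutate(as_tibble(events), origin_call = call,
         min_dist = m_all, min_dist_within = m_w, min_dist_other = m_o,
         n_valid_sites = nvs, low_sites = nvs < min_sites)
}

#' Summarize recombination origin calls per recipient clade
#'
#' Counts and percentages (1 decimal) of each origin class among the called
#' events of each recipient clade, with optional grouped combinations of
#' classes (e.g. within-clade plus external).
#'
#' @param events Tibble with `recipient` and `origin_call` columns (events
#'   with `NA` calls are dropped from the denominators).
#' @param clades Clade assignment of recipients; omit to summarise all
#'   events together.
#' @param groups Optional named list of class combinations, e.g.
#'   `list(endogenous_or_external = c("within-clade", "external"))`.
#' @return Tibble with `clade`, `origin_call` (or group name), `n`, `total`
#'   and `percent`.
#' @export
summarize_origins <- function(events, clades = NULL, groups = NULL) {
  ev <- filter(as_tibble(events), !is.na(.data$origin_call))
  if (nrow(ev) == 0) {
    return(tibble(clade = character(), origin_call = character(),
                  n = integer(), total = integer(), percent = numeric()))
  }
  ev$clade <- if (is.null(clades)) "all" else
    unname(as_clades(clades, unique(ev$recipient))[ev$recipient])
  base <- ev |>
    group_by(.data$clade, .data$origin_call) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(total = sum(.data$n),
           percent = round(100 * .data$n / .data$total, 1)) |>
    ungroup()
  if (!is.null(groups)) {
    extra <- purrr::imap(groups, function(classes, name) {
      ev |>
        group_by(.data$clade) |>
        summarise(n = sum(.data$origin_call %in% classes),
                  total = n(), .groups = "drop") |>
        mutate(origin_call = name,
               percent = round(100 * .data$n / .data$total, 1))
    })
    base <- bind_rows(base, bind_rows(extra))
  }
  arrange(base, .data$clade, .data$origin_call)
}

#' Read a ClonalFrameML importation-status table
#'
#' Parses the standard `*.importation_status.txt` output (columns `Node`,
#' `Beg`, `End`, 1-based inclusive) into the 0-based half-open event table
#' used throughout this package.
#'
#' @param path Path to the importation-status file.
#' @return Tibble with `recipient`, `start`, `end`.
#' @export
read_importation_status <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("Node", "Beg", "End")
  if (!all(need %in% names(x))) {
    abort("Expected columns Node, Beg, End in the importation-status file.")
  }
  tibble(recipient = as.character(x$Node),
         start = as.integer(x$Beg) - 1L,
         end = as.integer(x$End))
}

#' Read ClonalFrameML EM parameter output
#'
#' Parses the `*.em.txt` two-column (parameter, point estimate) output and
#' returns the recombination parameters, inverting `1/delta` to the mean
#' tract length.
#'
#' @param path Path to the EM output file.
#' @return Tibble with `r_over_theta`, `delta`, `nu`.
#' @export
read_cfml_params <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  key <- x[[1]]; val <- as.numeric(x[[2]])
  get1 <- function(k) if (k %in% key) val[match(k, key)] else NA_real_
  delta <- get1("delta")
  if (is.na(delta) && !is.na(get1("1/delta"))) delta <- 1 / get1("1/delta")
  tibble(r_over_theta = get1("R/theta"), delta = delta, nu = get1("nu"))
}
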