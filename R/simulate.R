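#' Configuration for the two-clade species simulator
#'
#' Parameters describing a bacterial species split into two habitat-associated
#' clades. Defaults emulate a 37-strain, two-habitat species: 8 insect-associated
#' ("IA") and 29 free-living ("FL") genomes, ~3% between-clade core divergence
#' (ANI ~97%), modest within-clade diversity, homologous recombination with
#' within-clade, other-clade and external donors, habitat-specific accessory
#' genes, geographically confounded habitat labels (Central American vs East
#' Asian centroids), and a growth-rate advantage of the IA clade under one
#' planted condition. The default core length (200 kb) is a working scale;
#' raise `core_length` for genome-scale experiments.
#'
#' @param n_clade_a,n_clade_b Number of samples in clades A and B.
#' @param core_length Alignment length in bp.
#' @param theta Per-site mutation probability on each terminal (clonal) branch.
#' @param split_depth Expected per-site divergence between the two clade
#'   ancestors (half accumulates on each ancestral branch).
#' @param rho_rel Recombination events per clonal mutation (the R/theta ratio);
#'   each sample receives `Poisson(rho_rel * theta * core_length)` imports.
#' @param tract_mean Mean imported tract length in bp (geometric lengths).
#' @param donor_div Per-site divergence of an imported tract from its donor
#'   class reference sequence.
#' @param donor_mix Probabilities over donor classes
#'   `c(within, other, external)`; must sum to 1 (not renormalised).
#' @param n_habitat_genes_a,n_habitat_genes_b Planted clade-specific accessory
#'   genes (universal in one clade, absent in the other).
#' @param n_shared_core_genes,n_random_accessory Core and random accessory
#'   gene counts for the gene matrix.
#' @param core_dup_prob Probability that a core gene carries a second copy in
#'   one random genome (exercises the single-copy-core definition).
#' @param gene_noise Probability of flipping any planted habitat-gene cell;
#'   0 keeps the planted signal exact.
#' @param geo_centroids List with elements `a` and `b`, each `c(lat, lon)` in
#'   decimal degrees, plus an optional `b2`: a second, far-away centroid for
#'   clade B (alternate clade-B samples are placed around it), emulating a
#'   free-living lineage collected from two distant regions. Set `b2 = NULL`
#'   for a single clade-B region.
#' @param geo_dispersion_km Gaussian jitter (km) of sample coordinates around
#'   their clade centroid.
#' @param clade_labels Habitat labels for clades A and B.
#' @param growth_effect Added growth-rate (ABS450/h) of clade A on
#'   `growth_effect_condition`.
#' @param growth_conditions,growth_effect_condition Condition names for the
#'   growth assay and the one condition carrying the planted effect.
#' @param growth_base_slope Baseline linear-phase slope (ABS450/h).
#' @param growth_noise_sd Additive Gaussian noise on absorbance readings.
#' @param growth_replicates Replicates per strain and condition.
#' @param growth_hours,growth_interval Assay duration and sampling interval (h).
#' @param seed Integer seed; identical configurations give identical datasets.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_clade_a = 8, n_clade_b = 29,
                       core_length = 200000,
                       theta = 0.002,
                       split_depth = 0.03,
                       rho_rel = 0.5,
                       tract_mean = 88,
                       donor_div = 0.005,
                       donor_mix = c(within = 0.6, other = 0.1, external = 0.3),
                       n_habitat_genes_a = 98, n_habitat_genes_b = 150,
                       n_shared_core_genes = 560, n_random_accessory = 740,
                       core_dup_prob = 0.02,
                       gene_noise = 0,
                       geo_centroids = list(a = c(lat = 10, lon = -84),
                                            b = c(lat = 35, lon = 105),
                                            b2 = c(lat = -30, lon = 70)),
                       geo_dispersion_km = 500,
                       clade_labels = c(a = "IA", b = "FL"),
                       growth_effect = 0.03,
                       growth_conditions = c("control", "iron_limited"),
                       growth_effect_condition = "iron_limited",
                       growth_base_slope = 0.05,
                       growth_noise_sd = 0.005,
                       growth_replicates = 3,
                       growth_hours = 48, growth_interval = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  if (core_length <= 0) abort("`core_length` must be positive.")
  if (!(core_length > tract_mean && tract_mean > 0)) {
    abort("Require core_length > tract_mean > 0.")
  }
  probs <- c(theta, split_depth, donor_div, gene_noise, core_dup_prob, donor_mix)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].")
  }
  if (length(donor_mix) != 3) {
    abort("`donor_mix` needs exactly 3 entries (within, other, external).")
  }
  if (abs(sum(donor_mix) - 1) > 1e-8) {
    abort(sprintf("`donor_mix` must sum to 1 (got %.6f); not renormalising.",
                  sum(donor_mix)))
  }
  names(cfg$donor_mix) <- c("within", "other", "external")
  counts <- c(n_clade_a, n_clade_b, n_habitat_genes_a, n_habitat_genes_b,
              n_shared_core_genes, n_random_accessory, growth_replicates)
  if (any(counts < 0)) abort("Counts must be nonnegative.")
  if (n_clade_a + n_clade_b < 2) abort("Need at least 2 samples in total.")
  if (rho_rel < 0) abort("`rho_rel` must be nonnegative.")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Mutate `seq` at sites drawn with probability `rate`, resampling uniformly
# among the 3 alternative bases (finite sites; homoplasy allowed).
mutate_sites <- function(seq, rate) {
  hit <- which(runif(length(seq)) < rate)
  if (length(hit) > 0) {
    seq[hit] <- vapply(seq[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
  }
  list(seq = seq, n = length(hit), pos = hit)
}

#' Simulate a two-clade species dataset with full ground truth
#'
#' Forward simulation on a star-within-clades genealogy: a species root gives
#' rise to two clade ancestors (split mutations half on each branch), each
#' leaf descends from its clade ancestor on an independent terminal branch
#' (clonal mutations at rate `theta`), and homologous recombination overwrites
#' geometric-length tracts with DNA from a within-clade, other-clade or
#' external donor (the external reference diverges from the root at
#' `3 * split_depth`). Tracts are placed without overlap within a recipient so
#' that donor truth and substitution accounting stay exact. The function also
#' emits a gene presence/copy-number matrix with planted clade-specific genes,
#' sample metadata with clade-confounded geography, and replicated growth
#' curves with a planted clade-by-condition effect.
#'
#' @param config A [sim_config()].
#' @return A list of class `"two_clade_sim"` with elements `alignment`
#'   (a [core_alignment()]), `genes` (gene x sample integer copy-number
#'   matrix), `metadata` (tibble: sample, habitat, lat, lon), `growth`
#'   (tibble: sample, condition, replicate, time_h, abs450), `truth`
#'   (class `"sim_truth"`: planted fixed-difference positions [0-based],
#'   recombination events with donor truth, clade assignment, planted gene
#'   ids, realized mutation/import counts, and ancestral node sequences), and
#'   the `config`.
#' @seealso [source_panel()] to assemble the node-plus-leaf panel used for
#'   recombination origin assignment; [realized_rm()] for the realized
#'   recombination-to-mutation substitution ratio.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  set.seed(config$seed)
  L <- config$core_length
  lab <- config$clade_labels
  ids_a <- sprintf("%s_%02d", lab[["a"]], seq_len(config$n_clade_a))
  ids_b <- sprintf("%s_%02d", lab[["b"]], seq_len(config$n_clade_b))
  samples <- c(ids_a, ids_b)
  clade_of <- setNames(rep(c(lab[["a"]], lab[["b"]]),
                           c(config$n_clade_a, config$n_clade_b)), samples)

  root <- sample(DNA_BASES, L, replace = TRUE)
  anc_a <- mutate_sites(root, config$split_depth / 2)$seq
  anc_b <- mutate_sites(root, config$split_depth / 2)$seq
  fixed_pos <- which(anc_a != anc_b) - 1L   # 0-based

  aln <- matrix("", nrow = length(samples), ncol = L,
                dimnames = list(samples, NULL))
  n_mut <- 0L
  for (s in samples) {
    anc <- if (clade_of[[s]] == lab[["a"]]) anc_a else anc_b
    m <- mutate_sites(anc, config$theta)
    aln[s, ] <- m$seq
    n_mut <- n_mut + m$n
  }

  # --- homologous recombination ---------------------------------------------
  n_imp <- 0L
  events <- list()
  ev_rate <- config$rho_rel * config$theta * L
  for (s in samples) {
    n_ev <- rpois(1, ev_rate)
    if (n_ev == 0) next
    occupied <- logical(L)
    own_anc <- if (clade_of[[s]] == lab[["a"]]) anc_a else anc_b
    other_anc <- if (clade_of[[s]] == lab[["a"]]) anc_b else anc_a
    for (k in seq_len(n_ev)) {
      len <- min(rgeom(1, 1 / config$tract_mean) + 1L, L)
      start <- NA_integer_
      for (try in 1:100) {  # non-overlapping placement within the recipient
        cand <- sample.int(L - len + 1L, 1) - 1L
        if (!any(occupied[(cand + 1L):(cand + len)])) { start <- cand; break }
      }
      if (is.na(start)) next
      occupied[(start + 1L):(start + len)] <- TRUE
      cls <- sample(c("within", "other", "external"), 1,
                    prob = config$donor_mix)
      idx <- (start + 1L):(start + len)
      # each external event draws an independent outside lineage, diverged
      # from the species root at 3 x split_depth
      template <- switch(cls, within = own_anc[idx], other = other_anc[idx],
                         external = mutate_sites(root[idx],
                                                 3 * config$split_depth)$seq)
      donor <- mutate_sites(template, config$donor_div)$seq
      n_imp <- n_imp + sum(donor != aln[s, idx])
      aln[s, idx] <- donor
      events[[length(events) + 1L]] <-
        tibble(recipient = s, start = start, end = start + len,
               donor_truth = cls)
    }
  }
  events <- if (length(events) > 0) bind_rows(events) else
    tibble(recipient = character(), start = integer(), end = integer(),
           donor_truth = character())

  genes <- simulate_gene_matrix(config, samples, clade_of)
  metadata <- simulate_metadata(config, samples, clade_of)
  growth <- simulate_growth(config, samples, clade_of)

  nodes <- rbind(anc_a = anc_a, anc_b = anc_b, root = root)
  truth <- structure(list(
    planted_fixed_diff_positions = fixed_pos,
    recomb_events = events,
    clade_assignment = clade_of,
    planted_genes = list(a = genes$planted_a, b = genes$planted_b),
    realized_mutation_count = n_mut,
    realized_imported_substitutions = n_imp,
    node_seqs = nodes,
    node_clades = c(anc_a = lab[["a"]], anc_b = lab[["b"]],
                    root = "ancestral")
  ), class = "sim_truth")

  structure(list(alignment = core_alignment(aln), genes = genes$matrix,
                 metadata = metadata, growth = growth, truth = truth,
                 config = config),
            class = "two_clade_sim")
}

simulate_gene_matrix <- function(config, samples, clade_of) {
  lab <- config$clade_labels
  in_a <- clade_of[samples] == lab[["a"]]
  blocks <- list()

  if (config$n_shared_core_genes > 0) {
    core <- matrix(1L, config$n_shared_core_genes, length(samples),
                   dimnames = list(sprintf("core_%04d",
                                           seq_len(config$n_shared_core_genes)),
                                   samples))
    dup <- which(runif(nrow(core)) < config$core_dup_prob)
    for (g in dup) core[g, sample.int(ncol(core), 1)] <- 2L
    blocks$core <- core
  }
  plant <- function(n, present, prefix) {
    if (n == 0) return(NULL)
    m <- matrix(rep(as.integer(present), each = n), n, length(samples),
                dimnames = list(sprintf("%s_%03d", prefix, seq_len(n)),
                                samples))
    if (config$gene_noise > 0) {
      flip <- matrix(runif(length(m)) < config$gene_noise, nrow(m))
      m[flip] <- 1L - m[flip]
    }
    m
  }
  blocks$hab_a <- plant(config$n_habitat_genes_a, in_a,
                        paste0(tolower(lab[["a"]]), "_gene"))
  blocks$hab_b <- plant(config$n_habitat_genes_b, !in_a,
                        paste0(tolower(lab[["b"]]), "_gene"))
  if (config$n_random_accessory > 0) {
    p <- runif(config$n_random_accessory, 0.15, 0.85)
    acc <- matrix(rbinom(config$n_random_accessory * length(samples), 1,
                         rep(p, times = length(samples))),
                  config$n_random_accessory, length(samples),
                  dimnames = list(sprintf("acc_%04d",
                                          seq_len(config$n_random_accessory)),
                                  samples))
    acc <- acc[rowSums(acc) > 0, , drop = FALSE]  # absent-everywhere: not pan
    blocks$acc <- acc
  }
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  m <- if (length(blocks) == 0) {
    matrix(integer(), 0, length(samples), dimnames = list(NULL, samples))
  } else {
    do.call(rbind, blocks)
  }
  list(matrix = m,
       planted_a = if (is.null(blocks$hab_a)) character() else
         rownames(blocks$hab_a),
       planted_b = if (is.null(blocks$hab_b)) character() else
         rownames(blocks$hab_b))
}

simulate_metadata <- function(config, samples, clade_of) {
  lab <- config$clade_labels
  cent <- config$geo_centroids
  km_lat <- 110.574
  lat <- lon <- numeric(length(samples))
  b_rank <- cumsum(clade_of[samples] == lab[["b"]])
  for (i in seq_along(samples)) {
    c0 <- if (clade_of[[samples[i]]] == lab[["a"]]) {
      cent$a
    } else if (!is.null(cent$b2) && b_rank[i] %% 2 == 0) {
      cent$b2   # alternate clade-B samples: second sampling region
    } else {
      cent$b
    }
    lat[i] <- c0[["lat"]] + rnorm(1, 0, config$geo_dispersion_km / km_lat)
    km_lon <- 111.320 * cos(c0[["lat"]] * pi / 180)
    lon[i] <- c0[["lon"]] + rnorm(1, 0, config$geo_dispersion_km / km_lon)
  }
  tibble(sample = samples, habitat = unname(clade_of[samples]),
         lat = pmin(pmax(lat, -90), 90),
         lon = ((lon + 180) %% 360) - 180)
}

simulate_growth <- function(config, samples, clade_of) {
  if (config$growth_replicates == 0 || length(config$growth_conditions) == 0) {
    return(tibble(sample = character(), condition = character(),
                  replicate = integer(), time_h = numeric(),
                  abs450 = numeric()))
  }
  lab <- config$clade_labels
  times <- seq(0, config$growth_hours, by = config$growth_interval)
  grid <- expand.grid(sample = samples, condition = config$growth_conditions,
                      replicate = seq_len(config$growth_replicates),
                      stringsAsFactors = FALSE)
  curves <- purrr::pmap(grid, function(sample, condition, replicate) {
    slope <- config$growth_base_slope +
      if (clade_of[[sample]] == lab[["a"]] &&
          condition == config$growth_effect_condition)
        config$growth_effect else 0
    t_lag <- runif(1, 4, 8)
    t_stop <- t_lag + runif(1, 8, 16)
    abs450 <- 0.05 + slope * (pmin(pmax(times, t_lag), t_stop) - t_lag) +
      rnorm(length(times), 0, config$growth_noise_sd)
    tibble(sample = sample, condition = condition,
           replicate = as.integer(replicate), time_h = times,
           abs450 = abs450)
  })
  bind_rows(curves)
}

#' Realized recombination-to-mutation substitution ratio
#'
#' The ratio of substitutions introduced by homologous recombination to
#' substitutions introduced by clonal mutation in a simulated dataset — the
#' realized counterpart of the parametric product computed by
#' [rm_from_params()].
#'
#' @param truth A `"sim_truth"` object from [simulate_dataset()].
#' @return A single number, imported substitutions per clonal mutation.
#' @export
realized_rm <- function(truth) {
  if (!inherits(truth, "sim_truth")) abort("`truth` must be a sim_truth.")
  if (truth$realized_mutation_count <= 0) {
    abort("r/m is undefined: no clonal mutations were realized.")
  }
  truth$realized_imported_substitutions / truth$realized_mutation_count
}

#' Assemble the donor source panel of a simulated dataset
#'
#' Combines the simulated leaf sequences with the clade ancestor and root
#' sequences recorded in the simulation truth, labelled by clade (the root is
#' labelled `"ancestral"`), in the form expected by [assign_origins()].
#'
#' @param sim A `"two_clade_sim"` object.
#' @return List with `seqs` (sequence matrix, rows = panel members) and
#'   `clades` (named labels per row).
#' @export
source_panel <- function(sim) {
  if (!inherits(sim, "two_clade_sim")) abort("`sim` must be a two_clade_sim.")
  seqs <- rbind(unclass(sim$alignment), sim$truth$node_seqs)
  clades <- c(sim$truth$clade_assignment, sim$truth$node_clades)
  list(seqs = seqs, clades = clades[rownames(seqs)])
}

#' @export
print.two_clade_sim <- function(x, ...) {
  cat(sprintf(
    "<two_clade_sim> %d samples (%s), %d bp core, %d genes, %d recomb events\n",
    nrow(x$alignment),
    paste(sprintf("%d %s", table(x$metadata$habitat)[unique(x$metadata$habitat)],
                  unique(x$metadata$habitat)), collapse = " + "),
    ncol(x$alignment), nrow(x$genes), nrow(x$truth$recomb_events)))
  invisible(x)
}
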