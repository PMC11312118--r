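# Synthetic-data generator: ground-truthed gene families, similarity hit
# tables, Cq tables and growth curves. Everything is seeded and deterministic
# so downstream inference can be benchmarked against planted truth.

#' Configuration for the gene-family / hit-table simulator
#'
#' Families are planted with one ancestral member per species plus, with
#' probability \code{dup_rate} per family and species, a within-species
#' duplicate. Similarity scores are simulated directly at the e-value level:
#' within-family pairs draw log-uniform e-values from
#' \code{within_family_evalue_range}, a fraction
#' \code{background_hit_fraction} of cross-family pairs draw from
#' \code{background_evalue_range}. The two ranges must not overlap; the gap
#' between them is the planted separation that the paralogy threshold scan
#' is expected to recover.
#'
#' @param n_species Number of species (ignored when \code{species} is given).
#' @param n_families Number of planted gene families.
#' @param dup_rate Probability, per family and species, of a within-species
#'   duplication event (adds one duplicate copy).
#' @param within_family_evalue_range Length-2 numeric, low/high e-value
#'   bounds for hits between members of the same family.
#' @param background_evalue_range Length-2 numeric, low/high e-value bounds
#'   for spurious cross-family hits. Must lie entirely above the
#'   within-family range.
#' @param background_hit_fraction Fraction of cross-family gene pairs that
#'   receive a background hit.
#' @param species Optional character vector of species labels.
#' @param seed Integer seed driving all draws.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_species = 4L,
                         n_families = 25L,
                         dup_rate = 0.3,
                         within_family_evalue_range = c(1e-100, 1e-30),
                         background_evalue_range = c(1e-6, 1e-4),
                         background_hit_fraction = 0.3,
                         species = NULL,
                         seed = 1L) {
  if (is.null(species)) {
    if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 1)
      stopf("n_species must be a positive count")
    species <- sprintf("sp%02d", seq_len(n_species))
  }
  if (anyDuplicated(species)) stopf("species labels must be unique")
  if (!is.numeric(n_families) || length(n_families) != 1L || n_families < 1)
    stopf("n_families must be a positive count")
  if (!is.numeric(dup_rate) || dup_rate < 0 || dup_rate > 1)
    stopf("dup_rate must be a probability in [0, 1]")
  if (!is.numeric(background_hit_fraction) ||
      background_hit_fraction < 0 || background_hit_fraction > 1)
    stopf("background_hit_fraction must be a probability in [0, 1]")
  chk_range <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
      stopf("%s must be an increasing pair of positive e-values", what)
  }
  chk_range(within_family_evalue_range, "within_family_evalue_range")
  chk_range(background_evalue_range, "background_evalue_range")
  if (within_family_evalue_range[2] >= background_evalue_range[1])
    stopf("e-value ranges must not overlap: within-family max (%g) must lie below background min (%g)",
          within_family_evalue_range[2], background_evalue_range[1])
  structure(list(
    species = as.character(species),
    n_families = as.integer(n_families),
    dup_rate = dup_rate,
    within_family_evalue_range = within_family_evalue_range,
    background_evalue_range = background_evalue_range,
    background_hit_fraction = background_hit_fraction,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Simulate planted gene families across species
#'
#' Each family receives one ancestral gene per species; with probability
#' \code{dup_rate} per (family, species) a within-species duplicate is added,
#' forming a duplication group. The returned truth object is the reference
#' against which orthology and paralogy inference is scored.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A \code{family_truth} list with elements \code{members} (data
#'   frame: \code{family_id}, \code{species}, \code{gene_id},
#'   \code{is_duplicate}), \code{species} (roster) and \code{config}.
#' @export
simulate_families <- function(config) {
  if (!inherits(config, "synth_config")) stopf("config must be a synth_config")
  set.seed(config$seed)
  fam_ids <- sprintf("fam%03d", seq_len(config$n_families))
  rows <- vector("list", config$n_families * length(config$species))
  k <- 0L
  for (f in fam_ids) {
    for (sp in config$species) {
      n_dup <- if (stats::runif(1) < config$dup_rate) 1L else 0L
      ids <- sprintf("%s_%s_g%d", sp, f, seq_len(1L + n_dup))
      k <- k + 1L
      rows[[k]] <- data.frame(
        family_id = f, species = sp, gene_id = ids,
        is_duplicate = c(FALSE, rep(TRUE, n_dup)),
        stringsAsFactors = FALSE
      )
    }
  }
  members <- do.call(rbind, rows)
  rownames(members) <- NULL
  structure(list(members = members, species = config$species, config = config),
            class = "family_truth")
}

#' Planted duplication groups of a family truth
#'
#' @param truth A \code{family_truth}.
#' @return Data frame with one row per (family, species) duplication group of
#'   size >= 2: \code{family_id}, \code{species}, \code{size}.
#' @export
duplication_groups <- function(truth) {
  if (!inherits(truth, "family_truth")) stopf("truth must be a family_truth")
  m <- truth$members
  agg <- stats::aggregate(list(size = m$gene_id),
                          by = list(family_id = m$family_id, species = m$species),
                          FUN = length)
  agg <- agg[agg$size >= 2L, , drop = FALSE]
  agg <- agg[order(agg$family_id, agg$species), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.family_truth <- function(x, ...) {
  cat(sprintf("family_truth: %d families, %d species, %d genes (%d duplicates)\n",
              length(unique(x$members$family_id)), length(x$species),
              nrow(x$members), sum(x$members$is_duplicate)))
  invisible(x)
}

log10_uniform <- function(n, range) 10^stats::runif(n, log10(range[1]), log10(range[2]))

# bitscore as a decreasing function of e-value plus a small jitter that never
# overturns the e-value order across the planted ranges
sim_bitscore <- function(evalue) {
  round(-log10(pmax(evalue, 1e-200)) * 2 + stats::runif(length(evalue), 0, 0.4), 1)
}

#' Simulate an all-vs-all similarity hit table from planted families
#'
#' Every within-family gene pair is emitted in both directions with e-values
#' drawn log-uniformly from the within-family range (the two directions draw
#' independently, as real reciprocal searches do). A fraction of cross-family
#' pairs receives background hits from the background range. Self-hits are
#' emitted with e-value 0.
#'
#' @param truth A \code{family_truth} from \code{\link{simulate_families}}.
#' @param config The \code{\link{synth_config}} used to build it.
#' @param seed Seed for the score draws; defaults to \code{config$seed}.
#' @return A \code{\link{hit_table}}.
#' @export
simulate_hit_table <- function(truth, config = truth$config, seed = config$seed) {
  if (!inherits(truth, "family_truth")) stopf("truth must be a family_truth")
  set.seed(seed)
  m <- truth$members
  genes <- m$gene_id
  species_of <- stats::setNames(m$species, genes)
  fam_of <- stats::setNames(m$family_id, genes)

  pair_rows <- function(a, b, range) {
    n <- length(a)
    e_ab <- log10_uniform(n, range)
    e_ba <- log10_uniform(n, range)
    within <- range[2] <= config$within_family_evalue_range[2]
    ident <- function(k) round(stats::runif(k, if (within) 55 else 20,
                                            if (within) 95 else 35), 1)
    len <- sample(150:600, n, replace = TRUE)
    make <- function(q, s, e, id, l) data.frame(
      query_id = q, subject_id = s, pct_identity = id, align_len = l,
      mismatches = as.integer(round(l * (100 - id) / 100)), gap_opens = 0L,
      q_start = 1L, q_end = l, s_start = 1L, s_end = l,
      evalue = e, bitscore = sim_bitscore(e), stringsAsFactors = FALSE
    )
    rbind(make(a, b, e_ab, ident(n), len), make(b, a, e_ba, ident(n), len))
  }

  blocks <- list()
  # self-hits
  blocks[[1]] <- data.frame(
    query_id = genes, subject_id = genes, pct_identity = 100, align_len = 400L,
    mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = 400L,
    s_start = 1L, s_end = 400L, evalue = 0, bitscore = 800,
    stringsAsFactors = FALSE
  )
  # within-family pairs (all species combinations, including duplicates)
  idx <- utils::combn(length(genes), 2)
  same_family <- fam_of[genes[idx[1, ]]] == fam_of[genes[idx[2, ]]]
  if (any(same_family)) {
    blocks[[length(blocks) + 1L]] <- pair_rows(
      genes[idx[1, same_family]], genes[idx[2, same_family]],
      config$within_family_evalue_range
    )
  }
  # background cross-family pairs
  cross <- which(!same_family)
  if (length(cross) && config$background_hit_fraction > 0) {
    take <- cross[stats::runif(length(cross)) < config$background_hit_fraction]
    if (length(take)) {
      blocks[[length(blocks) + 1L]] <- pair_rows(
        genes[idx[1, take]], genes[idx[2, take]],
        config$background_evalue_range
      )
    }
  }
  hits <- do.call(rbind, blocks)
  rownames(hits) <- NULL
  hit_table(hits, species_of)
}

#' Ground truth for the Cq-table simulator
#'
#' Defaults mirror an RT-qPCR screen in \emph{Amphidinium carterae}: five
#' candidate reference genes (ATUB, BTUB, UB, CDK, GAPDH, of which CDK and UB
#' are planted as the stable pair), four writer/eraser targets, a control and
#' four stress conditions (nitrogen depletion, phosphate depletion, and Zn
#' addition at 5x and 10x). Treatment effects are in Cq cycles: a negative
#' effect lowers Cq, i.e. up-regulates (one cycle = one log2 fold at
#' efficiency 2).
#'
#' @param genes Data frame with columns \code{gene}, \code{role}
#'   (\code{"candidate_RG"} or \code{"target"}), \code{baseline_cq},
#'   \code{noise_sd} (cycles), \code{efficiency} (fold per cycle, in (1, 2]).
#' @param conditions Character vector of condition labels; the first is the
#'   control.
#' @param effects Data frame \code{gene}, \code{condition},
#'   \code{effect_cycles}; omitted combinations have effect 0.
#' @param loading_shift_sd SD (cycles) of the per-sample loading shift.
#' @return A \code{cq_truth} list.
#' @export
cq_truth <- function(genes = NULL, conditions = NULL, effects = NULL,
                     loading_shift_sd = 0.3) {
  if (is.null(genes)) {
    genes <- data.frame(
      gene = c("ATUB", "BTUB", "UB", "CDK", "GAPDH",
               "ALKBH9B", "ALKBH10B", "FIP37", "MTB"),
      role = c(rep("candidate_RG", 5), rep("target", 4)),
      baseline_cq = c(22, 23, 21, 24, 20, 26, 27, 25, 28),
      noise_sd = c(0.5, 0.8, 0.15, 0.15, 0.9, 0.3, 0.3, 0.3, 0.3),
      efficiency = 2,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(conditions))
    conditions <- c("control", "N_depletion", "P_depletion", "Zn5", "Zn10")
  if (is.null(effects)) {
    effects <- data.frame(
      gene = c("ALKBH10B", "ALKBH10B", "ALKBH10B",
               "ALKBH9B", "ALKBH9B", "ALKBH9B", "FIP37"),
      condition = c("P_depletion", "Zn5", "Zn10",
                    "P_depletion", "Zn5", "Zn10", "Zn5"),
      effect_cycles = c(-2.5, -3.2, 6.1, -2.0, -2.4, 2.7, -1.5),
      stringsAsFactors = FALSE
    )
  }
  need <- c("gene", "role", "baseline_cq", "noise_sd", "efficiency")
  if (!all(need %in% names(genes))) stopf("genes must have columns %s", toString(need))
  if (any(genes$noise_sd < 0)) stopf("noise SDs must be >= 0")
  if (any(genes$efficiency <= 1 | genes$efficiency > 2))
    stopf("efficiencies must lie in (1, 2]")
  if (anyDuplicated(genes$gene)) stopf("gene labels must be unique")
  if (length(conditions) < 1) stopf("at least one condition required")
  bad <- setdiff(effects$gene, genes$gene)
  if (length(bad)) stopf("effects reference unknown genes: %s", toString(bad))
  bad <- setdiff(effects$condition, conditions)
  if (length(bad)) stopf("effects reference unknown conditions: %s", toString(bad))
  structure(list(genes = genes, conditions = conditions, effects = effects,
                 loading_shift_sd = loading_shift_sd),
            class = "cq_truth")
}

#' Simulate a Cq table with planted effects and noise
#'
#' Cq(gene, sample) = gene baseline + per-sample loading shift + treatment
#' effect + Normal(0, gene noise SD).
#'
#' @param truth A \code{\link{cq_truth}}.
#' @param n_samples_per_condition Replicates per condition (>= 1).
#' @param seed Integer seed.
#' @return A \code{\link{cq_table}} carrying the truth as attribute
#'   \code{"truth"}.
#' @export
simulate_cq_table <- function(truth = cq_truth(), n_samples_per_condition = 3L,
                              seed = 1L) {
  if (!inherits(truth, "cq_truth")) stopf("truth must be a cq_truth")
  if (n_samples_per_condition < 1) stopf("n_samples_per_condition must be >= 1")
  set.seed(seed)
  genes <- truth$genes
  conds <- rep(truth$conditions, each = n_samples_per_condition)
  samples <- sprintf("%s_r%d", conds,
                     rep(seq_len(n_samples_per_condition), length(truth$conditions)))
  shift <- stats::rnorm(length(samples), 0, truth$loading_shift_sd)
  eff_mat <- matrix(0, nrow(genes), length(samples),
                    dimnames = list(genes$gene, samples))
  if (nrow(truth$effects)) {
    for (i in seq_len(nrow(truth$effects))) {
      e <- truth$effects[i, ]
      eff_mat[e$gene, conds == e$condition] <- e$effect_cycles
    }
  }
  noise <- matrix(stats::rnorm(nrow(genes) * length(samples)),
                  nrow(genes)) * genes$noise_sd
  cq <- genes$baseline_cq + eff_mat +
    matrix(shift, nrow(genes), length(samples), byrow = TRUE) + noise
  dimnames(cq) <- list(genes$gene, samples)
  out <- cq_table(cq,
                  gene_info = genes[, c("gene", "role")],
                  sample_info = data.frame(sample = samples, condition = conds,
                                           stringsAsFactors = FALSE),
                  efficiency = stats::setNames(genes$efficiency, genes$gene))
  attr(out, "truth") <- list(truth = truth, loading_shift = shift)
  out
}

#' Simulate an exponential growth series
#'
#' N(t) = n0 * exp(rate * t) * (1 + eps), eps ~ Normal(0, noise_cv).
#'
#' @param rate Net growth rate, per day.
#' @param n0 Initial cell concentration, cells/mL (default 5000).
#' @param days Numeric vector of sampling times in days.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return A \code{growth_series} data frame with columns \code{day},
#'   \code{density}.
#' @export
simulate_growth <- function(rate = 0.45, n0 = 5000, days = 0:7,
                            noise_cv = 0.05, seed = 1L) {
  if (!is.numeric(n0) || n0 <= 0) stopf("n0 must be > 0")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  set.seed(seed)
  eps <- if (noise_cv > 0) stats::rnorm(length(days), 0, noise_cv) else 0
  dens <- n0 * exp(rate * days) * (1 + eps)
  if (any(dens <= 0))
    stopf("noise_cv %g produced non-positive densities; use a smaller value", noise_cv)
  structure(data.frame(day = days, density = dens),
            class = c("growth_series", "data.frame"), rate = rate)
}

# writers / readers ----------------------------------------------------------

#' Write and read family truth tables
#'
#' Plain TSV round-trip of the planted family membership.
#'
#' @param truth A \code{family_truth}.
#' @param path Output/input TSV path.
#' @return \code{read_family_truth} returns a \code{family_truth} (without
#'   the generating config).
#' @export
write_family_truth <- function(truth, path) {
  utils::write.table(truth$members, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_truth
#' @export
read_family_truth <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$is_duplicate <- as.logical(m$is_duplicate)
  structure(list(members = m, species = sort(unique(m$species)), config = NULL),
            class = "family_truth")
}

#' Write a growth series to TSV
#' @param series A \code{growth_series} data frame.
#' @param path Output/input TSV path.
#' @export
write_growth_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_series
#' @export
read_growth_series <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(d, class = c("growth_series", "data.frame"))
}
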