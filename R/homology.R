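# Homology inference from BLAST tabular (outfmt-6) hits: bidirectional best
# hits for orthology, and a paralogy e-value cutoff chosen to maximize the
# number of within-species duplicated-gene networks.

OUTFMT6_COLS <- c("query_id", "subject_id", "pct_identity", "align_len",
                  "mismatches", "gap_opens", "q_start", "q_end",
                  "s_start", "s_end", "evalue", "bitscore")

#' Construct a hit table
#'
#' Wraps a 12-column data frame of similarity hits (outfmt-6 semantics)
#' together with a gene-to-species map covering every query and subject id.
#'
#' @param hits Data frame with the outfmt-6 columns (\code{query_id},
#'   \code{subject_id}, \code{pct_identity}, \code{align_len},
#'   \code{mismatches}, \code{gap_opens}, \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end}, \code{evalue}, \code{bitscore}).
#' @param species_of Named character vector mapping gene id to species, or a
#'   function of gene ids returning species labels (see
#'   \code{\link{species_from_prefix}}).
#' @return A \code{hit_table} object.
#' @export
hit_table <- function(hits, species_of) {
  missing_cols <- setdiff(OUTFMT6_COLS, names(hits))
  if (length(missing_cols)) stopf("hits lacks columns: %s", toString(missing_cols))
  if (any(hits$evalue < 0)) stopf("e-values must be >= 0")
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stopf("pct_identity must lie in [0, 100]")
  genes <- unique(c(hits$query_id, hits$subject_id))
  if (is.function(species_of)) {
    species_of <- stats::setNames(species_of(genes), genes)
  }
  unmapped <- genes[!genes %in% names(species_of) | is.na(species_of[genes])]
  if (length(unmapped))
    stopf("gene ids without a species mapping: %s%s",
          toString(utils::head(unmapped, 5)),
          if (length(unmapped) > 5) sprintf(" (and %d more)", length(unmapped) - 5) else "")
  structure(list(hits = hits, species_of = species_of[genes]),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("hit_table: %d hits, %d genes, %d species\n",
              nrow(x$hits), length(x$species_of),
              length(unique(x$species_of))))
  invisible(x)
}

#' Species-from-id-prefix rule
#'
#' Returns a function mapping gene ids to the substring before the first
#' separator, for id schemes like \code{"sp01_fam003_g1"}.
#'
#' @param sep Separator character (default \code{"_"}).
#' @return A function usable as \code{species_of} in \code{\link{hit_table}}.
#' @export
species_from_prefix <- function(sep = "_") {
  function(ids) sub(paste0(sep, ".*$"), "", ids)
}

#' Read a BLAST tabular (outfmt-6) hit file
#'
#' Parses a 12-column tab-separated hit file (the \code{-outfmt 6} /
#' \code{-m 8} dialect, no header) and resolves every gene to a species.
#'
#' @param path Path to the TSV.
#' @param species_of As in \code{\link{hit_table}}.
#' @return A \code{\link{hit_table}}.
#' @export
read_hit_table <- function(path, species_of) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0L) stopf("empty hit file: %s", path)
  bad <- which(nf != 12L)
  if (length(bad))
    stopf("line %d of %s has %d columns; expected 12", bad[1], path, nf[bad[1]])
  hits <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                            col.names = OUTFMT6_COLS, stringsAsFactors = FALSE)
  hit_table(hits, species_of)
}

#' Write a hit table as outfmt-6 TSV
#' @param table A \code{\link{hit_table}}.
#' @param path Output path.
#' @export
write_hit_table <- function(table, path) {
  utils::write.table(table$hits[, OUTFMT6_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read the gene-to-species map as a two-column TSV
#' @param table A \code{\link{hit_table}} (for writing).
#' @param path TSV path.
#' @export
write_species_map <- function(table, path) {
  utils::write.table(
    data.frame(gene_id = names(table$species_of), species = table$species_of),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_map
#' @export
read_species_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$species, d$gene_id)
}

# ordering used everywhere a "best" hit is taken: minimum e-value, then
# maximum bitscore, then lexicographically smallest subject id
best_row <- function(hits) {
  hits[order(hits$evalue, -hits$bitscore, hits$subject_id), , drop = FALSE][1, , drop = FALSE]
}

#' Best hit of a gene in a target species
#'
#' The subject in \code{target_species} with minimum e-value; ties broken by
#' maximum bitscore, then lexicographically smallest subject id.
#'
#' @param table A \code{\link{hit_table}}.
#' @param gene Query gene id.
#' @param target_species Species to search in.
#' @param evalue_ceiling Hits above this e-value are ignored.
#' @return The best subject gene id, or \code{NA_character_} if none.
#' @export
best_hit <- function(table, gene, target_species, evalue_ceiling = Inf) {
  h <- table$hits
  keep <- h$query_id == gene &
    table$species_of[h$subject_id] == target_species &
    h$subject_id != gene &
    h$evalue <= evalue_ceiling
  if (!any(keep)) return(NA_character_)
  best_row(h[keep, , drop = FALSE])$subject_id
}

# per-query best subject for a whole query set, vectorized
best_hits_all <- function(hits) {
  o <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Bidirectional best hits between two species
#'
#' A pair (a, b) is emitted iff b is the best hit of a in species B and a is
#' the best hit of b in species A, with both directions at or below the
#' e-value ceiling.
#'
#' @param table A \code{\link{hit_table}}.
#' @param species_a,species_b Distinct species labels.
#' @param evalue_ceiling Working e-value ceiling (default 1e-5).
#' @return Data frame \code{gene_a}, \code{gene_b}, \code{species_a},
#'   \code{species_b}, \code{evalue_ab}, \code{evalue_ba}, sorted by
#'   \code{gene_a}; each unordered pair appears once, with \code{gene_a}
#'   belonging to \code{species_a}.
#' @export
bbh_orthologs <- function(table, species_a, species_b, evalue_ceiling = 1e-5) {
  if (identical(species_a, species_b))
    stopf("species_a and species_b must differ")
  sp <- table$species_of
  for (s in c(species_a, species_b))
    if (!s %in% sp) stopf("species '%s' absent from hit table", s)
  h <- table$hits
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      species_a = character(), species_b = character(),
                      evalue_ab = numeric(), evalue_ba = numeric(),
                      stringsAsFactors = FALSE)
  ab <- h[sp[h$query_id] == species_a & sp[h$subject_id] == species_b &
            h$evalue <= evalue_ceiling, , drop = FALSE]
  ba <- h[sp[h$query_id] == species_b & sp[h$subject_id] == species_a &
            h$evalue <= evalue_ceiling, , drop = FALSE]
  if (!nrow(ab) || !nrow(ba)) return(empty)
  best_ab <- best_hits_all(ab)
  best_ba <- best_hits_all(ba)
  back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  mutual <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  best_ab <- best_ab[mutual, , drop = FALSE]
  if (!nrow(best_ab)) return(empty)
  e_ba <- stats::setNames(best_ba$evalue, best_ba$query_id)
  out <- data.frame(gene_a = best_ab$query_id, gene_b = best_ab$subject_id,
                    species_a = species_a, species_b = species_b,
                    evalue_ab = best_ab$evalue,
                    evalue_ba = unname(e_ba[best_ab$subject_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bidirectional best hits for all species pairs
#'
#' @param table A \code{\link{hit_table}}.
#' @param evalue_ceiling As in \code{\link{bbh_orthologs}}.
#' @return Row-bound \code{\link{bbh_orthologs}} results over every
#'   unordered species pair, in lexicographic pair order.
#' @export
bbh_all_pairs <- function(table, evalue_ceiling = 1e-5) {
  spp <- sort(unique(table$species_of))
  out <- list()
  for (i in seq_along(spp)) for (j in seq_along(spp)) if (i < j)
    out[[length(out) + 1L]] <- bbh_orthologs(table, spp[i], spp[j], evalue_ceiling)
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_a = character(), gene_b = character(),
                      species_a = character(), species_b = character(),
                      evalue_ab = numeric(), evalue_ba = numeric(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# within-species undirected candidate paralog pairs with their effective
# e-value: min over the two search directions
within_species_pairs <- function(table, species) {
  sp <- table$species_of
  if (!species %in% sp) stopf("species '%s' absent from hit table", species)
  h <- table$hits
  keep <- sp[h$query_id] == species & sp[h$subject_id] == species &
    h$query_id != h$subject_id
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  key <- paste(a, b, sep = "\r")
  ev <- tapply(h$evalue, key, min)
  ab <- strsplit(names(ev), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(ab, `[`, "", 1L),
                    gene_b = vapply(ab, `[`, "", 2L),
                    evalue = as.numeric(ev), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default e-value grid for the paralogy threshold scan
#'
#' Decade steps from 1e-5 down to 1e-180.
#'
#' @return Numeric vector of cutoffs, ascending.
#' @export
default_evalue_grid <- function() 10^seq(-180, -5)

#' Scan e-value cutoffs to maximize the number of duplicated-gene networks
#'
#' For each cutoff, within-species genes are joined by an edge when either
#' search direction of the pair has e-value at or below the cutoff
#' (self-hits excluded); the objective is the number of connected components
#' of size >= 2 ("duplicated-gene networks"), summed over the given species.
#' The chosen cutoff attains the maximum; ties go to the most stringent
#' (smallest) cutoff. The scan is incremental (edges sorted once, merged with
#' a union-find as the cutoff loosens).
#'
#' @param table A \code{\link{hit_table}}.
#' @param species One species label (per-species cutoff, the default usage),
#'   or several to optimize one pooled cutoff.
#' @param grid Cutoff grid with >= 2 values (default
#'   \code{\link{default_evalue_grid}}).
#' @return A \code{paralog_scan} list: \code{grid} (ascending),
#'   \code{count_at} (named by cutoff), \code{chosen_cutoff},
#'   \code{species}, \code{pooled}.
#' @export
paralog_threshold_scan <- function(table, species, grid = default_evalue_grid()) {
  if (length(grid) < 2L) stopf("grid must contain at least 2 cutoffs")
  grid <- sort(unique(grid))
  pairs <- do.call(rbind, lapply(species, function(s) within_species_pairs(table, s)))
  counts <- integer(length(grid))
  if (nrow(pairs)) {
    genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
    ia <- match(pairs$gene_a, genes)
    ib <- match(pairs$gene_b, genes)
    o <- order(pairs$evalue)
    ia <- ia[o]; ib <- ib[o]; ev <- pairs$evalue[o]
    parent <- seq_along(genes)
    size <- rep(1L, length(genes))
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    n_dup <- 0L  # running count of components of size >= 2
    e <- 1L
    for (g in seq_along(grid)) {
      while (e <= length(ev) && ev[e] <= grid[g]) {
        ra <- find(ia[e]); rb <- find(ib[e])
        if (ra != rb) {
          sa <- size[ra]; sb <- size[rb]
          if (sa == 1L && sb == 1L) n_dup <- n_dup + 1L
          else if (sa > 1L && sb > 1L) n_dup <- n_dup - 1L
          if (sa < sb) { tmp <- ra; ra <- rb; rb <- tmp }
          parent[rb] <- ra
          size[ra] <- sa + sb
        }
        e <- e + 1L
      }
      counts[g] <- n_dup
    }
  }
  chosen <- grid[which.max(counts)]  # first max = smallest cutoff on ties
  structure(list(grid = grid,
                 count_at = stats::setNames(counts, sprintf("%g", grid)),
                 chosen_cutoff = chosen, species = species,
                 pooled = length(species) > 1L),
            class = "paralog_scan")
}

#' @export
print.paralog_scan <- function(x, ...) {
  cat(sprintf("paralog_scan (%s): chosen cutoff %g, %d duplicated-gene networks\n",
              paste(x$species, collapse = "+"), x$chosen_cutoff,
              max(x$count_at)))
  invisible(x)
}

#' Within-species paralog edges at a cutoff
#'
#' Undirected within-species edges whose effective e-value (minimum over the
#' two search directions) is at or below the cutoff; self-loops excluded.
#'
#' @param table A \code{\link{hit_table}}.
#' @param species Species label.
#' @param cutoff E-value cutoff, typically
#'   \code{paralog_threshold_scan(...)$chosen_cutoff}.
#' @return Data frame \code{gene_a}, \code{gene_b}, \code{species},
#'   \code{evalue}, with \code{gene_a < gene_b}, sorted.
#' @export
paralog_edges <- function(table, species, cutoff) {
  pairs <- within_species_pairs(table, species)
  out <- pairs[pairs$evalue <= cutoff, , drop = FALSE]
  out$species <- rep(species, nrow(out))
  rownames(out) <- NULL
  out[, c("gene_a", "gene_b", "species", "evalue")]
}

#' Write a threshold-scan table to TSV
#' @param scan A \code{paralog_scan}.
#' @param path Output path.
#' @export
write_scan_table <- function(scan, path) {
  utils::write.table(
    data.frame(cutoff = scan$grid, n_duplicated_networks = unname(scan$count_at),
               chosen = scan$grid == scan$chosen_cutoff),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
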