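# Independent brute-force reference implementations used to cross-check the
# package's vectorized/incremental code paths. Deliberately written in the
# plainest possible style (per-element loops, no shared helpers).

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# every ATG anywhere, extended codon-by-codon to the first stop or the last
# complete codon
oracle_find_orfs <- function(seq, min_aa_len, strands = "both") {
  stops <- c("TAA", "TAG", "TGA")
  scan_one <- function(s, strand) {
    n <- nchar(s)
    res <- list()
    for (i in 0:(n - 3)) {
      if (substr(s, i + 1, i + 3) != "ATG") next
      j <- i
      end <- NA
      has_stop <- FALSE
      while (j + 3 <= n) {
        codon <- substr(s, j + 1, j + 3)
        if (j > i && codon %in% stops) {
          end <- j + 3
          has_stop <- TRUE
          break
        }
        j <- j + 3
      }
      if (!has_stop) end <- i + 3 * ((n - i) %/% 3)
      aa_len <- (end - i) / 3 - has_stop
      if (aa_len >= min_aa_len) {
        res[[length(res) + 1]] <- data.frame(start = i, end = end,
                                             strand = strand,
                                             frame = i %% 3,
                                             aa_length = aa_len,
                                             has_stop = has_stop)
      }
    }
    if (length(res)) do.call(rbind, res) else
      data.frame(start = integer(), end = integer(), strand = character(),
                 frame = integer(), aa_length = integer(), has_stop = logical())
  }
  out <- scan_one(seq, "+")
  if (strands == "both") out <- rbind(out, scan_one(oracle_revcomp(seq), "-"))
  out <- out[order(out$strand, out$start, -out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# explicit per-gene double loop for mutual best hits
oracle_bbh <- function(table, species_a, species_b, ceiling = 1e-5) {
  h <- table$hits
  sp <- table$species_of
  best_of <- function(gene, target) {
    rows <- which(h$query_id == gene & sp[h$subject_id] == target &
                    h$subject_id != gene & h$evalue <= ceiling)
    if (!length(rows)) return(NA_character_)
    best <- rows[1]
    for (r in rows[-1]) {
      if (h$evalue[r] < h$evalue[best] ||
          (h$evalue[r] == h$evalue[best] && h$bitscore[r] > h$bitscore[best]) ||
          (h$evalue[r] == h$evalue[best] && h$bitscore[r] == h$bitscore[best] &&
             h$subject_id[r] < h$subject_id[best])) best <- r
    }
    h$subject_id[best]
  }
  genes_a <- sort(names(sp)[sp == species_a])
  pairs <- character(0)
  for (a in genes_a) {
    b <- best_of(a, species_b)
    if (is.na(b)) next
    back <- best_of(b, species_a)
    if (!is.na(back) && back == a) pairs <- c(pairs, paste(a, b, sep = "\r"))
  }
  pairs
}

bbh_pairs_as_keys <- function(bb) paste(bb$gene_a, bb$gene_b, sep = "\r")

# per-row double loop over the hit table for within-species paralog pairs
oracle_paralog_edges <- function(table, species, cutoff) {
  h <- table$hits
  sp <- table$species_of
  seen <- new.env()
  for (r in seq_len(nrow(h))) {
    q <- h$query_id[r]; s <- h$subject_id[r]
    if (q == s) next
    if (sp[q] != species || sp[s] != species) next
    key <- paste(min(q, s), max(q, s), sep = "\r")
    old <- seen[[key]]
    if (is.null(old) || h$evalue[r] < old) seen[[key]] <- h$evalue[r]
  }
  keys <- ls(seen)
  keys[vapply(keys, function(k) seen[[k]] <= cutoff, TRUE)]
}

paralog_edges_as_keys <- function(pe) paste(pe$gene_a, pe$gene_b, sep = "\r")

# naive per-cutoff component count via igraph on the filtered edge list
oracle_dup_network_count <- function(table, species, cutoff) {
  total <- 0L
  for (s in species) {
    pe <- paralog_edges(table, s, cutoff)
    if (!nrow(pe)) next
    g <- igraph::graph_from_data_frame(pe[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    total <- total + sum(igraph::components(g)$csize >= 2)
  }
  total
}

# small random transcript generator
random_transcript <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Cq truth with the planted stable-pair scenario: two tight genes vs three
# loose ones, a single condition, used by the stability recovery tests
stable_pair_truth <- function() {
  cq_truth(
    genes = data.frame(
      gene = c("RG1", "RG2", "RG3", "RG4", "RG5"),
      role = "candidate_RG",
      baseline_cq = c(21, 24, 22, 23, 20),
      noise_sd = c(0.15, 0.15, 0.8, 0.85, 0.9),
      efficiency = 2),
    conditions = "control",
    effects = data.frame(gene = character(), condition = character(),
                         effect_cycles = numeric()),
    loading_shift_sd = 0.3)
}
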