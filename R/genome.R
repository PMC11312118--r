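# Genome-mapping ingestion, identity filtering and reconciliation of genome
# presence with transcriptome presence into expressed / genomic_only / absent
# calls. Genome mappings are consumed as summarized spliced-alignment reports
# (one best identity per query and genome), not produced: running the aligner
# itself is out of scope, which keeps the stage free of tool/version coupling.

#' Read a genome-mapping summary table
#'
#' Tab-separated file with header columns \code{query_id},
#' \code{query_length_bp}, \code{pct_identity} and optionally
#' \code{genome_id} and \code{coverage}. Each row summarizes the mapping of
#' one query sequence on one genome (best alignment identity).
#'
#' @param path TSV path.
#' @param genome_id Genome label applied to all rows lacking a
#'   \code{genome_id} column.
#' @return Data frame \code{query_id}, \code{query_length_bp},
#'   \code{pct_identity}, \code{genome_id} (and \code{coverage} if present).
#' @export
read_mappings <- function(path, genome_id = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("query_id", "query_length_bp", "pct_identity")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stopf("mapping table lacks columns: %s", toString(missing_cols))
  if (!"genome_id" %in% names(d)) {
    if (is.null(genome_id)) stopf("supply genome_id or a genome_id column")
    d$genome_id <- rep(genome_id, nrow(d))
  }
  bad <- which(!is.finite(d$pct_identity) | d$pct_identity < 0 | d$pct_identity > 100)
  if (length(bad))
    stopf("row %d: pct_identity %s outside [0, 100]", bad[1],
          format(d$pct_identity[bad[1]]))
  bad <- which(!is.finite(d$query_length_bp) | d$query_length_bp <= 0)
  if (length(bad)) stopf("row %d: query_length_bp must be > 0", bad[1])
  d
}

#' Filter genome mappings at an identity cutoff
#'
#' Keeps records with \code{pct_identity >= min_identity}. The comparison is
#' inclusive: a mapping at exactly the cutoff survives.
#'
#' @param records Data frame from \code{\link{read_mappings}}.
#' @param min_identity Percent identity cutoff in [0, 100] (default 40, the
#'   screen's reliability threshold).
#' @return The surviving records.
#' @export
filter_mappings <- function(records, min_identity = 40) {
  if (min_identity < 0 || min_identity > 100)
    stopf("min_identity must lie in [0, 100]")
  out <- records[records$pct_identity >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-level presence of each GOI per species
#'
#' A (GOI, species) cell is genome-present iff at least one surviving
#' mapping record exists for any query of that GOI on the genome assigned to
#' that species. Species without an own genome may use a surrogate genome of
#' a related species; surrogate use is recorded in the provenance.
#'
#' @param records Filtered records from \code{\link{filter_mappings}}. Only
#'   the best (maximum-identity) record per (query, genome) is used.
#' @param genome_to_species Data frame \code{genome_id}, \code{species},
#'   \code{surrogate} (logical: TRUE when the genome belongs to a related
#'   species rather than the species itself). One genome may serve several
#'   species.
#' @param query_to_goi Named vector query id to GOI name; parsed from the
#'   query ids by default.
#' @param vocabulary GOI names (rows).
#' @return A \code{presence_matrix} (GOI x species) with attributes
#'   \code{"evidence"} (query ids per present cell) and \code{"surrogate"}
#'   (named logical per species).
#' @export
genome_presence <- function(records, genome_to_species, query_to_goi = NULL,
                            vocabulary = goi_vocabulary()) {
  need <- c("genome_id", "species", "surrogate")
  if (!all(need %in% names(genome_to_species)))
    stopf("genome_to_species must have columns %s", toString(need))
  unmapped <- setdiff(unique(records$genome_id), genome_to_species$genome_id)
  if (length(unmapped))
    stopf("genomes without a species mapping: %s", toString(unmapped))
  if (is.null(query_to_goi)) {
    q <- unique(records$query_id)
    query_to_goi <- stats::setNames(goi_from_query_id(q), q)
  }
  bad <- setdiff(unique(unname(query_to_goi[records$query_id])), vocabulary)
  if (length(bad)) stopf("queries map to GOIs outside the vocabulary: %s",
                         toString(bad))
  # best record per (query, genome)
  o <- order(records$query_id, records$genome_id, -records$pct_identity)
  r <- records[o, , drop = FALSE]
  r <- r[!duplicated(paste(r$query_id, r$genome_id, sep = "\r")), , drop = FALSE]

  roster <- unique(genome_to_species$species)
  m <- matrix("absent", length(vocabulary), length(roster),
              dimnames = list(vocabulary, roster))
  evidence <- list()
  for (i in seq_len(nrow(genome_to_species))) {
    sp <- genome_to_species$species[i]
    rr <- r[r$genome_id == genome_to_species$genome_id[i], , drop = FALSE]
    if (!nrow(rr)) next
    gois <- unname(query_to_goi[rr$query_id])
    for (g in unique(gois)) {
      m[g, sp] <- "present"
      key <- paste(g, sp, sep = "|")
      evidence[[key]] <- sort(unique(c(evidence[[key]],
                                       rr$query_id[gois == g])))
    }
  }
  surrogate <- stats::setNames(
    vapply(roster, function(sp)
      any(genome_to_species$surrogate[genome_to_species$species == sp]), TRUE),
    roster)
  structure(m, evidence = evidence, surrogate = surrogate,
            class = c("presence_matrix", "matrix"))
}

#' Reconcile transcriptome presence with genome presence
#'
#' Cell-wise classification: transcriptome-present is \code{expressed};
#' transcriptome-absent but genome-present is \code{genomic_only} (the gene
#' exists but was not expressed in the experimental conditions behind the
#' assembly); absent from both is \code{absent}.
#'
#' @param transcriptome A \code{\link{presence_matrix}} from
#'   \code{\link{presence_matrix}}.
#' @param genome A \code{\link{presence_matrix}} from
#'   \code{\link{genome_presence}} over the same GOIs and species.
#' @return A \code{reconciled_matrix}: character matrix of
#'   \code{"expressed"}/\code{"genomic_only"}/\code{"absent"} with
#'   provenance attributes \code{"transcript_evidence"},
#'   \code{"mapping_evidence"} and \code{"surrogate"}.
#' @export
reconcile <- function(transcriptome, genome) {
  if (!identical(dim(transcriptome), dim(genome)) ||
      !identical(rownames(transcriptome), rownames(genome)) ||
      !identical(sort(colnames(transcriptome)), sort(colnames(genome))))
    stopf("transcriptome and genome matrices must share GOIs and species")
  mapping_evidence <- attr(genome, "evidence")
  surrogate <- attr(genome, "surrogate")
  if (!is.null(surrogate)) surrogate <- surrogate[colnames(transcriptome)]
  genome <- genome[, colnames(transcriptome), drop = FALSE]  # drops attributes
  out <- matrix("absent", nrow(transcriptome), ncol(transcriptome),
                dimnames = dimnames(transcriptome))
  out[unclass(genome) == "present"] <- "genomic_only"
  out[unclass(transcriptome) == "present"] <- "expressed"
  structure(out,
            transcript_evidence = attr(transcriptome, "evidence"),
            mapping_evidence = mapping_evidence,
            surrogate = surrogate,
            class = c("reconciled_matrix", "matrix"))
}

#' @export
print.reconciled_matrix <- function(x, ...) {
  y <- unclass(x)
  attributes(y)[c("transcript_evidence", "mapping_evidence", "surrogate")] <- NULL
  print(y)
  sur <- attr(x, "surrogate")
  if (any(sur %||% FALSE))
    cat("surrogate genome used for:", toString(names(sur)[sur]), "\n")
  invisible(x)
}

# bundled fixtures ------------------------------------------------------------

extdata <- function(file) {
  system.file("extdata", file, package = "m6ascreen", mustWork = TRUE)
}

#' Bundled microalgal screening fixtures
#'
#' Small plain-text tables bundled with the package, transcribed from the
#' published screen of the four microalgae:
#' \code{m6a_goi_inventory()} — the reported GOI transcript inventory
#' (transcript id, species, writer/eraser); \code{m6a_genome_mappings()} —
#' the reported genome-scan summaries of the writer/eraser query sequences
#' on the three available genomes (best identity per query);
#' \code{m6a_genome_species_map()} — which genome stands for which species,
#' with surrogate flags (the \emph{A. carterae} genome also serves
#' \emph{A. tamutum}; \emph{C. fusiformis} and \emph{T. striata} genomes
#' stand in for \emph{C. closterium} and \emph{T. suecica}).
#'
#' @return Data frames as described above; the inventory has the columns of
#'   a \code{\link{screen_goi}} result (\code{transcript_id}, \code{species},
#'   \code{goi_name}).
#' @export
m6a_goi_inventory <- function() {
  d <- utils::read.delim(extdata("goi_inventory.tsv"), stringsAsFactors = FALSE)
  d
}

#' @rdname m6a_goi_inventory
#' @export
m6a_genome_mappings <- function() {
  read_mappings(extdata("genome_mappings.tsv"))
}

#' @rdname m6a_goi_inventory
#' @export
m6a_genome_species_map <- function() {
  d <- utils::read.delim(extdata("genome_species_map.tsv"),
                         stringsAsFactors = FALSE)
  d$surrogate <- as.logical(d$surrogate)
  d
}
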