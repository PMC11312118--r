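# ORF prediction from assembled transcripts and isoform collapsing.
# Selection uses only the stated rules: ATG-initiated ORFs above a minimum
# amino-acid length, removal of ORFs entirely contained in a longer one, and
# (per transcript) the protein with the most functional annotations.

STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# translate a vector of codons under the standard genetic code; any codon
# containing N (or otherwise unknown) becomes X
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

validate_nt <- function(seq, id = "transcript") {
  if (!nzchar(seq)) stopf("%s has an empty sequence", id)
  if (grepl("[^ACGTN]", seq))
    stopf("%s contains characters outside {A,C,G,T,N}", id)
  seq
}

# all ATG-initiated ORFs on one oriented sequence; coordinates are 0-based
# half-open on that sequence
orfs_one_strand <- function(seq, min_aa_len, strand) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1L) next
    starts_nt <- frame + 3L * (seq_len(n_codons) - 1L)  # 0-based codon starts
    codons <- substring(seq, starts_nt + 1L, starts_nt + 3L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% STOP_CODONS)
    # first in-frame stop strictly after the start codon
    nxt <- stops[findInterval(atg, stops) + 1L]
    end_codon <- ifelse(is.na(nxt), n_codons, nxt)       # codon index of end
    has_stop <- !is.na(nxt)
    start0 <- starts_nt[atg]
    end0 <- frame + 3L * end_codon
    aa_len <- (end0 - start0) %/% 3L - has_stop
    keep <- aa_len >= min_aa_len
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        start = start0[keep], end = end0[keep], strand = strand,
        frame = frame, aa_length = aa_len[keep], has_stop = has_stop[keep]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), aa_length = integer(),
                      has_stop = logical()))
  }
  do.call(rbind, out)
}

#' Find open reading frames in a transcript
#'
#' Returns every ATG-initiated ORF that ends at an in-frame stop codon or at
#' the transcript end (last complete codon) and encodes at least
#' \code{min_aa_len} residues. Coordinates are 0-based half-open on the
#' reported strand, i.e. on the reverse complement for \code{"-"} ORFs; the
#' stop codon, when present, is included in \code{[start, end)} but not
#' counted in \code{aa_length}. Codons containing N translate to X and never
#' open or close an ORF.
#'
#' @param sequence Nucleotide string over \{A,C,G,T,N\} (case-insensitive).
#' @param min_aa_len Minimum protein length in residues (default 100, chosen
#'   to limit false-positive ORFs in de novo assemblies).
#' @param strands \code{"both"} (default; assembled transcripts are not
#'   reliably oriented) or \code{"forward"}.
#' @param transcript_id Optional id attached to the output.
#' @return Data frame with columns \code{transcript_id}, \code{start},
#'   \code{end}, \code{strand}, \code{frame}, \code{aa_length},
#'   \code{has_stop}, ordered by strand (+ before -), start, then longest
#'   first.
#' @export
find_orfs <- function(sequence, min_aa_len = 100L,
                      strands = c("both", "forward"),
                      transcript_id = NA_character_) {
  strands <- match.arg(strands)
  if (min_aa_len < 1L) stopf("min_aa_len must be >= 1")
  seq <- validate_nt(toupper(sequence), transcript_id)
  res <- orfs_one_strand(seq, min_aa_len, "+")
  if (strands == "both") {
    res <- rbind(res, orfs_one_strand(revcomp(seq), min_aa_len, "-"))
  }
  res <- res[order(res$strand, res$start, -res$end), , drop = FALSE]
  res <- cbind(transcript_id = rep(transcript_id, nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Remove ORFs entirely contained in a longer ORF
#'
#' Among candidate ORFs of one transcript, drops every ORF whose
#' \code{[start, end)} interval lies entirely within another surviving ORF's
#' interval on the same strand; the longer one is kept (exact duplicates keep
#' a single copy).
#'
#' @param candidates Data frame as returned by \code{\link{find_orfs}}.
#' @return The surviving subset, in \code{\link{find_orfs}} order.
#' @export
filter_contained <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  keep_rows <- logical(nrow(candidates))
  for (str in unique(candidates$strand)) {
    idx <- which(candidates$strand == str)
    len <- candidates$end[idx] - candidates$start[idx]
    # longest first so containment is always tested against kept survivors;
    # ties resolved by start so exact duplicates collapse to the first
    ord <- idx[order(-len, candidates$start[idx])]
    kept <- integer(0)
    for (i in ord) {
      contained <- any(candidates$start[kept] <= candidates$start[i] &
                         candidates$end[i] <= candidates$end[kept])
      if (!contained) kept <- c(kept, i)
    }
    keep_rows[kept] <- TRUE
  }
  out <- candidates[keep_rows, , drop = FALSE]
  out[order(out$strand, out$start, -out$end), , drop = FALSE]
}

orf_protein <- function(seq_fwd, seq_rev, start, end, strand, has_stop) {
  s <- if (strand == "+") seq_fwd else seq_rev
  cds_end <- end - 3L * has_stop  # drop the stop codon from the translation
  codon_starts <- seq.int(start, cds_end - 3L, by = 3L)
  translate_codons(substring(s, codon_starts + 1L, codon_starts + 3L))
}

#' Predict a proteome from assembled transcripts
#'
#' Runs \code{\link{find_orfs}} on every transcript, optionally removes
#' contained ORFs (\code{\link{filter_contained}}), and translates under the
#' standard genetic code (stop codon excluded from the protein). A transcript
#' can yield several proteins when several non-nested ORFs reach the minimum
#' length. Protein ids are \code{transcript_id|start-end|strand}.
#'
#' @param transcripts Named character vector of nucleotide sequences (names
#'   are transcript ids), e.g. from \code{\link{read_transcripts}}.
#' @param min_aa_len,strands As in \code{\link{find_orfs}}.
#' @param drop_contained Apply the containment filter (default TRUE).
#' @return Data frame with columns \code{protein_id}, \code{transcript_id},
#'   \code{aa_sequence}, \code{aa_length}, \code{start}, \code{end},
#'   \code{strand}, \code{frame}, \code{has_stop}.
#' @export
predict_proteome <- function(transcripts, min_aa_len = 100L,
                             strands = c("both", "forward"),
                             drop_contained = TRUE) {
  strands <- match.arg(strands)
  if (length(transcripts) && is.null(names(transcripts)))
    stopf("transcripts must be named by transcript id")
  if (anyDuplicated(names(transcripts)))
    stopf("transcript ids must be unique")
  out <- vector("list", length(transcripts))
  for (i in seq_along(transcripts)) {
    id <- names(transcripts)[i]
    seq <- toupper(transcripts[[i]])
    orfs <- find_orfs(seq, min_aa_len, strands, transcript_id = id)
    if (drop_contained) orfs <- filter_contained(orfs)
    if (!nrow(orfs)) next
    seq_rev <- if (any(orfs$strand == "-")) revcomp(seq) else ""
    aa <- vapply(seq_len(nrow(orfs)), function(j)
      orf_protein(seq, seq_rev, orfs$start[j], orfs$end[j],
                  orfs$strand[j], orfs$has_stop[j]), "")
    out[[i]] <- data.frame(
      protein_id = sprintf("%s|%d-%d|%s", id, orfs$start, orfs$end, orfs$strand),
      transcript_id = id, aa_sequence = aa, aa_length = orfs$aa_length,
      start = orfs$start, end = orfs$end, strand = orfs$strand,
      frame = orfs$frame, has_stop = orfs$has_stop, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(protein_id = character(), transcript_id = character(),
                      aa_sequence = character(), aa_length = integer(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), has_stop = logical())
  }
  rownames(res) <- NULL
  res
}

#' Collapse protein isoforms to one protein per transcript
#'
#' Keeps, for each transcript, the predicted protein with the highest number
#' of functional annotations; ties go to the longer protein, then to the
#' lexicographically smallest protein id. Proteins absent from the annotation
#' table count 0 annotations.
#'
#' @param proteome Data frame from \code{\link{predict_proteome}}.
#' @param annotations Data frame with columns \code{protein_id},
#'   \code{signature_id} (one row per assigned signature), or NULL.
#' @param count_distinct Count distinct signature ids (default) rather than
#'   raw annotation rows.
#' @return One row per transcript, with added columns
#'   \code{annotation_count} and \code{annotation_ids}
#'   (semicolon-separated).
#' @export
collapse_isoforms <- function(proteome, annotations = NULL,
                              count_distinct = TRUE) {
  counts <- stats::setNames(integer(nrow(proteome)), proteome$protein_id)
  sigs <- stats::setNames(character(nrow(proteome)), proteome$protein_id)
  if (!is.null(annotations) && nrow(annotations)) {
    unknown <- setdiff(unique(annotations$protein_id), proteome$protein_id)
    if (length(unknown)) {
      warning(sprintf("annotations reference %d unknown protein id(s), ignored: %s",
                      length(unknown), toString(utils::head(unknown, 3))),
              call. = FALSE)
      annotations <- annotations[annotations$protein_id %in% proteome$protein_id, ,
                                 drop = FALSE]
    }
    split_sigs <- split(annotations$signature_id, annotations$protein_id)
    for (p in names(split_sigs)) {
      s <- split_sigs[[p]]
      if (count_distinct) s <- unique(s)
      counts[p] <- length(s)
      sigs[p] <- paste(sort(s), collapse = ";")
    }
  }
  proteome$annotation_count <- unname(counts[proteome$protein_id])
  proteome$annotation_ids <- unname(sigs[proteome$protein_id])
  o <- order(proteome$transcript_id, -proteome$annotation_count,
             -proteome$aa_length, proteome$protein_id)
  p <- proteome[o, , drop = FALSE]
  p <- p[!duplicated(p$transcript_id), , drop = FALSE]
  rownames(p) <- NULL
  p
}

# FASTA / table IO ------------------------------------------------------------

#' Read transcripts from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase nucleotide sequences; names
#'   are the first whitespace-delimited token of each header.
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write predicted proteins to FASTA
#' @param proteome Data frame from \code{\link{predict_proteome}}.
#' @param path Output FASTA path.
#' @export
write_proteins <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteome$aa_sequence,
                                                proteome$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write an ORF/protein table to TSV
#' @param proteome Data frame from \code{\link{predict_proteome}} or
#'   \code{\link{collapse_isoforms}}.
#' @param path Output path.
#' @export
write_orf_table <- function(proteome, path) {
  utils::write.table(proteome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Two-or-more-column TSV whose first two columns are protein id and
#' signature id (one row per assigned signature).
#'
#' @param path TSV path (with header).
#' @return Data frame \code{protein_id}, \code{signature_id}.
#' @export
read_annotations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stopf("annotation table needs at least 2 columns")
  stats::setNames(d[, 1:2], c("protein_id", "signature_id"))
}
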