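#' Transcript databases
#'
#' A transcript database pairs cDNA sequences (5'->3', one per transcript
#' accession) with a transcript -> gene assignment. Gene identifiers are
#' opaque text (symbol, Entrez id, ...); a gene is simply the set of
#' transcripts assigned to it, and every scoring definition (specificity,
#' coverage, robustness) is expressed over these sets.
#'
#' @param sequences named character vector of cDNA sequences (names are
#'   transcript accessions) or a `Biostrings::DNAStringSet`.
#' @param gene_of named character vector mapping transcript accession to
#'   gene id.
#' @return An object of class `transcript_db` with elements `seq` (named
#'   character) and `gene` (named character), restricted to transcripts
#'   present in both inputs.
#' @details Transcripts lacking a gene assignment are excluded entirely
#'   rather than treated as an anonymous "other gene": specificity is
#'   defined only over genes, and unassigned accessions would otherwise
#'   silently destroy specificity scores.
#' @export
transcript_db <- function(sequences, gene_of) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- structure(as.character(sequences), names = names(sequences))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            is.character(gene_of), !is.null(names(gene_of)))
  keep <- intersect(names(sequences), names(gene_of))
  if (length(keep) == 0) {
    stop("no transcript accession is shared between the sequences and the ",
         "gene map", call. = FALSE)
  }
  n_drop <- length(sequences) - length(keep)
  if (n_drop > 0) {
    message(n_drop, " transcript(s) without a gene assignment dropped")
  }
  bad <- !grepl("^[ACGT]+$", sequences[keep])
  if (any(bad)) {
    stop("transcript with non-ACGT characters: ", keep[which(bad)[1]],
         call. = FALSE)
  }
  structure(list(seq = sequences[keep], gene = gene_of[keep]),
            class = "transcript_db")
}

#' Read a transcriptome from FASTA plus a gene-map table
#'
#' The transcript accession is the first whitespace-delimited token of
#' each FASTA header. The gene map is a two-column tab-separated table
#' (`transcript_id`, `gene_id`); a header row is detected and skipped if
#' the first field is literally `transcript_id`.
#'
#' @param fasta_path path to the cDNA FASTA file.
#' @param gene_map_path path to the transcript -> gene table.
#' @return A [transcript_db()].
#' @export
read_transcriptome <- function(fasta_path, gene_map_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  names(x) <- sub("\\s.*$", "", names(x))
  first <- strsplit(readLines(gene_map_path, n = 1L), "\t", fixed = TRUE)[[1]]
  gm <- utils::read.delim(gene_map_path, header = identical(first[1], "transcript_id"),
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(gm) < 2L) stop("gene map must have two columns", call. = FALSE)
  gene_of <- structure(gm[[2]], names = gm[[1]])
  missing_seq <- setdiff(names(gene_of), names(x))
  if (length(missing_seq) > 0) {
    warning(length(missing_seq),
            " gene-map transcript(s) absent from the FASTA ignored",
            call. = FALSE)
    gene_of <- gene_of[setdiff(names(gene_of), missing_seq)]
  }
  transcript_db(x, gene_of)
}

#' Write a transcript database to FASTA plus a gene-map table
#' @param db a [transcript_db()].
#' @param fasta_path,gene_map_path output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_transcriptome <- function(db, fasta_path, gene_map_path) {
  stopifnot(inherits(db, "transcript_db"))
  x <- Biostrings::DNAStringSet(db$seq)
  Biostrings::writeXStringSet(x, fasta_path, width = 80L)
  utils::write.table(data.frame(transcript_id = names(db$gene),
                                gene_id = unname(db$gene)),
                     gene_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, gene_map = gene_map_path))
}

#' Transcript lengths (bases)
#' @param db a [transcript_db()].
#' @param transcript_id accession(s); default all.
#' @return Named integer vector of sequence lengths.
#' @export
transcript_lengths <- function(db, transcript_id = names(db$seq)) {
  structure(nchar(db$seq[transcript_id]), names = transcript_id)
}

#' Transcripts belonging to a gene
#' @param db a [transcript_db()].
#' @param gene_id a gene identifier.
#' @return Character vector of transcript accessions (possibly empty).
#' @export
transcripts_of <- function(db, gene_id) {
  names(db$gene)[db$gene == gene_id]
}

#' @export
print.transcript_db <- function(x, ...) {
  cat("transcript_db:", length(x$seq), "transcripts,",
      length(unique(x$gene)), "genes\n")
  invisible(x)
}
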