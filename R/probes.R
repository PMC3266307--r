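#' Probe tables
#'
#' A probe table holds the individual probe sequences of one or more
#' probe sets: one row per probe, grouped by probe-set identifier in file
#' order. Probes are the 25-base oligonucleotides fixed to the array; a
#' probe set (typically 11 probes on U133-class arrays) is the unit that
#' is scored and reported.
#'
#' @param probeset_id,probe_id,sequence character vectors of equal length.
#' @return A data.frame of class `probe_table` with those three columns.
#' @details Validation: sequences must be non-empty uppercase A/C/G/T
#'   (ambiguity codes such as N are rejected); lengths other than 25
#'   bases raise a warning only; probe ids must be unique within a probe
#'   set.
#' @export
probe_table <- function(probeset_id, probe_id, sequence) {
  df <- data.frame(probeset_id = as.character(probeset_id),
                   probe_id = as.character(probe_id),
                   sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  validate_probe_table(df)
}

validate_probe_table <- function(df, lines = NULL) {
  bad <- !grepl("^[ACGT]+$", df$sequence)
  if (any(bad)) {
    where <- if (is.null(lines)) paste("row", which(bad)[1]) else
      paste("line", lines[which(bad)[1]])
    stop("probe sequence with non-ACGT characters (", where, "): ",
         df$sequence[which(bad)[1]], call. = FALSE)
  }
  if (any(nchar(df$sequence) != 25L)) {
    warning(sum(nchar(df$sequence) != 25L),
            " probe(s) are not 25 bases long", call. = FALSE)
  }
  dup <- duplicated(df[c("probeset_id", "probe_id")])
  if (any(dup)) {
    stop("duplicate probe_id within probe set: ",
         df$probeset_id[which(dup)[1]], " / ", df$probe_id[which(dup)[1]],
         call. = FALSE)
  }
  if (any(grepl(":", df$probeset_id, fixed = TRUE))) {
    stop("probeset_id may not contain ':' (reserved for probe naming)",
         call. = FALSE)
  }
  class(df) <- c("probe_table", "data.frame")
  df
}

#' Split a probe table into one data.frame per probe set
#' @param probes a [probe_table()].
#' @return Named list of `probe_table` subsets, in order of first
#'   appearance.
#' @export
probe_sets <- function(probes) {
  split(as.data.frame(probes), factor(probes$probeset_id,
                                      levels = unique(probes$probeset_id)))
}

#' Read probes from an Affymetrix probe-tab file
#'
#' Parses the tab-separated "probe tab" text format distributed by the
#' array manufacturer: one probe per row with a header line. Probe ids
#' are taken from a `Probe ID` column when present, formed from X/Y
#' coordinate columns when those are present, and otherwise synthesized
#' as `<probeset_id>:<ordinal>`.
#'
#' @param path path to the probe-tab file.
#' @param probeset_col,sequence_col names of the required columns.
#' @param probe_col,x_col,y_col names of the optional id columns.
#' @return A [probe_table()], grouped by probe set in file order.
#' @export
read_probe_tab <- function(path,
                           probeset_col = "Probe Set Name",
                           sequence_col = "Probe Sequence",
                           probe_col = "Probe ID",
                           x_col = "Probe X", y_col = "Probe Y") {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  for (col in c(probeset_col, sequence_col)) {
    if (!col %in% names(df)) {
      stop("probe-tab file ", path, " is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  ps <- df[[probeset_col]]
  if (probe_col %in% names(df)) {
    pid <- df[[probe_col]]
  } else if (all(c(x_col, y_col) %in% names(df))) {
    pid <- paste0(ps, ":", df[[x_col]], ".", df[[y_col]])
  } else {
    pid <- paste0(ps, ":", stats::ave(seq_along(ps), ps, FUN = seq_along))
  }
  out <- data.frame(probeset_id = ps, probe_id = pid,
                    sequence = df[[sequence_col]], stringsAsFactors = FALSE)
  ord <- order(factor(out$probeset_id, levels = unique(out$probeset_id)))
  lines <- (seq_len(nrow(out)) + 1L)[ord]  # +1 for the header line
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  validate_probe_table(out, lines = lines)
}

#' Write probes to a probe-tab file
#' @param probes a [probe_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_tab <- function(probes, path) {
  stopifnot(inherits(probes, "probe_table"))
  df <- data.frame(`Probe Set Name` = probes$probeset_id,
                   `Probe ID` = probes$probe_id,
                   `Probe Sequence` = probes$sequence,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probes from a FASTA file
#'
#' FASTA headers must encode the probe-set identifier and a within-set
#' probe label; `id_pattern` is a regular expression with two capture
#' groups extracting them (default: `PSID:label`). Probe ids are
#' normalized to `<probeset_id>:<label>`, so parsing a FASTA written by
#' [write_probe_fasta()] agrees with the probe-tab representation of the
#' same probes.
#'
#' @param path path to the FASTA file.
#' @param id_pattern regular expression with exactly two capture groups.
#' @return A [probe_table()].
#' @export
read_probe_fasta <- function(path, id_pattern = "^([^:]+):(.+)$") {
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  m <- regmatches(headers, regexec(id_pattern, headers))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop("FASTA header does not match id_pattern '", id_pattern, "': ",
         headers[which(bad)[1]], call. = FALSE)
  }
  ps <- vapply(m, `[`, "", 2L)
  lab <- vapply(m, `[`, "", 3L)
  out <- data.frame(probeset_id = ps, probe_id = paste0(ps, ":", lab),
                    sequence = as.character(x), stringsAsFactors = FALSE)
  ord <- order(factor(out$probeset_id, levels = unique(out$probeset_id)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  validate_probe_table(out)
}

#' Write probes to a FASTA file
#'
#' Headers are written as `<probeset_id>:<label>`, where the label is the
#' probe id with any leading `<probeset_id>:` prefix stripped.
#'
#' @param probes a [probe_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  stopifnot(inherits(probes, "probe_table"))
  prefix <- paste0(probes$probeset_id, ":")
  lab <- ifelse(startsWith(probes$probe_id, prefix),
                substring(probes$probe_id, nchar(prefix) + 1L),
                probes$probe_id)
  x <- Biostrings::DNAStringSet(probes$sequence)
  names(x) <- paste0(probes$probeset_id, ":", lab)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
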