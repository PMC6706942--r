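#' Read a protein FASTA file into a proteome data frame
#'
#' Parses a (possibly gzip-compressed) protein FASTA file and returns one row
#' per entry. Sequences are uppercased and a single terminal stop symbol
#' \code{'*'} is stripped; an internal \code{'*'} is rejected because the
#' downstream charge model assumes a single uninterrupted chain (internal
#' stops usually flag pseudogenes or frameshifts). The accepted alphabet is
#' the 20 standard residues plus the ambiguity/rare codes X, B, Z, J, U, O.
#' The proteome identity comes from the \code{proteome_id} argument, not from
#' FASTA headers, because header dialects vary across NCBI/Prokka/MAG
#' sources; the protein id is the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a FASTA file (plain or .gz).
#' @param proteome_id identifier recorded in every returned row.
#' @return a data frame with columns \code{protein_id}, \code{proteome_id},
#'   \code{sequence}. An empty file yields a zero-row data frame with a
#'   warning.
#' @export
read_proteome <- function(path, proteome_id) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (!is.character(proteome_id) || length(proteome_id) != 1L) {
    stopf("`proteome_id` must be a single string")
  }
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                     warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning(sprintf("empty FASTA file: %s", path), call. = FALSE)
    return(data.frame(protein_id = character(), proteome_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  # structural pre-scan: produces line-numbered errors that the permissive
  # Biostrings reader does not
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stopf("malformed FASTA at line %d: expected a '>' header before sequence",
          nonblank[1])
  }
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) next
    if (grepl("[^A-Za-z*]", ln)) {
      stopf("malformed FASTA at line %d: invalid character in sequence '%s'",
            i, substr(ln, 1, 40))
    }
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stopf("duplicate protein_id in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  bad <- grepl("\\*", seqs, fixed = FALSE)
  if (any(bad)) {
    stopf("internal stop symbol '*' in protein(s): %s",
          paste(head(ids[bad], 5), collapse = ", "))
  }
  if (any(nchar(seqs) == 0)) {
    stopf("zero-length sequence for protein(s): %s",
          paste(head(ids[nchar(seqs) == 0], 5), collapse = ", "))
  }
  data.frame(protein_id = ids, proteome_id = proteome_id, sequence = seqs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a proteome data frame to FASTA
#'
#' @param proteome data frame with columns \code{protein_id}, \code{sequence}.
#' @param path output path (plain text).
#' @param width line-wrap width (default 60).
#' @return the path, invisibly.
#' @export
write_proteome <- function(proteome, path, width = 60L) {
  seqs <- as_sequences(proteome)
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a proteome metadata table
#'
#' Reads a TSV with header columns \code{proteome_id}, \code{habitat},
#' \code{taxon}. Habitat labels are restricted to the four classes used in
#' habitat comparison (\code{freshwater}, \code{brackish}, \code{marine},
#' \code{halophile}); empty strings and NA are allowed (unlabelled
#' proteomes). \code{taxon} is a free-form grouping label (typically the
#' phylum).
#'
#' @param path path to the TSV.
#' @return data frame with columns \code{proteome_id}, \code{habitat},
#'   \code{taxon}.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  required <- c("proteome_id", "habitat", "taxon")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stopf("metadata is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  md <- md[required]
  md$habitat[!nzchar(md$habitat)] <- NA_character_
  md$taxon[!nzchar(md$taxon)] <- NA_character_
  bad <- !is.na(md$habitat) & !md$habitat %in% HABITAT_LEVELS
  if (any(bad)) {
    stopf("unknown habitat label(s): %s; allowed: %s",
          paste(unique(md$habitat[bad]), collapse = ", "),
          paste(HABITAT_LEVELS, collapse = ", "))
  }
  if (anyDuplicated(md$proteome_id)) {
    stopf("duplicated proteome_id row(s): %s",
          paste(unique(md$proteome_id[duplicated(md$proteome_id)]),
                collapse = ", "))
  }
  md
}
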