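#' Sanitize a raw amino-acid string to the 20 canonical residues
#'
#' All feature encodings are defined over the 20 canonical amino acids only,
#' so sequences are normalized before any computation: the string is
#' uppercased; the ambiguity/rare codes `U` (selenocysteine), `B` (Asx),
#' `Z` (Glx) and `J` (Leu/Ile) are mapped to their nearest canonical parent
#' (`C`, `N`, `Q`, `L`); `X`, stop (`*`), gap characters, whitespace, digits
#' and any other symbol are removed.
#'
#' Sanitization is idempotent. An empty result is allowed; callers decide how
#' to treat length-0 sequences ([read_fasta] drops them with a warning).
#'
#' @param raw a character string (one sequence).
#' @return a list with `sequence` (canonical uppercase string),
#'   `n_substituted` and `n_removed` (integer tallies).
#' @examples
#' sanitize_sequence("acde")$sequence      # "ACDE"
#' sanitize_sequence("AXU")                # "AC", 1 substitution, 1 removal
#' @export
sanitize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(raw)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  sub_map <- c(U = "C", B = "N", Z = "Q", J = "L")
  n_sub <- sum(chars %in% names(sub_map))
  hit <- chars %in% names(sub_map)
  chars[hit] <- sub_map[chars[hit]]
  keep <- chars %in% AA_ALPHABET20
  n_rm <- sum(!keep)
  list(sequence = paste(chars[keep], collapse = ""),
       n_substituted = as.integer(n_sub),
       n_removed = as.integer(n_rm))
}

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a `protein_records` data frame, sanitizing each
#' sequence with [sanitize_sequence]. Records whose sanitized sequence is
#' empty are dropped with a warning. Duplicate ids are kept as-is (a message
#' notes them); file order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a data frame of class `protein_records` with columns `id`,
#'   `description`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read FASTA file '%s'", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1L && nzchar(first) && !startsWith(first, ">"))
    stop_data(sprintf("'%s' is not FASTA: sequence data before any '>' header", path))
  aa <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop_io(sprintf("failed to parse '%s': %s",
                                                     path, conditionMessage(e))))
  headers <- names(aa)
  if (is.null(headers)) headers <- character(0)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(aa)
  san <- lapply(seqs, sanitize_sequence)
  clean <- vapply(san, `[[`, character(1), "sequence")
  empty <- !nzchar(clean)
  if (any(empty)) {
    warning(sprintf("dropped %d record(s) with no canonical residues after sanitization: %s",
                    sum(empty), paste(ids[empty], collapse = ", ")),
            call. = FALSE)
  }
  if (anyDuplicated(ids[!empty]))
    message("note: duplicate ids present in '", path, "'")
  protein_records(id = ids[!empty], sequence = clean[!empty],
                  description = desc[!empty])
}

#' Construct a protein_records table
#'
#' @param id character vector of non-empty record ids.
#' @param sequence character vector of canonical (sanitized) sequences.
#' @param description optional free-text descriptions.
#' @return data frame of class `protein_records`.
#' @export
protein_records <- function(id, sequence, description = rep("", length(id))) {
  stopifnot(length(id) == length(sequence))
  if (length(id) && any(!nzchar(id))) stop_data("record ids must be non-empty")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"), sequence)
  if (any(bad))
    stop_data(sprintf("non-canonical residues in record(s): %s (sanitize first)",
                      paste(id[bad], collapse = ", ")))
  df <- data.frame(id = as.character(id),
                   description = as.character(description),
                   sequence = as.character(sequence),
                   length = nchar(sequence),
                   stringsAsFactors = FALSE)
  class(df) <- c("protein_records", "data.frame")
  df
}

#' Write protein records to a FASTA file
#'
#' Round-trip property: `read_fasta(write_fasta(r, path))` reproduces the ids
#' and sequences of `r`.
#'
#' @param records a `protein_records` table.
#' @param path output path.
#' @param line_width sequence line width (default 60).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("directory '%s' does not exist", dir))
  if (nrow(records) == 0L) {
    ok <- tryCatch({ file.create(path); TRUE }, warning = function(w) FALSE)
    if (!ok) stop_io(sprintf("cannot write '%s'", path))
    return(invisible(path))
  }
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- ifelse(nzchar(records$description),
                     paste(records$id, records$description),
                     records$id)
  tryCatch(Biostrings::writeXStringSet(x, filepath = path, width = line_width),
           error = function(e) stop_io(sprintf("cannot write '%s': %s",
                                               path, conditionMessage(e))))
  invisible(path)
}
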