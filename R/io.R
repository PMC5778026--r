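# Standard-format I/O: FASTA (via Biostrings), BED (0-based half-open),
# TSV with required-column checks, JSON, and a minimal SAM subset
# (POS/FLAG/SEQ only) sufficient for placement exchange.

#' Read a FASTA file into a named character vector
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_cid("io", "FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a BED file (0-based half-open) into a data frame
#'
#' Columns beyond the first four are ignored. The `name` column is required
#' because region roles are carried there.
#'
#' @param path path to a BED file.
#' @return data.frame with chrom, start0, end0, name.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_cid("io", "BED file not found: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    abort_cid("io", "BED file %s needs >= 4 columns (chrom,start,end,name)", path)
  data.frame(chrom = df[[1]], start0 = as.integer(df[[2]]),
             end0 = as.integer(df[[3]]), name = as.character(df[[4]]),
             stringsAsFactors = FALSE)
}

#' Write a BED file (0-based half-open)
#' @param df data.frame with chrom, start0, end0, name.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  need <- c("chrom", "start0", "end0", "name")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_cid("io", "BED frame missing column(s): %s",
                              paste(miss, collapse = ", "))
  write.table(df[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV file, asserting required columns
#'
#' @param path path to a header-bearing TSV.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) abort_cid("io", "TSV file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort_cid("io_column", "TSV %s is missing required column(s): %s",
              path, paste(miss, collapse = ", "))
  df
}

#' Write a data frame as TSV (header, UTF-8, unquoted)
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

read_json <- function(path, simplify = TRUE)
  jsonlite::read_json(path, simplifyVector = simplify)

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write read placements as minimal SAM
#'
#' Only the fields the coverage stage consumes are meaningful: FLAG (strand),
#' POS (1-based leftmost) and SEQ. MAPQ/CIGAR are filled with placeholders.
#'
#' @param placements data.frame with read_id, start0, width, strand.
#' @param ref_name reference sequence name.
#' @param ref_len reference length (for the @SQ header).
#' @param path output path.
#' @export
write_sam_minimal <- function(placements, ref_name, ref_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len))), con)
  if (nrow(placements)) {
    flag <- ifelse(placements$strand == "-", 16L, 0L)
    seqf <- placements$seq %||% strrep("N", placements$width)
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     placements$read_id, flag, ref_name,
                     placements$start0 + 1L, placements$width, seqf)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a minimal SAM file into a placement table
#'
#' Parses POS, FLAG and SEQ; unmapped records (FLAG 0x4) are dropped.
#'
#' @param path path to a SAM file.
#' @return data.frame with read_id, start0, width, strand.
#' @export
read_sam_minimal <- function(path) {
  if (!file.exists(path)) abort_cid("io", "SAM file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(read_id = character(), start0 = integer(),
                      width = integer(), strand = character()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 10L)
  if (length(bad))
    abort_cid("io", "malformed SAM record at data line %d", bad[1])
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  data.frame(
    read_id = vapply(fields, `[[`, character(1), 1L),
    start0 = vapply(fields, function(f) as.integer(f[4]), integer(1)) - 1L,
    width = vapply(fields, function(f) nchar(f[10]), integer(1)),
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    stringsAsFactors = FALSE
  )
}
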