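# Plain-text sequence file I/O. FASTQ is framed directly over (optionally
# gzipped) text connections so the simulator can stream chunked appends and
# the demultiplexer keeps read names and sequences together.

#' Read a FASTQ file
#'
#' Reads a (optionally gzipped) FASTQ file into a `data.table` of read
#' names (up to the first whitespace) and sequences. Malformed files —
#' truncated records or a missing `+` separator — raise an error naming the
#' offending record.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return `data.table` with columns `name`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0L) stop("empty FASTQ file: ", path)
  if (n %% 4L != 0L)
    stop("truncated FASTQ file ", path, ": record ", n %/% 4L + 1L,
         " is incomplete (", n %% 4L, " of 4 lines)")
  heads <- lines[seq(1L, n, by = 4L)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad) > 0L)
    stop("malformed FASTQ file ", path, ": record ", bad[1L],
         " does not start with '@'")
  seps <- lines[seq(3L, n, by = 4L)]
  bad <- which(!startsWith(seps, "+"))
  if (length(bad) > 0L)
    stop("malformed FASTQ file ", path, ": record ", bad[1L],
         " lacks the '+' separator")
  name <- sub("\\s.*$", "", substring(heads, 2L))
  data.table::data.table(name = name, seq = lines[seq(2L, n, by = 4L)])
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("write_fasta() requires named sequences")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Uses Biostrings when available (the conventional reader); falls back to a
#' minimal two-state reader otherwise.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, "", collapse = "")
  names(seqs) <- sub("\\s.*$", "", substring(lines[hdr], 2L))
  seqs
}
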