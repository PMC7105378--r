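## Plain-text I/O: FASTA/FASTQ via Biostrings, tab-separated tables with
## documented headers, and a flat key=value config format.

#' Write a genome to FASTA
#'
#' @param genome DNA string.
#' @param path output file.
#' @param name sequence name.
#' @export
write_genome_fasta <- function(genome, path, name = "synthetic_phage") {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return DNA string.
#' @export
read_genome_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path)[[1]])
}

#' Write simulated reads to FASTQ (Phred 33, constant quality)
#'
#' @param reads a `simulated_reads` data.frame (or any data.frame with
#'   `read_id` and `sequence`).
#' @param path output file.
#' @param quality_char constant per-base quality character (default "I",
#'   Q40).
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' @param path input file.
#' @param format "fastq" or "fasta"; guessed from the extension by default.
#' @return data.frame with `read_id` and `sequence`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.f(ast)?a$", path, ignore.case = TRUE))
      "fasta" else "fastq"
  x <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(read_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a tab-separated table
#'
#' Thin wrappers fixing the dialect (tab-separated, header, no quoting, no
#' row names) used by every pipeline output.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a resistance matrix from a long-format TSV
#'
#' Columns: `host_id`, `host_timepoint`, `phage_id`, `phage_timepoint`,
#' `score` (0, 0.5 or 1).
#'
#' @param path TSV file.
#' @return a [resistance_matrix()].
#' @export
read_resistance_tsv <- function(path) {
  resistance_matrix(read_tsv_table(path))
}

#' Write a generator config as flat key=value text
#'
#' @param config a [generator_config()].
#' @param path output file.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' Read a flat key=value generator config
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path key=value file written by [write_config()].
#' @return a [generator_config()].
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  defaults <- formals(generator_config)
  known <- setdiff(names(defaults), "")
  if (length(bad <- setdiff(keys, known)))
    cc_stop("crisprcolony_config_error", "unknown config key(s): %s",
            paste(bad, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] %in% c("repeat_seq", "leader_seq", "pam")) vals[i]
    else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(generator_config, args)
}
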