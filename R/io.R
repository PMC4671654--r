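# Standard-format I/O: headered TSV with provenance comments, BED, FASTA,
# and the Rmap TSV dialect.

#' Write a headered, tab-delimited table with provenance comments
#'
#' Provenance (e.g. seed, config hash, package version) is written as
#' leading `# key: value` comment lines; the header and rows follow.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @param provenance Named character vector or list written as comments.
#' @return `path`, invisibly.
#' @export
write_pipeline_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a headered, tab-delimited table
#'
#' Skips `#` comment lines; rejects rows whose field count differs from the
#' header, naming the offending line number.
#'
#' @param path Input path.
#' @param required Column names that must be present.
#' @return A `data.frame` with type-converted columns.
#' @export
read_pipeline_tsv <- function(path, required = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop("no header in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  bad <- which(lengths(fields) != ncols)
  if (length(bad))
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(lineno[bad], collapse = ", "),
         ": expected ", ncols, " fields")
  header <- fields[[1]]
  body <- fields[-1]
  df <- as.data.frame(
    lapply(seq_len(ncols), function(j)
      utils::type.convert(vapply(body, `[[`, character(1), j), as.is = TRUE)),
    stringsAsFactors = FALSE, optional = TRUE)
  names(df) <- header
  if (!is.null(required) && !all(required %in% header))
    stop("missing required column(s) in ", path, ": ",
         paste(setdiff(required, header), collapse = ", "))
  df
}

#' Serialize architecture or haplotype elements as BED
#'
#' One line per element; the strand column carries the orientation.
#' Coordinates are 0-based half-open as BED requires.
#'
#' @param x A `LocusArchitecture` (reference coordinates) or `Haplotype`
#'   (haplotype-frame coordinates, chrom suffixed with the label).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(x, path) {
  if (inherits(x, "LocusArchitecture")) {
    el <- x$elements
    chrom <- x$chrom
  } else if (inherits(x, "Haplotype")) {
    el <- hap_elements(x)
    chrom <- paste0(x$arch$chrom, "_", x$label)
  } else stop("x must be a LocusArchitecture or Haplotype")
  bed <- data.frame(chrom = chrom, start = el$start, end = el$end,
                    name = el$name, score = 0L,
                    strand = ifelse(el$orientation >= 0, "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export discordant ESP calls as a BED custom track
#'
#' @param esps ESP table (with `chrom`, `pos1`, `pos2`).
#' @param calls Matching call table from [classify_esp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discordant_bed <- function(esps, calls, path) {
  disc <- calls$class %in% c("deletion", "insertion", "inversion")
  bed <- data.frame(chrom = esps$chrom[disc],
                    start = pmin(esps$pos1, esps$pos2)[disc],
                    end = pmax(esps$pos1, esps$pos2)[disc],
                    name = paste(calls$clone_id, calls$class, sep = "|")[disc],
                    score = 0L, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path Input path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write Rmaps as TSV (one line per map: id, enzyme, comma-joined kb)
#' @param maps List of `Rmap` objects.
#' @param path Output path.
#' @param provenance Optional provenance comments.
#' @return `path`, invisibly.
#' @export
write_rmaps_tsv <- function(maps, path, provenance = NULL) {
  df <- data.frame(
    map_id = vapply(maps, function(m) m$map_id, character(1)),
    enzyme = vapply(maps, function(m) m$enzyme, character(1)),
    fragments_kb = vapply(maps, function(m)
      paste(sprintf("%.4f", m$fragments), collapse = ","), character(1)))
  write_pipeline_tsv(df, path, provenance)
}

#' Read Rmaps from TSV
#' @param path Input path.
#' @return List of `Rmap` objects.
#' @export
read_rmaps_tsv <- function(path) {
  df <- read_pipeline_tsv(path, required = c("map_id", "enzyme",
                                             "fragments_kb"))
  lapply(seq_len(nrow(df)), function(i)
    new_rmap(as.numeric(strsplit(df$fragments_kb[i], ",")[[1]]),
             map_id = df$map_id[i], enzyme = df$enzyme[i]))
}
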