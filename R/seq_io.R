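RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize an RNA sequence string
#'
#' Upper-cases, maps T to U (DNA input accepted) and validates that the
#' result contains only A, C, G, U.
#'
#' @param x character vector of sequences.
#' @param context optional label (e.g. a record id) used in error messages.
#' @return character vector of normalized RNA sequences.
#' @export
normalize_rna <- function(x, context = NULL) {
  x <- chartr("T", "U", toupper(x))
  if (!is.null(context)) context <- rep_len(as.character(context), length(x))
  m <- regexpr("[^ACGU]", x)
  hit <- which(m > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    offending <- substr(x[i], m[i], m[i])
    where <- if (is.null(context)) "" else paste0(" in '", context[i], "'")
    stop("invalid RNA character '", offending, "'", where, call. = FALSE)
  }
  empty <- which(!nzchar(x))
  if (length(empty) > 0L) {
    stop("empty sequence", if (!is.null(context))
      paste0(" for '", context[empty[1L]], "'") else "", call. = FALSE)
  }
  x
}

#' Construct a labeled sequence record
#'
#' @param id text identifier.
#' @param sequence RNA string; T is mapped to U and case is folded.
#' @param label one of `"positive"`, `"negative"`, `"unknown"`.
#' @param rbp optional RBP name tag (used for leave-one-protein-out
#'   grouping).
#' @param origin optional provenance, e.g. a one-row region record.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, label = "unknown", rbp = NA_character_,
                       origin = NULL) {
  label <- match.arg(label, c("positive", "negative", "unknown"))
  rec <- structure(
    list(id = as.character(id),
         sequence = unname(normalize_rna(sequence, id)),
         label = label, rbp = as.character(rbp), origin = origin),
    class = "seq_record")
  rec
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s%s] %d nt: %s>\n", x$id, x$label,
              if (!is.na(x$rbp)) paste0(", ", x$rbp) else "",
              nchar(x$sequence),
              if (nchar(x$sequence) > 40)
                paste0(substr(x$sequence, 1, 40), "...") else x$sequence))
  invisible(x)
}

#' Sequences of a record list as a character vector
#' @param records list of `seq_record`.
#' @return named character vector of sequences.
#' @export
record_sequences <- function(records) {
  vapply(records, function(r) r$sequence, character(1),
         USE.NAMES = FALSE) |> stats::setNames(
           vapply(records, function(r) r$id, character(1)))
}

#' Labels of a record list
#' @param records list of `seq_record`.
#' @return character vector of labels.
#' @export
record_labels <- function(records) {
  vapply(records, function(r) r$label, character(1))
}

#' RBP tags of a record list
#' @param records list of `seq_record`.
#' @return character vector of RBP tags (NA where untagged).
#' @export
record_rbps <- function(records) {
  vapply(records, function(r) r$rbp, character(1))
}

#' Read RNA sequences from a FASTA file
#'
#' Sequences are normalized (upper case, T mapped to U) and validated
#' against the RNA alphabet.  An optional label and RBP tag are applied to
#' every record.
#'
#' @param path FASTA file.
#' @param label optional label applied to all records.
#' @param rbp optional RBP tag applied to all records.
#' @return list of [seq_record()] in file order.
#' @export
read_fasta <- function(path, label = "unknown", rbp = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA at line ", first, ": '", lines[first],
         "' (expected a '>' header)", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  lapply(seq_along(set), function(i) {
    seq_record(ids[i], seqs[i], label = label, rbp = rbp)
  })
}

#' Write sequence records to a FASTA file
#'
#' @param records list of [seq_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(record_sequences(records))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load a genome from a multi-record FASTA file
#'
#' @param path DNA FASTA file; one record per chromosome.
#' @return a `genome_source`: a named DNAStringSet-backed chromosome map.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  genome_source(set)
}

#' Construct a genome source from named DNA strings
#'
#' @param x named character vector or named `DNAStringSet`; names are
#'   chromosome names, values DNA over A/C/G/T/N.
#' @return an object of class `genome_source`.
#' @export
genome_source <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("genome chromosomes must be named", call. = FALSE)
  structure(list(seqs = x), class = "genome_source")
}

#' Chromosome lengths of a genome source
#' @param genome a `genome_source`.
#' @return named integer vector of lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

genome_chrom <- function(genome, chrom) {
  i <- match(chrom, names(genome$seqs))
  if (is.na(i)) stop("unknown chromosome '", chrom, "'", call. = FALSE)
  genome$seqs[[i]]
}

#' Construct a region table
#'
#' Coordinates are 0-based half-open (`[start, end)`), BED-style.
#'
#' @param rbp,chrom,start,end,affinity,strand vectors, recycled to a
#'   common length.
#' @return data.frame with class `region_table`.
#' @export
region_table <- function(rbp, chrom, start, end, affinity = NA_real_,
                         strand = "+") {
  df <- data.frame(rbp = as.character(rbp), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   affinity = as.numeric(affinity),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L)) stop("negative region start", call. = FALSE)
  if (any(df$end <= df$start))
    stop("region end must exceed start (0-based half-open)", call. = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  class(df) <- c("region_table", "data.frame")
  df
}

#' Read a tab-separated region table
#'
#' Columns: rbp, chrom, start, end, affinity, strand.  Internally
#' coordinates are 0-based half-open; set `one_based = TRUE` when the file
#' uses 1-based inclusive coordinates (start is shifted down by one).
#'
#' @param path TSV file with a header row.
#' @param one_based logical; input convention flag.
#' @return a `region_table`.
#' @export
read_region_table <- function(path, one_based = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rbp", "chrom", "start", "end", "affinity", "strand")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("region table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  start <- df$start - if (one_based) 1L else 0L
  region_table(df$rbp, df$chrom, start, df$end, df$affinity, df$strand)
}

#' Write a region table to TSV
#' @param regions a `region_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the RNA sequence of a genomic region
#'
#' Slices `[start, end)` from the chromosome; on the '-' strand the slice
#' is reverse-complemented before DNA-to-RNA transcription (T to U).
#'
#' @param genome a `genome_source`.
#' @param region one-row `region_table` (or list with fields chrom, start,
#'   end, strand, rbp).
#' @param label label for the resulting record.
#' @param on_n `"error"`, `"skip"` (returns NULL with a warning) for
#'   slices containing ambiguous N bases; no profile feature is defined
#'   for N.
#' @return a [seq_record()], or NULL when skipped.
#' @export
extract_region_sequence <- function(genome, region, label = "unknown",
                                    on_n = c("error", "skip")) {
  on_n <- match.arg(on_n)
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- as.list(region)
  }
  chrom <- genome_chrom(genome, region$chrom)
  if (region$start < 0L || region$end > length(chrom)) {
    stop(sprintf("region [%d,%d) outside chromosome '%s' (length %d)",
                 region$start, region$end, region$chrom, length(chrom)),
         call. = FALSE)
  }
  dna <- Biostrings::subseq(chrom, start = region$start + 1L,
                            end = region$end)
  if (identical(region$strand, "-")) dna <- Biostrings::reverseComplement(dna)
  s <- as.character(dna)
  if (grepl("N", s, fixed = TRUE)) {
    if (on_n == "error") stop("ambiguous base N in region slice", call. = FALSE)
    warning(sprintf("skipping region %s:[%d,%d): contains N", region$chrom,
                    region$start, region$end), call. = FALSE)
    return(NULL)
  }
  id <- sprintf("%s:%d-%d(%s)", region$chrom, region$start, region$end,
                region$strand)
  seq_record(id, s, label = label,
             rbp = if (!is.null(region$rbp)) region$rbp else NA_character_,
             origin = region)
}

#' Extract sequences for every row of a region table
#'
#' @inheritParams extract_region_sequence
#' @param regions a `region_table`.
#' @return list of [seq_record()]; N-containing slices are dropped with a
#'   warning when `on_n = "skip"`.
#' @export
extract_region_sequences <- function(genome, regions, label = "unknown",
                                     on_n = "skip") {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    extract_region_sequence(genome, regions[i, , drop = FALSE],
                            label = label, on_n = on_n)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Filter candidate binding regions
#'
#' Keeps regions with exactly the requested length, affinity strictly
#' above the threshold, and the requested strand; input order is
#' preserved.  Defaults reproduce the study design: 25-nt regions on the
#' '+' strand with affinity > 0.9.
#'
#' @param regions a `region_table`.
#' @param length required region length in nt.
#' @param min_affinity exclusive lower bound on the affinity score;
#'   regions with missing affinity are dropped.
#' @param strand required strand.
#' @return the filtered `region_table`.
#' @export
filter_regions <- function(regions, length = 25L, min_affinity = 0.9,
                           strand = "+") {
  keep <- (regions$end - regions$start) == length &
    !is.na(regions$affinity) & regions$affinity > min_affinity &
    regions$strand == strand
  regions[keep, , drop = FALSE]
}
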