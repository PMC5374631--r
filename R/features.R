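#' k-mer composition of an RNA sequence
#'
#' Relative frequency of every length-k word: counts are divided by the
#' number of k-mer windows, `|seq| - k + 1`, so the 4^k-element vector
#' sums to 1.
#'
#' @param seq RNA string (or [seq_record()]).
#' @param k word size (1, 2 or 3).
#' @return numeric vector of length 4^k, named by k-mer, lexicographic
#'   order A < C < G < U.
#' @export
kmer_composition <- function(seq, k) {
  s <- as_sequences(if (inherits(seq, "seq_record")) list(seq) else seq)
  stopifnot(k %in% 1:3)
  if (nchar(s) < k) stop("sequence shorter than k = ", k, call. = FALSE)
  syms <- kmer_symbols(k)
  code <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_ALPHABET)
  L <- nchar(s) - k + 1L
  idx <- code[seq_len(L)]
  if (k > 1L) for (d in seq_len(k - 1L)) {
    idx <- (idx - 1L) * 4L + code[seq_len(L) + d]
  }
  stats::setNames(tabulate(idx, nbins = length(syms)) / L, syms)
}

#' The 84-element composition block (mono + di + tri)
#' @param seq RNA string of length >= 3.
#' @return numeric vector of length 84; each sub-block sums to 1.
#' @export
rna_composition <- function(seq) {
  c(kmer_composition(seq, 1L), kmer_composition(seq, 2L),
    kmer_composition(seq, 3L))
}

fv_layout <- function(blocks, lengths) {
  data.frame(block = blocks, length = as.integer(lengths),
             stringsAsFactors = FALSE)
}

feature_vector <- function(values, layout) {
  stopifnot(sum(layout$length) == length(values))
  structure(values, layout = layout, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  l <- attr(x, "layout")
  cat(sprintf("<feature_vector of %d elements: %s>\n", length(x),
              paste(sprintf("%s[%d]", l$block, l$length), collapse = " | ")))
  invisible(x)
}

#' Block layout of a feature vector
#' @param fv a `feature_vector`.
#' @return data.frame with columns `block`, `length`.
#' @export
fv_blocks <- function(fv) attr(fv, "layout")

## indices covered by a short sequence placed at 0-based offset o against
## a w-column mono matrix; dinucleotide column j needs both j and j+1
covered_mono <- function(o, m, w) (o + 1L):(o + m)
covered_di <- function(o, m, w) if (m >= 2L) (o + 1L):(o + m - 1L) else integer(0)

#' Encode an RNA sequence into its profile + composition feature vector
#'
#' The canonical layout for a window of w nucleotides is
#' `mPWM[w] | dPWM[w-1] | composition[84]` (133 elements for w = 25).
#' Sequences longer than w are scanned for the length-w window with the
#' maximum mono log-odds sum ([best_offset()]); profile blocks come from
#' that window while compositions cover the entire sequence.  Sequences
#' shorter than w are aligned against the matrix columns at their best
#' offset and profile cells with no covered nucleotide are filled with 0
#' (a di-nucleotide cell is zero-filled unless both of its positions are
#' covered); compositions again cover the entire sequence.
#'
#' @param seq RNA string or [seq_record()]; length >= 3.
#' @param mpwm mono-nucleotide `pwm` over w positions.
#' @param dpwm di-nucleotide `pwm` over w-1 positions, built from the same
#'   training set.
#' @param blocks which blocks to emit, any subset of
#'   `c("mpwm", "dpwm", "composition")`; default all three.
#' @return a `feature_vector` (length 2w + 83 with all blocks).
#' @export
encode_rna <- function(seq, mpwm, dpwm,
                       blocks = c("mpwm", "dpwm", "composition")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  s <- as_sequences(if (inherits(seq, "seq_record")) list(seq) else seq)
  w <- ncol(mpwm)
  stopifnot(attr(mpwm, "k") == 1L, attr(dpwm, "k") == 2L, ncol(dpwm) == w - 1L)
  m <- nchar(s)
  if (m < 3L) stop("sequence shorter than 3 nt: tri-nucleotide composition undefined",
                   call. = FALSE)
  if (m == w) {
    mono <- profile_terms(s, mpwm)
    di <- profile_terms(s, dpwm)
  } else if (m > w) {
    o <- best_offset(s, mpwm)
    win <- substr(s, o + 1L, o + w)
    mono <- profile_terms(win, mpwm)
    di <- profile_terms(win, dpwm)
  } else {
    o <- best_offset(s, mpwm)
    code <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_ALPHABET)
    mono <- numeric(w)
    cm <- covered_mono(o, m, w)
    mono[cm] <- unclass(mpwm)[cbind(code, cm)]
    di <- numeric(w - 1L)
    cd <- covered_di(o, m, w)
    if (length(cd) > 0L) {
      didx <- (code[seq_len(m - 1L)] - 1L) * 4L + code[2:m]
      di[cd] <- unclass(dpwm)[cbind(didx, cd)]
    }
  }
  parts <- list(mpwm = mono, dpwm = di,
                composition = if ("composition" %in% blocks)
                  rna_composition(s) else NULL)
  keep <- blocks
  values <- unlist(parts[keep], use.names = FALSE)
  feature_vector(values, fv_layout(keep, vapply(parts[keep], length,
                                                integer(1))))
}

## 7 physicochemical amino-acid groups (dipole/volume clustering)
CTD_GROUPS <- list(
  g1 = c("A", "G", "V"),
  g2 = c("C"),
  g3 = c("M", "S", "T", "Y"),
  g4 = c("F", "I", "L", "P"),
  g5 = c("H", "N", "Q", "W"),
  g6 = c("K", "R"),
  g7 = c("D", "E"))

ctd_group_index <- local({
  idx <- integer(0)
  for (g in seq_along(CTD_GROUPS)) idx[CTD_GROUPS[[g]]] <- g
  idx
})

#' Composition/transition/distribution (CTD) descriptor of a protein
#'
#' The 20 standard amino acids are collapsed into 7 physicochemical
#' groups (by dipole and volume): \{A,G,V\}, \{C\}, \{M,S,T,Y\},
#' \{F,I,L,P\}, \{H,N,Q,W\}, \{K,R\}, \{D,E\}.  The descriptor has 63
#' elements:
#' * composition (7): frequency of each group;
#' * transition (21): for each unordered pair of distinct groups, the
#'   number of adjacent residue pairs belonging to that pair of groups,
#'   divided by `length - 1`; pair order (1,2), (1,3), ..., (6,7);
#' * distribution (35): for each group, the sequence positions (divided
#'   by the protein length) of its 1st occurrence and of occurrence
#'   number `ceiling(q * c)` for q = 25, 50, 75, 100% where c is the
#'   group's occurrence count; absent groups contribute five zeros.
#'
#' @param protein amino-acid string (20-letter alphabet), length >= 2.
#' @return numeric vector of length 63.
#' @export
encode_protein_ctd <- function(protein) {
  p <- toupper(protein)
  if (nchar(p) < 2L) stop("protein shorter than 2 residues", call. = FALSE)
  aa <- strsplit(p, "", fixed = TRUE)[[1L]]
  grp <- unname(ctd_group_index[aa])
  if (anyNA(grp)) {
    stop("non-standard amino acid '", aa[which(is.na(grp))[1L]], "'",
         call. = FALSE)
  }
  n <- length(grp)
  comp <- tabulate(grp, nbins = 7L) / n
  pairs <- which(upper.tri(matrix(0, 7, 7)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  a <- grp[-n]; b <- grp[-1L]
  lo <- pmin(a, b); hi <- pmax(a, b)
  trans <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(lo == pairs[i, "row"] & hi == pairs[i, "col"])
  }, numeric(1)) / (n - 1L)
  qs <- c(0.25, 0.5, 0.75, 1.0)
  distr <- unlist(lapply(1:7, function(g) {
    pos <- which(grp == g)
    cg <- length(pos)
    if (cg == 0L) return(numeric(5))
    ranks <- c(1L, pmax(1L, ceiling(qs * cg)))
    pos[ranks] / n
  }), use.names = FALSE)
  stats::setNames(c(comp, trans, distr),
                  c(paste0("comp.g", 1:7),
                    paste0("trans.g", pairs[, "row"], "g", pairs[, "col"]),
                    paste0("dist.g", rep(1:7, each = 5), ".",
                           rep(c("first", "q25", "q50", "q75", "q100"), 7))))
}

#' Append a protein CTD block to an RNA feature vector
#'
#' @param rna_fv a `feature_vector` from [encode_rna()].
#' @param protein_fv optional 63-element CTD vector from
#'   [encode_protein_ctd()]; NULL leaves the vector unchanged.
#' @return a `feature_vector`; 196 = 133 + 63 elements for w = 25 with
#'   all RNA blocks.
#' @export
assemble <- function(rna_fv, protein_fv = NULL) {
  if (is.null(protein_fv)) return(rna_fv)
  stopifnot(length(protein_fv) == 63L)
  layout <- rbind(fv_blocks(rna_fv), fv_layout("protein", 63L))
  feature_vector(c(unclass(rna_fv), unname(protein_fv)), layout)
}

#' Encode a set of records into a feature matrix
#'
#' @param records list of [seq_record()] (or character vector).
#' @param mpwm,dpwm training PWMs, as for [encode_rna()].
#' @param blocks RNA blocks to emit (see [encode_rna()]).
#' @param protein optional named list/vector mapping RBP tag to a protein
#'   CTD vector; when given, each record's tag selects the appended block.
#' @return list with `x` (numeric matrix, rows = records), `layout`
#'   (block layout data.frame) and `labels` (character vector, when
#'   records carry labels).
#' @export
encode_set <- function(records, mpwm, dpwm,
                       blocks = c("mpwm", "dpwm", "composition"),
                       protein = NULL) {
  if (is.character(records)) {
    records <- lapply(seq_along(records), function(i)
      seq_record(paste0("s", i), records[i]))
  }
  fvs <- lapply(records, function(r) {
    fv <- encode_rna(r, mpwm, dpwm, blocks = blocks)
    if (!is.null(protein)) {
      if (is.na(r$rbp) || is.null(protein[[r$rbp]]))
        stop("no protein descriptor for RBP tag '", r$rbp, "'", call. = FALSE)
      fv <- assemble(fv, protein[[r$rbp]])
    }
    fv
  })
  x <- do.call(rbind, lapply(fvs, unclass))
  rownames(x) <- vapply(records, function(r) r$id, character(1))
  list(x = x, layout = fv_blocks(fvs[[1L]]), labels = record_labels(records))
}

#' Write a labeled feature matrix in sparse SVM-light format
#'
#' One line per row: label then `index:value` pairs (1-based indices,
#' zeros omitted).  A sidecar `<path>.layout` records the block layout.
#'
#' @param x numeric feature matrix.
#' @param y labels; "positive" maps to +1, anything else to -1 (numeric
#'   labels are passed through).
#' @param path output file.
#' @param layout optional layout data.frame for the sidecar.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(x, y, path, layout = NULL) {
  ynum <- if (is.numeric(y)) y else ifelse(y == "positive", 1L, -1L)
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(c(format(ynum[i]),
            sprintf("%d:%.17g", nz, x[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(layout)) {
    utils::write.table(layout, paste0(path, ".layout"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
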