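#' k-mer symbols in lexicographic order
#'
#' Lexicographic order over A < C < G < U, fixing the row layout of every
#' frequency matrix, PWM and composition block.
#'
#' @param k word size.
#' @return character vector of the 4^k k-mers.
#' @export
kmer_symbols <- function(k) {
  stopifnot(k >= 1L)
  grids <- rev(rep(list(RNA_ALPHABET), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

as_sequences <- function(seqs) {
  if (is.character(seqs)) seqs else record_sequences(seqs)
}

## positions x (n - k + 1) integer matrix of k-mer row indices, one row
## per sequence; sequences must share length n
kmer_index_matrix <- function(seqs, k) {
  n <- nchar(seqs[1L])
  chars <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                        RNA_ALPHABET),
                  nrow = length(seqs), ncol = n, byrow = TRUE)
  L <- n - k + 1L
  idx <- matrix(0L, nrow = length(seqs), ncol = L)
  for (j in seq_len(L)) {
    code <- chars[, j]
    if (k > 1L) for (d in seq_len(k - 1L)) {
      code <- (code - 1L) * 4L + chars[, j + d]
    }
    idx[, j] <- code
  }
  idx
}

#' Per-position k-mer frequency matrix
#'
#' Counts the k-mer starting at each position across a set of equal-length
#' sequences and converts counts to smoothed relative frequencies:
#' `freq(s, j) = (count(s, j) + alpha) / (n_seqs + 4^k * alpha)`.
#'
#' @param seqs character vector or list of [seq_record()], all of length
#'   `n`.
#' @param k word size, 1 (mono-) or 2 (di-nucleotides).
#' @param n expected sequence length; defaults to the length of the first
#'   sequence.
#' @param alpha nonnegative additive pseudocount.
#' @return a `freq_matrix`: 4^k x (n-k+1) matrix of frequencies with
#'   attributes `k`, `alpha`, `n`, `n_sequences`; every column sums to 1.
#' @export
count_kmer_frequencies <- function(seqs, k = 1L, n = NULL, alpha = 0) {
  seqs <- as_sequences(seqs)
  if (length(seqs) == 0L) stop("no sequences to count", call. = FALSE)
  stopifnot(k %in% c(1L, 2L), alpha >= 0)
  if (is.null(n)) n <- nchar(seqs[1L])
  lens <- nchar(seqs)
  if (any(lens != n)) {
    i <- which(lens != n)[1L]
    nm <- names(seqs)[i]
    stop("sequence ", if (!is.null(nm) && nzchar(nm)) paste0("'", nm, "' ")
         else paste0("#", i, " "),
         "has length ", lens[i], ", expected ", n, call. = FALSE)
  }
  if (n < k) stop("sequences shorter than k", call. = FALSE)
  syms <- kmer_symbols(k)
  idx <- kmer_index_matrix(seqs, k)
  L <- ncol(idx)
  counts <- matrix(0, nrow = length(syms), ncol = L,
                   dimnames = list(syms, NULL))
  for (j in seq_len(L)) {
    tab <- tabulate(idx[, j], nbins = length(syms))
    counts[, j] <- tab
  }
  freq <- (counts + alpha) / (length(seqs) + length(syms) * alpha)
  structure(freq, k = k, alpha = alpha, n = as.integer(n),
            n_sequences = length(seqs), class = c("freq_matrix", "matrix"))
}

#' Build a log-odds position weight matrix
#'
#' Contrasts positive (binding) against negative (non-binding) training
#' sequences: `score(s, j) = ln(freq_pos(s, j) / freq_neg(s, j))`, both
#' frequency matrices smoothed with the same pseudocount.  `k = 1` gives
#' the mono-nucleotide matrix (4 x n), `k = 2` the di-nucleotide matrix
#' (16 x (n-1)).
#'
#' @param pos,neg positive / negative training sequences (character vector
#'   or list of [seq_record()]), all of one common length `n`.
#' @param k word size, 1 or 2.
#' @param alpha additive pseudocount; must be positive unless both
#'   frequency matrices are everywhere nonzero.
#' @return a `pwm`: 4^k x L score matrix (natural-log units) with
#'   attributes `k`, `n`, `alpha`.
#' @export
build_pwm <- function(pos, neg, k = 1L, alpha = 1) {
  pos <- as_sequences(pos); neg <- as_sequences(neg)
  n <- nchar(pos[1L])
  fp <- count_kmer_frequencies(pos, k = k, n = n, alpha = alpha)
  fn <- count_kmer_frequencies(neg, k = k, n = n, alpha = alpha)
  if (any(fp == 0) || any(fn == 0)) {
    stop("zero frequency encountered with alpha = ", alpha,
         "; set alpha > 0 to keep log-odds finite", call. = FALSE)
  }
  score <- matrix(log(as.numeric(fp) / as.numeric(fn)), nrow = nrow(fp),
                  dimnames = list(rownames(fp), NULL))
  structure(score, k = k, n = as.integer(n), alpha = alpha,
            class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm k=%d, %d x %d, alpha=%g, trained on %d-nt sequences>\n",
              attr(x, "k"), nrow(x), ncol(x), attr(x, "alpha"), attr(x, "n")))
  print(round(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 3))
  if (ncol(x) > 6L) cat("... (", ncol(x) - 6L, " more positions)\n", sep = "")
  invisible(x)
}

#' Per-position profile terms of a sequence under a PWM
#'
#' Element j is the matrix score of the k-mer of `seq` starting at
#' position j.  This vector is the mPWM (or dPWM) block of the feature
#' vector.
#'
#' @param seq RNA string whose length matches the PWM's training length.
#' @param pwm a `pwm` from [build_pwm()].
#' @return numeric vector of length `ncol(pwm)`.
#' @export
profile_terms <- function(seq, pwm) {
  seq <- as_sequences(if (inherits(seq, "seq_record")) list(seq) else seq)
  k <- attr(pwm, "k")
  if (nchar(seq) != attr(pwm, "n")) {
    stop("sequence length ", nchar(seq), " does not match PWM training length ",
         attr(pwm, "n"), call. = FALSE)
  }
  idx <- kmer_index_matrix(seq, k)[1L, ]
  unclass(pwm)[cbind(idx, seq_along(idx))]
}

#' Best ungapped alignment offset of a sequence against a mono PWM
#'
#' For a sequence of length m and a matrix over w positions:
#' * m >= w: returns the start offset (0-based) of the length-w window
#'   with the maximum sum of log-odds scores, offsets `0..m-w`;
#' * m < w: slides the whole sequence along the matrix columns (full
#'   containment, offsets `0..w-m`) and returns the offset maximizing the
#'   sum over the covered columns.
#'
#' Ties are broken toward the smallest offset.
#'
#' @param seq RNA string (or [seq_record()]).
#' @param pwm_mono a mono-nucleotide `pwm` (`k = 1`).
#' @return integer 0-based offset.
#' @export
best_offset <- function(seq, pwm_mono) {
  stopifnot(attr(pwm_mono, "k") == 1L)
  s <- as_sequences(if (inherits(seq, "seq_record")) list(seq) else seq)
  m <- nchar(s)
  w <- ncol(pwm_mono)
  score <- unclass(pwm_mono)
  code <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_ALPHABET)
  if (m >= w) {
    sums <- vapply(0:(m - w), function(o) {
      sum(score[cbind(code[(o + 1L):(o + w)], seq_len(w))])
    }, numeric(1))
  } else {
    sums <- vapply(0:(w - m), function(o) {
      sum(score[cbind(code, (o + 1L):(o + m))])
    }, numeric(1))
  }
  which.max(sums) - 1L
}

#' Write a PWM to a tab-separated file
#'
#' One header comment line carries k, the training length n and the
#' pseudocount; scores are printed at 17 significant digits so that a
#' read/write round trip is bit-stable.
#'
#' @param pwm a `pwm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pwm k=%d n=%d alpha=%s", attr(pwm, "k"),
                     attr(pwm, "n"), sprintf("%.17g", attr(pwm, "alpha"))),
             con)
  syms <- rownames(pwm)
  m <- unclass(pwm)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(syms[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PWM written by [write_pwm()]
#'
#' @param path PWM file.
#' @return a `pwm`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  if (!grepl("^# pwm ", hdr)) stop("not a PWM file: ", path, call. = FALSE)
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (length(m) == 0L) stop("PWM header lacks ", key, call. = FALSE)
    as.numeric(sub(paste0(key, "="), "", m, fixed = TRUE))
  }
  k <- as.integer(get_num("k")); n <- as.integer(get_num("n"))
  alpha <- get_num("alpha")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  syms <- vapply(body, `[`, character(1), 1L)
  m <- t(vapply(body, function(x) as.numeric(x[-1L]),
                numeric(length(body[[1L]]) - 1L)))
  rownames(m) <- syms
  structure(m, k = k, n = n, alpha = alpha, class = c("pwm", "matrix"))
}
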