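## Shared fixtures, all generated in code.

rand_rna <- function(len = 25L) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

## small PWM pair trained on random sequences (seeded by the caller)
toy_pwms <- function(n = 40L, len = 25L, alpha = 1) {
  pos <- replicate(n, rand_rna(len))
  neg <- replicate(n, rand_rna(len))
  list(mpwm = build_pwm(pos, neg, k = 1L, alpha = alpha),
       dpwm = build_pwm(pos, neg, k = 2L, alpha = alpha))
}

write_tmp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}

## well-separated 2D-style toy classification problem embedded in
## d features
toy_xy <- function(n_per_class = 20L, d = 5L, gap = 4) {
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d) + gap,
             matrix(rnorm(n_per_class * d), ncol = d) - gap)
  y <- rep(c("positive", "negative"), each = n_per_class)
  list(x = x, y = y)
}

## brute-force alignment oracle, written independently of best_offset:
## enumerates every admissible placement and sums scores position by
## position with explicit loops
brute_best_offset <- function(seq, pwm) {
  chars <- strsplit(seq, "")[[1]]
  score <- unclass(pwm)
  m <- length(chars)
  w <- ncol(score)
  best <- -Inf
  best_o <- NA_integer_
  offsets <- if (m >= w) 0:(m - w) else 0:(w - m)
  for (o in offsets) {
    total <- 0
    if (m >= w) {
      for (j in 1:w) total <- total + score[chars[o + j], j]
    } else {
      for (p in 1:m) total <- total + score[chars[p], o + p]
    }
    if (total > best + 1e-12) { best <- total; best_o <- o }
  }
  best_o
}
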