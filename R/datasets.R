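#' Labeled sequence set
#'
#' A list of records plus a ratio descriptor and provenance notes
#' (filters applied, seeds used).
#'
#' @param records list of [seq_record()].
#' @param provenance named list of notes.
#' @return a `labeled_set`.
#' @export
labeled_set <- function(records, provenance = list()) {
  labels <- record_labels(records)
  structure(list(records = records,
                 n_positive = sum(labels == "positive"),
                 n_negative = sum(labels == "negative"),
                 provenance = provenance),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("<labeled_set: %d positive, %d negative, %d groups>\n",
              x$n_positive, x$n_negative,
              length(unique(stats::na.omit(record_rbps(x$records))))))
  invisible(x)
}

dataset_records <- function(data) {
  if (inherits(data, "labeled_set")) data$records else data
}

#' Sample random background (non-binding) regions from a genome
#'
#' Draws fixed-length regions uniformly over admissible '+'-strand start
#' positions, excluding any interval overlapping a known binding region
#' and any slice containing N.  The default multiplicity in the study
#' design is 10 negatives per positive.
#'
#' @param genome a `genome_source`.
#' @param n number of regions to draw.
#' @param length region length (nt).
#' @param exclude optional `region_table` of intervals that must not be
#'   overlapped (e.g. the positive regions).
#' @param seed integer seed.
#' @return list of [seq_record()] labeled "negative".
#' @export
sample_negatives_random <- function(genome, n, length = 25L, exclude = NULL,
                                    seed = 1L) {
  stopifnot(n >= 1L)
  lens <- genome_lengths(genome)
  chroms <- names(lens)
  admissible <- pmax(lens - length + 1L, 0L)
  if (sum(admissible) < 1L)
    stop("genome too short for regions of length ", length, call. = FALSE)
  ok_overlap <- function(chrom, start) {
    if (is.null(exclude)) return(TRUE)
    ex <- exclude[exclude$chrom == chrom, , drop = FALSE]
    if (nrow(ex) == 0L) return(TRUE)
    !any(start < ex$end & (start + length) > ex$start)
  }
  out <- vector("list", n)
  got <- 0L
  withr::with_seed(seed, {
    tries <- 0L
    max_tries <- max(10000L, 1000L * n)
    while (got < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not find ", n, " admissible regions after ", max_tries,
             " draws; genome exhausted?", call. = FALSE)
      }
      chrom <- sample(chroms, 1L, prob = admissible)
      start <- sample.int(admissible[[chrom]], 1L) - 1L
      if (!ok_overlap(chrom, start)) next
      reg <- list(chrom = chrom, start = start, end = start + length,
                  strand = "+", rbp = NA_character_)
      rec <- suppressWarnings(
        extract_region_sequence(genome, reg, label = "negative",
                                on_n = "skip"))
      if (is.null(rec)) next
      got <- got + 1L
      rec$id <- sprintf("neg_%d_%s:%d-%d", got, chrom, start, start + length)
      out[[got]] <- rec
    }
  })
  out
}

#' Sample upstream negatives at a fixed distance from positives
#'
#' For each positive region the negative of the same length ends exactly
#' `distance` bases before the region start, on the region's strand (for
#' '-' regions "upstream" lies at larger genomic coordinates).  Regions
#' falling off the chromosome are skipped with a warning.  Distances from
#' 1 to 1001 nt probe how background similarity decays near binding
#' sites.
#'
#' @param positives a `region_table` of binding regions.
#' @param genome a `genome_source`.
#' @param distance gap in nt between negative end and positive start
#'   (>= 1).
#' @param length negative region length.
#' @return list of [seq_record()] labeled "negative", tagged with the
#'   positive's RBP.
#' @export
sample_negatives_upstream <- function(positives, genome, distance,
                                      length = 25L) {
  stopifnot(distance >= 1L)
  lens <- genome_lengths(genome)
  out <- list()
  for (i in seq_len(nrow(positives))) {
    p <- as.list(positives[i, , drop = FALSE])
    if (identical(p$strand, "-")) {
      start <- p$end + distance
      end <- start + length
      if (end > lens[[p$chrom]]) {
        warning("skipping upstream negative for region ", i,
                ": beyond chromosome end", call. = FALSE)
        next
      }
    } else {
      end <- p$start - distance
      start <- end - length
      if (start < 0L) {
        warning("skipping upstream negative for region ", i,
                ": beyond chromosome start", call. = FALSE)
        next
      }
    }
    reg <- list(chrom = p$chrom, start = start, end = end,
                strand = p$strand, rbp = p$rbp)
    rec <- suppressWarnings(
      extract_region_sequence(genome, reg, label = "negative",
                              on_n = "skip"))
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  out
}

## global alignment identity: match +1, mismatch 0, gaps free (including
## end gaps); identity = matches / alignment length
alignment_identity <- function(a, b) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    chartr("U", "T", a), chartr("U", "T", b), type = "overlap",
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 0)
  Biostrings::pid(aln, type = "PID2") / 100
}

#' Greedy redundancy removal by alignment identity
#'
#' Sequences are scanned in input order; one is dropped when its global
#' alignment identity (matches over alignment length; match +1, mismatch
#' 0, gaps free) to any retained representative — or, in two-set mode, to
#' any member of `reference` — reaches the threshold, otherwise it
#' becomes a representative.  This greedy identity clustering plays the
#' role CD-HIT-EST plays on real data (threshold 0.8 within a set, 0.8 or
#' 0.9 across sets).
#'
#' @param seqs list of [seq_record()].
#' @param threshold identity threshold t in (0, 1]; drop at identity
#'   >= t.
#' @param reference optional list of [seq_record()]; two-set mode.
#' @return the surviving records, input order preserved.
#' @export
redundancy_filter <- function(seqs, threshold = 0.8, reference = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  ref_seqs <- if (is.null(reference)) character(0) else
    record_sequences(reference)
  kept <- logical(length(seqs))
  reps <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]$sequence
    against <- c(reps, ref_seqs)
    dup <- FALSE
    for (r in against) {
      if (alignment_identity(s, r) >= threshold) { dup <- TRUE; break }
    }
    if (!dup) {
      kept[i] <- TRUE
      reps <- c(reps, s)
    }
  }
  seqs[kept]
}

#' Build class-ratio datasets (1:1 ... 1:10)
#'
#' Each dataset keeps all positives and pairs them with `r * n_pos`
#' negatives drawn from the pool without replacement.  Sampling is
#' nested: the negatives of a smaller ratio are a subset of every larger
#' ratio's, so datasets differ only by added negatives.
#'
#' @param pos list of positive [seq_record()].
#' @param neg_pool list of negative [seq_record()].
#' @param ratios integer negative multiplicities (default 1, 2, 4, 6, 8,
#'   10).
#' @param seed integer seed for the pool shuffle.
#' @return named list of [labeled_set()], one per ratio ("1:1", ...).
#' @export
make_ratio_datasets <- function(pos, neg_pool, ratios = c(1, 2, 4, 6, 8, 10),
                                seed = 1L) {
  need <- max(ratios) * length(pos)
  if (length(neg_pool) < need) {
    stop("negative pool has ", length(neg_pool), " sequences; ", need,
         " needed for ratio 1:", max(ratios), call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(neg_pool))
  out <- lapply(ratios, function(r) {
    labeled_set(c(pos, shuffled[seq_len(r * length(pos))]),
                provenance = list(ratio = paste0("1:", r), seed = seed,
                                  nested = TRUE))
  })
  stats::setNames(out, paste0("1:", ratios))
}

#' Stratified train/test split
#'
#' Splits by label and RBP group: within each stratum a seeded shuffle,
#' with per-label training totals hitting `round(fraction * n_label)`
#' (floors plus largest-remainder top-up across strata).  Strata of one
#' sequence go wholly to training with a warning.
#'
#' @param set a [labeled_set()] or list of records.
#' @param fraction training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` ([labeled_set()]s).
#' @export
split_train_test <- function(set, fraction = 0.7, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  records <- dataset_records(set)
  labels <- record_labels(records)
  rbps <- record_rbps(records)
  rbps[is.na(rbps)] <- "<none>"
  train_idx <- integer(0)
  for (lab in unique(labels)) {
    in_label <- which(labels == lab)
    target <- round(fraction * length(in_label))
    strata <- split(in_label, rbps[in_label])
    takes <- vapply(strata, function(s) floor(fraction * length(s)),
                    numeric(1))
    singles <- vapply(strata, length, integer(1)) == 1L
    if (any(singles)) {
      warning("stratum too small to split; sent wholly to training",
              call. = FALSE)
      takes[singles] <- 1L
    }
    rem <- vapply(strata, function(s) fraction * length(s), numeric(1)) -
      floor(vapply(strata, function(s) fraction * length(s), numeric(1)))
    short <- target - sum(takes)
    if (short > 0L) {
      order_rem <- order(-rem)
      for (j in order_rem) {
        if (short == 0L) break
        if (!singles[j] && takes[j] < length(strata[[j]])) {
          takes[j] <- takes[j] + 1L
          short <- short - 1L
        }
      }
    }
    withr::with_seed(seed + match(lab, unique(labels)), {
      for (j in seq_along(strata)) {
        s <- shuffle(strata[[j]])
        train_idx <- c(train_idx, s[seq_len(min(takes[j], length(s)))])
      }
    })
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(records), train_idx)
  prov <- list(fraction = fraction, seed = seed)
  list(train = labeled_set(records[train_idx], prov),
       test = labeled_set(records[test_idx], prov))
}

#' Positional motif model for synthetic data
#'
#' Describes the generative ground truth the synthetic fixture plants: a
#' per-column nucleotide probability table for positives and a background
#' distribution for negatives.  The default emulates a short RBP
#' recognition element: an 8-nt core with consensus UGUAUAUA at columns
#' 9-16, each core column placing probability 0.85 on its consensus
#' letter (the other three sharing the remainder), uniform flanks and
#' uniform background.
#'
#' @param w sequence length (default 25).
#' @param core_start first core column (1-based).
#' @param consensus core consensus string (letters over A/C/G/U).
#' @param consensus_prob probability of the consensus letter at each core
#'   column.
#' @param background length-4 background probabilities (A, C, G, U).
#' @return a `motif_model`: list with `table` (4 x w column-stochastic
#'   matrix), `background`, `w`.
#' @export
motif_model <- function(w = 25L, core_start = 9L, consensus = "UGUAUAUA",
                        consensus_prob = 0.85,
                        background = rep(0.25, 4)) {
  stopifnot(consensus_prob > 0, consensus_prob <= 1,
            abs(sum(background) - 1) < 1e-9)
  core <- strsplit(normalize_rna(consensus), "", fixed = TRUE)[[1L]]
  stopifnot(core_start >= 1L, core_start + length(core) - 1L <= w)
  tab <- matrix(0.25, nrow = 4L, ncol = w,
                dimnames = list(RNA_ALPHABET, NULL))
  for (j in seq_along(core)) {
    col <- rep((1 - consensus_prob) / 3, 4)
    col[match(core[j], RNA_ALPHABET)] <- consensus_prob
    tab[, core_start + j - 1L] <- col
  }
  structure(list(table = tab, background = stats::setNames(background,
                                                           RNA_ALPHABET),
                 w = as.integer(w)), class = "motif_model")
}

#' Uniform (uninformative) motif model
#'
#' Positives and negatives are drawn from the same uniform distribution;
#' downstream classifiers should perform at chance (MCC near 0).
#'
#' @param w sequence length.
#' @return a `motif_model`.
#' @export
motif_model_null <- function(w = 25L) {
  m <- motif_model(w = w, consensus_prob = 0.25001)
  m$table[] <- 0.25
  m
}

#' True per-position log-odds of a motif model
#'
#' The analytic ln(positive frequency / background frequency) table the
#' empirical mono-nucleotide PWM estimates.
#'
#' @param model a [motif_model()].
#' @return 4 x w numeric matrix.
#' @export
motif_true_logodds <- function(model) {
  log(model$table / model$background)
}

#' Generate a synthetic labeled sequence set with known ground truth
#'
#' Positives are drawn column-wise from the motif model's positional
#' table, negatives i.i.d. from its background; records are tagged
#' round-robin with synthetic RBP names so grouped (leave-one-protein-
#' out) evaluation is exercisable.  The defaults mirror the study
#' conditions of the desk-scale fixture: 2,000 sequences per class, 25
#' nt, 14 RBP groups.
#'
#' @param model a [motif_model()].
#' @param n_pos,n_neg class sizes.
#' @param n_groups number of synthetic RBP groups.
#' @param seed integer seed.
#' @return a [labeled_set()].
#' @export
synth_generate <- function(model = motif_model(), n_pos = 2000L,
                           n_neg = 2000L, n_groups = 14L, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, n_groups >= 1L)
  w <- model$w
  groups <- sprintf("RBP%02d", seq_len(n_groups))
  withr::with_seed(seed, {
    pos_mat <- vapply(seq_len(w), function(j) {
      sample(RNA_ALPHABET, n_pos, replace = TRUE, prob = model$table[, j])
    }, character(n_pos))
    neg_mat <- vapply(seq_len(w), function(j) {
      sample(RNA_ALPHABET, n_neg, replace = TRUE, prob = model$background)
    }, character(n_neg))
  })
  collapse <- function(m) apply(m, 1L, paste, collapse = "")
  pos_seqs <- collapse(matrix(pos_mat, nrow = n_pos))
  neg_seqs <- collapse(matrix(neg_mat, nrow = n_neg))
  pos <- lapply(seq_len(n_pos), function(i) {
    seq_record(sprintf("pos_%04d", i), pos_seqs[i], label = "positive",
               rbp = groups[((i - 1L) %% n_groups) + 1L])
  })
  neg <- lapply(seq_len(n_neg), function(i) {
    seq_record(sprintf("neg_%04d", i), neg_seqs[i], label = "negative",
               rbp = groups[((i - 1L) %% n_groups) + 1L])
  })
  labeled_set(c(pos, neg),
              provenance = list(generator = "synth_generate", seed = seed,
                                n_groups = n_groups))
}

#' Write a labeled set as FASTA plus a label sidecar
#'
#' @param set a [labeled_set()].
#' @param fasta_path sequences (FASTA).
#' @param sidecar_path tab-separated id/label/rbp table; defaults to
#'   `<fasta_path>.labels.tsv`.
#' @return `fasta_path`, invisibly.
#' @export
write_labeled_set <- function(set, fasta_path,
                              sidecar_path = paste0(fasta_path,
                                                    ".labels.tsv")) {
  records <- dataset_records(set)
  write_fasta(records, fasta_path)
  utils::write.table(
    data.frame(id = vapply(records, function(r) r$id, character(1)),
               label = record_labels(records), rbp = record_rbps(records)),
    sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a labeled set written by [write_labeled_set()]
#'
#' @param fasta_path sequences (FASTA).
#' @param sidecar_path label sidecar.
#' @return a [labeled_set()].
#' @export
read_labeled_set <- function(fasta_path,
                             sidecar_path = paste0(fasta_path,
                                                   ".labels.tsv")) {
  recs <- read_fasta(fasta_path)
  meta <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
  idx <- match(vapply(recs, function(r) r$id, character(1)), meta$id)
  if (anyNA(idx)) stop("sidecar is missing ids from the FASTA", call. = FALSE)
  recs <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    r$label <- meta$label[idx[i]]
    r$rbp <- as.character(meta$rbp[idx[i]])
    r
  })
  labeled_set(recs)
}
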