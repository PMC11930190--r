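# Kennard-Stone sample-set partitioning.
#
# K-S is deterministic: it seeds with the two most distant samples and then
# repeatedly adds the sample whose minimum distance to the selected set is
# largest, giving calibration sets that span the feature space. All models in
# the pipeline consume partitions produced here so every stage sees identical
# splits.

#' Kennard-Stone ordering of samples
#'
#' Returns a total order over all rows: the first two indices are the pair
#' with maximum Euclidean distance (ties broken by the lowest index pair);
#' each subsequent index maximizes its minimum distance to the selected set
#' (ties by lowest index).
#'
#' @param features numeric matrix (n x p) or `spectrum_set`.
#' @return integer vector of length n.
#' @export
kennard_stone_order <- function(features) {
  if (inherits(features, "spectrum_set")) features <- features$absorbance
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("Kennard-Stone needs at least 2 samples")
  if (anyNA(features)) stop("missing values in feature matrix")
  D <- as.matrix(dist(features))
  # seed pair: maximum distance, lowest (i, j) on ties (row-major scan of
  # the upper triangle)
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(n - 1)) {
    row <- D[i, (i + 1):n]
    m <- max(row)
    if (m > best) { best <- m; bi <- i; bj <- i + which.max(row) }
  }
  sel <- c(bi, bj)
  remaining <- setdiff(seq_len(n), sel)
  mind <- pmin(D[, bi], D[, bj])
  while (length(remaining)) {
    cand <- remaining[which.max(mind[remaining])]  # which.max -> lowest index tie-break
    sel <- c(sel, cand)
    remaining <- setdiff(remaining, cand)
    mind <- pmin(mind, D[, cand])
  }
  as.integer(sel)
}

# Largest-remainder apportionment of n into round(f * n) blocks.
largest_remainder <- function(n, fractions) {
  q <- fractions * n
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    # distribute leftover units by descending fractional part, ties by
    # earlier partition
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Kennard-Stone split into named partitions
#'
#' The first `round(f1 * n)` samples of the K-S order form the first
#' partition, the next block the second, and so on; block sizes come from
#' largest-remainder rounding so they differ from exact proportions by at
#' most one.
#'
#' @param features matrix or `spectrum_set`.
#' @param fractions named numeric proportions summing to 1 (e.g.
#'   `c(calibration = 0.7, test = 0.3)`).
#' @param per_class optional factor; when supplied, K-S runs separately
#'   inside every class and partitions are unions over classes.
#' @return a `split_indices` object: named list of integer index vectors,
#'   with the fractions and sizes attached.
#' @export
ks_split <- function(features, fractions = c(calibration = 0.7, test = 0.3),
                     per_class = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (is.null(names(fractions)))
    names(fractions) <- paste0("partition", seq_along(fractions))
  feat <- if (inherits(features, "spectrum_set")) features$absorbance else
    as.matrix(features)
  n <- nrow(feat)
  assign_block <- function(ord) {
    sizes <- largest_remainder(length(ord), fractions)
    if (any(sizes == 0)) stop("a partition rounds to zero samples")
    splitf <- rep(seq_along(sizes), sizes)
    split(ord, splitf)
  }
  if (is.null(per_class)) {
    parts <- assign_block(kennard_stone_order(feat))
  } else {
    per_class <- as.factor(per_class)
    parts <- vector("list", length(fractions))
    for (cl in levels(per_class)) {
      idx <- which(per_class == cl)
      blk <- assign_block(idx[kennard_stone_order(feat[idx, , drop = FALSE])])
      for (b in seq_along(blk))
        parts[[b]] <- c(parts[[b]], blk[[b]])
    }
    parts <- lapply(parts, sort)
  }
  names(parts) <- names(fractions)
  structure(lapply(parts, as.integer),
            fractions = fractions,
            sizes = vapply(parts, length, integer(1)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  s <- attr(x, "sizes")
  cat("<split_indices>", paste(sprintf("%s: %d", names(x), s), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a split to CSV (sample_id, partition)
#'
#' @param split a `split_indices`.
#' @param sample_ids character ids indexed by the split.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, sample_ids, path) {
  df <- do.call(rbind, lapply(names(split), function(p)
    data.frame(sample_id = sample_ids[split[[p]]], partition = p)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
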