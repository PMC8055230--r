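contingency_table <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have equal length.")
  }
  if (length(labels_a) < 1) abort("Empty labelings.")
  unname(table(factor(labels_a), factor(labels_b)))
}

same_partition <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  sum(ct > 0) == max(nrow(ct), ncol(ct))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-adjusted pair-counting agreement computed from the contingency
#' table of the two labelings. Takes values in `[-1, 1]`: 1 iff the
#' partitions are identical up to relabeling, around 0 for independent
#' labelings. Degenerate cases with a vanishing adjustment denominator
#' (e.g. both partitions a single cluster) return 1 when the partitions
#' coincide and 0 otherwise.
#'
#' @param labels_a,labels_b Vectors of cluster labels for the same items.
#' @return Scalar index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(as.numeric(same_partition(labels_a, labels_b)))
  }
  (sum_ij - expected) / (max_index - expected)
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Expected mutual information under the permutation (hypergeometric) model.
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
      emi <- emi + sum(exp(lp) * (nij / n) * log(n * nij / (ai * bj)))
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information adjusted for chance under the permutation model, with
#' max normalization:
#' \eqn{AMI = (MI - E[MI]) / (\max(H_a, H_b) - E[MI])}.
#' Equals 1 for identical partitions and has expectation approximately 0
#' for independent random labelings.
#'
#' @inheritParams adjusted_rand_index
#' @return Scalar index.
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  p <- ct / n
  nz <- ct > 0
  mi <- sum(p[nz] * log(ct[nz] * n / outer(a, b)[nz]))
  emi <- expected_mutual_information(a, b, n)
  denom <- max(entropy_counts(a), entropy_counts(b)) - emi
  if (abs(denom) < 1e-12) {
    return(as.numeric(same_partition(labels_a, labels_b)))
  }
  (mi - emi) / denom
}

#' Fowlkes-Mallows index between two partitions
#'
#' Geometric mean of pairwise precision and recall:
#' \eqn{FMI = TP / \sqrt{(TP + FP)(TP + FN)}} where pairs of items are
#' counted as true positives when co-clustered in both partitions.
#'
#' @inheritParams adjusted_rand_index
#' @return Scalar index in `[0, 1]`.
#' @export
fowlkes_mallows <- function(labels_a, labels_b) {
  ct <- contingency_table(labels_a, labels_b)
  tp <- sum(choose(ct, 2))
  pa <- sum(choose(rowSums(ct), 2))
  pb <- sum(choose(colSums(ct), 2))
  if (pa == 0 || pb == 0) {
    return(as.numeric(same_partition(labels_a, labels_b)))
  }
  tp / sqrt(pa * pb)
}
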