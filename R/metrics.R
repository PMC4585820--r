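.jointEntropies <- function(c1, c2) {
  if (!setequal(c1@nodes, c2@nodes))
    stop("partitions are over different node sets")
  m1 <- c1@membership
  m2 <- c2@membership[match(c1@nodes, c2@nodes)]
  n <- length(m1)
  joint <- table(m1, m2) / n
  H12 <- -sum(.plogp(as.numeric(joint)))
  H1 <- -sum(.plogp(rowSums(joint)))
  H2 <- -sum(.plogp(colSums(joint)))
  list(H1 = H1, H2 = H2, H12 = H12)
}

#' Normalized Variation of Information
#'
#' `NVI(C1, C2) = [H(C1|C2) + H(C2|C1)] / H(C1, C2)` with base-2 entropies
#' (the normalization cancels the base). NVI is a metric on partitions: 0
#' iff the partitions are identical, 1 iff they are statistically
#' independent. When both partitions are all-in-one the joint entropy is 0
#' and NVI is defined as 0.
#'
#' @param c1,c2 [Partition-class] objects over the same node set.
#' @return A value in `[0, 1]`.
#' @examples
#' p1 <- Partition(c(1, 1, 2, 2)); p2 <- Partition(c(1, 2, 1, 2))
#' nvi(p1, p2)  # 1: statistically independent
#' nvi(p1, p1)  # 0
#' @export
nvi <- function(c1, c2) {
  h <- .jointEntropies(c1, c2)
  if (h$H12 == 0) return(0)
  ((h$H12 - h$H2) + (h$H12 - h$H1)) / h$H12
}

#' Normalized Mutual Information (joint-entropy normalization)
#'
#' `NMI(C1, C2) = I(C1; C2) / H(C1, C2)`. With this normalization
#' `nvi(a, b) + nmi(a, b) = 1` for every pair of partitions; note that
#' other common NMI variants normalize by `(H1 + H2) / 2` or
#' `max(H1, H2)` instead.
#'
#' @inheritParams nvi
#' @return A value in `[0, 1]`; 1 for identical partitions (including the
#'   degenerate case of two all-in-one partitions), 0 for independent ones.
#' @export
nmi <- function(c1, c2) {
  h <- .jointEntropies(c1, c2)
  if (h$H12 == 0) return(1)
  (h$H1 + h$H2 - h$H12) / h$H12
}
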