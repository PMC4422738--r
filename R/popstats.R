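#' Observed heterozygosity per locus
#'
#' The proportion of heterozygous genotypes among non-missing genotypes at
#' each locus, for a set of individuals (typically one genetic cluster).
#'
#' @param x A genotype table.
#' @param subset Optional character vector of individuals; defaults to all.
#' @return Tibble `locus`, `n_typed`, `h_obs`. Loci with zero non-missing
#'   genotypes are dropped with a warning; the conventional summary
#'   statistic is the unweighted mean of `h_obs` over loci.
#' @export
observed_heterozygosity <- function(x, subset = NULL) {
  if (is.null(subset)) subset <- individuals(x)
  sub <- dplyr::filter(tibble::as_tibble(x), .data$individual %in% subset)
  out <- dplyr::summarise(
    dplyr::group_by(sub, locus = factor(.data$locus, levels = loci(x))),
    n_typed = sum(!is.na(.data$allele1)),
    h_obs = ifelse(.data$n_typed > 0,
                   sum(.data$allele1 != .data$allele2, na.rm = TRUE) / .data$n_typed,
                   NA_real_),
    .groups = "drop"
  )
  if (any(out$n_typed == 0)) {
    warning("locus with no typed genotypes excluded: ",
            paste(out$locus[out$n_typed == 0], collapse = ", "), call. = FALSE)
    out <- out[out$n_typed > 0, , drop = FALSE]
  }
  out$locus <- as.character(out$locus)
  out
}

#' Unbiased expected heterozygosity per locus
#'
#' Nei's gene diversity with the small-sample correction
#' `2N/(2N - 1) * (1 - sum p^2)`, computed from an allele count table.
#'
#' @param counts An [allele_counts()] table.
#' @return Tibble `locus`, `n_copies`, `uh_exp`. Loci with fewer than two
#'   typed gene copies are excluded with a warning.
#' @export
unbiased_expected_het <- function(counts) {
  out <- dplyr::summarise(
    dplyr::group_by(counts, .data$locus),
    n_copies = .data$total[1],
    uh_exp = (.data$n_copies / (.data$n_copies - 1)) * (1 - sum(.data$freq^2)),
    .groups = "drop"
  )
  if (any(out$n_copies < 2)) {
    warning("locus with < 2 gene copies excluded: ",
            paste(out$locus[out$n_copies < 2], collapse = ", "), call. = FALSE)
    out <- out[out$n_copies >= 2, , drop = FALSE]
  }
  out
}

#' Rarefied allelic richness per locus
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' diploid individuals (`2g` gene copies), computed by the hypergeometric
#' rarefaction formula
#' `A_R(l) = sum_a (1 - choose(2N_l - c_a, 2g) / choose(2N_l, 2g))`.
#' Rarefaction makes allele counts comparable across clusters of unequal
#' sample size.
#'
#' @param counts An [allele_counts()] table.
#' @param g Rarefaction base in diploid individuals; must satisfy
#'   `2 * g <= total` at every locus.
#' @return Tibble `locus`, `a_r`.
#' @export
allelic_richness <- function(counts, g) {
  stopifnot(g >= 1)
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$locus),
                             total = .data$total[1], .groups = "drop")
  short <- totals$locus[totals$total < 2 * g]
  if (length(short) > 0) {
    stop("rarefaction base 2g = ", 2 * g,
         " exceeds the typed gene copies at locus ",
         paste(short, collapse = ", "), "; lower g", call. = FALSE)
  }
  # lchoose(m, k) = -Inf when m < k, so exp() implements choose(m, k) = 0
  dplyr::summarise(
    dplyr::group_by(counts, .data$locus),
    a_r = sum(1 - exp(lchoose(.data$total - .data$count, 2 * g) -
                        lchoose(.data$total, 2 * g))),
    .groups = "drop"
  )
}

#' Classify cluster alleles as low-frequency and/or private
#'
#' For every allele observed in the focal cluster, computes its frequency
#' from the cluster's unfiltered counts, flags it as *low-frequency* when
#' the frequency is strictly below `threshold`, and as *private* when the
#' allele is absent from every other cluster of the dataset. Low-frequency
#' alleles are used to flag possibly immigrant or admixed genotypes before
#' founder estimation; privacy is always assessed against the full dataset.
#'
#' @param x A genotype table.
#' @param clusters Cluster assignment tibble (`individual`, `cluster`).
#' @param focal Label of the focal cluster.
#' @param threshold Low-frequency cut-off as a strict upper bound
#'   (default 0.02).
#' @return Tibble `locus`, `allele`, `count`, `freq`, `is_low_frequency`,
#'   `is_private`.
#' @export
classify_alleles <- function(x, clusters, focal, threshold = 0.02) {
  stopifnot(threshold > 0, threshold < 1)
  clusters <- validate_clusters(x, clusters)
  members <- clusters$individual[clusters$cluster == focal]
  if (length(members) == 0) stop("cluster '", focal, "' is empty", call. = FALSE)
  others <- clusters$individual[clusters$cluster != focal]

  focal_counts <- allele_counts(x, members)
  if (length(others) > 0) {
    other_counts <- allele_counts(x, others)
    other_key <- paste(other_counts$locus, other_counts$allele)
  } else {
    other_key <- character(0)
  }
  tibble::tibble(
    locus = focal_counts$locus,
    allele = focal_counts$allele,
    count = focal_counts$count,
    freq = focal_counts$freq,
    is_low_frequency = focal_counts$freq < threshold,
    is_private = !(paste(focal_counts$locus, focal_counts$allele) %in% other_key)
  )
}

# Weir & Cockerham (1984) variance components for one locus and one pair of
# clusters. geno is the locus slice of the genotype table restricted to the
# two clusters; returns c(a = ..., bc = a + b + c summand) accumulated over
# alleles, or NULL when the locus is uninformative for the pair.
wc_components_locus <- function(geno, grp) {
  keep <- !is.na(geno$allele1)
  geno <- geno[keep, , drop = FALSE]
  grp <- grp[keep]
  n_i <- as.vector(table(grp)[c("1", "2")])
  if (any(is.na(n_i)) || any(n_i < 2)) return(NULL)
  alleles <- sort(unique(c(geno$allele1, geno$allele2)))
  if (length(alleles) < 2) return(NULL)

  r <- 2
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  a_sum <- 0
  abc_sum <- 0
  for (al in alleles) {
    copies <- (geno$allele1 == al) + (geno$allele2 == al)
    het <- (geno$allele1 == al) != (geno$allele2 == al)
    p_i <- tapply(copies, grp, sum) / (2 * n_i)
    h_i <- tapply(het, grp, mean)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (1 / (n_bar - 1)) *
         (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
         ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
    cc <- h_bar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  c(a = a_sum, abc = abc_sum)
}

#' Pairwise F_ST between genetic clusters
#'
#' Multi-locus Weir & Cockerham (1984) theta for every pair of clusters:
#' the ratio of the summed among-population variance component to the
#' summed total variance over all alleles and loci. Negative estimates are
#' reported as computed (they are expected around zero differentiation)
#' unless `floor_zero = TRUE`.
#'
#' @param x A genotype table.
#' @param clusters Cluster assignment tibble; every cluster must contain at
#'   least two individuals.
#' @param floor_zero Truncate negative estimates at 0 for reporting.
#' @return Tibble `cluster_a`, `cluster_b`, `theta` (one row per unordered
#'   pair; `NA` with a warning for pairs sharing no polymorphic locus).
#'   Convert to a symmetric matrix with [fst_matrix()].
#' @export
pairwise_fst <- function(x, clusters, floor_zero = FALSE) {
  clusters <- validate_clusters(x, clusters)
  labels <- unique(clusters$cluster)
  if (length(labels) < 2) stop("need at least two clusters", call. = FALSE)
  sizes <- table(clusters$cluster)
  if (any(sizes < 2)) {
    stop("cluster(s) with fewer than 2 individuals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::as_tibble(x)
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    m1 <- clusters$individual[clusters$cluster == pr[1]]
    m2 <- clusters$individual[clusters$cluster == pr[2]]
    sub <- tbl[tbl$individual %in% c(m1, m2), , drop = FALSE]
    grp <- ifelse(sub$individual %in% m1, "1", "2")
    comps <- purrr::map(split(seq_len(nrow(sub)), sub$locus), function(idx) {
      wc_components_locus(sub[idx, , drop = FALSE], grp[idx])
    })
    comps <- purrr::compact(comps)
    if (length(comps) == 0) {
      warning("clusters ", pr[1], " and ", pr[2],
              " share no polymorphic locus; theta undefined", call. = FALSE)
      theta <- NA_real_
    } else {
      sums <- Reduce(`+`, comps)
      theta <- unname(sums["a"] / sums["abc"])
      if (floor_zero && !is.na(theta)) theta <- max(theta, 0)
    }
    tibble::tibble(cluster_a = pr[1], cluster_b = pr[2], theta = theta)
  })
  class(res) <- c("pairwise_fst", class(res))
  res
}

#' @rdname pairwise_fst
#' @param fst A [pairwise_fst()] result.
#' @return For `fst_matrix()`, a symmetric numeric matrix with zero
#'   diagonal.
#' @export
fst_matrix <- function(fst) {
  labels <- unique(c(fst$cluster_a, fst$cluster_b))
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_len(nrow(fst))) {
    m[fst$cluster_a[i], fst$cluster_b[i]] <- fst$theta[i]
    m[fst$cluster_b[i], fst$cluster_a[i]] <- fst$theta[i]
  }
  m
}

#' Per-cluster diversity summary table
#'
#' One row per cluster with the standard microsatellite diversity report:
#' sample size `N`, mean alleles per locus `A`, total allele count
#' `A_total`, rarefied allelic richness `A_R` at base `g`, mean observed
#' heterozygosity `H_O`, mean unbiased expected heterozygosity `uH_E`,
#' private allele count `pA` and the frequency range of private alleles
#' (`freq_pA`, from unfiltered counts).
#'
#' @param x A genotype table.
#' @param clusters Cluster assignment tibble.
#' @param g Rarefaction base in diploid individuals. Defaults to the
#'   largest base every cluster and locus supports (the minimum per-locus
#'   typed sample over clusters); for datasets shaped like a multi-cluster
#'   microsatellite survey with a smallest cluster of 13, this reproduces
#'   the conventional base of 13.
#' @return Tibble with one row per cluster (cluster order = order of first
#'   appearance in `clusters`).
#' @export
cluster_stats <- function(x, clusters, g = NULL) {
  clusters <- validate_clusters(x, clusters)
  labels <- unique(clusters$cluster)
  counts_by_cluster <- purrr::map(setNames(labels, labels), function(cl) {
    allele_counts(x, clusters$individual[clusters$cluster == cl])
  })
  if (is.null(g)) {
    g <- floor(min(purrr::map_dbl(counts_by_cluster,
                                  function(ct) min(ct$total))) / 2)
  }
  purrr::map_dfr(setNames(labels, labels), function(cl) {
    members <- clusters$individual[clusters$cluster == cl]
    ct <- counts_by_cluster[[cl]]
    per_locus_A <- dplyr::count(ct, .data$locus, name = "n_alleles")
    ho <- observed_heterozygosity(x, members)
    uhe <- unbiased_expected_het(ct)
    ar <- allelic_richness(ct, g)
    cls <- classify_alleles(x, clusters, cl, threshold = 0.02)
    priv <- cls[cls$is_private, , drop = FALSE]
    tibble::tibble(
      cluster = cl,
      N = length(members),
      A = mean(per_locus_A$n_alleles),
      A_total = sum(per_locus_A$n_alleles),
      A_R = mean(ar$a_r),
      H_O = mean(ho$h_obs),
      uH_E = mean(uhe$uh_exp),
      pA = nrow(priv),
      freq_pA_min = if (nrow(priv) > 0) min(priv$freq) else NA_real_,
      freq_pA_max = if (nrow(priv) > 0) max(priv$freq) else NA_real_
    )
  })
}
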