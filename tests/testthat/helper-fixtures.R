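# Fixtures are built in code; nothing is read from disk.

# A minimal genotype table from vectors.
toy_geno <- function(ind, locus, a1, a2) {
  suppressWarnings(as_geno_tbl(tibble::tibble(
    individual = ind, locus = locus,
    allele1 = as.integer(a1), allele2 = as.integer(a2))))
}

# Random fully-typed dataset: n_ind individuals, n_loc loci, alleles drawn
# uniformly from 1..n_all (per locus the realized allele set may be smaller).
random_geno <- function(n_ind, n_loc, n_all, seed) {
  withr::with_seed(seed, {
    long <- expand.grid(individual = sprintf("i%03d", seq_len(n_ind)),
                        locus = sprintf("L%d", seq_len(n_loc)),
                        stringsAsFactors = FALSE)
    long$allele1 <- sample.int(n_all, nrow(long), replace = TRUE)
    long$allele2 <- sample.int(n_all, nrow(long), replace = TRUE)
    as_geno_tbl(long)
  })
}

one_cluster <- function(g, label = "X") {
  tibble::tibble(individual = individuals(g), cluster = label)
}

# Two-cluster filter fixture: cluster A has 30 fully typed individuals at
# one diagnostic locus. Allele 99 is a singleton private to A (carrier
# A01); allele 98 is a singleton in A (carrier A02) but common in cluster
# B. Both singletons have frequency 1/60 < 0.02. A second monomorphic
# locus keeps the dataset multilocus.
filter_fixture <- function() {
  n <- 30
  ind_a <- sprintf("A%02d", seq_len(n))
  a1 <- c(99L, 98L, rep(1L, n - 2))
  a2 <- c(1L, 1L, rep(c(1L, 2L), length.out = n - 2))
  ind_b <- sprintf("B%02d", 1:10)
  long <- dplyr::bind_rows(
    tibble::tibble(individual = ind_a, locus = "L1", allele1 = a1, allele2 = a2),
    tibble::tibble(individual = ind_a, locus = "L2", allele1 = 5L, allele2 = 5L),
    tibble::tibble(individual = ind_b, locus = "L1",
                   allele1 = rep(c(98L, 1L), 5), allele2 = 2L),
    tibble::tibble(individual = ind_b, locus = "L2", allele1 = 5L, allele2 = 5L)
  )
  g <- as_geno_tbl(long)
  cl <- tibble::tibble(individual = c(ind_a, ind_b),
                       cluster = rep(c("A", "B"), c(n, 10)))
  list(genotypes = g, clusters = cl)
}

# Filtered-cluster wrapper for a single-cluster dataset.
whole_cluster <- function(g) {
  apply_filter(g, one_cluster(g), "X", "all")
}

# Brute-force rarefaction: mean number of distinct alleles over all
# choose(2N, k) subsamples of k gene copies, by full enumeration.
brute_rarefaction <- function(copies, k) {
  idx <- utils::combn(length(copies), k)
  mean(apply(idx, 2, function(j) length(unique(copies[j]))))
}

# Brute-force capture probability under equal frequencies: enumerate all
# A^k assignments of k gene copies to A alleles; exact rational result
# returned as (favourable, total).
brute_equal_capture <- function(A, k) {
  grid <- do.call(expand.grid, rep(list(seq_len(A)), k))
  hits <- sum(apply(grid, 1, function(row) length(unique(row)) == A))
  c(hits = hits, total = A^k)
}
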