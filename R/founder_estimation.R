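#' Founder estimation configuration
#'
#' Bundles the tunable parameters of the minimum-founder search. The
#' defaults implement the standard protocol: 1,000 Monte Carlo replicates
#' per candidate founder number, acceptance when the estimated capture
#' probability reaches 0.05, a low-frequency cut-off of 0.02 for the
#' genotype filters, and an automatic scan bound equal to the cluster size
#' (three times the cluster size for the empirical-frequency model, whose
#' estimates routinely exceed the sample size).
#'
#' @param mode Resampling model: `"resample"` draws allele copies without
#'   replacement from the cluster's per-locus pools (analysis of the
#'   observed profiles themselves); `"empirical"` draws with replacement
#'   from the per-locus empirical allele frequencies; `"equal"` draws with
#'   replacement assuming equal frequencies of the observed alleles (a
#'   deliberate drift heuristic that down-weights common alleles).
#' @param replicates Monte Carlo replicates per founder count.
#' @param success_threshold Capture probability required to accept a
#'   founder count; acceptance is decided on success counts
#'   (`>= ceiling(success_threshold * replicates)`) to avoid float
#'   comparisons.
#' @param low_freq_threshold Strict frequency cut-off used by the genotype
#'   filters.
#' @param n_max Scan bound: `"auto"` (cluster size; 3x for `"empirical"`)
#'   or a positive integer.
#' @param seed Root seed; per-(cluster, mode, variant, n) substreams are
#'   derived deterministically so any cell is independently reproducible.
#' @param resample_unit For `mode = "resample"` only: `"alleles"` pools
#'   allele copies per locus (the default, matching the documented model);
#'   `"genotypes"` draws whole diploid profiles instead, for sensitivity
#'   analysis.
#' @return A list of class `founder_config`.
#' @export
founder_config <- function(mode = c("resample", "empirical", "equal"),
                           replicates = 1000,
                           success_threshold = 0.05,
                           low_freq_threshold = 0.02,
                           n_max = "auto",
                           seed = 1L,
                           resample_unit = c("alleles", "genotypes")) {
  mode <- match.arg(mode)
  resample_unit <- match.arg(resample_unit)
  stopifnot(replicates >= 1,
            success_threshold > 0, success_threshold < 1,
            low_freq_threshold > 0, low_freq_threshold < 1,
            identical(n_max, "auto") || (is.numeric(n_max) && n_max >= 1))
  structure(list(mode = mode,
                 replicates = as.integer(replicates),
                 success_threshold = success_threshold,
                 low_freq_threshold = low_freq_threshold,
                 n_max = n_max,
                 seed = as.integer(seed),
                 resample_unit = resample_unit),
            class = "founder_config")
}

# Deterministic 31-bit substream seed from a root seed and a path of
# identifiers (cluster label, mode, variant, founder count, ...).
derive_seed <- function(root, ...) {
  key <- paste(c(root, ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Filter a cluster's genotypes before founder estimation
#'
#' Recently immigrated or admixed individuals can carry alleles that were
#' never present in the founders and so inflate the founder estimate. The
#' filters flag alleles whose frequency in the focal cluster is strictly
#' below `threshold` (computed once, on the unfiltered cluster) and remove
#' every individual carrying at least one flagged allele:
#'
#' * `"all"` — no filtering; the complete set of genotypes.
#' * `"drop_low_freq"` — remove carriers of any low-frequency allele.
#' * `"drop_nonprivate_low_freq"` — remove carriers of low-frequency
#'   alleles that also occur in another cluster; carriers of exclusively
#'   private low-frequency alleles are retained (private rare alleles may
#'   be genuine founder alleles declining under drift, not immigrants).
#'
#' The target allele set and per-locus pools are recomputed on the retained
#' individuals, so alleles carried only by removed individuals drop out of
#' the capture target.
#'
#' @param x A genotype table.
#' @param clusters Cluster assignment tibble.
#' @param cluster Focal cluster label.
#' @param variant Filter variant (see above).
#' @param threshold Strict low-frequency cut-off (default 0.02).
#' @return An object of class `filtered_cluster`: retained/removed
#'   individuals, the recomputed allele count table, the target allele
#'   set, and per-locus allele copy pools.
#' @export
apply_filter <- function(x, clusters, cluster,
                         variant = c("all", "drop_low_freq",
                                     "drop_nonprivate_low_freq"),
                         threshold = 0.02) {
  variant <- match.arg(variant)
  clusters <- validate_clusters(x, clusters)
  members <- clusters$individual[clusters$cluster == cluster]
  if (length(members) == 0) stop("cluster '", cluster, "' is empty", call. = FALSE)

  cls <- classify_alleles(x, clusters, cluster, threshold = threshold)
  flagged <- switch(variant,
    all = cls[0, , drop = FALSE],
    drop_low_freq = cls[cls$is_low_frequency, , drop = FALSE],
    drop_nonprivate_low_freq =
      cls[cls$is_low_frequency & !cls$is_private, , drop = FALSE]
  )

  tbl <- tibble::as_tibble(x)
  sub <- tbl[tbl$individual %in% members, , drop = FALSE]
  if (nrow(flagged) > 0) {
    key <- paste(flagged$locus, flagged$allele)
    hit <- (paste(sub$locus, sub$allele1) %in% key) |
      (paste(sub$locus, sub$allele2) %in% key)
    hit[is.na(sub$allele1)] <- FALSE
    carrier_rows <- sub[hit, , drop = FALSE]
    removed_ids <- unique(carrier_rows$individual)
    removed <- dplyr::summarise(
      dplyr::group_by(carrier_rows, individual = .data$individual),
      offending = paste(unique(paste0(.data$locus, ":",
                                      ifelse(paste(.data$locus, .data$allele1) %in% key,
                                             .data$allele1, .data$allele2))),
                        collapse = ","),
      .groups = "drop"
    )
  } else {
    removed_ids <- character(0)
    removed <- tibble::tibble(individual = character(0), offending = character(0))
  }
  retained <- setdiff(members, removed_ids)
  if (length(retained) == 0) {
    stop("filter '", variant, "' removed every individual of cluster '",
         cluster, "'; use variant \"all\"", call. = FALSE)
  }

  counts <- allele_counts(x, retained)
  kept <- tbl[tbl$individual %in% retained & !is.na(tbl$allele1), , drop = FALSE]
  pools <- purrr::map(setNames(loci(x), loci(x)), function(l) {
    rows <- kept[kept$locus == l, , drop = FALSE]
    c(rows$allele1, rows$allele2)
  })

  structure(list(cluster = cluster,
                 variant = variant,
                 threshold = threshold,
                 n_cluster = length(members),
                 retained = retained,
                 removed = removed,
                 counts = counts,
                 target = counts[c("locus", "allele", "count", "total", "freq")],
                 pools = pools,
                 classification = cls),
            class = "filtered_cluster")
}

#' @export
print.filtered_cluster <- function(x, ...) {
  cat(sprintf("<filtered_cluster> '%s', variant %s: %d/%d retained, %d target alleles\n",
              x$cluster, x$variant, length(x$retained), x$n_cluster,
              nrow(x$target)))
  invisible(x)
}

# Per-locus count/frequency vectors of the capture target, in locus order.
target_by_locus <- function(fc) {
  split(fc$target, factor(fc$target$locus, levels = unique(fc$target$locus)))
}

#' Simulate one set of founder genotypes
#'
#' Draws the allele content of `n` diploid founders (`2n` gene copies per
#' locus, loci independent — no linkage, no mutation) under one of the
#' three resampling models: without replacement from the cluster's
#' per-locus copy pools (`"resample"`), with replacement from the empirical
#' frequencies (`"empirical"`), or with replacement from equal frequencies
#' over the observed alleles (`"equal"`). When the pool at a locus holds
#' fewer than `2n` copies (possible under missing data), the entire pool is
#' drawn and a message is emitted once.
#'
#' @param fc A [apply_filter()] result.
#' @param n Number of diploid founders to simulate.
#' @param mode Resampling model.
#' @return Tibble `locus`, `allele`, `copies` with `sum(copies)` per locus
#'   equal to `2 * n` (or the pool size when smaller, `"resample"` only).
#' @export
simulate_founder_genotypes <- function(fc, n,
                                       mode = c("resample", "empirical", "equal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fc, "filtered_cluster"), n >= 1)
  per_locus <- target_by_locus(fc)
  short <- FALSE
  out <- purrr::map_dfr(per_locus, function(tl) {
    k <- 2L * as.integer(n)
    if (mode == "resample") {
      total <- tl$total[1]
      if (k >= total) {
        short <<- short || k > total
        copies <- tl$count
      } else {
        copies <- as.vector(rmvhyper(1, tl$count, k))
      }
    } else {
      p <- if (mode == "empirical") tl$freq else rep(1 / nrow(tl), nrow(tl))
      copies <- as.vector(rmultinom(1, k, p))
    }
    tibble::tibble(locus = tl$locus[1], allele = tl$allele, copies = copies)
  })
  if (short) message("pool smaller than 2n at >=1 locus; entire pool drawn")
  out
}

# Multivariate hypergeometric sampler: draws k copies without replacement
# from categories with counts `counts`, replicated `reps` times. Returns a
# length(counts) x reps matrix. Sequential conditional rhyper, vectorized
# over replicates.
rmvhyper <- function(reps, counts, k) {
  A <- length(counts)
  total <- sum(counts)
  stopifnot(k <= total)
  out <- matrix(0L, nrow = A, ncol = reps)
  rem_k <- rep.int(k, reps)
  rem_total <- total
  for (i in seq_len(A)) {
    if (i == A) {
      out[i, ] <- rem_k
    } else {
      x <- rhyper(reps, m = counts[i], n = rem_total - counts[i], k = rem_k)
      out[i, ] <- x
      rem_k <- rem_k - x
      rem_total <- rem_total - counts[i]
    }
  }
  out
}

# Per-locus capture indicators over `reps` replicates for one locus of the
# target. Returns a logical vector of length reps.
locus_capture_mc <- function(tl, n, mode, reps, pools = NULL) {
  k <- 2L * as.integer(n)
  A <- nrow(tl)
  if (mode == "resample") {
    total <- tl$total[1]
    if (k >= total) return(rep(TRUE, reps))
    if (k < A) return(rep(FALSE, reps))
    draws <- rmvhyper(reps, tl$count, k)
  } else {
    if (k < A) return(rep(FALSE, reps))
    p <- if (mode == "empirical") tl$freq else rep(1 / A, A)
    draws <- rmultinom(reps, k, p)
  }
  colSums(draws == 0L) == 0L
}

# Genotype-unit variant of mode "resample": founders are whole diploid
# profiles sampled without replacement from the retained individuals.
capture_mc_genotype_unit <- function(fc, x, n, reps) {
  tbl <- tibble::as_tibble(x)
  kept <- tbl[tbl$individual %in% fc$retained, , drop = FALSE]
  per_ind <- split(kept, kept$individual)
  target_keys <- paste(fc$target$locus, fc$target$allele)
  n_eff <- min(n, length(per_ind))
  vapply(seq_len(reps), function(r) {
    ids <- sample(names(per_ind), n_eff)
    rows <- dplyr::bind_rows(per_ind[ids])
    rows <- rows[!is.na(rows$allele1), , drop = FALSE]
    seen <- unique(c(paste(rows$locus, rows$allele1),
                     paste(rows$locus, rows$allele2)))
    all(target_keys %in% seen)
  }, logical(1))
}

#' Monte Carlo capture probability
#'
#' Estimates the probability that `n` simulated founders jointly carry
#' every allele of the filtered cluster's target set at every locus, as
#' the fraction of successful replicates.
#'
#' @inheritParams simulate_founder_genotypes
#' @param replicates Number of Monte Carlo replicates.
#' @param seed Optional integer seed (the RNG state is restored afterwards).
#' @param x Required only for `resample_unit = "genotypes"`: the genotype
#'   table the cluster was filtered from.
#' @param resample_unit See [founder_config()].
#' @return One-row tibble `n`, `successes`, `replicates`, `p_hat`.
#' @export
capture_probability_mc <- function(fc, n, mode = c("resample", "empirical", "equal"),
                                   replicates = 1000, seed = NULL,
                                   resample_unit = "alleles", x = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fc, "filtered_cluster"), replicates >= 1, n >= 1)
  run <- function() {
    if (mode == "resample" && resample_unit == "genotypes") {
      if (is.null(x)) stop("genotype-unit resampling needs the genotype table `x`",
                           call. = FALSE)
      return(sum(capture_mc_genotype_unit(fc, x, n, replicates)))
    }
    ok <- rep(TRUE, replicates)
    for (tl in target_by_locus(fc)) {
      ok[ok] <- locus_capture_mc(tl, n, mode, sum(ok))
      if (!any(ok)) break
    }
    sum(ok)
  }
  successes <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(n = as.integer(n), successes = as.integer(successes),
                 replicates = as.integer(replicates),
                 p_hat = successes / replicates)
}

#' Exact capture probability by inclusion-exclusion
#'
#' Closed-form counterpart of [capture_probability_mc()]: the probability
#' that `2n` gene copies per locus contain every target allele, multiplied
#' over independent loci. Per locus the probability that no target allele
#' is missed is computed by inclusion-exclusion over allele subsets `S`:
#'
#' * `"equal"`: `sum_j (-1)^j choose(A, j) ((A - j)/A)^(2n)`;
#' * `"empirical"`: `sum_S (-1)^|S| (1 - sum_{a in S} p_a)^(2n)`;
#' * `"resample"`: `sum_S (-1)^|S| choose(2N - c_S, 2n) / choose(2N, 2n)`
#'   with `choose(m, k) = 0` for `m < k`.
#'
#' Subset enumeration is exponential in the per-locus allele count, so
#' modes `"resample"` and `"empirical"` refuse loci above `cap` alleles;
#' use the Monte Carlo estimator there.
#'
#' @inheritParams simulate_founder_genotypes
#' @param cap Per-locus allele-count cap for subset enumeration.
#' @return A single probability.
#' @export
capture_probability_exact <- function(fc, n,
                                      mode = c("resample", "empirical", "equal"),
                                      cap = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(fc, "filtered_cluster"), n >= 1)
  k <- 2L * as.integer(n)
  prod(purrr::map_dbl(target_by_locus(fc), function(tl) {
    A <- nrow(tl)
    # alternating sums can undershoot 0 by float cancellation; clamp
    clamp01 <- function(p) min(max(p, 0), 1)
    if (mode == "equal") {
      j <- 0:A
      return(clamp01(sum((-1)^j * choose(A, j) * ((A - j) / A)^k)))
    }
    if (A > cap) {
      stop("locus ", tl$locus[1], " has ", A, " alleles (> cap = ", cap,
           "); use capture_probability_mc()", call. = FALSE)
    }
    # enumerate subset sums incrementally: values[s] = sum over S, odd[s] = |S| parity
    vals <- 0
    odd <- FALSE
    weights <- if (mode == "empirical") tl$freq else tl$count
    for (w in weights) {
      vals <- c(vals, vals + w)
      odd <- c(odd, !odd)
    }
    sign <- ifelse(odd, -1, 1)
    if (mode == "empirical") {
      base <- pmax(1 - vals, 0)
      clamp01(sum(sign * base^k))
    } else {
      total <- tl$total[1]
      if (k >= total) return(1)
      clamp01(sum(sign * exp(lchoose(total - vals, k) - lchoose(total, k))))
    }
  }))
}

#' Minimum founder number for a filtered cluster
#'
#' Scans candidate founder counts `n = 1, 2, ...` in ascending order with
#' independent Monte Carlo replicates per `n`, and returns the first `n`
#' whose estimated capture probability reaches the acceptance threshold
#' (success-count rule). The scan is linear (no binary search) because the
#' Monte Carlo estimate is only stochastically monotone in `n`. If no
#' candidate up to the scan bound qualifies the estimate is censored.
#'
#' @param fc A [apply_filter()] result.
#' @param config A [founder_config()].
#' @param x Genotype table, required only for genotype-unit resampling.
#' @return An object of class `founder_estimate` with the capture curve
#'   over all tested `n`; see [tidy.founder_estimate()],
#'   [glance.founder_estimate()] and [autoplot.founder_estimate()].
#' @export
minimum_founders <- function(fc, config = founder_config(), x = NULL) {
  stopifnot(inherits(fc, "filtered_cluster"), inherits(config, "founder_config"))
  n_max <- if (identical(config$n_max, "auto")) {
    if (config$mode == "empirical") 3L * length(fc$retained)
    else length(fc$retained)
  } else {
    as.integer(config$n_max)
  }
  need <- as.integer(ceiling(config$success_threshold * config$replicates))

  curve <- vector("list", n_max)
  found <- NA_integer_
  for (n in seq_len(n_max)) {
    cell_seed <- derive_seed(config$seed, fc$cluster, config$mode, fc$variant, n)
    res <- capture_probability_mc(fc, n, config$mode,
                                  replicates = config$replicates,
                                  seed = cell_seed,
                                  resample_unit = config$resample_unit, x = x)
    curve[[n]] <- res
    if (res$successes >= need) {
      found <- n
      break
    }
  }
  structure(list(cluster = fc$cluster,
                 mode = config$mode,
                 variant = fc$variant,
                 observed_allele_total = nrow(fc$target),
                 min_founders = found,
                 censored = is.na(found),
                 n_max = n_max,
                 n_retained = length(fc$retained),
                 curve = dplyr::bind_rows(curve),
                 config = config),
            class = "founder_estimate")
}

#' @export
print.founder_estimate <- function(x, ...) {
  est <- if (x$censored) paste0("> ", x$n_max, " (censored)") else x$min_founders
  cat(sprintf(
    "<founder_estimate> cluster '%s', mode %s, variant %s\n  %d target alleles; minimum founders: %s\n",
    x$cluster, x$mode, x$variant, x$observed_allele_total, est))
  invisible(x)
}

#' Tidiers for founder estimates
#'
#' `tidy()` returns the capture curve (one row per tested founder count);
#' `glance()` returns a one-row summary.
#'
#' @param x A [minimum_founders()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy founder_estimate
#' @export
tidy.founder_estimate <- function(x, ...) {
  dplyr::mutate(x$curve,
                cluster = x$cluster, mode = x$mode, variant = x$variant,
                .before = 1)
}

#' @rdname tidy.founder_estimate
#' @method glance founder_estimate
#' @export
glance.founder_estimate <- function(x, ...) {
  tibble::tibble(cluster = x$cluster, mode = x$mode, variant = x$variant,
                 observed_alleles = x$observed_allele_total,
                 min_founders = x$min_founders, censored = x$censored,
                 n_max = x$n_max, n_retained = x$n_retained,
                 replicates = x$config$replicates,
                 success_threshold = x$config$success_threshold,
                 seed = x$config$seed)
}

#' Plot a capture curve
#'
#' Estimated capture probability against the simulated founder count, with
#' the acceptance threshold and the selected minimum marked.
#'
#' @param object A [minimum_founders()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot founder_estimate
#' @export
autoplot.founder_estimate <- function(object, ...) {
  cv <- object$curve
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$n, y = .data$p_hat)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$config$success_threshold,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "simulated founder individuals (n)",
      y = expression(hat(P)(capture)),
      title = sprintf("Cluster %s - %s model, filter %s",
                      object$cluster, object$mode, object$variant),
      subtitle = if (object$censored) {
        sprintf("censored: no n <= %d reached the threshold", object$n_max)
      } else {
        sprintf("minimum founders = %d", object$min_founders)
      }
    ) +
    ggplot2::theme_minimal()
  if (!object$censored) {
    p <- p + ggplot2::geom_vline(xintercept = object$min_founders,
                                 colour = "firebrick", linetype = "dotted")
  }
  p
}

#' Founder-estimate report over clusters, models and filter variants
#'
#' Runs the full estimation grid — every cluster crossed with the requested
#' resampling models and filter variants — and returns a tidy report table
#' shaped like the classical three-panel founder table: observed allele
#' total after filtering and the minimum-founder estimate per model, with
#' footnotes where a filter variant degenerates:
#'
#' * `no_low_freq` — the cluster has no low-frequency allele, so the
#'   low-frequency filter changes nothing (variant identical to `"all"`).
#' * `no_private` — the cluster has no private allele, so the non-private
#'   filter variant is not applicable (cells are skipped).
#' * `all_low_freq_private` — every low-frequency allele is private, so
#'   the non-private variant removes nobody (identical to `"all"`).
#'
#' The equal-frequency model is by default run only on unfiltered clusters
#' (`equal_unfiltered_only = TRUE`), since its drift heuristic targets the
#' full observed allele inventory.
#'
#' A failing cell is reported with its error message in `footnote`, not
#' fatal to the run.
#'
#' @param x A genotype table.
#' @param clusters Cluster assignment tibble.
#' @param modes Resampling models to run.
#' @param variants Filter variants to run.
#' @param replicates,success_threshold,low_freq_threshold,n_max,seed,resample_unit
#'   Passed to [founder_config()]; `seed` is the root seed for the whole
#'   grid.
#' @param equal_unfiltered_only Restrict the `"equal"` model to variant
#'   `"all"`.
#' @param keep_estimates Attach the full `founder_estimate` objects (with
#'   capture curves) as attribute `"estimates"`.
#' @return Tibble with one row per cluster x variant x mode:
#'   `cluster`, `variant`, `observed_alleles`, `n_retained`, `mode`,
#'   `min_founders`, `censored`, `n_max`, `footnote`.
#' @export
run_founder_table <- function(x, clusters,
                              modes = c("resample", "empirical", "equal"),
                              variants = c("all", "drop_low_freq",
                                           "drop_nonprivate_low_freq"),
                              replicates = 1000,
                              success_threshold = 0.05,
                              low_freq_threshold = 0.02,
                              n_max = "auto",
                              seed = 1L,
                              resample_unit = "alleles",
                              equal_unfiltered_only = TRUE,
                              keep_estimates = FALSE) {
  clusters <- validate_clusters(x, clusters)
  labels <- unique(clusters$cluster)
  modes <- match.arg(modes, several.ok = TRUE)
  variants <- match.arg(variants, several.ok = TRUE)

  estimates <- list()
  rows <- list()
  for (cl in labels) {
    cls <- classify_alleles(x, clusters, cl, threshold = low_freq_threshold)
    any_low <- any(cls$is_low_frequency)
    any_priv <- any(cls$is_private)
    all_low_priv <- any_low && all(cls$is_private[cls$is_low_frequency])
    for (variant in variants) {
      footnote <- NA_character_
      if (variant == "drop_low_freq" && !any_low) {
        footnote <- "no_low_freq"
      }
      if (variant == "drop_nonprivate_low_freq") {
        if (!any_priv) footnote <- "no_private"
        else if (!any_low) footnote <- "no_low_freq"
        else if (all_low_priv) footnote <- "all_low_freq_private"
      }
      if (identical(footnote, "no_private")) {
        for (mode in modes) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cluster = cl, variant = variant, observed_alleles = NA_integer_,
            n_retained = NA_integer_, mode = mode,
            min_founders = NA_integer_, censored = NA, n_max = NA_integer_,
            footnote = footnote)
        }
        next
      }
      fc <- tryCatch(
        apply_filter(x, clusters, cl, variant, threshold = low_freq_threshold),
        error = function(e) e)
      for (mode in modes) {
        if (mode == "equal" && equal_unfiltered_only && variant != "all") next
        if (inherits(fc, "error")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cluster = cl, variant = variant, observed_alleles = NA_integer_,
            n_retained = NA_integer_, mode = mode,
            min_founders = NA_integer_, censored = NA, n_max = NA_integer_,
            footnote = paste0("error: ", conditionMessage(fc)))
          next
        }
        cfg <- founder_config(mode = mode, replicates = replicates,
                              success_threshold = success_threshold,
                              low_freq_threshold = low_freq_threshold,
                              n_max = n_max, seed = seed,
                              resample_unit = resample_unit)
        est <- tryCatch(minimum_founders(fc, cfg, x = x), error = function(e) e)
        if (inherits(est, "error")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cluster = cl, variant = variant,
            observed_alleles = nrow(fc$target),
            n_retained = length(fc$retained), mode = mode,
            min_founders = NA_integer_, censored = NA, n_max = NA_integer_,
            footnote = paste0("error: ", conditionMessage(est)))
          next
        }
        if (keep_estimates) {
          estimates[[paste(cl, mode, variant, sep = ".")]] <- est
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cluster = cl, variant = variant,
          observed_alleles = est$observed_allele_total,
          n_retained = est$n_retained, mode = mode,
          min_founders = est$min_founders, censored = est$censored,
          n_max = est$n_max, footnote = footnote)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_estimates) attr(out, "estimates") <- estimates
  out
}
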