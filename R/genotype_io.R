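#' Diploid multilocus genotype tables
#'
#' A `geno_tbl` is a tibble in long form with one row per individual and
#' locus, holding an unordered pair of integer allele codes. It is the
#' package's central data structure: one row per (individual, locus) cell,
#' columns `individual`, `locus`, `allele1`, `allele2`. A genotype with any
#' missing allele is treated as wholly missing (both alleles `NA`), which
#' keeps per-locus gene-copy totals even. Allele codes are opaque integers
#' (microsatellite fragment lengths or arbitrary labels); no repeat-unit
#' arithmetic is assumed.
#'
#' Locus order and individual order are preserved in the `"loci"` and
#' `"individuals"` attributes and respected by all writers.
#'
#' @param x A data frame with columns `individual`, `locus`, `allele1`,
#'   `allele2`. Allele columns are coerced to integer; `NA` in either
#'   position marks the genotype missing.
#' @param loci Optional character vector fixing locus order (defaults to
#'   order of first appearance).
#' @param individuals Optional character vector fixing individual order.
#'
#' @return A tibble of class `geno_tbl` with one row per
#'   individual-by-locus cell; genotype pairs are stored sorted so that
#'   datasets differing only in within-genotype allele order compare equal.
#' @export
#' @examples
#' g <- as_geno_tbl(tibble::tibble(
#'   individual = c("i1", "i2"), locus = "L1",
#'   allele1 = c(101L, 101L), allele2 = c(103L, 101L)
#' ))
#' allele_counts(g)
as_geno_tbl <- function(x, loci = NULL, individuals = NULL) {
  required <- c("individual", "locus", "allele1", "allele2")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[required]
  x$individual <- as.character(x$individual)
  x$locus <- as.character(x$locus)
  x$allele1 <- as.integer(x$allele1)
  x$allele2 <- as.integer(x$allele2)

  dup <- duplicated(x[c("individual", "locus")])
  if (any(dup)) {
    bad <- x[dup, , drop = FALSE]
    stop("duplicate genotype row(s) for ",
         paste(unique(paste0(bad$individual, "/", bad$locus)), collapse = ", "),
         call. = FALSE)
  }

  half <- xor(is.na(x$allele1), is.na(x$allele2))
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) treated as wholly missing",
            call. = FALSE)
    x$allele1[half] <- NA_integer_
    x$allele2[half] <- NA_integer_
  }
  swap <- !is.na(x$allele1) & x$allele1 > x$allele2
  tmp <- x$allele1[swap]
  x$allele1[swap] <- x$allele2[swap]
  x$allele2[swap] <- tmp

  if (is.null(loci)) loci <- unique(x$locus)
  if (is.null(individuals)) individuals <- unique(x$individual)
  stopifnot(all(x$locus %in% loci), all(x$individual %in% individuals))

  # complete the individual x locus grid; untyped cells become MISSING
  grid <- tidyr::expand_grid(individual = individuals, locus = loci)
  x <- dplyr::left_join(grid, x, by = c("individual", "locus"))

  structure(x,
            loci = loci,
            individuals = individuals,
            class = c("geno_tbl", class(tibble::tibble())))
}

#' @export
print.geno_tbl <- function(x, ...) {
  n_ind <- length(attr(x, "individuals"))
  n_loc <- length(attr(x, "loci"))
  n_miss <- sum(is.na(x$allele1))
  cat(sprintf("<geno_tbl> %d individuals x %d loci (%d missing genotypes)\n",
              n_ind, n_loc, n_miss))
  NextMethod()
}

#' Ordered locus and individual accessors
#'
#' @param x A [as_geno_tbl()] genotype table.
#' @return Character vector of locus (respectively individual) identifiers
#'   in dataset order.
#' @export
loci <- function(x) attr(x, "loci")

#' @rdname loci
#' @export
individuals <- function(x) attr(x, "individuals")

#' Read a GENEPOP genotype file
#'
#' Parses the classical GENEPOP text dialect: a title line, one locus name
#' per line (or a single comma-separated line), `POP` separators, and
#' per-individual rows `id , g1 g2 ...` where each genotype is a
#' concatenated pair of fixed-width allele codes. Both 2-digit and 3-digit
#' code widths are supported; the width is auto-detected from the file and
#' mixing widths is an error. Allele code `00`/`000` marks a missing
#' allele; a genotype with one missing allele is treated as wholly missing
#' (with a warning).
#'
#' `POP` blocks are surfaced as a *suggested* grouping (see
#' [genepop_pops()]), not fused into the analysis clustering: genetic
#' clusters usually come from an assignment method, not from sampling
#' sites, so every analysis function takes an explicit cluster table.
#'
#' @param path Path to a GENEPOP file.
#' @return A [as_geno_tbl()] genotype table; the per-individual POP block
#'   index is attached as attribute `"pops"`.
#' @seealso [write_genepop()], [genepop_pops()]
#' @export
read_genepop <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("GENEPOP file too short: ", path, call. = FALSE)

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found in ", path, call. = FALSE)
  if (first_pop < 3) stop("POP separator before any locus name in ", path, call. = FALSE)

  header <- lines[2:(first_pop - 1)]
  if (length(header) == 1 && grepl(",", header)) {
    locus_names <- trimws(strsplit(header, ",")[[1]])
  } else {
    locus_names <- trimws(header)
  }
  locus_names <- locus_names[locus_names != ""]
  n_loci <- length(locus_names)

  body <- lines[first_pop:length(lines)]
  pop_idx <- 0L
  rows <- list()
  width <- NA_integer_
  for (k in seq_along(body)) {
    ln <- body[k]
    if (toupper(trimws(ln)) == "POP") {
      pop_idx <- pop_idx + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) {
      stop("GENEPOP line ", first_pop + k - 1L,
           " has no 'id ,' separator: ", trimws(ln), call. = FALSE)
    }
    id <- trimws(parts[1])
    genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    genos <- genos[genos != ""]
    if (length(genos) != n_loci) {
      stop("GENEPOP line ", first_pop + k - 1L, " (individual '", id, "') has ",
           length(genos), " genotype(s) but ", n_loci, " loci are declared",
           call. = FALSE)
    }
    widths <- nchar(genos)
    if (!all(widths %in% c(4L, 6L))) {
      stop("GENEPOP line ", first_pop + k - 1L,
           ": genotype codes must be 4 or 6 characters wide", call. = FALSE)
    }
    w <- unique(widths) / 2L
    if (length(w) > 1) {
      stop("GENEPOP line ", first_pop + k - 1L,
           ": mixed 2- and 3-digit allele codes", call. = FALSE)
    }
    if (is.na(width)) {
      width <- w
    } else if (w != width) {
      stop("inconsistent allele code width in ", path,
           " (both ", 2 * width, "- and ", 2 * w, "-character genotypes)",
           call. = FALSE)
    }
    a1 <- as.integer(substr(genos, 1L, width))
    a2 <- as.integer(substr(genos, width + 1L, 2L * width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      individual = id, pop = pop_idx, locus = locus_names,
      allele1 = a1, allele2 = a2
    )
  }
  long <- dplyr::bind_rows(rows)
  g <- as_geno_tbl(long[c("individual", "locus", "allele1", "allele2")],
                   loci = locus_names)
  attr(g, "pops") <- dplyr::distinct(long, .data$individual, .data$pop)
  g
}

#' Suggested grouping from GENEPOP POP blocks
#'
#' @param x A genotype table produced by [read_genepop()].
#' @return A tibble `individual`, `cluster` where the cluster label is the
#'   POP block index (`"pop1"`, `"pop2"`, ...), usable as a cluster
#'   assignment if the sampling groups are the units of analysis.
#' @export
genepop_pops <- function(x) {
  pops <- attr(x, "pops")
  if (is.null(pops)) stop("no POP block information attached", call. = FALSE)
  tibble::tibble(individual = pops$individual,
                 cluster = paste0("pop", pops$pop))
}

#' Write a GENEPOP genotype file
#'
#' @param x A genotype table.
#' @param path Output path.
#' @param clusters Optional cluster tibble (`individual`, `cluster`); when
#'   given, individuals are grouped into POP blocks by cluster (in cluster
#'   order of first appearance), otherwise a single POP block is written.
#' @param title Title line.
#' @param digits Allele code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, clusters = NULL, title = "founderest export",
                          digits = 3) {
  stopifnot(digits %in% c(2, 3))
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  wide <- x
  wide$code <- paste0(fmt(wide$allele1), fmt(wide$allele2))
  mat <- tidyr::pivot_wider(wide[c("individual", "locus", "code")],
                            names_from = "locus", values_from = "code")
  mat <- mat[match(individuals(x), mat$individual), c("individual", loci(x))]

  if (is.null(clusters)) {
    groups <- list(individuals(x))
  } else {
    clusters <- validate_clusters(x, clusters)
    groups <- split(clusters$individual, factor(clusters$cluster,
                                                levels = unique(clusters$cluster)))
  }
  out <- c(title, loci(x))
  for (grp in groups) {
    out <- c(out, "POP")
    rows <- mat[match(grp, mat$individual), , drop = FALSE]
    out <- c(out, paste0(rows$individual, " ,  ",
                         apply(rows[-1], 1, paste, collapse = " ")))
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Read and write long-form genotype tables
#'
#' The long-form interchange format is a delimited table (TSV or CSV,
#' auto-detected from the extension) with columns `individual`, `cluster`,
#' `locus`, `allele1`, `allele2`; empty allele fields mark missing data.
#' `read_long_table()` returns both the genotype table and the cluster
#' assignment carried in the `cluster` column; the pair round-trips through
#' `write_long_table()` bit-exactly up to row order.
#'
#' @param path Path to the delimited file.
#' @return For `read_long_table()`, a list with elements `genotypes` (a
#'   [as_geno_tbl()] table) and `clusters` (tibble `individual`,
#'   `cluster`).
#' @export
read_long_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    individual = readr::col_character(),
    cluster = readr::col_character(),
    locus = readr::col_character(),
    allele1 = readr::col_integer(),
    allele2 = readr::col_integer()
  ), na = c("", "NA"))
  expected <- c("individual", "cluster", "locus", "allele1", "allele2")
  if (!identical(sort(names(raw)), sort(expected))) {
    extra <- setdiff(names(raw), expected)
    lacking <- setdiff(expected, names(raw))
    stop("long table columns must be exactly {",
         paste(expected, collapse = ", "), "}",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         if (length(lacking)) paste0("; missing: ", paste(lacking, collapse = ", ")),
         call. = FALSE)
  }
  g <- as_geno_tbl(raw[c("individual", "locus", "allele1", "allele2")])
  cl <- dplyr::distinct(raw, .data$individual, .data$cluster)
  if (anyDuplicated(cl$individual)) {
    stop("individual(s) mapped to more than one cluster: ",
         paste(cl$individual[duplicated(cl$individual)], collapse = ", "),
         call. = FALSE)
  }
  list(genotypes = g, clusters = tibble::as_tibble(cl))
}

#' @rdname read_long_table
#' @param x A genotype table.
#' @param clusters Cluster tibble (`individual`, `cluster`).
#' @export
write_long_table <- function(x, clusters, path) {
  clusters <- validate_clusters(x, clusters)
  out <- dplyr::left_join(tibble::as_tibble(x), clusters, by = "individual")
  out <- out[c("individual", "cluster", "locus", "allele1", "allele2")]
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read a cluster assignment table
#'
#' @param path TSV/CSV with columns `individual` and `cluster`.
#' @return Tibble `individual`, `cluster`.
#' @export
read_clusters <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    individual = readr::col_character(), cluster = readr::col_character()
  ))
  tibble::as_tibble(cl)
}

#' @rdname read_clusters
#' @param clusters Cluster tibble to write.
#' @export
write_clusters <- function(clusters, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(clusters, path, delim = delim)
  invisible(path)
}

# Check a cluster assignment against a dataset: every mapped individual must
# exist, each individual maps to one cluster, clusters are non-empty by
# construction. Returns the tibble with character columns.
validate_clusters <- function(x, clusters) {
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("individual", "cluster") %in% names(clusters)))
  clusters$individual <- as.character(clusters$individual)
  clusters$cluster <- as.character(clusters$cluster)
  unknown <- setdiff(clusters$individual, individuals(x))
  if (length(unknown) > 0) {
    stop("cluster assignment names individual(s) absent from the dataset: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(clusters$individual)) {
    stop("individual(s) assigned to more than one cluster", call. = FALSE)
  }
  clusters
}

#' Per-locus allele copy counts and frequencies
#'
#' Tabulates allele copies over the non-missing genotypes of a set of
#' individuals. This table is the substrate of every frequency-based
#' computation in the package: per locus it lists each observed allele, its
#' copy count, the typed gene-copy total (2 x non-missing genotypes), and
#' the relative frequency. Alleles with zero copies in the subset are
#' omitted.
#'
#' @param x A genotype table.
#' @param subset Optional character vector of individuals; defaults to all.
#' @return Tibble `locus`, `allele`, `count`, `total`, `freq`, ordered by
#'   dataset locus order then allele code. Within each locus,
#'   `sum(count) == total` and `sum(freq) == 1`.
#' @export
allele_counts <- function(x, subset = NULL) {
  if (is.null(subset)) subset <- individuals(x)
  if (length(subset) == 0) stop("empty individual subset", call. = FALSE)
  unknown <- setdiff(subset, individuals(x))
  if (length(unknown) > 0) {
    stop("subset names unknown individual(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  sub <- dplyr::filter(tibble::as_tibble(x),
                       .data$individual %in% subset, !is.na(.data$allele1))
  long <- tidyr::pivot_longer(sub, c("allele1", "allele2"),
                              values_to = "allele")
  counts <- dplyr::count(long, .data$locus, .data$allele, name = "count")
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$locus),
                          total = sum(.data$count),
                          freq = .data$count / .data$total)
  counts <- dplyr::ungroup(counts)
  counts$locus <- factor(counts$locus, levels = loci(x))
  counts <- dplyr::arrange(counts, .data$locus, .data$allele)
  counts$locus <- as.character(counts$locus)
  counts
}
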