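#' Circular kernel density estimate on the ori-anchored scale
#'
#' Gaussian-kernel density of normalized gene positions on the circular
#' 0-100% scale. Circular wrap is handled by tripling the data at -100/0/
#' +100 offsets, evaluating an ordinary Gaussian KDE on a 512-point grid
#' over one period, and renormalizing so the density integrates to 1 over
#' the period. Bandwidth defaults to Silverman's rule-of-thumb on the
#' unwrapped sample.
#'
#' @param positions Numeric vector in `[0, 100)`, at least 2 values.
#' @param bandwidth Kernel standard deviation in percentage points;
#'   default `NULL` uses `stats::bw.nrd0` on `positions`.
#' @param n_grid Grid size over one period (default 512).
#' @return List (`density_estimate`) with `grid`, `density`, `bandwidth`.
#' @export
kde_circular <- function(positions, bandwidth = NULL, n_grid = 512L) {
  positions <- as.numeric(positions)
  if (length(positions) < 2L)
    stop("kernel density estimation needs at least 2 positions")
  if (any(positions < 0 | positions >= 100))
    stop("positions must lie in [0, 100)")
  if (is.null(bandwidth)) {
    bandwidth <- if (stats::sd(positions) > 0) stats::bw.nrd0(positions) else 1
  }
  stopifnot(bandwidth > 0)
  step <- 100 / n_grid
  grid <- seq(0, 100 - step, by = step)
  x3 <- c(positions - 100, positions, positions + 100)
  d <- stats::density(x3, bw = bandwidth, from = 0, to = 100 - step,
                      n = n_grid)$y
  d <- d / (sum(d) * step)  # renormalize over one circular period
  structure(list(grid = grid, density = d, bandwidth = bandwidth),
            class = "density_estimate")
}

#' Modes of a circular density estimate
#'
#' Circular local maxima of the estimated density, tallest first, optionally
#' pruned to peaks above a fraction of the global maximum.
#'
#' @param de A `density_estimate` from [kde_circular()].
#' @param min_height_frac Keep peaks taller than this fraction of the
#'   tallest (default 0.25).
#' @return Numeric vector of grid positions of the modes.
#' @export
density_modes <- function(de, min_height_frac = 0.25) {
  d <- de$density
  n <- length(d)
  left <- d[c(n, seq_len(n - 1L))]
  right <- d[c(seq_len(n)[-1L], 1L)]
  peak <- d >= left & d >= right & (d > left | d > right)
  idx <- which(peak & d >= min_height_frac * max(d))
  idx <- idx[order(d[idx], decreasing = TRUE)]
  de$grid[idx]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test on normalized positions treated linearly on the
#' ori-anchored `[0, 100)` scale. `D` is the supremum over all sample
#' points of the absolute ECDF difference. The asymptotic p-value uses the
#' Kolmogorov distribution at `sqrt(n_eff) * D` with effective sample size
#' `n_x n_y / (n_x + n_y)`; the exact-permutation p-value enumerates every
#' assignment of the pooled values to the two samples (available for
#' `n_x + n_y <= 16`).
#'
#' @param x,y Numeric samples (non-empty).
#' @param method `"asymptotic"` (default) or `"exact_permutation"`.
#' @return List (`ks_result`) with `d_statistic`, `p_value`, `n_x`, `n_y`,
#'   `method`.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "exact_permutation")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  D <- ks_statistic(x, y)
  if (method == "asymptotic") {
    ne <- nx * ny / (nx + ny)
    p <- kolmogorov_sf(sqrt(ne) * D)
  } else {
    n <- nx + ny
    if (n > 16L)
      stop("exact permutation p available only for n_x + n_y <= 16")
    pooled <- c(x, y)
    # enumerate all assignments via signed indicators in sorted order:
    # the running sum at sorted point t is ECDF_x(t) - ECDF_y(t)
    ord <- order(pooled)
    sorted_pos <- integer(n); sorted_pos[ord] <- seq_len(n)
    v <- pooled[ord]
    eval_at <- c(v[-1] != v[-n], TRUE)  # evaluate after the last tied value
    idx <- utils::combn(n, nx)
    w <- matrix(-1 / ny, n, ncol(idx))
    w[cbind(as.vector(sorted_pos[idx]),
            rep(seq_len(ncol(idx)), each = nx))] <- 1 / nx
    cum <- apply(w, 2L, cumsum)
    dperm <- apply(abs(cum[eval_at, , drop = FALSE]), 2L, max)
    p <- mean(dperm >= D - 1e-12)
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(d_statistic = D, p_value = p, n_x = nx, n_y = ny,
                 method = method), class = "ks_result")
}

# sup over all sample points of |ECDF_x - ECDF_y| (two-sided, tie-safe)
ks_statistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- vapply(v, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(v, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# Kolmogorov survival function Q(t) = 2 sum_{k>=1} (-1)^{k-1} exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- seq_len(100)
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(q, 0), 1)
}

#' Per-genus mean c-di-GMP gene counts
#'
#' Total c-di-GMP-metabolizing genes per genome (sum over the four enzyme
#' groups), averaged within each genus (sum of counts divided by the number
#' of genomes), plus order-level quartile summaries of the genus means.
#'
#' @param counts Per-genome counts table from [classify_genomes()].
#' @param taxonomy Taxonomy table (`genome_id`, `order`, `genus`, ...).
#' @return List with `genus_means` (`order`, `genus`, `n_genomes`,
#'   `mean_count`) and `order_summary` (`order`, `q1`, `median`, `q3` of
#'   genus means).
#' @export
per_genus_mean_counts <- function(counts, taxonomy) {
  tab <- merge(counts, taxonomy, by = "genome_id")
  tab$total <- rowSums(tab[, CDG_CLASSES, drop = FALSE])
  sp <- split(tab, list(tab$order, tab$genus), drop = TRUE)
  genus_means <- do.call(rbind, lapply(sp, function(d) data.frame(
    order = d$order[1], genus = d$genus[1], n_genomes = nrow(d),
    mean_count = sum(d$total) / nrow(d), stringsAsFactors = FALSE)))
  genus_means <- genus_means[order(genus_means$order, genus_means$genus), ]
  rownames(genus_means) <- NULL
  os <- split(genus_means, genus_means$order)
  order_summary <- do.call(rbind, lapply(os, function(d) {
    q <- stats::quantile(d$mean_count, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(order = d$order[1], q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(order_summary) <- NULL
  list(genus_means = genus_means, order_summary = order_summary)
}

#' Per-genome enzyme-class ratios and genus means
#'
#' Ratios GGDEF:EAL, GGDEF:GGDEF_EAL and GGDEF:HD_GYP computed per genome;
#' a ratio with a zero denominator is undefined (`NA`) and excluded from
#' the genus mean rather than imputed.
#'
#' @inheritParams per_genus_mean_counts
#' @return List with `per_genome` (one row per genome, `NA` where
#'   undefined) and `genus_means` (`order`, `genus`, mean over defined
#'   per-genome ratios, `NA` when no genome in the genus has a defined
#'   ratio).
#' @export
class_ratios <- function(counts, taxonomy) {
  tab <- merge(counts, taxonomy, by = "genome_id")
  rat <- function(den) ifelse(tab[[den]] > 0, tab$GGDEF / tab[[den]], NA_real_)
  per_genome <- data.frame(
    genome_id = tab$genome_id, order = tab$order, genus = tab$genus,
    GGDEF_EAL_ratio = rat("EAL"),
    GGDEF_GGDEF_EAL_ratio = rat("GGDEF_EAL"),
    GGDEF_HD_GYP_ratio = rat("HD_GYP"), stringsAsFactors = FALSE)
  sp <- split(per_genome, list(per_genome$order, per_genome$genus), drop = TRUE)
  gmean <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  genus_means <- do.call(rbind, lapply(sp, function(d) data.frame(
    order = d$order[1], genus = d$genus[1],
    GGDEF_EAL_ratio = gmean(d$GGDEF_EAL_ratio),
    GGDEF_GGDEF_EAL_ratio = gmean(d$GGDEF_GGDEF_EAL_ratio),
    GGDEF_HD_GYP_ratio = gmean(d$GGDEF_HD_GYP_ratio),
    stringsAsFactors = FALSE)))
  genus_means <- genus_means[order(genus_means$order, genus_means$genus), ]
  rownames(genus_means) <- rownames(per_genome) <- NULL
  list(per_genome = per_genome, genus_means = genus_means)
}

#' Median per-genome count of one enzyme class
#'
#' 50% quantile of per-genome counts, with linear interpolation at even n
#' (`stats::median` default convention).
#'
#' @param counts Per-genome counts table.
#' @param class One of `"GGDEF"`, `"EAL"`, `"GGDEF_EAL"`, `"HD_GYP"`.
#' @param taxonomy Optional taxonomy table; with `order` given, restricts
#'   to that order's genomes.
#' @param order Optional order name.
#' @return Numeric median.
#' @export
median_counts <- function(counts, class, taxonomy = NULL, order = NULL) {
  stopifnot(class %in% CDG_CLASSES)
  if (!is.null(order)) {
    stopifnot(!is.null(taxonomy))
    keep <- taxonomy$genome_id[taxonomy$order == order]
    counts <- counts[counts$genome_id %in% keep, , drop = FALSE]
  }
  if (!nrow(counts)) stop("no genomes to summarize")
  stats::median(counts[[class]])
}

#' Spearman correlation of chromosome size with gene count
#'
#' Rank correlation (tie-corrected) between the largest replicon's length
#' and the genome's total c-di-GMP gene count; only the biggest replicon
#' per genome enters, and the p-value comes from the t approximation.
#'
#' @param chromosome_lengths Numeric vector: largest-replicon length per
#'   genome.
#' @param gene_counts Integer vector, same order.
#' @return List with `rho`, `p_value`, `n`, `defined` (`FALSE` when either
#'   vector is constant, in which case `rho` is `NA`).
#' @export
size_count_correlation <- function(chromosome_lengths, gene_counts) {
  stopifnot(length(chromosome_lengths) == length(gene_counts))
  n <- length(gene_counts)
  if (n < 3) stop("need at least 3 genomes")
  if (stats::sd(chromosome_lengths) == 0 || stats::sd(gene_counts) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(chromosome_lengths, gene_counts,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}
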