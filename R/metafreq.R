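#' Length-normalized hit rate
#'
#' Raw metagenomic hit counts scale with gene length; dividing by the mean
#' query length in kilobases puts genes of different sizes on a common
#' per-kb scale.
#'
#' @param count Non-negative integer hit count.
#' @param length_kb Mean query length in kilobases; must be positive.
#' @return `count / length_kb`.
#' @examples
#' hits_per_kb(10, 0.5)  # 20
#' @export
hits_per_kb <- function(count, length_kb) {
  if (any(length_kb <= 0)) stop("length_kb must be positive")
  if (any(count < 0)) stop("negative hit count")
  count / length_kb
}

#' Read a per-site gene count table
#'
#' Long TSV with header columns `site_id`, `taxon`, `gene`, `hits`,
#' `mean_query_length_kb`, `iron`: one row per site x taxon x gene.
#'
#' @param path File path.
#' @return Validated `data.frame`.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("site_id", "taxon", "gene", "hits",
              "mean_query_length_kb", "iron")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$hits < 0)) stop("negative hit count in site table")
  if (any(df$mean_query_length_kb <= 0)) stop("non-positive gene length")
  df
}

#' Per-site gene frequency normalized by single-copy core genes
#'
#' Estimates, per site (and taxon bin), the fraction of genomes carrying a
#' target gene: the target's length-normalized hit rate divided by the mean
#' length-normalized hit rate of single-copy core genes (default `recA`,
#' `rpoB`, `gyrB`, `psbO`).  Because each core gene occurs once per genome,
#' their mean per-kb rate estimates the per-genome sequencing depth, and the
#' ratio is a per-genome carriage frequency, insensitive to depth.
#' Sites where every core gene has zero hits cannot be normalized and are
#' flagged `excluded` rather than divided by zero.
#'
#' @param sites Long `data.frame` as returned by [read_site_table()] (or
#'   [simulate_metagenome()]).
#' @param target Gene name of the target (default `"fld"`).
#' @param cores Character vector of core gene names.
#' @param blacklist Site ids to drop before any computation (e.g. a sample
#'   suspected of contamination).
#' @return `data.frame` of class `"frequency_profile"`: `site_id`, `taxon`,
#'   `iron`, `frequency`, `excluded`, with the core gene set recorded in
#'   attribute `core_genes_used` and the number of excluded sites in
#'   attribute `n_excluded`.
#' @examples
#' st <- data.frame(site_id = "s1", taxon = "syn",
#'                  gene = c("fld", "recA", "rpoB", "gyrB", "psbO"),
#'                  hits = c(10, 10, 10, 10, 10),
#'                  mean_query_length_kb = c(0.5, 1, 1, 1, 1), iron = 0.2)
#' gene_frequency(st)  # frequency 2
#' @export
gene_frequency <- function(sites, target = "fld",
                           cores = c("recA", "rpoB", "gyrB", "psbO"),
                           blacklist = NULL) {
  if (length(blacklist))
    sites <- sites[!sites$site_id %in% blacklist, , drop = FALSE]
  key <- interaction(sites$site_id, sites$taxon, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    s <- sites[key == k, , drop = FALSE]
    genes_here <- s$gene
    miss <- setdiff(c(target, cores), genes_here)
    if (length(miss))
      stop("site ", s$site_id[1], " taxon ", s$taxon[1],
           " missing gene(s): ", paste(miss, collapse = ", "))
    rate <- function(g) {
      row <- s[s$gene == g, , drop = FALSE][1, ]
      hits_per_kb(row$hits, row$mean_query_length_kb)
    }
    core_rates <- vapply(cores, rate, numeric(1))
    excluded <- all(core_rates == 0)
    freq <- if (excluded) NA_real_ else rate(target) / mean(core_rates)
    data.frame(site_id = s$site_id[1], taxon = s$taxon[1],
               iron = s$iron[1], frequency = freq, excluded = excluded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "core_genes_used") <- cores
  attr(out, "n_excluded") <- sum(out$excluded)
  class(out) <- c("frequency_profile", "data.frame")
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of midranks (average ranks for ties).
#' The two-sided p-value is computed by exhaustive permutation enumeration
#' for `n < 10` (exact, valid under ties) and by the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` df for `n >= 10`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, all finite.
#' @return List with `rho`, `p`, `n`, `method`.
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- .all_permutations(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= obs - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(1, p)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all n! permutations of 1..n, rows = permutations (iterative insertion)
.all_permutations <- function(n) {
  perms <- matrix(1L, 1L, 1L)
  if (n == 1L) return(perms)
  for (k in 2:n) {
    old <- perms
    perms <- matrix(0L, nrow(old) * k, k)
    r <- 0L
    for (i in seq_len(nrow(old))) {
      for (pos in seq_len(k)) {
        r <- r + 1L
        perms[r, ] <- append(old[i, ], k, after = pos - 1L)
      }
    }
  }
  perms
}

#' Frequency-iron correlation per taxon
#'
#' Spearman correlation between the per-site gene frequency and the
#' environmental covariate, computed separately per taxon bin.  Sites
#' flagged `excluded` (no core hits) are dropped first; taxa with fewer
#' than `min_sites` valid sites are skipped with a warning.
#'
#' @param profiles A `"frequency_profile"` from [gene_frequency()].
#' @param min_sites Minimum valid sites per taxon (default 3).
#' @return `data.frame` with `taxon`, `rho`, `p`, `n_sites`,
#'   `n_excluded`.
#' @export
site_correlation <- function(profiles, min_sites = 3L) {
  rows <- lapply(unique(profiles$taxon), function(tx) {
    s <- profiles[profiles$taxon == tx, , drop = FALSE]
    n_exc <- sum(s$excluded)
    s <- s[!s$excluded, , drop = FALSE]
    if (nrow(s) < min_sites) {
      warning("taxon ", tx, " skipped: only ", nrow(s),
              " valid site(s)")
      return(NULL)
    }
    sc <- spearman_cor(s$frequency, s$iron)
    data.frame(taxon = tx, rho = sc$rho, p = sc$p,
               n_sites = sc$n, n_excluded = n_exc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no taxon had enough valid sites")
  rownames(out) <- NULL
  out
}
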