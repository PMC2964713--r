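#' Per-site Poisson-corrected divergence
#'
#' For one alignment column, computes the fraction `p` of sequence pairs
#' (both non-gap, non-`X` at the column) that differ, and the
#' Poisson-corrected divergence `d = -ln(1 - p)`. A completely saturated
#' column (`p = 1`) is capped at `-ln(1 / (2 * n_pairs))` and flagged.
#'
#' @param aln A [protein_alignment()].
#' @param site Column index (1-based).
#' @return A one-row tibble with columns `site`, `n_nongap`, `n_pairs`,
#'   `p_diff`, `d`, `capped`, `informative`. Columns with fewer than 2
#'   usable residues are `informative = FALSE` with `d = NA`.
#' @examples
#' aln <- protein_alignment(c(a = "MK", b = "MK", c = "MR", d = "MR"))
#' site_poisson_divergence(aln, 1)$d  # invariant column: 0
#' @export
site_poisson_divergence <- function(aln, site) {
  stopifnot(site >= 1, site <= aln$length)
  col <- aln$mat[, site]
  res <- col[!col %in% c("-", "X")]
  n <- length(res)
  if (n < 2) {
    return(tibble(site = site, n_nongap = n, n_pairs = 0L, p_diff = NA_real_,
                  d = NA_real_, capped = FALSE, informative = FALSE))
  }
  n_pairs <- n * (n - 1) / 2
  tab <- table(res)
  same <- sum(tab * (tab - 1) / 2)
  p <- (n_pairs - same) / n_pairs
  capped <- p >= 1
  d <- if (capped) -log(1 / (2 * n_pairs)) else -log(1 - p)
  tibble(site = site, n_nongap = n, n_pairs = as.integer(n_pairs),
         p_diff = p, d = d, capped = capped, informative = TRUE)
}

#' Conservation profile with bootstrap threshold
#'
#' Computes the per-column Poisson divergence for every informative column,
#' then bootstraps `n_boot` columns with replacement to build the null
#' distribution of site divergences. A site is called conserved when its
#' divergence falls at or below the lower `tail` quantile of that
#' distribution (ties inclusive, so invariant columns always qualify).
#'
#' @param aln A [protein_alignment()].
#' @param n_boot Number of bootstrap column draws (>= 1000).
#' @param tail Lower-tail fraction defining "unusually conserved"
#'   (default 0.01, i.e. the lower 1\% of the distribution).
#' @param seed Integer seed; the bootstrap is fully reproducible.
#' @return Object of class `conservation_profile`: list with `sites`
#'   (tibble as in [site_poisson_divergence()], plus `conserved`),
#'   `threshold`, `tail`, `n_boot`, `seed`, `conserved_sites` (integer
#'   vector of column indices).
#' @export
conservation_profile <- function(aln, n_boot = 1e6, tail = 0.01, seed = 1L) {
  if (n_boot < 1000) abort("n_boot must be >= 1000")
  stopifnot(tail > 0, tail < 1)
  sites <- dplyr::bind_rows(lapply(seq_len(aln$length), function(i)
    site_poisson_divergence(aln, i)))
  d_inf <- sites$d[sites$informative]
  if (!length(d_inf))
    abort("all columns uninformative: no conservation profile",
          class = "compevo_degenerate_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "conservation_bootstrap"))
  boot <- sample(d_inf, n_boot, replace = TRUE)
  # empirical (type 1) quantile keeps the threshold on observed d values
  threshold <- as.numeric(quantile(boot, probs = tail, type = 1))
  sites$conserved <- sites$informative & !is.na(sites$d) & sites$d <= threshold
  structure(list(sites = sites, threshold = threshold, tail = tail,
                 n_boot = n_boot, seed = seed,
                 conserved_sites = sites$site[sites$conserved]),
            class = "conservation_profile")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d sites, threshold d <= %.4g (lower %.3g tail), %d conserved\n",
              nrow(x$sites), x$threshold, x$tail, length(x$conserved_sites)))
  invisible(x)
}

#' @rdname conservation_profile
#' @param x A `conservation_profile`.
#' @param ... Unused.
#' @export
tidy.conservation_profile <- function(x, ...) x$sites

#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(n_sites = nrow(x$sites),
         n_informative = sum(x$sites$informative),
         n_conserved = length(x$conserved_sites),
         threshold = x$threshold, tail = x$tail, n_boot = x$n_boot)
}

#' @export
autoplot.conservation_profile <- function(object, ...) {
  df <- object$sites[object$sites$informative, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$d)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$site, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$conserved), size = 1.2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "alignment column", y = "Poisson divergence d",
                  colour = "conserved") +
    ggplot2::theme_minimal()
}

#' Write a conservation profile as TSV
#'
#' @param profile A [conservation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(profile, path) {
  df <- profile$sites[, c("site", "d", "conserved")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
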