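#' @export
plot.ppi_matrix <- function(x, scheme = classification_scheme(), ...) {
  p <- length(x$proteins)
  v <- x$values
  img <- matrix(as.integer(classify_mfi(pmax(v, 0), scheme)), p, p)
  img[x$missing] <- NA
  graphics::image(seq_len(p), seq_len(p), t(img[p:1, , drop = FALSE]),
                  col = c("white", "steelblue", "gold", "firebrick"),
                  zlim = c(1, 4), axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(p), labels = x$proteins, las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::axis(2, at = seq_len(p), labels = rev(x$proteins), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::box()
  invisible(x)
}

#' @export
plot.permutation_result <- function(x, ...) {
  graphics::hist(x$null_sample, breaks = 50, col = "grey85", border = NA,
                 main = sprintf("null %s over %d draws; p = %.3g",
                                x$statistic, x$n_perm, x$p),
                 xlab = sprintf("%s of %d sampled pairs", x$statistic,
                                x$n_pairs),
                 xlim = range(c(x$null_sample, x$s_obs)), ...)
  graphics::abline(v = x$s_obs, col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
plot.overlap_result <- function(x, ...) {
  graphics::hist(x$null_samples, breaks = 50, col = "grey85", border = NA,
                 main = sprintf("random-surface null; empirical p = %.3g",
                                x$p_empirical),
                 xlab = "mean inter-surface contacts",
                 xlim = range(c(x$null_samples, x$misc_o)), ...)
  graphics::abline(v = x$misc_o, col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
plot.patchy_trajectory <- function(x, ...) {
  counts <- x$reaction_counts
  if (nrow(counts) == 0) stop("trajectory has no recorded points")
  graphics::matplot(x$steps, counts, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(counts), "viridis"),
                    xlab = "step", ylab = "cumulative reactions",
                    main = sprintf("%s (seed %d)", x$mode, x$seed), ...)
  graphics::legend("topleft", legend = colnames(counts), bty = "n",
                   col = grDevices::hcl.colors(ncol(counts), "viridis"),
                   lty = 1, cex = 0.7)
  invisible(x)
}
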