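#' Per-position residue enrichment/depletion statistics
#'
#' Two-sample-logo style contrast of positive vs negative windows: for
#' every (position, residue) cell a two-proportion z-test compares the
#' residue's frequency between classes (pooled-variance z, no continuity
#' correction, two-sided). Gaps and \code{X} are excluded from the
#' denominators. A cell is \code{enriched} when the positive-class
#' frequency is higher and p < alpha, \code{depleted} when lower and
#' p < alpha, otherwise \code{none}.
#'
#' @param posWindows,negWindows character vectors of equal-length peptides
#'   (or \code{\linkS4class{SiteWindowSet}} objects, split by label).
#' @param alpha significance level (default 0.05, uncorrected).
#' @return data.frame with columns \code{position} (offset \code{-w..+w}),
#'   \code{residue}, \code{fPos}, \code{fNeg}, \code{z}, \code{p},
#'   \code{status}.
#' @export
logoStats <- function(posWindows, negWindows, alpha = 0.05) {
  if (is(posWindows, "SiteWindowSet")) posWindows <- peptides(posWindows)
  if (is(negWindows, "SiteWindowSet")) negWindows <- peptides(negWindows)
  if (length(posWindows) == 0L || length(negWindows) == 0L)
    .stopf("both classes must be non-empty")
  L <- unique(nchar(c(posWindows, negWindows)))
  if (length(L) != 1L) .stopf("windows have unequal lengths")
  w <- (L - 1L) %/% 2L
  pm <- do.call(rbind, .splitChars(posWindows))
  nm <- do.call(rbind, .splitChars(negWindows))
  out <- vector("list", L)
  for (i in seq_len(L)) {
    pc <- pm[, i]
    nc <- nm[, i]
    n1 <- sum(.isStandard(pc))
    n2 <- sum(.isStandard(nc))
    cell <- data.frame(position = i - w - 1L, residue = AA_ALPHABET20,
                       fPos = NA_real_, fNeg = NA_real_, z = NA_real_,
                       p = NA_real_, status = "none",
                       stringsAsFactors = FALSE)
    if (n1 == 0L || n2 == 0L) {
      .warnf("no usable residues at offset %+d in one class", i - w - 1L)
      out[[i]] <- cell
      next
    }
    x1 <- vapply(AA_ALPHABET20, function(a) sum(pc == a), 0L)
    x2 <- vapply(AA_ALPHABET20, function(a) sum(nc == a), 0L)
    p1 <- x1 / n1
    p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- ifelse(se > 0, (p1 - p2) / se, 0)
    p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
    cell$fPos <- p1
    cell$fNeg <- p2
    cell$z <- z
    cell$p <- p
    cell$status <- ifelse(p < alpha & p1 > p2, "enriched",
                          ifelse(p < alpha & p1 < p2, "depleted", "none"))
    out[[i]] <- cell
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-position conservation contrast via Kruskal-Wallis
#'
#' For each window position, the per-window average PSSM value (the mean
#' over the 20 profile columns of that row) is compared between positive
#' and negative windows with a Kruskal-Wallis test; raw p-values are
#' Bonferroni-corrected by the number of positions (\code{2w + 1}).
#'
#' @param posProfiles,negProfiles lists of
#'   \code{\linkS4class{WindowProfile}}.
#' @param alpha significance level on the corrected p (default 0.05).
#' @return data.frame with columns \code{position} (offset), \code{H},
#'   \code{p}, \code{pBonferroni}, \code{significant}.
#' @export
kruskalWallisPositions <- function(posProfiles, negProfiles, alpha = 0.05) {
  if (length(posProfiles) == 0L || length(negProfiles) == 0L)
    .stopf("both groups must be non-empty")
  rowApv <- function(p) rowMeans(p@scores)
  pm <- do.call(rbind, lapply(posProfiles, rowApv))
  nm <- do.call(rbind, lapply(negProfiles, rowApv))
  if (ncol(pm) != ncol(nm)) .stopf("window sizes differ between groups")
  L <- ncol(pm)
  w <- (L - 1L) %/% 2L
  res <- lapply(seq_len(L), function(i) {
    g1 <- pm[, i]
    g2 <- nm[, i]
    if (length(unique(c(g1, g2))) == 1L) {
      data.frame(position = i - w - 1L, H = 0, p = 1)
    } else {
      kw <- stats::kruskal.test(list(g1, g2))
      data.frame(position = i - w - 1L, H = unname(kw$statistic),
                 p = unname(kw$p.value))
    }
  })
  res <- do.call(rbind, res)
  res$pBonferroni <- pmin(1, res$p * L)
  res$significant <- res$pBonferroni < alpha
  res
}
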