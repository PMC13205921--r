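## Phenotype heterosis, genetic gain over release years, correlation
## utilities and the Fisher z comparison of two correlations.

#' Mid-parent heterosis of hybrid phenotypes
#'
#' For every hybrid x trait x density cell with both parents measured:
#' mid_parent = (P1 + P2) / 2, absolute heterosis = F1 - mid_parent, percent
#' heterosis = 100 * absolute / mid_parent (undefined, NA and flagged, when
#' the mid-parent value is zero). Cells lacking a parent are skipped with a
#' reason recorded in \code{attr(, "skipped")}.
#'
#' @param phenotypes data.frame with genotype_id, role, trait, density,
#'   value (and release_year for hybrids)
#' @param manifest trio manifest
#' @return data.frame of HeterosisRecord rows
#' @export
computeHeterosis <- function(phenotypes, manifest) {
  out <- list(); skipped <- list()
  hyb <- phenotypes[phenotypes$role == "hybrid", , drop = FALSE]
  for (i in seq_len(nrow(hyb))) {
    h <- hyb[i, ]
    tr <- manifest[manifest$hybrid_id == h$genotype_id, , drop = FALSE]
    if (!nrow(tr)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(hybrid_id = h$genotype_id, trait = h$trait,
                   density = h$density, reason = "no trio manifest entry")
      next
    }
    pv <- function(id) {
      v <- phenotypes$value[phenotypes$genotype_id == id &
                              phenotypes$trait == h$trait &
                              phenotypes$density == h$density]
      if (length(v)) mean(v) else NA_real_
    }
    p1 <- pv(tr$female_id); p2 <- pv(tr$male_id)
    if (is.na(p1) || is.na(p2)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(hybrid_id = h$genotype_id, trait = h$trait,
                   density = h$density,
                   reason = paste("missing",
                                  if (is.na(p1)) "female" else "male",
                                  "parent value"))
      next
    }
    mid <- (p1 + p2) / 2
    ab <- h$value - mid
    out[[length(out) + 1L]] <- data.frame(
      hybrid_id = h$genotype_id, trait = h$trait, density = h$density,
      mid_parent = mid, absolute_heterosis = ab,
      percent_heterosis = if (mid == 0) NA_real_ else 100 * ab / mid,
      undefined_percent = mid == 0,
      release_year = h$release_year, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(hybrid_id = character(), trait = character(),
               density = character(), mid_parent = numeric(),
               absolute_heterosis = numeric(),
               percent_heterosis = numeric(), undefined_percent = logical(),
               release_year = integer(), stringsAsFactors = FALSE)
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    NULL
  res
}

#' Genetic gain: linear regression of performance on release year
#'
#' @param values trait (or heterosis) values per hybrid
#' @param years release years
#' @return list with slope (units per year), intercept, r2 and p
#' @importFrom stats lm coef pt pnorm cor
#' @export
geneticGain <- function(values, years) {
  ok <- is.finite(values) & is.finite(years)
  if (sum(ok) < 3) stop("genetic gain requires at least 3 hybrids")
  if (length(unique(years[ok])) < 2)
    stop("genetic gain requires at least 2 distinct release years")
  fit <- lm(values[ok] ~ years[ok])
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = s$r.squared,
       p = unname(s$coefficients[2, 4]), n = sum(ok))
}

#' Fisher z comparison of two correlation coefficients
#'
#' \code{z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))} with the
#' two-sided normal p-value. Swapping r1 and r2 negates z and leaves p
#' unchanged.
#'
#' @param r1,n1 first correlation and its sample size
#' @param r2,n2 second correlation and its sample size
#' @return list with z and p
#' @export
fisherZCompare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors (n >= 3, finite)
#' @return list with n, r, r2 and p; zero variance yields NA with a warning
#' @export
correlateTraits <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation requires at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(n = n, r = NA_real_, r2 = NA_real_, p = NA_real_))
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(n = n, r = r, r2 = r^2, p = 2 * pt(-abs(tstat), df = n - 2))
}
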