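## Parent-guided phasing of hybrid heterozygous SNPs.
##
## Rule table (applied in order):
##   any member missing ("./." or NA)            -> missing
##   either parent heterozygous                  -> parent_het
##   parents same homozygote, hybrid that same   -> uninformative
##   parents same homozygote, hybrid anything else -> conflict
##   parents opposite homozygotes, hybrid het    -> kept, phased
##     (0|1 when female is 0/0 and male 1/1, 1|0 when opposite)
##   parents opposite homozygotes, hybrid homozygous -> conflict
##     (contradicts Mendelian expectation at an informative site)
## Malformed genotype codes are rejected per record (counted), not fatal.

.phaseOne <- function(fem, mal, hyb) {
  valid <- c("0/0", "0/1", "1/1")
  if (is.na(fem) || is.na(mal) || is.na(hyb) ||
      fem == "./." || mal == "./." || hyb == "./.")
    return(c("none", "missing"))
  if (!(fem %in% valid) || !(mal %in% valid) || !(hyb %in% valid))
    return(c("none", "malformed"))
  if (fem == "0/1" || mal == "0/1") return(c("none", "parent_het"))
  if (fem == mal) {
    if (hyb == fem) return(c("none", "uninformative"))
    return(c("none", "conflict"))
  }
  if (hyb != "0/1") return(c("none", "conflict"))
  if (fem == "0/0") c("0|1", "kept") else c("1|0", "kept")
}

#' Phase hybrid heterozygous SNPs from parental homozygous genotypes
#'
#' Assigns every trio record exactly one filter label and, for informative
#' records (opposite parental homozygotes, heterozygous hybrid), the phased
#' hybrid genotype: \code{0|1} when the female parent is 0/0 and the male
#' 1/1, \code{1|0} for the opposite configuration. Heterozygous-parent
#' records, parent-hybrid Mendelian conflicts (including a hybrid homozygous
#' at an informative site) and missing genotypes are labelled and excluded
#' from phasing; records where both parents carry the same homozygote are
#' uninformative for allele-specific expression. Malformed genotype codes are
#' rejected per record with a count in the summary, never fatally.
#'
#' @param trios a \linkS4class{TrioGenotypes} or a data.frame with columns
#'   female_gt, male_gt, hybrid_gt (plus identifiers)
#' @return a \linkS4class{TrioGenotypes} with \code{phased_gt} and
#'   \code{filter_reason} filled and the label counts in
#'   \code{phasingSummary()}
#' @examples
#' df <- data.frame(snp_id = "s1", chrom = "chr1", pos = 1L,
#'                  hybrid_id = "H1", female_id = "F1", male_id = "M1",
#'                  female_gt = "0/0", male_gt = "1/1", hybrid_gt = "0/1")
#' phasingSummary(phaseTrio(TrioGenotypes(df)))
#' @export
phaseTrio <- function(trios) {
  if (!is(trios, "TrioGenotypes")) trios <- TrioGenotypes(trios)
  rec <- trioRecords(trios)
  n <- nrow(rec)
  fem <- as.character(rec$female_gt)
  mal <- as.character(rec$male_gt)
  hyb <- as.character(rec$hybrid_gt)
  valid <- c("0/0", "0/1", "1/1")
  isMiss <- is.na(fem) | is.na(mal) | is.na(hyb) |
    fem == "./." | mal == "./." | hyb == "./."
  isMalf <- !isMiss & (!(fem %in% valid) | !(mal %in% valid) |
                         !(hyb %in% valid))
  reason <- rep(NA_character_, n)
  phase <- rep("none", n)
  reason[isMiss] <- "missing"
  reason[isMalf] <- "malformed"
  todo <- !isMiss & !isMalf
  pHet <- todo & (fem == "0/1" | mal == "0/1")
  reason[pHet] <- "parent_het"
  todo <- todo & !pHet
  same <- todo & fem == mal
  reason[same & hyb == fem] <- "uninformative"
  reason[same & hyb != fem] <- "conflict"
  opp <- todo & fem != mal
  inf <- opp & hyb == "0/1"
  reason[opp & !inf] <- "conflict"
  reason[inf] <- "kept"
  phase[inf & fem == "0/0"] <- "0|1"
  phase[inf & fem == "1/1"] <- "1|0"

  rec$phased_gt <- phase
  rec$filter_reason <- reason
  counts <- table(factor(reason, levels = c(.FILTER_REASONS, "malformed")))
  out <- new("TrioGenotypes", records = rec,
             summary = setNames(as.integer(counts), names(counts)))
  validObject(out)
  if (counts[["malformed"]] > 0)
    warning(counts[["malformed"]], " record(s) with malformed genotype codes",
            " rejected")
  out
}
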