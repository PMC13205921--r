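# Independent phasing oracle: expected label for one trio derived from
# Mendelian gamete logic, not from the implementation's rule table.
phaseOracle <- function(fem, mal, hyb) {
  gts <- c("0/0", "0/1", "1/1")
  if (!all(c(fem, mal, hyb) %in% gts)) return(c("none", "missing"))
  if (fem == "0/1" || mal == "0/1") return(c("none", "parent_het"))
  gamete <- function(g) substr(g, 1, 1)  # a homozygote transmits one allele
  expected <- paste(sort(c(gamete(fem), gamete(mal))), collapse = "/")
  informative <- fem != mal
  if (!informative) {
    if (hyb == expected) return(c("none", "uninformative"))
    return(c("none", "conflict"))
  }
  if (hyb != expected) return(c("none", "conflict"))
  if (fem == "0/0") c("0|1", "kept") else c("1|0", "kept")
}
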