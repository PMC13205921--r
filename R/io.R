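## Plain-text input/output: TSV tables for every pipeline stage, a minimal
## GT-only VCF for trio genotypes, and YAML for configuration/metadata.

.writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read trio genotypes from a VCF plus a trio manifest
#'
#' The VCF must contain one sample column per line named in the manifest
#' (hybrid_id, female_id, male_id). Only the GT subfield is used; phased
#' separators are accepted and normalised to unphased codes, so an already
#' phased VCF round-trips through \code{\link{phaseTrio}} unchanged.
#'
#' @param vcfFile path to a VCF (uncompressed or bgzipped)
#' @param manifest data.frame with hybrid_id, female_id, male_id
#' @return a \linkS4class{TrioGenotypes}
#' @export
readTrioVCF <- function(vcfFile, manifest) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(vcfFile, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  norm <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    g[g == "1/0"] <- "0/1"
    g[is.na(g) | g == "." | g == "./."] <- "./."
    g
  }
  snp_id <- fix[, "ID"]
  noid <- is.na(snp_id) | snp_id == "."
  snp_id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    h <- manifest$hybrid_id[i]; f <- manifest$female_id[i]
    m <- manifest$male_id[i]
    miss <- setdiff(c(h, f, m), colnames(gt))
    if (length(miss))
      stop("samples missing from VCF: ", paste(miss, collapse = ", "))
    data.frame(snp_id = snp_id, chrom = fix[, "CHROM"],
               pos = as.integer(fix[, "POS"]), hybrid_id = h,
               female_id = f, male_id = m,
               female_gt = norm(gt[, f]), male_gt = norm(gt[, m]),
               hybrid_gt = norm(gt[, h]), stringsAsFactors = FALSE)
  })
  TrioGenotypes(do.call(rbind, recs))
}

#' Write trio genotypes as a minimal VCF
#'
#' One VCF per call with one sample column per line (parents unphased, the
#' hybrid's GT phased with \code{|} where phasing succeeded). REF/ALT are
#' placeholder A/G alleles: the tables this package consumes carry genotype
#' codes, not sequence.
#'
#' @param trios a \linkS4class{TrioGenotypes} (phased or not)
#' @param path output path
#' @return the path, invisibly
#' @export
writeTrioVCF <- function(trios, path) {
  rec <- as.data.frame(trioRecords(trios))
  snps <- unique(rec[, c("snp_id", "chrom", "pos")])
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  lines <- unique(unlist(rec[, c("female_id", "male_id", "hybrid_id")]))
  gtm <- matrix("./.", nrow(snps), length(lines),
                dimnames = list(snps$snp_id, lines))
  gtm[cbind(rec$snp_id, rec$female_id)] <- rec$female_gt
  gtm[cbind(rec$snp_id, rec$male_id)] <- rec$male_gt
  hybGT <- ifelse(!is.na(rec$phased_gt) & rec$phased_gt != "none",
                  rec$phased_gt, rec$hybrid_gt)
  gtm[cbind(rec$snp_id, rec$hybrid_id)] <- hybGT
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", lines), collapse = "\t"))
  body <- paste(snps$chrom, snps$pos, snps$snp_id, "A", "G", ".", "PASS",
                ".", "GT", apply(gtm, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) {
    v <- slot(config, s)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  names(out) <- nm
  out
}

#' Write a simulated study to plain-text files
#'
#' @param study the list returned by \code{\link{simulateStudy}}
#' @param outdir output directory (created if needed)
#' @return outdir, invisibly
#' @importFrom yaml write_yaml
#' @export
writeStudy <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  writeTrioVCF(study$trios, p("genotypes.vcf"))
  .writeTSV(as.data.frame(trioRecords(study$trios)), p("genotypes.tsv"))
  .writeTSV(study$snpGene, p("snp_gene_map.tsv"))
  .writeTSV(study$alleleCounts, p("allele_counts.tsv"))
  se <- study$expression
  cnt <- as.data.frame(SummarizedExperiment::assay(se, "counts"))
  cnt <- cbind(gene_id = rownames(cnt), cnt)
  .writeTSV(cnt, p("counts.tsv"))
  fp <- as.data.frame(SummarizedExperiment::assay(se, "fpkm"))
  fp <- cbind(gene_id = rownames(fp), fp)
  .writeTSV(fp, p("fpkm.tsv"))
  .writeTSV(as.data.frame(SummarizedExperiment::colData(se)),
            p("sample_metadata.tsv"))
  .writeTSV(as.data.frame(SummarizedExperiment::rowData(se)),
            p("gene_info.tsv"))
  .writeTSV(study$phenotypes, p("phenotypes.tsv"))
  .writeTSV(study$annotations, p("annotations.tsv"))
  .writeTSV(study$carriers, p("carriers.tsv"))
  .writeTSV(study$manifest, p("trios.tsv"))
  dir.create(p("truth"), showWarnings = FALSE)
  .writeTSV(study$truth$trios$records, p("truth/trio_records.tsv"))
  .writeTSV(study$truth$trios$snps, p("truth/snps.tsv"))
  .writeTSV(study$truth$expression$genes, p("truth/genes.tsv"))
  .writeTSV(study$truth$expression$hybrids, p("truth/hybrid_entropy.tsv"))
  .writeTSV(study$truth$phenotypes$pairs, p("truth/deleterious_pairs.tsv"))
  .writeTSV(study$truth$phenotypes$gerp_counts, p("truth/gerp_counts.tsv"))
  .writeTSV(study$truth$phenotypes$heterosis, p("truth/heterosis.tsv"))
  .writeTSV(study$truth$alleleCounts$beta0, p("truth/ase_beta0.tsv"))
  yaml::write_yaml(.configAsList(study$config), p("config.yaml"))
  invisible(outdir)
}

#' Read expression counts, FPKM and sample metadata into a
#' SummarizedExperiment
#'
#' @param countsFile,fpkmFile gene x sample TSVs whose first column is
#'   gene_id
#' @param metadataFile sample metadata TSV with sample_id, genotype_id,
#'   role, stage, density, replicate
#' @param geneInfoFile optional TSV with gene_id and length
#' @return a \code{SummarizedExperiment}
#' @export
readExpression <- function(countsFile, fpkmFile, metadataFile,
                           geneInfoFile = NULL) {
  cnt <- .readTSV(countsFile)
  fp <- .readTSV(fpkmFile)
  md <- .readTSV(metadataFile)
  genes <- cnt[[1]]
  cm <- as.matrix(cnt[, -1, drop = FALSE]); rownames(cm) <- genes
  fm <- as.matrix(fp[, -1, drop = FALSE]); rownames(fm) <- fp[[1]]
  fm <- fm[genes, colnames(cm), drop = FALSE]
  md <- md[match(colnames(cm), md$sample_id), , drop = FALSE]
  rd <- if (!is.null(geneInfoFile)) {
    gi <- .readTSV(geneInfoFile)
    DataFrame(gi[match(genes, gi$gene_id), , drop = FALSE])
  } else DataFrame(gene_id = genes)
  SummarizedExperiment(assays = list(counts = cm, fpkm = fm),
                       colData = DataFrame(md, row.names = md$sample_id),
                       rowData = rd)
}
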