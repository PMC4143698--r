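#' Write simulated genotypes as VCF
#'
#' Minimal VCF v4.2 with a GT-only FORMAT field; positions are 1-based.
#' Missing calls are written `./.`; variants flagged triallelic get a second
#' ALT allele so that downstream biallelic filters can act on the file alone.
#'
#' @param sim Output of [simulate_genotypes()] (or [simulate_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sim, path) {
  G <- sim$genotypes
  v <- sim$variants
  stopifnot(ncol(G) == nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=wgrpart",
               "##contig=<ID=chrS1>",
               "##FILTER=<ID=q10,Description=\"Failed quality control\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G)), collapse = "\t"), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    g <- G[, i]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    alt <- if (v$biallelic[i]) v$alt[i] else paste0(v$alt[i], ",T")
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], alt, ".",
            if (v$qc_pass[i]) "PASS" else "q10", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Uses vcfR to parse; alt-allele dosage is the count of non-reference
#' alleles in GT, `NA` for missing calls. QC pass is `FILTER %in% c("PASS",
#' ".")` and biallelic means a single ALT allele.
#'
#' @param path VCF file path.
#' @return A list with `genotypes` (subjects x variants) and `variants`
#'   (data.frame `variant_id`, `chrom`, `pos`, `qc_pass`, `biallelic`).
#' @export
read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- apply(gt, 2, function(col) {
    a <- strsplit(col, "[/|]")
    vapply(a, function(x) {
      if (any(x == "." | is.na(x))) NA_real_ else sum(x != "0")
    }, numeric(1))
  })
  dos <- t(dos)  # subjects x variants
  storage.mode(dos) <- "integer"
  colnames(dos) <- fix$ID
  variants <- data.frame(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    qc_pass = fix$FILTER %in% c("PASS", ".") | is.na(fix$FILTER),
    biallelic = !grepl(",", fix$ALT),
    stringsAsFactors = FALSE
  )
  list(genotypes = dos, variants = variants)
}

#' Write gene intervals as BED
#'
#' Standard 4-column BED: 0-based half-open intervals.
#' @param genes Gene table from [simulate_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a 4-column BED file of gene intervals
#' @param path BED file path.
#' @return data.frame (`chrom`, `start`, `end`, `name`).
#' @export
read_bed <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(g)[1:4] <- c("chrom", "start", "end", "name")
  g[, 1:4]
}

#' Write the long-format phenotype table as TSV
#' @param pheno Phenotype data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype TSV
#' @param path TSV with columns `subject_id`, `visit`, `SBP`, `age`, `sex`,
#'   `smoke`, `bpmed`.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "SBP", "age", "sex", "smoke", "bpmed")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  ph
}

#' Write the generating truth of a simulation as JSON
#' @param truth A `true_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_true_model <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
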