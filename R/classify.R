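#' Filter variants on QC status and allele count
#'
#' Retains variants that pass quality control and are biallelic; everything
#' else is tallied by reason. An empty retained set is allowed.
#'
#' @param variants data.frame with logical columns `qc_pass` and `biallelic`.
#' @return A list: `variants` (retained rows), `idx` (retained row indices),
#'   `n_excluded`, and `reasons` (named counts; a variant failing both is
#'   counted under `qc_fail`).
#' @export
filter_variants <- function(variants) {
  stopifnot(all(c("qc_pass", "biallelic") %in% names(variants)))
  keep <- variants$qc_pass & variants$biallelic
  reasons <- c(qc_fail = sum(!variants$qc_pass),
               multiallelic = sum(variants$qc_pass & !variants$biallelic))
  list(variants = variants[keep, , drop = FALSE],
       idx = which(keep),
       n_excluded = sum(!keep),
       reasons = reasons)
}

#' Minor allele frequency of one genotype column
#'
#' Allele-1 frequency over non-missing calls, folded to `min(f, 1 - f)` so
#' the result is the frequency of the *minor* allele.
#'
#' @param g Dosages in \{0, 1, 2, NA\}.
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("all genotype calls missing")
  if (!all(g %in% 0:2)) stop("dosages must be 0, 1 or 2")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Per-variant MAF for a genotype matrix
#' @param X Subjects x variants dosage matrix.
#' @return Numeric vector of folded MAFs.
#' @export
compute_maf_matrix <- function(X) {
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0)) stop("variant(s) with all calls missing")
  f <- colSums(X, na.rm = TRUE) / (2 * n_obs)
  pmin(f, 1 - f)
}

maf_class_levels <- c("very_rare", "rare", "common")

#' Classify MAF into frequency classes
#'
#' Very rare: MAF < 1%; rare: 1% <= MAF <= 5% (both boundaries belong to
#' rare, consistent with the strict inequalities defining the other two
#' classes); common: MAF > 5%. The partition is exhaustive and disjoint on
#' \[0, 0.5\]; monomorphic variants (MAF 0) fall in very_rare.
#'
#' @param maf Vector of folded MAFs in \[0, 0.5\].
#' @return Factor with levels `very_rare`, `rare`, `common`.
#' @export
classify_maf <- function(maf) {
  if (any(maf < 0 | maf > 0.5))
    stop("MAF must lie in [0, 0.5] (folded)")
  cls <- ifelse(maf < 0.01, "very_rare",
                ifelse(maf <= 0.05, "rare", "common"))
  factor(cls, levels = maf_class_levels)
}

region_class_levels <- c("genic", "flanking", "outside")

#' Classify variants as genic, flanking or outside
#'
#' A variant is genic if it falls inside any gene's transcribed interval
#' (introns included); otherwise flanking if within `flank_bp` outside any
#' gene; otherwise outside. Genic takes precedence over flanking. Gene
#' intervals are 0-based half-open (BED); variant positions are 1-based.
#' All genes matched at the winning precedence level are reported,
#' comma-separated.
#'
#' @param variants data.frame with `chrom` and `pos` (1-based).
#' @param genes Gene intervals (`chrom`, `start`, `end`, `name`), 0-based
#'   half-open.
#' @param flank_bp Flank width in bp (default 50,000).
#' @return data.frame with `region_class` (factor) and `genes` (character,
#'   `NA` outside).
#' @export
annotate_region <- function(variants, genes, flank_bp = 50000) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  if (nrow(genes) > 0 && any(genes$end <= genes$start))
    stop("malformed gene interval: end <= start")
  n <- nrow(variants)
  region <- rep("outside", n)
  hit_genes <- rep(NA_character_, n)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    gch <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gch) == 0) next
    q <- IRanges::IRanges(start = variants$pos[vi], width = 1)
    # 0-based half-open [s, e) covers 1-based positions s+1 .. e
    genic_rng <- IRanges::IRanges(start = gch$start + 1L, end = gch$end)
    foot_rng <- IRanges::IRanges(start = gch$start + 1L - flank_bp,
                                 end = gch$end + flank_bp)
    hg <- IRanges::findOverlaps(q, genic_rng)
    hf <- IRanges::findOverlaps(q, foot_rng)
    qg <- S4Vectors::queryHits(hg); sg <- S4Vectors::subjectHits(hg)
    qf <- S4Vectors::queryHits(hf); sf <- S4Vectors::subjectHits(hf)
    is_genic <- unique(qg)
    is_flank <- setdiff(unique(qf), is_genic)
    region[vi[is_genic]] <- "genic"
    region[vi[is_flank]] <- "flanking"
    if (length(qg))
      hit_genes[vi[is_genic]] <- vapply(
        split(gch$name[sg], qg), paste, character(1), collapse = ",")
    if (length(is_flank)) {
      keep <- qf %in% is_flank
      hit_genes[vi[is_flank]] <- vapply(
        split(gch$name[sf[keep]], qf[keep]), paste, character(1),
        collapse = ",")
    }
  }
  data.frame(region_class = factor(region, levels = region_class_levels),
             genes = hit_genes, stringsAsFactors = FALSE)
}

#' Annotate a filtered variant set
#'
#' Computes folded MAF from the genotype matrix (on whichever cohort the
#' matrix represents), classifies it, and adds the genic/flanking region
#' call.
#'
#' @param variants Variant table (must include `variant_id`, `chrom`, `pos`).
#' @param X Genotype matrix whose columns correspond to `variants` rows.
#' @param genes Gene-interval table.
#' @param flank_bp Flank width in bp.
#' @return The variant table with `maf`, `maf_class`, `region_class`,
#'   `genes` columns appended.
#' @export
annotate_variants <- function(variants, X, genes, flank_bp = 50000) {
  if (ncol(X) != nrow(variants))
    stop("genotype matrix and variant table are not conformable")
  maf <- compute_maf_matrix(X)
  reg <- annotate_region(variants, genes, flank_bp)
  out <- variants
  out$maf <- maf
  out$maf_class <- classify_maf(maf)
  out$region_class <- reg$region_class
  out$genes <- reg$genes
  out
}

#' Build the 12 marker sets
#'
#' Crosses region category \{all, genic, flanking\} with MAF category
#' \{all, common, rare, very_rare\}. Variants classified `outside` are
#' excluded from every set. Set membership is by variant (a variant flanking
#' two genes is counted once).
#'
#' @param ann Annotated variant table from [annotate_variants()].
#' @return A list of class `marker_sets`: `sets` (named list of integer
#'   index vectors into `ann` rows), `table` (data.frame of set sizes) and
#'   `crosstab` (counts with integer percents of the grand total).
#' @export
build_marker_sets <- function(ann) {
  stopifnot(all(c("maf_class", "region_class") %in% names(ann)))
  inside <- ann$region_class != "outside"
  regions <- c("all", "genic", "flanking")
  mafs <- c("all", "common", "rare", "very_rare")
  sets <- list()
  rows <- list()
  for (r in regions) {
    r_ok <- if (r == "all") inside else inside & ann$region_class == r
    for (m in mafs) {
      ok <- if (m == "all") r_ok else r_ok & ann$maf_class == m
      nm <- paste(r, m, sep = "_")
      sets[[nm]] <- which(ok)
      rows[[nm]] <- data.frame(set_name = nm, region = r, maf_class = m,
                               size = sum(ok), stringsAsFactors = FALSE)
    }
  }
  counts <- matrix(vapply(rows, function(d) d$size, integer(1)),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(regions, mafs))
  structure(list(sets = sets,
                 table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 crosstab = crosstab_percent(counts)),
            class = "marker_sets")
}

# round half away from zero, as used for printed integer percents
round_half_up <- function(x) floor(x + 0.5)

#' Counts-with-percent cross-tabulation
#'
#' Formats a regions x MAF-classes count grid with each cell's integer
#' percent of the grand total (the `all_all` cell), rounding half up.
#'
#' @param counts 3 x 4 integer matrix (rows all/genic/flanking, columns
#'   all/common/rare/very_rare).
#' @return data.frame with `<count>` and `<pct>` columns per MAF category.
#' @export
crosstab_percent <- function(counts) {
  grand <- counts["all", "all"]
  pct <- if (grand > 0) round_half_up(100 * counts / grand) else counts * NA
  out <- data.frame(region = rownames(counts), stringsAsFactors = FALSE)
  for (m in colnames(counts)) {
    out[[m]] <- counts[, m]
    out[[paste0(m, "_pct")]] <- as.integer(pct[, m])
  }
  out
}

#' @export
print.marker_sets <- function(x, ...) {
  cat("12 marker sets (region x MAF class):\n")
  print(x$crosstab, row.names = FALSE)
  invisible(x)
}
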