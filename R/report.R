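#' Format "mean +/- SD" to three decimals
#' @param m Mean.
#' @param s SD.
#' @return Character scalar like `"0.250 ± 0.063"`.
#' @export
format_mean_sd <- function(m, s) sprintf("%.3f ± %.3f", m, s)

set_grid_regions <- c("all", "genic", "flanking")
set_grid_mafs <- c("all", "common", "rare", "very_rare")

# Arrange a named per-set vector into the 3 x 4 region-by-MAF grid;
# missing cells become NA.
as_set_grid <- function(values) {
  grid <- matrix(NA_real_, nrow = 3, ncol = 4,
                 dimnames = list(set_grid_regions, set_grid_mafs))
  for (r in set_grid_regions)
    for (m in set_grid_mafs) {
      nm <- paste(r, m, sep = "_")
      if (nm %in% names(values)) grid[r, m] <- values[[nm]]
    }
  grid
}

#' Assemble the report tables
#'
#' Three grids with rows all/genic/flanking and columns
#' all/common/rare/very_rare: variant counts with integer percents of the
#' grand total, full-set R-squared (3 decimals), and resampled
#' "mean +/- SD" cells. Missing cells render as `NA`.
#'
#' @param per_set data.frame from [run_per_set()] (may be `NULL`).
#' @param resample_results Named list of [resample_fixed_size()] results
#'   (may be `NULL`).
#' @param marker_sets A [build_marker_sets()] object (may be `NULL`).
#' @param dir If non-`NULL`, write each table as a TSV there.
#' @return Named list of data.frames (`counts`, `r2_full`, `r2_resampled`),
#'   omitting tables whose inputs were not given.
#' @export
report_tables <- function(per_set = NULL, resample_results = NULL,
                          marker_sets = NULL, dir = NULL) {
  out <- list()
  if (!is.null(marker_sets)) out$counts <- marker_sets$crosstab
  if (!is.null(per_set)) {
    v <- stats::setNames(per_set$r2_full, per_set$set_name)
    g <- as_set_grid(as.list(v))
    df <- data.frame(region = rownames(g), stringsAsFactors = FALSE)
    for (m in colnames(g)) df[[m]] <- sprintf("%.3f", g[, m])
    df[df == "NA"] <- NA
    out$r2_full <- df
  }
  if (!is.null(resample_results)) {
    cells <- lapply(resample_results, function(s)
      format_mean_sd(s$r2_mean, s$r2_sd))
    g <- matrix(NA_character_, nrow = 3, ncol = 4,
                dimnames = list(set_grid_regions, set_grid_mafs))
    for (nm in names(cells)) {
      parts <- strsplit(nm, "_")[[1]]
      r <- parts[1]; m <- paste(parts[-1], collapse = "_")
      if (r %in% rownames(g) && m %in% colnames(g))
        g[r, m] <- cells[[nm]]
    }
    df <- data.frame(region = rownames(g), stringsAsFactors = FALSE)
    for (m in colnames(g)) df[[m]] <- g[, m]
    out$r2_resampled <- df
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      utils::write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "NA")
  }
  out
}

#' Printed variant counts of the hypertension gene panel
#'
#' Published per-gene tallies of genic and flanking variants for the 31
#' hypertension-pathway genes on odd-numbered chromosomes (with +/- 50 kb
#' flanks), together with the QC exclusion count and the post-QC
#' region-by-MAF cross-tabulation. These printed counts are the only piece
#' of the restricted cohort that is public, and serve as bookkeeping
#' fixtures: the initial variant total is the sum of the per-gene counts,
#' and the cross-tab marginals and integer percents must reproduce from
#' the counts.
#'
#' @return A list: `genes` (data.frame `gene`, `chromosome`, `genic`,
#'   `flanking`), `n_qc_excluded`, and `maf_counts` (3 x 4 matrix, rows
#'   all/genic/flanking, columns all/common/rare/very_rare).
#' @export
panel_counts <- function() {
  path <- system.file("extdata", "hypertension_panel_gene_counts.tsv",
                      package = "wgrpart")
  genes <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  mpath <- system.file("extdata", "hypertension_panel_maf_counts.tsv",
                       package = "wgrpart")
  m <- utils::read.table(mpath, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  maf <- as.matrix(m[, c("all", "common", "rare", "very_rare")])
  rownames(maf) <- m$region
  list(genes = genes, n_qc_excluded = 4470L, maf_counts = maf)
}
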