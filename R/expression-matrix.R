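#' Gene-by-sample expression matrix with panel metadata
#'
#' Lightweight container for a gene x sample grid of expression values,
#' either raw read counts (`mode = "counts"`) or RPKM (`mode = "rpkm"`),
#' together with the per-gene exon-model length in bp, the per-sample
#' total of mapped reads, and a sample sheet describing the cultivar x
#' stage layout of the panel.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Counts must be
#'   non-negative integers; RPKM non-negative reals.
#' @param samples data.frame with columns `sample_id`, `cultivar`,
#'   `stage` (integer 1..7) and `maturity_group` (`"post_ripening"` or
#'   `"non_post_ripening"`); one row per column of `values`.
#' @param mode `"counts"` or `"rpkm"`.
#' @param gene_length named numeric vector of exon-union lengths in bp
#'   (names = gene ids), or `NULL` if unknown.
#' @param total_mapped named numeric vector of per-sample mapped-read
#'   totals, or `NULL` if unknown. Required before RPKM computation.
#' @return an object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, samples, mode = c("counts", "rpkm"),
                             gene_length = NULL, total_mapped = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must be a matrix with gene rownames and sample colnames")
  if (anyNA(values)) stop("expression values must not contain NA")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (mode == "counts" && any(values != floor(values)))
    stop("counts must be integers")
  samples <- validate_sample_sheet(samples)
  if (!setequal(colnames(values), samples$sample_id))
    stop("matrix samples and sample sheet disagree: ",
         paste(symdiff_chr(colnames(values), samples$sample_id), collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(gene_length)) {
    gene_length <- gene_length[rownames(values)]
    if (anyNA(gene_length) || any(gene_length <= 0))
      stop("gene_length must be > 0 for every gene in the matrix")
  }
  if (!is.null(total_mapped)) {
    total_mapped <- total_mapped[colnames(values)]
    if (anyNA(total_mapped) || any(total_mapped <= 0))
      stop("total_mapped must be > 0 for every sample in the matrix")
  }
  structure(list(values = values, samples = samples, mode = mode,
                 gene_length = gene_length, total_mapped = total_mapped),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples (%d cultivars, stages %s)\n",
              x$mode, nrow(x$values), ncol(x$values),
              length(unique(x$samples$cultivar)),
              paste(range(x$samples$stage), collapse = "-")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Validate a cultivar x stage sample sheet
#'
#' Checks column presence, stage range (1..7), uniqueness of
#' (cultivar, stage) pairs and of sample ids, and the maturity-group
#' factor levels.
#'
#' @param samples data.frame candidate sample sheet.
#' @return the sheet with columns coerced to canonical types.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "cultivar", "stage", "maturity_group")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$cultivar <- as.character(samples$cultivar)
  samples$stage <- as.integer(samples$stage)
  samples$maturity_group <- as.character(samples$maturity_group)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sheet")
  if (anyDuplicated(samples[, c("cultivar", "stage")]))
    stop("duplicate (cultivar, stage) pair in sheet")
  if (any(samples$stage < 1L | samples$stage > 7L))
    stop("stages must lie in 1..7")
  ok <- samples$maturity_group %in% c("post_ripening", "non_post_ripening")
  if (!all(ok)) stop("maturity_group must be post_ripening or non_post_ripening")
  samples
}

#' Default five-cultivar, seven-stage pear panel sheet
#'
#' The standard panel layout: five cultivars sampled at six fruit
#' developmental stages plus one post-harvest senescence stage
#' (stage 7). Two cultivars continue ripening after harvest
#' (post-ripening group); the other three are eaten at harvest.
#'
#' @param cultivars character vector of cultivar codes.
#' @param post_ripening subset of `cultivars` in the post-ripening group.
#' @return a sample sheet data.frame (35 rows for the default panel).
#' @export
pear_sample_sheet <- function(cultivars = c("NG", "SK", "HS", "YL", "KX"),
                              post_ripening = c("NG", "SK")) {
  stopifnot(all(post_ripening %in% cultivars))
  sheet <- expand.grid(stage = 1:7, cultivar = cultivars,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- sheet[, c("cultivar", "stage")]
  sheet$sample_id <- paste0(sheet$cultivar, "_", sheet$stage)
  sheet$maturity_group <- ifelse(sheet$cultivar %in% post_ripening,
                                 "post_ripening", "non_post_ripening")
  validate_sample_sheet(sheet)
}

# samples of one cultivar ordered by stage
cultivar_samples <- function(em, cultivar) {
  sub <- em$samples[em$samples$cultivar == cultivar, , drop = FALSE]
  if (nrow(sub) == 0L) stop("cultivar not in sample sheet: ", cultivar)
  sub$sample_id[order(sub$stage)]
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))
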