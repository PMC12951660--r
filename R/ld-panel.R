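#' Pairwise LD panel with derived LD scores
#'
#' An `ld_panel` couples a variant panel with its matrix of pairwise allelic
#' correlations r and the derived per-variant LD scores
#' \eqn{\ell_j = \sum_k r_{jk}^2} (the row sum of squared correlations,
#' including the variant itself, hence always \eqn{\ge 1}). The squared
#' correlations drive LD clumping; the LD scores drive LD-score regression.
#'
#' @param variant_ids character vector of variant identifiers.
#' @param positions 1-based base-pair coordinates, same length.
#' @param r square symmetric correlation matrix with unit diagonal and
#'   entries in \[-1, 1\].
#' @param chromosome chromosome label(s), recycled to the panel length.
#'
#' @return An object of class `ld_panel`: a list with `variant_ids`,
#'   `chromosome`, `positions`, `r` and recomputed `ld_scores`.
#' @export
ld_panel <- function(variant_ids, positions, r, chromosome = "1") {
  variant_ids <- as.character(variant_ids)
  m <- length(variant_ids)
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids in LD panel", call. = FALSE)
  if (length(positions) != m) stop("positions length mismatch", call. = FALSE)
  r <- as.matrix(r)
  if (nrow(r) != m || ncol(r) != m) {
    stop("correlation matrix is not ", m, " x ", m, call. = FALSE)
  }
  if (max(abs(r - t(r))) > 1e-8) stop("correlation matrix is asymmetric", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12)) stop("correlation entries outside [-1, 1]", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-8) stop("correlation diagonal is not 1", call. = FALSE)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids,
                 chromosome = rep_len(as.character(chromosome), m),
                 positions = as.numeric(positions),
                 r = r,
                 ld_scores = rowSums(r^2)),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("ld_panel: %d variants, mean LD score %.3f\n",
              length(x$variant_ids), mean(x$ld_scores)))
  invisible(x)
}

#' Read an LD panel from a variant table and a dense matrix file
#'
#' The variant table is tab-separated with columns `variant_id`,
#' `chromosome`, `position`; the matrix file holds the dense correlation
#' matrix, one tab-separated row per variant, in the same order. LD scores
#' are always recomputed from the matrix, never trusted from disk.
#'
#' @param variant_path path to the variant table.
#' @param matrix_path path to the dense correlation matrix.
#' @return An [ld_panel].
#' @export
read_ld_panel <- function(variant_path, matrix_path) {
  vt <- utils::read.delim(variant_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("variant_id", "position")) {
    if (is.null(vt[[col]])) stop("variant table missing column: ", col, call. = FALSE)
  }
  if (is.null(vt$chromosome)) vt$chromosome <- "1"
  r <- as.matrix(utils::read.table(matrix_path, header = FALSE, sep = "\t"))
  if (nrow(r) != ncol(r)) stop("LD matrix is not square", call. = FALSE)
  if (nrow(r) != nrow(vt)) {
    stop("LD matrix dimension does not match the variant table", call. = FALSE)
  }
  ld_panel(vt$variant_id, vt$position, r, chromosome = vt$chromosome)
}

#' Write an LD panel to a variant table and a dense matrix file
#'
#' @param panel an [ld_panel].
#' @param variant_path,matrix_path output paths (see [read_ld_panel()]).
#' @return `variant_path`, invisibly.
#' @export
write_ld_panel <- function(panel, variant_path, matrix_path) {
  vt <- data.frame(variant_id = panel$variant_ids,
                   chromosome = panel$chromosome,
                   position = fmt_num(panel$positions),
                   stringsAsFactors = FALSE)
  utils::write.table(vt, variant_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- apply(panel$r, 1L, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(m, matrix_path)
  invisible(variant_path)
}
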