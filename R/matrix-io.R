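#' Write a labeled square matrix as TSV
#'
#' Round-tripping through [read_matrix()] reproduces values to 1e-9.
#'
#' @param m Square numeric matrix with identical row and column labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (nrow(m) > 0 && !identical(rownames(m), colnames(m)))
    stop("row labels do not match column labels")
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square matrix from TSV
#' @param path File written by [write_matrix()].
#' @return Labeled numeric matrix.
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    labs <- setdiff(names(df), "label")
    m <- matrix(numeric(0), 0, 0)
    return(m)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$label
  if (!identical(rownames(m), colnames(m)))
    stop("label mismatch between rows and columns in ", path)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around `ape::nj()` with standard clamping of negative branch
#' lengths to zero; stands in for full ML phylogenies when only a quick
#' topology from a relatedness matrix is needed.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal,
#'   labeled, n >= 3.
#' @return Newick string (unrooted tree).
#' @export
build_nj_tree <- function(d) {
  stopifnot(is.matrix(d))
  if (nrow(d) < 3) stop("need at least 3 taxa for neighbor joining")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::write.tree(tr)
}
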