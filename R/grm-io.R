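#' Genomic relationship matrix container
#'
#' Holds a symmetric n x n relatedness matrix together with individual IDs
#' and (optionally) the number of SNPs that contributed to each pair.
#' Diagonal entries estimate 1 + genomic inbreeding; off-diagonals estimate
#' additive relatedness between pairs of individuals.
#'
#' @param fid,iid character vectors of family / individual IDs.
#' @param values symmetric numeric n x n matrix.
#' @param pair_snp_counts optional symmetric n x n matrix of SNP counts per
#'   pair.
#' @return An object of class `"grm"`.
#' @export
grm <- function(fid, iid, values, pair_snp_counts = NULL) {
  fid <- as.character(fid); iid <- as.character(iid)
  values <- as.matrix(values)
  obj <- structure(list(fid = fid, iid = iid, values = values,
                        pair_snp_counts = pair_snp_counts),
                   class = "grm")
  validate_grm(obj)
  obj
}

validate_grm <- function(x) {
  stopifnot(inherits(x, "grm"))
  n <- length(x$fid)
  if (length(x$iid) != n) stop("fid and iid lengths differ")
  if (!all(dim(x$values) == c(n, n)))
    stop("GRM matrix dimensions do not match the ", n, " IDs")
  if (anyDuplicated(id_key(x$fid, x$iid)))
    stop("duplicate individual IDs in GRM")
  if (!isSymmetric(unname(x$values), tol = 1e-8))
    stop("GRM matrix is not symmetric")
  if (any(!is.finite(diag(x$values))))
    stop("non-finite GRM diagonal")
  if (!is.null(x$pair_snp_counts)) {
    if (!all(dim(x$pair_snp_counts) == c(n, n)))
      stop("pair_snp_counts dimensions do not match")
    if (any(x$pair_snp_counts < 0))
      stop("negative pair_snp_counts")
  }
  invisible(x)
}

#' @export
print.grm <- function(x, ...) {
  n <- length(x$fid)
  off <- x$values[upper.tri(x$values)]
  cat("GRM:", n, "individuals\n")
  cat(sprintf("  diagonal   mean %.4f  range [%.4f, %.4f]\n",
              mean(diag(x$values)), min(diag(x$values)), max(diag(x$values))))
  if (length(off))
    cat(sprintf("  off-diag   mean %.4f  max %.4f\n", mean(off), max(off)))
  invisible(x)
}

#' @export
dim.grm <- function(x) rep(length(x$fid), 2)

#' Subset a GRM by individual index, keeping ID order
#'
#' @param x a `"grm"` object.
#' @param i integer or logical index over individuals.
#' @return A `"grm"` object.
#' @export
subset_grm <- function(x, i) {
  grm(x$fid[i], x$iid[i], x$values[i, i, drop = FALSE],
      if (!is.null(x$pair_snp_counts))
        x$pair_snp_counts[i, i, drop = FALSE])
}

# lower-triangle (row-major, including diagonal) index pairs for n
lower_tri_rowwise <- function(n) {
  cbind(rep(seq_len(n), seq_len(n)), sequence(seq_len(n)))
}

#' Read a GCTA binary GRM
#'
#' Reads the GCTA triplet `prefix.grm.bin` / `prefix.grm.N.bin` /
#' `prefix.grm.id`. The `.bin` files hold little-endian 32-bit floats for
#' the lower triangle including the diagonal, ordered row by row
#' ((1,1), (2,1), (2,2), ...); the `.id` file has two whitespace-separated
#' columns (family ID, individual ID).
#'
#' @param prefix path stem of the triplet.
#' @return A [grm()] object (with `pair_snp_counts` if `.grm.N.bin` is
#'   present).
#' @export
read_grm_gcta <- function(prefix) {
  id_path <- paste0(prefix, ".grm.id")
  bin_path <- paste0(prefix, ".grm.bin")
  n_path <- paste0(prefix, ".grm.N.bin")
  if (!file.exists(id_path)) stop("missing file: ", id_path)
  if (!file.exists(bin_path)) stop("missing file: ", bin_path)
  ids <- utils::read.table(id_path, header = FALSE, colClasses = "character")
  n <- nrow(ids)
  nel <- n * (n + 1) / 2
  expected <- 4 * nel
  if (file.size(bin_path) != expected)
    stop("GRM format error: ", bin_path, " has ", file.size(bin_path),
         " bytes but ", n, " IDs imply ", expected)
  con <- file(bin_path, "rb"); on.exit(close(con), add = TRUE)
  vals <- readBin(con, what = "numeric", n = nel, size = 4,
                  endian = "little")
  idx <- lower_tri_rowwise(n)
  G <- matrix(0, n, n)
  G[idx] <- vals
  G[idx[, c(2, 1)]] <- vals
  counts <- NULL
  if (file.exists(n_path)) {
    if (file.size(n_path) != expected)
      stop("GRM format error: ", n_path, " has ", file.size(n_path),
           " bytes but expected ", expected)
    con2 <- file(n_path, "rb"); on.exit(close(con2), add = TRUE)
    nv <- readBin(con2, what = "numeric", n = nel, size = 4,
                  endian = "little")
    counts <- matrix(0, n, n)
    counts[idx] <- nv
    counts[idx[, c(2, 1)]] <- nv
  }
  grm(ids[, 1], ids[, 2], G, counts)
}

#' Write a GCTA binary GRM
#'
#' Emits the triplet `prefix.grm.bin`, `prefix.grm.N.bin` (if
#' `pair_snp_counts` is present) and `prefix.grm.id` in the exact layout
#' read by [read_grm_gcta()]. Values are quantized to 32-bit floats.
#'
#' @param x a [grm()] object.
#' @param prefix output path stem.
#' @return Invisibly, the paths written.
#' @export
write_grm_gcta <- function(x, prefix) {
  validate_grm(x)
  n <- length(x$fid)
  idx <- lower_tri_rowwise(n)
  id_path <- paste0(prefix, ".grm.id")
  bin_path <- paste0(prefix, ".grm.bin")
  utils::write.table(data.frame(x$fid, x$iid), id_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  con <- file(bin_path, "wb")
  writeBin(as.double(x$values[idx]), con, size = 4, endian = "little")
  close(con)
  out <- c(bin_path, id_path)
  if (!is.null(x$pair_snp_counts)) {
    n_path <- paste0(prefix, ".grm.N.bin")
    con2 <- file(n_path, "wb")
    writeBin(as.double(x$pair_snp_counts[idx]), con2, size = 4,
             endian = "little")
    close(con2)
    out <- c(out, n_path)
  }
  invisible(out)
}
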