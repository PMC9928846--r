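#' Genotype dosage container
#'
#' Bundles an individuals-by-SNPs additive dosage matrix with individual IDs
#' and SNP metadata. Dosages count copies of allele A2, so each entry is 0,
#' 1 or 2; missing genotypes are `NA`.
#'
#' @param fid character vector of family IDs.
#' @param iid character vector of individual IDs (the pair (fid, iid) must
#'   be unique).
#' @param dosage numeric matrix, `length(fid)` rows and `nrow(map)` columns,
#'   entries in \{0, 1, 2, NA\}.
#' @param map data.frame of SNP metadata with columns `snp_id`,
#'   `chromosome`, `position`, `allele_a1`, `allele_a2`.
#'
#' @return An object of class `"genotypes"`: a list with elements `fid`,
#'   `iid`, `dosage` and `map`.
#' @export
genotypes <- function(fid, iid, dosage, map) {
  fid <- as.character(fid)
  iid <- as.character(iid)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  dimnames(dosage) <- NULL
  if (is.null(map)) {
    map <- data.frame(snp_id = paste0("snp", seq_len(ncol(dosage))),
                      chromosome = "0", position = seq_len(ncol(dosage)),
                      allele_a1 = "A", allele_a2 = "B",
                      stringsAsFactors = FALSE)
  }
  obj <- structure(list(fid = fid, iid = iid, dosage = dosage, map = map),
                   class = "genotypes")
  validate_genotypes(obj)
  obj
}

validate_genotypes <- function(x) {
  stopifnot(inherits(x, "genotypes"))
  n <- length(x$fid)
  if (length(x$iid) != n)
    stop("fid and iid lengths differ")
  if (nrow(x$dosage) != n)
    stop("dosage matrix has ", nrow(x$dosage), " rows but there are ", n,
         " individual IDs")
  if (ncol(x$dosage) != nrow(x$map))
    stop("dosage matrix has ", ncol(x$dosage), " columns but map describes ",
         nrow(x$map), " SNPs")
  key <- paste(x$fid, x$iid, sep = "\t")
  if (anyDuplicated(key))
    stop("duplicate individual IDs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (anyDuplicated(x$map$snp_id))
    stop("duplicate SNP IDs in map")
  if (any(x$map$position < 0, na.rm = TRUE))
    stop("negative SNP position in map")
  d <- x$dosage
  bad <- !is.na(d) & !(d %in% c(0, 1, 2))
  if (any(bad))
    stop("dosage values outside {0, 1, 2, NA}")
  invisible(x)
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Genotype dosages:", length(x$fid), "individuals x",
      nrow(x$map), "SNPs\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) c(length(x$fid), nrow(x$map))

id_key <- function(fid, iid) paste(fid, iid, sep = "\t")

#' Subset a genotype object by individual index
#'
#' @param x a `"genotypes"` object.
#' @param i integer or logical index over individuals.
#' @param j integer or logical index over SNPs.
#' @return A `"genotypes"` object.
#' @export
subset_genotypes <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_along(x$fid)
  if (is.null(j)) j <- seq_len(nrow(x$map))
  genotypes(x$fid[i], x$iid[i], x$dosage[i, j, drop = FALSE],
            x$map[j, , drop = FALSE])
}

#' Read genotypes from disk
#'
#' Two plain-text dialects are supported. `format = "dosage_tsv"` is a
#' whitespace-delimited table whose header row is `FID IID <snp ids...>` and
#' whose body holds dosages in \{0, 1, 2\} with `NA` for missing calls.
#' `format = "ped"` reads a PLINK text pedigree file together with its
#' `.map` companion; genotypes of "0 0" (or any half-missing call) become
#' missing, and dosages count copies of allele A2, the lexicographically
#' later of the two alleles observed at each SNP.
#'
#' @param path file path. For `"ped"`, the `.ped` file; the `.map` file is
#'   found by swapping the extension unless `map_path` is given.
#' @param format `"dosage_tsv"` or `"ped"`.
#' @param map_path optional explicit path of the `.map` file.
#' @return A [genotypes()] object.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "ped"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         dosage_tsv = read_dosage_tsv(path),
         ped = read_ped(path, map_path))
}

read_dosage_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  if (length(header) < 3 || toupper(header[1]) != "FID" ||
      toupper(header[2]) != "IID")
    stop("dosage TSV must start with header 'FID IID <snp ids>': ", path)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           colClasses = c("character", "character",
                                          rep("numeric", length(header) - 2)),
                           na.strings = c("NA", "-9"))
  dos <- as.matrix(tab[, -(1:2), drop = FALSE])
  bad <- which(!is.na(dos) & !(dos %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("malformed dosage at line ", bad[1, 1] + 1L, " of ", path,
         " (value ", dos[bad[1, 1], bad[1, 2]], ")")
  map <- data.frame(snp_id = colnames(dos), chromosome = "0",
                    position = seq_len(ncol(dos)),
                    allele_a1 = "A", allele_a2 = "B",
                    stringsAsFactors = FALSE)
  genotypes(tab[[1]], tab[[2]], dos, map)
}

read_ped <- function(ped_path, map_path = NULL) {
  if (is.null(map_path))
    map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path)) stop("missing .map companion: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4)
    stop(".map must have 4 columns (chr, snp, cM, bp): ", map_path)
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) stop("empty .ped file: ", ped_path)
  fid <- character(n); iid <- character(n)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (r in seq_len(n)) {
    tok <- strsplit(trimws(lines[r]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m)
      stop("malformed .ped line ", r, ": expected ", 6 + 2 * m,
           " fields, found ", length(tok))
    fid[r] <- tok[1]; iid[r] <- tok[2]
    g <- tok[-(1:6)]
    a1[r, ] <- g[seq(1, 2 * m, by = 2)]
    a2[r, ] <- g[seq(2, 2 * m, by = 2)]
  }
  dos <- matrix(NA_real_, n, m)
  all1 <- character(m); all2 <- character(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2)
      stop("SNP ", map_raw[j, 2], " has more than two alleles")
    if (length(obs) == 0) obs <- c("0", "0")
    if (length(obs) == 1) obs <- c("0", obs)
    all1[j] <- obs[1]; all2[j] <- obs[2]
    ok <- a1[, j] != "0" & a2[, j] != "0"
    dos[ok, j] <- (a1[ok, j] == obs[2]) + (a2[ok, j] == obs[2])
  }
  map <- data.frame(snp_id = map_raw[, 2], chromosome = map_raw[, 1],
                    position = as.integer(map_raw[, 4]),
                    allele_a1 = all1, allele_a2 = all2,
                    stringsAsFactors = FALSE)
  genotypes(fid, iid, dos, map)
}

#' Write genotypes to disk
#'
#' Inverse of [read_genotypes()]; both dialects round-trip dosages exactly
#' (for `"ped"` the alleles written are A1/A2 from the map, missing cells
#' become "0 0").
#'
#' @param geno a [genotypes()] object.
#' @param path output path (`.ped` for format `"ped"`; its `.map` companion
#'   is written alongside).
#' @param format `"dosage_tsv"` or `"ped"`.
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(geno, path, format = c("dosage_tsv", "ped")) {
  format <- match.arg(format)
  validate_genotypes(geno)
  if (format == "dosage_tsv") {
    tab <- data.frame(FID = geno$fid, IID = geno$iid,
                      geno$dosage, check.names = FALSE)
    colnames(tab) <- c("FID", "IID", geno$map$snp_id)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  map_path <- sub("\\.ped$", ".map", path)
  utils::write.table(
    data.frame(geno$map$chromosome, geno$map$snp_id, 0, geno$map$position),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  n <- length(geno$fid); m <- nrow(geno$map)
  gcols <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    d <- geno$dosage[, j]
    A <- geno$map$allele_a1[j]; B <- geno$map$allele_a2[j]
    first <- ifelse(is.na(d), "0", ifelse(d >= 1, B, A))
    second <- ifelse(is.na(d), "0", ifelse(d == 2, B, A))
    gcols[, 2 * j - 1] <- first
    gcols[, 2 * j] <- second
  }
  body <- cbind(geno$fid, geno$iid, "0", "0", "0", "-9", gcols)
  writeLines(apply(body, 1, paste, collapse = " "), path)
  invisible(c(path, map_path))
}

#' Read a phenotype table
#'
#' Reads a PLINK/GCTA `.phen`-style whitespace-delimited file: columns FID,
#' IID then one or more numeric trait columns; `NA` and `-9` code missing
#' values. A header line is detected automatically (third token
#' non-numeric).
#'
#' @param path file path.
#' @param trait_names optional character vector naming the trait columns;
#'   defaults to header names or `trait1, trait2, ...`.
#' @return A data.frame with columns `FID`, `IID` and one column per trait.
#' @export
read_phen <- function(path, trait_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3]))) &&
    !(first[3] %in% c("NA", "-9"))
  tab <- utils::read.table(path, header = has_header,
                           colClasses = c("character", "character",
                                          rep("numeric",
                                              length(first) - 2)),
                           na.strings = c("NA", "-9"))
  if (ncol(tab) < 3) stop("phenotype file needs FID, IID and >= 1 trait")
  if (is.null(trait_names)) {
    trait_names <- if (has_header) colnames(tab)[-(1:2)] else
      paste0("trait", seq_len(ncol(tab) - 2))
  }
  colnames(tab) <- c("FID", "IID", trait_names)
  tab
}

#' Write a phenotype table in .phen layout
#'
#' @param phen data.frame with columns FID, IID and trait columns.
#' @param path output path.
#' @param header write a header line (default TRUE; GCTA itself expects no
#'   header, pass FALSE for strict compatibility).
#' @return Invisibly, `path`.
#' @export
write_phen <- function(phen, path, header = TRUE) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header, na = "NA")
  invisible(path)
}
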