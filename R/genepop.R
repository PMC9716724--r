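## GenePop text format for diploid microsatellite genotypes, plus a
## lossless CSV dialect for allele labels that do not fit 2-3 digit codes.

#' Write genotypes in GenePop format
#'
#' Allele labels must be integer-coercible; they are zero-padded to two or
#' three digits (three if any code exceeds 99). Missing loci are written as
#' all-zero codes. One population block is written.
#'
#' @param genotypes a [MultilocusGenotypes-class].
#' @param path output file.
#' @param title first (title) line of the file.
#' @return invisibly, `path`.
#' @export
writeGenepop <- function(genotypes, path, title = "pandaNet genotypes") {
  a1 <- genotypes@allele1
  a2 <- genotypes@allele2
  codes <- suppressWarnings(as.integer(c(a1, a2)))
  if (any(is.na(codes) & !is.na(c(a1, a2)))) {
    stop("GenePop requires integer-coercible allele labels; ",
         "use writeGenotypesCsv() for arbitrary labels")
  }
  digits <- if (any(codes > 99, na.rm = TRUE)) 3L else 2L
  fmt <- paste0("%0", digits, "d")
  enc <- function(x) {
    out <- sprintf(fmt, suppressWarnings(as.integer(x)))
    out[is.na(x)] <- strrep("0", digits)
    out
  }
  body <- paste0(enc(a1), enc(a2))
  dim(body) <- dim(a1)
  lines <- c(title, colnames(a1), "Pop",
             vapply(seq_len(nrow(a1)), function(i) {
               paste0(rownames(a1)[i], " ,  ",
                      paste(body[i, ], collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a GenePop file
#'
#' Supports locus names one per line or comma-separated on one line, and
#' 2- or 3-digit diploid codes. All population blocks are pooled. Allele
#' labels are returned zero-padded at the file's code width; all-zero codes
#' become missing loci.
#'
#' @param path GenePop file.
#' @return a [MultilocusGenotypes-class].
#' @export
readGenepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  popIdx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(popIdx) == 0L) stop("not a GenePop file: no 'Pop' line")
  header <- lines[2:(popIdx[1L] - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]

  recs <- lines[setdiff(seq(popIdx[1L] + 1L, length(lines)), popIdx)]
  ids <- character(length(recs))
  a1 <- matrix(NA_character_, length(recs), length(loci))
  a2 <- a1
  for (i in seq_along(recs)) {
    parts <- strsplit(recs[i], ",")[[1L]]
    if (length(parts) < 2L) stop("malformed GenePop record: ", recs[i])
    ids[i] <- trimws(parts[1L])
    codes <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(codes) != length(loci)) {
      stop("record ", ids[i], ": expected ", length(loci), " loci, got ",
           length(codes))
    }
    w <- nchar(codes[1L]) / 2L
    x1 <- substr(codes, 1L, w)
    x2 <- substr(codes, w + 1L, 2L * w)
    miss <- x1 == strrep("0", w) | x2 == strrep("0", w)
    x1[miss] <- NA_character_
    x2[miss] <- NA_character_
    a1[i, ] <- x1
    a2[i, ] <- x2
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  multilocusGenotypes(a1, a2)
}

#' Write genotypes as long-format CSV (lossless allele labels)
#'
#' @param genotypes a [MultilocusGenotypes-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGenotypesCsv <- function(genotypes, path) {
  a1 <- genotypes@allele1
  df <- data.frame(
    id = rep(rownames(a1), times = ncol(a1)),
    locus = rep(colnames(a1), each = nrow(a1)),
    allele1 = as.vector(a1),
    allele2 = as.vector(genotypes@allele2),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from the long-format CSV dialect
#'
#' @param path CSV with columns id, locus, allele1, allele2.
#' @return a [MultilocusGenotypes-class].
#' @export
readGenotypesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(allele1 = "character",
                                       allele2 = "character"))
  ids <- unique(df$id)
  loci <- unique(df$locus)
  a1 <- matrix(NA_character_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  ij <- cbind(match(df$id, ids), match(df$locus, loci))
  a1[ij] <- df$allele1
  a2[ij] <- df$allele2
  multilocusGenotypes(a1, a2)
}
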