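#' Diploid multilocus genotype dataset
#'
#' Container for codominant diploid genotypes grouped by sampling site.
#' Alleles are integer codes (for microsatellites typically repeat numbers
#' or fragment sizes); nothing downstream assumes they are repeat lengths
#' except the stepwise-mutation simulator. A missing genotype has both
#' alleles \code{NA}; half-called genotypes are invalid.
#'
#' @param alleles integer array \code{n_individuals x n_loci x 2}; both
#'   slices \code{NA} where a genotype is missing
#' @param loci character vector of locus names (unique)
#' @param ind data.frame with columns \code{id} and \code{site}
#' @param sites optional data.frame of site metadata with column
#'   \code{site_id} (plus e.g. \code{latitude}, \code{longitude},
#'   \code{river}); defaults to the distinct sites in \code{ind}
#' @return object of class \code{genotype_dataset}
#' @export
genotype_dataset <- function(alleles, loci, ind, sites = NULL) {
  stopifnot(is.array(alleles), length(dim(alleles)) == 3L, dim(alleles)[3] == 2L)
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (dim(alleles)[2] != length(loci)) stop("allele array / loci mismatch")
  if (dim(alleles)[1] != nrow(ind)) stop("allele array / individual mismatch")
  if (!all(c("id", "site") %in% names(ind))) stop("ind needs columns id, site")
  half <- xor(is.na(alleles[, , 1, drop = FALSE]), is.na(alleles[, , 2, drop = FALSE]))
  if (any(half)) stop("half-called genotypes (exactly one missing allele) are not allowed")
  if (is.null(sites)) sites <- data.frame(site_id = unique(ind$site))
  if (!all(ind$site %in% sites$site_id)) stop("every individual's site must appear in sites")
  structure(list(alleles = alleles, loci = loci,
                 ind = data.frame(id = as.character(ind$id),
                                  site = as.character(ind$site)),
                 sites = sites),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$ind), "individuals,", length(x$loci),
      "loci,", length(unique(x$ind$site)), "sites\n")
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

n_loci <- function(ds) length(ds$loci)
site_ids <- function(ds) unique(ds$ind$site)

#' Per-site sample sizes
#' @param ds genotype_dataset
#' @return named integer vector, one entry per site in first-appearance order
#' @export
site_sizes <- function(ds) {
  tab <- table(factor(ds$ind$site, levels = site_ids(ds)))
  setNames(as.integer(tab), names(tab))
}

## indices of individuals belonging to one site
site_index <- function(ds, site) which(ds$ind$site == site)

## n_ind x 2 allele matrix for one locus (possibly restricted to rows)
locus_alleles <- function(ds, locus, rows = NULL) {
  j <- match(locus, ds$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  a <- ds$alleles[, j, , drop = FALSE]
  dim(a) <- c(dim(ds$alleles)[1], 2L)
  if (!is.null(rows)) a <- a[rows, , drop = FALSE]
  a
}

#' Read a GENEPOP file
#'
#' Parses the GENEPOP dialect for diploid data: a title line, one locus name
#' per line (or a single comma-separated line), \code{Pop} separators, then
#' one individual per line as \code{id , g1 g2 ...} with 2- or 3-digit allele
#' coding and \code{00}/\code{000} meaning missing. Both coding widths are
#' autodetected from genotype string length. Population blocks are assigned
#' site ids from the id of each block's first individual up to a trailing
#' \code{_<n>} suffix, or from \code{site_names} if given.
#'
#' @param path file path
#' @param site_names optional character vector overriding site ids, one per
#'   population block
#' @return \code{genotype_dataset}
#' @export
read_genepop <- function(path, site_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a GENEPOP file: too short")
  body <- lines[-1]                         # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop == 1) stop("no locus names before first Pop")
  locus_lines <- trimws(body[seq_len(first_pop - 1)])
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci); loci <- loci[nzchar(loci)]
  nl <- length(loci)

  rows <- body[-seq_len(first_pop - 1)]
  pop_id <- cumsum(toupper(trimws(rows)) == "POP")
  keep <- toupper(trimws(rows)) != "POP"
  geno_rows <- rows[keep]; pop_of_row <- pop_id[keep]
  if (length(geno_rows) == 0 || any(!seq_len(max(pop_id)) %in% pop_of_row))
    stop("empty population block in GENEPOP file")

  n <- length(geno_rows)
  arr <- array(NA_integer_, dim = c(n, nl, 2L))
  ids <- character(n)
  line_no_offset <- 1 + (first_pop - 1) + 1  # title + loci + position bookkeeping
  for (i in seq_len(n)) {
    parts <- strsplit(geno_rows[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed genotype line (no comma): '",
                                trimws(geno_rows[i]), "'")
    ids[i] <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != nl)
      stop("individual '", ids[i], "': expected ", nl, " genotypes, found ",
           length(gts))
    for (j in seq_len(nl)) {
      g <- gts[j]
      w <- nchar(g)
      if (!w %in% c(4L, 6L) || grepl("[^0-9]", g))
        stop("individual '", ids[i], "', locus ", loci[j],
             ": malformed genotype '", g, "'")
      half <- w / 2L
      a1 <- as.integer(substr(g, 1L, half))
      a2 <- as.integer(substr(g, half + 1L, w))
      if (xor(a1 == 0L, a2 == 0L))
        stop("individual '", ids[i], "', locus ", loci[j],
             ": half-called genotype '", g, "'")
      if (a1 != 0L) arr[i, j, ] <- c(a1, a2)
    }
  }

  npop <- max(pop_of_row)
  if (is.null(site_names)) {
    firsts <- ids[match(seq_len(npop), pop_of_row)]
    site_names <- make.unique(sub("_[0-9]+$", "", firsts))
  }
  if (length(site_names) != npop) stop("site_names length != number of Pop blocks")
  genotype_dataset(arr, loci,
                   data.frame(id = ids, site = site_names[pop_of_row]))
}

#' Write a GENEPOP file
#'
#' @param ds genotype_dataset
#' @param path output path
#' @param digits 2 or 3, allele coding width
#' @param title first line of the file
#' @export
write_genepop <- function(ds, path, digits = 3, title = "riverpopgen export") {
  stopifnot(digits %in% c(2, 3))
  if (any(ds$alleles >= 10^digits, na.rm = TRUE))
    stop("allele codes too large for ", digits, "-digit coding")
  fmt <- function(a) ifelse(is.na(a), strrep("0", digits),
                            formatC(a, width = digits, flag = "0"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (s in site_ids(ds)) {
    writeLines("Pop", con)
    for (i in site_index(ds, s)) {
      g <- paste0(fmt(ds$alleles[i, , 1]), fmt(ds$alleles[i, , 2]))
      writeLines(paste0(ds$ind$id[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Filter individuals by number of missing loci
#'
#' Retains individuals with at most \code{max_missing_loci} missing loci
#' (the study design keeps fish typed at nine of ten loci or better, i.e.
#' \code{max_missing_loci = 1}). Sites that lose all their individuals are
#' dropped with a warning.
#'
#' @param ds genotype_dataset
#' @param max_missing_loci maximum tolerated number of missing loci
#' @return filtered genotype_dataset
#' @export
filter_individuals <- function(ds, max_missing_loci = 1) {
  stopifnot(max_missing_loci >= 0)
  nmiss <- rowSums(is.na(ds$alleles[, , 1, drop = FALSE]))
  keep <- nmiss <= max_missing_loci
  lost_sites <- setdiff(site_ids(ds), unique(ds$ind$site[keep]))
  if (length(lost_sites))
    warning("sites dropped (no individuals left): ",
            paste(lost_sites, collapse = ", "))
  sites <- ds$sites[ds$sites$site_id %in% ds$ind$site[keep], , drop = FALSE]
  genotype_dataset(ds$alleles[keep, , , drop = FALSE], ds$loci,
                   ds$ind[keep, , drop = FALSE], sites)
}

#' Remove a locus from the dataset
#'
#' Used to exclude loci compromised by null alleles before any further
#' analysis.
#'
#' @param ds genotype_dataset
#' @param locus_name locus to drop
#' @return genotype_dataset without that locus
#' @export
drop_locus <- function(ds, locus_name) {
  j <- match(locus_name, ds$loci)
  if (is.na(j)) stop("unknown locus: ", locus_name)
  if (length(ds$loci) == 1L) stop("cannot drop the last locus")
  genotype_dataset(ds$alleles[, -j, , drop = FALSE], ds$loci[-j], ds$ind, ds$sites)
}

#' Subset a dataset to a set of sites
#' @param ds genotype_dataset
#' @param sites character vector of site ids to keep
#' @return genotype_dataset restricted to those sites
#' @export
subset_sites <- function(ds, sites) {
  if (!all(sites %in% site_ids(ds))) stop("unknown site(s)")
  keep <- ds$ind$site %in% sites
  genotype_dataset(ds$alleles[keep, , , drop = FALSE], ds$loci,
                   ds$ind[keep, , drop = FALSE],
                   ds$sites[ds$sites$site_id %in% sites, , drop = FALSE])
}
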