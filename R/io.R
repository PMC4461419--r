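#' Read a GenePop file
#'
#' Parses the classic GenePop text format for diploid codominant data:
#' a title line, one locus name per line (or a single comma-separated
#' line), then `POP` blocks of `id , 001002 003003 ...` records.  Both
#' 2-digit and 3-digit allele codes are accepted; an all-zero code marks
#' a missing genotype.
#'
#' @param path path to a GenePop file.
#' @return a list with `genotypes` (a [GenotypeMatrix-class]) and `pop`
#'   (character vector of population labels, one per individual, taken
#'   from the last individual id of each `POP` block as per GenePop
#'   convention, or `pop1`, `pop2`, ... when ids are uninformative).
#' @export
readGenepop <- function(path) {
  if (!file.exists(path)) stop("GenePop file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("not a GenePop file: ", path)
  body <- lines[-1]
  popIdx <- grep("^pop$", body, ignore.case = TRUE)
  if (!length(popIdx)) stop("no POP line found in ", path)
  locusLines <- body[seq_len(popIdx[1] - 1)]
  loci <- trimws(unlist(strsplit(locusLines, ",")))
  loci <- loci[nzchar(loci)]
  nLoci <- length(loci)

  ids <- character(); pops <- character()
  a1 <- list(); a2 <- list()
  popNo <- 0L
  for (ln in body[-seq_len(popIdx[1] - 1)]) {
    if (grepl("^pop$", ln, ignore.case = TRUE)) { popNo <- popNo + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("malformed genotype line: ", ln)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    if (length(codes) != nLoci)
      stop("individual ", id, " has ", length(codes), " genotypes, expected ",
           nLoci)
    digits <- nchar(codes[1]) / 2
    x1 <- as.integer(substr(codes, 1, digits))
    x2 <- as.integer(substr(codes, digits + 1, 2 * digits))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, paste0("pop", popNo))
    a1[[length(a1) + 1L]] <- x1; a2[[length(a2) + 1L]] <- x2
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  m1 <- do.call(rbind, a1); m2 <- do.call(rbind, a2)
  rownames(m1) <- ids; colnames(m1) <- loci
  list(genotypes = genotypeMatrix(m1, m2), pop = pops)
}

#' Write a GenePop file
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @param pop optional character vector of population labels; individuals
#'   are written in one `POP` block per label (in order of first
#'   appearance).  Default: a single block.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
writeGenepop <- function(g, path, pop = NULL, title = "cryptolin export") {
  stopifnot(methods::is(g, "GenotypeMatrix"))
  if (is.null(pop)) pop <- rep("pop1", nInd(g))
  stopifnot(length(pop) == nInd(g))
  code <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(lociNames(g), con)
  for (p in unique(pop)) {
    writeLines("POP", con)
    for (i in which(pop == p)) {
      codes <- paste0(code(g@allele1[i, ]), code(g@allele2[i, ]))
      writeLines(paste(individualNames(g)[i], ",",
                       paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA file into a HaplotypeSet
#'
#' Each record is one individual's sequence; identical sequences are
#' collapsed into haplotypes via [collapseHaplotypes()].
#'
#' @param path path to an aligned FASTA file.
#' @return a [HaplotypeSet-class].
#' @export
readHaplotypeFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  collapseHaplotypes(Biostrings::readDNAStringSet(path))
}

#' Write individual haplotype sequences to FASTA
#'
#' Writes one record per assigned individual (its haplotype's sequence),
#' so the file round-trips through [readHaplotypeFasta()].
#'
#' @param h a [HaplotypeSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeFasta <- function(h, path) {
  stopifnot(methods::is(h, "HaplotypeSet"))
  seqs <- haplotypeSequences(h)[haplotypeAssignment(h)]
  names(seqs) <- names(haplotypeAssignment(h))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a flowering-census CSV
#'
#' Expected layout: one row per individual with an `individual` column, a
#' `lineage` column and one column per census date (column name = ordinal
#' day, optionally prefixed with `d`).
#'
#' @param path path to the CSV.
#' @return a [FloweringSchedule-class].
#' @export
readScheduleCsv <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("individual", "lineage") %in% names(df)))
  dateCols <- setdiff(names(df), c("individual", "lineage"))
  dates <- as.numeric(sub("^d", "", dateCols))
  v <- as.matrix(df[, dateCols, drop = FALSE])
  rownames(v) <- df$individual
  floweringSchedule(v[, order(dates), drop = FALSE], sort(dates), df$lineage)
}

#' Write a flowering-census CSV
#' @param s a [FloweringSchedule-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScheduleCsv <- function(s, path) {
  v <- scheduleValues(s)
  df <- data.frame(individual = rownames(v),
                   lineage = as.character(lineageLabels(s)),
                   check.names = FALSE)
  dcols <- as.data.frame(v, check.names = FALSE)
  names(dcols) <- paste0("d", censusDates(s))
  utils::write.csv(cbind(df, dcols), path, row.names = FALSE)
  invisible(path)
}

#' Read a trait table CSV
#'
#' One row per individual; requires `individual` and `lineage` columns;
#' numeric trait columns, plus optional `herbivory_damaged`,
#' `herbivory_total` counts and `soil_moisture`.
#'
#' @param path path to the CSV.
#' @return a validated data.frame.
#' @export
readTraitCsv <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  validateTraitTable(df)
  df
}

#' Validate a trait table
#'
#' Checks the invariants of the per-individual trait table: damaged
#' capsule counts are non-negative and never exceed totals, and
#' proportions lie in \[0, 1\].
#'
#' @param df a data.frame with at least `individual` and `lineage`.
#' @return `df`, invisibly; stops on violation.
#' @export
validateTraitTable <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("individual", "lineage") %in% names(df)))
  if (all(c("herbivory_damaged", "herbivory_total") %in% names(df))) {
    if (any(df$herbivory_damaged < 0, na.rm = TRUE) ||
        any(df$herbivory_damaged > df$herbivory_total, na.rm = TRUE))
      stop("damaged capsule counts must satisfy 0 <= damaged <= total")
  }
  if ("soil_moisture" %in% names(df) &&
      any(df$soil_moisture < 0 | df$soil_moisture > 1, na.rm = TRUE))
    stop("soil moisture must be a proportion in [0, 1]")
  invisible(df)
}
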