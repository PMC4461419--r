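#' Construct a GenotypeMatrix
#'
#' @param allele1,allele2 integer matrices of allele labels (individuals
#'   in rows, loci in columns); `NA` in both marks a missing genotype.
#'   Row and column names identify individuals and loci; defaults are
#'   generated when absent.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' g <- genotypeMatrix(matrix(c(1L, 2L), 2, 1), matrix(c(1L, 3L), 2, 1))
#' nInd(g); nLoc(g)
#' @export
genotypeMatrix <- function(allele1, allele2) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  if (is.null(rownames(allele1)))
    rownames(allele1) <- paste0("ind", seq_len(nrow(allele1)))
  if (is.null(colnames(allele1)))
    colnames(allele1) <- paste0("loc", seq_len(ncol(allele1)))
  dimnames(allele2) <- dimnames(allele1)
  # unordered pairs: store with allele1 <= allele2 so identical genotypes
  # compare equal regardless of input order
  swap <- !is.na(allele1) & !is.na(allele2) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  methods::new("GenotypeMatrix", allele1 = allele1, allele2 = allele2)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nInd", "GenotypeMatrix", function(x) nrow(x@allele1))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nLoc", "GenotypeMatrix", function(x) ncol(x@allele1))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("individualNames", "GenotypeMatrix",
          function(x) rownames(x@allele1))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("lociNames", "GenotypeMatrix", function(x) colnames(x@allele1))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("alleleCalls", "GenotypeMatrix", function(x, locus) {
  cbind(a1 = x@allele1[, locus], a2 = x@allele2[, locus])
})

#' @rdname GenotypeMatrix-class
#' @param i individual index, name or logical vector.
#' @param j locus index, name or logical vector.
#' @param ... ignored.
#' @param drop ignored; subsetting always returns a `GenotypeMatrix`.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoc(x))
  genotypeMatrix(x@allele1[i, j, drop = FALSE],
                 x@allele2[i, j, drop = FALSE])
})

#' Combine GenotypeMatrix objects by row
#' @param x,... `GenotypeMatrix` objects with identical loci.
#' @export
setMethod("rbind2", signature("GenotypeMatrix", "GenotypeMatrix"),
          function(x, y) {
  stopifnot(identical(lociNames(x), lociNames(y)))
  genotypeMatrix(rbind(x@allele1, y@allele1), rbind(x@allele2, y@allele2))
})

setMethod("show", "GenotypeMatrix", function(object) {
  miss <- mean(is.na(object@allele1))
  cat("GenotypeMatrix with", nInd(object), "individuals x",
      nLoc(object), "loci\n")
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
})

# ---- HaplotypeSet ----------------------------------------------------------

#' Construct a HaplotypeSet
#'
#' @param sequences a named `DNAStringSet` of unique aligned haplotype
#'   sequences (equal width).
#' @param assignment named character vector, individual id -> haplotype id.
#' @return a [HaplotypeSet-class] object.
#' @export
haplotypeSet <- function(sequences, assignment = character()) {
  methods::new("HaplotypeSet", sequences = sequences,
               assignment = assignment)
}

#' @rdname HaplotypeSet-class
#' @export
setMethod("haplotypeFrequencies", "HaplotypeSet", function(x) {
  counts <- table(factor(x@assignment, levels = names(x@sequences)))
  stats::setNames(as.integer(counts), names(x@sequences))
})

#' @rdname HaplotypeSet-class
#' @export
setMethod("haplotypeAssignment", "HaplotypeSet", function(x) x@assignment)

#' @rdname HaplotypeSet-class
#' @export
setMethod("haplotypeSequences", "HaplotypeSet", function(x) x@sequences)

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet with", length(object@sequences), "haplotypes,",
      length(object@assignment), "assigned individuals\n")
  if (length(object@sequences))
    cat("  aligned width:", Biostrings::width(object@sequences)[1], "\n")
})

# ---- FloweringSchedule -----------------------------------------------------

#' Construct a FloweringSchedule
#'
#' @param values numeric matrix of proportions of flowering stems,
#'   individuals in rows, censuses in columns.
#' @param dates numeric vector of strictly increasing census dates
#'   (ordinal days).
#' @param lineage character vector of lineage labels, one per individual.
#' @return a [FloweringSchedule-class] object.
#' @export
floweringSchedule <- function(values, dates, lineage) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("ind", seq_len(nrow(values)))
  colnames(values) <- as.character(dates)
  methods::new("FloweringSchedule", values = values,
               dates = as.numeric(dates), lineage = as.character(lineage))
}

#' @rdname FloweringSchedule-class
#' @export
setMethod("scheduleValues", "FloweringSchedule", function(x) x@values)

#' @rdname FloweringSchedule-class
#' @export
setMethod("censusDates", "FloweringSchedule", function(x) x@dates)

#' @rdname FloweringSchedule-class
#' @export
setMethod("lineageLabels", "FloweringSchedule",
          function(x) stats::setNames(x@lineage, rownames(x@values)))

setMethod("show", "FloweringSchedule", function(object) {
  cat("FloweringSchedule:", nrow(object@values), "individuals,",
      length(object@dates), "censuses (days",
      min(object@dates), "-", max(object@dates), ")\n")
  print(table(object@lineage))
})

# ---- ClusterResult / HybridPosterior --------------------------------------

#' @rdname ClusterResult-class
#' @export
setMethod("posteriorMatrix", "ClusterResult", function(x) x@posterior)

#' @rdname ClusterResult-class
#' @export
setMethod("coassignmentMatrix", "ClusterResult",
          function(x) x@coassignment)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: K =", object@K, "\n")
  cat(sprintf("  mean log-likelihood: %.2f\n", object@meanLogLik))
  hard <- apply(object@posterior, 1, which.max)
  cat("  modal cluster sizes:",
      paste(tabulate(hard, object@K), collapse = " "), "\n")
})

#' @rdname HybridPosterior-class
#' @export
setMethod("posteriorMatrix", "HybridPosterior", function(x) x@posterior)

setMethod("show", "HybridPosterior", function(object) {
  cat("HybridPosterior over classes",
      paste(colnames(object@posterior), collapse = ", "), "\n")
  cat("  individuals:", nrow(object@posterior), "\n")
})

# ---- ParsimonyNetwork ------------------------------------------------------

#' @rdname ParsimonyNetwork-class
#' @export
setMethod("networkNodes", "ParsimonyNetwork", function(x) x@nodes)

#' @rdname ParsimonyNetwork-class
#' @export
setMethod("networkEdges", "ParsimonyNetwork", function(x) x@edges)

#' @rdname ParsimonyNetwork-class
#' @export
setMethod("networkLinks", "ParsimonyNetwork", function(x) x@links)

#' @rdname ParsimonyNetwork-class
#' @export
setMethod("networkComponents", "ParsimonyNetwork",
          function(x) x@components)

setMethod("show", "ParsimonyNetwork", function(object) {
  cat("ParsimonyNetwork: limit", object@limit, "steps\n")
  cat("  observed haplotypes:", sum(!object@nodes$inferred),
      " inferred intermediates:", sum(object@nodes$inferred), "\n")
  cat("  components:", length(unique(object@components)), "\n")
})
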