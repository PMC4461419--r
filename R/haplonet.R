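# Haplotype collapsing and fixed-limit statistical parsimony networks.
#
# The connection limit is a parameter (default 7 steps); the full
# probability-of-parsimony limit calculation is deliberately not part of
# this module.

#' Collapse aligned sequences into haplotypes
#'
#' Identical aligned sequences are collapsed into one haplotype.
#' Haplotypes are numbered `h1`, `h2`, ... by decreasing frequency,
#' breaking ties by first occurrence in the input.
#'
#' @param alignment a named `DNAStringSet` of equal-width aligned
#'   sequences, one per individual.
#' @return a [HaplotypeSet-class].
#' @export
collapseHaplotypes <- function(alignment) {
  if (length(alignment) == 0) stop("empty alignment")
  if (length(unique(Biostrings::width(alignment))) > 1)
    stop("aligned sequences must all have the same length")
  if (is.null(names(alignment)))
    names(alignment) <- paste0("ind", seq_along(alignment))
  seqs <- as.character(alignment)
  uniq <- unique(seqs)
  freq <- as.integer(table(factor(seqs, levels = uniq)))
  ord <- order(-freq, seq_along(uniq))
  uniq <- uniq[ord]
  ids <- paste0("h", seq_along(uniq))
  hapSeqs <- Biostrings::DNAStringSet(uniq)
  names(hapSeqs) <- ids
  assignment <- stats::setNames(ids[match(seqs, uniq)], names(alignment))
  haplotypeSet(hapSeqs, assignment)
}

#' Pairwise mutational step distances between haplotypes
#'
#' Hamming distances between aligned haplotype sequences under one of
#' three alignment-gap treatments:
#' * `indel_block_as_one` (default): a maximal run of columns gapped in
#'   exactly one of the two sequences counts as a single step; remaining
#'   columns are compared site by site.
#' * `fifth_state`: a gap is an ordinary fifth character state.
#' * `ignore`: columns gapped in either sequence are excluded.
#' Columns gapped in both sequences never contribute.
#'
#' @param h a [HaplotypeSet-class].
#' @param gapMode gap treatment, see above.
#' @return symmetric integer matrix of step counts.
#' @export
pairwiseSteps <- function(h,
    gapMode = c("indel_block_as_one", "fifth_state", "ignore")) {
  gapMode <- match.arg(gapMode)
  stopifnot(methods::is(h, "HaplotypeSet"))
  seqs <- as.character(haplotypeSequences(h))
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  nh <- length(chars)
  D <- matrix(0L, nh, nh, dimnames = list(names(seqs), names(seqs)))
  if (nh < 2) return(D)
  for (i in seq_len(nh - 1)) for (j in seq(i + 1, nh)) {
    x <- chars[[i]]; y <- chars[[j]]
    gx <- x == "-"; gy <- y == "-"
    both <- gx & gy
    d <- switch(gapMode,
      fifth_state = sum(x != y & !both),
      ignore = sum(x != y & !(gx | gy)),
      indel_block_as_one = {
        onegap <- xor(gx, gy) & !both
        runs <- rle(onegap)
        sum(x != y & !(gx | gy)) + sum(runs$values)
      })
    D[i, j] <- D[j, i] <- as.integer(d)
  }
  D
}

# disjoint-set union
.dsuFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build a fixed-limit statistical parsimony network
#'
#' Connects haplotypes by minimum mutational steps, Kruskal-style:
#' candidate pairs are taken in order of increasing step distance,
#' breaking ties by higher summed haplotype frequency and then by
#' lexicographic id pair, and a connection is made whenever it joins two
#' components that were still separate at the start of its distance
#' class.  Alternative connections of exactly the same length between
#' the same pair of components are therefore retained and flagged as
#' `loop` edges.  Pairs farther apart than `limit` steps are never
#' joined, so the result can be a forest.  Connections longer than one
#' step are expanded through inferred intermediate nodes of frequency 0.
#'
#' @param h a [HaplotypeSet-class].
#' @param limit connection limit in steps (default 7).
#' @param gapMode passed to [pairwiseSteps()].
#' @return a [ParsimonyNetwork-class].
#' @export
buildParsimonyNetwork <- function(h, limit = 7,
    gapMode = c("indel_block_as_one", "fifth_state", "ignore")) {
  stopifnot(methods::is(h, "HaplotypeSet"), limit >= 1)
  if (length(haplotypeSequences(h)) == 0) stop("empty haplotype set")
  D <- pairwiseSteps(h, match.arg(gapMode))
  ids <- rownames(D)
  nh <- length(ids)
  freq <- haplotypeFrequencies(h)

  cand <- which(upper.tri(D) & D <= limit & D > 0, arr.ind = TRUE)
  links <- data.frame(from = character(), to = character(),
                      steps = integer(), loop = logical(),
                      stringsAsFactors = FALSE)
  parent <- seq_len(nh)
  if (nrow(cand)) {
    cd <- data.frame(i = cand[, 1], j = cand[, 2],
                     steps = D[cand],
                     sumFreq = freq[ids[cand[, 1]]] + freq[ids[cand[, 2]]])
    ord <- order(cd$steps, -cd$sumFreq, ids[cd$i], ids[cd$j])
    cd <- cd[ord, ]
    for (d in sort(unique(cd$steps))) {
      snapshot <- vapply(seq_len(nh), function(i) .dsuFind(parent, i), 0L)
      for (r in which(cd$steps == d)) {
        i <- cd$i[r]; j <- cd$j[r]
        if (snapshot[i] == snapshot[j]) next
        ri <- .dsuFind(parent, i); rj <- .dsuFind(parent, j)
        isLoop <- ri == rj
        if (!isLoop) parent[ri] <- rj
        links <- rbind(links, data.frame(
          from = ids[i], to = ids[j], steps = d, loop = isLoop,
          stringsAsFactors = FALSE))
      }
    }
  }

  # expand multi-step links through inferred intermediates
  nodes <- data.frame(id = ids, frequency = as.integer(freq[ids]),
                      inferred = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  if (nrow(links)) for (r in seq_len(nrow(links))) {
    s <- links$steps[r]
    chain <- links$from[r]
    if (s > 1) {
      mids <- paste0(links$from[r], ".", links$to[r], ".i", seq_len(s - 1))
      nodes <- rbind(nodes, data.frame(id = mids, frequency = 0L,
                                       inferred = TRUE,
                                       stringsAsFactors = FALSE))
      chain <- c(chain, mids)
    }
    chain <- c(chain, links$to[r])
    edges <- rbind(edges, data.frame(from = chain[-length(chain)],
                                     to = chain[-1],
                                     stringsAsFactors = FALSE))
  }
  comp <- vapply(seq_len(nh), function(i) .dsuFind(parent, i), 0L)
  comp <- stats::setNames(as.integer(factor(comp, levels = unique(comp))),
                          ids)
  methods::new("ParsimonyNetwork", nodes = nodes, edges = edges,
               links = links, components = comp,
               limit = as.integer(limit))
}

#' Write network edges as CSV
#' @param net a [ParsimonyNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkCsv <- function(net, path) {
  utils::write.csv(networkLinks(net), path, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Minimal GraphML export (node frequency and inferred flag as
#' attributes) of the expanded single-step network.
#'
#' @param net a [ParsimonyNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkGraphml <- function(net, path) {
  nodes <- networkNodes(net); edges <- networkEdges(net)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="freq" for="node" attr.name="frequency" attr.type="int"/>',
    '  <key id="inf" for="node" attr.name="inferred" attr.type="boolean"/>',
    '  <graph edgedefault="undirected">'), con)
  for (r in seq_len(nrow(nodes)))
    writeLines(sprintf(
      '    <node id="%s"><data key="freq">%d</data><data key="inf">%s</data></node>',
      nodes$id[r], nodes$frequency[r],
      tolower(as.character(nodes$inferred[r]))), con)
  for (r in seq_len(nrow(edges)))
    writeLines(sprintf('    <edge source="%s" target="%s"/>',
                       edges$from[r], edges$to[r]), con)
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}
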