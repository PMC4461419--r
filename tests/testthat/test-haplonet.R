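library(Biostrings)

dss <- function(x) DNAStringSet(unlist(x))

test_that("identical sequences collapse into frequency-ordered haplotypes", {
  aln <- dss(list(i1 = "ACGT", i2 = "ACGT", i3 = "AGGT"))
  h <- collapseHaplotypes(aln)
  expect_equal(length(haplotypeSequences(h)), 2)
  expect_equal(haplotypeFrequencies(h), c(h1 = 2L, h2 = 1L))
  expect_equal(unname(haplotypeAssignment(h)[c("i1", "i3")]),
               c("h1", "h2"))

  # all-distinct input: n haplotypes of frequency 1
  aln <- dss(list(a = "AAAA", b = "AAAC", c = "AACC"))
  expect_equal(unname(haplotypeFrequencies(collapseHaplotypes(aln))),
               c(1L, 1L, 1L))
  expect_error(collapseHaplotypes(dss(list("AC", "ACG"))), "same length")
})

test_that("step distances respect the gap handling mode", {
  h <- haplotypeSet(dss(list(h1 = "ACGT", h2 = "ACGA")))
  expect_equal(pairwiseSteps(h)[1, 2], 1L)
  expect_equal(pairwiseSteps(h)[1, 1], 0L)

  h <- haplotypeSet(dss(list(h1 = "AC--T", h2 = "ACGGT")))
  expect_equal(pairwiseSteps(h, "indel_block_as_one")[1, 2], 1L)
  expect_equal(pairwiseSteps(h, "fifth_state")[1, 2], 2L)
  expect_equal(pairwiseSteps(h, "ignore")[1, 2], 0L)
  expect_error(pairwiseSteps(h, "banana"))
})

test_that("small parsimony networks have the expected shape", {
  # 2 haplotypes 2 steps apart, limit 7: one component, 1 intermediate
  seqs <- makeHapSeqs(c(h2 = 2))
  h <- haplotypeSet(dss(list(h1 = seqs$ref, h2 = seqs$h2)),
                    c(i1 = "h1", i2 = "h2"))
  net <- buildParsimonyNetwork(h, limit = 7)
  expect_equal(length(unique(networkComponents(net))), 1)
  expect_equal(sum(networkNodes(net)$inferred), 1)
  expect_equal(nrow(networkEdges(net)), 2)

  # 8 steps apart at limit 7: two components, no edges
  seqs <- makeHapSeqs(c(h2 = 8))
  h <- haplotypeSet(dss(list(h1 = seqs$ref, h2 = seqs$h2)),
                    c(i1 = "h1", i2 = "h2"))
  net <- buildParsimonyNetwork(h, limit = 7)
  expect_equal(length(unique(networkComponents(net))), 2)
  expect_equal(nrow(networkLinks(net)), 0)

  expect_error(buildParsimonyNetwork(
    haplotypeSet(DNAStringSet()), limit = 7), "empty")
})

test_that("a planted star topology is recovered exactly", {
  # central haplotype with satellites 1-2 steps away, distinct positions
  len <- 30
  ref <- rep("A", len)
  mk <- function(pos) {
    s <- ref; s[pos] <- "G"; paste(s, collapse = "")
  }
  aln <- dss(list(c1 = paste(ref, collapse = ""),
                  c2 = paste(ref, collapse = ""),
                  c3 = paste(ref, collapse = ""),  # center, frequency 3
                  s1 = mk(1), s2 = mk(2:3), s3 = mk(4), s4 = mk(5:6)))
  h <- collapseHaplotypes(aln)
  net <- buildParsimonyNetwork(h, limit = 7)
  links <- networkLinks(net)
  expect_equal(length(unique(networkComponents(net))), 1)
  # every link connects the center (h1, most frequent) to a satellite
  expect_true(all(links$from == "h1" | links$to == "h1"))
  expect_equal(sort(links$steps), c(1L, 1L, 2L, 2L))
  expect_false(any(links$loop))
})

test_that("network spanning weight matches a brute-force minimum", {
  set.seed(61)
  for (rep in 1:5) {
    nh <- sample(4:6, 1)
    # random binary sequences of length 12 over fresh positions
    len <- 12
    mat <- matrix(sample(c("A", "C"), nh * len, TRUE), nh, len)
    seqs <- apply(mat, 1, paste, collapse = "")
    if (anyDuplicated(seqs)) next
    names(seqs) <- paste0("x", seq_len(nh))
    h <- collapseHaplotypes(dss(as.list(seqs)))
    D <- pairwiseSteps(h)
    net <- buildParsimonyNetwork(h, limit = max(D))
    links <- networkLinks(net)
    treeWeight <- sum(links$steps[!links$loop])
    expect_equal(treeWeight, bruteMstWeight(D))
  }
})

test_that("the network is invariant to input sequence order", {
  set.seed(62)
  len <- 20
  mat <- matrix(sample(c("A", "C", "G"), 6 * len, TRUE), 6, len)
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("i", 1:6)
  h1 <- collapseHaplotypes(dss(as.list(seqs)))
  h2 <- collapseHaplotypes(dss(as.list(seqs[sample(6)])))
  n1 <- buildParsimonyNetwork(h1, limit = 20)
  n2 <- buildParsimonyNetwork(h2, limit = 20)
  canon <- function(net, h) {
    l <- networkLinks(net)
    seqOf <- as.character(haplotypeSequences(h))
    key <- apply(cbind(seqOf[l$from], seqOf[l$to]), 1,
                 function(r) paste(sort(r), collapse = "|"))
    sort(paste(key, l$steps))
  }
  expect_equal(canon(n1, h1), canon(n2, h2))
})

test_that("FASTA round-trips through the haplotype reader", {
  seqs <- makeHapSeqs(c(h2 = 2, h3 = 4))
  h <- haplotypeSet(dss(list(h1 = seqs$ref, h2 = seqs$h2, h3 = seqs$h3)),
                    c(i1 = "h1", i2 = "h2", i3 = "h2", i4 = "h3"))
  path <- tempfile(fileext = ".fa")
  writeHaplotypeFasta(h, path)
  back <- readHaplotypeFasta(path)
  expect_equal(sort(unname(haplotypeFrequencies(back))),
               sort(unname(haplotypeFrequencies(h))))
  expect_setequal(unname(as.character(haplotypeSequences(back))),
                  unname(as.character(haplotypeSequences(h))))
})
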