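test_that("the flat-cluster cap scales with chain length", {
  set.seed(11)
  p <- randomSymPae(300)
  cl <- clusterResidues(p)          # maxclust = round(0.1 * 300) = 30
  expect_lte(max(cl@index), 30L)
  expect_equal(max(cl@index), 30L)  # no ties: the cut yields exactly 30
  expect_error(clusterResidues(randomSymPae(1)), "protein too short")
})

test_that("zero-distance blocks co-cluster under single linkage", {
  # two 30-residue groups with identical profiles within a group; the cap
  # allows 6 clusters but the smallest qualifying cut height keeps each
  # block whole
  L <- 60
  g <- rep(1:2, each = 30)
  m <- outer(g, g, function(a, b) ifelse(a == b, 0, 25))
  p <- PaeMatrix(m, symmetrized = TRUE)
  cl <- clusterResidues(p, SpaedParams(maxClusterFraction = 0.1))
  expect_equal(max(cl@index), 2L)
  expect_equal(cl@index, g)
})

test_that("flat clusters match the brute-force single-linkage oracle", {
  set.seed(202)
  for (i in 1:25) {
    L <- sample(5:12, 1)
    k <- sample(2:4, 1)
    p <- randomSymPae(L)
    got <- clusterResidues(p, SpaedParams(maxClusterFraction = k / L))
    want <- oracleSingleLinkage(paeValues(p), k)
    expect_identical(canonicalLabels(got@index), canonicalLabels(want))
  }
})

test_that("clusters strictly larger than the threshold become domains", {
  # sizes {180, 140, 3, 2, 1...} -> 2 domains, 12 non-domain residues
  idx <- rep(seq_len(11), c(180, 140, 3, 2, rep(1, 7)))
  labels <- spaedr:::ResidueLabels(rep("cluster", length(idx)), idx)
  out <- assignDomains(labels)
  expect_equal(sum(out@tag == "domain" & out@index == 1), 180)
  expect_equal(sum(out@tag == "domain" & out@index == 2), 140)
  expect_equal(sum(out@tag == "non_domain"), 12)

  # boundary: a 26-residue cluster is a domain, a 25-residue one is not
  idx <- rep(1:2, c(26, 25))
  out <- assignDomains(spaedr:::ResidueLabels(rep("cluster", 51), idx))
  expect_equal(labelRuns(out), "D1:26 non_domain:25")

  # all singletons -> everything non-domain
  out <- assignDomains(spaedr:::ResidueLabels(rep("cluster", 30), 1:30))
  expect_true(all(out@tag == "non_domain"))
})

test_that("domain numbering follows sequence position, not cluster index", {
  idx <- rep(c(5, 1), c(40, 40))   # first-seen cluster has the higher id
  out <- assignDomains(spaedr:::ResidueLabels(rep("cluster", 80), idx))
  expect_equal(labelRuns(out), "D1:40 D2:40")
})

test_that("isDisordered follows the poorly-connected-fraction rule", {
  # pure near-diagonal band: every residue has <= 4 low-PAE neighbours
  expect_true(isDisordered(c(1, 30), bandPae(30)))
  # fully compact region: 29 low-PAE neighbours each
  allLow <- PaeMatrix(matrix(2, 30, 30) - diag(2, 30), symmetrized = TRUE)
  expect_false(isDisordered(c(1, 30), allLow))
  expect_error(isDisordered(c(5, 4), bandPae(30)), "empty region")
})

test_that("the disordered fraction is a strict inequality", {
  # contact graph over 30 residues: hubs 1..6 form a clique plus one pendant
  # edge each, so exactly 6 residues have 6 low-PAE neighbours and the other
  # 24 have at most one; 24/30 = 0.8 is not > 0.8
  hubs <- utils::combn(6, 2, simplify = FALSE)
  pendants <- lapply(1:6, function(i) c(i, 6 + i))
  p <- contactGraphPae(30, c(hubs, pendants))
  expect_false(isDisordered(c(1, 30), p))
  # removing one pendant edge leaves hub 6 with 5 neighbours: 25/30 > 0.8
  p2 <- contactGraphPae(30, c(hubs, pendants[1:5]))
  expect_true(isDisordered(c(1, 30), p2))
})

test_that("short terminal runs are absorbed into the nearest domain", {
  sym <- bandPae(62)   # content is irrelevant below the length cut-off
  labels <- labelsFromRuns(list(c("N", 12), c("D", 50)))
  out <- correctEnds(labels, sym)
  expect_equal(labelRuns(out), "D1:62")
})

test_that("long terminal runs are kept only when truly disordered", {
  # 35-residue near-diagonal band at the N-terminus -> disordered
  L <- 95
  m <- matrix(2, L, L)
  m[1:35, ] <- 20; m[, 1:35] <- 20
  band <- abs(outer(1:L, 1:L, "-")) <= 2
  m[band] <- 2
  diag(m) <- 0
  sym <- PaeMatrix(m, symmetrized = TRUE)
  labels <- labelsFromRuns(list(c("N", 35), c("D", 60)))
  out <- correctEnds(labels, sym)
  expect_equal(labelRuns(out), "disordered:35 D1:60")

  # same geometry but fully compact -> concatenated to the domain
  allLow <- PaeMatrix(matrix(2, L, L) - diag(2, L), symmetrized = TRUE)
  out <- correctEnds(labels, allLow)
  expect_equal(labelRuns(out), "D1:95")
})

test_that("both termini are corrected independently", {
  L <- 100
  allLow <- PaeMatrix(matrix(2, L, L) - diag(2, L), symmetrized = TRUE)
  labels <- labelsFromRuns(list(c("N", 10), c("D", 75), c("N", 15)))
  out <- correctEnds(labels, allLow)
  expect_equal(labelRuns(out), "D1:100")
})

test_that("interior gaps inside a domain are absorbed", {
  # D1 D1 D1 X X D1 D1 -> all seven residues D1
  labels <- spaedr:::ResidueLabels(
    rep(c("domain", "non_domain", "domain"), c(3, 2, 2)),
    c(1L, 1L, 1L, NA, NA, 1L, 1L))
  expect_equal(labelRuns(correctArtifacts(labels)), "D1:7")
})

test_that("a foreign domain run inside another domain's span is relabelled", {
  labels <- spaedr:::ResidueLabels(
    rep("domain", 5), c(1L, 1L, 2L, 1L, 1L))
  out <- correctArtifacts(labels)
  expect_equal(labelRuns(out), "D1:5")

  # the absorbed run may be large: a whole domain strictly inside another
  # domain's span is still a single sandwiched run
  idx <- c(rep(1L, 10), rep(2L, 40), rep(1L, 30))
  out <- correctArtifacts(spaedr:::ResidueLabels(rep("domain", 80), idx))
  expect_equal(labelRuns(out), "D1:80")
})

test_that("a split domain keeps its longest run, N-terminal-most on ties", {
  labels <- labelsFromRuns(list(c("D", 10), c("D", 40), c("D", 25)))
  # runs D1:10, D2:40, D3:25 -- contiguous already, untouched
  expect_equal(labelRuns(correctArtifacts(labels)), "D1:10 D2:40 D3:25")

  # D1 split around D2 with non-domain padding (so no single-run sandwich):
  # the 30-residue D1 run wins, the 10-residue run reverts to non_domain
  tag <- rep(c("domain", "non_domain", "domain", "non_domain", "domain"),
             c(10, 5, 40, 5, 30))
  idx <- c(rep(1L, 10), rep(NA, 5), rep(2L, 40), rep(NA, 5), rep(1L, 30))
  out <- correctArtifacts(spaedr:::ResidueLabels(tag, idx))
  expect_equal(labelRuns(out), "non_domain:15 D1:40 non_domain:5 D2:30")

  # equal-length split: the N-terminal run survives
  tag <- rep(c("domain", "non_domain", "domain", "non_domain", "domain"),
             c(20, 5, 40, 5, 20))
  idx <- c(rep(1L, 20), rep(NA, 5), rep(2L, 40), rep(NA, 5), rep(1L, 20))
  out <- correctArtifacts(spaedr:::ResidueLabels(tag, idx))
  expect_equal(labelRuns(out), "D1:20 non_domain:5 D2:40 non_domain:25")
})

test_that("already-contiguous labels are a fixed point of artifact repair", {
  labels <- labelsFromRuns(
    list(c("X", 20), c("D", 40), c("N", 8), c("D", 60)))
  expect_identical(correctArtifacts(labels), labels)
})

test_that("linker boundaries move by chain-wide low-PAE support", {
  # domains 1-100 and 111-200; candidate linker 101-110; residues 101-102
  # are in contact with ~150 residues, 103-110 with only 4 each
  L <- 200
  m <- matrix(20, L, L)
  m[1:100, 1:100] <- 2
  m[111:200, 111:200] <- 2
  for (r in 101:102) { m[r, 1:150] <- 2; m[1:150, r] <- 2 }
  for (r in 103:110) {
    nb <- c(r - 2, r - 1, r + 1, r + 2)
    m[r, nb] <- 2; m[nb, r] <- 2
  }
  diag(m) <- 0
  sym <- PaeMatrix(m, symmetrized = TRUE)
  labels <- labelsFromRuns(list(c("D", 100), c("N", 10), c("D", 90)))
  out <- adjustLinkers(labels, sym)
  expect_equal(labelRuns(out), "D1:102 linker:8 D2:90")

  # support everywhere -> the linker vanishes and the domains abut
  allLow <- PaeMatrix(matrix(2, L, L) - diag(2, L), symmetrized = TRUE)
  out <- adjustLinkers(labels, allLow)
  expect_equal(sum(out@tag == "linker"), 0L)
  expect_equal(sum(out@tag == "domain"), 200L)

  # no support anywhere -> untouched
  band <- bandPae(L, width = 1)
  out <- adjustLinkers(labels, band)
  expect_equal(labelRuns(out), "D1:100 linker:10 D2:90")
})

test_that("a clean two-domain chain is recovered within two residues", {
  arch <- Architecture(c("domain", "linker", "domain"), c(150, 8, 120),
                       seed = 7)
  sim <- generatePae(arch)
  seg <- spaedSegment(sim$pae)
  tab <- regionTable(seg)
  expect_equal(nDomains(seg), 2L)
  expect_equal(sum(tab$kind == "linker"), 1L)
  d <- tab[tab$kind == "domain", ]
  expect_lte(abs(d$end[1] - 150), 2)
  expect_lte(abs(d$start[2] - 159), 2)
})

test_that("a disordered N-terminus is reported as such", {
  arch <- Architecture(c("disordered_n", "domain"), c(40, 200), seed = 3)
  sim <- generatePae(arch)
  expect_true(isDisordered(c(1, 40), symmetrize(sim$pae)))
  seg <- spaedSegment(sim$pae)
  tab <- regionTable(seg)
  expect_equal(tab$kind, c("disordered", "domain"))
  expect_lte(abs(tab$end[1] - 40), 2)
})

test_that("degenerate inputs resolve by policy instead of failing", {
  # all-low 30-residue chain: one domain spanning everything
  set.seed(5)
  m <- matrix(runif(900, 0.5, 4), 30)
  m <- (m + t(m)) / 2; diag(m) <- 0
  seg <- spaedSegment(PaeMatrix(m, "low30", symmetrized = TRUE))
  expect_equal(regionTable(seg),
               data.frame(start = 1L, end = 30L, kind = "domain"))

  # 60-residue pure band: no cluster can seed a domain; single-region output
  seg <- spaedSegment(bandPae(60))
  tab <- regionTable(seg)
  expect_equal(nrow(tab), 1L)
  expect_equal(c(tab$start, tab$end), c(1L, 60L))
})

test_that("segmentation always tiles the chain and is deterministic", {
  for (s in c(21, 22, 23, 24, 25)) {
    sim <- generatePae(randomArchitecture(s))
    seg1 <- spaedSegment(sim$pae)
    seg2 <- spaedSegment(sim$pae)
    expect_identical(regionTable(seg1), regionTable(seg2))
    tab <- regionTable(seg1)
    expect_equal(tab$start[1], 1L)
    expect_equal(tab$end[nrow(tab)], length(sim$pae))
    if (nrow(tab) > 1)
      expect_true(all(tab$start[-1] == tab$end[-nrow(tab)] + 1L))
    # the kind vocabulary and linker/disordered placement invariants
    expect_true(all(tab$kind %in% c("domain", "linker", "disordered")))
    lk <- which(tab$kind == "linker")
    expect_false(any(diff(lk) == 1))
    dis <- which(tab$kind == "disordered")
    expect_true(all(dis %in% c(1L, nrow(tab))))
  }
})

test_that("relabeling preliminary clusters does not change the result", {
  sim <- generatePae(randomArchitecture(31))
  sym <- symmetrize(sim$pae)
  params <- SpaedParams()
  finish <- function(labels) {
    labels <- assignDomains(labels, params)
    labels <- correctEnds(labels, sym, params)
    labels <- correctArtifacts(labels)
    L <- length(labels)
    if (labels@tag[1] == "non_domain" || labels@tag[L] == "non_domain")
      labels <- correctEnds(labels, sym, params)
    adjustLinkers(labels, sym, params)
  }
  cl <- clusterResidues(sym, params)
  set.seed(99)
  perm <- sample(max(cl@index))
  shuffled <- spaedr:::ResidueLabels(cl@tag, perm[cl@index])
  expect_identical(finish(cl), finish(shuffled))
})

test_that("raising the domain-size threshold never adds domains", {
  for (s in c(41, 42, 43, 44, 45, 46)) {
    sim <- generatePae(randomArchitecture(s))
    counts <- vapply(c(25, 35, 50, 80), function(th)
      nDomains(spaedSegment(sim$pae, SpaedParams(minDomainCluster = th))),
      integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("predicted domain counts stay in the lysin range on clean input", {
  for (s in 61:70) {
    sim <- generatePae(randomArchitecture(s))
    expect_true(nDomains(spaedSegment(sim$pae)) %in% 1:4)
  }
})
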