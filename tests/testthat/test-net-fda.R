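makeConstTable <- function(vecs, nFrames = 2) {
  # vecs: data.frame(resid_i, resid_j, Fx, Fy, Fz [, chain_i, chain_j])
  if (is.null(vecs$chain_i)) vecs$chain_i <- "A"
  if (is.null(vecs$chain_j)) vecs$chain_j <- "A"
  rows <- do.call(rbind, lapply(seq_len(nFrames), function(f) {
    data.frame(chain_i = vecs$chain_i, resid_i = vecs$resid_i,
               chain_j = vecs$chain_j, resid_j = vecs$resid_j,
               class = "coulomb", frame = f, time = f,
               Fx = vecs$Fx, Fy = vecs$Fy, Fz = vecs$Fz,
               stringsAsFactors = FALSE)
  }))
  pairForceTable(rows, nFrames)
}

test_that("time averaging is the arithmetic mean with omitted-zero frames", {
  const <- makeConstTable(data.frame(resid_i = 1, resid_j = 2,
                                     Fx = 1, Fy = -2, Fz = 0.5), nFrames = 4)
  m <- timeAverage(const)
  expect_equal(unlist(forceEntries(m)[c("Fx", "Fy", "Fz")]),
               c(Fx = 1, Fy = -2, Fz = 0.5))
  # +v then -v averages to zero
  rows <- rbind(
    data.frame(chain_i = "A", resid_i = 1, chain_j = "A", resid_j = 2,
               class = "lj", frame = 1, time = 1, Fx = 3, Fy = 1, Fz = -1),
    data.frame(chain_i = "A", resid_i = 1, chain_j = "A", resid_j = 2,
               class = "lj", frame = 2, time = 2, Fx = -3, Fy = -1, Fz = 1))
  m2 <- timeAverage(pairForceTable(rows, 2))
  expect_equal(abs(forceEntries(m2)$Fx), 0)
  # seeded noisy series: mean within sampling bound 4 sd / sqrt(n)
  set.seed(11)
  n <- 100
  mu <- c(2, -1, 0.5)
  rows <- do.call(rbind, lapply(1:n, function(f) data.frame(
    chain_i = "A", resid_i = 1, chain_j = "A", resid_j = 2,
    class = "coulomb", frame = f, time = f,
    Fx = mu[1] + rnorm(1), Fy = mu[2] + rnorm(1), Fz = mu[3] + rnorm(1))))
  m3 <- forceEntries(timeAverage(pairForceTable(rows, n)))
  expect_lt(max(abs(c(m3$Fx, m3$Fy, m3$Fz) - mu)), 4 / sqrt(n))
  expect_error(timeAverage(const, window = integer(0)), "empty")
})

test_that("netFDA: identity, linearity and injected-delta recovery", {
  base <- data.frame(resid_i = c(1, 1, 2), resid_j = c(2, 3, 3),
                     Fx = c(1, 0, -2), Fy = c(0, 2, 1), Fz = c(3, -1, 0))
  t1 <- makeConstTable(base)
  # forced == free -> all-zero table
  z <- netFDA(list(t1, t1), list(t1, t1))
  ze <- forceEntries(z)
  expect_lt(max(abs(as.matrix(ze[c("Fx", "Fy", "Fz")]))), 1e-12)
  # forced = free + delta on one pair -> exactly delta there, zero elsewhere
  shifted <- base
  shifted[1, c("Fx", "Fy", "Fz")] <- shifted[1, c("Fx", "Fy", "Fz")] +
    c(5, -4, 2)
  t2 <- makeConstTable(shifted)
  net <- netFDA(list(t2, t2), list(t1, t1))
  ne <- forceEntries(net)
  hit <- ne$resid_i == 1 & ne$resid_j == 2
  expect_equal(unlist(ne[hit, c("Fx", "Fy", "Fz")]),
               c(Fx = 5, Fy = -4, Fz = 2), tolerance = 1e-12)
  expect_lt(max(abs(as.matrix(ne[!hit, c("Fx", "Fy", "Fz")]))), 1e-12)
  # linearity: common offset X cancels
  off <- base
  off[, c("Fx", "Fy", "Fz")] <- off[, c("Fx", "Fy", "Fz")] + 7
  net2 <- netFDA(list(makeConstTable(off)), list(makeConstTable(off)))
  expect_lt(max(abs(as.matrix(forceEntries(net2)[c("Fx", "Fy", "Fz")]))),
            1e-12)
})

test_that("netFDA recovers a seeded delta within the noise bound", {
  nf <- makeNetForcePair(nFrames = 60, noiseSd = 1.5, seed = 21)
  net <- netFDA(nf$forced, nf$free)
  e <- forceEntries(net)
  d1 <- nf$truth$delta[[1]]
  hit <- e$resid_i == d1$resid_i & e$resid_j == d1$resid_j
  got <- unlist(e[hit, c("Fx", "Fy", "Fz")])
  # se per component of (mean of 2 forced) - (mean of 2 free), n frames each
  se <- nf$truth$noiseSd / sqrt(nf$truth$nFrames)
  expect_lt(max(abs(got - d1$F)), 5 * se)
})

test_that("inconsistent residue universes raise an alignment error", {
  t1 <- makeConstTable(data.frame(resid_i = 1, resid_j = 2,
                                  Fx = 1, Fy = 0, Fz = 0))
  t2 <- makeConstTable(data.frame(resid_i = 1, resid_j = 3,
                                  Fx = 1, Fy = 0, Fz = 0))
  expect_error(netFDA(list(t1), list(t2)), "alignment error")
})

test_that("C4 symmetrisation: fixed point, single-chain average, idempotence", {
  map <- new("SymmetryMap", axis = c(0, 0, 1), center = c(0, 0, 0),
             chains = c("A", "B", "C", "D"))
  v <- c(2, 1, -0.5)
  Rz <- function(k) ChannelMech:::.rotationMatrix(c(0, 0, 1), k * pi / 2)
  # exactly C4-symmetric input is a fixed point
  symRows <- do.call(rbind, lapply(0:3, function(k) {
    vk <- as.numeric(Rz(k) %*% v)
    data.frame(chain_i = LETTERS[k + 1], resid_i = 10, chain_j = LETTERS[k + 1],
               resid_j = 20, class = "coulomb", Fx = vk[1], Fy = vk[2],
               Fz = vk[3], stringsAsFactors = FALSE)
  }))
  net <- new("NetForceTable", entries = symRows, nForced = 1L, nFree = 1L)
  out <- symmetrizeC4(net, map)
  oe <- forceEntries(out)
  refRow <- oe[oe$chain_i == "A", ]
  expect_equal(unlist(refRow[c("Fx", "Fy", "Fz")]),
               c(Fx = v[1], Fy = v[2], Fz = v[3]), tolerance = 1e-12)
  # one chain carries v, others zero -> reference gets v / 4
  oneRow <- symRows[1, ]
  net1 <- new("NetForceTable", entries = oneRow, nForced = 1L, nFree = 1L)
  o1 <- forceEntries(symmetrizeC4(net1, map))
  r1 <- o1[o1$chain_i == "A", ]
  expect_equal(unlist(r1[c("Fx", "Fy", "Fz")]),
               c(Fx = v[1], Fy = v[2], Fz = v[3]) / 4, tolerance = 1e-12)
  # idempotence
  twice <- forceEntries(symmetrizeC4(out, map))
  ord <- function(d) d[order(d$chain_i, d$resid_i, d$chain_j, d$resid_j,
                             d$class), ]
  expect_equal(ord(twice)$Fx, ord(oe)$Fx, tolerance = 1e-12)
  expect_equal(ord(twice)$Fy, ord(oe)$Fy, tolerance = 1e-12)
})

test_that("symmetrisation reduces noise toward the planted symmetric truth", {
  set.seed(31)
  map <- new("SymmetryMap", axis = c(0, 0, 1), center = c(0, 0, 0),
             chains = c("A", "B", "C", "D"))
  v <- c(1.5, -0.8, 0.6)
  Rz <- function(k) ChannelMech:::.rotationMatrix(c(0, 0, 1), k * pi / 2)
  rows <- do.call(rbind, lapply(0:3, function(k) {
    vk <- as.numeric(Rz(k) %*% v) + rnorm(3, sd = 0.3)
    data.frame(chain_i = LETTERS[k + 1], resid_i = 10,
               chain_j = LETTERS[k + 1], resid_j = 20, class = "coulomb",
               Fx = vk[1], Fy = vk[2], Fz = vk[3], stringsAsFactors = FALSE)
  }))
  net <- new("NetForceTable", entries = rows, nForced = 1L, nFree = 1L)
  oe <- forceEntries(symmetrizeC4(net, map))
  symRef <- unlist(oe[oe$chain_i == "A", c("Fx", "Fy", "Fz")])
  errSym <- sqrt(sum((symRef - v)^2))
  errChains <- vapply(0:3, function(k) {
    raw <- unlist(rows[k + 1, c("Fx", "Fy", "Fz")])
    back <- as.numeric(Rz(-k) %*% raw)
    sqrt(sum((back - v)^2))
  }, numeric(1))
  expect_lt(errSym, min(errChains) + 1e-12)
})

test_that("threshold filter removes weak pairs with a strict cut", {
  toPN <- 1.66054
  mk <- function(magPN) magPN / toPN  # x-aligned vector of given pN size
  rows <- data.frame(chain_i = "A", resid_i = c(1, 1), chain_j = "A",
                     resid_j = c(2, 3), class = "coulomb",
                     Fx = c(mk(4.9), mk(5.1)), Fy = 0, Fz = 0,
                     stringsAsFactors = FALSE)
  net <- new("NetForceTable", entries = rows, nForced = 1L, nFree = 1L)
  kept <- forceEntries(thresholdFilter(net, 5))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$resid_j, 3)
  # threshold zero is the identity
  expect_equal(nrow(forceEntries(thresholdFilter(net, 0))), 2L)
  expect_error(thresholdFilter(net, -1), ">= 0")
})

test_that("domain aggregation sums vectors and ranks application points", {
  rows <- data.frame(chain_i = "A", resid_i = c(101, 102, 102),
                     chain_j = "A", resid_j = c(201, 201, 202),
                     class = "coulomb",
                     Fx = c(1, -1, 0), Fy = c(0, 0, 2), Fz = c(0, 0, 0),
                     stringsAsFactors = FALSE)
  # stored force is on resid_i BY resid_j; force on TRP (2xx) is -v
  net <- new("NetForceTable", entries = rows, nForced = 1L, nFree = 1L)
  mapping <- data.frame(label = c("LH", "TRP"), chain = "A",
                        first = c(101, 201), last = c(110, 210))
  agg <- aggregateDomains(net, mapping, source = "LH", target = "TRP")
  r201 <- agg$perResidue[agg$perResidue$resid == 201, ]
  expect_equal(unlist(r201[c("Fx", "Fy", "Fz")]),
               c(Fx = 0, Fy = 0, Fz = 0))  # +v and -v cancel
  r202 <- agg$perResidue[agg$perResidue$resid == 202, ]
  expect_equal(r202$Fy, -2)
  expect_equal(agg$total, c(0, -2, 0))
  # planted concentration: top-2 residues carry the injected vectors
  nf <- makeNetForcePair(nFrames = 40, noiseSd = 0.5, seed = 5)
  net2 <- netFDA(nf$forced, nf$free)
  agg2 <- aggregateDomains(net2, nf$domainMap, source = "LH",
                           target = "TRP")
  top2 <- agg2$perResidue$resid[1:2]
  planted <- vapply(nf$truth$delta, function(d) d$resid_j, numeric(1))
  expect_setequal(top2, planted)
  # overlapping labels are an error
  bad <- rbind(mapping, data.frame(label = "XX", chain = "A", first = 201,
                                   last = 205))
  expect_error(aggregateDomains(net, bad, "LH", "TRP"), "mapping error")
})

test_that("aggregation commutes with thresholding only at threshold zero", {
  nf <- makeNetForcePair(nFrames = 30, noiseSd = 1, seed = 8)
  net <- netFDA(nf$forced, nf$free)
  mapping <- nf$domainMap
  a0 <- aggregateDomains(net, mapping, "LH", "TRP")
  a0f <- aggregateDomains(thresholdFilter(net, 0), mapping, "LH", "TRP")
  expect_equal(a0f$total, a0$total, tolerance = 1e-12)
  a5 <- aggregateDomains(thresholdFilter(net, 5), mapping, "LH", "TRP")
  expect_false(isTRUE(all.equal(a5$total, a0$total)))
})
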