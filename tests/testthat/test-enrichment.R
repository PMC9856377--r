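deTable <- function(gene, log2fc, pvalue, padj = pvalue) {
  data.frame(gene = gene, log2fc = log2fc, pvalue = pvalue, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("DE selection honors thresholds and carries fold-change signs", {
  tab <- deTable(c("SLC12A2", "CLCA1", "SCNN1A", "up1"),
                 c(-1.8, -1.9, 0.3, 2.5),
                 c(0.0005, 0.002, 0.906, 0.001))
  all <- selectDEGenes(tab, lfcThreshold = 0, pThreshold = 1)
  expect_length(all, 4)
  sel <- selectDEGenes(tab, lfcThreshold = 1, pThreshold = 0.05)
  expect_equal(sel[["SLC12A2"]], -1L)
  expect_equal(sel[["up1"]], 1L)
  expect_false("SCNN1A" %in% names(sel))
  none <- selectDEGenes(tab, lfcThreshold = 10, pThreshold = 1e-9)
  expect_length(none, 0)
  expect_error(rankRegulators(tab, list(R = data.frame(
    target = "x", sign = 1L)), lfcThreshold = 10, pThreshold = 1e-9),
    "empty")
  expect_error(selectDEGenes(tab[0, ]), "empty")
  # raw-p selection exposed by flag
  rawSel <- selectDEGenes(deTable("g", 2, 0.01, padj = 0.2),
                          useAdjusted = FALSE)
  expect_equal(names(rawSel), "g")
})

test_that("overlap p-value equals the exact hypergeometric tail", {
  # worked case: universe 20, 5 targets, 4 DE genes, overlap 3 -> 155/4845
  p <- overlapPvalue(paste0("g", 1:4), paste0("g", c(1:3, 10, 11)), 20)
  expect_equal(p, 155 / 4845, tolerance = 1e-12)
  # brute force over all C(20,4) possible DE draws agrees
  draws <- combn(20, 4)
  hits <- sum(apply(draws, 2, function(s) sum(s %in% c(1:3, 10, 11)) >= 3))
  expect_equal(p, hits / ncol(draws), tolerance = 1e-12)
  # degenerate cases
  expect_equal(overlapPvalue("a", c("b", "c"), 10), 1)  # overlap 0
  expect_equal(overlapPvalue(paste0("g", 1:5), paste0("g", 1:5), 5), 1)
  expect_error(overlapPvalue(paste0("g", 1:5), paste0("h", 1:5), 6),
               "smaller than the union")
  expect_error(overlapPvalue(character(), "a", 10), "empty")
})

test_that("activation z-score counts sign concordance with unit weights", {
  tg <- setNames(rep(1L, 4), paste0("t", 1:4))
  expect_equal(activationZscore(tg, tg), 2)
  mix <- setNames(c(rep(1L, 9), -1L), paste0("t", 1:10))
  expect_equal(activationZscore(mix, setNames(rep(1L, 10), paste0("t", 1:10))),
               8 / sqrt(10), tolerance = 1e-12)
  even <- setNames(c(1L, 1L, -1L, -1L), paste0("t", 1:4))
  expect_equal(activationZscore(even, setNames(rep(1L, 4), paste0("t", 1:4))),
               0)
  # undefined (no overlap) is NA, not zero
  expect_true(is.na(activationZscore(c(a = 1L), c(b = 1L))))
})

test_that("z-score bound and antisymmetry hold over random cases", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(1:15, 1)
    de <- setNames(sample(c(-1L, 1L), n, replace = TRUE), paste0("t", 1:n))
    tg <- setNames(sample(c(-1L, 1L), n, replace = TRUE), paste0("t", 1:n))
    z <- activationZscore(de, tg)
    expect_lte(abs(z), sqrt(n) + 1e-12)
    expect_equal(activationZscore(-de, tg), -z, tolerance = 1e-12)
  }
})

test_that("regulator ranking orders by p, then |z|, then name", {
  tab <- deTable(paste0("g", 1:20),
                 c(rep(2, 6), rep(0, 14)), c(rep(1e-4, 6), rep(0.9, 14)))
  net <- list(
    hit = data.frame(target = paste0("g", 1:5), sign = 1L),
    miss = data.frame(target = paste0("g", 10:14), sign = 1L))
  res <- rankRegulators(tab, net)
  expect_equal(res$regulator[1], "hit")
  expect_lt(res$overlap_p[1], res$overlap_p[2])
  expect_equal(res$n_overlap, c(5L, 0L))
  # identical stats tie-break lexicographically
  net2 <- list(
    beta = data.frame(target = paste0("g", 1:5), sign = 1L),
    alpha = data.frame(target = paste0("g", 1:5), sign = 1L))
  expect_equal(rankRegulators(tab, net2)$regulator, c("alpha", "beta"))
  # duplicate targets within one regulator are rejected
  bad <- list(r = data.frame(target = c("g1", "g1"), sign = 1L))
  expect_error(rankRegulators(tab, bad), "duplicate")
})

test_that("an activated regulator is recovered from its simulated table", {
  net <- list(
    ACT = data.frame(target = paste0("a", 1:10),
                     sign = c(rep(1L, 7), rep(-1L, 3))),
    OTHER = data.frame(target = paste0("b", 1:10), sign = 1L))
  tab <- simulateDETable(net, c(ACT = 1L), nGenes = 200, effectLog2fc = 2,
                         noiseSd = 0, seed = 5)
  # targets got exactly sign * effect
  expect_equal(tab$log2fc[match(paste0("a", 1:7), tab$gene)], rep(2, 7))
  expect_equal(tab$log2fc[match(paste0("a", 8:10), tab$gene)], rep(-2, 3))
  expect_true(all(tab$log2fc[match(paste0("b", 1:10), tab$gene)] == 0))
  res <- rankRegulators(tab, net, universeSize = 200)
  expect_equal(res$regulator[1], "ACT")
  expect_equal(res$z_score[1], sqrt(10), tolerance = 1e-12)  # all-agree max
  # no active regulators and no noise: an all-zero fold-change column
  null <- simulateDETable(net, nGenes = 100, noiseSd = 0, seed = 2)
  expect_true(all(null$log2fc == 0))
  expect_error(simulateDETable(net, c(NOPE = 1L), nGenes = 100),
               "unknown regulator")
})

test_that("network TSV round-trips through its reader and writer", {
  net <- list(
    TNF = data.frame(target = c("x1", "x2", "x3"), sign = c(1L, 1L, -1L)),
    IL4 = data.frame(target = c("y1", "y2"), sign = 1L))
  path <- tempfile(fileext = ".tsv")
  writeRegulatorNetwork(net, path)
  back <- readRegulatorNetwork(path)
  expect_setequal(names(back), names(net))
  for (r in names(net)) {
    m <- merge(net[[r]], back[[r]], by = "target")
    expect_equal(m$sign.x, m$sign.y)
  }
  unlink(path)
})
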