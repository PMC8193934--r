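test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(genIngredients(seed = 42L), genIngredients(seed = 42L))
  expect_identical(genDiseaseSources(seed = 42L),
                   genDiseaseSources(seed = 42L))
  expect_identical(genPPI(seed = 42L, nBackground = 30L, moduleSize = 10L),
                   genPPI(seed = 42L, nBackground = 30L, moduleSize = 10L))
  expect_identical(genDETable(nGenes = 500L, nUp = 10L, nDown = 20L,
                              seed = 42L),
                   genDETable(nGenes = 500L, nUp = 10L, nDown = 20L,
                              seed = 42L))
  u <- sprintf("G%02d", 1:50)
  expect_identical(genAnnotations(u, query = u[1:10], seed = 42L),
                   genAnnotations(u, query = u[1:10], seed = 42L))
  # and the RNG state of the session is left untouched
  set.seed(1); before <- .Random.seed
  invisible(genIngredients(seed = 9L))
  expect_identical(.Random.seed, before)
})

test_that("ingredient generator plants the exact pass fraction incl. bounds", {
  sim <- genIngredients(nHerbs = 5L, nPerHerb = 20L, fracPass = 0.4,
                        seed = 13L)
  tab <- sim$table
  pass <- tab$ob >= 20 & tab$dl >= 0.1
  expect_equal(sum(pass), 40L)
  expect_setequal(tab$molecule_id[pass], sim$ledger$passSet)
  expect_true(all(tab$ob >= 0 & tab$ob <= 100))
  expect_true(all(tab$dl >= 0 & tab$dl <= 1))
})

test_that("disease sources cover every union gene at least once", {
  sim <- genDiseaseSources(nSources = 5L, unionSize = 200L,
                           redundancy = 0.25, seed = 3L)
  expect_length(sim$sources, 5L)
  union <- sort(unique(unlist(sim$sources, use.names = FALSE)))
  expect_equal(union, sim$ledger$union)
  expect_equal(length(union), 200L)
  # single-source degenerate case
  solo <- genDiseaseSources(nSources = 1L, unionSize = 50L, seed = 3L)
  expect_equal(solo$sources[[1L]], solo$ledger$union)
})

test_that("PPI generator plants the module at the expected density", {
  m <- 30L
  nPairs <- choose(m, 2)
  p <- 0.8
  counts <- vapply(1:8, function(s)
    genPPI(nBackground = 40L, moduleSize = m, pModule = p,
           seed = s)$ledger$nModuleEdges, numeric(1))
  # each count is Binomial(C(m,2), p); check a 3-sigma band per seed
  sigma <- sqrt(nPairs * p * (1 - p))
  expect_true(all(abs(counts - nPairs * p) <= 3 * sigma))
  # scores survive the 0.7 reader threshold by construction
  sim <- genPPI(nBackground = 40L, moduleSize = m, seed = 1L)
  expect_true(all(sim$edges$score >= 0.7))
})

test_that("zero background probability leaves background nodes isolated", {
  sim <- genPPI(nBackground = 25L, moduleSize = 10L, pBackground = 0,
                pCross = 0, seed = 7L)
  g <- buildPPI(sim$edges)
  expect_setequal(nodeNames(g), sim$ledger$module)
})

test_that("null annotation sets rarely produce a significant term", {
  universe <- sprintf("G%03d", 1:300)
  anySig <- vapply(1:40, function(i) {
    sim <- genAnnotations(universe, nTerms = 40L, planted = FALSE,
                          seed = 500L + i)
    set.seed(i)
    q <- GeneSet(sample(universe, 30))
    res <- enrich(q, sim$annotations, universe = universe,
                  byNamespace = FALSE)
    any(res$padj < 0.05)
  }, logical(1))
  expect_lte(mean(anySig), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})
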