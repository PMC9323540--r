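writeTempSeries <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("readSeries preserves order and validates its input", {
  f <- writeTempSeries(c("id,smiles,logK", "b,CC,1.1", "a,C,0.3",
                         "c,CCC,2.0"))
  s <- readSeries(f, solute = "hexane")
  expect_s4_class(s, "PropertySeries")
  expect_identical(cationIds(s), c("b", "a", "c"))
  expect_equal(unname(logK(s)), c(1.1, 0.3, 2.0))
  expect_identical(solute(s), "hexane")

  expect_error(readSeries(writeTempSeries("id,smiles,logK")),
               "no records")
  expect_error(readSeries(writeTempSeries(c("id,logK", "a,1"))),
               "missing column 'smiles'")
  expect_error(
    readSeries(writeTempSeries(c("id,smiles,logK", "a,C,1", "a,C,2"))),
    "duplicate id 'a' at row 2")
  expect_error(
    readSeries(writeTempSeries(c("id,smiles,logK", "a,C,1", "b,C,oops"))),
    "unparseable logK 'oops' at row 2")
})

test_that("series round-trip through writeSeries is lossless", {
  s <- PropertySeries("benzene", c("x", "y"), c("C", "CC"), c(2.4, 3.0))
  f <- tempfile(fileext = ".csv")
  writeSeries(s, f)
  s2 <- readSeries(f, solute = "benzene")
  expect_identical(cationIds(s2), cationIds(s))
  expect_equal(logK(s2), logK(s))
})

test_that("computeDescriptors fixes the matrix contract around the engine", {
  s <- PropertySeries("hexane", c("a", "b", "c"), c("C", "CC", "CCC"),
                      c(0.3, 1.1, 2.0))
  constEngine <- function(sm)
    matrix(c(rep(1, length(sm)), rep(2, length(sm))), ncol = 2,
           dimnames = list(NULL, c("d1", "d2")))
  m <- computeDescriptors(s, constEngine)
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(rowIds(m), c("a", "b", "c"))
  expect_false(isStandardized(m))

  # determinism: same series, same engine, identical matrices
  expect_identical(as.matrix(computeDescriptors(s, constEngine)),
                   as.matrix(m))

  # non-finite engine output becomes NA
  nanEngine <- function(sm)
    matrix(c(1, Inf, 3, 4, NaN, 6), ncol = 2,
           dimnames = list(NULL, c("d1", "d2")))
  m2 <- computeDescriptors(s, nanEngine)
  expect_true(is.na(as.matrix(m2)["b", "d1"]))
  expect_true(is.na(as.matrix(m2)["b", "d2"]))

  # engine failure is attributed to the offending cation
  fussy <- function(sm) {
    if (any(sm == "CC")) stop("cannot parse")
    matrix(1, length(sm), 2, dimnames = list(NULL, c("d1", "d2")))
  }
  expect_error(computeDescriptors(s, fussy), "cation 'b'")
})

test_that("pruning removes missing, constant and collinear descriptors in order", {
  set.seed(42)
  base <- matrix(rnorm(40), 10, 4,
                 dimnames = list(NULL, c("v1", "v2", "v3", "v4")))
  m <- DescriptorMatrix(cbind(base,
                              const = rep(7, 10),
                              nacol = c(NA, rnorm(9)),
                              v1dup = base[, "v1"]))
  pr <- pruneDescriptors(m, collinearityThreshold = 0.95)
  expect_setequal(descriptorNames(pr), c("v1", "v2", "v3", "v4"))
  log <- removalLog(pr)
  expect_identical(log$reason[log$descriptor == "const"], "constant")
  expect_identical(log$reason[log$descriptor == "nacol"], "missing")
  # identical columns: the later one is dropped, the earlier kept
  expect_identical(log$reason[log$descriptor == "v1dup"],
                   "collinear with v1")
  expect_error(pruneDescriptors(DescriptorMatrix(
    cbind(a = rnorm(10), b = rep(1, 10)))), "fewer than 2")
})

test_that("standardization centers and scales with stored statistics", {
  m <- DescriptorMatrix(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  z <- standardizeDescriptors(m)
  expect_equal(as.matrix(z)[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(isStandardized(z))

  # idempotence: standardizing an already-standard column changes nothing
  z2 <- standardizeDescriptors(DescriptorMatrix(as.matrix(z)))
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-9)

  # direct recomputation oracle on a random 10x4 matrix
  set.seed(7)
  r <- DescriptorMatrix(matrix(rnorm(40, 5, 3), 10, 4,
                               dimnames = list(NULL, letters[1:4])))
  zr <- as.matrix(standardizeDescriptors(r))
  expect_true(all(abs(colMeans(zr)) < 1e-12))
  expect_true(all(abs(apply(zr, 2, sd) - 1) < 1e-12))

  # new-cation application uses the stored full-series statistics
  znew <- applyStandardization(z, cbind(a = 2, b = 20))
  expect_equal(drop(znew), c(a = 0, b = -0.3779645), tolerance = 1e-6)

  expect_error(standardizeDescriptors(DescriptorMatrix(
    cbind(a = rep(1, 5), b = rnorm(5)))), "zero standard deviation")
})

test_that("fold assignment deals sorted observations round-robin", {
  # n = 10, 10 folds: singleton folds, smallest response in fold 1
  y <- c(5, 1, 3, 2, 4, 9, 7, 6, 8, 10)
  fa <- assignFolds(y, 10)
  expect_equal(sort(tabulate(foldOf(fa), 10)), rep(1L, 10))
  expect_equal(foldOf(fa)[which.min(y)], 1L)

  # n = 57, 10 folds: sizes forced to 6x7 then 5x3
  set.seed(1)
  fa57 <- assignFolds(rnorm(57), 10)
  expect_equal(tabulate(foldOf(fa57), 10), c(rep(6L, 7), rep(5L, 3)))

  # ties: earlier input row gets the lower rank
  faTie <- assignFolds(c(2, 1, 1), 3)
  expect_equal(foldOf(faTie), c(3L, 1L, 2L))

  expect_error(assignFolds(y, 1), "at least 2 folds")
  expect_error(assignFolds(c(1, 2), 5), "more folds")
})

test_that("folds partition the data and interleave response ranges", {
  set.seed(11)
  for (n in c(23, 57, 60)) {
    y <- rnorm(n)
    fa <- assignFolds(y, 10)
    f <- foldOf(fa)
    expect_equal(sort(unname(unlist(split(seq_len(n), f)))), seq_len(n))
    # stratification: each fold's j-th smallest member sits within one
    # round-robin step of every other fold's j-th smallest
    ranks <- rank(y, ties.method = "first")
    byFold <- split(ranks, f)
    depth <- min(lengths(byFold))
    for (j in seq_len(depth)) {
      jth <- vapply(byFold, function(r) sort(r)[j], numeric(1))
      expect_lte(diff(range(jth)), 9)
    }
  }
})

test_that("pruning is a fixed point after standardization", {
  d <- makePlantedLinear(syntheticSpec(n = 40, p = 30, seed = 3))
  z <- as.matrix(standardizeDescriptors(pruneDescriptors(d$X, 0.95)))
  # nothing left for a second prune: no constants, no collinear pair
  expect_true(all(apply(z, 2, sd) > 0))
  cz <- abs(cor(z))
  diag(cz) <- 0
  expect_lt(max(cz), 0.95)
})

test_that("descriptor matrices round-trip as delimited text", {
  d <- makePlantedLinear(syntheticSpec(n = 15, p = 10, seed = 9))
  f <- tempfile(fileext = ".csv")
  writeDescriptorMatrix(d$X, f)
  m2 <- readDescriptorMatrix(f)
  expect_identical(rowIds(m2), rowIds(d$X))
  expect_identical(descriptorNames(m2), descriptorNames(d$X))
  expect_equal(as.matrix(m2), as.matrix(d$X), tolerance = 1e-12)
})

test_that("a QsarDB-style text archive maps onto series plus descriptors", {
  dir <- tempfile("qdbtoy_")
  dir.create(dir)
  write.csv(data.frame(id = c("a", "b", "c"), smiles = c("C", "CC", "CCC")),
            file.path(dir, "compounds.csv"), row.names = FALSE)
  write.csv(data.frame(id = c("a", "b", "c"), value = c(0.2, 1.0, 2.2)),
            file.path(dir, "properties.csv"), row.names = FALSE)
  write.csv(data.frame(id = c("a", "b", "c"), d1 = 1:3, d2 = c(4, 4, 5)),
            file.path(dir, "descriptors.csv"), row.names = FALSE)
  arc <- readQsardbArchive(dir, solute = "hexane")
  expect_equal(unname(logK(arc$series)), c(0.2, 1.0, 2.2))
  expect_identical(descriptorNames(arc$descriptors), c("d1", "d2"))
  expect_error(readQsardbArchive(tempfile()), "not found")
})
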